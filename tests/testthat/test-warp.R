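test_that("Delaunay triangulation tiles the convex hull and keeps circumcircles empty", {
  set.seed(8)
  pts <- cbind(stats::runif(20, 0, 100), stats::runif(20, 0, 100))
  tris <- delaunay_triangulation(pts)
  expect_true(is.matrix(tris) && ncol(tris) == 3)

  tri_area <- function(t) {
    a <- pts[t[1], ]; b <- pts[t[2], ]; c <- pts[t[3], ]
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  }
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  nh <- length(hull)
  hull_area <- abs(sum(hx * hy[c(2:nh, 1)] - hx[c(2:nh, 1)] * hy)) / 2
  expect_equal(sum(apply(tris, 1, tri_area)), hull_area, tolerance = 1e-9)

  # the empty-circumcircle property, checked directly
  for (r in seq_len(nrow(tris))) {
    t <- tris[r, ]
    a <- pts[t[1], ]; b <- pts[t[2], ]; c <- pts[t[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
             (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
             (sum(c^2)) * (b[1] - a[1])) / d
    r2 <- sum((a - c(ux, uy))^2)
    inside <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2 < r2 - 1e-7
    inside[t] <- FALSE
    expect_false(any(inside))
  }
})

test_that("the identity warp reproduces the image", {
  img <- matrix(stats::runif(96 * 96, min = 0.1, max = 0.9), 96)
  pts <- cbind(c(20, 70, 45, 30, 60), c(25, 20, 50, 75, 70))
  out <- warp_image(img, pts, pts)
  expect_lt(max(abs(out - img)), 1e-10)
})

test_that("a pure translation warp shifts a linear ramp exactly", {
  size <- 96
  ramp <- matrix(rep(0:(size - 1), each = size), size) / size  # value = x/size
  src <- cbind(c(20, 70, 45, 25, 65), c(25, 20, 48, 70, 72))
  dst <- src
  dst[, 1] <- dst[, 1] + 6.5
  # restrict the warp to landmark-only triangles so every triangle's affine
  # map is the pure translation (the automatic canvas anchors stay fixed and
  # would blend translated and unmoved vertices near the hull)
  tri <- fpbench:::delaunay_triangulation(dst)
  out <- warp_image(ramp, src, dst, triangles = tri)
  # interior pixels (inside the translated hull) read the source 6.5 px to
  # the left; bilinear sampling is exact on a linear ramp
  interior <- out[40:60, 40:60]
  expected <- ramp[40:60, 40:60 - 7] + 0.5 / size
  expect_lt(max(abs(interior - expected)), 1e-9)
})

test_that("degenerate destination triangles are rejected", {
  img <- matrix(0, 32, 32)
  src <- cbind(c(5, 16, 27), c(5, 16, 27))
  tri <- matrix(c(1L, 2L, 3L), 1)
  expect_error(warp_image(img, src, src, triangles = tri),
               "degenerate")
})

test_that("warping to the mean landmarks relocates a marked landmark", {
  ds <- annotated_frontal_200()[1:30]
  fs_small <- fit_face_space(ds, n_shape = 10, n_appearance = 10)
  im <- ds[[1]]
  # stamp a bright dot at one landmark, warp to the mean configuration, and
  # find the dot near the mean landmark position
  k <- 13  # an outline point
  marked <- im$pixels
  marked <- fpbench:::fill_ellipse(marked, im$landmarks[k, 1],
                                   im$landmarks[k, 2], 2, 2, 1)
  warped <- warp_to_mean(annotated_image(marked, im$landmarks), fs_small)
  base <- warp_to_mean(im, fs_small)
  diff <- abs(warped - base)
  hot <- which(diff > 0.5 * max(diff), arr.ind = TRUE)
  cx <- mean(hot[, 2] - 1); cy <- mean(hot[, 1] - 1)
  target <- fs_small$mean_landmarks[k, ]
  expect_lt(sqrt((cx - target[1])^2 + (cy - target[2])^2), 2)
})
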