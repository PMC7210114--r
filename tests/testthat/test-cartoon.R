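test_that("cartoon parameter vectors are validated against the 11-value grid", {
  expect_identical(cartoon_grid(), -5:5)
  expect_length(cartoon_param_names(), 19)
  p <- cartoon_params(rep(0, 19))
  expect_s3_class(p, "cartoon_params")
  expect_identical(names(p), cartoon_param_names())
  expect_error(cartoon_params(rep(0, 18)), "length 19")
  expect_error(cartoon_params(c(rep(0, 18), 6)), "within")
  expect_error(cartoon_params(c(rep(0, 18), 0.5)), "grid")
})

test_that("the zero vector renders the mean face deterministically", {
  a <- render_cartoon(rep(0, 19))
  b <- render_cartoon(rep(0, 19))
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(dim(a), c(224L, 224L))
})

test_that("inter-eye distance increases the rendered pupil separation monotonically", {
  sep_at <- function(v) {
    p <- rep(0, 19)
    p[9] <- v  # inter_eye_distance
    lm <- fpbench:::face_geometry(p)$landmarks
    # iris landmarks follow the 8-point eye contours in the schema
    abs(lm[53, "x"] - lm[52, "x"])
  }
  seps <- vapply(c(-5, -2, 0, 2, 5), sep_at, numeric(1))
  expect_true(all(diff(seps) > 0))
})

test_that("gaze direction changes pixels only inside the eye regions", {
  p0 <- rep(0, 19)
  p1 <- p0
  p1[13] <- 4  # gaze_direction
  d <- abs(render_cartoon(p1) - render_cartoon(p0))
  changed <- which(d > 1e-9, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  g <- fpbench:::face_geometry(p0)
  pad <- g$iris$r_px + 3
  in_eye <- function(rowcol, eye) {
    x <- rowcol[, 2] - 1; y <- rowcol[, 1] - 1
    abs(x - eye[1]) <= g$eye$rx + pad & abs(y - eye[2]) <= g$eye$ry + pad
  }
  expect_true(all(in_eye(changed, g$eye$l) | in_eye(changed, g$eye$r)))
})

test_that("sampled cartoon sets store grid-valued parameters with uniform margins", {
  set <- sample_cartoon_set(5000, seed = 13, render = FALSE)
  expect_length(set, 5000)
  cols <- fpbench:::cartoon_param_columns(set$meta)
  expect_length(cols, 19)
  pm <- as.matrix(set$meta[, cols])
  expect_true(all(pm %in% cartoon_grid()))
  # marginal frequency of each grid value within 3 SE of 1/11
  se <- sqrt((1 / 11) * (10 / 11) / 5000)
  for (j in c(1, 7, 19)) {
    freq <- tabulate(pm[, j] + 6, nbins = 11) / 5000
    expect_true(all(abs(freq - 1 / 11) < 3.5 * se))
  }
  # determinism and single-image call
  set2 <- sample_cartoon_set(5000, seed = 13, render = FALSE)
  expect_identical(set$meta, set2$meta)
  one <- sample_cartoon_set(1, seed = 2)
  expect_length(one, 1)
  expect_identical(dim(one$images[[1]]), c(224L, 224L))
})
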