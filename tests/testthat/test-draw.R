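test_that("polygon fill deposits the exact analytic area", {
  img <- fpbench:::blank_canvas(64)
  # pixel-aligned 10x10 square
  out <- fpbench:::fill_polygon(img, c(9.5, 19.5, 19.5, 9.5),
                                c(9.5, 9.5, 19.5, 19.5), 1)
  expect_equal(sum(out), 100, tolerance = 1e-9)
  # half-pixel offset: boundary pixels get half coverage
  out2 <- fpbench:::fill_polygon(img, c(10, 20, 20, 10), c(10, 10, 20, 20), 1)
  expect_equal(sum(out2), 100, tolerance = 1e-9)
  expect_equal(out2[12, 11], 0.5)   # left edge pixel (row y=11, col x=10)
  expect_equal(out2[11, 12], 0.5)   # top edge pixel
})

test_that("polygon fill mass matches the shoelace area of random convex polygons", {
  set.seed(21)
  for (rep in 1:5) {
    nv <- sample(3:8, 1)
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    rad <- stats::runif(nv, 5, 22)
    xs <- 32 + rad * cos(ang)
    ys <- 32 + rad * sin(ang)
    area <- abs(sum(xs * ys[c(2:nv, 1)] - xs[c(2:nv, 1)] * ys)) / 2
    out <- fpbench:::fill_polygon(fpbench:::blank_canvas(64), xs, ys, 1)
    # sub-row sampling makes the coverage approximate near sloped edges
    expect_equal(sum(out), area, tolerance = 0.02)
  }
})

test_that("ellipse and capsule fills are anti-aliased and area-consistent", {
  out <- fpbench:::fill_ellipse(fpbench:::blank_canvas(64), 31.5, 31.5, 10, 6, 1)
  expect_equal(sum(out), pi * 10 * 6, tolerance = 0.03)
  expect_true(all(out >= 0 & out <= 1))
  cap <- fpbench:::fill_capsule(fpbench:::blank_canvas(64), 10, 30, 50, 30, 3, 1)
  expect_equal(sum(cap), 40 * 6 + pi * 9, tolerance = 0.03)
})

test_that("horizontal flips are exact involutions", {
  img <- matrix(stats::runif(64 * 64), 64)
  expect_identical(fpbench:::flip_horizontal(fpbench:::flip_horizontal(img)), img)
  expect_identical(fpbench:::flip_x(c(0, 63), 64), c(63, 0))
})
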