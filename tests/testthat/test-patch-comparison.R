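test_that("cosine similarity matches hand-computed values and rejects bad input", {
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(3, 4), c(3, 4)), 1)
  expect_error(cosine_similarity(c(1, 0), c(0, 0)), "zero histogram")
  expect_error(cosine_similarity(c(-1, 2), c(1, 2)), "nonnegative")
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

test_that("null bands are center +/- 2 SD and reproducible", {
  nb <- null_band(0.5, 0.1, n_samples = 100, seed = 3)
  expect_equal(unname(nb$band), c(0.3, 0.7))

  # reference RSM with non-degenerate off-diagonal spread
  ref <- stats::cor(fpbench:::with_seed(9, matrix(stats::rnorm(80), 10, 8)))
  a <- random_rsm_null(ref, n = 200, seed = 9)
  b <- random_rsm_null(ref, n = 200, seed = 9)
  expect_identical(attr(a, "samples"), attr(b, "samples"))
  expect_true(is.finite(a$sd) && a$sd > 0)

  expect_error(random_histogram_null("spectrum", rep(1, 20)), "unknown histogram kind")
  nh <- random_histogram_null("fpu", c(rep(4, 10), rep(0, 10)), n = 50, seed = 2)
  expect_s3_class(nh, "null_band")
  ns <- random_sta_null(10, n = 50, seed = 4)
  expect_true(abs(ns$center) < 0.2)
})

test_that("the bootstrap CI degenerates on constant samples and validates input", {
  ci <- bootstrap_mean_ci(rep(0.7, 20), n_boot = 100, seed = 1)
  expect_equal(as.numeric(ci[c("lower", "upper")]), c(0.7, 0.7))
  expect_error(bootstrap_mean_ci(1), "at least 2 samples")
  ci2 <- bootstrap_mean_ci(stats::rnorm(50), n_boot = 200, seed = 2)
  expect_lt(ci2[["lower"]], ci2[["upper"]])
})

test_that("RSM correlations intersect on stimulus names", {
  set.seed(11)
  m <- matrix(stats::rnorm(64), 8)
  rsm <- stats::cor(m)
  nm <- paste0("frontal:", 1:8)
  dimnames(rsm) <- list(nm, nm)
  expect_equal(rsm_correlation(rsm, rsm), 1)

  # a reference with a subset of stimuli, in scrambled order
  sub <- sample(nm, 5)
  ref <- rsm[sub, sub]
  expect_equal(rsm_correlation(rsm, ref), 1)
  expect_error(rsm_correlation(rsm, rsm[1:2, 1:2]), "fewer than 3 common")
})

test_that("comparison reports assemble references and survive a JSON round trip", {
  metrics <- list(
    layer1 = list(sii = 0.25,
                  spi_mean = list(value = 0.4,
                                  band = c(lower = -0.1, upper = 0.1))),
    layer2 = list(sii = 1)
  )
  refs <- list(sii = list(value = 1 / 8, patch = "ML",
                          provenance = "packaged_constant"))
  rep <- build_report(metrics, refs)
  expect_s3_class(rep, "layer_patch_report")
  expect_identical(nrow(rep), 3L)
  r1 <- rep[rep$layer == "layer1" & rep$metric == "sii", ]
  expect_equal(r1$reference, 1 / 8)
  expect_identical(r1$provenance, "packaged_constant")
  r2 <- rep[rep$metric == "spi_mean", ]
  expect_identical(r2$provenance, "no reference")
  expect_true(r2$outside_band)  # 0.4 lies outside [-0.1, 0.1]

  path <- tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- report_from_json(path)
  expect_equal(back$value, rep$value)
  expect_equal(back$band_upper, rep$band_upper)
  expect_identical(back$patch, rep$patch)
  expect_identical(back$outside_band, rep$outside_band)
})

test_that("packaged reference constants are tagged with their provenance", {
  rc <- reference_constants()
  expect_identical(rc$provenance, "packaged_constant")
  expect_equal(unname(rc$sii), rep(1 / 8, 3))
  expect_true(rc$spi_mean[["ML"]] > 0 && rc$spi_mean[["AM"]] < 0)
})
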