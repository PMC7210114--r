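test_that("a fitted face space has the requested structure and unit training scales", {
  ds <- annotated_frontal_200()[1:60]
  fs <- fit_face_space(ds, n_shape = 12, n_appearance = 12)
  expect_s3_class(fs, "face_space_model")
  expect_identical(dim(fs$shape_basis), c(190L, 12L))
  expect_identical(ncol(fs$appearance_basis), 12L)
  expect_length(fs$shape_scale, 12)
  expect_identical(fs$n_train, 60L)

  # training projections have unit variance per dimension (SD-scaled space)
  proj <- t(vapply(ds, function(im) project_image(fs, im), numeric(24)))
  expect_equal(unname(apply(proj, 2, stats::sd)), rep(1, 24), tolerance = 1e-6)
  # and zero mean
  expect_lt(max(abs(colMeans(proj))), 1e-8)
})

test_that("rank-deficient training data is rejected with the achievable rank", {
  two <- annotated_frontal_200()[1:2]
  ds <- rep(two, 15)  # rank-1 landmark variation
  expect_error(fit_face_space(ds, n_shape = 5, n_appearance = 5),
               "rank deficiency in the shape data: only 1 components")
  expect_error(fit_face_space(annotated_frontal_200()[1:10]),
               "length")  # fewer images than n_shape + 1
})

test_that("feature sampling is seeded and reconstruction validates its input", {
  f1 <- sample_feature_vectors(5, seed = 3)
  f2 <- sample_feature_vectors(5, seed = 3)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(5L, 50L))

  fs <- face_space_200()
  expect_error(reconstruct_image(fs, rep(0, 10)), "length")
  expect_error(reconstruct_image(fs, rep(50, 50)),
               "landmarks leave the canvas")
})

test_that("projection inverts reconstruction for a moderate feature vector", {
  fs <- face_space_200()
  f <- fpbench:::with_seed(31, stats::rnorm(50, 0, 1))
  g <- project_image(fs, reconstruct_image(fs, f))
  expect_gt(stats::cor(f, g), 0.99)
})

test_that("cross-view fits validate their inputs and report residuals", {
  src <- sample_feature_vectors(30, seed = 1, dim = 8)
  tgt <- src * 2
  map <- fit_cross_view_map(src, tgt, source_view = "right_profile")
  expect_s3_class(map, "cross_view_map")
  expect_lt(map$residual_rmse, 1e-10)
  out <- apply_cross_view_map(map, src[1, ])
  expect_equal(as.numeric(out), as.numeric(tgt[1, ]), tolerance = 1e-8)

  expect_error(fit_cross_view_map(src[1:5, ], tgt[1:5, ]),
               "underdetermined.*need at least 9")
})
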