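test_that("the face-selectivity index follows its definition and clamps", {
  # baseline subtraction and the plain formula
  tab <- compute_fsi(face_responses = c(4, 3), object_responses = c(2, 1),
                     baseline_response = c(1, 1))
  expect_equal(tab$fsi, c((3 - 1) / (3 + 1), (2 - 0) / (2 + 0)))
  expect_identical(tab$selected, c(TRUE, TRUE))

  # clamps: face above baseline with object below -> +1; the reverse -> -1
  tab <- compute_fsi(c(2, 0.5), c(0.5, 2), baseline_response = 1)
  expect_equal(tab$fsi, c(1, -1))

  # both at or below baseline -> unresponsive, NA, never selected
  tab <- compute_fsi(c(1, 0.2), c(0.7, 1), baseline_response = 1)
  expect_true(all(is.na(tab$fsi)))
  expect_false(any(tab$selected))

  # threshold is strict: FSI exactly 1/3 is not selected
  tab <- compute_fsi(2, 1.5, baseline_response = 1)
  expect_equal(tab$fsi, 1 / 3)
  expect_false(tab$selected)

  # matrix and vector inputs agree
  fm <- matrix(c(2, 4, 6, 1, 2, 3), nrow = 2, byrow = TRUE)
  om <- matrix(c(1, 2, 3, 0.5, 1, 1.5), nrow = 2, byrow = TRUE)
  expect_equal(compute_fsi(fm, om, 0)$fsi,
               compute_fsi(rowMeans(fm), rowMeans(om), 0)$fsi)

  expect_error(compute_fsi(numeric(0), 1, 0), "empty face")
  expect_error(compute_fsi(c(1, 2), 1, 0), "unit counts differ")
})

test_that("the untrained CNN fixture satisfies the activation contract", {
  cnn <- cnn_small()
  expect_s3_class(cnn, "layered_model")
  expect_identical(cnn$layer_names, c("layer1", "layer2"))
  # geometry: 224 -> conv k11 s4 (54) -> pool 2 (27); conv k5 (23) -> pool 2 (11)
  expect_equal(cnn$n_units, c(6 * 27 * 27, 8 * 11 * 11))

  probes <- make_selectivity_probes(2, 2, seed = 8)
  r1 <- probe(cnn, probes)
  expect_named(r1, c("layer1", "layer2"))
  expect_identical(dim(r1$layer1), c(4374L, 5L))
  expect_true(all(r1$layer2 >= 0))

  # weights are a pure function of the seed
  r2 <- probe(untrained_cnn_fixture(depth = 2, widths = c(6, 8), seed = 3),
              probes)
  expect_identical(unclass(r1$layer2), unclass(r2$layer2))

  # a unit filter returns exactly the corresponding rows
  pick <- list(layer1 = c(5L, 100L, 2000L), layer2 = c(1L, 900L))
  rf <- probe(cnn, probes, units = pick)
  expect_equal(as.numeric(rf$layer1), as.numeric(unclass(r1$layer1)[pick$layer1, ]))
  expect_equal(as.numeric(rf$layer2), as.numeric(unclass(r1$layer2)[pick$layer2, ]))

  # canvas mismatch is rejected
  bad <- stimulus_set(list(matrix(0, 32, 32)), data.frame(image_id = 1))
  expect_error(probe(cnn, bad), "does not match the model input size")
})

test_that("face-selective unit extraction needs one blank and honors the cap", {
  fv_units <- lapply(face_views()[1:2], function(v) {
    designed_unit("view_template", preferred = v)
  })
  pop <- make_designed_population(c(fv_units, list(designed_unit("null_random"))),
                                  seed = 2)
  probes <- make_selectivity_probes(4, 4, seed = 8)
  sel <- select_face_units(pop, probes)
  expect_named(sel, "designed")
  # the frontal template responds to faces only -> strongly selected
  expect_true(1 %in% sel$designed$selected)

  capped <- select_face_units(pop, probes, cap = 1)
  expect_lte(length(capped$designed$selected), 1)

  noblank <- stimulus_set(probes$images[1:8], probes$meta[1:8, ])
  expect_error(select_face_units(pop, noblank), "exactly one blank")
})

test_that("occlusion footprints grow with depth", {
  cnn <- cnn_small()
  f1 <- occlusion_footprint(cnn, "layer1", patch = 56, step = 56)
  f2 <- occlusion_footprint(cnn, "layer2", patch = 56, step = 56)
  expect_true(f1 > 0 && f1 <= 1)
  expect_gte(f2, f1)
})
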