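test_that("annotated faces carry the fixed landmark schema and are deterministic", {
  ds <- make_annotated_face_dataset(3, "frontal", seed = 4)
  expect_length(ds, 3)
  for (im in ds) {
    expect_s3_class(im, "annotated_image")
    expect_identical(nrow(im$landmarks), 95L)
    expect_true(all(im$landmarks >= 0 & im$landmarks <= 223))
    expect_true(all(im$pixels >= 0 & im$pixels <= 1))
  }
  expect_identical(sum(landmark_schema()), 95L)

  ds2 <- make_annotated_face_dataset(3, "frontal", seed = 4)
  expect_identical(ds[[1]]$pixels, ds2[[1]]$pixels)
  expect_identical(ds[[3]]$landmarks, ds2[[3]]$landmarks)
  # distinct identities differ in their landmarks
  expect_gt(max(abs(ds[[1]]$landmarks - ds[[2]]$landmarks)), 1)
})

test_that("unknown view labels are rejected with the supported list", {
  expect_error(make_annotated_face_dataset(2, "three_quarter"),
               "unknown view.*frontal.*left_profile")
  expect_error(render_identity(synthetic_face_identity(1), "sideways"),
               "supported views")
})

test_that("face-view sets have one image per (identity, view) pair", {
  fv <- make_face_view_set(3, c("frontal", "up"), seed = 9)
  expect_s3_class(fv, "stimulus_set")
  expect_length(fv, 6)
  expect_false(anyDuplicated(fv$meta[, c("identity", "view")]) > 0)
  expect_error(make_face_view_set(2, c("frontal", "frontal")), "duplicate")

  single <- make_face_view_set(1, "frontal", seed = 9)
  expect_length(single, 1)
})

test_that("left views are exact horizontal mirrors of right views", {
  id <- synthetic_face_identity(5, seed = 12)
  for (pair in list(c("left_profile", "right_profile"),
                    c("left_half_profile", "right_half_profile"))) {
    left <- render_identity(id, pair[1])
    right <- render_identity(id, pair[2])
    expect_identical(left$pixels, right$pixels[, rev(seq_len(224))])
    expect_equal(left$landmarks[, "x"], 223 - right$landmarks[, "x"])
    expect_equal(left$landmarks[, "y"], right$landmarks[, "y"])
  }
})

test_that("selectivity probes contain faces, objects, and one zero blank", {
  probes <- make_selectivity_probes(6, 5, seed = 5)
  expect_length(probes, 12)
  expect_identical(as.integer(table(probes$meta$category)[c("face", "object", "blank")]),
                   c(6L, 5L, 1L))
  blank <- probes$images[[which(probes$meta$category == "blank")]]
  expect_true(all(blank == 0))
  # the two categories are separable under a simple pixel-energy statistic
  energy <- vapply(probes$images, function(im) mean(im^2), numeric(1))
  expect_true(mean(energy[probes$meta$category == "object"]) !=
                mean(energy[probes$meta$category == "face"]))
  expect_error(make_selectivity_probes(0, 5), "n_faces")
})

test_that("designed template units prefer their preferred condition", {
  fv <- make_face_view_set(4, c("frontal", "right_profile"), seed = 2)
  pop <- make_designed_population(list(
    designed_unit("view_template", preferred = "frontal"),
    designed_unit("identity_template", preferred = 2),
    designed_unit("null_random")
  ), seed = 6)
  resp <- probe(pop, fv)$designed
  is_frontal <- fv$meta$view == "frontal"
  expect_gt(mean(resp[1, is_frontal]), mean(resp[1, !is_frontal]))
  is_id2 <- fv$meta$identity == 2
  expect_gt(mean(resp[2, is_id2]), mean(resp[2, !is_id2]))

  # null units are reproducible noise
  resp2 <- probe(make_designed_population(list(
    designed_unit("view_template", preferred = "frontal"),
    designed_unit("identity_template", preferred = 2),
    designed_unit("null_random")
  ), seed = 6), fv)$designed
  expect_identical(resp[3, ], resp2[3, ])
  expect_gt(stats::sd(resp[3, ]), 0)
})

test_that("linear designed units require ground-truth feature vectors", {
  fv <- make_face_view_set(2, "frontal", seed = 2)
  pop <- make_designed_population(list(designed_unit("shape_linear")), seed = 1)
  expect_error(probe(pop, fv), "feature vectors")

  feats <- sample_feature_vectors(40, seed = 3)
  set <- feature_stimulus_set(feats)
  r <- probe(pop, set)$designed
  k <- pop$meta$units[[1]]$kernel
  expect_equal(as.numeric(r), pmax(feats %*% k, 0)[, 1])
  # drawn shape kernels concentrate their mass in the shape half
  expect_gt(sum(k[1:25]^2), sum(k[26:50]^2))
})

test_that("polarity-contrast units follow the signed part-pair difference", {
  mos <- build_covering_set(seed = 3, render = FALSE)
  pop <- make_designed_population(list(
    designed_unit("polarity_contrast", part_a = "forehead",
                  part_b = "left_eye", polarity = 1)
  ), seed = 1)
  r <- probe(pop, mos)$designed[1, ]
  ia <- mos$meta$i01
  ib <- mos$meta$i02
  expect_gt(mean(r[ia > ib]), mean(r[ia < ib]))
  expect_equal(as.numeric(r), pmax(ia - ib, 0))
})

test_that("unknown designed-unit kinds are rejected", {
  expect_error(designed_unit("gabor"), "unknown designed-unit kind")
})
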