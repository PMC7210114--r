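test_that("response similarity matrices are ordered, labeled, and flag degenerate stimuli", {
  meta <- data.frame(identity = c(2, 1, 2, 1),
                     view = c("up", "frontal", "frontal", "up"))
  vals <- matrix(c(1, 0, 2,
                   0, 1, 2,
                   3, 3, 3,
                   1, 2, 2), nrow = 3)  # stimulus 3 is constant across units
  r <- response_matrix(vals, layer = "L")
  rsm <- compute_rsm(r, meta, view_order = c("frontal", "up"))
  expect_identical(dim(unclass(rsm)), c(4L, 4L))
  expect_identical(rownames(rsm), c("frontal:1", "frontal:2", "up:1", "up:2"))
  expect_equal(diag(unclass(rsm)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(rsm), t(unclass(rsm)), ignore_attr = TRUE)
  # the constant stimulus (original index 3 -> ordered position 2) is flagged
  flagged_pos <- which(attr(rsm, "ordering") == 3)
  expect_identical(attr(rsm, "flagged"), flagged_pos)
  expect_true(all(unclass(rsm)[flagged_pos, -flagged_pos] == 0))
})

test_that("the size ladder centers rescaled stimuli on a mid-gray canvas", {
  base <- stimulus_set(list(matrix(1, 224, 224)),
                       data.frame(image_id = 1, category = "face"))
  ladder <- make_size_ladder(base, sizes = c(224, 112))
  expect_length(ladder, 2)
  expect_identical(ladder$meta$size_px, c(224, 112))
  small <- ladder$images[[2]]
  expect_identical(dim(small), c(224L, 224L))
  expect_true(all(small[57:168, 57:168] == 1))
  expect_true(all(small[1:56, ] == 0.5))
})

test_that("the size-invariance index takes its closed-form values", {
  sizes <- c(224, 196, 168, 140, 112, 84, 56)
  prof <- function(face) data.frame(size_px = sizes, r_face = face,
                                    r_object = rep(1, 7))
  # preferred at every size -> smallest size over the canvas
  expect_equal(compute_sii(prof(rep(2, 7))), 0.25)
  # preference holds down to 112 px and breaks at 84
  expect_equal(compute_sii(prof(c(2, 2, 2, 2, 2, 1, 2))), 0.5)
  # no preference at the full size -> 1
  expect_equal(compute_sii(prof(c(1, 2, 2, 2, 2, 2, 2))), 1)
  expect_error(compute_sii(prof(rep(2, 7))[0, ]), "empty")
})

test_that("the spike-triggered average recovers linear kernels and flags silent units", {
  feats <- sample_feature_vectors(4000, seed = 5)
  k <- fpbench:::with_seed(6, {
    v <- stats::rnorm(50)
    v / sqrt(sum(v^2))
  })
  resp <- rbind(pmax(feats %*% k, 0)[, 1],  # linear-rectified unit
                rep(2, 4000))               # constant unit
  sta <- compute_sta(resp, feats)
  expect_gt(cosine_of(sta$sta[1, ], k), 0.9)
  expect_identical(sta$flagged, 2L)
  expect_true(is.na(sta$spi[2]))
})

test_that("tuning-curve estimation detects designed tuning and nothing else", {
  set <- sample_cartoon_set(900, seed = 10, render = FALSE)
  meta <- set$meta
  resp <- response_matrix(rbind(
    meta$p05^2,                                      # tuned to feature 5
    fpbench:::with_seed(3, stats::rnorm(900)),       # pure noise
    rep(1, 900)                                      # constant
  ), layer = "L")
  tc <- estimate_tuning_curves(resp, meta, n_perm = 400, alpha = 0.01, seed = 2)
  expect_true(tc$significant[1, 5])
  expect_identical(dim(tc$curves), c(3L, 19L, 11L))
  expect_true(all(tc$p_values[3, ] == 1))
  expect_lte(sum(tc$significant[2, ]), 2)
  expect_identical(tc$fpu, rowSums(tc$significant))
  expect_identical(unname(tc$upf), unname(colSums(tc$significant)))
  # the raw curve of the designed unit follows the quadratic profile
  expect_gt(stats::cor(tc$raw_curves[1, 5, ], (-5:5)^2), 0.99)

  h <- fpu_histogram(tc$fpu)
  expect_length(h, 20)
  expect_identical(names(h), as.character(0:19))
  expect_identical(sum(h), 3L)

  # a grid value never sampled is an explicit error
  bad <- meta[meta$p01 != 0, ]
  expect_error(estimate_tuning_curves(resp[, meta$p01 != 0], bad, n_perm = 10),
               "never sampled")
})

test_that("smoothing preserves constants and normalizes at the boundaries", {
  x <- matrix(5, 2, 11)
  expect_equal(fpbench:::smooth_gaussian(x), x)
  y <- fpbench:::smooth_gaussian(matrix(c(rep(0, 5), 1, rep(0, 5)), 1))
  expect_equal(sum(y), 1, tolerance = 1e-3)
  expect_equal(which.max(y), 6L)
})

test_that("polarity preferences recover a designed contrast unit", {
  mos <- build_covering_set(seed = 6, render = FALSE)
  meta <- mos$meta
  ia <- meta$i04; ib <- meta$i10   # nose vs mouth
  resp <- response_matrix(rbind(
    pmax(ia - ib, 0),
    rep(1, nrow(meta))
  ), layer = "L")
  pol <- polarity_preferences(resp, meta, n_perm = 300, alpha = 0.01, seed = 4)
  expect_length(pol$histogram, 110)
  target <- which(pol$pairs$a == "nose" & pol$pairs$b == "mouth")
  expect_identical(pol$table$direction[1, target], "A>B")
  expect_lt(pol$table$p_values[1, target], 0.01)
  # the constant unit prefers nothing
  expect_true(all(pol$table$p_values[2, ] == 1))
  expect_length(pol$table$empty_pairs, 0)
  expect_equal(sum(pol$histogram), sum(pol$table$p_values < 0.01))
})

test_that("STA view correlations are perfect for identical populations", {
  a <- matrix(stats::rnorm(20 * 50), 20)
  vc <- sta_view_correlation(a, a)
  expect_equal(vc$mean, 1)
  expect_equal(vc$per_dim, rep(1, 50))
  vc2 <- sta_view_correlation(a, -a, dims = 1:10)
  expect_equal(vc2$mean, -1)
  expect_error(sta_view_correlation(a[1:2, ], a[1:2, ]), "at least 3 units")
})
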