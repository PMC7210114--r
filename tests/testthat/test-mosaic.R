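test_that("the mosaic design enumerates 11 parts and 55 stable pairs", {
  parts <- mosaic_part_names()
  expect_length(parts, 11)
  expect_length(mosaic_grid(), 11)
  pp <- part_pairs()
  expect_identical(nrow(pp), 55L)
  expect_false(any(pp$a == pp$b))
  expect_false(anyDuplicated(paste(pmin(pp$a, pp$b), pmax(pp$a, pp$b))) > 0)
  expect_identical(pp, part_pairs())  # stable ordering
})

test_that("the fragmentation mask partitions the face area", {
  mask <- fpbench:::mosaic_mask()
  expect_true(all(mask %in% 0:11))
  counts <- tabulate(mask, nbins = 11)
  expect_true(all(counts > 50))  # every part has real area
})

test_that("mosaic renders fill parts uniformly on a mid-gray background", {
  g <- mosaic_grid()
  m <- mosaic_intensities(rep(g[8], 11))
  img <- render_mosaic(m)
  mask <- fpbench:::mosaic_mask()
  expect_true(all(img[mask > 0] == g[8]))
  expect_true(all(img[mask == 0] == 0.5))

  # changing only the forehead changes only forehead pixels
  v2 <- rep(g[8], 11)
  v2[1] <- g[2]
  img2 <- render_mosaic(mosaic_intensities(v2))
  d <- img2 != img
  expect_true(all(mask[d] == 1))
  expect_true(any(d))
})

test_that("off-grid or malformed intensities are rejected", {
  expect_error(mosaic_intensities(rep(0.5, 10)), "length 11")
  expect_error(mosaic_intensities(rep(0.33, 11)), "grid")
  expect_error(mosaic_intensities(rep(1.2, 11)), "grid|\\[0, *1\\]")
})

test_that("the covering constructor hits every (pair, level, direction) cell", {
  set <- build_covering_set(seed = 4, render = FALSE)
  expect_length(set, 432)
  cov <- verify_coverage(set)
  expect_true(cov$ok)
  expect_identical(nrow(cov$missing), 0L)

  # a different seed gives a different but still covering table
  set2 <- build_covering_set(seed = 9, render = FALSE)
  expect_true(verify_coverage(set2)$ok)
  expect_false(identical(set$meta, set2$meta))
})

test_that("coverage verification reports deficiencies", {
  set <- build_covering_set(seed = 4, render = FALSE)
  dark <- mosaic_grid()[1]
  keep <- set$meta$i01 != dark
  pruned <- stimulus_set(set$images[keep], set$meta[keep, ])
  cov <- verify_coverage(pruned)
  expect_false(cov$ok)
  expect_gt(nrow(cov$missing), 0)
  expect_true(all(cov$missing$part == "forehead"))
  expect_true(all(cov$missing$level == dark))

  empty <- stimulus_set(list(), set$meta[0, ])
  expect_false(verify_coverage(empty)$ok)

  expect_error(verify_coverage(stimulus_set(list(), data.frame())),
               "intensity")
})
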