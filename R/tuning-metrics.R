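# Per-population tuning statistics.

#' Population response similarity matrix
#'
#' Pearson correlation, across units, between the population response vectors
#' of every stimulus pair. Rows/columns are ordered by (view group, identity)
#' when the metadata is supplied. Stimuli whose response vector has zero
#' variance get zero correlations and are flagged.
#'
#' @param responses a [response_matrix()] (units x stimuli), >= 2 units
#' @param meta optional stimulus metadata with `view` and `identity` used for
#'   ordering
#' @param view_order optional explicit ordering of view groups
#' @return an object of class `rsm`: the stimuli x stimuli correlation matrix
#'   with attributes `ordering` (stimulus indices used) and `flagged`
#' @export
compute_rsm <- function(responses, meta = NULL, view_order = NULL) {
  stopifnot(nrow(responses) >= 2)
  ord <- seq_len(ncol(responses))
  labels <- NULL
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == ncol(responses))
    vo <- if (is.null(view_order)) unique(meta$view) else view_order
    ord <- order(match(meta$view, vo), meta$identity)
    labels <- paste(meta$view[ord], meta$identity[ord], sep = ":")
  }
  m <- unclass(responses)[, ord, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  flagged <- which(sds == 0)
  rsm <- suppressWarnings(stats::cor(m))
  rsm[flagged, ] <- 0
  rsm[, flagged] <- 0
  diag(rsm) <- 1
  if (!is.null(labels)) dimnames(rsm) <- list(labels, labels)
  structure(rsm, ordering = ord, flagged = flagged,
            class = c("rsm", "matrix", "array"))
}

#' Build the size-ladder stimulus set
#'
#' Each base image is bilinearly downscaled to every size in the ladder and
#' centered on a mid-gray canvas.
#'
#' @param base a [stimulus_set()] of full-size face and object images
#' @param sizes pixel widths of the ladder (descending by convention)
#' @param canvas canvas side in pixels
#' @return a [stimulus_set()] with `size_px` metadata
#' @export
make_size_ladder <- function(base,
                             sizes = c(224, 196, 168, 140, 112, 84, 56),
                             canvas = CANVAS_SIZE) {
  images <- list(); meta <- NULL
  for (s in sizes) {
    for (i in seq_along(base$images)) {
      img <- base$images[[i]]
      small <- if (s == nrow(img)) img else resize_bilinear(img, s, s)
      out <- matrix(0.5, canvas, canvas)
      o <- floor((canvas - s) / 2)
      out[o + seq_len(s), o + seq_len(s)] <- small
      images[[length(images) + 1]] <- out
    }
    m <- base$meta
    m$size_px <- s
    meta <- rbind(meta, m)
  }
  meta$image_id <- seq_len(nrow(meta))
  stimulus_set(images, meta)
}

#' Population response profile over stimulus sizes
#'
#' @param responses a [response_matrix()] on a size-ladder set
#' @param meta the ladder metadata (`size_px`, `category`)
#' @param baseline per-unit baseline (response to the blank image); default 0
#' @return an object of class `size_profile`: data.frame of mean face and
#'   object responses per size
#' @export
compute_size_profile <- function(responses, meta, baseline = 0) {
  stopifnot(ncol(responses) == nrow(meta))
  vals <- sweep(unclass(responses), 1, baseline)
  sizes <- sort(unique(meta$size_px), decreasing = TRUE)
  prof <- do.call(rbind, lapply(sizes, function(s) {
    data.frame(
      size_px = s,
      r_face = mean(vals[, meta$size_px == s & meta$category == "face"]),
      r_object = mean(vals[, meta$size_px == s & meta$category == "object"]))
  }))
  structure(prof, class = c("size_profile", "data.frame"))
}

#' Size-invariance index
#'
#' The smallest stimulus size, as a fraction of the canvas, at which the mean
#' face response exceeds `ratio` times the mean object response at that size
#' and at every larger tested size; 1 if no size qualifies. Lower values mean
#' stronger size invariance.
#'
#' @param profile a [compute_size_profile()] result
#' @param ratio required face/object preference factor (default 1.4)
#' @param canvas canvas side in pixels
#' @return a fraction in (0, 1]
#' @export
compute_sii <- function(profile, ratio = 1.4, canvas = CANVAS_SIZE) {
  if (nrow(profile) == 0) stop("empty size ladder")
  prof <- profile[order(profile$size_px, decreasing = TRUE), ]
  ok <- prof$r_face > ratio * prof$r_object
  if (!ok[1]) return(1)
  run <- which(!ok)
  last <- if (length(run)) run[1] - 1 else nrow(prof)
  prof$size_px[last] / canvas
}

#' Spike-triggered average and shape-preference index
#'
#' The STA is the weighted average of the stimulus feature vectors, with
#' weights the unit's mean-subtracted responses rectified at zero and
#' normalized to sum to one (scale-invariant; for zero-mean Gaussian features
#' this estimator aligns with the unit's linear kernel under a
#' rectified-linear response). SPI = (S - A)/(S + A) with S, A the Euclidean
#' norms of the shape and appearance halves.
#'
#' @param responses numeric vector (one unit) or units x stimuli matrix
#' @param features n x 50 matrix of the stimuli's feature vectors
#' @param n_shape number of leading shape dimensions (default 25)
#' @return list with `sta` (units x dims), `S`, `A`, `spi` (NA and flagged
#'   when a unit's rectified weights are all zero)
#' @export
compute_sta <- function(responses, features, n_shape = 25) {
  if (is.null(dim(responses))) responses <- matrix(responses, 1)
  responses <- unclass(responses)
  stopifnot(ncol(responses) == nrow(features))
  w <- responses - rowMeans(responses)
  w[w < 0] <- 0
  wsum <- rowSums(w)
  ok <- wsum > 0
  sta <- matrix(0, nrow(responses), ncol(features))
  if (any(ok)) {
    sta[ok, ] <- (w[ok, , drop = FALSE] %*% features) / wsum[ok]
  }
  S <- sqrt(rowSums(sta[, seq_len(n_shape), drop = FALSE]^2))
  A <- sqrt(rowSums(sta[, -seq_len(n_shape), drop = FALSE]^2))
  spi <- ifelse(S + A > 0, (S - A) / (S + A), NA_real_)
  spi[!ok] <- NA_real_
  list(sta = sta, S = S, A = A, spi = spi, flagged = which(!ok))
}

#' Per-dimension correlation between STAs of two views
#'
#' For each feature dimension, the Pearson correlation across units between
#' the STA values of the two views, plus the mean over a dimension subset.
#'
#' @param stas_view_a,stas_view_b units x dims STA matrices (same unit order)
#' @param dims dimension subset for the mean (default all)
#' @return list with `per_dim` correlations and `mean`
#' @export
sta_view_correlation <- function(stas_view_a, stas_view_b, dims = NULL) {
  stopifnot(all(dim(stas_view_a) == dim(stas_view_b)))
  if (nrow(stas_view_a) < 3) stop("need at least 3 units")
  per_dim <- vapply(seq_len(ncol(stas_view_a)), function(j) {
    safe_cor(stas_view_a[, j], stas_view_b[, j])
  }, numeric(1))
  if (is.null(dims)) dims <- seq_along(per_dim)
  list(per_dim = per_dim, mean = mean(per_dim[dims], na.rm = TRUE))
}

# Discrete Gaussian smoothing (sd = 1 grid step), kernel renormalized at the
# boundaries. `x` may be a matrix (smoothing along rows).
smooth_gaussian <- function(x, sd = 1) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- ncol(x)
  kern <- stats::dnorm(-(n - 1):(n - 1), sd = sd)
  out <- x
  for (j in seq_len(n)) {
    w <- kern[(n - j + 1):(2 * n - j)]
    w <- w / sum(w)
    out[, j] <- as.numeric(x %*% w)
  }
  out
}

# Draw a matrix of permutation indices (n x n_perm), seeded.
permutation_indices <- function(n, n_perm, seed) {
  with_seed(seed, vapply(seq_len(n_perm), function(i) sample.int(n),
                         integer(n)))
}

#' Cartoon tuning curves with permutation significance
#'
#' For each unit and each of the 19 cartoon parameters: the marginal mean
#' response at each of the 11 grid values (regardless of the remaining
#' parameters), smoothed with a unit-variance discrete Gaussian. Significance
#' of each (unit, feature) tuning is a one-way permutation ANOVA on the
#' unsmoothed per-value means.
#'
#' @param responses a [response_matrix()] on a cartoon set (units x stimuli)
#' @param meta cartoon metadata carrying `p01..p19`
#' @param n_perm number of permutations (default 1000)
#' @param alpha per-feature significance level (default 0.01)
#' @param seed seed for the permutations
#' @return list with `curves` (units x 19 x 11 array, smoothed), `p_values`
#'   (units x 19), `significant` (logical units x 19), `fpu` (per-unit count
#'   of significant features), `upf` (per-feature count of tuned units)
#' @export
estimate_tuning_curves <- function(responses, meta, n_perm = 1000,
                                   alpha = 0.01, seed = 1) {
  R <- unclass(responses)
  cols <- cartoon_param_columns(meta)
  n <- ncol(R); U <- nrow(R)
  stopifnot(n == nrow(meta))
  grid <- cartoon_grid()
  # per-feature group index (stimuli x 19), values 1..11
  gidx <- vapply(cols, function(cl) match(meta[[cl]], grid), integer(n))
  if (any(is.na(gidx))) stop("cartoon parameters off the -5..5 grid")
  counts <- apply(gidx, 2, tabulate, nbins = 11)
  if (any(counts == 0)) {
    stop("some grid value was never sampled for some feature; ",
         "use a larger stimulus set")
  }
  # indicator matrix G: stimuli x (19*11), one block of 11 columns per feature
  G <- matrix(0, n, 19 * 11)
  for (k in 1:19) G[cbind(seq_len(n), (k - 1) * 11 + gidx[, k])] <- 1
  nvec <- as.numeric(counts)              # column counts of G
  agg <- kronecker(diag(19), matrix(1, 11, 1))  # (19*11) x 19 block sums

  tot <- rowSums(R)
  sstot <- rowSums(R^2) - tot^2 / n
  f_from_sums <- function(S) {
    # S: U x (19*11) group sums -> F statistics U x 19
    ssb <- (S^2 %*% (agg / nvec)) - tot^2 / n
    ssw <- sstot - ssb
    (ssb / 10) / pmax(ssw, 1e-300) * (n - 11)
  }
  f_obs <- f_from_sums(R %*% G)
  pmat <- permutation_indices(n, n_perm, derive_seed(seed, "null"))
  exceed <- matrix(0, U, 19)
  for (j in seq_len(n_perm)) {
    Sj <- R[, pmat[, j], drop = FALSE] %*% G
    exceed <- exceed + (f_from_sums(Sj) >= f_obs)
  }
  p_values <- (1 + exceed) / (1 + n_perm)
  constant <- sstot <= 1e-12
  p_values[constant, ] <- 1
  significant <- p_values < alpha

  raw <- array(0, c(U, 19, 11))
  curves <- array(0, c(U, 19, 11))
  means <- sweep(R %*% G, 2, nvec, `/`)
  for (k in 1:19) {
    mk <- means[, (k - 1) * 11 + (1:11), drop = FALSE]
    raw[, k, ] <- mk
    curves[, k, ] <- smooth_gaussian(mk)
  }
  fpu <- rowSums(significant)
  upf <- colSums(significant)
  names(upf) <- cartoon_param_names()
  list(curves = curves, raw_curves = raw, p_values = p_values,
       significant = significant, fpu = fpu, upf = upf)
}

#' Histogram of features-per-unit counts
#'
#' @param fpu integer vector of per-unit significant-feature counts
#' @return counts over 0..19 (length 20)
#' @export
fpu_histogram <- function(fpu) {
  h <- tabulate(fpu + 1, nbins = 20)
  names(h) <- 0:19
  h
}

#' Contrast-polarity preferences over the 55 part-pairs
#'
#' For each unit and each part-pair (A, B): compares the mean response where
#' A is lighter than B against the mean where A is darker, irrespective of
#' the other 9 parts (images with tied intensities are excluded for that
#' pair). Significance by a two-sample permutation test on the condition
#' means; direction is the sign of the observed difference.
#'
#' @param responses a [response_matrix()] on a mosaic set
#' @param meta mosaic metadata carrying `i01..i11`
#' @param n_perm number of permutations (default 1000)
#' @param alpha per-pair significance level (default 0.01)
#' @param seed seed for the permutations
#' @return list with `table` (per unit x pair: difference, p-value,
#'   direction), `histogram` (110 signed bins: 55 pairs x {A>B, A<B} counts
#'   of significant preferences), `pairs`
#' @export
polarity_preferences <- function(responses, meta, n_perm = 1000, alpha = 0.01,
                                 seed = 1) {
  R <- unclass(responses)
  cols <- mosaic_intensity_columns(meta)
  intens <- as.matrix(meta[, cols])
  n <- ncol(R); U <- nrow(R)
  stopifnot(n == nrow(meta))
  pp <- part_pairs()
  parts <- mosaic_part_names()
  npair <- nrow(pp)
  # condition indicators: n x npair for A>B and A<B
  C1 <- matrix(0, n, npair); C2 <- matrix(0, n, npair)
  for (r in seq_len(npair)) {
    ia <- intens[, match(pp$a[r], parts)]
    ib <- intens[, match(pp$b[r], parts)]
    C1[ia > ib + 1e-9, r] <- 1
    C2[ib > ia + 1e-9, r] <- 1
  }
  n1 <- colSums(C1); n2 <- colSums(C2)
  empty <- n1 == 0 | n2 == 0
  scale1 <- ifelse(n1 > 0, 1 / n1, 0)
  scale2 <- ifelse(n2 > 0, 1 / n2, 0)
  D <- sweep(C1, 2, scale1, `*`) - sweep(C2, 2, scale2, `*`)
  d_obs <- R %*% D
  pmat <- permutation_indices(n, n_perm, derive_seed(seed, "null"))
  exceed <- matrix(0, U, npair)
  for (j in seq_len(n_perm)) {
    exceed <- exceed + (abs(R[, pmat[, j], drop = FALSE] %*% D) >= abs(d_obs))
  }
  p_values <- (1 + exceed) / (1 + n_perm)
  constant <- apply(R, 1, stats::sd) == 0
  p_values[constant, ] <- 1
  sig <- p_values < alpha & !matrix(empty, U, npair, byrow = TRUE)
  direction <- matrix("none", U, npair)
  direction[sig & d_obs > 0] <- "A>B"
  direction[sig & d_obs < 0] <- "A<B"
  hist <- c(colSums(sig & d_obs > 0), colSums(sig & d_obs < 0))
  names(hist) <- c(paste0(pp$a, ">", pp$b), paste0(pp$a, "<", pp$b))
  list(table = list(difference = d_obs, p_values = p_values,
                    direction = direction, empty_pairs = which(empty)),
       histogram = hist, pairs = pp)
}
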