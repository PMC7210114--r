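# Layer-versus-face-patch comparison statistics: similarity metrics against
# reference data, randomized null bands, bootstrap confidence intervals, and
# report assembly.

#' Packaged reference constants
#'
#' Scalar reference values for the macaque face patches. Only summary numbers
#' are packaged; digitized matrices and histograms must be supplied by the
#' user as CSV/JSON.
#'
#' @return named list with provenance tags
#' @export
reference_constants <- function() {
  list(
    spi_mean = c(ML = 0.29, AM = -0.19),
    sii = c(ML = 1 / 8, AL = 1 / 8, AM = 1 / 8),
    sta_corr_mean = c(AM = 0.31),
    provenance = "packaged_constant"
  )
}

# Upper-triangle off-diagonal entries of a square matrix.
upper_offdiag <- function(m) m[upper.tri(m)]

#' Correlation between two response similarity matrices
#'
#' Pearson correlation over the off-diagonal upper triangle (the diagonal is
#' identically one and would inflate the correlation). If the reference omits
#' stimulus groups (e.g. a missing view), the matrices are intersected on
#' their row/column names first.
#'
#' @param rsm_model,rsm_reference square correlation matrices; name rows and
#'   columns `view:identity` to enable intersection
#' @return a correlation coefficient
#' @export
rsm_correlation <- function(rsm_model, rsm_reference) {
  a <- as.matrix(rsm_model); b <- as.matrix(rsm_reference)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    common <- intersect(rownames(a), rownames(b))
    if (length(common) < 3) stop("fewer than 3 common stimuli after intersection")
    a <- a[common, common]; b <- b[common, common]
  }
  if (!all(dim(a) == dim(b))) {
    stop("RSM dimensions differ after intersection: ", nrow(a), " vs ", nrow(b))
  }
  stats::cor(upper_offdiag(a), upper_offdiag(b))
}

#' A null band
#' @param center,sd center and standard deviation of the null statistic
#' @param n_samples,seed provenance of the randomization
#' @return object of class `null_band` with `band = center +/- 2 sd`
#' @export
null_band <- function(center, sd, n_samples, seed) {
  structure(list(center = center, sd = sd,
                 band = c(lower = center - 2 * sd, upper = center + 2 * sd),
                 n_samples = n_samples, seed = seed),
            class = "null_band")
}

#' @export
print.null_band <- function(x, ...) {
  cat(sprintf("<null_band> %.4f +/- 2*%.4f -> [%.4f, %.4f] (n=%d)\n",
              x$center, x$sd, x$band[1], x$band[2], x$n_samples))
  invisible(x)
}

#' Null band for RSM correlations from random similarity matrices
#'
#' Generates symmetric matrices with unit diagonal whose off-diagonals are
#' Gaussian with mean and variance matched to the reference RSM, and collects
#' the distribution of their correlations with the reference.
#'
#' @param reference a reference RSM
#' @param n number of random matrices (default 1000)
#' @param seed integer seed
#' @return a [null_band()]; the simulated correlations in attribute `samples`
#' @export
random_rsm_null <- function(reference, n = 1000, seed = 1) {
  ref <- as.matrix(reference)
  off <- upper_offdiag(ref)
  mu <- mean(off); sdev <- stats::sd(off)
  k <- length(off)
  sims <- with_seed(seed, vapply(seq_len(n), function(i) {
    stats::cor(stats::rnorm(k, mu, sdev), off)
  }, numeric(1)))
  structure(null_band(mean(sims), stats::sd(sims), n, seed), samples = sims)
}

#' Cosine similarity between two nonnegative histograms
#'
#' @param hist_a,hist_b nonnegative vectors of equal length, not all zero
#' @return value in `[0, 1]`
#' @export
cosine_similarity <- function(hist_a, hist_b) {
  stopifnot(length(hist_a) == length(hist_b))
  if (any(hist_a < 0) || any(hist_b < 0)) stop("histograms must be nonnegative")
  na <- sqrt(sum(hist_a^2)); nb <- sqrt(sum(hist_b^2))
  if (na == 0 || nb == 0) stop("zero histogram has no cosine similarity")
  sum(hist_a * hist_b) / (na * nb)
}

#' Null band for histogram cosine similarities
#'
#' Randomized reference construction per histogram kind: for features-per-unit
#' each unit draws a tuned-feature count uniformly from 0..19; for
#' units-per-feature each feature draws a tuned-unit count uniformly from
#' 0..100; the polarity kind reuses the units-per-feature construction per
#' signed bin.
#'
#' @param kind one of `"fpu"`, `"upf"`, `"polarity"`
#' @param reference the reference histogram (length 20 for fpu, 19 for upf,
#'   110 for polarity)
#' @param n number of random distributions (default 1000)
#' @param seed integer seed
#' @param n_units number of units for the fpu construction (default: sum of
#'   the reference histogram)
#' @return a [null_band()]; simulated similarities in attribute `samples`
#' @export
random_histogram_null <- function(kind, reference, n = 1000, seed = 1,
                                  n_units = NULL) {
  if (!kind %in% c("fpu", "upf", "polarity")) {
    stop("unknown histogram kind '", kind, "'; use fpu, upf or polarity")
  }
  gen <- switch(kind,
    fpu = {
      if (is.null(n_units)) n_units <- max(1, round(sum(reference)))
      function() fpu_histogram(sample(0:19, n_units, replace = TRUE))
    },
    upf = function() sample(0:100, length(reference), replace = TRUE),
    polarity = function() sample(0:100, length(reference), replace = TRUE)
  )
  sims <- with_seed(seed, vapply(seq_len(n), function(i) {
    cosine_similarity(gen(), reference)
  }, numeric(1)))
  structure(null_band(mean(sims), stats::sd(sims), n, seed), samples = sims)
}

#' Null band for mean STA correlations from random STA vectors
#'
#' Draws two independent sets of standard-Gaussian STA matrices of the given
#' population size, computes the mean per-dimension correlation across units,
#' and returns the +/- 2 SD band.
#'
#' @param n_units population size
#' @param n_dims STA dimensionality (default 50)
#' @param dims dimension subset for the mean (default all)
#' @param n number of replicates (default 1000)
#' @param seed integer seed
#' @return a [null_band()]; samples in attribute `samples`
#' @export
random_sta_null <- function(n_units, n_dims = 50, dims = NULL, n = 1000,
                            seed = 1) {
  stopifnot(n_units >= 3)
  sims <- with_seed(seed, vapply(seq_len(n), function(i) {
    a <- matrix(stats::rnorm(n_units * n_dims), n_units)
    b <- matrix(stats::rnorm(n_units * n_dims), n_units)
    sta_view_correlation(a, b, dims = dims)$mean
  }, numeric(1)))
  structure(null_band(mean(sims), stats::sd(sims), n, seed), samples = sims)
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param samples numeric vector (>= 2 values)
#' @param n_boot bootstrap iterations (default 200)
#' @param level confidence level (default 0.95)
#' @param seed integer seed
#' @return named vector `c(lower, upper)` with attribute `means`
#' @export
bootstrap_mean_ci <- function(samples, n_boot = 200, level = 0.95, seed = 1) {
  if (length(samples) < 2) stop("need at least 2 samples to bootstrap")
  means <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    mean(sample(samples, replace = TRUE))
  }, numeric(1)))
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(c(lower = qs[1], upper = qs[2]), means = means)
}

#' Assemble a layer-versus-patch comparison report
#'
#' @param layer_metrics named list: per layer, a named list of metric values
#'   (scalars, or lists with `value` plus optional `band` from a null band)
#' @param references named list: per metric, a list with `value`, `patch` and
#'   `provenance` (`user_supplied` or `packaged_constant`)
#' @return object of class `layer_patch_report`: a data.frame with one row
#'   per layer x metric
#' @export
build_report <- function(layer_metrics, references = list()) {
  stopifnot(length(layer_metrics) >= 1)
  rows <- list()
  for (layer in names(layer_metrics)) {
    for (metric in names(layer_metrics[[layer]])) {
      entry <- layer_metrics[[layer]][[metric]]
      if (!is.list(entry)) entry <- list(value = entry)
      ref <- references[[metric]]
      band <- entry$band
      rows[[length(rows) + 1]] <- data.frame(
        layer = layer, metric = metric,
        value = as.numeric(entry$value)[1],
        reference = if (!is.null(ref)) as.numeric(ref$value)[1] else NA_real_,
        patch = if (!is.null(ref$patch)) ref$patch else NA_character_,
        provenance = if (!is.null(ref$provenance)) ref$provenance
        else if (is.null(ref)) "no reference" else "user_supplied",
        band_lower = if (!is.null(band)) band[["lower"]] else NA_real_,
        band_upper = if (!is.null(band)) band[["upper"]] else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  rep <- do.call(rbind, rows)
  rep$outside_band <- !is.na(rep$band_lower) &
    (rep$value < rep$band_lower | rep$value > rep$band_upper)
  structure(rep, class = c("layer_patch_report", "data.frame"))
}

#' Serialize / parse a layer-patch report (lossless JSON round trip)
#' @param report a [build_report()] result
#' @param path optional file to write
#' @return JSON string (invisibly, when writing to a file)
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(report), digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname report_to_json
#' @param json JSON string or file path
#' @export
report_from_json <- function(json) {
  df <- jsonlite::fromJSON(json)
  df$patch <- as.character(df$patch)
  structure(df, class = c("layer_patch_report", "data.frame"))
}
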