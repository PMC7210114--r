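#' @keywords internal
"_PACKAGE"

# Canvas side used throughout; all stimuli live on a square grayscale raster.
CANVAS_SIZE <- 224L

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators in the package are pure functions of their parameters and a
#' seed; this helper guarantees they neither depend on nor disturb the global
#' RNG stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific child seed from a parent seed; keeps independent
# stages decoupled while remaining reproducible from one root seed.
derive_seed <- function(seed, stream) {
  offsets <- c(stimuli = 11L, faces = 23L, objects = 37L, cartoon = 41L,
               mosaic = 53L, space = 67L, sample = 71L, model = 83L,
               probe = 89L, null = 97L, units = 101L, boot = 103L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else
    (sum(utf8ToInt(stream)) %% 1009L)
  # double arithmetic: 2147483629 * 7919 < 2^53, so this is exact where the
  # equivalent integer arithmetic would overflow
  as.integer(((as.numeric(seed) %% 2147483629) * 7919 + off) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear resampling of a grayscale raster
#'
#' @param img numeric matrix in `[0,1]` (rows = y, cols = x)
#' @param out_h,out_w output dimensions in pixels
#' @return numeric matrix `out_h x out_w`
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  # map output pixel centers onto input pixel centers
  ys <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  ys <- clamp(ys, 0, in_h - 1); xs <- clamp(xs, 0, in_w - 1)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, in_h - 1); x1 <- pmin(x0 + 1, in_w - 1)
  fy <- ys - y0; fx <- xs - x0
  i00 <- img[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
  i01 <- img[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
  i10 <- img[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
  i11 <- img[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
  fyv <- rep(fy, out_w); fxv <- rep(fx, each = out_h)
  v <- i00 * (1 - fyv) * (1 - fxv) + i01 * (1 - fyv) * fxv +
    i10 * fyv * (1 - fxv) + i11 * fyv * fxv
  matrix(v, out_h, out_w)
}

# Bilinear lookup of img at arbitrary (x, y) 0-based pixel coordinates,
# clamped at the border. Vectorized over coordinates.
sample_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 0, w - 1); y <- clamp(y, 0, h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
    img[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
    img[cbind(y1 + 1, x1 + 1)] * fy * fx
}

# Pearson correlation that tolerates zero-variance inputs (returns NA).
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
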