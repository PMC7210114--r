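# Mosaic face stimuli for the contrast-polarity experiment.
#
# A mosaic face fragments a mean face area into 11 uniform-intensity parts on
# a mid-gray background. Intensities take one of 11 grid levels in [0, 1].
# The covering stimulus set guarantees that every part-pair is observed at
# every intensity level.

#' Names of the 11 mosaic face parts
#' @return character vector of length 11
#' @export
mosaic_part_names <- function() {
  c("forehead", "left_eye", "right_eye", "nose", "upper_lip",
    "left_cheek", "right_cheek", "lower_left_cheek", "lower_right_cheek",
    "mouth", "chin")
}

#' The 11 mosaic intensity levels
#' @return numeric vector, an evenly spaced grid in `[0, 1]`
#' @export
mosaic_grid <- function() seq(0, 1, length.out = 11)

#' Enumerate the 55 unordered part-pairs
#'
#' Stable ordering: pairs in `combn` order over [mosaic_part_names()].
#'
#' @return data.frame with columns `a`, `b`
#' @export
part_pairs <- function() {
  cmb <- utils::combn(mosaic_part_names(), 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

# Label mask of the canonical polygonal fragmentation: 0 = background,
# 1..11 = parts in mosaic_part_names() order. The bands partition the face
# ellipse, so no pixel belongs to two parts. Cached per canvas size.
mosaic_mask_env <- new.env(parent = emptyenv())

#' Fragmentation mask of the mosaic face
#' @param size canvas side in pixels
#' @return integer matrix of part labels (0 = background)
#' @export
mosaic_mask <- function(size = CANVAS_SIZE) {
  key <- as.character(size)
  if (!is.null(mosaic_mask_env[[key]])) return(mosaic_mask_env[[key]])
  cx <- size / 2; cy <- 0.54 * size
  rx <- 0.30 * size; ry <- 0.38 * size
  xg <- matrix(rep(0:(size - 1), each = size), size)
  yg <- matrix(rep(0:(size - 1), times = size), size)
  inside <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
  t <- (yg - (cy - ry)) / (2 * ry)        # vertical position in [0, 1]
  dx <- (xg - cx) / rx                    # lateral position in [-1, 1]
  lab <- matrix(0L, size, size)
  part <- function(name) match(name, mosaic_part_names())
  sel <- function(cond) inside & cond & lab == 0L
  lab[sel(t < 0.30)] <- part("forehead")
  lab[sel(t < 0.62 & abs(dx) <= 0.18)] <- part("nose")
  lab[sel(t < 0.45 & dx < 0)] <- part("left_eye")
  lab[sel(t < 0.45)] <- part("right_eye")
  lab[sel(t < 0.62 & dx < 0)] <- part("left_cheek")
  lab[sel(t < 0.62)] <- part("right_cheek")
  lab[sel(t < 0.72 & abs(dx) <= 0.50)] <- part("upper_lip")
  lab[sel(t < 0.84 & abs(dx) <= 0.50)] <- part("mouth")
  lab[sel(t < 0.84 & dx < 0)] <- part("lower_left_cheek")
  lab[sel(t < 0.84)] <- part("lower_right_cheek")
  lab[sel(TRUE)] <- part("chin")
  mosaic_mask_env[[key]] <- lab
  lab
}

#' Construct a validated mosaic intensity vector
#'
#' @param values numeric length 11, each on the 11-step grid of
#'   [mosaic_grid()]
#' @return an object of class `mosaic_intensities`
#' @export
mosaic_intensities <- function(values) {
  if (length(values) != 11) {
    stop("mosaic intensities must have length 11, got ", length(values))
  }
  grid <- mosaic_grid()
  idx <- vapply(values, function(v) {
    d <- abs(grid - v)
    if (min(d) > 1e-9) NA_integer_ else which.min(d)
  }, integer(1))
  if (any(is.na(idx))) {
    stop("intensity values must be on the 11-step grid in [0, 1]; offending ",
         "positions: ", paste(which(is.na(idx)), collapse = ", "))
  }
  values <- grid[idx]
  names(values) <- mosaic_part_names()
  structure(values, class = "mosaic_intensities")
}

#' Render a mosaic face
#'
#' Each part region is filled uniformly with its intensity; the background is
#' mid-gray (0.5).
#'
#' @param m a [mosaic_intensities()] vector (or numeric length 11 on the grid)
#' @param size canvas side in pixels
#' @return numeric matrix in `[0,1]`
#' @export
render_mosaic <- function(m, size = CANVAS_SIZE) {
  if (!inherits(m, "mosaic_intensities")) m <- mosaic_intensities(m)
  mask <- mosaic_mask(size)
  img <- matrix(0.5, size, size)
  for (k in 1:11) img[mask == k] <- m[k]
  img
}

# Intensity columns of a mosaic metadata table (i01..i11).
mosaic_intensity_columns <- function(meta) {
  cols <- sprintf("i%02d", 1:11)
  if (!all(cols %in% names(meta))) {
    stop("metadata lacks the 11 mosaic intensity columns i01..i11")
  }
  cols
}

#' Build the covering mosaic stimulus set
#'
#' Emits `n_images` mosaic faces in which each part holds a unique intensity
#' level (a random permutation of the 11 grid levels per image), repaired if
#' needed so that for every part-pair and every intensity level the set
#' contains at least one exemplar where that pair shows that level.
#'
#' @param seed integer seed
#' @param n_images design size (default 432)
#' @param render if `FALSE`, only metadata is generated
#' @return a [stimulus_set()] with intensity columns `i01..i11`
#' @export
build_covering_set <- function(seed = 1, n_images = 432, render = TRUE) {
  stopifnot(n_images >= 11)
  lv <- with_seed(seed, {
    m <- t(vapply(seq_len(n_images), function(i) sample.int(11),
                  integer(11)))
    # repair pass: guarantee each (part, level) cell is observed
    for (iter in 1:100) {
      missing <- which(vapply(1:11, function(p) {
        vapply(1:11, function(v) !any(m[, p] == v), logical(1))
      }, logical(11)), arr.ind = TRUE)
      if (nrow(missing) == 0) break
      for (r in seq_len(nrow(missing))) {
        v <- missing[r, 1]; p <- missing[r, 2]
        i <- sample.int(n_images, 1)
        q <- which(m[i, ] == v)
        m[i, q] <- m[i, p]; m[i, p] <- v
      }
    }
    m
  })
  grid <- mosaic_grid()
  intens <- matrix(grid[lv], nrow = n_images)
  colnames(intens) <- sprintf("i%02d", 1:11)
  images <- vector("list", n_images)
  if (render) {
    for (i in seq_len(n_images)) images[[i]] <- render_mosaic(intens[i, ])
  }
  meta <- data.frame(image_id = seq_len(n_images), identity = NA_integer_,
                     view = NA_character_, size_px = CANVAS_SIZE,
                     category = "mosaic")
  meta <- cbind(meta, as.data.frame(intens))
  stimulus_set(images, meta)
}

#' Verify the covering property of a mosaic stimulus set
#'
#' Checks that for every part-pair and every intensity level, at least one
#' image shows part `a` at that level with part `b` at a different level,
#' and symmetrically.
#'
#' @param set a [stimulus_set()] whose metadata carries `i01..i11`
#' @return list with `ok` (logical) and `missing` (data.frame of part, level
#'   combinations lacking an exemplar)
#' @export
verify_coverage <- function(set) {
  if (!inherits(set, "stimulus_set")) stop("expected a stimulus_set")
  cols <- mosaic_intensity_columns(set$meta)
  intens <- as.matrix(set$meta[, cols])
  if (nrow(intens) == 0) {
    return(list(ok = FALSE,
                missing = data.frame(part = character(), level = numeric())))
  }
  grid <- mosaic_grid()
  pp <- part_pairs()
  parts <- mosaic_part_names()
  missing <- list()
  for (r in seq_len(nrow(pp))) {
    ia <- intens[, match(pp$a[r], parts)]
    ib <- intens[, match(pp$b[r], parts)]
    for (v in grid) {
      if (!any(abs(ia - v) < 1e-9 & abs(ib - v) > 1e-9)) {
        missing[[length(missing) + 1]] <-
          data.frame(part = pp$a[r], other = pp$b[r], level = v)
      }
      if (!any(abs(ib - v) < 1e-9 & abs(ia - v) > 1e-9)) {
        missing[[length(missing) + 1]] <-
          data.frame(part = pp$b[r], other = pp$a[r], level = v)
      }
    }
  }
  missing <- if (length(missing)) do.call(rbind, missing) else
    data.frame(part = character(), other = character(), level = numeric())
  list(ok = nrow(missing) == 0, missing = unique(missing))
}
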