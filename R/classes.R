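# Core S3 containers.

#' Construct an annotated image
#'
#' An annotated image is a grayscale raster on the fixed 224x224 canvas plus
#' an ordered set of (x, y) landmark coordinates in 0-based pixel units
#' (origin top-left, x rightward, y downward).
#'
#' @param pixels numeric matrix in `[0,1]`
#' @param landmarks numeric matrix with columns `x`, `y`
#' @return an object of class `annotated_image`
#' @export
annotated_image <- function(pixels, landmarks) {
  stopifnot(is.matrix(pixels), is.matrix(landmarks), ncol(landmarks) == 2)
  if (any(landmarks[, 1] < 0) || any(landmarks[, 1] > ncol(pixels) - 1) ||
      any(landmarks[, 2] < 0) || any(landmarks[, 2] > nrow(pixels) - 1)) {
    bad <- which(landmarks[, 1] < 0 | landmarks[, 1] > ncol(pixels) - 1 |
                   landmarks[, 2] < 0 | landmarks[, 2] > nrow(pixels) - 1)
    stop("landmarks outside the canvas at indices: ",
         paste(bad, collapse = ", "))
  }
  structure(list(pixels = pixels, landmarks = landmarks),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %dx%d canvas, %d landmarks\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$landmarks)))
  invisible(x)
}

#' Construct a stimulus set
#'
#' An ordered collection of rasters with one metadata record per image.
#'
#' @param images list of numeric matrices
#' @param meta data.frame with one row per image; standard columns are
#'   `image_id`, `identity`, `view`, `size_px`, `category`, plus optional
#'   parameter columns
#' @return an object of class `stimulus_set`
#' @export
stimulus_set <- function(images, meta) {
  stopifnot(is.list(images), is.data.frame(meta))
  if (length(images) != nrow(meta)) {
    stop("images and metadata lengths differ (", length(images), " vs ",
         nrow(meta), ")")
  }
  if (is.null(meta$image_id)) meta$image_id <- seq_len(nrow(meta))
  structure(list(images = images, meta = meta), class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d images", length(x$images)))
  if (!is.null(x$meta$category)) {
    tb <- table(x$meta$category)
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.stimulus_set <- function(x) length(x$images)

# Concatenate stimulus sets, aligning metadata columns.
combine_stimulus_sets <- function(...) {
  sets <- list(...)
  cols <- unique(unlist(lapply(sets, function(s) names(s$meta))))
  metas <- lapply(sets, function(s) {
    m <- s$meta
    for (cl in setdiff(cols, names(m))) m[[cl]] <- NA
    m[, cols, drop = FALSE]
  })
  meta <- do.call(rbind, metas)
  meta$image_id <- seq_len(nrow(meta))
  stimulus_set(do.call(c, lapply(sets, function(s) s$images)), meta)
}

#' Construct a response matrix
#'
#' @param values numeric matrix, units x stimuli
#' @param layer layer name
#' @param stimulus_ids optional ordered stimulus identifiers
#' @return an object of class `response_matrix` (a numeric matrix with
#'   attributes `layer` and `stimulus_ids`)
#' @export
response_matrix <- function(values, layer = "layer", stimulus_ids = NULL) {
  stopifnot(is.matrix(values))
  if (any(!is.finite(values))) stop("response matrix has non-finite entries")
  if (is.null(stimulus_ids)) stimulus_ids <- seq_len(ncol(values))
  stopifnot(length(stimulus_ids) == ncol(values))
  structure(values, layer = layer, stimulus_ids = stimulus_ids,
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> layer '%s': %d units x %d stimuli\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  invisible(x)
}
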