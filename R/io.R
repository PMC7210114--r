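# Plain-file writers: PNG images, CSV metadata/tables, JSON summaries.

#' Write a stimulus set to disk
#'
#' One PNG per image plus a metadata CSV with the per-image records
#' (identity, view, size, category, and any parameter columns).
#'
#' @param set a [stimulus_set()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the metadata CSV path
#' @export
write_stimulus_set <- function(set, dir, prefix = "stim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(set$images)) {
    if (is.null(set$images[[i]])) next
    png::writePNG(clamp(set$images[[i]], 0, 1),
                  file.path(dir, sprintf("%s_%05d.png", prefix, i)))
  }
  path <- file.path(dir, paste0(prefix, "_meta.csv"))
  utils::write.csv(set$meta, path, row.names = FALSE)
  invisible(path)
}

#' Write the mosaic fragmentation as a labeled-mask PNG
#'
#' Part labels 1..11 are encoded as evenly spaced gray levels (background 0).
#'
#' @param path output PNG path
#' @param size canvas side in pixels
#' @return invisibly, the label-to-gray mapping
#' @export
write_mosaic_mask <- function(path, size = CANVAS_SIZE) {
  mask <- mosaic_mask(size)
  levels <- seq(0, 1, length.out = 12)
  png::writePNG(matrix(levels[mask + 1L], size, size), path)
  invisible(stats::setNames(levels[-1], mosaic_part_names()))
}

#' Write a face-space model to a directory of CSV files
#'
#' Plain-text serialization: mean landmarks, bases, scales and the mean
#' texture as CSV, plus a JSON sidecar with provenance.
#'
#' @param model a [face_space_model()]
#' @param dir output directory
#' @param provenance optional list stored in the sidecar
#' @return invisibly, `dir`
#' @export
write_face_space <- function(model, dir, provenance = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.csv(as.data.frame(x), file.path(dir, name), row.names = FALSE)
  }
  wr(model$mean_landmarks, "mean_landmarks.csv")
  wr(model$shape_basis, "shape_basis.csv")
  wr(model$appearance_basis, "appearance_basis.csv")
  wr(model$mean_texture, "mean_texture.csv")
  wr(data.frame(shape_scale = model$shape_scale,
                appearance_scale = model$appearance_scale), "scales.csv")
  wr(model$triangles, "triangles.csv")
  side <- c(list(view = model$view, n_shape = model$n_shape,
                 n_appearance = model$n_appearance, canvas = model$canvas,
                 n_train = model$n_train), provenance)
  jsonlite::write_json(side, file.path(dir, "model.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a face-space model written by [write_face_space()]
#' @param dir model directory
#' @return a `face_space_model`
#' @export
read_face_space <- function(dir) {
  rd <- function(name) as.matrix(utils::read.csv(file.path(dir, name)))
  side <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  scales <- utils::read.csv(file.path(dir, "scales.csv"))
  lm <- rd("mean_landmarks.csv")
  dimnames(lm) <- list(NULL, c("x", "y"))
  tri <- rd("triangles.csv")
  storage.mode(tri) <- "integer"
  dimnames(tri) <- NULL
  structure(list(
    mean_landmarks = lm,
    shape_basis = unname(rd("shape_basis.csv")),
    shape_scale = scales$shape_scale,
    mean_texture = unname(rd("mean_texture.csv")),
    appearance_basis = unname(rd("appearance_basis.csv")),
    appearance_scale = scales$appearance_scale,
    triangles = tri, view = side$view,
    n_shape = side$n_shape, n_appearance = side$n_appearance,
    canvas = side$canvas, n_train = side$n_train
  ), class = "face_space_model")
}

#' Write a response matrix as CSV (units x stimuli)
#' @param responses a [response_matrix()]
#' @param path CSV path
#' @return invisibly, `path`
#' @export
write_response_matrix <- function(responses, path) {
  df <- as.data.frame(unclass(responses))
  names(df) <- paste0("s", attr(responses, "stimulus_ids"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
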