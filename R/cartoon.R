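# Cartoon face stimuli for the facial-geometry tuning experiment.
#
# Each cartoon face has seven elementary parts (hair, face outline, eyes,
# irises, eyebrows, mouth, nose) whose geometry is controlled by 19 named
# parameters, each taking one of the 11 grid values -5, -4, ..., +5; zero is
# the average face and +/-5 the extreme features.

#' Grid values allowed for each cartoon parameter
#' @return integer vector -5..5
#' @export
cartoon_grid <- function() -5:5

#' Construct a validated cartoon parameter vector
#'
#' @param values numeric vector of length 19, each value on the grid
#'   `-5, -4, ..., +5`; may be named with [cartoon_param_names()]
#' @return an object of class `cartoon_params`
#' @export
cartoon_params <- function(values) {
  if (length(values) != 19) {
    stop("cartoon parameters must have length 19, got ", length(values))
  }
  if (any(!is.finite(values)) || any(values < -5 | values > 5)) {
    stop("cartoon parameter values must lie within [-5, 5]")
  }
  if (any(abs(values - round(values)) > 1e-9)) {
    stop("cartoon parameter values must be on the integer grid -5..5")
  }
  values <- as.numeric(round(values))
  names(values) <- cartoon_param_names()
  structure(values, class = "cartoon_params")
}

#' Render a cartoon face
#'
#' Deterministic rasterization of a 19-parameter cartoon face on the 224x224
#' canvas; the all-zero vector renders the mean face. Parameter effects are
#' geometrically monotone (e.g. a larger inter-eye distance value strictly
#' increases the rendered pupil separation).
#'
#' @param p a [cartoon_params()] vector (or numeric length 19 on the grid)
#' @param size canvas side in pixels
#' @return numeric matrix in `[0,1]`
#' @export
render_cartoon <- function(p, size = CANVAS_SIZE) {
  if (!inherits(p, "cartoon_params")) p <- cartoon_params(p)
  geom <- face_geometry(as.numeric(p), view = "frontal", size = size)
  render_face_geometry(geom)
}

#' Sample a random cartoon stimulus set
#'
#' Each of the 19 parameters is drawn independently and uniformly from the
#' 11-value grid; the drawn parameter vector is stored in the metadata
#' (columns `p01` ... `p19`, named after [cartoon_param_names()] in
#' `attr(meta, "param_names")`).
#'
#' @param n number of images
#' @param seed integer seed
#' @param render if `FALSE`, images are left `NULL` and only metadata is
#'   produced (useful when only the design matrix is needed)
#' @return a [stimulus_set()]
#' @export
sample_cartoon_set <- function(n, seed = 1, render = TRUE) {
  stopifnot(n >= 1)
  pm <- with_seed(seed, matrix(sample(cartoon_grid(), n * 19, replace = TRUE),
                               nrow = n, ncol = 19))
  colnames(pm) <- sprintf("p%02d", 1:19)
  images <- vector("list", n)
  if (render) {
    for (i in seq_len(n)) images[[i]] <- render_cartoon(pm[i, ])
  }
  meta <- data.frame(image_id = seq_len(n), identity = NA_integer_,
                     view = "frontal", size_px = CANVAS_SIZE,
                     category = "cartoon")
  meta <- cbind(meta, as.data.frame(pm))
  attr(meta, "param_names") <- cartoon_param_names()
  stimulus_set(images, meta)
}

# Columns of a stimulus-set metadata table holding cartoon parameters.
cartoon_param_columns <- function(meta) {
  cols <- sprintf("p%02d", 1:19)
  if (!all(cols %in% names(meta))) {
    stop("metadata lacks the 19 cartoon parameter columns p01..p19")
  }
  cols
}
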