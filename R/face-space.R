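# The 50-dimensional shape-appearance face space.
#
# Following the active-appearance-model construction: the first 25 principal
# components of the landmark coordinates give the shape dimensions; each image
# is then morphed so its landmarks match the mean landmarks, and the first 25
# principal components of the shape-normalized images give the appearance
# dimensions. Feature values are expressed in SD units of the training
# distribution, so sampling from an isotropic standard Gaussian spans natural
# variation.

#' Fit a shape-appearance face space
#'
#' @param dataset list of [annotated_image()] with a consistent landmark count
#' @param n_shape,n_appearance number of retained shape / appearance PCs
#' @param view view label stored with the model
#' @return an object of class `face_space_model` with fields
#'   `mean_landmarks`, `shape_basis` (2K x n_shape), `shape_scale`,
#'   `mean_texture`, `appearance_basis` (pixels x n_appearance),
#'   `appearance_scale`, `triangles`, `view`
#' @export
fit_face_space <- function(dataset, n_shape = 25, n_appearance = 25,
                           view = "frontal") {
  stopifnot(length(dataset) >= n_shape + 1)
  k <- nrow(dataset[[1]]$landmarks)
  lm_mat <- t(vapply(dataset, function(im) {
    if (nrow(im$landmarks) != k) stop("inconsistent landmark counts")
    as.numeric(im$landmarks)
  }, numeric(2 * k)))
  mean_lm <- matrix(colMeans(lm_mat), k, 2,
                    dimnames = list(NULL, c("x", "y")))

  shape <- principal_basis(lm_mat, n_shape, "shape")

  triangles <- delaunay_triangulation(rbind(mean_lm, canvas_anchors()))
  warped <- vapply(dataset, function(im) {
    as.numeric(warp_image(im$pixels, im$landmarks, mean_lm, triangles))
  }, numeric(length(dataset[[1]]$pixels)))
  warped <- t(warped)
  appearance <- principal_basis(warped, n_appearance, "appearance")

  structure(list(
    mean_landmarks = mean_lm,
    shape_basis = shape$basis, shape_scale = shape$scale,
    mean_texture = matrix(appearance$center, nrow(dataset[[1]]$pixels)),
    appearance_basis = appearance$basis, appearance_scale = appearance$scale,
    triangles = triangles, view = view,
    n_shape = n_shape, n_appearance = n_appearance,
    canvas = nrow(dataset[[1]]$pixels), n_train = length(dataset)
  ), class = "face_space_model")
}

# PCA helper returning an orthonormal basis with deterministic signs (largest
# |loading| positive) and per-PC scales (training SDs).
principal_basis <- function(X, n_pc, what) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0, nv = min(nrow(X), ncol(X)))
  scale <- sv$d / sqrt(nrow(X) - 1)
  tol <- max(scale) * 1e-8
  achievable <- sum(scale > tol)
  if (achievable < n_pc) {
    stop("rank deficiency in the ", what, " data: only ", achievable,
         " components with nonzero variance are achievable, ", n_pc,
         " requested")
  }
  basis <- sv$v[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    if (basis[which.max(abs(basis[, j])), j] < 0) basis[, j] <- -basis[, j]
  }
  list(center = center, basis = basis, scale = scale[seq_len(n_pc)])
}

#' @export
print.face_space_model <- function(x, ...) {
  cat(sprintf(
    "<face_space_model> view '%s': %d shape + %d appearance dims (%d train)\n",
    x$view, x$n_shape, x$n_appearance, x$n_train))
  invisible(x)
}

#' Warp an annotated image to the mean landmark configuration
#'
#' @param img an [annotated_image()]
#' @param model a [face_space_model()] (or a landmark matrix)
#' @return shape-normalized raster
#' @export
warp_to_mean <- function(img, model) {
  mean_lm <- if (inherits(model, "face_space_model")) model$mean_landmarks
  else model
  tri <- if (inherits(model, "face_space_model")) model$triangles else NULL
  warp_image(img$pixels, img$landmarks, mean_lm, tri)
}

#' Sample feature vectors from the isotropic standard Gaussian
#'
#' @param n number of vectors
#' @param seed integer seed
#' @param dim dimensionality (default 50)
#' @return n x dim matrix
#' @export
sample_feature_vectors <- function(n, seed = 1, dim = 50) {
  stopifnot(n >= 1)
  with_seed(seed, matrix(stats::rnorm(n * dim), n, dim))
}

#' Reconstruct a face image from a feature vector
#'
#' Shape dimensions synthesize the target landmarks, appearance dimensions
#' synthesize the shape-normalized texture, and the texture is warped from
#' the mean configuration to the target landmarks.
#'
#' @param model a [face_space_model()]
#' @param f numeric feature vector (shape dims first)
#' @return an [annotated_image()] carrying the synthesized landmarks
#' @export
reconstruct_image <- function(model, f) {
  ns <- model$n_shape
  stopifnot(length(f) == ns + model$n_appearance, all(is.finite(f)))
  lm_vec <- as.numeric(model$mean_landmarks) +
    as.numeric(model$shape_basis %*% (f[1:ns] * model$shape_scale))
  k <- nrow(model$mean_landmarks)
  lm <- matrix(lm_vec, k, 2, dimnames = list(NULL, c("x", "y")))
  off <- which(lm[, 1] < 0 | lm[, 1] > model$canvas - 1 |
                 lm[, 2] < 0 | lm[, 2] > model$canvas - 1)
  if (length(off)) {
    stop("synthesized landmarks leave the canvas at indices: ",
         paste(off, collapse = ", "))
  }
  tex_vec <- as.numeric(model$mean_texture) +
    as.numeric(model$appearance_basis %*%
                 (f[(ns + 1):length(f)] * model$appearance_scale))
  tex <- matrix(tex_vec, model$canvas)
  pixels <- warp_image(tex, model$mean_landmarks, lm, model$triangles)
  annotated_image(pixels, lm)
}

#' Project an annotated image into the face space
#'
#' Shape dimensions are the scaled shape-PC coordinates of the landmarks;
#' appearance dimensions are the scaled appearance-PC coordinates of the
#' shape-normalized image.
#'
#' @param model a [face_space_model()]
#' @param img an [annotated_image()]
#' @return numeric feature vector of length `n_shape + n_appearance`
#' @export
project_image <- function(model, img) {
  lm_c <- as.numeric(img$landmarks) - as.numeric(model$mean_landmarks)
  f_shape <- as.numeric(crossprod(model$shape_basis, lm_c)) / model$shape_scale
  warped <- warp_to_mean(img, model)
  tex_c <- as.numeric(warped) - as.numeric(model$mean_texture)
  f_app <- as.numeric(crossprod(model$appearance_basis, tex_c)) /
    model$appearance_scale
  c(f_shape, f_app)
}

#' Fit an affine map between two face spaces
#'
#' Least-squares regression from source-view feature vectors to frontal-view
#' feature vectors of the same identities.
#'
#' @param source n x d matrix of source-view feature vectors
#' @param target n x d matrix of frontal-view feature vectors (same row order)
#' @param source_view,target_view labels stored with the map
#' @return an object of class `cross_view_map` with `matrix` (d x d),
#'   `offset` (d), and a residual RMSE summary
#' @export
fit_cross_view_map <- function(source, target, source_view = "profile",
                               target_view = "frontal") {
  stopifnot(is.matrix(source), is.matrix(target),
            nrow(source) == nrow(target), ncol(source) == ncol(target))
  d <- ncol(source)
  if (nrow(source) < d + 1) {
    stop("underdetermined fit: ", nrow(source), " identity pairs for ",
         d, " dimensions; need at least ", d + 1)
  }
  X <- cbind(1, source)
  fit <- stats::lm.fit(X, target)
  coefs <- fit$coefficients
  resid <- target - X %*% coefs
  structure(list(matrix = t(coefs[-1, , drop = FALSE]),
                 offset = as.numeric(coefs[1, ]),
                 residual_rmse = sqrt(mean(resid^2)),
                 source_view = source_view, target_view = target_view),
            class = "cross_view_map")
}

#' Apply a cross-view map to feature vectors
#'
#' @param map a [fit_cross_view_map()] result
#' @param f matrix of source-view feature vectors (rows) or a single vector
#' @return mapped feature vectors in the target (frontal) space
#' @export
apply_cross_view_map <- function(map, f) {
  if (is.null(dim(f))) f <- matrix(f, 1)
  res <- f %*% t(map$matrix)
  sweep(res, 2, map$offset, `+`)
}

#' @export
print.cross_view_map <- function(x, ...) {
  cat(sprintf("<cross_view_map> %s -> %s, residual RMSE %.4g\n",
              x$source_view, x$target_view, x$residual_rmse))
  invisible(x)
}
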