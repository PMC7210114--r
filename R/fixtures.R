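# Synthetic fixtures: procedurally rendered annotated faces, multi-view face
# sets, selectivity probes, and designed unit populations with known ground
# truth. These stand in for the external image databases a physiology-style
# protocol would otherwise require, so that every downstream analysis can be
# exercised end to end with exact landmarks and known tuning.

#' Create a synthetic face identity
#'
#' An identity is a deterministic function of `(id, seed)`: 19 facial geometry
#' parameters, a set of texture knobs (tones and smooth shading), and
#' coefficients of a smooth landmark deformation basis that gives identities
#' richer shape variation than the geometry knobs alone.
#'
#' @param id integer identity label
#' @param seed integer seed shared by a dataset
#' @return an object of class `synthetic_face_identity`
#' @export
synthetic_face_identity <- function(id, seed = 1) {
  s <- (derive_seed(seed, "faces") + 131L * as.integer(id)) %% 2147483629L
  with_seed(s, {
    geometry <- clamp(stats::rnorm(19, 0, 1.1), -3, 3)
    tones <- default_tones()
    tones$skin <- clamp(0.55 + stats::rnorm(1, 0, 0.05), 0.40, 0.72)
    tones$hair <- clamp(0.25 + stats::rnorm(1, 0, 0.06), 0.10, 0.40)
    tones$iris <- clamp(0.08 + abs(stats::rnorm(1, 0, 0.04)), 0.05, 0.22)
    texture <- list(gradient_x = stats::rnorm(1, 0, 0.12),
                    gradient_y = stats::rnorm(1, 0, 0.12),
                    wave_amp = abs(stats::rnorm(1, 0, 0.05)),
                    shading = stats::rnorm(N_SHADE))
    deform <- stats::rnorm(N_DEFORM, 0, 0.6)
    structure(list(id = as.integer(id), generator_params = geometry,
                   tones = tones, texture = texture, deform = deform),
              class = "synthetic_face_identity")
  })
}

#' Render one view of a synthetic identity
#'
#' Left-side views are produced as the exact horizontal mirror of the
#' corresponding right-side view (pixels flipped, landmark x mirrored).
#'
#' @param identity a [synthetic_face_identity()]
#' @param view one of [face_views()]
#' @return an [annotated_image()]
#' @export
render_identity <- function(identity, view = "frontal") {
  vp <- view_params(view)  # validates the label
  if (!is.null(vp$base)) {
    right <- render_identity(identity, vp$base)
    lm <- right$landmarks
    lm[, 1] <- flip_x(lm[, 1], ncol(right$pixels))
    return(annotated_image(flip_horizontal(right$pixels), lm))
  }
  geom <- face_geometry(identity$generator_params, view = view,
                        deform = identity$deform, scale = IDENTITY_SCALE)
  img <- render_face_geometry(geom, tones = identity$tones,
                              texture = identity$texture)
  annotated_image(img, geom$landmarks)
}

#' Generate a dataset of annotated faces in one view
#'
#' Every image is rendered from its identity's parameters and carries the 95
#' exact rendered control points as landmarks. Different views of the same
#' `(id, seed)` share the identity, so frontal/profile pairs are matched.
#'
#' @param n_ids number of identities (>= 2)
#' @param view one of [face_views()]
#' @param seed integer seed
#' @return list of [annotated_image()], one per identity
#' @export
make_annotated_face_dataset <- function(n_ids, view = "frontal", seed = 1) {
  stopifnot(n_ids >= 2)
  view_params(view)  # reject unknown labels up front
  lapply(seq_len(n_ids), function(i) {
    render_identity(synthetic_face_identity(i, seed), view)
  })
}

#' Generate a face-view stimulus set
#'
#' One image per (identity, view) combination; mirror-symmetric views are
#' related by an exact horizontal flip of the render.
#'
#' @param n_ids number of identities
#' @param views view labels (no duplicates), default all 8
#' @param seed integer seed
#' @return a [stimulus_set()] ordered by view group, then identity
#' @export
make_face_view_set <- function(n_ids, views = face_views(), seed = 1) {
  stopifnot(n_ids >= 1)
  if (anyDuplicated(views)) stop("duplicate view labels are not allowed")
  for (v in views) view_params(v)
  ids <- lapply(seq_len(n_ids), synthetic_face_identity, seed = seed)
  images <- list(); meta <- NULL
  for (v in views) {
    for (i in seq_len(n_ids)) {
      images[[length(images) + 1]] <- render_identity(ids[[i]], v)$pixels
    }
    meta <- rbind(meta, data.frame(identity = seq_len(n_ids), view = v))
  }
  meta$image_id <- seq_len(nrow(meta))
  meta$size_px <- CANVAS_SIZE
  meta$category <- "face"
  stimulus_set(images, meta)
}

# A structured non-face image: a smooth random texture field overlaid with a
# few random polygons. Any non-face class suffices for exercising the
# face-selectivity machinery.
object_image <- function(seed, size = CANVAS_SIZE) {
  with_seed(seed, {
    xg <- matrix(rep(0:(size - 1), each = size), size) / size
    yg <- matrix(rep(0:(size - 1), times = size), size) / size
    img <- matrix(0, size, size)
    for (k in 1:5) {
      fx <- stats::runif(1, 0.5, 4); fy <- stats::runif(1, 0.5, 4)
      ph <- stats::runif(2)
      img <- img + stats::runif(1, 0.3, 1) *
        cos(2 * pi * (fx * xg + ph[1])) * cos(2 * pi * (fy * yg + ph[2]))
    }
    img <- (img - min(img)) / (max(img) - min(img)) * 0.6 + 0.2
    n_poly <- sample(3:6, 1)
    for (k in seq_len(n_poly)) {
      cx <- stats::runif(1, 0.2, 0.8) * size
      cy <- stats::runif(1, 0.2, 0.8) * size
      nv <- sample(3:7, 1)
      angs <- sort(stats::runif(nv, 0, 2 * pi))
      rad <- stats::runif(nv, 0.06, 0.22) * size
      img <- fill_polygon(img, cx + rad * cos(angs), cy + rad * sin(angs),
                          stats::runif(1, 0.05, 0.95))
    }
    clamp(img, 0, 1)
  })
}

#' Generate the selectivity probe set
#'
#' `n_faces` rendered frontal faces, `n_objects` structured non-face images,
#' plus one all-zero blank image (the baseline stimulus), in that order.
#'
#' @param n_faces,n_objects counts (>= 1)
#' @param seed integer seed
#' @return a [stimulus_set()] with `category` in face/object/blank
#' @export
make_selectivity_probes <- function(n_faces = 50, n_objects = 50, seed = 1) {
  stopifnot(n_faces >= 1, n_objects >= 1)
  faces <- lapply(seq_len(n_faces), function(i) {
    render_identity(synthetic_face_identity(i, seed), "frontal")$pixels
  })
  oseed <- derive_seed(seed, "objects")
  objects <- lapply(seq_len(n_objects), function(i) {
    object_image((oseed + 977L * i) %% 2147483629L)
  })
  images <- c(faces, objects, list(blank_canvas()))
  meta <- data.frame(
    image_id = seq_along(images),
    identity = c(seq_len(n_faces), rep(NA, n_objects + 1)),
    view = c(rep("frontal", n_faces), rep(NA, n_objects + 1)),
    size_px = CANVAS_SIZE,
    category = c(rep("face", n_faces), rep("object", n_objects), "blank")
  )
  stimulus_set(images, meta)
}

#' Construct a designed unit
#'
#' Designed units have closed-form response functions with retrievable ground
#' truth; populations of them serve as test oracles for the tuning analyses.
#' The `shape_linear`/`appearance_linear` kinds read the stimulus's
#' ground-truth 50-D feature vector from the stimulus-set metadata (a
#' metadata oracle intended for testing, not a model of vision).
#'
#' @param kind one of `view_template`, `identity_template`, `shape_linear`,
#'   `appearance_linear`, `polarity_contrast`, `null_random`
#' @param preferred preferred view/identity label (template kinds)
#' @param kernel 50-D weight vector (linear kinds); if `NULL`, drawn at
#'   population-construction time with mass in the corresponding half
#' @param part_a,part_b,polarity mosaic part labels and sign (+1 means the
#'   unit prefers `part_a` lighter than `part_b`)
#' @param noise_sd response noise standard deviation
#' @return an object of class `designed_unit`
#' @export
designed_unit <- function(kind, preferred = NULL, kernel = NULL,
                          part_a = NULL, part_b = NULL, polarity = 1,
                          noise_sd = 0) {
  kinds <- c("view_template", "identity_template", "shape_linear",
             "appearance_linear", "polarity_contrast", "null_random")
  if (!kind %in% kinds) {
    stop("unknown designed-unit kind '", kind, "'; supported: ",
         paste(kinds, collapse = ", "))
  }
  stopifnot(noise_sd >= 0)
  structure(list(kind = kind, preferred = preferred, kernel = kernel,
                 part_a = part_a, part_b = part_b, polarity = polarity,
                 noise_sd = noise_sd),
            class = "designed_unit")
}

# Evaluate one designed unit on a stimulus set (deterministic given seed).
designed_unit_response <- function(unit, stimuli, seed) {
  n <- length(stimuli)
  meta <- stimuli$meta
  base <- switch(unit$kind,
    view_template = {
      if (is.null(meta$view)) stop("stimulus set has no view metadata")
      ifelse(!is.na(meta$view) & meta$view == unit$preferred, 1, 0.15)
    },
    identity_template = {
      if (is.null(meta$identity)) stop("stimulus set has no identity metadata")
      ifelse(!is.na(meta$identity) & meta$identity == unit$preferred, 1, 0.1)
    },
    shape_linear = ,
    appearance_linear = {
      fm <- attr(meta, "feature_matrix")
      if (is.null(fm)) {
        stop("stimulus set carries no ground-truth feature vectors; ",
             "linear designed units require them")
      }
      pmax(fm %*% unit$kernel, 0)[, 1]
    },
    polarity_contrast = {
      cols <- sprintf("i%02d", 1:11)
      if (!all(cols %in% names(meta))) {
        stop("stimulus set has no mosaic intensity metadata")
      }
      ia <- meta[[sprintf("i%02d", match(unit$part_a, mosaic_part_names()))]]
      ib <- meta[[sprintf("i%02d", match(unit$part_b, mosaic_part_names()))]]
      pmax(unit$polarity * (ia - ib), 0)
    },
    null_random = rep(0, n)
  )
  sd <- if (unit$kind == "null_random") max(unit$noise_sd, 1) else unit$noise_sd
  if (sd > 0) base <- base + with_seed(seed, stats::rnorm(n, 0, sd))
  base
}

#' Build a designed population satisfying the layered-model contract
#'
#' @param units list of [designed_unit()]
#' @param seed integer seed controlling response noise and any randomly drawn
#'   kernels
#' @return a [layered_model()] with a single layer named `"designed"`
#' @export
make_designed_population <- function(units, seed = 1) {
  stopifnot(length(units) >= 1)
  units <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    if (!inherits(u, "designed_unit")) stop("all units must be designed_unit")
    if (u$kind %in% c("shape_linear", "appearance_linear") &&
        is.null(u$kernel)) {
      u$kernel <- with_seed(derive_seed(seed, "units") + i, {
        k <- stats::rnorm(50) * 0.05
        idx <- if (u$kind == "shape_linear") 1:25 else 26:50
        k[idx] <- stats::rnorm(25)
        k / sqrt(sum(k^2))
      })
    }
    u
  })
  unit_seeds <- derive_seed(seed, "units") + 7L * seq_along(units)
  layered_model(
    layer_names = "designed",
    n_units = length(units),
    input_size = CANVAS_SIZE,
    activate = function(stimuli, unit_filter = NULL) {
      idx <- if (is.null(unit_filter)) seq_along(units) else unit_filter
      vals <- vapply(idx, function(i) {
        designed_unit_response(units[[i]], stimuli, unit_seeds[i])
      }, numeric(length(stimuli)))
      list(designed = t(matrix(vals, ncol = length(idx))))
    },
    meta = list(units = units)
  )
}
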