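# The layered-model activation contract, an untrained CNN fixture, response
# recording, and face-selective population extraction.

#' Construct a layered model
#'
#' The activation contract: `activate(stimuli, unit_filter = NULL)` maps a
#' [stimulus_set()] to a named list of units x stimuli matrices, one per
#' layer, deterministic given the model's weights/seed, with constant unit
#' counts across stimulus sets.
#'
#' @param layer_names ordered layer names
#' @param n_units integer vector of per-layer unit counts
#' @param activate the activation function
#' @param input_size expected canvas side in pixels
#' @param meta optional list of model details
#' @return an object of class `layered_model`
#' @export
layered_model <- function(layer_names, n_units, activate,
                          input_size = CANVAS_SIZE, meta = list()) {
  stopifnot(is.character(layer_names), is.function(activate))
  n_units <- rep_len(n_units, length(layer_names))
  structure(list(layer_names = layer_names, n_units = n_units,
                 activate = activate, input_size = input_size, meta = meta),
            class = "layered_model")
}

#' @export
print.layered_model <- function(x, ...) {
  cat(sprintf("<layered_model> %d layers: %s\n", length(x$layer_names),
              paste(sprintf("%s(%d)", x$layer_names, x$n_units),
                    collapse = ", ")))
  invisible(x)
}

#' Record model responses to a stimulus set
#'
#' @param model a [layered_model()]
#' @param stimuli a [stimulus_set()] on the model's input canvas
#' @param units optional named list (per layer) of unit indices to retain
#' @return named list of [response_matrix()], one per layer, with columns in
#'   stimulus order
#' @export
probe <- function(model, stimuli, units = NULL) {
  stopifnot(inherits(model, "layered_model"), inherits(stimuli, "stimulus_set"))
  imgs <- stimuli$images
  if (length(imgs) && !is.null(imgs[[1]])) {
    sz <- dim(imgs[[1]])
    if (any(sz != model$input_size)) {
      stop("stimulus canvas ", sz[1], "x", sz[2],
           " does not match the model input size ", model$input_size, "x",
           model$input_size)
    }
  }
  acts <- model$activate(stimuli, unit_filter = units)
  out <- list()
  for (li in seq_along(model$layer_names)) {
    ln <- model$layer_names[li]
    m <- acts[[ln]]
    want <- if (!is.null(units) && !is.null(units[[ln]])) units[[ln]] else NULL
    if (!is.null(want) && nrow(m) == model$n_units[li]) {
      m <- m[want, , drop = FALSE]  # model ignored the filter; subset here
    }
    out[[ln]] <- response_matrix(m, layer = ln,
                                 stimulus_ids = stimuli$meta$image_id)
  }
  out
}

#' Face-selectivity index and face-selective unit extraction
#'
#' FSI = (Rf - Ro) / (Rf + Ro) on baseline-subtracted mean responses, where
#' the baseline is the response to the all-zero blank image. FSI is clamped
#' to +1 when Rf > 0 and Ro < 0, and to -1 when Rf < 0 and Ro > 0. Units with
#' both means <= 0 are unresponsive: their FSI is undefined (NA) and they are
#' never selected. A unit is selected when FSI > 1/3 (strict).
#'
#' @param face_responses units x n_face matrix (or vector of per-unit means)
#' @param object_responses units x n_object matrix (or vector)
#' @param baseline_response per-unit response to the blank image
#' @param threshold selection threshold (default 1/3)
#' @return a data.frame with columns `fsi`, `r_face_mean`, `r_object_mean`,
#'   `selected`
#' @export
compute_fsi <- function(face_responses, object_responses, baseline_response,
                        threshold = 1 / 3) {
  as_means <- function(x, what) {
    if (is.null(x) || length(x) == 0) stop("empty ", what, " responses")
    if (is.matrix(x)) rowMeans(x) else as.numeric(x)
  }
  rf <- as_means(face_responses, "face") - baseline_response
  ro <- as_means(object_responses, "object") - baseline_response
  if (length(rf) != length(ro)) stop("unit counts differ between face and object responses")
  fsi <- ifelse(rf + ro == 0, NA_real_, (rf - ro) / (rf + ro))
  fsi[rf > 0 & ro < 0] <- 1
  fsi[rf < 0 & ro > 0] <- -1
  fsi[rf <= 0 & ro <= 0] <- NA_real_   # unresponsive: FSI undefined
  fsi <- clamp(fsi, -1, 1)
  data.frame(fsi = fsi, r_face_mean = rf, r_object_mean = ro,
             selected = !is.na(fsi) & fsi > threshold)
}

#' Select face-selective units of every layer
#'
#' Probes the model with a selectivity set (faces, objects, and one blank)
#' and applies [compute_fsi()] per layer.
#'
#' @param model a [layered_model()]
#' @param probes a [stimulus_set()] from [make_selectivity_probes()]
#' @param cap optional maximum number of selected units kept per layer
#'   (random subsample, seeded); mirrors capping very wide layers
#' @param seed seed for the subsample
#' @return named list per layer: `fsi` table and `selected` unit indices
#' @export
select_face_units <- function(model, probes, cap = Inf, seed = 1) {
  resp <- probe(model, probes)
  face_idx <- which(probes$meta$category == "face")
  obj_idx <- which(probes$meta$category == "object")
  blank_idx <- which(probes$meta$category == "blank")
  if (length(blank_idx) != 1) stop("probe set must contain exactly one blank image")
  lapply(resp, function(m) {
    tab <- compute_fsi(m[, face_idx, drop = FALSE],
                       m[, obj_idx, drop = FALSE],
                       m[, blank_idx])
    sel <- which(tab$selected)
    if (length(sel) > cap) {
      sel <- sort(with_seed(derive_seed(seed, "units"),
                            sample(sel, cap)))
    }
    list(fsi = tab, selected = sel, layer = attr(m, "layer"))
  })
}

# ---- untrained CNN fixture -------------------------------------------------

# im2col patch-index matrix for a H x W x C input, kernel k, stride s.
im2col_indices <- function(h, w, ch, k, s) {
  oh <- (h - k) %/% s + 1L; ow <- (w - k) %/% s + 1L
  # offsets within a patch (column-major within channel, channels stacked)
  off <- as.integer(outer(
    as.integer(outer(0:(k - 1), (0:(k - 1)) * h, `+`)),
    (0:(ch - 1)) * h * w, `+`))
  starts <- as.integer(outer((0:(oh - 1)) * s, (0:(ow - 1)) * s * h, `+`))
  idx <- outer(starts, off, `+`) + 1L
  list(idx = idx, oh = oh, ow = ow)
}

max_pool <- function(a_mat, oh, ow, nf, p = 2L) {
  ph <- oh %/% p; pw <- ow %/% p
  x <- array(a_mat, c(oh, ow, nf))
  if (ph < 1 || pw < 1) return(list(x = x, oh = oh, ow = ow))
  ri <- (seq_len(ph) - 1L) * p + 1L
  ci <- (seq_len(pw) - 1L) * p + 1L
  out <- x[ri, ci, , drop = FALSE]
  for (dy in 0:(p - 1)) for (dx in 0:(p - 1)) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, x[ri + dy, ci + dx, , drop = FALSE])
  }
  list(x = out, oh = ph, ow = pw)
}

#' An untrained convolutional network fixture
#'
#' A random-weight convolution / ReLU / max-pool stack with growing receptive
#' fields; weights are reproducible from the seed. Every spatial unit of every
#' feature map is exposed as a distinct unit.
#'
#' @param depth number of convolutional layers (>= 2)
#' @param widths channel counts per layer (recycled to `depth`)
#' @param seed integer seed for the weights
#' @param input_size canvas side in pixels
#' @param kernels,strides,pools per-layer kernel sizes, strides and pooling
#'   factors (recycled)
#' @return a [layered_model()]
#' @export
untrained_cnn_fixture <- function(depth = 4, widths = c(12, 24, 32, 48),
                                  seed = 1, input_size = CANVAS_SIZE,
                                  kernels = c(11, 5, 3, 3),
                                  strides = c(4, 1, 1, 1),
                                  pools = c(2, 2, 1, 1)) {
  stopifnot(depth >= 2)
  if (length(widths) > depth) {
    stop("more widths (", length(widths), ") than layers (", depth, ")")
  }
  widths <- rep_len(widths, depth)
  kernels <- rep_len(kernels, depth)
  strides <- rep_len(strides, depth)
  pools <- rep_len(as.integer(pools), depth)

  # resolve layer geometry and draw weights
  layers <- list()
  h <- input_size; w <- input_size; ch <- 1L
  wseed <- derive_seed(seed, "model")
  for (l in seq_len(depth)) {
    k <- kernels[l]; s <- strides[l]
    if (h < k || w < k) stop("layer ", l, ": feature map smaller than kernel")
    ic <- im2col_indices(h, w, ch, k, s)
    fan_in <- k * k * ch
    wts <- with_seed(wseed + l, list(
      W = matrix(stats::rnorm(fan_in * widths[l], 0, sqrt(2 / fan_in)),
                 fan_in, widths[l]),
      b = stats::rnorm(widths[l], 0, 0.1)))
    layers[[l]] <- list(ic = ic, W = wts$W, b = wts$b, pool = pools[l],
                        nf = widths[l])
    pooled <- if (pools[l] > 1) {
      c(ic$oh %/% pools[l], ic$ow %/% pools[l])
    } else c(ic$oh, ic$ow)
    h <- pooled[1]; w <- pooled[2]; ch <- widths[l]
    layers[[l]]$out_h <- h; layers[[l]]$out_w <- w
  }
  layer_names <- sprintf("layer%d", seq_len(depth))
  n_units <- vapply(layers, function(l) l$out_h * l$out_w * l$nf, numeric(1))

  forward_one <- function(img) {
    x <- array(img, c(dim(img), 1))
    outs <- vector("list", depth)
    for (l in seq_len(depth)) {
      ly <- layers[[l]]
      patches <- matrix(x[ly$ic$idx], nrow(ly$ic$idx))
      a <- pmax(sweep(patches %*% ly$W, 2, ly$b, `+`), 0)
      if (ly$pool > 1) {
        pl <- max_pool(a, ly$ic$oh, ly$ic$ow, ly$nf, ly$pool)
        x <- pl$x
      } else {
        x <- array(a, c(ly$ic$oh, ly$ic$ow, ly$nf))
      }
      outs[[l]] <- as.numeric(x)
    }
    outs
  }

  layered_model(
    layer_names = layer_names,
    n_units = n_units,
    input_size = input_size,
    meta = list(depth = depth, widths = widths, seed = seed),
    activate = function(stimuli, unit_filter = NULL) {
      n <- length(stimuli)
      keep <- lapply(seq_len(depth), function(l) {
        f <- unit_filter[[layer_names[l]]]
        if (is.null(f)) seq_len(n_units[l]) else f
      })
      res <- lapply(seq_len(depth), function(l) {
        matrix(0, length(keep[[l]]), n)
      })
      for (i in seq_len(n)) {
        outs <- forward_one(stimuli$images[[i]])
        for (l in seq_len(depth)) res[[l]][, i] <- outs[[l]][keep[[l]]]
      }
      names(res) <- layer_names
      res
    }
  )
}

#' Measure a unit's receptive-field footprint by occlusion
#'
#' Gradient-free probe: slides a gray occluding patch over a reference image
#' and reports the fraction of the canvas where occlusion changes the summed
#' layer response.
#'
#' @param model a [layered_model()]
#' @param layer layer name
#' @param img reference raster (defaults to a fixed noise image)
#' @param patch occluder side in pixels
#' @param step stride of the occluder grid
#' @return fraction of probed positions with a response change
#' @export
occlusion_footprint <- function(model, layer, img = NULL, patch = 32,
                                step = 32) {
  size <- model$input_size
  if (is.null(img)) {
    img <- with_seed(7, matrix(stats::runif(size * size), size, size))
  }
  base_set <- stimulus_set(list(img), data.frame(image_id = 1))
  ref <- model$activate(base_set)[[layer]][, 1]
  pos <- seq(1, size - patch + 1, by = step)
  changed <- 0; total <- 0
  for (py in pos) for (px in pos) {
    occ <- img
    occ[py:(py + patch - 1), px:(px + patch - 1)] <- 0.5
    a <- model$activate(stimulus_set(list(occ),
                                     data.frame(image_id = 1)))[[layer]][, 1]
    total <- total + 1
    if (sum(abs(a - ref)) > 1e-9) changed <- changed + 1
  }
  changed / total
}
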