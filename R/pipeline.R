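# End-to-end orchestration: generate -> probe -> select -> analyze -> compare,
# from a single declarative configuration with per-stage seeds.

#' Default run configuration
#'
#' The default cardinalities follow the physiology protocols: a 25-identity x
#' 8-view face-view set, 50 + 50 selectivity probes plus one blank, a 7-step
#' size ladder from 224 down to 56 px, a face space trained on 200 annotated
#' faces per view with 2000 sampled faces, 5000 cartoon faces, and a
#' 432-image covering mosaic set.
#'
#' @param seed root seed; every stage derives its own stream from it
#' @param ... overrides of the default fields
#' @return an object of class `run_config`
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_identities = 25,
    views = face_views(),
    n_face_probes = 50, n_object_probes = 50,
    size_ladder = c(224, 196, 168, 140, 112, 84, 56),
    ladder_n_face_ids = 8, ladder_n_objects = 16,
    face_space_train = 200, face_space_samples = 2000,
    profile_view = "right_profile",
    cartoon_n = 5000,
    mosaic_n = 432,
    units_cap = 100,
    sta_dims = NULL,
    n_perm = 1000, alpha = 0.01,
    n_null = 1000, n_boot = 200,
    metrics = c("view_identity", "size_invariance", "shape_appearance",
                "view_tolerance", "facial_geometry", "contrast_polarity"),
    model = list(type = "untrained_cnn", depth = 4,
                 widths = c(12, 24, 32, 48)),
    references = list(),
    output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a [run_config()] (or plain list)
#' @return character vector of all problems found (length 0 when valid)
#' @export
validate_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  pos <- function(field) {
    v <- config[[field]]
    chk(is.numeric(v) && length(v) == 1 && is.finite(v) && v >= 1,
        paste0(field, " must be a positive count"))
  }
  for (f in c("n_identities", "n_face_probes", "n_object_probes",
              "ladder_n_face_ids", "ladder_n_objects", "face_space_train",
              "face_space_samples", "cartoon_n", "mosaic_n", "n_perm",
              "n_null", "n_boot")) pos(f)
  bad_views <- setdiff(config$views, face_views())
  chk(length(bad_views) == 0,
      paste0("unknown views: ", paste(bad_views, collapse = ", ")))
  chk(!anyDuplicated(config$views), "duplicate views in config")
  chk(all(config$size_ladder >= 1 & config$size_ladder <= CANVAS_SIZE),
      "size ladder entries must lie in [1, 224]")
  known_metrics <- c("view_identity", "size_invariance", "shape_appearance",
                     "view_tolerance", "facial_geometry", "contrast_polarity")
  bad <- setdiff(config$metrics, known_metrics)
  chk(length(bad) == 0,
      paste0("unknown metric name(s): ", paste(bad, collapse = ", "),
             "; known metrics: ", paste(known_metrics, collapse = ", ")))
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha must lie in (0, 1)")
  if (!is.null(config$model) && is.list(config$model)) {
    chk(identical(config$model$type, "untrained_cnn"),
        "model$type must be 'untrained_cnn' (or pass a layered_model to run_pipeline)")
  }
  chk(config$profile_view %in% face_views(), "unknown profile_view")
  errs
}

# Build the model named by the config.
config_model <- function(config) {
  m <- config$model
  untrained_cnn_fixture(
    depth = if (is.null(m$depth)) 4 else m$depth,
    widths = if (is.null(m$widths)) c(12, 24, 32, 48) else m$widths,
    seed = derive_seed(config$seed, "model"))
}

#' Run the full benchmark pipeline
#'
#' Generates the stimulus sets, probes the model, extracts face-selective
#' populations, computes every enabled tuning metric, compares against the
#' available references, and (when `output_dir` is set) writes per-metric
#' outputs, the comparison report, and a manifest with seeds and content
#' hashes. Rerunning with the same configuration reproduces identical
#' metric outputs.
#'
#' @param config a [run_config()]
#' @param model optional [layered_model()] overriding `config$model`
#' @param quiet suppress progress messages
#' @return list with `selection`, `metrics`, `report`, `manifest`
#' @export
run_pipeline <- function(config = run_config(), model = NULL, quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  if (is.null(model)) model <- config_model(config)
  manifest <- list(config = unclass(config),
                   seeds = list(root = seed),
                   status = list())
  metrics <- list()
  layer_rows <- stats::setNames(vector("list", length(model$layer_names)),
                                model$layer_names)
  for (ln in model$layer_names) layer_rows[[ln]] <- list()
  refs <- list()

  # ---- selection --------------------------------------------------------
  say("stage select: %d+%d probes", config$n_face_probes, config$n_object_probes)
  probes <- make_selectivity_probes(config$n_face_probes,
                                    config$n_object_probes,
                                    seed = derive_seed(seed, "stimuli"))
  selection <- select_face_units(model, probes, cap = Inf)
  blank_resp <- probe(model, stimulus_set(
    probes$images[length(probes)], probes$meta[length(probes), , drop = FALSE]))
  selected <- lapply(selection, function(s) s$selected)
  capped <- lapply(selected, function(idx) {
    if (length(idx) > config$units_cap) {
      sort(with_seed(derive_seed(seed, "units"), sample(idx, config$units_cap)))
    } else idx
  })
  for (ln in model$layer_names) {
    say("  %s: %d/%d face-selective units (cap %d for unit-level analyses)",
        ln, length(selected[[ln]]), nrow(selection[[ln]]$fsi),
        length(capped[[ln]]))
  }
  metrics$selection <- lapply(selection, function(s) s$fsi)
  usable <- vapply(selected, function(x) length(x) >= 3, logical(1))
  manifest$status$selection <- "ok"

  enabled <- function(m) m %in% config$metrics

  # ---- view-identity tuning --------------------------------------------
  if (enabled("view_identity")) {
    say("stage view_identity: %d ids x %d views", config$n_identities,
        length(config$views))
    fv <- make_face_view_set(config$n_identities, config$views,
                             seed = derive_seed(seed, "stimuli"))
    fv_resp <- probe(model, fv, units = selected)
    metrics$rsm <- list()
    for (ln in model$layer_names[usable]) {
      rsm <- compute_rsm(fv_resp[[ln]], fv$meta, view_order = config$views)
      metrics$rsm[[ln]] <- rsm
      if (!is.null(config$references$rsm)) {
        for (patch in names(config$references$rsm)) {
          ref <- config$references$rsm[[patch]]
          cc <- rsm_correlation(rsm, ref)
          nb <- random_rsm_null(ref, n = config$n_null,
                                seed = derive_seed(seed, "null"))
          key <- paste0("rsm_correlation_", patch)
          layer_rows[[ln]][[key]] <- list(value = cc, band = nb$band)
          refs[[key]] <- list(value = 1, patch = patch,
                              provenance = "user_supplied")
        }
      }
    }
    rm(fv, fv_resp)
    gc(FALSE)
    manifest$status$view_identity <- "ok"
  }

  # ---- size invariance --------------------------------------------------
  if (enabled("size_invariance")) {
    say("stage size_invariance: ladder of %d sizes", length(config$size_ladder))
    base_faces <- make_face_view_set(
      config$ladder_n_face_ids,
      c("frontal", "left_profile", "right_profile"),
      seed = derive_seed(seed, "faces"))
    oseed <- derive_seed(seed, "objects") + 5000L
    objs <- lapply(seq_len(config$ladder_n_objects), function(i) {
      object_image((oseed + 31L * i) %% 2147483629L)
    })
    obj_set <- stimulus_set(objs, data.frame(
      image_id = seq_along(objs), identity = NA, view = NA,
      size_px = CANVAS_SIZE, category = "object"))
    ladder <- make_size_ladder(combine_stimulus_sets(base_faces, obj_set),
                               sizes = config$size_ladder)
    ladder_resp <- probe(model, ladder, units = selected)
    metrics$sii <- list()
    for (ln in model$layer_names[usable]) {
      bl <- blank_resp[[ln]][selected[[ln]], 1]
      prof <- compute_size_profile(ladder_resp[[ln]], ladder$meta, baseline = bl)
      sii <- compute_sii(prof, canvas = CANVAS_SIZE)
      metrics$sii[[ln]] <- list(profile = prof, sii = sii)
      layer_rows[[ln]]$sii <- sii
    }
    rm(base_faces, obj_set, ladder, ladder_resp)
    gc(FALSE)
    refs$sii <- list(value = reference_constants()$sii[["ML"]], patch = "ML/AL/AM",
                     provenance = "packaged_constant")
    manifest$status$size_invariance <- "ok"
  }

  # ---- shape-appearance & view tolerance --------------------------------
  need_space <- enabled("shape_appearance") || enabled("view_tolerance")
  if (need_space) {
    say("stage face_space: fitting on %d faces/view", config$face_space_train)
    sseed <- derive_seed(seed, "space")
    frontal_ds <- make_annotated_face_dataset(config$face_space_train,
                                              "frontal", seed = sseed)
    frontal_fs <- fit_face_space(frontal_ds, view = "frontal")
    fvecs <- sample_feature_vectors(config$face_space_samples,
                                    seed = derive_seed(seed, "sample"))
    say("  reconstructing %d frontal faces", nrow(fvecs))
    frontal_resp <- probe_chunked(model, nrow(fvecs), capped, function(idx) {
      reconstruct_set(frontal_fs, fvecs[idx, , drop = FALSE])
    })
    metrics$sta_frontal <- list()
    for (ln in model$layer_names[usable]) {
      sta <- compute_sta(frontal_resp[[ln]], fvecs)
      metrics$sta_frontal[[ln]] <- sta
      if (enabled("shape_appearance")) {
        layer_rows[[ln]]$spi_mean <- mean(sta$spi, na.rm = TRUE)
      }
    }
    if (enabled("shape_appearance")) {
      rc <- reference_constants()
      refs$spi_mean <- list(value = rc$spi_mean[["AM"]], patch = "AM",
                            provenance = "packaged_constant")
      if (!is.null(config$references$spi_samples)) {
        ci <- bootstrap_mean_ci(config$references$spi_samples,
                                n_boot = config$n_boot,
                                seed = derive_seed(seed, "boot"))
        refs$spi_mean$ci <- ci
      }
      manifest$status$shape_appearance <- "ok"
    }
    if (enabled("view_tolerance")) {
      say("  profile face space (%s)", config$profile_view)
      profile_ds <- make_annotated_face_dataset(config$face_space_train,
                                                config$profile_view,
                                                seed = sseed)
      profile_fs <- fit_face_space(profile_ds, view = config$profile_view)
      src <- t(vapply(seq_along(profile_ds), function(i) {
        project_image(profile_fs, profile_ds[[i]])
      }, numeric(50)))
      tgt <- t(vapply(seq_along(frontal_ds), function(i) {
        project_image(frontal_fs, frontal_ds[[i]])
      }, numeric(50)))
      cmap <- fit_cross_view_map(src, tgt, source_view = config$profile_view)
      rm(profile_ds, frontal_ds)
      gc(FALSE)
      pvecs <- sample_feature_vectors(config$face_space_samples,
                                      seed = derive_seed(seed, "sample") + 1L)
      say("  reconstructing %d profile faces", nrow(pvecs))
      profile_resp <- probe_chunked(model, nrow(pvecs), capped, function(idx) {
        reconstruct_set(profile_fs, pvecs[idx, , drop = FALSE])
      })
      mapped <- apply_cross_view_map(cmap, pvecs)
      metrics$sta_profile <- list()
      metrics$sta_correlation <- list()
      for (ln in model$layer_names[usable]) {
        sta_p <- compute_sta(profile_resp[[ln]], mapped)
        metrics$sta_profile[[ln]] <- sta_p
        vc <- sta_view_correlation(metrics$sta_frontal[[ln]]$sta, sta_p$sta,
                                   dims = config$sta_dims)
        metrics$sta_correlation[[ln]] <- vc
        nb <- random_sta_null(nrow(sta_p$sta), dims = config$sta_dims,
                              n = config$n_null,
                              seed = derive_seed(seed, "null"))
        layer_rows[[ln]]$sta_corr_mean <- list(value = vc$mean, band = nb$band)
      }
      metrics$cross_view_map <- cmap
      refs$sta_corr_mean <- list(
        value = reference_constants()$sta_corr_mean[["AM"]], patch = "AM",
        provenance = "packaged_constant")
      manifest$status$view_tolerance <- "ok"
    }
  }

  # ---- facial geometry ---------------------------------------------------
  if (enabled("facial_geometry")) {
    say("stage facial_geometry: %d cartoon faces", config$cartoon_n)
    cartoons <- sample_cartoon_set(config$cartoon_n,
                                   seed = derive_seed(seed, "cartoon"),
                                   render = FALSE)
    pmat <- as.matrix(cartoons$meta[sprintf("p%02d", 1:19)])
    cart_resp <- probe_chunked(model, config$cartoon_n, capped, function(idx) {
      stimulus_set(lapply(idx, function(i) render_cartoon(pmat[i, ])),
                   cartoons$meta[idx, , drop = FALSE])
    })
    metrics$tuning <- list()
    for (ln in model$layer_names[usable]) {
      tc <- estimate_tuning_curves(cart_resp[[ln]], cartoons$meta,
                                   n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   seed = derive_seed(seed, "null"))
      metrics$tuning[[ln]] <- tc
      if (!is.null(config$references$fpu)) {
        h <- fpu_histogram(tc$fpu)
        cs <- cosine_similarity(h, config$references$fpu)
        nb <- random_histogram_null("fpu", config$references$fpu,
                                    n = config$n_null,
                                    seed = derive_seed(seed, "null"))
        layer_rows[[ln]]$fpu_cosine <- list(value = cs, band = nb$band)
        refs$fpu_cosine <- list(value = 1, patch = "ML",
                                provenance = "user_supplied")
      }
      if (!is.null(config$references$upf)) {
        cs <- cosine_similarity(tc$upf, config$references$upf)
        nb <- random_histogram_null("upf", config$references$upf,
                                    n = config$n_null,
                                    seed = derive_seed(seed, "null"))
        layer_rows[[ln]]$upf_cosine <- list(value = cs, band = nb$band)
        refs$upf_cosine <- list(value = 1, patch = "ML",
                                provenance = "user_supplied")
      }
      layer_rows[[ln]]$fpu_mean <- mean(tc$fpu)
    }
    manifest$status$facial_geometry <- "ok"
  }

  # ---- contrast polarity -------------------------------------------------
  if (enabled("contrast_polarity")) {
    say("stage contrast_polarity: covering set of %d mosaics", config$mosaic_n)
    mosaics <- build_covering_set(seed = derive_seed(seed, "mosaic"),
                                  n_images = config$mosaic_n)
    mos_resp <- probe(model, mosaics, units = capped)
    mosaics$images <- vector("list", length(mosaics))
    gc(FALSE)
    metrics$polarity <- list()
    for (ln in model$layer_names[usable]) {
      pol <- polarity_preferences(mos_resp[[ln]], mosaics$meta,
                                  n_perm = config$n_perm,
                                  alpha = config$alpha,
                                  seed = derive_seed(seed, "null"))
      metrics$polarity[[ln]] <- pol
      if (!is.null(config$references$polarity)) {
        cs <- cosine_similarity(pol$histogram, config$references$polarity)
        nb <- random_histogram_null("polarity", config$references$polarity,
                                    n = config$n_null,
                                    seed = derive_seed(seed, "null"))
        layer_rows[[ln]]$polarity_cosine <- list(value = cs, band = nb$band)
        refs$polarity_cosine <- list(value = 1, patch = "ML",
                                     provenance = "user_supplied")
      }
      layer_rows[[ln]]$polarity_n_significant <- sum(pol$histogram)
    }
    manifest$status$contrast_polarity <- "ok"
  }

  # ---- report ------------------------------------------------------------
  layer_rows <- layer_rows[vapply(layer_rows, length, integer(1)) > 0]
  report <- if (length(layer_rows)) build_report(layer_rows, refs) else NULL
  result <- list(selection = selection, selected = selected, capped = capped,
                 metrics = metrics, report = report, manifest = manifest,
                 model = model)

  if (!is.null(config$output_dir)) {
    result$manifest <- write_run_outputs(result, config)
  }
  result
}

# Reconstruct a set of faces from sampled feature vectors; the ground-truth
# vectors travel in the metadata (attribute `feature_matrix`).
# Probe a large stimulus family in chunks: `make_chunk(idx)` materializes the
# stimulus_set for the given stimulus indices, which is probed and discarded,
# so at most `chunk` rendered canvases are held in memory at a time.
probe_chunked <- function(model, n, units, make_chunk, chunk = 200L) {
  res <- NULL
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- seq.int(start, min(start + chunk - 1L, n))
    part <- probe(model, make_chunk(idx), units = units)
    if (is.null(res)) {
      res <- lapply(part, function(m) matrix(0, nrow(m), n))
      names(res) <- names(part)
    }
    for (ln in names(part)) res[[ln]][, idx] <- part[[ln]]
    rm(part)
    gc(FALSE)
  }
  for (ln in names(res)) res[[ln]] <- response_matrix(res[[ln]], layer = ln)
  res
}

reconstruct_set <- function(model, fvecs) {
  images <- vector("list", nrow(fvecs))
  for (i in seq_len(nrow(fvecs))) {
    images[[i]] <- clamp(reconstruct_image(model, fvecs[i, ])$pixels, 0, 1)
  }
  meta <- data.frame(image_id = seq_len(nrow(fvecs)), identity = NA,
                     view = model$view, size_px = CANVAS_SIZE,
                     category = "face")
  attr(meta, "feature_matrix") <- fvecs
  stimulus_set(images, meta)
}

# Write report, per-metric tables and a manifest with content hashes.
write_run_outputs <- function(result, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  put <- function(path) outputs <<- c(outputs, path)

  if (!is.null(result$report)) {
    report_to_json(result$report, file.path(dir, "report.json"))
    utils::write.csv(as.data.frame(result$report),
                     file.path(dir, "report.csv"), row.names = FALSE)
    put(file.path(dir, "report.json")); put(file.path(dir, "report.csv"))
  }
  for (ln in names(result$metrics$rsm)) {
    p <- file.path(dir, sprintf("rsm_%s.csv", ln))
    utils::write.csv(as.data.frame(unclass(result$metrics$rsm[[ln]])), p,
                     row.names = FALSE)
    put(p)
  }
  summ <- list()
  for (ln in names(result$selection)) {
    summ[[ln]] <- list(
      n_units = nrow(result$selection[[ln]]$fsi),
      n_selected = length(result$selected[[ln]]),
      sii = result$metrics$sii[[ln]]$sii,
      spi_mean = if (!is.null(result$metrics$sta_frontal[[ln]])) {
        mean(result$metrics$sta_frontal[[ln]]$spi, na.rm = TRUE)
      },
      sta_corr_mean = result$metrics$sta_correlation[[ln]]$mean,
      fpu_mean = if (!is.null(result$metrics$tuning[[ln]])) {
        mean(result$metrics$tuning[[ln]]$fpu)
      })
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  put(file.path(dir, "summary.json"))

  manifest <- result$manifest
  manifest$package_version <- as.character(utils::packageVersion("fpbench"))
  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest
}
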