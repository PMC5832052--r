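#' Default pipeline parameters
#'
#' Central registry of every tunable stage parameter with its default:
#' smoothing (Perona–Malik iterations/kappa/step), region growing
#' (coefficient 0.3, 40-pixel window, 26-connectivity, hole filling),
#' classification threshold, vesselness scales/threshold, and the
#' small-region cutoff.
#'
#' @return A nested list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    smooth = list(n_iter = 10, kappa = 50, step = 0.15),
    grow = list(coefficient = 0.3, window_edge = 40, connectivity = 26,
                fill_holes = TRUE, seal_radius = 1),
    classify = list(threshold = 0.5, rco_method = "product"),
    vessel = list(scales_mm = c(1, 2, 3, 4), alpha = 0.5, beta = 0.5,
                  threshold = 0.3, mask_dilate = 2),
    postproc = list(min_voxels = 30),
    train = list(hidden = 18, max_iter = 5000,
                 fractions = c(0.70, 0.15, 0.15))
  )
}

merge_params <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]])) {
      defaults[[nm]] <- merge_params(defaults[[nm]], override[[nm]])
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

resolve_volume <- function(x, scan_id) {
  if (is.character(x)) x <- read_ct_volume(x)
  if (!inherits(x, "ct_volume")) {
    stop("each scan must be a ct_volume or a NIfTI path", call. = FALSE)
  }
  x$scan_id <- scan_id  # positional ids keep output names predictable
  x
}

process_scan <- function(volume, model, params, seed_points = NULL,
                         log = NULL) {
  note <- function(stage, txt) {
    line <- sprintf("[%s] %s: %s", volume$scan_id, stage, txt)
    message(line)
    c(log, line)
  }
  sm <- anisotropic_diffusion(volume, n_iter = params$smooth$n_iter,
                              kappa = params$smooth$kappa,
                              step = params$smooth$step)
  log <- note("smooth", sprintf("%d iterations, kappa %.0f HU",
                                params$smooth$n_iter, params$smooth$kappa))
  seeds <- if (is.null(seed_points)) {
    auto_seed_points(sm)
  } else {
    lapply(seed_points, function(s) seed_point(sm, s[1], s[2], s[3]))
  }
  if (length(seeds) == 0) stop("no usable seed points found", call. = FALSE)
  log <- note("seeds", paste(vapply(seeds, function(s) {
    sprintf("(%d,%d,%d)=%.0fHU", s$slice, s$row, s$col, s$value)
  }, ""), collapse = " "))
  lung <- segment_lungs(sm, seeds, coefficient = params$grow$coefficient,
                        window_edge = params$grow$window_edge,
                        connectivity = params$grow$connectivity,
                        fill_holes = params$grow$fill_holes,
                        seal_radius = params$grow$seal_radius)
  log <- note("lung", sprintf("%d voxels", sum(lung$bits)))
  cand <- classify_volume(model, sm, lung,
                          threshold = params$classify$threshold,
                          rco_method = params$classify$rco_method)
  log <- note("classify", sprintf("%d candidate voxels", sum(cand$bits)))
  vmask <- dilate3(lung$bits, 26L, iterations = params$vessel$mask_dilate)
  vmap <- vesselness(sm, scales_mm = params$vessel$scales_mm,
                     alpha = params$vessel$alpha, beta = params$vessel$beta,
                     mask = vmask)
  vessels <- segment_vessels(vmap, threshold = params$vessel$threshold)
  log <- note("vessels", sprintf("%d vessel voxels", sum(vessels$bits)))
  cleaned <- remove_vessels(cand, vessels)
  log <- note("remove_vessels", sprintf("%d voxels remain",
                                        sum(cleaned$bits)))
  final <- remove_small_regions(cleaned,
                                min_voxels = params$postproc$min_voxels)
  log <- note("postproc", sprintf("%d voxels in final injured mask",
                                  sum(final$bits)))
  vr <- injured_fraction(final, lung)
  log <- note("volumetrics",
              sprintf("lung %.1f ml, injured %.1f ml, fraction %.3f",
                      vr$whole_lung_ml, vr$injured_ml, vr$injured_fraction))
  list(volumetrics = vr, smoothed = sm, lung = lung, candidate = cand,
       vessel_map = vmap, vessels = vessels, injured = final, log = log)
}

#' Run the full injury-quantification pipeline
#'
#' Orchestrates smooth → segment lung → texture features → network
#' classification → vesselness → vessel removal → small-region removal →
#' volumetrics for one or two scans, and the prognostic ratio when two scans
#' are given. Every parameter and seed is recorded in the run log; reruns
#' with the same configuration are bit-reproducible.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{scans}{list of one or two scans, each a [ct_volume()] or a
#'       NIfTI path (admission first).}
#'     \item{model}{a trained `pq_ann`, or a path to a model JSON; omit to
#'       train from `training_data`.}
#'     \item{training_data}{labelled feature tibble (see [build_dataset()])
#'       used to train a model when none is supplied.}
#'     \item{seed_points}{optional list (per scan) of `(slice, row, col)`
#'       seed triples; default automatic seed proposal.}
#'     \item{seed}{RNG seed for training (default 1).}
#'     \item{params}{overrides of [pipeline_defaults()].}
#'     \item{output_dir}{optional directory for masks, reports and the log.}
#'   }
#' @return A list: `volumetrics` (tibble, one row per scan), `ratio`
#'   (`pq_ratio` tibble or `NULL` for a single scan), `scans` (per-scan
#'   intermediates), `model`, `log` (character).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), length(config$scans) >= 1,
            length(config$scans) <= 2)
  params <- merge_params(pipeline_defaults(), config$params %||% list())
  seed <- config$seed %||% 1L
  log <- c(sprintf("pqct pipeline run, seed %d, config hash %s", seed,
                   rlang::hash(config[setdiff(names(config), "scans")])))
  model <- config$model
  if (is.character(model)) model <- read_ann_model(model)
  if (is.null(model)) {
    if (is.null(config$training_data)) {
      stop("config needs either a trained model or training_data",
           call. = FALSE)
    }
    model <- train_injury_ann(config$training_data,
                              hidden = params$train$hidden,
                              max_iter = params$train$max_iter,
                              fractions = params$train$fractions,
                              seed = seed)
    log <- c(log, sprintf("trained %d-%d-1 network on %d samples",
                          nrow(model$w_hidden), ncol(model$w_hidden),
                          model$training_record$n_train))
  }
  scans <- list()
  for (i in seq_along(config$scans)) {
    res <- tryCatch({
      vol <- resolve_volume(config$scans[[i]], sprintf("scan%d", i))
      process_scan(vol, model, params,
                   seed_points = config$seed_points[[i]] %||% NULL,
                   log = character())
    },
      error = function(e) {
        stop(sprintf("scan %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    log <- c(log, res$log)
    scans[[vol$scan_id]] <- res
  }
  volumetrics <- dplyr::bind_rows(lapply(scans, `[[`, "volumetrics"))
  ratio <- NULL
  if (length(scans) == 2) {
    ratio <- fraction_ratio(scans[[1]]$volumetrics, scans[[2]]$volumetrics)
    log <- c(log, sprintf("ratio of injured lung volume fractions: %.4f",
                          ratio$ratio))
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(scans)) {
      write_mask(scans[[id]]$lung,
                 file.path(config$output_dir, paste0(id, "_lung.nii.gz")))
      write_mask(scans[[id]]$injured,
                 file.path(config$output_dir, paste0(id, "_injured.nii.gz")))
    }
    utils::write.csv(volumetrics,
                     file.path(config$output_dir, "volumetrics.csv"),
                     row.names = FALSE)
    if (!is.null(ratio)) {
      jsonlite::write_json(as.list(ratio),
                           file.path(config$output_dir, "ratio.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    writeLines(log, file.path(config$output_dir, "run_log.txt"))
  }
  list(volumetrics = volumetrics, ratio = ratio, scans = scans,
       model = model, log = log)
}
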