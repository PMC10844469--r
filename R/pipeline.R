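# End-to-end virtual experiments: configuration handling, per-cell CSV I/O,
# and orchestration of culture generation -> concentration field -> response
# simulation -> calibration -> calling -> spatial and resampling summaries.

.cell_columns <- c("cell_id", "x_um", "y_um", "nuc_intensity",
                   "cyt_intensity", "nuc_cyt_ratio", "conc_nM",
                   "ground_truth", "called", "n_neighbors", "experiment_id")

#' Default pipeline configuration
#'
#' A complete nested configuration for one virtual experiment. Modes:
#' `single_cell` anchors the dispensing point on the cell nearest the field
#' center and uses single-cell probe geometry; `cluster` dispenses at the
#' field center from the cluster geometry; `whole_culture` applies a uniform
#' bath concentration to every cell (stimulus removed by dilution wash after
#' `t_stim_min`, so no concentration field is involved).
#'
#' @param mode `"single_cell"`, `"cluster"`, or `"whole_culture"`.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A named list of config blocks (`experiment`, `culture`,
#'   `response`, `dispense`, `spatial`, `calibration`, `stats`), class
#'   `pipeline_config`.
#' @export
default_pipeline_config <- function(mode = c("single_cell", "cluster",
                                             "whole_culture"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  density <- if (mode == "whole_culture") 3750 else 400
  dispense <- switch(mode,
    single_cell = list(mode = "single_cell", c0_nM = 5500, height_um = NULL,
                       flow_m3_per_s = NULL, duration_s = 300,
                       diffusivity_m2_per_s = 5e-10, aperture_radius_um = 1),
    cluster = list(mode = "cluster", c0_nM = 318, height_um = NULL,
                   flow_m3_per_s = NULL, duration_s = 300,
                   diffusivity_m2_per_s = 5e-10, aperture_radius_um = 1),
    whole_culture = NULL
  )
  structure(list(
    experiment = list(
      mode = mode, t_stim_min = 5, seed = as.integer(seed),
      experiment_id = paste0(mode, "-", seed),
      bath_conc_nM = if (mode == "whole_culture") 100 else NULL,
      use_imaging = FALSE, output_dir = NULL,
      center_threshold_nM = 30
    ),
    culture = list(density = density, field_width = 1000,
                   field_height = 1000, cluster_rate = density / 8,
                   cluster_spread = 12),
    response = as.list(unclass(response_params())),
    dispense = dispense,
    spatial = list(neighbor_radius = 18, bin_size = 100, ring_width = 50,
                   sparse_max = 1000, dense_min = 2500),
    calibration = list(n_resting = 1000, quantile = 0.95),
    stats = list(n_boot = 2000, n_resamples = 2000)
  ), class = "pipeline_config")
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to the mode's defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment$mode)) {
    stop("config must set experiment: mode")
  }
  cfg <- default_pipeline_config(raw$experiment$mode,
                                 seed = raw$experiment$seed %||% 1L)
  for (block in names(raw)) {
    if (!block %in% names(cfg)) {
      stop("unknown config block: ", block)
    }
    for (key in names(raw[[block]])) {
      if (!key %in% names(cfg[[block]]) &&
          !(block == "dispense" && is.null(cfg$dispense))) {
        stop("unknown config key: ", block, ".", key)
      }
      cfg[[block]][[key]] <- raw[[block]][[key]]
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.config_hash <- function(config) {
  config$experiment$output_dir <- NULL # output location is not scientific
  s <- yaml::as.yaml(config)
  # small rolling hash; provenance marker, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read the canonical per-cell CSV
#'
#' Fixed column order `cell_id, x_um, y_um, nuc_intensity, cyt_intensity,
#' nuc_cyt_ratio, conc_nM, ground_truth, called, n_neighbors,
#' experiment_id`, preceded by `#`-comment header lines recording the
#' package version, seed, and config hash.
#'
#' @param cells Per-cell table.
#' @param path CSV path.
#' @param config Optional `pipeline_config` for the provenance header.
#' @param seed Seed recorded in the header.
#' @return `write_cell_table` returns `path` invisibly; `read_cell_table`
#'   returns the table.
#' @export
write_cell_table <- function(cells, path, config = NULL, seed = NA) {
  stopifnot(is.data.frame(cells))
  extra <- setdiff(.cell_columns, names(cells))
  for (col in extra) cells[[col]] <- NA
  cells <- cells[, c(.cell_columns,
                     setdiff(names(cells), .cell_columns)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fluidcell %s",
                     as.character(utils::packageVersion("fluidcell"))), con)
  writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config_hash: %s", .config_hash(config)), con)
  }
  utils::write.csv(cells, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# derive independent stage seeds from the master seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 9973L) %% 2147480017L
}

#' Run one virtual experiment end to end
#'
#' Generates a culture, builds the concentration field (or uniform bath),
#' simulates the stimulus response, calibrates an activation cutoff on an
#' independent resting companion culture, calls activation, computes
#' neighbor counts, the radial activation profile, the binned activation
#' map, and the overall / center-region fractions activated with bootstrap
#' uncertainty. Fully reproducible from the config: the same config and
#' seed give identical outputs.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @return List of class `virtual_experiment` with `cells`, `calibration`,
#'   `result` (overall `experiment_result`), `center_result` (localized
#'   modes), `target_called` (single-cell mode), `radial_profile`, `bins`,
#'   `density_class`, `field`, `config`.
#' @export
run_virtual_experiment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  exp <- config$experiment
  seed <- exp$seed
  params <- do.call(response_params, config$response)
  cc <- culture_config(
    density = config$culture$density,
    field_width = config$culture$field_width,
    field_height = config$culture$field_height,
    cluster_rate = config$culture$cluster_rate %||%
      (config$culture$density / 8),
    cluster_spread = config$culture$cluster_spread,
    seed = .stage_seed(seed, 1L)
  )
  cells <- generate_culture(cc, params)
  area_mm2 <- cc$field_width * cc$field_height / 1e6

  field <- NULL
  bath <- NULL
  target_id <- NA_integer_
  if (exp$mode == "whole_culture") {
    bath <- exp$bath_conc_nM
    if (is.null(bath)) stop("whole_culture mode requires bath_conc_nM")
  } else {
    d <- config$dispense
    cond <- dispense_conditions(
      mode = d$mode, c0_nM = d$c0_nM, height_um = d$height_um,
      flow_m3_per_s = d$flow_m3_per_s,
      duration_s = exp$t_stim_min * 60,
      diffusivity_m2_per_s = d$diffusivity_m2_per_s,
      aperture_radius_um = d$aperture_radius_um
    )
    origin <- c(0, 0)
    if (exp$mode == "single_cell" && nrow(cells) > 0) {
      # probe is positioned over a cell: target the cell nearest the center
      i <- which.min(cells$x_um^2 + cells$y_um^2)
      origin <- c(cells$x_um[i], cells$y_um[i])
      target_id <- cells$cell_id[i]
    }
    field <- concentration_field(cond, origin)
  }

  cells <- simulate_response(
    cells, t_stim_min = exp$t_stim_min, density = cc$density,
    params = params, seed = .stage_seed(seed, 2L),
    field = field, bath_conc_nM = bath
  )

  if (isTRUE(exp$use_imaging) && nrow(cells) > 0) {
    pair <- render_images(cells, seed = .stage_seed(seed, 3L),
                          field_width = cc$field_width,
                          field_height = cc$field_height)
    quant <- quantify_images(pair)
    quant <- quant[!quant$qc_excluded, , drop = FALSE]
    # re-link quantified cells to ground truth by nearest centroid
    if (nrow(quant) > 0 && nrow(cells) > 0) {
      nn <- vapply(seq_len(nrow(quant)), function(i) {
        which.min((cells$x_um - quant$x_um[i])^2 +
                    (cells$y_um - quant$y_um[i])^2)
      }, integer(1))
      quant$ground_truth <- cells$ground_truth[nn]
      quant$conc_nM <- cells$conc_nM[nn]
    }
    cells <- quant
  }

  # calibration on an independent resting companion culture
  ncal <- config$calibration$n_resting
  resting <- withr::with_seed(.stage_seed(seed, 4L), {
    stats::rlnorm(ncal, log(params$resting_log_median),
                  params$resting_log_sd)
  })
  calib <- fit_cutoff(resting, config$calibration$quantile)
  cells <- call_activation(cells, calib)

  sp <- do.call(spatial_params, config$spatial)
  cells <- neighbor_counts(cells, sp)
  cells$experiment_id <- exp$experiment_id

  labels <- list(mode = exp$mode, t_stim_min = exp$t_stim_min,
                 density = cc$density)
  result <- if (nrow(cells) > 0) {
    fraction_activated(cells, n_boot = config$stats$n_boot,
                       seed = .stage_seed(seed, 5L), labels = labels)
  } else NULL

  profile_origin <- if (!is.null(field)) field$origin else c(0, 0)
  radial <- radial_activation_profile(cells, origin = profile_origin,
                                      ring_width = sp$ring_width)
  bins <- bin_fraction_activated(cells, sp, field = field,
                                 origin = profile_origin)
  center <- NULL
  if (!is.null(field) && nrow(cells) > 0) {
    center <- center_fraction(cells, field, exp$center_threshold_nM,
                              n_boot = config$stats$n_boot,
                              seed = .stage_seed(seed, 6L), labels = labels)
  }
  target_called <- if (!is.na(target_id)) {
    isTRUE(cells$called[match(target_id, cells$cell_id)])
  } else NA

  out <- structure(list(
    cells = cells, calibration = calib, result = result,
    center_result = center, target_called = target_called,
    radial_profile = radial, bins = bins,
    density_class = density_classify(cells, area_mm2, sp),
    field = field, config = config
  ), class = "virtual_experiment")

  if (!is.null(exp$output_dir)) {
    dir.create(exp$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_table(cells, file.path(exp$output_dir, "cells.csv"),
                     config = config, seed = seed)
    utils::write.csv(radial,
                     file.path(exp$output_dir, "radial_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(bins, file.path(exp$output_dir, "bins.csv"),
                     row.names = FALSE)
    write_calibration(calib, file.path(exp$output_dir, "calibration.json"))
  }
  out
}

#' @export
print.virtual_experiment <- function(x, ...) {
  cat("Virtual experiment (", x$config$experiment$mode, "): ",
      nrow(x$cells), " cells, density class ", x$density_class, "\n",
      sep = "")
  if (!is.null(x$result)) print(x$result)
  if (!is.null(x$center_result) && !isTRUE(x$center_result$empty_center)) {
    cat("Center region: ")
    print(x$center_result)
  }
  invisible(x)
}

#' Run a panel of replicate virtual experiments
#'
#' Independent replicates of one configuration under distinct seeds, with a
#' pooled summary. For single-cell mode the pooled fraction is over the
#' target cells (one per replicate), mirroring how replicate experiments
#' are aggregated; otherwise it pools all cells.
#'
#' @param config Template `pipeline_config`.
#' @param n_replicates Number of replicates (>= 1).
#' @param seeds Optional integer seeds, one per replicate; duplicated seeds
#'   draw a warning.
#' @return List of class `replicate_panel` with `experiments`, `summary`
#'   (per-replicate table), `pooled` (pooled `experiment_result`).
#' @export
replicate_panel <- function(config, n_replicates,
                            seeds = config$experiment$seed +
                              seq_len(n_replicates) - 1L) {
  stopifnot(inherits(config, "pipeline_config"), n_replicates >= 1,
            length(seeds) == n_replicates)
  if (anyDuplicated(seeds)) warning("duplicate seeds across replicates")
  runs <- lapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$experiment$seed <- as.integer(seeds[i])
    cfg$experiment$experiment_id <-
      paste0(config$experiment$mode, "-", seeds[i])
    run_virtual_experiment(cfg)
  })
  single <- config$experiment$mode == "single_cell"
  per_rep <- do.call(rbind, lapply(runs, function(r) {
    data.frame(
      experiment_id = r$config$experiment$experiment_id,
      n_cells = nrow(r$cells),
      fraction_activated =
        if (!is.null(r$result)) r$result$fraction_activated else NA_real_,
      center_fraction = if (!is.null(r$center_result)) {
        r$center_result$fraction_activated
      } else NA_real_,
      target_called = r$target_called,
      density_class = r$density_class,
      stringsAsFactors = FALSE
    )
  }))
  pooled_calls <- if (single) {
    calls <- per_rep$target_called
    calls[!is.na(calls)]
  } else {
    unlist(lapply(runs, function(r) r$cells$called))
  }
  pooled <- if (length(pooled_calls) > 0) {
    fraction_activated(pooled_calls,
                       n_boot = config$stats$n_boot,
                       seed = .stage_seed(config$experiment$seed, 7L),
                       labels = list(mode = config$experiment$mode,
                                     pooled_over = n_replicates))
  } else NULL
  structure(list(experiments = runs, summary = per_rep, pooled = pooled),
            class = "replicate_panel")
}

#' @export
print.replicate_panel <- function(x, ...) {
  cat("Replicate panel:", nrow(x$summary), "experiments\n")
  print(x$summary)
  if (!is.null(x$pooled)) {
    cat("Pooled: ")
    print(x$pooled)
  }
  invisible(x)
}
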