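# Calibration-cutoff activation calling: a cell counts as activated when its
# nuclear/cytoplasmic reporter ratio exceeds the 95th percentile of a resting
# calibration population imaged under the same conditions.

#' Fit an activation cutoff from a resting calibration sample
#'
#' The cutoff is the empirical `quantile` (default 0.95, i.e. the top 5% of
#' the resting population) of the resting nuclear/cytoplasmic ratios, using
#' the linear-interpolation convention between order statistics
#' (`stats::quantile` type 7). Separate cutoffs are fitted per experimental
#' setup; the sample is retained in the model for provenance.
#'
#' @param resting_ratios Numeric vector of resting-population ratios; at
#'   least 20 positive values are required for a usable calibration.
#' @param quantile Calibration quantile in (0, 1).
#' @return An object of class `calibration_model` with fields
#'   `resting_sample`, `quantile`, `cutoff`.
#' @export
fit_cutoff <- function(resting_ratios, quantile = 0.95) {
  if (!is.numeric(resting_ratios) || length(resting_ratios) < 20) {
    stop("calibration needs at least 20 resting ratios")
  }
  if (anyNA(resting_ratios) || any(resting_ratios <= 0)) {
    stop("resting ratios must be positive and complete")
  }
  stopifnot(quantile > 0, quantile < 1)
  cutoff <- unname(stats::quantile(resting_ratios, quantile, type = 7))
  structure(
    list(resting_sample = resting_ratios, quantile = quantile,
         cutoff = cutoff),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Calibration model: cutoff %.4g at the %.3g quantile of %d resting cells\n",
    x$cutoff, x$quantile, length(x$resting_sample)))
  invisible(x)
}

#' Serialize / restore a calibration model
#'
#' Written as JSON with the resting sample, quantile, cutoff, and a content
#' hash of the sample for provenance.
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the restored `calibration_model` (the cutoff is re-derived from
#'   the sample and checked against the stored value).
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(
    resting_sample = model$resting_sample,
    quantile = model$quantile,
    cutoff = model$cutoff,
    sample_hash = .sample_hash(model$resting_sample)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- fit_cutoff(obj$resting_sample, obj$quantile)
  if (abs(model$cutoff - obj$cutoff) > 1e-8 * max(1, abs(obj$cutoff))) {
    stop("stored cutoff does not match the stored sample")
  }
  model
}

# cheap order-insensitive content hash (no digest dependency)
.sample_hash <- function(x) {
  s <- sort(x)
  sprintf("n%d-%.10e-%.10e-%.10e", length(s), sum(s), sum(s^2), s[length(s)])
}

#' Call activation against a calibration cutoff
#'
#' A cell is called activated when its ratio is strictly greater than the
#' cutoff; a ratio exactly at the cutoff is conservatively not called.
#' Flags are written to the `called` column only.
#'
#' @param cells Per-cell table with `nuc_cyt_ratio`.
#' @param model A [fit_cutoff()] calibration model.
#' @return `cells` with `called` filled.
#' @export
call_activation <- function(cells, model) {
  stopifnot(is.data.frame(cells), inherits(model, "calibration_model"))
  if (nrow(cells) == 0) {
    cells$called <- logical(0)
    return(cells)
  }
  if (!"nuc_cyt_ratio" %in% names(cells) || anyNA(cells$nuc_cyt_ratio)) {
    bad <- if ("cell_id" %in% names(cells)) {
      cells$cell_id[is.na(cells$nuc_cyt_ratio)]
    } else which(is.na(cells$nuc_cyt_ratio))
    stop("missing nuc_cyt_ratio for cells: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  cells$called <- cells$nuc_cyt_ratio > model$cutoff
  cells
}

#' Fraction of cells activated, with bootstrap uncertainty
#'
#' Point estimate `n_activated / n_cells`; uncertainty from resampling cells
#' with replacement: the bootstrap standard error is the standard deviation
#' of the resampled fractions, and the confidence interval is the 2.5/97.5
#' percentile interval.
#'
#' @param cells Per-cell table with a logical `called` column, or a logical
#'   vector of calls.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer seed.
#' @param labels Optional named list of condition labels (e.g. `c_max`,
#'   `t_stim`, `density_class`) carried into the result.
#' @return An object of class `experiment_result` with `n_cells`,
#'   `n_activated`, `fraction_activated`, `bootstrap_se`, `ci_low`,
#'   `ci_high`, `labels`.
#' @export
fraction_activated <- function(cells, n_boot = 5000, seed = 1L,
                               labels = list()) {
  calls <- if (is.data.frame(cells)) cells$called else cells
  if (is.null(calls) || length(calls) < 1 || anyNA(calls)) {
    stop("need at least one cell with a non-missing activation call")
  }
  if (n_boot < 100) stop("n_boot must be at least 100")
  calls <- as.logical(calls)
  n <- length(calls)
  frac <- mean(calls)
  boots <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(calls[idx], nrow = n_boot))
  })
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  structure(
    list(n_cells = n, n_activated = sum(calls), fraction_activated = frac,
         bootstrap_se = stats::sd(boots),
         ci_low = min(ci[1], frac), ci_high = max(ci[2], frac),
         n_boot = n_boot, seed = as.integer(seed), labels = labels),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "Fraction activated: %.3f (%d/%d), bootstrap SE %.3f, 95%% CI [%.3f, %.3f]\n",
    x$fraction_activated, x$n_activated, x$n_cells, x$bootstrap_se,
    x$ci_low, x$ci_high))
  if (length(x$labels)) {
    cat("  ", paste(names(x$labels), unlist(x$labels), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Cumulative fold-dilution of a serial dilution wash
#'
#' Agonist is removed from adherent cultures by repeatedly removing part of
#' the well contents and replacing it with fresh medium. Each round dilutes
#' the residual agonist by `(V - removed + added) / (V - removed)`; the
#' returned value is that factor to the power `n_rounds`. With the default
#' `added = removed` this is `(V / (V - removed))^n_rounds`: four rounds of
#' replacing 250 uL of a 300 uL well give 6^4 = 1296, i.e. roughly 1:1000.
#'
#' @param well_volume Total well volume (uL).
#' @param removed_volume Volume removed each round (uL), strictly less than
#'   `well_volume`.
#' @param added_volume Volume added back each round (uL); defaults to
#'   `removed_volume`.
#' @param n_rounds Number of rounds (non-negative integer).
#' @return Cumulative fold dilution (dimensionless, >= 1).
#' @export
serial_dilution_factor <- function(well_volume, removed_volume,
                                   added_volume = removed_volume,
                                   n_rounds) {
  stopifnot(well_volume > 0, removed_volume > 0, added_volume > 0,
            n_rounds >= 0, n_rounds == round(n_rounds))
  if (removed_volume >= well_volume) {
    stop("removed_volume must be strictly less than well_volume")
  }
  residual <- well_volume - removed_volume
  ((residual + added_volume) / residual)^n_rounds
}
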