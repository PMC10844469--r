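# Synthetic culture generator: clustered cell layouts (Thomas process),
# resting/activated reporter-ratio distributions, and the dose-time-density
# activation response model that drives the simulated stimulus response.

#' Culture configuration
#'
#' Macrophage-like cells grow in clumps rather than an even confluency; cell
#' positions are drawn from a Thomas cluster process (Poisson parents,
#' Gaussian-dispersed offspring). The field is centered on the origin, which
#' is where the dispensing probe sits in localized-stimulation experiments.
#'
#' @param density Target intensity in cells/mm^2.
#' @param field_width,field_height Field dimensions in um.
#' @param cluster_rate Parent clusters per mm^2; defaults to `density / 8`
#'   (mean 8 cells per cluster).
#' @param cluster_spread Offspring dispersion sigma in um.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `culture_config`.
#' @export
culture_config <- function(density,
                           field_width = 1000,
                           field_height = 1000,
                           cluster_rate = density / 8,
                           cluster_spread = 12,
                           seed = 1L) {
  stopifnot(
    is.numeric(density), length(density) == 1, density >= 0,
    field_width > 0, field_height > 0,
    is.numeric(cluster_spread), cluster_spread > 0,
    is.numeric(seed), length(seed) == 1
  )
  if (density > 0) stopifnot(cluster_rate > 0)
  structure(
    list(density = density, field_width = field_width,
         field_height = field_height, cluster_rate = cluster_rate,
         cluster_spread = cluster_spread, seed = as.integer(seed)),
    class = "culture_config"
  )
}

#' Plating-density presets
#'
#' `"sparse"` (400 cells/mm^2) is on par with tissue-resident macrophage
#' density and the single-cell stimulation experiments; `"dense"`
#' (2500 cells/mm^2) is confluent; `"moderate"` sits between;
#' `"dense_culture"` (3750 cells/mm^2) matches the dense whole-culture
#' plating used for density comparisons.
#'
#' @param name Preset name.
#' @param ... Passed on to [culture_config()] (e.g. `seed`, field size).
#' @return A `culture_config`.
#' @export
culture_preset <- function(name = c("sparse", "moderate", "dense",
                                    "dense_culture"), ...) {
  name <- match.arg(name)
  density <- switch(name, sparse = 400, moderate = 1500,
                    dense = 2500, dense_culture = 3750)
  culture_config(density = density, ...)
}

#' Activation response model parameters
#'
#' Probability that a cell activates as a function of local agonist
#' concentration, stimulation time, and culture density. The dose term is a
#' logistic in log10 concentration; density raises the effective EC50
#' multiplicatively, and that shift decays linearly with stimulation time so
#' that long stimulation restores activation in dense cultures.
#'
#' Defaults: `ec50_base = 100` nM (the single-cell threshold), slope 4,
#' background 0.05 (the top-5% cutoff false-positive rate), `density_ref`
#' 1000 cells/mm^2, `density_coef` chosen so the effective threshold at
#' 3750 cells/mm^2 and 5-min stimulation is tenfold the sparse threshold,
#' minimum stimulation 5 min, full restoration at 15 min. Resting ratios are
#' log-normal with median 0.75, activated with median 1.5 (log-sd 0.2 each).
#'
#' @param ec50_base Baseline half-activation concentration (nM).
#' @param hill_slope Logistic slope per decade of concentration.
#' @param background_rate Activation probability with no stimulus.
#' @param density_coef Strength of the density-driven EC50 shift.
#' @param density_ref Density (cells/mm^2) above which the shift engages.
#' @param t_min_stim Minimum stimulation time (min) that elicits a response.
#' @param t_restore Stimulation time (min) at which the density shift is gone.
#' @param resting_log_median,resting_log_sd Resting nuclear/cytoplasmic ratio
#'   log-normal parameters (median on natural scale, sd on log scale).
#' @param activated_log_median,activated_log_sd Activated-ratio counterparts.
#' @return An object of class `response_params`.
#' @export
response_params <- function(ec50_base = 100,
                            hill_slope = 4,
                            background_rate = 0.05,
                            density_coef = 9 / 2.75,
                            density_ref = 1000,
                            t_min_stim = 5,
                            t_restore = 15,
                            resting_log_median = 0.75,
                            resting_log_sd = 0.2,
                            activated_log_median = 1.5,
                            activated_log_sd = 0.2) {
  stopifnot(
    ec50_base > 0, hill_slope > 0,
    background_rate >= 0, background_rate < 1,
    density_coef >= 0, density_ref > 0,
    t_min_stim < t_restore,
    resting_log_median > 0, resting_log_sd > 0,
    activated_log_median > 0, activated_log_sd > 0
  )
  structure(as.list(environment()), class = "response_params")
}

# empty per-cell table with the canonical column schema
.empty_cells <- function() {
  data.frame(
    cell_id = integer(0), x_um = numeric(0), y_um = numeric(0),
    nuc_intensity = numeric(0), cyt_intensity = numeric(0),
    nuc_cyt_ratio = numeric(0), conc_nM = numeric(0),
    ground_truth = logical(0), called = logical(0),
    n_neighbors = integer(0), experiment_id = character(0),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic resting culture
#'
#' Cell positions follow a Thomas cluster process: parents from a homogeneous
#' Poisson process at `cluster_rate` (drawn in a field buffered by 4 sigma so
#' edge clusters contribute), offspring counts Poisson with mean
#' `density / cluster_rate`, offspring positions Gaussian around parents,
#' offspring falling outside the field discarded. Every cell starts resting:
#' nuclear/cytoplasmic ratios are drawn from the resting log-normal, and
#' cytoplasmic intensities from a broad log-normal baseline.
#'
#' @param config A [culture_config()].
#' @param params A [response_params()] supplying the resting-ratio
#'   distribution.
#' @return Per-cell `data.frame` with columns `cell_id`, `x_um`, `y_um`,
#'   `nuc_intensity`, `cyt_intensity`, `nuc_cyt_ratio`, `conc_nM`,
#'   `ground_truth`, `called`, `n_neighbors`, `experiment_id`.
#' @export
generate_culture <- function(config, params = response_params()) {
  stopifnot(inherits(config, "culture_config"),
            inherits(params, "response_params"))
  area_mm2 <- config$field_width * config$field_height / 1e6
  if (config$density * area_mm2 > 1e6) {
    stop("refusing to generate more than 1e6 expected cells; ",
         "reduce density or field size")
  }
  if (config$density == 0) return(.empty_cells())
  withr::with_seed(config$seed, {
    buf <- 4 * config$cluster_spread
    w <- config$field_width + 2 * buf
    h <- config$field_height + 2 * buf
    n_parents <- stats::rpois(1, config$cluster_rate * w * h / 1e6)
    x <- y <- numeric(0)
    if (n_parents > 0) {
      px <- stats::runif(n_parents, -w / 2, w / 2)
      py <- stats::runif(n_parents, -h / 2, h / 2)
      n_off <- stats::rpois(n_parents, config$density / config$cluster_rate)
      x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_spread)
      y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_spread)
      keep <- abs(x) <= config$field_width / 2 &
        abs(y) <= config$field_height / 2
      x <- x[keep]; y <- y[keep]
    }
    n <- length(x)
    if (n == 0) {
      .empty_cells()
    } else {
      ratio <- stats::rlnorm(n, log(params$resting_log_median),
                             params$resting_log_sd)
      cyt <- stats::rlnorm(n, log(1000), 0.15)
      data.frame(
        cell_id = seq_len(n), x_um = x, y_um = y,
        nuc_intensity = ratio * cyt, cyt_intensity = cyt,
        nuc_cyt_ratio = ratio, conc_nM = NA_real_,
        ground_truth = FALSE, called = NA,
        n_neighbors = NA_integer_, experiment_id = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  })
}

#' Activation probability under the dose-time-density response model
#'
#' For stimulation times below `t_min_stim` the response stays at background.
#' Otherwise
#' `p = b + (1 - b) * plogis(k * (log10(C) - log10(ec50_eff)))` with
#' `ec50_eff = ec50_base * (1 + density_coef * max(0, density/density_ref - 1) * h(t))`
#' and `h(t) = max(0, (t_restore - t) / (t_restore - t_min_stim))`, so the
#' density-driven threshold shift fades as stimulation lengthens.
#'
#' @param conc_nM Local agonist concentration(s), nM.
#' @param t_stim_min Stimulation time in minutes.
#' @param density Culture density in cells/mm^2.
#' @param params A [response_params()].
#' @return Activation probability/ies in `[0, 1)`.
#' @export
activation_probability <- function(conc_nM, t_stim_min, density,
                                   params = response_params()) {
  stopifnot(all(conc_nM >= 0), t_stim_min >= 0, density >= 0)
  b <- params$background_rate
  if (t_stim_min < params$t_min_stim) {
    return(rep_len(b, length(conc_nM)))
  }
  ec50 <- effective_ec50(t_stim_min, density, params)
  logdose <- ifelse(conc_nM > 0, log10(conc_nM), -Inf)
  b + (1 - b) * stats::plogis(params$hill_slope * (logdose - log10(ec50)))
}

#' Effective half-activation concentration
#'
#' The density- and time-shifted EC50 used by [activation_probability()].
#'
#' @inheritParams activation_probability
#' @return EC50 in nM.
#' @export
effective_ec50 <- function(t_stim_min, density, params = response_params()) {
  ht <- max(0, (params$t_restore - t_stim_min) /
              (params$t_restore - params$t_min_stim))
  excess <- max(0, density / params$density_ref - 1)
  params$ec50_base * (1 + params$density_coef * excess * ht)
}

#' Simulate the stimulus response of a culture
#'
#' Each cell's ground-truth activation is a Bernoulli draw at its
#' [activation_probability()]; activated cells redraw their
#' nuclear/cytoplasmic ratio from the activated log-normal, resting cells
#' from the resting log-normal. Local concentrations come from a
#' [concentration_field()] evaluated at the end of dispensing, from a uniform
#' bath concentration, or from a pre-filled `conc_nM` column.
#'
#' @param cells Per-cell table from [generate_culture()].
#' @param t_stim_min Stimulation time in minutes.
#' @param density Culture density (cells/mm^2) entering the response model.
#' @param params A [response_params()].
#' @param seed Integer seed.
#' @param field Optional [concentration_field()].
#' @param bath_conc_nM Optional uniform bath concentration (whole-culture
#'   stimulation).
#' @return `cells` with `conc_nM`, `ground_truth`, updated ratios and
#'   intensities.
#' @export
simulate_response <- function(cells, t_stim_min, density,
                              params = response_params(), seed = 1L,
                              field = NULL, bath_conc_nM = NULL) {
  stopifnot(is.data.frame(cells))
  if (!is.null(field)) {
    stopifnot(inherits(field, "concentration_field"))
    cells <- concentration_at_cells(cells, field$conditions,
                                    origin = field$origin)
  } else if (!is.null(bath_conc_nM)) {
    stopifnot(bath_conc_nM >= 0)
    cells$conc_nM <- rep_len(bath_conc_nM, nrow(cells))
  }
  if (nrow(cells) == 0) return(cells)
  if (anyNA(cells$conc_nM)) {
    stop("cells lack local concentrations; supply `field` or `bath_conc_nM`")
  }
  p <- activation_probability(cells$conc_nM, t_stim_min, density, params)
  withr::with_seed(as.integer(seed), {
    act <- stats::runif(nrow(cells)) < p
    n_act <- sum(act)
    ratio <- cells$nuc_cyt_ratio
    if (n_act > 0) {
      ratio[act] <- stats::rlnorm(n_act, log(params$activated_log_median),
                                  params$activated_log_sd)
    }
    ratio[!act] <- stats::rlnorm(sum(!act), log(params$resting_log_median),
                                 params$resting_log_sd)
    cells$nuc_cyt_ratio <- ratio
    cells$nuc_intensity <- ratio * cells$cyt_intensity
    cells$ground_truth <- act
  })
  cells
}
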