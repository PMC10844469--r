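# Dose-response fitting: log-dose logistic activation curves per stimulation
# time, fitted by binomial maximum likelihood, and threshold extraction.

#' Fit a log-dose logistic activation curve
#'
#' Fits `p(C) = b + (1 - b) * plogis(k * (log10(C) - log10(EC50)))` to
#' per-concentration activation counts under a binomial likelihood. The
#' background `b` is fixed (default 0.05, the calibration false-positive
#' rate) rather than free, for identifiability with the small dose panels
#' typical of these experiments. Optimization is multi-start: a log-spaced
#' EC50 grid spanning the dosed range seeds `stats::optim`, and the best
#' converged fit is kept, so the result is deterministic.
#'
#' @param points `data.frame` with columns `conc` (nM), `n` (cells), and
#'   `n_activated`; at least 3 distinct positive concentrations.
#' @param fixed_background Background activation probability in `[0, 1)`.
#' @return An object of class `dose_curve` with `ec50`, `slope`,
#'   `background`, `points`, `deviance`, `log_lik`.
#' @export
fit_dose_curve <- function(points, fixed_background = 0.05) {
  stopifnot(is.data.frame(points),
            all(c("conc", "n", "n_activated") %in% names(points)))
  stopifnot(all(points$conc > 0), all(points$n >= 1),
            all(points$n_activated >= 0),
            all(points$n_activated <= points$n),
            fixed_background >= 0, fixed_background < 1)
  if (length(unique(points$conc)) < 3) {
    stop("need at least 3 distinct concentrations")
  }
  b <- fixed_background
  frac <- points$n_activated / points$n
  if (all(points$n_activated == 0)) {
    stop("no activation at any dose; threshold unidentifiable")
  }
  if (all(points$n_activated == points$n)) {
    stop("complete activation at every dose; threshold unidentifiable")
  }
  x <- log10(points$conc)
  nll <- function(par) { # par = (log10 ec50, log slope)
    k <- exp(par[2])
    p <- b + (1 - b) * stats::plogis(k * (x - par[1]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(points$n_activated, points$n, p, log = TRUE))
  }
  grid <- seq(min(x) - 1, max(x) + 1, length.out = 25)
  starts <- expand.grid(m = grid, logk = log(c(1, 4, 10)))
  grid_nll <- mapply(function(m, lk) nll(c(m, lk)), starts$m, starts$logk)
  best <- NULL
  for (i in order(grid_nll)[1:5]) {
    fit <- try(stats::optim(c(starts$m[i], starts$logk[i]), nll,
                            method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10)),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("dose-curve optimization failed")
  # saturated-model log-likelihood for the deviance
  psat <- pmin(pmax(frac, 1e-12), 1 - 1e-12)
  ll_sat <- sum(stats::dbinom(points$n_activated, points$n, psat, log = TRUE))
  structure(
    list(ec50 = 10^best$par[1], slope = exp(best$par[2]), background = b,
         points = points, log_lik = -best$value,
         deviance = 2 * (ll_sat + best$value)),
    class = "dose_curve"
  )
}

#' @export
print.dose_curve <- function(x, ...) {
  cat(sprintf(
    "Dose curve: EC50 = %.4g nM, slope = %.3g per decade, background = %.3g\n",
    x$ec50, x$slope, x$background))
  cat(sprintf("  %d dose points, deviance %.3g\n", nrow(x$points),
              x$deviance))
  invisible(x)
}

#' Predicted activation fraction from a fitted dose curve
#'
#' @param object A `dose_curve`.
#' @param conc_nM Concentrations (nM).
#' @param ... Unused.
#' @return Predicted activation probabilities.
#' @export
predict.dose_curve <- function(object, conc_nM, ...) {
  logdose <- ifelse(conc_nM > 0, log10(conc_nM), -Inf)
  object$background + (1 - object$background) *
    stats::plogis(object$slope * (logdose - log10(object$ec50)))
}

#' Concentration at which a fitted curve crosses an activation level
#'
#' Analytic inversion of the fitted logistic: the concentration where the
#' predicted activation fraction equals `level`. At the curve midpoint
#' `(background + 1) / 2` this returns the EC50.
#'
#' @param curve A `dose_curve`.
#' @param level Activation level, strictly between `background` and 1.
#' @return Concentration in nM.
#' @export
threshold_crossing <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "dose_curve"))
  b <- curve$background
  if (level <= b || level >= 1) {
    stop("level must lie strictly between the background (", b, ") and 1")
  }
  q <- (level - b) / (1 - b)
  10^(log10(curve$ec50) + stats::qlogis(q) / curve$slope)
}

#' Export a dose curve as a plotting table
#'
#' @param curve A `dose_curve`.
#' @param n_grid Number of log-spaced concentrations.
#' @return `data.frame` with `conc_nM` and `fraction_activated` over a
#'   log-spaced grid spanning the dosed range.
#' @export
dose_curve_table <- function(curve, n_grid = 100) {
  stopifnot(inherits(curve, "dose_curve"))
  rng <- range(curve$points$conc)
  conc <- 10^seq(log10(rng[1] / 3), log10(rng[2] * 3), length.out = n_grid)
  data.frame(conc_nM = conc,
             fraction_activated = predict(curve, conc))
}
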