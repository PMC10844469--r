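# Dispensing-diffusion model: agonist concentration field under continuous
# picoliter dispensing from a micropipette aperture held above the dish.

# Calibration anchors: (C0 nM, height um) pairs at which C_max = 100 nM.
.flow_anchors <- list(
  single_cell = list(c0 = 5500, height = 4),
  cluster     = list(c0 = 318,  height = 20)
)
.anchor_cmax <- 100 # nM

#' Calibrated volumetric dispensing rate
#'
#' The absolute flow rate out of the probe is not directly measurable; it is
#' pinned by requiring that the canonical reservoir concentration / retraction
#' height pair for each stimulation mode produces a peak surface concentration
#' (`C_max`) of 100 nM: `C0 = 5.5` uM at 4 um for single-cell mode and
#' `C0 = 0.318` uM at 20 um for cluster mode.
#'
#' @param mode `"single_cell"` or `"cluster"`.
#' @param diffusivity Agonist diffusion coefficient (m^2/s).
#' @return Volumetric flow in m^3/s (about 0.23 pL/s single-cell, 20 pL/s
#'   cluster at the default diffusivity).
#' @export
calibrated_flow <- function(mode = c("single_cell", "cluster"),
                            diffusivity = 5e-10) {
  mode <- match.arg(mode)
  a <- .flow_anchors[[mode]]
  # C_max = Q * c0 / (2 pi D h)  =>  Q = C_max * 2 pi D h / c0
  .anchor_cmax * 2 * pi * diffusivity * (a$height * 1e-6) / a$c0
}

#' Dispensing conditions
#'
#' Bundle of probe geometry and dispensing parameters that define the agonist
#' concentration field. Heights default to the retraction distance used for
#' each mode (4 um single-cell, 20 um cluster); flow defaults to the
#' calibrated rate for the mode (see [calibrated_flow()]).
#'
#' @param mode `"single_cell"` or `"cluster"`.
#' @param c0_nM Reservoir agonist concentration in nM.
#' @param height_um Aperture-to-surface distance in um.
#' @param flow_m3_per_s Volumetric dispensing rate in m^3/s.
#' @param duration_s Dispensing time in s (default 300 s = 5 min).
#' @param diffusivity_m2_per_s Agonist diffusion coefficient; default
#'   5e-10 m^2/s, the Stokes-Einstein scale for a ~314 Da small molecule
#'   such as R848.
#' @param aperture_radius_um Probe opening radius (um); half the 2 um
#'   aperture diameter.
#' @return An object of class `dispense_conditions`.
#' @export
dispense_conditions <- function(mode = c("single_cell", "cluster"),
                                c0_nM,
                                height_um = NULL,
                                flow_m3_per_s = NULL,
                                duration_s = 300,
                                diffusivity_m2_per_s = 5e-10,
                                aperture_radius_um = 1) {
  mode <- match.arg(mode)
  if (is.null(height_um)) {
    height_um <- .flow_anchors[[mode]]$height
  }
  if (is.null(flow_m3_per_s)) {
    flow_m3_per_s <- calibrated_flow(mode, diffusivity_m2_per_s)
  }
  stopifnot(
    is.numeric(c0_nM), length(c0_nM) == 1, is.finite(c0_nM), c0_nM > 0,
    is.numeric(flow_m3_per_s), flow_m3_per_s > 0,
    is.numeric(height_um), height_um > 0,
    is.numeric(duration_s), duration_s > 0,
    is.numeric(diffusivity_m2_per_s), diffusivity_m2_per_s > 0,
    is.numeric(aperture_radius_um), aperture_radius_um > 0
  )
  structure(
    list(mode = mode, c0_nM = c0_nM, height_um = height_um,
         flow_m3_per_s = flow_m3_per_s, duration_s = duration_s,
         diffusivity_m2_per_s = diffusivity_m2_per_s,
         aperture_radius_um = aperture_radius_um),
    class = "dispense_conditions"
  )
}

#' @export
print.dispense_conditions <- function(x, ...) {
  cat("Dispensing conditions (", x$mode, ")\n", sep = "")
  cat(sprintf("  C0 = %g nM, height = %g um, flow = %.3g pL/s\n",
              x$c0_nM, x$height_um, x$flow_m3_per_s * 1e15))
  cat(sprintf("  duration = %g s, D = %.3g m^2/s, aperture radius = %g um\n",
              x$duration_s, x$diffusivity_m2_per_s, x$aperture_radius_um))
  cat(sprintf("  C_max = %.4g nM\n", steady_state_concentration(0, x)))
  invisible(x)
}

# effective radial coordinate: in-plane distance with the dispensing height
# folded in, floored at the aperture radius to regularize the singularity
.r_eff_um <- function(r_um, cond) {
  pmax(sqrt(r_um^2 + cond$height_um^2), cond$aperture_radius_um)
}

.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Steady-state agonist concentration
#'
#' Concentration at in-plane distance `r` from the point beneath the aperture
#' once dispensing has reached steady state: a continuous point source of
#' strength `flow * c0` above a reflecting plane (image-source factor 2),
#' `C(r) = flow * c0 / (2 pi D r_eff)` with
#' `r_eff = max(sqrt(r^2 + height^2), aperture_radius)`.
#' `C_max = C(0)` is the peak beneath the dispensing point.
#'
#' @param r_um In-plane radial distance(s) from the dispensing point (um).
#' @param cond A [dispense_conditions()] object.
#' @return Concentration(s) in nM.
#' @export
steady_state_concentration <- function(r_um, cond) {
  stopifnot(inherits(cond, "dispense_conditions"))
  if (!is.numeric(r_um) || any(!is.finite(r_um)) || any(r_um < 0)) {
    stop("`r_um` must be finite and non-negative")
  }
  r_eff_m <- .r_eff_um(r_um, cond) * 1e-6
  cond$flow_m3_per_s * cond$c0_nM /
    (2 * pi * cond$diffusivity_m2_per_s * r_eff_m)
}

#' Time-dependent agonist concentration
#'
#' Build-up during dispensing follows the switched-on continuous point
#' source, `C(r, t) = C_ss(r) * erfc(r_eff / (2 sqrt(D t)))` for
#' `t <= duration`; after the probe stops, the field decays by superposition
#' of the switched-on solution with a negative source started at `duration`:
#' `C(r, t) = C_on(r, t) - C_on(r, t - duration)`. The agonist diffuses away
#' from the stimulated area within minutes of probe removal.
#'
#' @param r_um In-plane radial distance(s) (um).
#' @param t_s Time(s) since the start of dispensing (s).
#' @param cond A [dispense_conditions()] object.
#' @return Concentration(s) in nM; `r_um` and `t_s` are recycled together.
#' @export
transient_concentration <- function(r_um, t_s, cond) {
  stopifnot(inherits(cond, "dispense_conditions"))
  if (!is.numeric(t_s) || any(!is.finite(t_s)) || any(t_s < 0)) {
    stop("`t_s` must be finite and non-negative")
  }
  css <- steady_state_concentration(r_um, cond)
  n <- max(length(r_um), length(t_s))
  r_um <- rep_len(r_um, n); t_s <- rep_len(t_s, n)
  css <- rep_len(css, n)
  d_um2 <- cond$diffusivity_m2_per_s * 1e12 # um^2/s
  reff <- .r_eff_um(r_um, cond)
  on_factor <- function(t) {
    f <- numeric(length(t))
    pos <- t > 0
    f[pos] <- .erfc(reff[pos] / (2 * sqrt(d_um2 * t[pos])))
    f
  }
  conc <- css * on_factor(t_s)
  off <- t_s > cond$duration_s
  if (any(off)) {
    conc[off] <- conc[off] - css[off] * on_factor(t_s[off] - cond$duration_s)
  }
  pmax(conc, 0)
}

#' Annotate cells with their local agonist concentration
#'
#' Evaluates [transient_concentration()] at each cell's Euclidean in-plane
#' distance from the dispensing point and fills the `conc_nM` column; all
#' other columns are left untouched.
#'
#' @param cells Per-cell table with `x_um`, `y_um` columns.
#' @param cond A [dispense_conditions()] object.
#' @param t_s Time since the start of dispensing (s); defaults to the end of
#'   dispensing.
#' @param origin Dispensing point `c(x, y)` in um.
#' @return `cells` with `conc_nM` filled.
#' @export
concentration_at_cells <- function(cells, cond, t_s = cond$duration_s,
                                   origin = c(0, 0)) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0) {
    cells$conc_nM <- numeric(0)
    return(cells)
  }
  if (!all(c("x_um", "y_um") %in% names(cells)) ||
      anyNA(cells$x_um) || anyNA(cells$y_um)) {
    stop("cells must carry complete `x_um`, `y_um` positions")
  }
  r <- sqrt((cells$x_um - origin[1])^2 + (cells$y_um - origin[2])^2)
  cells$conc_nM <- transient_concentration(r, t_s, cond)
  cells
}

#' Peak-concentration uncertainty from cell-height ambiguity
#'
#' The distance between the probe opening and the cell surface is uncertain
#' by roughly a cell height, which translates into an interval of possible
#' `C_max` values. Returns the `[min, max]` of `C_max` over the supplied
#' height interval (the point source is monotone in height so the endpoints
#' suffice).
#'
#' @param cond A [dispense_conditions()] object.
#' @param height_range_um Length-2 numeric interval of plausible heights (um).
#' @return Named numeric `c(min = , max = )` in nM.
#' @export
cmax_uncertainty <- function(cond, height_range_um) {
  stopifnot(inherits(cond, "dispense_conditions"))
  if (!is.numeric(height_range_um) || length(height_range_um) != 2 ||
      any(!is.finite(height_range_um)) || any(height_range_um <= 0) ||
      height_range_um[1] > height_range_um[2]) {
    stop("`height_range_um` must be a non-empty positive interval c(lo, hi)")
  }
  vals <- vapply(height_range_um, function(h) {
    c2 <- cond
    c2$height_um <- h
    steady_state_concentration(0, c2)
  }, numeric(1))
  c(min = min(vals), max = max(vals))
}

#' Concentration field
#'
#' Thin wrapper binding [dispense_conditions()] to a dispensing origin so the
#' field can be passed around and evaluated at cell positions or on grids.
#'
#' @param cond A [dispense_conditions()] object.
#' @param origin Dispensing point `c(x, y)` in um.
#' @return An object of class `concentration_field`.
#' @export
concentration_field <- function(cond, origin = c(0, 0)) {
  stopifnot(inherits(cond, "dispense_conditions"),
            is.numeric(origin), length(origin) == 2, all(is.finite(origin)))
  structure(list(conditions = cond, origin = origin),
            class = "concentration_field")
}

#' Evaluate a concentration field
#'
#' @param field A [concentration_field()] object.
#' @param x_um,y_um Positions (um), recycled together.
#' @param t_s Time since dispensing start (s).
#' @return Concentrations in nM.
#' @export
field_concentration <- function(field, x_um, y_um,
                                t_s = field$conditions$duration_s) {
  stopifnot(inherits(field, "concentration_field"))
  r <- sqrt((x_um - field$origin[1])^2 + (y_um - field$origin[2])^2)
  transient_concentration(r, t_s, field$conditions)
}

#' Export a concentration profile as a long table
#'
#' @param cond A [dispense_conditions()] object.
#' @param r_um Radial distances (um).
#' @param t_s Times (s).
#' @return `data.frame` with columns `r_um`, `t_s`, `conc_nM`, one row per
#'   (r, t) combination; suitable for plotting.
#' @export
field_profile_table <- function(cond, r_um, t_s = cond$duration_s) {
  grid <- expand.grid(r_um = r_um, t_s = t_s)
  grid$conc_nM <- transient_concentration(grid$r_um, grid$t_s, cond)
  grid
}
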