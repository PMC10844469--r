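# Spatial summaries: neighbor counts within a fixed radius, density
# classification, square binning of activation, radial profiles, and
# center-region fractions under a concentration field.

#' Spatial analysis parameters
#'
#' @param neighbor_radius Neighborhood radius in um (default 18, about two
#'   cell lengths, the empirically chosen neighbor distance).
#' @param bin_size Square bin side in um (default 100).
#' @param ring_width Annulus width for radial profiles in um (default 50).
#' @param sparse_max Densities below this (cells/mm^2) are "sparse"
#'   (default 1000, the tissue-resident-macrophage scale).
#' @param dense_min Densities at or above this are "dense" (default 2500,
#'   confluent plating).
#' @return An object of class `spatial_params`.
#' @export
spatial_params <- function(neighbor_radius = 18, bin_size = 100,
                           ring_width = 50, sparse_max = 1000,
                           dense_min = 2500) {
  stopifnot(neighbor_radius > 0, bin_size > 0, ring_width > 0,
            sparse_max > 0, dense_min > 0, sparse_max < dense_min)
  structure(list(neighbor_radius = neighbor_radius, bin_size = bin_size,
                 ring_width = ring_width, sparse_max = sparse_max,
                 dense_min = dense_min),
            class = "spatial_params")
}

#' Count neighbors within a fixed radius
#'
#' For each cell, the number of OTHER cells whose Euclidean distance is at
#' most `neighbor_radius` (closed ball; the cell itself is excluded; no edge
#' correction). Duplicate coordinates are counted normally.
#'
#' @param cells Per-cell table with `x_um`, `y_um`.
#' @param params A [spatial_params()].
#' @return `cells` with `n_neighbors` filled.
#' @export
neighbor_counts <- function(cells, params = spatial_params()) {
  stopifnot(is.data.frame(cells), inherits(params, "spatial_params"))
  n <- nrow(cells)
  if (n == 0) {
    cells$n_neighbors <- integer(0)
    return(cells)
  }
  if (anyNA(cells$x_um) || anyNA(cells$y_um)) {
    stop("cell positions contain missing values")
  }
  d <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
  cells$n_neighbors <- as.integer(colSums(d <= params$neighbor_radius) - 1L)
  cells
}

#' Bin neighbor counts into the standard groups
#'
#' @param n_neighbors Integer vector of neighbor counts, or a per-cell table
#'   with an `n_neighbors` column.
#' @return Factor with levels `"0-1"`, `"2-3"`, `"4+"`.
#' @export
neighbor_bins <- function(n_neighbors) {
  if (is.data.frame(n_neighbors)) n_neighbors <- n_neighbors$n_neighbors
  stopifnot(!anyNA(n_neighbors), all(n_neighbors >= 0))
  cut(n_neighbors, breaks = c(-Inf, 1, 3, Inf),
      labels = c("0-1", "2-3", "4+"))
}

#' Classify overall culture density
#'
#' Overall density is `nrow(cells) / field_area_mm2`; cultures below
#' `sparse_max` are "sparse", at or above `dense_min` "dense", otherwise
#' "moderate".
#'
#' @param cells Per-cell table (only the row count is used).
#' @param field_area_mm2 Field area in mm^2.
#' @param params A [spatial_params()].
#' @return One of `"sparse"`, `"moderate"`, `"dense"`.
#' @export
density_classify <- function(cells, field_area_mm2,
                             params = spatial_params()) {
  if (!is.numeric(field_area_mm2) || field_area_mm2 <= 0) {
    stop("field_area_mm2 must be positive")
  }
  density <- nrow(cells) / field_area_mm2
  if (density < params$sparse_max) "sparse"
  else if (density >= params$dense_min) "dense"
  else "moderate"
}

#' Fraction activated in square spatial bins
#'
#' Cells are assigned to a square grid anchored at the dispensing point with
#' half-open intervals `[k * bin, (k + 1) * bin)`; each cell falls in exactly
#' one bin. Bins report center coordinates, cell count, fraction of called
#' cells (`NA` when empty), and, when a field is supplied, the agonist
#' concentration at the bin center.
#'
#' @param cells Per-cell table with positions and `called` flags.
#' @param params A [spatial_params()].
#' @param field Optional [concentration_field()].
#' @param origin Grid anchor (dispensing point), um.
#' @return `data.frame` with `bin_x`, `bin_y` (centers, um), `n_cells`,
#'   `fraction_activated`, and `conc_nM` if a field was given.
#' @export
bin_fraction_activated <- function(cells, params = spatial_params(),
                                   field = NULL, origin = c(0, 0)) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0) {
    out <- data.frame(bin_x = numeric(0), bin_y = numeric(0),
                      n_cells = integer(0), fraction_activated = numeric(0))
    if (!is.null(field)) out$conc_nM <- numeric(0)
    return(out)
  }
  b <- params$bin_size
  ix <- floor((cells$x_um - origin[1]) / b)
  iy <- floor((cells$y_um - origin[2]) / b)
  key <- paste(ix, iy, sep = ",")
  keys <- sort(unique(key))
  ord <- match(keys, key) # one representative row per bin
  out <- data.frame(
    bin_x = origin[1] + (ix[ord] + 0.5) * b,
    bin_y = origin[2] + (iy[ord] + 0.5) * b,
    n_cells = as.integer(tapply(rep(1L, nrow(cells)), key, sum)[keys]),
    fraction_activated = tapply(as.numeric(cells$called), key, mean)[keys],
    row.names = NULL
  )
  if (!is.null(field)) {
    out$conc_nM <- field_concentration(field, out$bin_x, out$bin_y)
  }
  out
}

#' Radial activation profile
#'
#' Fraction of called cells in concentric annuli of width `ring_width`
#' around `origin`. Under a localized stimulus the fraction is highest at
#' the center and decays towards the background rate with distance.
#'
#' @param cells Per-cell table with positions and `called` flags.
#' @param origin Center of the profile, um.
#' @param ring_width Annulus width, um.
#' @param max_r Outer radius; defaults to the farthest cell.
#' @return `data.frame` with `r_mid`, `r_lo`, `r_hi`, `n_cells`,
#'   `fraction_activated` (`NA` and flagged `empty` when a ring holds no
#'   cells).
#' @export
radial_activation_profile <- function(cells, origin = c(0, 0),
                                      ring_width = 50, max_r = NULL) {
  stopifnot(is.data.frame(cells), ring_width > 0)
  r <- sqrt((cells$x_um - origin[1])^2 + (cells$y_um - origin[2])^2)
  if (is.null(max_r)) max_r <- if (nrow(cells)) max(r) else ring_width
  edges <- seq(0, ceiling(max_r / ring_width) * ring_width, by = ring_width)
  if (length(edges) < 2) edges <- c(0, ring_width)
  ring <- cut(r, breaks = edges, include.lowest = TRUE, right = FALSE)
  n <- as.integer(table(ring))
  frac <- as.numeric(tapply(as.numeric(cells$called), ring, mean))
  data.frame(
    r_lo = edges[-length(edges)],
    r_hi = edges[-1],
    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
    n_cells = n,
    fraction_activated = frac,
    empty = n == 0L
  )
}

#' Fraction activated in the high-concentration center region
#'
#' Restricts to cells whose local steady-state concentration is at least
#' `threshold_conc` (the disc inside the dashed contour where activation
#' stays above 50% for the condition; 30 nM for a 90 nM peak, 100 nM for a
#' 900 nM peak) and returns their [fraction_activated()].
#'
#' @param cells Per-cell table with positions and `called` flags.
#' @param field A [concentration_field()].
#' @param threshold_conc Concentration defining the center region, nM.
#' @param n_boot,seed Passed to [fraction_activated()].
#' @param labels Condition labels carried into the result.
#' @return An `experiment_result`; when no cell lies in the center the
#'   result has `n_cells = 0` and is flagged `empty_center = TRUE`.
#' @export
center_fraction <- function(cells, field, threshold_conc,
                            n_boot = 2000, seed = 1L, labels = list()) {
  stopifnot(inherits(field, "concentration_field"), threshold_conc > 0)
  css <- steady_state_concentration(
    sqrt((cells$x_um - field$origin[1])^2 +
           (cells$y_um - field$origin[2])^2),
    field$conditions
  )
  inside <- css >= threshold_conc
  if (!any(inside)) {
    return(structure(
      list(n_cells = 0L, n_activated = 0L, fraction_activated = NA_real_,
           bootstrap_se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           n_boot = n_boot, seed = as.integer(seed), labels = labels,
           empty_center = TRUE),
      class = "experiment_result"
    ))
  }
  res <- fraction_activated(cells[inside, , drop = FALSE], n_boot = n_boot,
                            seed = seed, labels = labels)
  res$empty_center <- FALSE
  res
}
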