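# Ligand budget: order-of-magnitude comparison of free agonist molecules in
# a sample volume against the receptor-bound pool, ruling out ligand
# depletion as an explanation for density effects.

.avogadro <- 6.02214076e23

#' Ligand-budget scenario
#'
#' A sample box on the dish surface (default 45 um on each side and 5 um
#' high, about 10 pL) enclosing one cell in a sparse culture or a small
#' cluster in a dense culture, bathed in agonist at `concentration`.
#'
#' @param concentration_nM Agonist concentration in the box, nM.
#' @param n_cells Cells enclosed by the box (1 sparse, 9 dense by default
#'   presets).
#' @param receptors_per_cell Receptor copies per cell (order-of-magnitude
#'   input; default 5000).
#' @param kd_nM Receptor-ligand dissociation constant, nM (default 100).
#' @param box_side_um,box_height_um Box geometry, um.
#' @return An object of class `budget_scenario`.
#' @export
budget_scenario <- function(concentration_nM = 100, n_cells = 1,
                            receptors_per_cell = 5000, kd_nM = 100,
                            box_side_um = 45, box_height_um = 5) {
  stopifnot(concentration_nM >= 0, n_cells >= 0,
            receptors_per_cell >= 0, kd_nM > 0,
            box_side_um > 0, box_height_um > 0)
  structure(
    list(concentration_nM = concentration_nM, n_cells = n_cells,
         receptors_per_cell = receptors_per_cell, kd_nM = kd_nM,
         box_side_um = box_side_um, box_height_um = box_height_um,
         volume_um3 = box_side_um^2 * box_height_um),
    class = "budget_scenario"
  )
}

#' Dense- and sparse-culture budget presets
#'
#' @param name `"sparse"` (1 cell per box) or `"dense"` (9 cells per box).
#' @param ... Overrides passed to [budget_scenario()].
#' @return A `budget_scenario`.
#' @export
budget_preset <- function(name = c("sparse", "dense"), ...) {
  name <- match.arg(name)
  budget_scenario(n_cells = switch(name, sparse = 1, dense = 9), ...)
}

#' Free ligand molecules in the sample volume
#'
#' `concentration * volume * N_A`, with nM converted to mol/L and
#' 1 um^3 = 1e-15 L. A 45 x 45 x 5 um box at 100 nM holds about 6.1e5
#' molecules.
#'
#' @param scenario A [budget_scenario()].
#' @return Molecule count.
#' @export
free_ligand_count <- function(scenario) {
  stopifnot(inherits(scenario, "budget_scenario"))
  scenario$concentration_nM * 1e-9 * scenario$volume_um3 * 1e-15 * .avogadro
}

#' Receptor-bound ligand molecules in the sample volume
#'
#' `n_cells * receptors_per_cell * occupancy` with equilibrium occupancy
#' `C / (C + Kd)` (at most full occupancy).
#'
#' @param scenario A [budget_scenario()].
#' @return Molecule count.
#' @export
bound_ligand_count <- function(scenario) {
  stopifnot(inherits(scenario, "budget_scenario"))
  occupancy <- scenario$concentration_nM /
    (scenario$concentration_nM + scenario$kd_nM)
  scenario$n_cells * scenario$receptors_per_cell * min(occupancy, 1)
}

#' Free-to-bound ligand ratio
#'
#' Even for a dense cluster this ratio is in the tens to hundreds: free
#' ligand vastly outnumbers what the enclosed cells can bind, so uptake by
#' neighbors cannot meaningfully deplete the local agonist.
#'
#' @param scenario A [budget_scenario()].
#' @return List with `free`, `bound`, `ratio` (`Inf` with
#'   `unbounded = TRUE` when nothing is bound).
#' @export
free_to_bound_ratio <- function(scenario) {
  free <- free_ligand_count(scenario)
  bound <- bound_ligand_count(scenario)
  if (bound == 0) {
    list(free = free, bound = 0, ratio = Inf, unbounded = TRUE)
  } else {
    list(free = free, bound = bound, ratio = free / bound, unbounded = FALSE)
  }
}

#' Budget summary table for a set of scenarios
#'
#' @param scenarios Named list of [budget_scenario()] objects.
#' @return `data.frame` with one row per scenario: free, bound, ratio.
#' @export
budget_table <- function(scenarios) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1)
  rows <- lapply(names(scenarios), function(nm) {
    r <- free_to_bound_ratio(scenarios[[nm]])
    data.frame(scenario = nm, n_cells = scenarios[[nm]]$n_cells,
               concentration_nM = scenarios[[nm]]$concentration_nM,
               free_molecules = r$free, bound_molecules = r$bound,
               free_to_bound = r$ratio)
  })
  do.call(rbind, rows)
}
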