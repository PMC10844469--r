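# Dispensing-diffusion model: closed-form point-source field with build-up
# and decay, checked against printed anchors and an independent radial
# finite-difference solver.

cluster_cond <- dispense_conditions("cluster", c0_nM = 318)
single_cond <- dispense_conditions("single_cell", c0_nM = 5500)

test_that("steady-state field is linear in C0 and hits the calibrated peaks", {
  r <- c(0, 10, 50, 200)
  base <- steady_state_concentration(r, cluster_cond)
  doubled <- steady_state_concentration(
    r, dispense_conditions("cluster", c0_nM = 636))
  expect_equal(doubled, 2 * base, tolerance = 1e-12)

  # calibration anchors: both modes peak at 100 nM for their canonical C0
  expect_equal(steady_state_concentration(0, cluster_cond), 100,
               tolerance = 1e-6)
  expect_equal(steady_state_concentration(0, single_cond), 100,
               tolerance = 1e-6)
  expect_error(steady_state_concentration(-1, cluster_cond), "non-negative")
})

test_that("field is non-negative, radially non-increasing, and regularized", {
  r <- seq(0, 800, by = 5)
  conc <- steady_state_concentration(r, cluster_cond)
  expect_true(all(conc >= 0))
  expect_true(all(diff(conc) <= 1e-12))
  # the aperture floor caps the peak instead of diverging
  tiny_h <- dispense_conditions("cluster", c0_nM = 318, height_um = 1e-6)
  expect_true(is.finite(steady_state_concentration(0, tiny_h)))
})

test_that("steady model matches the finite-difference oracle within 5%", {
  oracle <- fd_steady_oracle(cluster_cond)
  r <- c(5, 10, 20, 50, 100, 200, 300, 500)
  reff <- sqrt(r^2 + cluster_cond$height_um^2)
  model <- steady_state_concentration(r, cluster_cond)
  expect_true(all(abs(model - oracle(reff)) / oracle(reff) < 0.02))
})

test_that("diffusive flux through a hemisphere equals the source rate", {
  # evaluate with the height folded out so the radial coordinate is clean
  cond <- dispense_conditions("cluster", c0_nM = 318, height_um = 1e-9)
  s_rate <- cond$flow_m3_per_s * cond$c0_nM # nM m^3 / s
  for (rho_um in c(50, 150, 400)) {
    h <- 0.01
    dc_drho <- (steady_state_concentration(rho_um + h, cond) -
                  steady_state_concentration(rho_um - h, cond)) / (2 * h)
    flux <- -cond$diffusivity_m2_per_s * (dc_drho / 1e-6) *
      2 * pi * (rho_um * 1e-6)^2
    expect_equal(flux, s_rate, tolerance = 0.01)
  }
})

test_that("transient build-up starts at zero, grows monotonically, and saturates", {
  r <- c(10, 50, 120)
  expect_equal(transient_concentration(r, 0, cluster_cond), rep(0, 3))
  for (ri in r) {
    ts <- seq(0.5, cluster_cond$duration_s, length.out = 40)
    cc <- transient_concentration(rep(ri, 40), ts, cluster_cond)
    expect_true(all(diff(cc) >= -1e-12))
  }
  # erfc -> 1 limit: long dispensing reaches steady state
  long_cond <- dispense_conditions("cluster", c0_nM = 318, duration_s = 1e12)
  reff2 <- 50^2 + 20^2
  t_big <- 1e7 * reff2 / (cluster_cond$diffusivity_m2_per_s * 1e12)
  expect_equal(
    transient_concentration(50, t_big, long_cond),
    steady_state_concentration(50, long_cond),
    tolerance = 1e-3
  )
  expect_error(transient_concentration(10, -1, cluster_cond), "non-negative")
})

test_that("transient solution matches the finite-difference oracle", {
  sol_on <- fd_radial_solver(cluster_cond, t_end_s = 300)
  r <- c(5, 20, 50, 100, 300, 500)
  reff <- sqrt(r^2 + cluster_cond$height_um^2)
  model <- transient_concentration(r, 300, cluster_cond)
  expect_true(all(abs(model - sol_on(reff)) / sol_on(reff) < 0.05))

  # post-dispense decay profile at duration + 120 s
  sol_off <- fd_radial_solver(cluster_cond, t_end_s = 420, off_at_s = 300)
  m <- transient_concentration(50, 420, cluster_cond)
  o <- sol_off(sqrt(50^2 + cluster_cond$height_um^2))
  expect_lt(abs(m - o) / o, 0.05)
})

test_that("agonist decays away within minutes of probe removal", {
  r <- seq(0, 100, by = 10)
  after <- transient_concentration(r, cluster_cond$duration_s + 300,
                                   cluster_cond)
  steady <- steady_state_concentration(r, cluster_cond)
  expect_true(all(after < 0.10 * steady))
})

test_that("cells are annotated by radial distance with symmetry preserved", {
  cells <- data.frame(cell_id = 1:10,
                      x_um = 60 * cos(seq(0, 2 * pi, length.out = 10)),
                      y_um = 60 * sin(seq(0, 2 * pi, length.out = 10)))
  ann <- concentration_at_cells(cells, cluster_cond, t_s = 300)
  expect_equal(length(unique(round(ann$conc_nM, 9))), 1) # equal on a ring
  expect_identical(ann$x_um, cells$x_um)

  at_origin <- concentration_at_cells(
    data.frame(cell_id = 1, x_um = 0, y_um = 0), cluster_cond,
    t_s = cluster_cond$duration_s,
    origin = c(0, 0))
  # cell right beneath the probe sees ~C_max once near steady state
  expect_equal(at_origin$conc_nM, 100, tolerance = 0.05)

  empty <- concentration_at_cells(cells[0, ], cluster_cond)
  expect_equal(nrow(empty), 0)
  expect_error(
    concentration_at_cells(data.frame(cell_id = 1, x_um = NA, y_um = 2),
                           cluster_cond),
    "positions")
})

test_that("cell-height ambiguity yields the reported C_max uncertainty", {
  # degenerate interval collapses to a point at C_max
  deg <- cmax_uncertainty(single_cond, c(4, 4))
  expect_equal(unname(deg["min"]), unname(deg["max"]))
  expect_equal(unname(deg["min"]),
               steady_state_concentration(0, single_cond))

  # heights spanning one to two cell heights: factor-2 span whose width is
  # about 50% of the nominal peak ("about 50% uncertainty in C_max")
  u <- cmax_uncertainty(single_cond, c(4, 8))
  expect_equal(unname(u["max"] / u["min"]), 2, tolerance = 1e-9)
  expect_equal(unname((u["max"] - u["min"]) / u["max"]), 0.5,
               tolerance = 1e-9)

  # widening the interval never shrinks it
  wide <- cmax_uncertainty(single_cond, c(3, 9))
  expect_lte(wide["min"], u["min"])
  expect_gte(wide["max"], u["max"])
  expect_error(cmax_uncertainty(single_cond, c(8, 4)), "interval")
})

test_that("profile export is long-format and consistent with the field", {
  tab <- field_profile_table(cluster_cond, r_um = c(0, 50, 100),
                             t_s = c(60, 300))
  expect_named(tab, c("r_um", "t_s", "conc_nM"))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$conc_nM[tab$r_um == 50 & tab$t_s == 300],
               transient_concentration(50, 300, cluster_cond))
})
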