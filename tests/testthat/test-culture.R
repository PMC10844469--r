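# Synthetic culture generator and dose-time-density response model.

test_that("empty and degenerate cultures are handled", {
  empty <- generate_culture(culture_config(density = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("cell_id", "x_um", "y_um", "nuc_cyt_ratio") %in%
                    names(empty)))
  expect_error(
    generate_culture(culture_config(density = 5000, field_width = 20000,
                                    field_height = 20000, seed = 1)),
    "1e6")
})

test_that("realized intensity matches the configured density", {
  # Thomas process is stationary: mean count = density * area
  counts <- vapply(1:200, function(s) {
    nrow(generate_culture(culture_config(density = 400, seed = s)))
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 400), 3 * se)
})

test_that("presets produce the intended density classes", {
  sparse <- generate_culture(culture_preset("sparse", seed = 11))
  expect_lt(nrow(sparse) / 1, 1000) # 1 mm^2 field
  expect_equal(density_classify(sparse, 1), "sparse")
  dense <- generate_culture(culture_preset("dense", seed = 11))
  expect_equal(density_classify(dense, 1), "dense")
})

test_that("positions stay inside the field and clustering is real", {
  cfg <- culture_config(density = 800, field_width = 600,
                        field_height = 400, seed = 7)
  cells <- generate_culture(cfg)
  expect_true(all(abs(cells$x_um) <= 300 & abs(cells$y_um) <= 200))
  # clustered layout: mean nearest-neighbor distance well below the
  # Poisson expectation 1 / (2 sqrt(intensity))
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  diag(d) <- Inf
  nn <- mean(apply(d, 1, min))
  poisson_nn <- 1 / (2 * sqrt(nrow(cells) / (600 * 400)))
  expect_lt(nn, 0.8 * poisson_nn)
})

test_that("generation is deterministic given the seed", {
  a <- generate_culture(culture_config(density = 500, seed = 42))
  b <- generate_culture(culture_config(density = 500, seed = 42))
  expect_identical(a, b)
  c2 <- generate_culture(culture_config(density = 500, seed = 43))
  expect_false(identical(a, c2))
})

test_that("activation probability has the stated limits and midpoint", {
  p <- response_params()
  expect_equal(activation_probability(0, 5, 400, p), p$background_rate)
  # below the minimum stimulation time nothing responds
  expect_equal(activation_probability(1e5, 3, 400, p), p$background_rate)
  # logistic midpoint at the effective EC50 with zero background
  p0 <- response_params(background_rate = 0)
  ec <- effective_ec50(5, 400, p0)
  expect_equal(activation_probability(ec, 5, 400, p0), 0.5)
})

test_that("dense 5-min threshold is tenfold the sparse threshold", {
  p <- response_params()
  expect_equal(effective_ec50(5, 3750, p) / effective_ec50(5, 400, p), 10)
  # and the shift is gone at the restoring stimulation time
  expect_equal(effective_ec50(15, 3750, p), p$ec50_base)
})

test_that("activation probability is monotone in dose, time, and density", {
  p <- response_params()
  conc <- 10^seq(-1, 4, length.out = 30)
  probs <- activation_probability(conc, 5, 2000, p)
  expect_true(all(diff(probs) >= 0))
  for (cc in c(30, 100, 500)) {
    by_t <- vapply(c(5, 8, 11, 15, 30), function(t) {
      activation_probability(cc, t, 3000, p)
    }, numeric(1))
    expect_true(all(diff(by_t) >= -1e-12))
    by_d <- vapply(c(200, 1000, 2000, 3750), function(dd) {
      activation_probability(cc, 5, dd, p)
    }, numeric(1))
    expect_true(all(diff(by_d) <= 1e-12))
  }
})

test_that("simulated activation recovers configured probabilities", {
  p <- response_params()
  cells <- generate_culture(culture_config(density = 2000, seed = 3), p)
  cells <- cells[1:2000, ]
  # target p in {background, 0.5, 0.85} via the matching dose
  target_p <- c(0.06, 0.5, 0.85)
  doses <- vapply(target_p, function(tp) {
    q <- (tp - p$background_rate) / (1 - p$background_rate)
    if (q <= 0) 0 else {
      10^(log10(effective_ec50(15, 2000, p)) +
            stats::qlogis(q) / p$hill_slope)
    }
  }, numeric(1))
  for (i in seq_along(target_p)) {
    sim <- simulate_response(cells, t_stim_min = 15, density = 2000,
                             params = p, seed = 100 + i,
                             bath_conc_nM = doses[i])
    ci <- stats::binom.test(sum(sim$ground_truth), nrow(sim),
                            conf.level = 0.99)$conf.int
    expect_gte(target_p[i], ci[1])
    expect_lte(target_p[i], ci[2])
  }
})

test_that("zero-dose response sits at background and saturating dose at one", {
  p <- response_params()
  cells <- generate_culture(culture_config(density = 1000, seed = 5), p)
  sim0 <- simulate_response(cells, 5, 1000, p, seed = 8, bath_conc_nM = 0)
  ci <- stats::binom.test(sum(sim0$ground_truth), nrow(sim0),
                          conf.level = 0.99)$conf.int
  expect_gte(p$background_rate, ci[1])
  expect_lte(p$background_rate, ci[2])
  # probability forced to one activates everything
  p1 <- response_params(background_rate = 0.999999)
  sim1 <- simulate_response(cells, 15, 1000, p1, seed = 8,
                            bath_conc_nM = 1e6)
  expect_true(all(sim1$ground_truth))
  # activated ratios sit above resting ones on the whole
  expect_gt(median(sim1$nuc_cyt_ratio), median(sim0$nuc_cyt_ratio))
})

test_that("single-cell targeting beats a dense uniform bath at 100 nM / 5 min", {
  p <- response_params()
  # target cell right beneath the probe in a sparse culture
  p_target <- activation_probability(100, 5, 400, p)
  # same concentration as a bath on a dense culture
  p_bath <- activation_probability(100, 5, 3750, p)
  expect_gt(p_target, 0.5)
  expect_lt(p_bath, 0.1)
})

test_that("simulation requires concentrations and is seed-deterministic", {
  p <- response_params()
  cells <- generate_culture(culture_config(density = 300, seed = 2), p)
  expect_error(simulate_response(cells, 5, 300, p, seed = 1),
               "concentrations")
  a <- simulate_response(cells, 5, 300, p, seed = 9, bath_conc_nM = 200)
  b <- simulate_response(cells, 5, 300, p, seed = 9, bath_conc_nM = 200)
  expect_identical(a, b)
})
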