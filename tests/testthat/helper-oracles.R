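# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: the diffusion oracle is a finite-volume
# radial PDE solver, the spatial oracle a double loop, and the resampling
# oracles exhaustive enumerations.

# --- finite-difference (finite-volume) radial diffusion solver -------------
# Spherically symmetric diffusion into a half-space from a continuous point
# source on a reflecting plane: dC/dt = D (C'' + 2/rho C'), with the source
# entering as a flux S through the hemisphere at the inner boundary and
# C -> 0 far away. Returns a function conc(rho_um, t_s). Source can be
# switched off at `off_at_s` to model post-dispense decay.
fd_radial_solver <- function(cond, t_end_s, off_at_s = Inf,
                             drho = 4, rho_max = 2500) {
  d_um2 <- cond$diffusivity_m2_per_s * 1e12          # um^2/s
  s_rate <- cond$flow_m3_per_s * 1e18 * cond$c0_nM   # nM * um^3 / s
  rho0 <- cond$aperture_radius_um
  centers <- seq(rho0 + drho / 2, rho_max, by = drho)
  n <- length(centers)
  faces <- c(rho0, centers + drho / 2)               # n + 1 faces
  vol <- (2 * pi / 3) * (faces[-1]^3 - faces[-(n + 1)]^3)
  area <- 2 * pi * faces^2                           # hemisphere areas

  # tridiagonal diffusion operator (outer boundary held at 0)
  lower <- upper <- diag_v <- numeric(n)
  for (i in seq_len(n)) {
    a_in <- if (i == 1) 0 else d_um2 * area[i] / (drho * vol[i])
    a_out <- d_um2 * area[i + 1] / (drho * vol[i])
    if (i > 1) lower[i] <- a_in
    if (i < n) upper[i] <- a_out
    diag_v[i] <- -(a_in + a_out)
  }
  lmat <- matrix(0, n, n)
  diag(lmat) <- diag_v
  lmat[cbind(2:n, 1:(n - 1))] <- lower[2:n]
  lmat[cbind(1:(n - 1), 2:n)] <- upper[1:(n - 1)]

  src <- numeric(n)
  src[1] <- s_rate / vol[1]

  run_phase <- function(conc, t_from, t_to, dt) {
    if (t_to <= t_from) return(list(conc = conc, t = t_from))
    steps <- ceiling((t_to - t_from) / dt)
    dt <- (t_to - t_from) / steps
    ainv <- solve(diag(n) - dt * lmat)
    t <- t_from
    for (k in seq_len(steps)) {
      on <- if (t < off_at_s) 1 else 0
      conc <- ainv %*% (conc + dt * src * on)
      t <- t + dt
    }
    list(conc = as.numeric(conc), t = t)
  }

  conc <- numeric(n)
  # fine steps early (steep build-up), then coarse; split again at switch-off
  breaks <- sort(unique(pmin(c(5, off_at_s, off_at_s + 5, t_end_s), t_end_s)))
  breaks <- breaks[breaks > 0]
  t_cur <- 0
  for (b in breaks) {
    dt <- if (b - t_cur <= 10 || t_cur < 5 ||
              (t_cur >= off_at_s && t_cur < off_at_s + 5)) 0.05 else 0.5
    res <- run_phase(conc, t_cur, b, dt)
    conc <- res$conc
    t_cur <- res$t
  }
  function(rho_um) stats::approx(centers, conc, xout = rho_um,
                                 rule = 2)$y
}

# steady-state oracle: integrate the steady flux relation outward, i.e. a
# direct quadrature of dC/drho = -S / (2 pi D rho^2) from infinity inward
fd_steady_oracle <- function(cond, drho = 0.5, rho_max = 50000) {
  d_um2 <- cond$diffusivity_m2_per_s * 1e12
  s_rate <- cond$flow_m3_per_s * 1e18 * cond$c0_nM
  faces <- seq(cond$aperture_radius_um, rho_max, by = drho)
  mid <- (faces[-1] + faces[-length(faces)]) / 2
  dc <- s_rate * drho / (2 * pi * d_um2 * mid^2)
  conc <- rev(cumsum(rev(dc))) # C at faces[-length], tail ~ S/(2 pi D R)
  conc <- conc + s_rate / (2 * pi * d_um2 * rho_max)
  function(rho_um) stats::approx(faces[-length(faces)], conc,
                                 xout = rho_um, rule = 2)$y
}

# --- spatial oracle --------------------------------------------------------
brute_force_neighbors <- function(x, y, radius) {
  n <- length(x)
  counts <- integer(n)
  for (i in seq_len(n)) {
    k <- 0L
    for (j in seq_len(n)) {
      if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= radius) {
        k <- k + 1L
      }
    }
    counts[i] <- k
  }
  counts
}

# --- resampling oracles ----------------------------------------------------
# exact distribution of the with-replacement resampled fraction for a pool
# of binary calls and sample size k: Binomial(k, mean(pool)) / k
exact_exceedance_prob <- function(pool, k, observed_frac) {
  p <- mean(pool)
  sum(stats::dbinom(0:k, k, p)[(0:k) / k >= observed_frac - 1e-12])
}

# exhaustive permutation distribution of the weighted between-group SS for
# small groups; returns the exact p-value for the observed grouping
exact_anova_p <- function(groups) {
  values <- unlist(groups)
  sizes <- lengths(groups)
  n <- length(values)
  stat <- function(v) {
    grand <- mean(v)
    idx <- split(seq_len(n), rep(seq_along(sizes), sizes))
    sum(sizes * (vapply(idx, function(i) mean(v[i]), numeric(1)) - grand)^2)
  }
  obs <- stat(values)
  perms <- all_permutations(n)
  stats_all <- apply(perms, 1, function(ord) stat(values[ord]))
  mean(stats_all >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# small helper: binary call vector with a given number of successes
calls_of <- function(n_true, n_total) {
  c(rep(TRUE, n_true), rep(FALSE, n_total - n_true))
}
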