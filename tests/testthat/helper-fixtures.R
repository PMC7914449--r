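# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# --- scenario builders -----------------------------------------------------

# DEPE-like two-transition scan: gel-to-fluid at 35 degC, fluid-to-HII at
# 62 degC (enthalpies per the pure-DEPE calorimetry row).
depe_params <- function(noise_sd = 0, seed = 1L, baseline = FALSE) {
  thermogram_params(
    list(list(Tm = 35, dH = 7.1094, dH_vH = 600),
         list(Tm = 62, dH = 0.5, dH_vH = 800)),
    baseline_slope = if (baseline) 0.002 else 0,
    baseline_intercept = if (baseline) 0.05 else 0,
    noise_sd = noise_sd, t_range = c(10, 70), t_step = 0.05, seed = seed)
}

# DMPC-at-8-degC-styled electron-density model (structural-table row).
dmpc_model <- function(eta = 0, n_lamellae = 20L) {
  lamellar_model_params(d = 64.0, zH = 19.5, sigmaH = 3.0, sigmaC = 5.4,
                        rho_ratio = -1, n_lamellae = n_lamellae, eta = eta)
}

saxd_grid <- function(n = 600L) seq(0.0075, 0.07, length.out = n)
waxd_grid <- function(n = 400L) seq(0.20, 0.29, length.out = n)

# --- independent oracles ---------------------------------------------------

# O(N^2) brute-force contact count with explicit minimum-image loops.
brute_contacts <- function(frame, groupA, groupB, box, cutoff) {
  A <- frame[frame$group == groupA, ]
  B <- frame[frame$group == groupB, ]
  cnt <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d2 <- 0
    for (k in c("x", "y", "z")) {
      L <- box[match(k, c("x", "y", "z"))]
      dd <- A[[k]][i] - B[[k]][j]
      dd <- dd - L * round(dd / L)
      d2 <- d2 + dd * dd
    }
    if (d2 < cutoff^2) cnt <- cnt + 1L
  }
  cnt
}

# Exhaustive lamellar order assignment over h in 1..6: minimises the RMS
# relative residual, preferring the smallest order sum among near-ties.
exhaustive_lamellar_orders <- function(s, hmax = 6L, tol = 0.03) {
  s <- sort(s)
  n <- length(s)
  combs <- utils::combn(seq_len(hmax), n, simplify = FALSE)
  best <- NULL
  for (h in combs) {
    inv_d <- sum(h * s) / sum(h^2)
    pred <- h * inv_d
    res <- sqrt(mean(((s - pred) / pred)^2))
    if (res > tol) next
    score <- c(res, sum(h))
    if (is.null(best) || res < best$res - 1e-12 ||
        (res < best$res + 1e-12 && sum(h) < best$sum_h))
      best <- list(h = h, res = res, sum_h = sum(h))
  }
  best
}

# Numerical-quadrature oracle for the two-state excess heat capacity:
# integrate the closed-form peak on a fine grid, independent of the
# generator's grid.
quad_two_state_dH <- function(Tm, dH, dH_vH, lo = Tm - 20, hi = Tm + 20) {
  f <- function(tc) {
    R <- 1.98720425864083e-3
    TK <- tc + 273.15; TmK <- Tm + 273.15
    lK <- -(dH_vH / R) * (1 / TK - 1 / TmK)
    dH * dH_vH / (R * TK^2) / (4 * cosh(lK / 2)^2)
  }
  stats::integrate(f, lo, hi, rel.tol = 1e-9)$value
}

# Edge positions of the ideal axially symmetric powder pattern by direct
# evaluation of the orientation law on a dense theta grid (independent of
# the histogram/convolution implementation).
powder_edges_oracle <- function(delta_sigma, phase, delta_iso = 0) {
  delta_eff <- switch(phase, lamellar = delta_sigma,
                      hexagonal = -delta_sigma / 2, isotropic = 0)
  th <- seq(0, pi / 2, length.out = 10001)
  pos <- delta_iso - (delta_eff / 3) * (3 * cos(th)^2 - 1)
  range(pos)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
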