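# Generators: determinism, the statistical structure downstream stages
# assume, and the documented error cases.

test_that("gen_thermogram integrates to dH and peaks at Tm", {
  # quadrature oracle for the closed-form peak, frozen expectation
  expect_equal(quad_two_state_dH(30, 6, 300), 6, tolerance = 1e-6)

  p <- thermogram_params(list(list(Tm = 30, dH = 6, dH_vH = 300)),
                         t_range = c(10, 50), t_step = 0.05, seed = 1)
  tg <- gen_thermogram(p)
  expect_lt(abs(trapz(tg$temperature, tg$cp) - 6), 0.06)   # within 1%
  expect_lt(abs(tg$temperature[which.max(tg$cp)] - 30), 0.05 + 1e-9)

  # identity case: nothing in, zero out
  p0 <- thermogram_params(list(), t_range = c(10, 20), t_step = 0.5, seed = 1)
  expect_true(all(gen_thermogram(p0)$cp == 0))

  # DEPE-like scenario: maxima at the stated transition temperatures
  tg2 <- gen_thermogram(depe_params())
  tr <- find_transitions(tg2)
  expect_length(tr, 2L)
  expect_lt(abs(tr[[1]]$t_max - 35), 0.05 + 1e-9)
  expect_lt(abs(tr[[2]]$t_max - 62), 0.05 + 1e-9)

  # invalid grid
  expect_error(gen_thermogram(thermogram_params(list(), t_range = c(10, 11),
                                                t_step = 0.5)),
               class = "memphys_invalid_grid")
  # invariant guards
  expect_error(thermogram_params(list(list(Tm = 30, dH = 6, dH_vH = 3))),
               "dH_vH")
})

test_that("gen_saxs_pattern places Bragg orders at h/d and is deterministic", {
  s <- saxd_grid()
  pat <- gen_saxs_pattern(dmpc_model(), s)
  expect_true(all(pat$intensity >= 0))
  pk <- pick_peaks(pat)
  ds <- 1 / pk$s_peak
  step <- s[2] - s[1]
  for (h in 1:3) {
    target <- h / 64
    expect_true(min(abs(pk$s_peak - target)) <= step,
                label = sprintf("order %d near %g", h, target))
  }
  # determinism with noise
  a <- gen_saxs_pattern(dmpc_model(), s, noise_sd = 50, seed = 42)
  b <- gen_saxs_pattern(dmpc_model(), s, noise_sd = 50, seed = 42)
  expect_identical(a$intensity, b$intensity)
  # windows with / without a Bragg order set the warning attribute
  ok_win <- gen_saxs_pattern(dmpc_model(), seq(0.012, 0.02, length.out = 50))
  expect_null(attr(ok_win, "warning"))
  empty_win <- gen_saxs_pattern(dmpc_model(), seq(0.001, 0.01,
                                                  length.out = 50))
  expect_identical(attr(empty_win, "warning"), "no_bragg_order")
})

test_that("gen_hexagonal_pattern peaks follow sqrt(h^2+hk+k^2)/d10", {
  s <- seq(0.0075, 0.07, length.out = 900)
  pat <- gen_hexagonal_pattern(60, s)
  pk <- pick_peaks(pat)
  step <- s[2] - s[1]
  expected <- sqrt(c(1, 3, 4, 7)) / 60
  expect_gte(nrow(pk), 4L)
  for (e in expected)
    expect_true(min(abs(pk$s_peak - e)) <= step, label = sprintf("peak %g", e))
  expect_identical(classify_phase_saxd(pk)$phase, "hexagonal_II")
  # degenerate single-peak window flags
  pat1 <- gen_hexagonal_pattern(60, seq(0.015, 0.02, length.out = 60))
  expect_identical(attr(pat1, "warning"), "single_peak_window")
})

test_that("gen_noesy_table: volumes ordered by overlap; scale cancels", {
  depth <- popc_des_depth_distribution()
  nt <- gen_noesy_table(depth, c("DES_III", "DES_IV"), tm = 0.3, seed = 1)
  expect_true(all(nt$cross >= 0))
  expect_true(all(nt$diagonal > 0))
  # cross-peak ordering matches the generating overlap ordering (per unit
  # proton count, which is what sigma sees)
  g <- function(l) depth$groups[[match(l, depth$labels)]]
  lig <- g("DES_III")
  ov <- vapply(rownames(nt$cross), function(l) {
    gi <- g(l)
    dnorm(lig$mean_z - gi$mean_z, 0, sqrt(lig$sd_z^2 + gi$sd_z^2))
  }, numeric(1))
  sig <- nt$cross[, "DES_III"] / (nt$diagonal[rownames(nt$cross)] * nt$tm)
  expect_identical(order(sig), order(ov))

  # disjoint distributions: essentially no contact
  far <- depth_distribution(list(
    list(label = "A", mean_z = 0, sd_z = 0.1, n_atoms = 5L, atom_mass = 14),
    list(label = "B", mean_z = 0.1, sd_z = 0.1, n_atoms = 5L, atom_mass = 14),
    list(label = "L", mean_z = 5, sd_z = 0.1, n_atoms = 5L, atom_mass = 14)))
  ntf <- gen_noesy_table(far, "L", tm = 0.3, seed = 1)
  expect_lt(max(ntf$cross), 1e-8 * max(ntf$diagonal))

  # empty ligand list errors
  expect_error(gen_noesy_table(depth, character(0), tm = 0.3),
               class = "memphys_invalid_input")

  # rescaling the table leaves rates unchanged (exact ratio invariance)
  r1 <- cross_relaxation_rates(nt)$rates
  nt2 <- gen_noesy_table(depth, c("DES_III", "DES_IV"), tm = 0.3,
                         scale = 3.7e4, seed = 1)
  r2 <- cross_relaxation_rates(nt2)$rates
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("gen_trajectory samples the stated depth distribution", {
  depth <- depth_distribution(list(
    list(label = "CH3", mean_z = 0, sd_z = 0.3, n_atoms = 100L,
         atom_mass = 15),
    list(label = "C2", mean_z = 1.4, sd_z = 0.25, n_atoms = 100L,
         atom_mass = 14)))
  tr <- gen_trajectory(depth, n_frames = 100, box = c(4, 4, 10), seed = 2)
  # counts conserved across frames
  for (f in tr$frames) expect_identical(as.vector(table(f$group)),
                                        c(100L, 100L))
  z <- unlist(lapply(tr$frames, function(f) f$z[f$group == "C2"]))
  se <- 0.25 / sqrt(length(z))
  expect_lt(abs(mean(z) - 1.4), 3 * se)
  expect_lt(abs(sd(z) / 0.25 - 1), 0.05)      # 10^4 samples, sd within 5%
  xy <- unlist(lapply(tr$frames, function(f) f$x))
  expect_gte(min(xy), 0); expect_lte(max(xy), 4)

  # single atom, single frame: exactly that coordinate count
  d1 <- depth_distribution(list(
    list(label = "A", mean_z = 0.5, sd_z = 0.2, n_atoms = 1L,
         atom_mass = 12)))
  t1 <- gen_trajectory(d1, 1, c(3, 3, 6), seed = 9)
  expect_identical(nrow(t1$frames[[1]]), 1L)

  # zero-atom group omitted with warning
  d0 <- depth_distribution(list(
    list(label = "A", mean_z = 0, sd_z = 0.2, n_atoms = 2L, atom_mass = 12),
    list(label = "B", mean_z = 1, sd_z = 0.2, n_atoms = 0L, atom_mass = 12)))
  expect_warning(t0 <- gen_trajectory(d0, 2, c(3, 3, 6), seed = 1),
                 "zero-atom")
  expect_false("B" %in% t0$frames[[1]]$group)

  # determinism
  ta <- gen_trajectory(depth, 3, c(4, 4, 10), seed = 7)
  tb <- gen_trajectory(depth, 3, c(4, 4, 10), seed = 7)
  expect_identical(ta$frames, tb$frames)
})
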