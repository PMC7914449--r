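# SAXD/WAXD: peak picking, indexing (with exhaustive-search oracle),
# classification, model fitting, thickness arithmetic.

test_that("pick_peaks finds printed-position reflections and ignores flats", {
  # flat pattern: no peaks
  flat <- diffraction_pattern(waxd_grid(), rep(1, 400), "WAXD")
  expect_identical(nrow(pick_peaks(flat)), 0L)

  # sharp 4.19 A + shoulder 4.10 A doublet resolvable with
  # shoulder-sensitive prominence
  pat <- gen_waxd_pattern(list(list(d = 4.19, height = 1, width_s = 0.0012),
                               list(d = 4.10, height = 0.45,
                                    width_s = 0.0018)),
                          waxd_grid())
  pk <- pick_peaks(pat, min_prominence = 0.05)
  expect_gte(nrow(pk), 2L)
  expect_lt(min(abs(pk$d - 4.19)), 0.02)
  expect_lt(min(abs(pk$d - 4.10)), 0.02)
})

test_that("index_lamellar accepts printed spacings and matches exhaustive search", {
  # printed DMPC 8 degC set: orders 1/2/3 at 3% tolerance
  pk <- data.frame(s_peak = 1 / c(64.03, 31.41, 20.40))
  il <- index_lamellar(pk)
  expect_identical(il$orders, 1:3)
  expect_false(il$indeterminate)
  # printed 15 degC pair
  il2 <- index_lamellar(data.frame(s_peak = 1 / c(72.18, 37.12)))
  expect_identical(il2$orders, 1:2)
  expect_false(il2$indeterminate)
  # single peak: d returned, order 1, zero residual
  il1 <- index_lamellar(data.frame(s_peak = 1 / 58))
  expect_equal(il1$d, 58)
  expect_identical(il1$orders, 1L)
  expect_identical(il1$residual, 0)

  # oracle equivalence: greedy equals exhaustive assignment over h in 1..6
  set.seed(99)
  for (rep_i in 1:20) {
    d_true <- runif(1, 50, 80)
    hs <- sort(sample(1:4, sample(2:4, 1)))
    s <- hs / d_true * (1 + runif(length(hs), -0.004, 0.004))
    gr <- index_lamellar(data.frame(s_peak = s))
    ex <- exhaustive_lamellar_orders(s)
    # same up to overall integer scaling of the order vector
    expect_false(is.null(ex))
    ratio <- gr$orders / ex$h
    expect_true(all(abs(ratio - ratio[1]) < 1e-9),
                label = "greedy and exhaustive assignments proportional")
  }

  # invariance to peak-list permutation and intensity rescaling
  pkp <- pk[c(3, 1, 2), , drop = FALSE]
  expect_equal(index_lamellar(pkp)$d, il$d)
})

test_that("index_hexagonal fits the 2D lattice law and flags degeneracy", {
  pk <- data.frame(s_peak = sqrt(c(1, 3, 4, 7)) / 60)
  ih <- index_hexagonal(pk)
  expect_identical(ih$indices, c("10", "11", "20", "21"))
  expect_lt(abs(ih$d10 - 60), 1e-9)
  expect_false(ih$indeterminate)
  # round-trip through the generator within 0.5%
  pat <- gen_hexagonal_pattern(60, seq(0.0075, 0.07, length.out = 900))
  ih2 <- index_hexagonal(pick_peaks(pat))
  expect_rel_equal(ih2$d10, 60, 0.005)
  # a 1 : 1/2 doublet is degenerate: lamellar wins on residual
  two <- data.frame(s_peak = c(1, 2) / 64)
  expect_gt(index_hexagonal(two)$residual, index_lamellar(two)$residual)
  expect_error(index_hexagonal(data.frame(s_peak = 0.016)), ">= 2")
})

test_that("classify_phase_saxd separates the printed lamellar and HII sets", {
  expect_identical(
    classify_phase_saxd(data.frame(s_peak = 1 / c(64.03, 31.41, 20.40)))$phase,
    "lamellar")
  hx <- classify_phase_saxd(data.frame(s_peak = sqrt(c(1, 3, 4, 7)) / 60))
  expect_identical(hx$phase, "hexagonal_II")
  expect_gt(nchar(hx$evidence), 0)
  expect_identical(classify_phase_saxd(data.frame(s_peak = 0.02))$phase,
                   "indeterminate")
})

test_that("classify_packing_waxd: gel doublet, gel singlet, fluid hump", {
  g <- waxd_grid()
  doublet <- gen_waxd_pattern(list(list(d = 4.19, height = 1,
                                        width_s = 0.0012),
                                   list(d = 4.10, height = 0.45,
                                        width_s = 0.0018)), g)
  expect_identical(as.character(classify_packing_waxd(doublet)),
                   "L_beta_prime")
  singlet <- gen_waxd_pattern(list(list(d = 4.15, height = 1,
                                        width_s = 0.0015)), g)
  expect_identical(as.character(classify_packing_waxd(singlet)),
                   "L_beta_or_P_beta_prime")
  hump <- gen_waxd_pattern(list(list(d = 4.4, height = 0.3,
                                     width_s = 0.02)), g)
  expect_identical(as.character(classify_packing_waxd(hump)), "fluid")
  expect_error(classify_packing_waxd(gen_saxs_pattern(dmpc_model(),
                                                      saxd_grid())),
               "WAXD")
})

test_that("derive_thickness reproduces the structural-table arithmetic", {
  # all six table rows, sigmaH = 3.0 implied by dB = 2(zH + 2 sigmaH)
  d <- c(64.0, 70.9, 72.8, 64.6, 65.6, 66.7)
  zH <- c(19.5, 19.2, 19.1, 18.0, 17.5, 17.5)
  th <- derive_thickness(d, zH, rep(3.0, 6))
  expect_equal(th$dHH, 2 * zH)
  expect_equal(th$dB, c(51.0, 50.4, 50.2, 48.0, 47.0, 47.0))
  expect_equal(th$dw, c(13.0, 20.5, 22.6, 16.6, 18.6, 19.7))
  expect_equal(th$dw + th$dB, d)                  # exact identity
  # boundary: zero water layer errors
  expect_error(derive_thickness(2 * (19 + 2 * 3), 19, 3),
               class = "memphys_negative_water")
  expect_error(derive_thickness(64, -1, 3), "positive")
})

test_that("fit_saxs round-trips generator parameters", {
  pat <- gen_saxs_pattern(dmpc_model(), saxd_grid())
  init <- lamellar_model_params(63, 20.2, 2.8, 5.8, -0.9, 20L, 0)
  fit <- fit_saxs(pat, init, n_starts = 2L)
  expect_rel_equal(fit$d, 64.0, 0.02)
  expect_rel_equal(fit$zH, 19.5, 0.02)
  expect_rel_equal(fit$sigmaH, 3.0, 0.02)
  expect_rel_equal(fit$sigmaC, 5.4, 0.02)
  # derived identities hold exactly
  expect_identical(fit$dHH, 2 * fit$zH)
  expect_identical(fit$dB, 2 * (fit$zH + 2 * fit$sigmaH))
  expect_identical(fit$dw + fit$dB, fit$d)
  # scale invariance: doubling intensities changes no structural parameter
  pat2 <- diffraction_pattern(pat$s, 2 * pat$intensity, "SAXD")
  fit2 <- fit_saxs(pat2, init, n_starts = 2L)
  expect_rel_equal(fit2$d, fit$d, 1e-4)
  expect_rel_equal(fit2$zH, fit$zH, 1e-3)
})
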