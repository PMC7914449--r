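# Trajectory analysis: centring, density profiles, contact counting (with
# brute-force oracle), NOESY concordance.

small_traj <- function(seed = 1L, n_frames = 5L) {
  depth <- depth_distribution(list(
    list(label = "A", mean_z = 0.5, sd_z = 0.4, n_atoms = 30L,
         atom_mass = 14),
    list(label = "B", mean_z = -0.5, sd_z = 0.4, n_atoms = 30L,
         atom_mass = 15)))
  gen_trajectory(depth, n_frames, box = c(3, 3, 6), seed = seed)
}

test_that("center_frames zeroes the reference COM and is idempotent", {
  tr <- small_traj()
  ct <- center_frames(tr, "A")
  for (f in ct$frames) {
    sel <- f$group == "A"
    com <- sum(f$z[sel] * f$mass[sel]) / sum(f$mass[sel])
    expect_lt(abs(com), 1e-9)
  }
  ct2 <- center_frames(ct, "A")
  expect_equal(ct2$frames, ct$frames, tolerance = 1e-12)
  expect_error(center_frames(tr, "missing"), "frame 1")
})

test_that("mass_density_profile conserves mass and has a closed form", {
  # one atom of mass m at z = 0 in a 4x4 box with 0.1 nm bins
  fr <- data.frame(group = "A", x = 1, y = 1, z = 0.001, mass = 15)
  tr <- group_trajectory(list(fr), c(4, 4, 6))
  dp <- mass_density_profile(tr, bin_width = 0.1)
  nz <- which(dp$density[, "A"] > 0)
  expect_length(nz, 1L)
  expect_equal(unname(dp$density[nz, "A"]), 15 / (16 * 0.1) * 1.66053906660,
               tolerance = 1e-9)
  # mass conservation, exact per group
  tr2 <- small_traj(seed = 3, n_frames = 8L)
  dp2 <- mass_density_profile(tr2, bin_width = 0.13)  # width gets adjusted
  area <- tr2$box[1] * tr2$box[2]
  for (g in c("A", "B")) {
    m_profile <- sum(dp2$density[, g]) * dp2$bin_width * area /
      1.66053906660
    m_true <- sum(tr2$frames[[1]]$mass[tr2$frames[[1]]$group == g])
    expect_equal(m_profile, m_true, tolerance = 1e-9)
  }
  # Gaussian-placed group: profile mean within 3 SE of generator mean_z
  depth <- depth_distribution(list(
    list(label = "G", mean_z = 0.8, sd_z = 0.3, n_atoms = 50L,
         atom_mass = 14)))
  tr3 <- gen_trajectory(depth, 40, c(4, 4, 8), seed = 5)
  dp3 <- mass_density_profile(tr3, bin_width = 0.05)
  w <- dp3$density[, "G"]
  mu <- sum(dp3$z * w) / sum(w)
  se <- 0.3 / sqrt(50 * 40)
  expect_lt(abs(mu - 0.8), 3 * se + dp3$bin_width / 2)
  # mirrored bilayer: symmetric profiles about 0 within sampling error
  depth_m <- depth_distribution(list(
    list(label = "CH3", mean_z = 0, sd_z = 0.3, n_atoms = 40L,
         atom_mass = 15),
    list(label = "C2", mean_z = 1.4, sd_z = 0.25, n_atoms = 40L,
         atom_mass = 14)))
  trm <- center_frames(gen_trajectory(depth_m, 60, c(4, 4, 8), seed = 6,
                                      mirror = TRUE), "CH3")
  dpm <- mass_density_profile(trm, bin_width = 0.2)
  prof <- dpm$density[, "C2"]
  mu_m <- sum(dpm$z * prof) / sum(prof)
  expect_lt(abs(mu_m), 0.1)
})

test_that("count_contacts equals the brute-force oracle, with wrap", {
  tr <- small_traj(seed = 7, n_frames = 10L)
  cc <- count_contacts(tr, "A", "B", 0.5)
  oracle <- vapply(tr$frames, brute_contacts, numeric(1),
                   groupA = "A", groupB = "B", box = tr$box, cutoff = 0.5)
  expect_identical(cc$per_frame, oracle)
  expect_equal(cc$mean_contacts, mean(oracle))
  # symmetry
  expect_equal(count_contacts(tr, "B", "A", 0.5)$mean_contacts,
               cc$mean_contacts)
  # explicit wrap case: atoms near opposite faces are neighbours
  fr <- data.frame(group = c("A", "B"), x = c(0.1, 2.9), y = c(0.1, 2.9),
                   z = c(-2.9, 2.9), mass = 14)
  trw <- group_trajectory(list(fr), c(3, 3, 6))
  expect_identical(count_contacts(trw, "A", "B", 0.5)$per_frame, 1)
  expect_identical(brute_contacts(fr, "A", "B", c(3, 3, 6), 0.5), 1L)
  # closed-form cases: 0.4 nm apart -> 1 contact; 0.6 nm -> 0
  near <- group_trajectory(list(data.frame(group = c("A", "B"),
                                           x = c(1, 1.4), y = 1, z = 0,
                                           mass = 14)), c(3, 3, 6))
  expect_identical(count_contacts(near, "A", "B", 0.5)$mean_contacts, 1)
  far <- group_trajectory(list(data.frame(group = c("A", "B"),
                                          x = c(1, 1.6), y = 1, z = 0,
                                          mass = 14)), c(3, 3, 6))
  expect_identical(count_contacts(far, "A", "B", 0.5)$mean_contacts, 0)
  expect_error(count_contacts(tr, "A", "A", 0.5), "disjoint")
})

test_that("contact counts are invariant to a rigid wrapped shift", {
  tr <- small_traj(seed = 11, n_frames = 4L)
  base <- count_contacts(tr, "A", "B", 0.5)$per_frame
  shift <- c(1.1, -0.7, 2.3)
  frames <- lapply(tr$frames, function(f) {
    f$x <- (f$x + shift[1]) %% 3
    f$y <- (f$y + shift[2]) %% 3
    f$z <- ((f$z + shift[3] + 3) %% 6) - 3
    f
  })
  trs <- group_trajectory(frames, tr$box)
  expect_equal(count_contacts(trs, "A", "B", 0.5)$per_frame, base)
})

test_that("profile_noesy_concordance agrees for coupled generators", {
  depth <- popc_des_depth_distribution()
  rhos <- numeric(20)
  for (i in 1:20) {
    nt <- gen_noesy_table(depth, c("DES_III", "DES_IV"), tm = 0.3,
                          noise_frac = 0.03, seed = 900 + i)
    cp <- cross_relaxation_rates(nt)
    tr <- center_frames(gen_trajectory(depth, 60, c(4, 4, 9),
                                       seed = 900 + i), "CH3")
    dp <- mass_density_profile(tr, bin_width = 0.1)
    conc <- profile_noesy_concordance(dp, cp)
    rhos[i] <- mean(vapply(conc, `[[`, numeric(1), "rho"))
  }
  expect_gt(min(rhos), 0.8)
  # identical and reversed rankings via hand-built profiles
  z <- seq(-2, 2, 0.05)
  mk <- function(mu) dnorm(z, mu, 0.3)
  dens <- cbind(L = mk(1.0), A = mk(1.0), B = mk(0.6), C = mk(0.2))
  dp2 <- structure(list(z = z, density = dens, bin_width = 0.05,
                        box = c(4, 4, 4), n_frames = 1),
                   class = "density_profile")
  rates <- matrix(c(3, 2, 1), 3, 1,
                  dimnames = list(c("A", "B", "C"), "L"))
  cp2 <- structure(list(rates = rates, tm = 0.3,
                        lipid_group_order = c("A", "B", "C")),
                   class = "cross_relaxation_profile")
  expect_equal(profile_noesy_concordance(dp2, cp2)[["L"]]$rho, 1)
  cp3 <- cp2; cp3$rates[, 1] <- c(1, 2, 3)
  expect_equal(profile_noesy_concordance(dp2, cp3)[["L"]]$rho, -1)
})
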