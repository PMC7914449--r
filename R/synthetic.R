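# Seeded generators for every input type the pipeline consumes. These state
# the world the analysis assumes (two-state endotherms, multilamellar Bragg
# patterns, axially symmetric powder lineshapes, overlap-driven NOESY volumes,
# Gaussian depth distributions); they are first-class, tested code.

R_GAS_KCAL <- 1.98720425864083e-3  # kcal mol^-1 K^-1

#' Thermogram generator parameters
#'
#' @param transitions list of `list(Tm=, dH=, dH_vH=)`: midpoint (degC),
#'   calorimetric enthalpy (kcal/mol), van't Hoff enthalpy (kcal/mol).
#'   `dH_vH >= dH` (a cooperative unit cannot be smaller than one molecule);
#'   larger `dH_vH` means a narrower, more cooperative endotherm.
#' @param baseline_slope,baseline_intercept linear instrument baseline
#'   (kcal/mol/degC per degC and kcal/mol/degC).
#' @param noise_sd additive Gaussian noise sd (kcal/mol/degC).
#' @param t_range length-2 numeric scan range (degC).
#' @param t_step grid step (degC), > 0.
#' @param seed integer seed, mandatory.
#' @return validated parameter list of class `thermogram_params`.
#' @export
thermogram_params <- function(transitions = list(),
                              baseline_slope = 0, baseline_intercept = 0,
                              noise_sd = 0, t_range = c(10, 70), t_step = 0.05,
                              seed = 1L) {
  stopifnot(is.list(transitions))
  for (tr in transitions) {
    stopifnot(all(c("Tm", "dH", "dH_vH") %in% names(tr)))
    if (tr$dH <= 0) stop("dH must be > 0")
    if (tr$dH_vH < tr$dH) stop("dH_vH must be >= dH (cooperativity >= 1 molecule)")
  }
  if (t_step <= 0) stop("t_step must be > 0")
  if (length(t_range) != 2L || t_range[2] <= t_range[1]) stop("bad t_range")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(transitions) > 1L) {
    tms <- vapply(transitions, `[[`, numeric(1), "Tm")
    transitions <- transitions[order(tms)]
  }
  structure(list(transitions = transitions, baseline_slope = baseline_slope,
                 baseline_intercept = baseline_intercept, noise_sd = noise_sd,
                 t_range = t_range, t_step = t_step, seed = as.integer(seed)),
            class = "thermogram_params")
}

# Two-state van't Hoff excess heat capacity (T, Tm in degC; returns
# kcal/mol/degC). K = exp[-(dH_vH/R)(1/T - 1/Tm)] in kelvin;
# Cp_xs = dH * dH_vH / (R T^2) * K/(1+K)^2. Integrates to dH exactly.
cp_two_state <- function(t_c, Tm, dH, dH_vH) {
  TK <- t_c + 273.15
  TmK <- Tm + 273.15
  lK <- -(dH_vH / R_GAS_KCAL) * (1 / TK - 1 / TmK)
  # K/(1+K)^2 = 1/(4 cosh^2(lK/2)) -- numerically safe for large |lK|
  sech2 <- 1 / cosh(lK / 2)^2
  dH * dH_vH / (R_GAS_KCAL * TK^2) * sech2 / 4
}

#' Generate a synthetic DSC thermogram
#'
#' Sum of two-state van't Hoff endotherms on a linear baseline with additive
#' Gaussian noise. With `noise_sd = 0`, the baseline-subtracted trace of an
#' isolated transition integrates to its `dH` (the model is an exact
#' derivative of the two-state progress curve) and peaks within one grid step
#' of `Tm`.
#'
#' @param params a [thermogram_params()] object.
#' @return a [thermogram()]; attribute `params` carries the generator inputs.
#' @export
#' @examples
#' p <- thermogram_params(list(list(Tm = 35, dH = 7.1, dH_vH = 180)),
#'                        t_range = c(20, 50), seed = 1)
#' tg <- gen_thermogram(p)
gen_thermogram <- function(params) {
  stopifnot(inherits(params, "thermogram_params"))
  tt <- seq(params$t_range[1], params$t_range[2], by = params$t_step)
  if (length(tt) < 10L)
    stop_memphys("temperature grid has fewer than 10 points",
                 "memphys_invalid_grid")
  cp <- params$baseline_intercept + params$baseline_slope * tt
  for (tr in params$transitions)
    cp <- cp + cp_two_state(tt, tr$Tm, tr$dH, tr$dH_vH)
  if (params$noise_sd > 0)
    cp <- cp + with_seed(params$seed, stats::rnorm(length(tt), 0, params$noise_sd))
  out <- thermogram(tt, cp, scan_rate = 1)
  attr(out, "params") <- params
  out
}

#' Lamellar electron-density model parameters
#'
#' Symmetric bilayer electron-density contrast: two positive Gaussians at
#' +/- zH (width sigmaH, the electron-dense headgroups) plus one negative
#' Gaussian at the centre (width sigmaC, amplitude `rho_ratio` < 0, the
#' terminal-methyl trough). Stacking disorder via a Caille-type factor.
#'
#' @param d repeat distance (A); @param zH headgroup position (A),
#'   0 < zH < d/2; @param sigmaH,sigmaC Gaussian widths (A), > 0;
#' @param rho_ratio trough/headgroup amplitude ratio (negative; no printed
#'   value exists for it, default -1 treats trough and headgroup contrast as
#'   equal in magnitude -- a common starting point for PC bilayers);
#' @param n_lamellae positively correlated lamellae (>= 1);
#' @param eta Caille bending-fluctuation parameter (>= 0; 0 = finite rigid
#'   lattice).
#' @return validated list of class `lamellar_model_params`.
#' @export
lamellar_model_params <- function(d, zH, sigmaH, sigmaC, rho_ratio = -1,
                                  n_lamellae = 20L, eta = 0) {
  if (!(zH > 0 && zH < d / 2)) stop("need 0 < zH < d/2")
  if (sigmaH <= 0 || sigmaC <= 0) stop("Gaussian widths must be > 0")
  if (n_lamellae < 1) stop("n_lamellae must be >= 1")
  if (eta < 0) stop("eta must be >= 0")
  if (rho_ratio >= 0) stop("rho_ratio must be negative (low-density trough)")
  structure(list(d = d, zH = zH, sigmaH = sigmaH, sigmaC = sigmaC,
                 rho_ratio = rho_ratio, n_lamellae = as.integer(n_lamellae),
                 eta = eta),
            class = "lamellar_model_params")
}

# Form factor of the symmetric 3-Gaussian electron-density profile at
# q = 2*pi*s (analytic Fourier transform; sqrt(2*pi) absorbed into scale).
saxs_form_factor <- function(q, zH, sigmaH, sigmaC, rho_ratio) {
  2 * sigmaH * cos(q * zH) * exp(-0.5 * sigmaH^2 * q^2) +
    rho_ratio * sigmaC * exp(-0.5 * sigmaC^2 * q^2)
}

# Interference (structure) factor for stacks of bilayers at spacing d.
# For a single domain of N lamellae, S = N + 2 sum (N-k) cos(kqd) (the
# Fejer kernel, whose sinc^2 side lobes real multilamellar samples do not
# show). Domain-size polydispersity is therefore built in: S is averaged
# over a uniform window of lamellae counts around N (width n_spread * N),
# which tapers the cosine coefficients and suppresses the fringes while
# leaving Bragg positions at s = h/d untouched. eta > 0 additionally
# applies modified-Caille bending-fluctuation damping,
# exp(-(qd/2pi)^2 eta gammaE) (pi k)^(-(qd/2pi)^2 eta), per term.
saxs_structure_factor <- function(q, d, n_lamellae, eta, n_spread = 0.3) {
  N <- as.integer(n_lamellae)
  w_half <- max(0L, as.integer(round(n_spread * N / 2)))
  Ns <- seq.int(max(1L, N - w_half), N + w_half)
  kmax <- max(Ns) - 1L
  S <- rep(mean(Ns), length(q))
  if (kmax >= 1L) {
    ks <- seq_len(kmax)
    ck <- vapply(ks, function(k) mean(pmax(Ns - k, 0)), numeric(1))
    C <- cos(outer(q * d, ks))                       # |q| x kmax
    if (eta > 0) {
      a <- (q * d / (2 * pi))^2 * eta
      gammaE <- 0.5772156649015329
      W <- exp(-a * gammaE) * exp(-outer(a, log(pi * ks)))
      S <- S + 2 * as.numeric((C * W) %*% ck)
    } else {
      S <- S + 2 * as.numeric(C %*% ck)
    }
  }
  S
}

saxs_model_intensity <- function(s, p, scale = 1) {
  q <- 2 * pi * s
  FF <- saxs_form_factor(q, p$zH, p$sigmaH, p$sigmaC, p$rho_ratio)
  S <- saxs_structure_factor(q, p$d, p$n_lamellae, p$eta)
  # powder (Lorentz) factor 1/q^2; S >= 0 guarded against tiny negative
  # round-off for eta > 0 truncation
  I <- pmax(S, 0) * FF^2 / q^2
  scale * I
}

#' Generate a multilamellar SAXD pattern
#'
#' Intensity = Caille-type structure factor x squared 3-Gaussian form factor
#' x Lorentz 1/q^2, plus optional additive Gaussian noise (clipped at zero).
#' With `eta = 0` and many lamellae, maxima sit at s = h/d to grid
#' resolution.
#'
#' @param params a [lamellar_model_params()].
#' @param s_grid strictly increasing positive s grid (1/A).
#' @param noise_sd additive noise sd (counts).
#' @param seed integer seed.
#' @param scale linear intensity scale.
#' @return a [diffraction_pattern()] (region `"SAXD"`); attribute `warning`
#'   is set to `"no_bragg_order"` if no h/d falls inside the grid.
#' @export
gen_saxs_pattern <- function(params, s_grid, noise_sd = 0, seed = 1L,
                             scale = 1) {
  stopifnot(inherits(params, "lamellar_model_params"))
  if (any(diff(s_grid) <= 0) || any(s_grid <= 0))
    stop("s_grid must be strictly increasing and positive")
  I <- saxs_model_intensity(s_grid, params, scale)
  if (noise_sd > 0) {
    I <- I + with_seed(seed, stats::rnorm(length(s_grid), 0, noise_sd))
    I <- pmax(I, 0)
  }
  out <- diffraction_pattern(s_grid, I, "SAXD")
  orders <- seq_len(floor(max(s_grid) * params$d))
  if (!any(orders / params$d >= min(s_grid)))
    attr(out, "warning") <- "no_bragg_order"
  attr(out, "params") <- params
  out
}

#' Generate an inverted-hexagonal (HII) SAXD pattern
#'
#' Bragg reflections of a 2D hexagonal lattice at
#' s = sqrt(h^2 + hk + k^2)/d10 for (h,k) = (1,0), (1,1), (2,0), (2,1),
#' i.e. spacing ratios 1 : 1/sqrt(3) : 1/2 : 1/sqrt(7), as narrow Gaussians
#' with decreasing amplitude on a 1/s falloff.
#'
#' @param d10 first-order spacing (A), > 0.
#' @param s_grid strictly increasing positive s grid (1/A).
#' @param noise_sd additive noise sd (counts).
#' @param seed integer seed.
#' @param peak_sd Gaussian peak width in s (1/A).
#' @return a [diffraction_pattern()]; attribute `warning` =
#'   `"single_peak_window"` when the grid window covers fewer than two
#'   reflections.
#' @export
gen_hexagonal_pattern <- function(d10, s_grid, noise_sd = 0, seed = 1L,
                                  peak_sd = 6e-4) {
  if (d10 <= 0) stop("d10 must be > 0")
  if (any(diff(s_grid) <= 0) || any(s_grid <= 0))
    stop("s_grid must be strictly increasing and positive")
  fac <- sqrt(c(1, 3, 4, 7))
  amp <- c(1, 0.45, 0.3, 0.2)
  s0 <- fac / d10
  I <- 0.02 / s_grid * mean(amp)  # weak diffuse background
  for (i in seq_along(s0))
    I <- I + amp[i] * exp(-0.5 * ((s_grid - s0[i]) / peak_sd)^2)
  if (noise_sd > 0) {
    I <- I + with_seed(seed, stats::rnorm(length(s_grid), 0, noise_sd))
    I <- pmax(I, 0)
  }
  out <- diffraction_pattern(s_grid, I, "SAXD")
  inside <- s0 >= min(s_grid) & s0 <= max(s_grid)
  if (sum(inside) < 2L) attr(out, "warning") <- "single_peak_window"
  attr(out, "d10") <- d10
  out
}

#' Generate a wide-angle (WAXD) chain-packing pattern
#'
#' Sum of Gaussian reflections in the 0.20-0.29 1/A region, used to emulate
#' gel (sharp ~4.2 A peak, optionally with a shoulder) and fluid (single
#' broad hump) chain-packing signatures.
#'
#' @param peaks list of `list(d=, height=, width_s=)`: position as a
#'   d-spacing (A), amplitude (counts), Gaussian sd in s (1/A).
#' @param s_grid strictly increasing positive s grid (1/A).
#' @param noise_sd additive noise sd; @param seed integer seed.
#' @return a [diffraction_pattern()] (region `"WAXD"`).
#' @export
gen_waxd_pattern <- function(peaks, s_grid, noise_sd = 0, seed = 1L) {
  if (any(diff(s_grid) <= 0) || any(s_grid <= 0))
    stop("s_grid must be strictly increasing and positive")
  I <- rep(0, length(s_grid))
  for (pk in peaks)
    I <- I + pk$height * exp(-0.5 * ((s_grid - 1 / pk$d) / pk$width_s)^2)
  if (noise_sd > 0) {
    I <- I + with_seed(seed, stats::rnorm(length(s_grid), 0, noise_sd))
    I <- pmax(I, 0)
  }
  diffraction_pattern(s_grid, I, "WAXD")
}

#' Depth distribution of grouped atoms along the bilayer normal
#'
#' Each group is a Gaussian in z (nm, bilayer centre at 0) with an atom
#' count and per-atom mass; this one object drives both the NOESY volume
#' generator and the trajectory generator, which is what makes the
#' NMR-vs-simulation concordance testable.
#'
#' @param groups list of `list(label=, mean_z=, sd_z=, n_atoms=, atom_mass=)`
#'   with `sd_z > 0`, unique labels, `n_atoms >= 0`, `atom_mass > 0` (Da).
#' @return validated list of class `depth_distribution`.
#' @export
depth_distribution <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  labs <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("group labels must be unique")
  for (g in groups) {
    if (g$sd_z <= 0) stop("sd_z must be > 0")
    if (g$n_atoms < 0) stop("n_atoms must be >= 0")
    if (g$atom_mass <= 0) stop("atom_mass must be > 0")
  }
  structure(list(groups = groups, labels = labs),
            class = "depth_distribution")
}

depth_group <- function(depth, label) {
  depth$groups[[match(label, depth$labels)]]
}

# Overlap of two Gaussian depth densities: integral of N(m1,s1) N(m2,s2) dz
# = dnorm(m1 - m2, 0, sqrt(s1^2 + s2^2)). Monotone in closeness of means.
gaussian_overlap <- function(m1, s1, m2, s2) {
  stats::dnorm(m1 - m2, mean = 0, sd = sqrt(s1^2 + s2^2))
}

#' Generate a NOESY volume table from a depth distribution
#'
#' Cross-peak volume between a ligand proton group and a lipid group is
#' proportional to mixing time x proton counts x the Gaussian overlap of
#' their depth distributions; diagonal volume is proportional to proton
#' count. A monotone contact-to-volume map, not a relaxation-matrix
#' simulation: sufficient for round-trip localisation tests. Multiplying
#' `scale` by any c > 0 leaves downstream cross-relaxation rates unchanged.
#'
#' @param depth a [depth_distribution()] containing both lipid and ligand
#'   groups.
#' @param ligand_groups character, labels within `depth` that belong to the
#'   ligand; the remaining labels are the lipid groups.
#' @param tm mixing time (s), > 0.
#' @param scale linear volume scale, > 0.
#' @param noise_frac multiplicative lognormal-ish noise fraction on cross
#'   peaks (0 = none).
#' @param seed integer seed.
#' @return a [noesy_volumes()].
#' @export
gen_noesy_table <- function(depth, ligand_groups, tm, scale = 1e4,
                            noise_frac = 0, seed = 1L) {
  stopifnot(inherits(depth, "depth_distribution"))
  if (length(ligand_groups) < 1L)
    stop_memphys("ligand_groups must be non-empty", "memphys_invalid_input")
  if (!all(ligand_groups %in% depth$labels))
    stop("ligand_groups absent from depth distribution")
  if (tm <= 0) stop("tm must be > 0")
  lipid <- setdiff(depth$labels, ligand_groups)
  if (length(lipid) < 1L)
    stop_memphys("no lipid groups left after removing ligand groups",
                 "memphys_invalid_input")
  diag_v <- vapply(lipid, function(l) scale * depth_group(depth, l)$n_atoms,
                   numeric(1))
  cross <- matrix(0, length(lipid), length(ligand_groups),
                  dimnames = list(lipid, ligand_groups))
  eps <- if (noise_frac > 0)
    with_seed(seed, matrix(stats::rnorm(length(cross), 0, noise_frac),
                           nrow(cross)))
  else matrix(0, nrow(cross), ncol(cross))
  for (j in seq_along(ligand_groups)) {
    gl <- depth_group(depth, ligand_groups[j])
    for (i in seq_along(lipid)) {
      gi <- depth_group(depth, lipid[i])
      ov <- gaussian_overlap(gl$mean_z, gl$sd_z, gi$mean_z, gi$sd_z)
      cross[i, j] <- scale * tm * gl$n_atoms * gi$n_atoms * ov *
        max(1 + eps[i, j], 0)
    }
  }
  noesy_volumes(tm, diag_v, cross)
}

#' Generate a grouped bilayer trajectory
#'
#' Per frame, each group's atoms are drawn independently with z ~
#' N(mean_z, sd_z) wrapped into [-Lz/2, Lz/2) and x,y uniform in the box.
#' With `mirror = TRUE` half of each group's atoms are drawn at -mean_z,
#' emulating the second leaflet of a symmetric bilayer.
#'
#' @param depth a [depth_distribution()].
#' @param n_frames number of frames (>= 1).
#' @param box numeric length-3 box (nm).
#' @param seed integer seed.
#' @param mirror logical, draw a mirrored leaflet (default FALSE).
#' @return a [group_trajectory()]; groups with `n_atoms = 0` are omitted
#'   with a warning.
#' @export
gen_trajectory <- function(depth, n_frames, box, seed = 1L, mirror = FALSE) {
  stopifnot(inherits(depth, "depth_distribution"))
  if (n_frames < 1L) stop("n_frames must be >= 1")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  groups <- depth$groups
  empty <- vapply(groups, function(g) g$n_atoms == 0L, logical(1))
  if (any(empty)) {
    warning("omitting zero-atom group(s): ",
            paste(depth$labels[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) == 0L) stop("no groups with atoms")
  Lz <- box[3]
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(fr) {
      parts <- lapply(groups, function(g) {
        n <- g$n_atoms
        mz <- rep(g$mean_z, n)
        if (mirror && n > 1L) mz[seq_len(n %/% 2L)] <- -g$mean_z
        z <- stats::rnorm(n, mz, g$sd_z)
        z <- ((z + Lz / 2) %% Lz) - Lz / 2
        data.frame(group = rep(g$label, n),
                   x = stats::runif(n, 0, box[1]),
                   y = stats::runif(n, 0, box[2]),
                   z = z,
                   mass = rep(g$atom_mass, n),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, parts)
    })
  })
  group_trajectory(frames, box)
}

#' Generate a 31P spectrum (powder lineshape plus noise)
#'
#' Wraps [simulate_31p_lineshape()] and adds seeded Gaussian noise.
#'
#' @inheritParams simulate_31p_lineshape
#' @param noise_sd additive noise sd relative to unit-area lineshape units.
#' @param seed integer seed.
#' @return a [spectrum31p()].
#' @export
gen_31p_spectrum <- function(delta_sigma, phase = c("lamellar", "hexagonal",
                                                    "isotropic"),
                             lb = 100, field_MHz = 242.9, noise_sd = 0,
                             seed = 1L, ppm_grid = NULL) {
  phase <- match.arg(phase)
  sp <- simulate_31p_lineshape(delta_sigma, phase, lb, field_MHz, ppm_grid)
  if (noise_sd > 0)
    sp$intensity <- sp$intensity +
      with_seed(seed, stats::rnorm(nrow(sp), 0, noise_sd))
  sp
}
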