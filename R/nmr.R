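# 31P powder lineshape simulation / classification and NOESY
# cross-relaxation depth localisation.
#
# Axially symmetric CSA convention used throughout: the shift anisotropy
# Delta = delta_par - delta_perp spans the powder pattern exactly, and the
# orientation law is delta(theta) = delta_iso - (Delta/3)(3 cos^2 theta - 1),
# so a negative Delta puts the intense perpendicular edge at high field
# (small ppm) with the parallel shoulder at low field -- the bilayer
# signature. Fast lateral diffusion around HII cylinders averages the tensor
# to an effective anisotropy of -Delta/2: skew reverses, span halves.

#' Simulate an axially symmetric 31P powder lineshape
#'
#' Numerical powder average of delta(theta) = delta_iso -
#' (Delta_eff/3)(3 cos^2 theta - 1) on a 1-degree theta grid with
#' sin(theta) weighting, convolved with a Lorentzian of `lb` Hz, area
#' normalised to 1. `Delta_eff` is `delta_sigma` for the lamellar phase,
#' `-delta_sigma/2` for the hexagonal phase, and 0 (a single symmetric
#' line) for the isotropic phase.
#'
#' @param delta_sigma chemical shift anisotropy (ppm); must be nonzero for
#'   anisotropic phases.
#' @param phase `"lamellar"`, `"hexagonal"` or `"isotropic"`.
#' @param lb Lorentzian line broadening (Hz), >= 0.
#' @param field_MHz spectrometer 31P frequency (MHz), > 0.
#' @param ppm_grid optional ppm axis (default 60..-60 ppm, 2048 points).
#' @param delta_iso isotropic shift (ppm), default 0.
#' @return a [spectrum31p()] with unit trapezoidal area (per ppm).
#' @export
simulate_31p_lineshape <- function(delta_sigma,
                                   phase = c("lamellar", "hexagonal",
                                             "isotropic"),
                                   lb = 100, field_MHz = 242.9,
                                   ppm_grid = NULL, delta_iso = 0) {
  phase <- match.arg(phase)
  if (field_MHz <= 0) stop("field_MHz must be > 0")
  if (lb < 0) stop("lb must be >= 0")
  if (phase != "isotropic" && delta_sigma == 0)
    stop("delta_sigma must be nonzero for anisotropic phases")
  if (is.null(ppm_grid)) ppm_grid <- seq(60, -60, length.out = 2048L)
  ppm_asc <- sort(ppm_grid)
  dppm <- ppm_asc[2] - ppm_asc[1]
  delta_eff <- switch(phase, lamellar = delta_sigma,
                      hexagonal = -delta_sigma / 2, isotropic = 0)
  y <- numeric(length(ppm_asc))
  if (delta_eff == 0) {
    i0 <- which.min(abs(ppm_asc - delta_iso))
    y[i0] <- 1 / dppm
  } else {
    theta <- (seq(0.5, 89.5, by = 1)) * pi / 180
    w <- sin(theta)
    pos <- delta_iso - (delta_eff / 3) * (3 * cos(theta)^2 - 1)
    bin <- findInterval(pos, ppm_asc - dppm / 2)
    bin <- pmin(pmax(bin, 1L), length(ppm_asc))
    for (k in seq_along(bin)) y[bin[k]] <- y[bin[k]] + w[k]
  }
  if (lb > 0) {
    gamma <- (lb / field_MHz) / 2      # Lorentzian HWHM in ppm
    half <- ceiling(12 * gamma / dppm)
    xk <- seq(-half, half) * dppm
    kern <- (gamma / pi) / (xk^2 + gamma^2)
    kern <- kern / sum(kern)
    n <- length(y)
    yp <- c(rep(0, half), y, rep(0, half))
    y <- as.numeric(stats::filter(yp, kern, sides = 2))[(half + 1L):(half + n)]
  }
  area <- trapz(ppm_asc, y)
  if (area > 0) y <- y / area
  spectrum31p(ppm_asc, y)  # constructor re-orders to decreasing ppm
}

# Weighted skewness of a lineshape about its first moment, using only the
# part above a floor (robust to baseline noise).
lineshape_skew <- function(ppm, y, floor_lvl = 0) {
  w <- pmax(y - floor_lvl, 0)
  if (sum(w) <= 0) return(0)
  m <- sum(w * ppm) / sum(w)
  v <- sum(w * (ppm - m)^2) / sum(w)
  if (v <= 0) return(0)
  sum(w * (ppm - m)^3) / sum(w) / v^1.5
}

# Outermost crossings of a fractional-height level: c(low-field edge (max
# ppm), high-field edge (min ppm)).
spectrum_edges <- function(ppm_asc, y, frac = 0.05) {
  lvl <- frac * max(y)
  above <- which(y >= lvl)
  if (length(above) == 0L) return(c(NA_real_, NA_real_))
  i1 <- min(above); i2 <- max(above)
  lo <- if (i1 > 1L) cross_at(ppm_asc, y, i1 - 1L, lvl) else ppm_asc[i1]
  hi <- if (i2 < length(y)) cross_at(ppm_asc, y, i2, lvl) else ppm_asc[i2]
  c(low_field = hi, high_field = lo)
}

#' Classify a 31P powder spectrum
#'
#' Decision by the sign of the lineshape skewness about its first moment: a
#' lamellar pattern is intense at the high-field (small-ppm) perpendicular
#' edge with a tail to low field (positive skew on a ppm axis); the HII
#' pattern is its mirror image (negative skew); near-zero skew is
#' isotropic. A mixture is reported when two resolvable apex components are
#' found. Edge positions are located at a configured fractional height.
#'
#' @param sp a [spectrum31p()] (baseline-corrected).
#' @param skew_threshold |skewness| below which the line counts as symmetric
#'   (default 0.25).
#' @param edge_frac fractional height for edge location (default 0.05).
#' @param mixture_prominence fractional prominence (of the apex) a second
#'   local maximum needs to signal phase coexistence (default 0.2).
#' @param mixture_min_sep minimum apex separation in ppm (default 5).
#' @param snr_min signal-to-noise below which the call is flagged
#'   indeterminate (default 5).
#' @return list `phase` ("lamellar", "hexagonal_II", "isotropic",
#'   "mixture"), `edges` (low/high field, ppm), `skewness`, `span` (ppm),
#'   `snr`, `indeterminate_low_snr`.
#' @export
classify_31p <- function(sp, skew_threshold = 0.25, edge_frac = 0.05,
                         mixture_prominence = 0.2, mixture_min_sep = 5,
                         snr_min = 5) {
  stopifnot(inherits(sp, "spectrum31p"))
  o <- order(sp$ppm)
  ppm <- sp$ppm[o]
  y <- sp$intensity[o]
  noise <- mad_noise(y)
  snr <- max(y) / max(noise, .Machine$double.eps)
  ys <- smooth_running(y, 9L)
  ys[ys < 0] <- 0
  edges <- spectrum_edges(ppm, ys, edge_frac)
  span <- as.numeric(edges[1] - edges[2])
  sk <- lineshape_skew(ppm, ys, floor_lvl = 2 * noise)
  # apex components for coexistence detection
  idx <- local_maxima(ys)
  if (length(idx)) {
    prom <- vapply(idx, function(i) peak_prominence(ys, i), numeric(1))
    idx <- idx[prom >= mixture_prominence * max(ys)]
  }
  n_apex <- 0L
  if (length(idx)) {
    pos <- ppm[idx]
    keep <- order(ys[idx], decreasing = TRUE)
    sel <- c()
    for (k in keep)
      if (!length(sel) || all(abs(pos[k] - pos[sel]) >= mixture_min_sep))
        sel <- c(sel, k)
    n_apex <- length(sel)
  }
  phase <- if (n_apex >= 2L) "mixture"
  else if (snr < snr_min) "isotropic"
  else if (sk > skew_threshold) "lamellar"
  else if (sk < -skew_threshold) "hexagonal_II"
  else "isotropic"
  list(phase = phase, edges = edges, skewness = sk, span = span, snr = snr,
       indeterminate_low_snr = snr < snr_min)
}

#' Cross-relaxation rates from a single-mixing-time NOESY volume table
#'
#' sigma_ij = A_ij / (A_jj * t_m): cross-peak volume over the reference
#' (lipid) group's diagonal volume per unit mixing time, in 1/s. Exactly
#' invariant to a global volume rescale and reciprocal in the mixing time.
#'
#' @param t a [noesy_volumes()].
#' @param group_order lipid group display order, membrane centre to polar
#'   group (default [lipid_group_order()]); unknown labels keep input order
#'   after the known ones.
#' @return object of class `cross_relaxation_profile`: list with `rates`
#'   (matrix lipid group x ligand proton, 1/s), `tm`, `lipid_group_order`.
#' @export
cross_relaxation_rates <- function(t, group_order = lipid_group_order()) {
  stopifnot(inherits(t, "noesy_volumes"))
  rows <- rownames(t$cross)
  missing <- setdiff(rows, names(t$diagonal))
  if (length(missing))
    stop_memphys(paste0("missing diagonal volume for group(s): ",
                        paste(missing, collapse = ", ")),
                 "memphys_missing_diagonal")
  rates <- sweep(t$cross, 1, t$diagonal[rows] * t$tm, "/")
  ord <- c(intersect(group_order, rows), setdiff(rows, group_order))
  rates <- rates[ord, , drop = FALSE]
  structure(list(rates = rates, tm = t$tm, lipid_group_order = ord),
            class = "cross_relaxation_profile")
}

#' @export
print.cross_relaxation_profile <- function(x, ...) {
  cat(sprintf("<cross_relaxation_profile> tm = %g s\n", x$tm))
  print(round(x$rates, 4))
  invisible(x)
}

#' Membrane location profile from cross-relaxation rates
#'
#' Per ligand proton, lipid groups ranked by decreasing sigma; the modal
#' location is the argmax. Ties are broken toward the group nearer the
#' polar interface (later in the centre-to-polar order) and reported.
#'
#' @param p a `cross_relaxation_profile` from [cross_relaxation_rates()].
#' @return list keyed by ligand proton: each a list `ranking` (data.frame
#'   group/sigma, descending), `modal` (label or NA when all rates are 0),
#'   `tied` (logical), `no_contact` (logical).
#' @export
location_profile <- function(p) {
  stopifnot(inherits(p, "cross_relaxation_profile"))
  if (nrow(p$rates) < 2L) stop("need >= 2 lipid groups with rates")
  out <- list()
  groups <- rownames(p$rates)
  polar_rank <- seq_along(groups)  # later = nearer polar interface
  for (lig in colnames(p$rates)) {
    sig <- p$rates[, lig]
    if (all(sig == 0)) {
      out[[lig]] <- list(ranking = data.frame(group = groups, sigma = sig),
                         modal = NA_character_, tied = FALSE,
                         no_contact = TRUE)
      next
    }
    o <- order(-sig, -polar_rank)
    top <- which(sig == max(sig))
    tied <- length(top) > 1L
    out[[lig]] <- list(
      ranking = data.frame(group = groups[o], sigma = as.numeric(sig[o]),
                           stringsAsFactors = FALSE),
      modal = groups[o[1L]], tied = tied, no_contact = FALSE)
  }
  out
}
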