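#' Construct a thermogram
#'
#' A temperature-indexed excess heat capacity trace, the unit of data of
#' differential scanning calorimetry: Cp (kcal mol^-1 degC^-1) on a strictly
#' increasing temperature grid (degC).
#'
#' @param temperature numeric, strictly increasing temperature grid (degC).
#' @param cp numeric, heat capacity at each grid point (kcal/mol/degC).
#' @param scan_rate scan rate metadata (degC/min), not used numerically.
#' @return an object of class `thermogram` (a data.frame with columns
#'   `temperature`, `cp` and attribute `scan_rate`).
#' @export
#' @examples
#' tg <- thermogram(seq(10, 40, 0.1), rep(0, 301))
thermogram <- function(temperature, cp, scan_rate = NA_real_) {
  temperature <- as.numeric(temperature)
  cp <- as.numeric(cp)
  if (length(temperature) != length(cp))
    stop("temperature and cp must have equal length")
  if (length(temperature) < 10L)
    stop_memphys("thermogram needs at least 10 points", "memphys_invalid_grid")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  if (any(!is.finite(cp))) stop("cp must be finite")
  structure(data.frame(temperature = temperature, cp = cp),
            scan_rate = scan_rate,
            class = c("thermogram", "data.frame"))
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d points, %.2f..%.2f degC\n",
              nrow(x), min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Construct a diffraction pattern
#'
#' Scattering-vector-indexed intensity trace. The scattering vector follows
#' the s = 2 sin(theta)/lambda convention (no 2*pi), so a lamellar repeat d
#' produces Bragg orders at s = h/d.
#'
#' @param s numeric, strictly increasing scattering vector grid (1/Angstrom).
#' @param intensity numeric counts, finite.
#' @param region `"SAXD"` (small-angle, ~0.0075-0.07 1/A) or `"WAXD"`
#'   (wide-angle, ~0.20-0.29 1/A).
#' @return object of class `diffraction_pattern`.
#' @export
diffraction_pattern <- function(s, intensity, region = c("SAXD", "WAXD")) {
  region <- match.arg(region)
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  if (length(s) != length(intensity)) stop("s and intensity lengths differ")
  if (any(diff(s) <= 0)) stop("s grid must be strictly increasing")
  if (any(s <= 0)) stop("s grid must be positive")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  structure(data.frame(s = s, intensity = intensity),
            region = region,
            class = c("diffraction_pattern", "data.frame"))
}

#' @export
print.diffraction_pattern <- function(x, ...) {
  cat(sprintf("<diffraction_pattern:%s> %d points, s in [%.4g, %.4g] 1/A\n",
              attr(x, "region"), nrow(x), min(x$s), max(x$s)))
  if (!is.null(attr(x, "warning")))
    cat("  warning:", attr(x, "warning"), "\n")
  invisible(x)
}

#' Construct a 31P NMR spectrum
#'
#' ppm axis stored decreasing left-to-right (low field, i.e. large ppm, on
#' the left), following the NMR display convention.
#'
#' @param ppm numeric chemical-shift axis, strictly monotone.
#' @param intensity numeric, finite.
#' @return object of class `spectrum31p`.
#' @export
spectrum31p <- function(ppm, intensity) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) stop("ppm and intensity lengths differ")
  d <- diff(ppm)
  if (all(d > 0)) { ppm <- rev(ppm); intensity <- rev(intensity) }
  else if (!all(d < 0)) stop("ppm axis must be strictly monotone")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  structure(data.frame(ppm = ppm, intensity = intensity),
            class = c("spectrum31p", "data.frame"))
}

#' @export
print.spectrum31p <- function(x, ...) {
  cat(sprintf("<spectrum31p> %d points, %.1f..%.1f ppm\n",
              nrow(x), x$ppm[1], x$ppm[nrow(x)]))
  invisible(x)
}

#' Construct a NOESY volume table
#'
#' Diagonal and cross-peak volumes of a single-mixing-time 2D NOESY
#' experiment: the raw material of cross-relaxation rate analysis.
#'
#' @param tm mixing time in seconds (> 0).
#' @param diagonal named numeric vector of diagonal peak volumes (> 0); names
#'   are lipid group labels.
#' @param cross numeric matrix of cross-peak volumes (>= 0); rownames are
#'   lipid groups (must each have a diagonal entry is *not* required here,
#'   only at rate computation), colnames are ligand protons.
#' @return object of class `noesy_volumes`.
#' @export
noesy_volumes <- function(tm, diagonal, cross) {
  if (!is.numeric(tm) || length(tm) != 1L || tm <= 0)
    stop("tm must be a positive scalar (seconds)")
  if (is.null(names(diagonal)) || anyDuplicated(names(diagonal)))
    stop("diagonal must be a named vector with unique names")
  if (any(diagonal <= 0)) stop("diagonal volumes must be > 0")
  cross <- as.matrix(cross)
  if (is.null(rownames(cross)) || is.null(colnames(cross)))
    stop("cross matrix needs rownames (lipid groups) and colnames (ligand protons)")
  if (any(cross < 0)) stop("cross-peak volumes must be >= 0")
  structure(list(tm = tm, diagonal = diagonal, cross = cross),
            class = "noesy_volumes")
}

#' @export
print.noesy_volumes <- function(x, ...) {
  cat(sprintf("<noesy_volumes> tm = %g s, %d lipid groups x %d ligand protons\n",
              x$tm, nrow(x$cross), ncol(x$cross)))
  invisible(x)
}

# Canonical lipid-group order, membrane centre -> polar interface.
#' Canonical POPC group order from bilayer centre to polar group
#'
#' Terminal methyl, bulk methylenes, the methylenes flanking the double bond,
#' acyl carbons C3 and C2, glycerol G1, and the choline gamma methyls.
#' @return character vector of group labels.
#' @export
lipid_group_order <- function() {
  c("CH3", "CH2n", "CH2C", "C3", "C2", "G1", "gamma")
}

#' Construct a grouped trajectory
#'
#' Frames of grouped, labelled 3D coordinates (nm) in a rectangular periodic
#' box. x,y in [0, Lx) x [0, Ly); z in [-Lz/2, Lz/2) with the bilayer centre
#' at z = 0.
#'
#' @param frames list of data.frames with columns `group`, `x`, `y`, `z`,
#'   `mass` (Da); per-group atom counts must be constant across frames.
#' @param box numeric length-3, box edges (Lx, Ly, Lz) in nm, positive.
#' @return object of class `group_trajectory`.
#' @export
group_trajectory <- function(frames, box) {
  if (!is.list(frames) || length(frames) < 1L) stop("frames must be a non-empty list")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths (nm)")
  counts0 <- NULL
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!all(c("group", "x", "y", "z", "mass") %in% names(f)))
      stop("each frame needs columns group,x,y,z,mass")
    cnt <- table(f$group)
    if (is.null(counts0)) counts0 <- cnt
    else if (!identical(as.vector(cnt), as.vector(counts0)) ||
             !identical(names(cnt), names(counts0)))
      stop(sprintf("frame %d: per-group atom counts differ from frame 1", i))
  }
  structure(list(frames = frames, box = box), class = "group_trajectory")
}

#' @export
print.group_trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("<group_trajectory> %d frames, %d atoms, %d groups, box %.2f x %.2f x %.2f nm\n",
              length(x$frames), nrow(f1), length(unique(f1$group)),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Construct a lamellar fit result
#'
#' Fitted Gaussian electron-density model parameters with derived
#' thicknesses. Invariants are enforced exactly: dHH = 2 zH,
#' dB = 2 (zH + 2 sigmaH), dw = d - dB.
#'
#' @param d repeat distance (A); @param zH headgroup Gaussian position (A);
#' @param sigmaH headgroup Gaussian width (A); @param sigmaC hydrocarbon
#'   trough width (A); @param rho_ratio trough/headgroup amplitude ratio
#'   (negative); @param n_lamellae positively correlated lamellae count;
#' @param eta Caille disorder parameter (>= 0); @param fit_residual
#'   dimensionless residual of the fit; @param scale linear intensity scale.
#' @return object of class `lamellar_fit`.
#' @export
lamellar_fit <- function(d, zH, sigmaH, sigmaC, rho_ratio = NA_real_,
                         n_lamellae = NA_integer_, eta = NA_real_,
                         fit_residual = NA_real_, scale = NA_real_) {
  th <- derive_thickness(d, zH, sigmaH)
  structure(list(d = d, zH = zH, sigmaH = sigmaH, sigmaC = sigmaC,
                 rho_ratio = rho_ratio, n_lamellae = n_lamellae, eta = eta,
                 dHH = th$dHH, dB = th$dB, dw = th$dw,
                 fit_residual = fit_residual, scale = scale),
            class = "lamellar_fit")
}

#' @export
print.lamellar_fit <- function(x, ...) {
  cat("<lamellar_fit>\n")
  cat(sprintf("  d = %.2f A, zH = %.2f A, sigmaH = %.2f A, sigmaC = %.2f A\n",
              x$d, x$zH, x$sigmaH, x$sigmaC))
  cat(sprintf("  dHH = %.2f A, dB = %.2f A, dw = %.2f A (residual %.3g)\n",
              x$dHH, x$dB, x$dw, x$fit_residual))
  invisible(x)
}
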