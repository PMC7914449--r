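# SAXD/WAXD analysis: Bragg peak picking, lamellar and inverted-hexagonal
# indexing, mesophase and chain-packing classification, and the Gaussian
# electron-density multilamellar model fit (repeat distance, headgroup
# position/width, hydrocarbon trough width -> dHH, dB, dw).

#' Pick peaks in a diffraction pattern
#'
#' Local maxima above a prominence threshold, with sub-grid apex position by
#' parabolic interpolation and width from half-prominence crossings. Each
#' peak carries its d-spacing d = 1/s.
#'
#' @param p a [diffraction_pattern()].
#' @param min_prominence absolute prominence threshold; default `NULL` uses
#'   5 x a robust noise estimate (floored at 0.5% of the intensity range).
#' @param smooth odd running-mean window for detection (default 1 = none).
#' @param min_sep minimum separation in s (1/A): any peak closer than this
#'   to a taller one is discarded as a satellite/fringe (default 0.002).
#' @return data.frame with columns `s_peak`, `d`, `height`, `width` (FWHM in
#'   s), sorted by s. Zero rows when nothing qualifies.
#' @export
pick_peaks <- function(p, min_prominence = NULL, smooth = 1L,
                       min_sep = 0.002) {
  stopifnot(inherits(p, "diffraction_pattern"))
  s <- p$s
  y <- smooth_running(p$intensity, smooth)
  if (is.null(min_prominence)) {
    noise <- mad_noise(y)
    min_prominence <- max(5 * noise, 0.005 * (max(y) - min(y)))
  }
  idx <- local_maxima(y)
  res <- list()
  for (i in idx) {
    prom <- peak_prominence(y, i)
    if (prom < min_prominence) next
    ap <- parabolic_apex(s, y, i)
    half <- y[i] - prom / 2
    li <- i; while (li > 1L && y[li - 1L] > half && y[li - 1L] <= y[li]) li <- li - 1L
    ri <- i; while (ri < length(y) && y[ri + 1L] > half && y[ri + 1L] <= y[ri]) ri <- ri + 1L
    x_l <- if (li > 1L) cross_at(s, y, li - 1L, half) else s[li]
    x_r <- if (ri < length(y)) cross_at(s, y, ri, half) else s[ri]
    res[[length(res) + 1L]] <- data.frame(s_peak = ap$x, d = 1 / ap$x,
                                          height = ap$y,
                                          width = max(x_r - x_l, 0))
  }
  if (length(res) == 0L)
    return(data.frame(s_peak = numeric(0), d = numeric(0),
                      height = numeric(0), width = numeric(0)))
  out <- do.call(rbind, res)
  if (min_sep > 0 && nrow(out) > 1L) {
    keep <- logical(nrow(out))
    for (i in order(out$height, decreasing = TRUE))
      keep[i] <- !any(keep & abs(out$s_peak - out$s_peak[i]) < min_sep)
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$s_peak), , drop = FALSE]
}

# Least-squares 1/d for s_i ~ f_i / d over assigned factors f (orders or
# hexagonal index moduli): minimises sum (s - f/d)^2, linear in 1/d.
ls_spacing <- function(s, f) sum(f * s) / sum(f^2)

index_residual <- function(s, f, inv_d) {
  pred <- f * inv_d
  sqrt(mean(((s - pred) / pred)^2))
}

#' Index a peak list as a lamellar (1 : 1/2 : 1/3 ...) series
#'
#' Greedy assignment from the lowest-s peak (order 1): each subsequent peak
#' gets the integer order nearest to its s-ratio against the previously
#' assigned peak, accepted when that consecutive ratio deviates by at most
#' `tol` (the printed convention deviates by ~2-3% from exact integer
#' ratios, so ratios are tested between neighbours, not against order 1).
#' The repeat distance is then least squares over all assigned orders.
#'
#' @param peaks data.frame from [pick_peaks()] (needs `s_peak`), >= 1 row.
#' @param tol relative ratio tolerance (default 0.03).
#' @param h1_max largest order considered for the lowest-s peak (default 3;
#'   lets series whose first order fell outside the window still index).
#' @return list `d` (A), `orders` (integer vector, NA for unassigned peaks),
#'   `residual` (RMS relative deviation), `n_assigned`, `indeterminate`.
#' @export
index_lamellar <- function(peaks, tol = 0.03, h1_max = 3L) {
  s <- sort(peaks$s_peak)
  if (length(s) < 1L) stop("need >= 1 peak")
  chain <- function(h1) {
    orders <- rep(NA_integer_, length(s))
    orders[1L] <- h1
    for (k in seq_along(s)[-1L]) {
      prev <- max(which(!is.na(orders[seq_len(k - 1L)])))
      ratio <- s[k] / s[prev]
      h <- as.integer(round(orders[prev] * ratio))
      if (h <= orders[prev]) next
      if (abs(ratio / (h / orders[prev]) - 1) <= tol) orders[k] <- h
    }
    orders
  }
  best <- NULL
  for (h1 in seq_len(max(1L, h1_max))) {
    orders <- chain(h1)
    ok <- !is.na(orders)
    inv_d <- ls_spacing(s[ok], orders[ok])
    res <- index_residual(s[ok], orders[ok], inv_d)
    cand <- list(d = 1 / inv_d, orders = orders, residual = res,
                 n_assigned = sum(ok),
                 indeterminate = sum(ok) < length(s) || res > tol)
    better <- is.null(best) ||
      cand$n_assigned > best$n_assigned ||
      (cand$n_assigned == best$n_assigned &&
       (cand$residual < best$residual - 1e-12 ||
        (abs(cand$residual - best$residual) <= 1e-12 &&
         sum(cand$orders, na.rm = TRUE) < sum(best$orders, na.rm = TRUE))))
    if (better) best <- cand
  }
  best
}

HEX_FACTORS <- sqrt(c(1, 3, 4, 7))          # (1,0) (1,1) (2,0) (2,1)
HEX_INDICES <- c("10", "11", "20", "21")

#' Index a peak list as a 2D hexagonal (HII) series
#'
#' Fits s_hk = sqrt(h^2 + hk + k^2) / d10 assigning the peaks, in order, to
#' the canonical first reflections (1,0), (1,1), (2,0), (2,1) -- spacing
#' ratios 1 : 1/sqrt(3) : 1/2 : 1/sqrt(7). No reflections are skipped: an
#' HII claim rests on the 1 : 1/sqrt(3) pair, so e.g. a 1 : 1/2 doublet is
#' forced onto (1,0), (1,1) and scored accordingly.
#'
#' @param peaks data.frame from [pick_peaks()], >= 2 rows.
#' @param tol relative tolerance for acceptance (default 0.03).
#' @return list `d10` (A), `indices` (character), `residual`, `n_assigned`,
#'   `indeterminate`.
#' @export
index_hexagonal <- function(peaks, tol = 0.03) {
  s <- sort(peaks$s_peak)
  if (length(s) < 2L) stop("need >= 2 peaks")
  n <- min(length(s), length(HEX_FACTORS))
  f <- HEX_FACTORS[seq_len(n)]
  su <- s[seq_len(n)]
  inv_d10 <- ls_spacing(su, f)
  res <- index_residual(su, f, inv_d10)
  list(d10 = 1 / inv_d10, indices = HEX_INDICES[seq_len(n)],
       residual = res, n_assigned = n,
       indeterminate = res > tol || length(s) > length(HEX_FACTORS))
}

#' Classify mesophase from small-angle peak spacing ratios
#'
#' Runs lamellar and hexagonal indexing and assigns the phase with the lower
#' residual, provided it is within tolerance and covers all peaks;
#' `indeterminate` otherwise (e.g. a single peak, or no ratio law fits).
#'
#' @param peaks data.frame from [pick_peaks()].
#' @param tol residual tolerance (default 0.03).
#' @return list `phase` ("lamellar", "hexagonal_II" or "indeterminate"),
#'   `evidence` (character), plus the two index results (`lamellar`, `hexagonal`).
#' @export
classify_phase_saxd <- function(peaks, tol = 0.03) {
  if (nrow(peaks) < 2L)
    return(list(phase = "indeterminate",
                evidence = "fewer than 2 peaks: ratio test impossible",
                lamellar = NULL, hexagonal = NULL))
  lam <- index_lamellar(peaks, tol)
  hex <- index_hexagonal(peaks, tol)
  lam_ok <- !lam$indeterminate
  hex_ok <- !hex$indeterminate
  if (lam_ok && (!hex_ok || lam$residual <= hex$residual)) {
    ph <- "lamellar"
    ev <- sprintf("orders %s at d = %.2f A fit 1:1/2:1/3 law (rms %.3g)",
                  paste(lam$orders[!is.na(lam$orders)], collapse = ","),
                  lam$d, lam$residual)
  } else if (hex_ok) {
    ph <- "hexagonal_II"
    ev <- sprintf("reflections %s at d10 = %.2f A fit 1:1/sqrt3:1/2:1/sqrt7 law (rms %.3g)",
                  paste(hex$indices, collapse = ","), hex$d10, hex$residual)
  } else {
    return(list(phase = "indeterminate",
                evidence = sprintf("no ratio law within tolerance (lamellar rms %.3g, hexagonal rms %.3g)",
                                   lam$residual, hex$residual),
                lamellar = lam, hexagonal = hex))
  }
  list(phase = ph, evidence = ev, lamellar = lam, hexagonal = hex)
}

# One- vs two-Gaussian description of the wide-angle reflection region.
fit_gaussians_waxd <- function(s, y, k) {
  i0 <- which.max(y)
  w0 <- max(mad_noise(y), diff(range(s)) / 50)
  if (k == 1L) {
    par0 <- c(y[i0], s[i0], diff(range(s)) / 10)
    fn <- function(p) sum((y - p[1] * exp(-0.5 * ((s - p[2]) / p[3])^2))^2)
    lower <- c(0, min(s), 1e-4)
    upper <- c(2 * max(y), max(s), diff(range(s)))
  } else {
    par0 <- c(y[i0], s[i0], diff(range(s)) / 30,
              0.4 * y[i0], s[i0] + diff(range(s)) / 15, diff(range(s)) / 30)
    fn <- function(p) {
      m <- p[1] * exp(-0.5 * ((s - p[2]) / p[3])^2) +
        p[4] * exp(-0.5 * ((s - p[5]) / p[6])^2)
      sum((y - m)^2)
    }
    lower <- c(0, min(s), 1e-4, 0, min(s), 1e-4)
    upper <- c(2 * max(y), max(s), diff(range(s)), 2 * max(y), max(s),
               diff(range(s)))
  }
  best <- NULL
  shifts <- if (k == 2L) c(-1, 1) else 0
  for (sh in shifts) {
    p0 <- par0
    if (k == 2L) p0[5] <- par0[2] + sh * diff(range(s)) / 15
    o <- stats::optim(p0, fn, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}

#' Classify chain packing from a wide-angle pattern
#'
#' Gel-phase packings give sharp ~4.1-4.2 A reflections: a sharp peak with a
#' resolvable shoulder indicates the tilted-chain L-beta-prime packing; a
#' single sharp symmetric peak indicates untilted L-beta or rippled
#' P-beta-prime; a single very broad hump indicates a fluid (L-alpha) phase.
#'
#' @param p a [diffraction_pattern()] with region `"WAXD"`.
#' @param broad_fwhm_s FWHM threshold in s (1/A) above which the reflection
#'   counts as a fluid hump (default 0.012).
#' @param shoulder_rss_ratio minimum one-/two-Gaussian RSS improvement
#'   factor to call a shoulder (default 5).
#' @param shoulder_min_amp minimum shoulder amplitude as a fraction of the
#'   main amplitude (default 0.15).
#' @param shoulder_min_sep minimum component separation in s (default 0.002).
#' @return one of `"L_beta_prime"`, `"L_beta_or_P_beta_prime"`, `"fluid"`,
#'   `"unknown"`, with attribute `evidence`.
#' @export
classify_packing_waxd <- function(p, broad_fwhm_s = 0.012,
                                  shoulder_rss_ratio = 5,
                                  shoulder_min_amp = 0.15,
                                  shoulder_min_sep = 0.002) {
  stopifnot(inherits(p, "diffraction_pattern"))
  if (attr(p, "region") != "WAXD") stop("expected a WAXD-region pattern")
  pk <- pick_peaks(p, smooth = 3L)
  if (nrow(pk) == 0L)
    return(structure("unknown", evidence = "no reflection detected"))
  main <- pk[which.max(pk$height), ]
  if (main$width > broad_fwhm_s)
    return(structure("fluid",
                     evidence = sprintf("single broad hump, FWHM %.4f 1/A > %.4f",
                                        main$width, broad_fwhm_s)))
  # a resolved second local maximum already counts as a shoulder
  if (nrow(pk) >= 2L && sort(pk$height, decreasing = TRUE)[2] >=
      shoulder_min_amp * main$height)
    return(structure("L_beta_prime",
                     evidence = "two resolved sharp reflections"))
  f1 <- fit_gaussians_waxd(p$s, p$intensity, 1L)
  f2 <- fit_gaussians_waxd(p$s, p$intensity, 2L)
  amps <- f2$par[c(1, 4)]
  seps <- abs(f2$par[5] - f2$par[2])
  shoulder <- f1$value / max(f2$value, .Machine$double.eps) >
    shoulder_rss_ratio &&
    min(amps) >= shoulder_min_amp * max(amps) &&
    seps >= shoulder_min_sep
  if (shoulder)
    structure("L_beta_prime",
              evidence = sprintf("two-component fit resolves a shoulder at d = %.2f A beside the %.2f A peak",
                                 1 / f2$par[5], 1 / f2$par[2]))
  else
    structure("L_beta_or_P_beta_prime",
              evidence = sprintf("single sharp symmetric reflection at d = %.2f A",
                                 main$d))
}

#' Derived bilayer thicknesses from the electron-density model
#'
#' Exact arithmetic: headgroup peak-peak distance dHH = 2 zH; membrane
#' thickness dB = 2 (zH + 2 sigmaH); water layer dw = d - dB.
#'
#' @param d repeat distance (A); @param zH headgroup Gaussian position (A);
#' @param sigmaH headgroup Gaussian width (A). All positive; vectorised.
#' @return list with numeric `dHH`, `dB`, `dw`.
#' @export
#' @examples
#' derive_thickness(64.0, 19.5, 3.0)  # dHH 39, dB 51, dw 13
derive_thickness <- function(d, zH, sigmaH) {
  if (any(d <= 0) || any(zH <= 0) || any(sigmaH <= 0))
    stop("d, zH, sigmaH must all be positive")
  dHH <- 2 * zH
  dB <- 2 * (zH + 2 * sigmaH)
  dw <- d - dB
  if (any(dw <= 0))
    stop_memphys("dB >= d: negative or zero water layer",
                 "memphys_negative_water")
  list(dHH = dHH, dB = dB, dw = dw)
}

#' Fit the Gaussian electron-density multilamellar model to a SAXD pattern
#'
#' Nonlinear least squares over (d, zH, sigmaH, sigmaC, rho_ratio, eta) with
#' the linear intensity scale profiled out analytically and the lamellae
#' count searched over a small integer grid around the initial value.
#' Multi-start from the supplied initial parameters plus random
#' perturbations. Derived thicknesses follow [derive_thickness()] exactly.
#'
#' @param p a [diffraction_pattern()] with region `"SAXD"`.
#' @param init a [lamellar_model_params()] initial guess.
#' @param n_starts number of perturbed restarts (default 5).
#' @param n_grid integer offsets around `init$n_lamellae` to try (default
#'   `0`, i.e. keep the initial N; pass e.g. `-2:2` to search).
#' @param seed seed for the restart perturbations.
#' @return a [lamellar_fit()].
#' @export
fit_saxs <- function(p, init, n_starts = 5L, n_grid = 0L, seed = 1L) {
  stopifnot(inherits(p, "diffraction_pattern"),
            inherits(init, "lamellar_model_params"))
  s <- p$s
  I_obs <- p$intensity
  # relative weighting damps the dominant first order; the floor keeps
  # near-zero (noise-only) stretches from dominating
  wt <- 1 / pmax(abs(I_obs), max(I_obs) * 0.01)

  make_model <- function(N) {
    function(par) {
      pr <- list(d = par[1], zH = par[2], sigmaH = par[3], sigmaC = par[4],
                 rho_ratio = par[5], n_lamellae = N, eta = par[6])
      M <- saxs_model_intensity(s, pr, scale = 1)
      sc <- sum(wt * M * I_obs) / max(sum(wt * M^2), .Machine$double.eps)
      if (!is.finite(sc) || sc <= 0) return(1e30)
      r <- sum(wt * (I_obs - sc * M)^2)
      # smooth barrier keeping the water layer physical (dB < d)
      dB_frac <- 2 * (par[2] + 2 * par[3]) / par[1]
      r <- r * (1 + exp(60 * (dB_frac - 0.95)))
      attr(r, "scale") <- sc
      r
    }
  }
  p0 <- c(init$d, init$zH, init$sigmaH, init$sigmaC, init$rho_ratio, init$eta)
  lower <- c(0.7 * init$d, 0.2 * init$zH, 0.2 * init$sigmaH,
             0.2 * init$sigmaC, -10, 0)
  upper <- c(1.3 * init$d, min(2 * init$zH, 0.5 * 1.3 * init$d),
             5 * init$sigmaH, 5 * init$sigmaC, -0.01, max(4 * init$eta, 0.2))
  best <- NULL
  with_seed(seed, {
    for (N in unique(pmax(init$n_lamellae + n_grid, 1L))) {
      fn <- function(par) as.numeric(make_model(N)(par))
      for (st in seq_len(n_starts)) {
        start <- if (st == 1L) p0 else {
          pp <- p0 * stats::runif(6, 0.95, 1.05)
          pp[6] <- max(p0[6] + stats::runif(1, -0.02, 0.02), 0)
          pmin(pmax(pp, lower), upper)
        }
        o <- tryCatch(
          stats::optim(start, fn, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(maxit = 400, factr = 1e4)),
          error = function(e) NULL)
        if (is.null(o)) next
        if (is.null(best) || o$value < best$value) {
          best <- o; best$N <- N
        }
      }
    }
  })
  if (is.null(best))
    stop_memphys("SAXS model fit failed to converge from any start",
                 "memphys_fit_failure")
  par <- best$par
  r_obj <- make_model(best$N)(par)
  sc <- attr(r_obj, "scale")
  rel <- sqrt(best$value / sum(wt * I_obs^2))
  lamellar_fit(d = par[1], zH = par[2], sigmaH = par[3], sigmaC = par[4],
               rho_ratio = par[5], n_lamellae = best$N, eta = par[6],
               fit_residual = rel, scale = sc)
}
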