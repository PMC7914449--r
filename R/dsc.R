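# DSC thermogram analysis: baseline subtraction, endotherm detection with
# tangent-intersection onset/end temperatures, enthalpy integration, and
# partial phase diagrams with fluid-immiscibility plateau detection.

#' Subtract an instrument baseline from a thermogram
#'
#' Fits a low-order polynomial baseline to points outside the exclusion
#' windows (the windows bracket the endotherms) and subtracts its prediction
#' everywhere, so inside a window the baseline is interpolated from the
#' flanks, never fitted to peak points.
#'
#' @param t a [thermogram()].
#' @param exclusion_windows list of `c(lo, hi)` temperature windows (degC)
#'   containing the transitions; must lie inside the scan range.
#' @param degree polynomial degree of the baseline (default 1, linear).
#' @return baseline-subtracted [thermogram()].
#' @export
subtract_baseline <- function(t, exclusion_windows = list(), degree = 1L) {
  stopifnot(inherits(t, "thermogram"))
  tt <- t$temperature
  keep <- rep(TRUE, length(tt))
  for (w in exclusion_windows) {
    if (w[1] < min(tt) || w[2] > max(tt))
      stop("exclusion window outside temperature range")
    keep <- keep & !(tt >= w[1] & tt <= w[2])
  }
  if (mean(keep) < 0.10)
    stop_memphys("exclusion windows cover > 90% of the grid",
                 "memphys_insufficient_baseline")
  fit <- stats::lm(cp ~ stats::poly(temperature, degree, raw = TRUE),
                   data = t[keep, , drop = FALSE])
  base <- stats::predict(fit, newdata = data.frame(temperature = tt))
  out <- thermogram(tt, t$cp - base, scan_rate = attr(t, "scan_rate"))
  attr(out, "params") <- attr(t, "params")
  out
}

# Tangent through the steepest point of a flank, intersected with Cp = 0.
tangent_zero <- function(tt, cp, idx) {
  # idx: indices of the flank (ascending temperature); steepest |slope| by
  # centred differences
  if (length(idx) < 3L) return(tt[idx[1]])
  d <- diff(cp[idx]) / diff(tt[idx])
  k <- which.max(abs(d))
  i <- idx[k]
  m <- d[k]
  x0 <- (tt[i] + tt[i + 1L]) / 2
  y0 <- (cp[i] + cp[i + 1L]) / 2
  if (m == 0) return(x0)
  x0 - y0 / m
}

#' Detect endothermic transitions in a baseline-subtracted thermogram
#'
#' Local maxima above a prominence threshold become transitions. Onset and
#' end temperatures come from the calorimetric convention: the steepest
#' leading/trailing tangents intersected with the zero baseline. The
#' enthalpy is the trapezoidal integral of the excess heat capacity over the
#' full endotherm support (from where the trace rises above the local noise
#' floor to where it returns, bounded by inter-peak minima) -- strict
#' onset-to-end truncation of a two-state peak would systematically lose
#' several percent of the area.
#'
#' @param t baseline-subtracted [thermogram()].
#' @param min_prominence peak prominence threshold (kcal/mol/degC); default
#'   `NULL` uses 5 x a robust (median-absolute-deviation) noise estimate.
#' @param support_fwhm half-width of the enthalpy integration support in
#'   FWHM units (default 4).
#' @return list of transitions sorted by `t_max`, each a list with
#'   `t_onset`, `t_end`, `t_max`, `dH` (kcal/mol), `fwhm` (degC), `height`.
#'   Empty list when nothing exceeds the threshold.
#' @export
find_transitions <- function(t, min_prominence = NULL, support_fwhm = 4) {
  stopifnot(inherits(t, "thermogram"))
  tt <- t$temperature
  cp <- t$cp
  noise <- mad_noise(cp)
  if (is.null(min_prominence)) min_prominence <- 5 * max(noise, 1e-12)
  # light smoothing for detection only when noise is appreciable
  k <- if (noise > 0 && noise > 1e-6 * max(abs(cp))) 5L else 1L
  cps <- smooth_running(cp, k)
  cand <- local_maxima(cps)
  cand <- cand[vapply(cand, function(i) peak_prominence(cps, i),
                      numeric(1)) >= min_prominence]
  if (length(cand) == 0L) return(list())
  cand <- cand[order(cps[cand], decreasing = TRUE)]
  # suppress maxima that are not separated from a larger one by a deep valley
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    ok <- TRUE
    for (jj in seq_len(ii - 1L)) {
      if (!keep[jj]) next
      rng <- sort(c(cand[ii], cand[jj]))
      valley <- min(cps[rng[1]:rng[2]])
      if (cps[cand[ii]] - valley < min_prominence) { ok <- FALSE; break }
    }
    keep[ii] <- ok
  }
  peaks <- sort(cand[keep])

  # floor used only to pick the tangent flank extent
  floor_lvl <- max(0.5 * noise, 1e-12)
  out <- vector("list", length(peaks))
  for (pi in seq_along(peaks)) {
    i <- peaks[pi]
    # region bounds: inter-peak minima (or trace ends)
    lo <- if (pi == 1L) 1L else {
      seg <- peaks[pi - 1L]:i; seg[which.min(cps[seg])]
    }
    hi <- if (pi == length(peaks)) length(tt) else {
      seg <- i:peaks[pi + 1L]; seg[which.min(cps[seg])]
    }
    # flank extent for tangent selection: last rise above the noise floor
    seg_l <- lo:i
    below_l <- which(cps[seg_l] <= floor_lvl)
    a0 <- if (length(below_l)) seg_l[max(below_l)] else lo
    seg_r <- i:hi
    below_r <- which(cps[seg_r] <= floor_lvl)
    b0 <- if (length(below_r)) seg_r[min(below_r)] else hi
    ap <- parabolic_apex(tt, cps, i)
    t_onset <- tangent_zero(tt, cps, a0:i)
    t_end <- tangent_zero(tt, cps, i:b0)
    t_onset <- min(t_onset, ap$x)
    t_end <- max(t_end, ap$x)
    half <- ap$y / 2
    li <- i; while (li > lo && cps[li - 1L] > half) li <- li - 1L
    ri <- i; while (ri < hi && cps[ri + 1L] > half) ri <- ri + 1L
    x_l <- if (li > 1L) cross_at(tt, cps, li - 1L, half) else tt[li]
    x_r <- if (ri < length(tt)) cross_at(tt, cps, ri, half) else tt[ri]
    fwhm <- max(x_r - x_l, 1e-9)
    # enthalpy over a deterministic support of +/- support_fwhm widths
    # around the apex (two-state tails beyond 4 FWHM are ~exp(-14)),
    # clipped at the inter-peak region bounds; integrating the raw trace
    # keeps the noise contribution unbiased
    a <- max(lo, which.min(abs(tt - (ap$x - support_fwhm * fwhm))))
    b <- min(hi, which.min(abs(tt - (ap$x + support_fwhm * fwhm))))
    dH <- trapz(tt[a:b], cp[a:b])
    out[[pi]] <- list(t_onset = t_onset, t_end = t_end, t_max = ap$x,
                      dH = max(dH, 0), fwhm = fwhm,
                      height = ap$y)
  }
  out[order(vapply(out, `[[`, numeric(1), "t_max"))]
}

#' Is a pretransition present before the main transition?
#'
#' The small gel-phase endotherm of phosphatidylcholines precedes the main
#' transition; its presence is flagged when a minor peak (enthalpy below a
#' configured fraction of the main peak's) occurs at lower temperature.
#'
#' @param transitions list from [find_transitions()].
#' @param main_index index of the main transition in `transitions`.
#' @param max_fraction minor/main enthalpy ratio threshold (default 0.5).
#' @return logical.
#' @export
detect_pretransition <- function(transitions, main_index, max_fraction = 0.5) {
  if (main_index < 1L || main_index > length(transitions))
    stop("main_index out of range")
  if (main_index == 1L) return(FALSE)
  dH_main <- transitions[[main_index]]$dH
  any(vapply(transitions[seq_len(main_index - 1L)],
             function(tr) tr$dH < max_fraction * dH_main, logical(1)))
}

#' Assemble a partial phase diagram and detect fluid immiscibility
#'
#' Converts lipid:additive molar ratios R (meaning R:1) to additive mole
#' fraction x = 1/(1 + R) and collects onset/end temperatures per
#' composition. Fluid immiscibility (the additive saturating rather than
#' mixing) shows as composition-independent boundaries: the detector scans
#' candidate plateau starts and flags the earliest composition from which
#' both onset and end are statistically flat (two-segment piecewise-linear
#' reading of the boundary).
#'
#' @param rows list of `list(molar_ratio =, transition =)` where
#'   `molar_ratio` is R in R:1 (use `Inf` for the pure lipid) and
#'   `transition` is one element of [find_transitions()] output. Duplicate
#'   compositions are merged by averaging with a warning.
#' @param transition_label label attached to every point (default "main").
#' @param plateau_tol temperature tolerance (degC) within which a boundary
#'   segment counts as flat: the plateau's onset (and end) range must stay
#'   inside `plateau_tol`, and the composition just before the plateau must
#'   deviate from the plateau mean by more than it (set it to the replicate
#'   scatter of the calorimeter, default 0.5 degC).
#' @param min_plateau_points minimum points in the plateau segment (>= 3).
#' @return list with `points` (data.frame: mole_fraction_additive, t_onset,
#'   t_end, transition_label), `immiscibility_flag`, `plateau_start`
#'   (mole fraction, or NA).
#' @export
build_phase_diagram <- function(rows, transition_label = "main",
                                plateau_tol = 0.5, min_plateau_points = 3L) {
  if (length(rows) < 3L) stop("need >= 3 compositions")
  x <- vapply(rows, function(r) 1 / (1 + r$molar_ratio), numeric(1))
  on <- vapply(rows, function(r) r$transition$t_onset, numeric(1))
  en <- vapply(rows, function(r) r$transition$t_end, numeric(1))
  if (any(x < 0 | x >= 1)) stop("mole fractions must be in [0, 1)")
  if (anyDuplicated(x)) {
    warning("duplicate compositions merged by averaging")
    on <- tapply(on, x, mean); en <- tapply(en, x, mean)
    x <- as.numeric(names(on)); on <- as.numeric(on); en <- as.numeric(en)
  }
  o <- order(x)
  x <- x[o]; on <- on[o]; en <- en[o]
  n <- length(x)

  flat <- function(yy) max(yy) - min(yy) <= plateau_tol
  plateau_start <- NA_real_
  flag <- FALSE
  for (j in seq_len(n - min_plateau_points + 1L)) {
    idx <- j:n
    if (!(flat(on[idx]) && flat(en[idx]))) next
    if (j == 1L) {
      # boundaries flat over the whole composition range: plateau from the
      # first composition (composition-independent by definition)
      flag <- TRUE
      plateau_start <- x[1L]
    } else {
      # a genuine plateau onset: the preceding composition must sit clearly
      # off the plateau
      dev_on <- abs(on[j - 1L] - mean(on[idx]))
      dev_en <- abs(en[j - 1L] - mean(en[idx]))
      if (dev_on > plateau_tol || dev_en > plateau_tol) {
        flag <- TRUE
        plateau_start <- x[j]
      }
    }
    break
  }
  pts <- data.frame(mole_fraction_additive = x, t_onset = on, t_end = en,
                    transition_label = transition_label,
                    stringsAsFactors = FALSE)
  list(points = pts, immiscibility_flag = flag, plateau_start = plateau_start)
}
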