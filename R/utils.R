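# Internal numeric helpers shared across modules.

#' Trapezoidal integral
#' @param x,y numeric vectors of equal length, x increasing.
#' @return scalar integral of y dx.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Robust noise estimate from first differences: for white noise of sd s,
# sd(diff) = s * sqrt(2); MAD makes it insensitive to the (smooth) signal.
mad_noise <- function(y) {
  d <- diff(y)
  stats::mad(d, center = 0) / sqrt(2)
}

# Indices of strict local maxima of y (plateaus take the first index).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(diff(sign(diff(y))) < 0) + 1L
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two saddle minima separating it from higher ground (or the
# trace ends).
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i
  while (j > 1L && y[j - 1L] <= y[i]) {
    j <- j - 1L
    if (y[j] < left_min) left_min <- y[j]
  }
  if (j == 1L) left_min <- min(y[1:i])
  right_min <- y[i]; j <- i
  while (j < n && y[j + 1L] <= y[i]) {
    j <- j + 1L
    if (y[j] < right_min) right_min <- y[j]
  }
  if (j == n) right_min <- min(y[i:n])
  y[i] - max(left_min, right_min)
}

# Sub-grid apex position by fitting a parabola through (i-1, i, i+1).
parabolic_apex <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(list(x = x[i], y = y[i]))
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (!is.finite(denom) || denom >= 0 || abs(denom) < .Machine$double.eps)
    return(list(x = x[i], y = y[i]))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  h <- (x[i + 1L] - x[i - 1L]) / 2
  list(x = x[i] + delta * h, y = y2 - 0.25 * (y1 - y3) * delta)
}

# Linear interpolation of the x where y crosses level, between indices i,i+1.
cross_at <- function(x, y, i, level) {
  if (y[i + 1L] == y[i]) return(x[i])
  x[i] + (level - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
}

# Running-mean smoother with odd window k (k <= 1 returns y unchanged).
smooth_running <- function(y, k) {
  k <- as.integer(k)
  if (k <= 1L) return(y)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(y)
  pad <- (k - 1L) %/% 2L
  yp <- c(rep(y[1L], pad), y, rep(y[n], pad))
  as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2))[(pad + 1L):(pad + n)]
}

stop_memphys <- function(msg, class) {
  stop(structure(class = c(class, "memphys_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
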