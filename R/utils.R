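# Internal helpers: classed conditions, plateau-aware peak finding,
# linear resampling, scoped RNG.

stop_is <- function(subclass, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("insolestride_", subclass), "insolestride_error",
              "error", "condition"),
    list(message = msg, call = call)
  ))
}

warn_is <- function(subclass, msg) {
  warning(structure(
    class = c(paste0("insolestride_", subclass), "insolestride_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @keywords internal
#' @noRd
check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x)) {
    stop_is("invalid_input",
            sprintf("`%s` must be a numeric vector of length >= %d with no NA",
                    name, min_len))
  }
  as.numeric(x)
}

# Plateau-aware local maxima: a maximal run of equal values is a local
# maximum when the values adjacent to the run on both sides are strictly
# lower. Ties resolve to the first sample of the run. Signal boundaries do
# not count as neighbours (no boundary maxima).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  if (k < 3L) return(integer(0))
  idx <- 2:(k - 1L)
  is_max <- runs$values[idx] > runs$values[idx - 1L] &
    runs$values[idx] > runs$values[idx + 1L]
  starts[idx][is_max]
}

# Topographic prominence of peak i: height above the higher of the two
# minima separating it from the nearest strictly higher ground on each side
# (or the signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(p - 1L)]) else min(left)
    right <- x[(p + 1L):length(x)]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
}

# MATLAB findpeaks-style selection: local maxima filtered by prominence
# (absolute units) then greedily thinned to a minimum index separation,
# keeping taller peaks first. Returns sorted indices.
find_peaks <- function(x, min_separation = 1L, min_prominence = 0) {
  peaks <- local_maxima(x)
  if (!length(peaks)) return(integer(0))
  if (min_prominence > 0) {
    prom <- peak_prominence(x, peaks)
    peaks <- peaks[prom >= min_prominence]
  }
  if (!length(peaks)) return(integer(0))
  ord <- peaks[order(-x[peaks], peaks)]
  keep <- integer(0)
  for (p in ord) {
    if (!length(keep) || all(abs(keep - p) >= min_separation)) {
      keep <- c(keep, p)
    }
  }
  sort(keep)
}

# Resample a vector to `n_out` points by linear interpolation on a
# normalized [0, 1] abscissa.
resample_linear <- function(x, n_out) {
  n <- length(x)
  if (n_out < 1L) stop_is("invalid_parameter", "`n_out` must be >= 1")
  if (n == 1L) return(rep(x, n_out))
  if (n == n_out) return(x)
  stats::approx(seq(0, 1, length.out = n), x,
                xout = seq(0, 1, length.out = n_out))$y
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards (single stream per call, no global side effects).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
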