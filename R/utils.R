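#' @useDynLib gaitreliab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft lm coef median qf rnorm sd var
#' @importFrom utils read.csv write.csv
NULL

GRAVITY_MS2 <- 9.80665

SENSORS <- c("left_foot", "right_foot", "low_back")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class, data = list()) {
  stop(structure(
    class = c(class, "gaitreliab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  ))
}

validation_error <- function(field, msg) {
  abort(sprintf("invalid field '%s': %s", field, msg),
        "gaitreliab_validation_error", list(field = field))
}

#' Scipy-style peak detection with height and distance constraints
#'
#' Finds local maxima of a series, keeps those at or above `height`, then
#' enforces a minimal horizontal spacing by discarding, in order of
#' decreasing height, any remaining peak closer than `distance` samples to
#' an already-accepted peak.
#'
#' @param x numeric series.
#' @param height minimal peak value (same units as `x`); `-Inf` to disable.
#' @param distance minimal spacing in samples (ceiling applied); `0` to
#'   disable.
#' @return integer vector of peak indices, ascending.
#' @export
find_peaks <- function(x, height = -Inf, distance = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # local maxima; flat tops take the midpoint of the plateau
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx <- idx[x[idx] >= height]
  if (length(idx) > 1L && distance > 0) {
    d <- ceiling(distance)
    keep <- rep(TRUE, length(idx))
    ord <- order(x[idx], decreasing = TRUE)
    for (k in ord) {
      if (!keep[k]) next
      close <- keep & abs(idx - idx[k]) < d
      close[k] <- FALSE
      keep[close] <- FALSE
    }
    idx <- idx[keep]
  }
  sort(idx)
}

# trapezoidal cumulative integral with step dt, starting at 0
cumtrapz <- function(x, dt) {
  if (length(x) < 2) return(numeric(length(x)))
  c(0, cumsum((x[-1] + x[-length(x)]) / 2)) * dt
}

# centred rolling mean with window w samples (edges use partial windows)
roll_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# runs of TRUE as a matrix of (start, end) indices
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

vec_norm <- function(m) sqrt(rowSums(m^2))

# active rotation about the vertical axis (right-handed)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
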