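#' Clock-hour helpers
#'
#' `wrapClock()` reduces an hour value onto `[0, 24)`. `unwrapClock()` maps
#' clock hours into the continuous window `(center - 12, center + 12]`, which
#' makes evening times that straddle midnight (e.g., 23.8 and 0.2) comparable
#' on a common linear scale. `circularMeanHours()` is the circular mean of
#' clock hours, returned in `[0, 24)`. `circularDiffHours()` is the signed
#' shortest difference `a - b` on the 24-h circle, in `(-12, 12]`.
#'
#' @param x,a,b Clock hours.
#' @param center Center of the unwrapping window.
#' @return Numeric vector of hours.
#' @examples
#' wrapClock(25.5)            # 1.5
#' unwrapClock(c(23.8, 0.2), center = 24)  # 23.8, 24.2
#' circularMeanHours(c(23.5, 0.5))         # 0
#' @export
wrapClock <- function(x) {
  y <- x %% 24
  y[y >= 24] <- 0      # `%%` can round a negative epsilon up to exactly 24
  y
}

#' @rdname wrapClock
#' @export
unwrapClock <- function(x, center = 12) {
  y <- (x - center + 12) %% 24
  y[y == 0] <- 24
  y + center - 12
}

#' @rdname wrapClock
#' @export
circularMeanHours <- function(x) {
  theta <- x * pi / 12
  wrapClock(atan2(mean(sin(theta)), mean(cos(theta))) * 12 / pi)
}

#' @rdname wrapClock
#' @export
circularDiffHours <- function(a, b) {
  d <- (a - b + 12) %% 24
  d[d == 0] <- 24
  d - 12
}

# Centered moving average with shrunken windows at the ends; window must be
# odd so the window is symmetric around each point.
movingAverage <- function(x, window) {
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Fill interior NAs by linear interpolation between nearest present
# neighbours; leading/trailing NAs are left as-is (callers drop them).
interpolateInterior <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  inner <- seq(ok[1L], ok[length(ok)])
  x[inner] <- stats::approx(ok, x[ok], xout = inner)$y
  x
}

stopIfNot <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
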