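#' Fit a two-level piecewise-constant model to a daily profile
#'
#' Exhaustively searches all ordered breakpoint pairs on the sampling grid
#' of a daily activity profile (window length at least one step, complement
#' at least one step, wrap-around across midnight allowed). For each
#' candidate window the in/out levels are the segment means -- the
#' SSE-optimal levels -- so the returned fit is the exact global SSE
#' minimizer. Ties are broken deterministically toward the shorter window,
#' then the earlier start. The clock window `[b1H, b2H)` is half-open on the
#' 24-h circle.
#'
#' The model approximates a profile by a level `alpha` inside the window and
#' `beta` outside. Independently of which segment the search reports as the
#' window, `sotH` and `wtH` label the start and end of the *lower*-level
#' segment: the sleep-onset and wake-time proxies.
#'
#' An all-constant profile yields a degenerate fit (`alpha == beta`,
#' `sse = 0`, canonical window `[0, 12)`, `degenerate = TRUE`).
#'
#' @param profile Numeric vector of activity sampled uniformly over
#'   `[0, 24)`; sample `i` sits at clock hour `(i-1) * stepH`. At least 4
#'   samples.
#' @param stepH Grid step in hours; must satisfy `stepH * length(profile)
#'   == 24`.
#' @return A [PiecewiseFit-class].
#' @examples
#' prof <- c(rep(2, 8), rep(14, 16))     # low on [0,8), high on [8,24)
#' fit <- fitPiecewise(prof)
#' sleepOnset(fit); wakeTime(fit)        # 0 and 8
#' @export
fitPiecewise <- function(profile, stepH = 24 / length(profile)) {
  x <- as.numeric(profile)
  n <- length(x)
  stopIfNot(n >= 4L, "profile needs at least 4 samples")
  stopIfNot(all(is.finite(x)), "profile must be finite")
  stopIfNot(abs(stepH * n - 24) < 1e-8, "stepH must divide 24 exactly")

  if (max(x) - min(x) <= 0) {
    return(new("PiecewiseFit", b1H = 0, b2H = 12, alpha = x[1L],
               beta = x[1L], sse = 0, sotH = 0, wtH = 12,
               degenerate = TRUE, stepH = stepH))
  }

  tot <- sum(x)
  qtot <- sum(x^2)
  cs <- c(0, cumsum(c(x, x)))         # circular prefix sums
  bestG <- -Inf
  bestS <- NA_integer_
  bestL <- NA_integer_
  starts <- seq_len(n)
  for (l in seq_len(n - 1L)) {
    sw <- cs[starts + l] - cs[starts]
    g <- sw^2 / l + (tot - sw)^2 / (n - l)
    i <- which.max(g)
    if (g[i] > bestG + 1e-12) {
      bestG <- g[i]
      bestS <- i
      bestL <- l
    }
  }
  sw <- cs[bestS + bestL] - cs[bestS]
  alpha <- sw / bestL
  beta <- (tot - sw) / (n - bestL)
  sse <- max(0, qtot - bestG)
  b1 <- (bestS - 1L) * stepH
  b2 <- ((bestS - 1L + bestL) %% n) * stepH
  if (alpha <= beta) {
    sot <- b1; wt <- b2
  } else {
    sot <- b2; wt <- b1
  }
  new("PiecewiseFit", b1H = b1, b2H = b2, alpha = alpha, beta = beta,
      sse = sse, sotH = sot, wtH = wt, degenerate = FALSE, stepH = stepH)
}

#' Level of the sleep (lower) and wake (higher) segments of a fit
#'
#' @param fit A [PiecewiseFit-class].
#' @return The segment level (a.u.).
#' @export
sleepLevel <- function(fit) min(fit@alpha, fit@beta)

#' @rdname sleepLevel
#' @export
wakeLevel <- function(fit) max(fit@alpha, fit@beta)

#' Sample a two-level piecewise-constant profile on a uniform grid
#'
#' Reconstructs the model profile with level `alpha` on the half-open clock
#' window `[sotH, wtH)` (wrapping midnight when `wtH <= sotH`) and `beta`
#' elsewhere, sampled at `t = 0, stepH, ..., 24 - stepH`. Window boundaries
#' snap to the nearest grid point, so a round trip through [fitPiecewise()]
#' on the same grid is exact.
#'
#' @param sotH,wtH Window boundaries (clock hours).
#' @param alpha,beta In-window and out-of-window levels (a.u.).
#' @param stepH Grid step (h); must divide 24.
#' @return Numeric vector of length `24 / stepH`.
#' @examples
#' prof <- piecewiseTemplate(21.71, 6.92, 3.72, 15.71, stepH = 0.01)
#' sleepOnset(fitPiecewise(prof))   # 21.71
#' @export
piecewiseTemplate <- function(sotH, wtH, alpha, beta, stepH = 0.01) {
  n <- round(24 / stepH)
  stopIfNot(abs(n * stepH - 24) < 1e-8, "stepH must divide 24 exactly")
  i0 <- round(wrapClock(sotH) / stepH)
  i1 <- round(wrapClock(wtH) / stepH)
  len <- (i1 - i0) %% n
  stopIfNot(len > 0, "window [sotH, wtH) must be nonempty on the grid")
  idx <- (seq_len(n) - 1L - i0) %% n
  ifelse(idx < len, alpha, beta)
}

#' Finite-difference derivative of a daily profile
#'
#' Fourth-order five-point central stencil
#' `(f[i-2] - 8 f[i-1] + 8 f[i+1] - f[i+2]) / (12 h)` at interior points,
#' second-order three-point central at the second and second-to-last points,
#' and first-order one-sided differences at the endpoints. No periodic wrap
#' (set `periodic = TRUE` for the wrapped variant, intended for sensitivity
#' analysis only).
#'
#' @param profile Numeric vector (at least 5 finite values).
#' @param stepH Sample spacing in hours (default 1).
#' @param periodic Use wrap-around five-point stencils everywhere.
#' @return Numeric vector of derivatives (a.u. per hour), same length.
#' @examples
#' activityDerivative(0:23)[3:22]  # exactly 1 at interior points
#' @export
activityDerivative <- function(profile, stepH = 1, periodic = FALSE) {
  f <- as.numeric(profile)
  n <- length(f)
  stopIfNot(n >= 5L, "profile needs at least 5 samples")
  stopIfNot(all(is.finite(f)), "profile must be finite")
  h <- stepH
  if (periodic) {
    im2 <- ((seq_len(n) - 3L) %% n) + 1L
    im1 <- ((seq_len(n) - 2L) %% n) + 1L
    ip1 <- (seq_len(n) %% n) + 1L
    ip2 <- ((seq_len(n) + 1L) %% n) + 1L
    return((f[im2] - 8 * f[im1] + 8 * f[ip1] - f[ip2]) / (12 * h))
  }
  d <- numeric(n)
  d[1L] <- (f[2L] - f[1L]) / h
  d[2L] <- (f[3L] - f[1L]) / (2 * h)
  i <- 3:(n - 2L)
  d[i] <- (f[i - 2L] - 8 * f[i - 1L] + 8 * f[i + 1L] - f[i + 2L]) / (12 * h)
  d[n - 1L] <- (f[n] - f[n - 2L]) / (2 * h)
  d[n] <- (f[n] - f[n - 1L]) / h
  d
}

#' Winding-down period and activity
#'
#' The winding-down period is the total time over which the activity
#' derivative is negative; the winding-down activity is the activity
#' integrated (rectangle rule) over those samples.
#'
#' @param profile Numeric activity profile.
#' @param deriv Its derivative from [activityDerivative()] (same length).
#' @param stepH Sample spacing (h).
#' @return Named numeric vector `c(periodH, activity)`.
#' @export
windingDown <- function(profile, deriv, stepH = 1) {
  stopIfNot(length(profile) == length(deriv),
            "profile and derivative must be aligned")
  neg <- deriv < 0
  c(periodH = stepH * sum(neg),
    activity = stepH * sum(profile[neg]))
}

#' Overall daily activity
#'
#' Rectangle-rule integral of the profile over the 24-h day.
#'
#' @param profile Numeric activity profile over `[0, 24)`.
#' @param stepH Sample spacing (h).
#' @return Total activity (a.u. h).
#' @examples
#' overallActivity(rep(5, 24))  # 120
#' @export
overallActivity <- function(profile, stepH = 1) {
  stopIfNot(all(is.finite(profile)) && all(profile >= 0),
            "profile must be finite and nonnegative")
  stepH * sum(profile)
}

#' Time to alertness
#'
#' The interval from the morning inactive-to-active transition -- the last
#' zero crossing of the activity derivative from nonpositive to positive
#' preceding its maximum (searched circularly across midnight, located by
#' linear interpolation) -- to the derivative's global maximum (located to
#' sub-step precision by parabolic interpolation through the maximum and its
#' neighbours). Returned modulo 24, nonnegative. When the derivative is
#' nowhere positive the marker is undefined and `NA` is returned.
#'
#' @param profile Numeric activity profile (only used for alignment checks;
#'   may be `NULL`).
#' @param deriv Derivative series from [activityDerivative()].
#' @param stepH Sample spacing (h); sample `i` sits at `(i-1) * stepH`.
#' @return Time to alertness in hours, or `NA_real_`.
#' @export
timeToAlertness <- function(profile = NULL, deriv, stepH = 1) {
  d <- as.numeric(deriv)
  n <- length(d)
  if (!is.null(profile))
    stopIfNot(length(profile) == n, "profile and derivative must be aligned")
  im <- which.max(d)
  if (d[im] <= 0) return(NA_real_)

  tPeak <- (im - 1L) * stepH
  if (im > 1L && im < n) {
    denom <- d[im - 1L] - 2 * d[im] + d[im + 1L]
    if (abs(denom) > 1e-12) {
      off <- 0.5 * (d[im - 1L] - d[im + 1L]) / denom
      if (abs(off) <= 1) tPeak <- tPeak + off * stepH
    }
  }

  tZero <- NA_real_
  for (off in seq_len(n)) {
    j <- ((im - off - 1L) %% n) + 1L        # walk backwards, circularly
    jn <- (j %% n) + 1L
    if (d[j] <= 0 && d[jn] > 0) {
      frac <- if (d[jn] > d[j]) (0 - d[j]) / (d[jn] - d[j]) else 0
      tZero <- ((j - 1L) + frac) * stepH
      break
    }
  }
  if (is.na(tZero)) return(NA_real_)
  (tPeak - tZero) %% 24
}

#' Compute all derivative-based markers for one profile
#'
#' Convenience wrapper: derivative, winding-down period/activity, overall
#' activity and time to alertness in one [MarkerSet-class].
#'
#' @param profile Numeric activity profile over `[0, 24)`.
#' @param stepH Sample spacing (h).
#' @param periodic Passed to [activityDerivative()].
#' @return A [MarkerSet-class].
#' @export
computeMarkers <- function(profile, stepH = 1, periodic = FALSE) {
  deriv <- activityDerivative(profile, stepH, periodic)
  wd <- windingDown(profile, deriv, stepH)
  new("MarkerSet",
      windingDownPeriodH = unname(wd["periodH"]),
      windingDownActivity = unname(wd["activity"]),
      overallActivity = overallActivity(profile, stepH),
      ttaH = timeToAlertness(profile, deriv, stepH))
}
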