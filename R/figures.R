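#' Render report figures
#'
#' Best-effort PNG figures for a pipeline report: one overlay per cluster
#' (hourly activity bars, derivative curve, piecewise-constant
#' approximation), cumulative distribution curves per marker across groups,
#' and a polar sleep-window plot (sleep onset as filled, wake time as open
#' circles, marker size proportional to cluster count). Figure failures are
#' logged as warnings, never fatal.
#'
#' @param report An `actiphenReport` from [runPipeline()].
#' @param outDir Output directory.
#' @param width,height Device size in pixels.
#' @return Character vector of files written, invisibly.
#' @export
renderFigures <- function(report, outDir, width = 900, height = 600) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character(0)
  emit <- function(name, expr) {
    path <- file.path(outDir, name)
    ok <- tryCatch({
      grDevices::png(path, width = width, height = height)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr()
      TRUE
    }, error = function(e) {
      warning(sprintf("figure %s failed: %s", name, conditionMessage(e)),
              call. = FALSE)
      FALSE
    })
    if (ok) written <<- c(written, path)
  }

  tab <- report$clusterTable
  if (!is.null(tab)) {
    for (g in names(report$clustering)) {
      res <- report$clustering[[g]]
      emit(sprintf("clusters_%s.png", gsub("[^A-Za-z0-9_-]", "_", g)),
           function() {
        k <- res@k
        nc <- ceiling(sqrt(k))
        graphics::par(mfrow = c(ceiling(k / nc), nc),
                      mar = c(3, 3, 2, 3))
        for (j in seq_len(k)) {
          center <- clusterCenters(res)[j, ]
          fit <- fitPiecewise(center, stepH = 1)
          pla <- piecewiseTemplate(fit@b1H, fit@b2H, fit@alpha, fit@beta,
                                   stepH = 1)
          deriv <- activityDerivative(center)
          graphics::barplot(center, names.arg = NULL, col = "grey80",
                            border = NA,
                            main = sprintf("%s cluster %d (n=%d)", g, j,
                                           res@clusterCounts[j]))
          at <- seq(0.7, by = 1.2, length.out = 24)
          graphics::lines(at, pla, col = "darkgreen", lwd = 2)
          graphics::par(new = TRUE)
          graphics::plot(at, deriv, type = "l", col = "red", axes = FALSE,
                         xlab = "", ylab = "")
          graphics::axis(4, col.axis = "red")
        }
      })
    }

    for (marker in c("winding_down_period_h", "winding_down_activity",
                     "overall_activity")) {
      emit(sprintf("cdf_%s.png", marker), function() {
        gs <- unique(tab$group)
        cols <- grDevices::hcl.colors(max(2L, length(gs)), "Dark 3")
        graphics::plot(range(tab[[marker]]), c(0, 1), type = "n",
                       xlab = marker, ylab = "cumulative fraction",
                       main = sprintf("Weighted CDF of %s", marker))
        for (i in seq_along(gs)) {
          tg <- tab[tab$group == gs[i], ]
          F <- weightedCdf(tg[[marker]], tg$count)
          graphics::plot(F, add = TRUE, col.points = NA, col = cols[i],
                         do.points = FALSE, verticals = TRUE)
        }
        graphics::legend("bottomright", legend = gs, col = cols, lwd = 2)
      })
    }

    emit("polar_sleep_windows.png", function() {
      graphics::par(pty = "s")
      graphics::plot(c(-1.3, 1.3), c(-1.3, 1.3), type = "n", axes = FALSE,
                     xlab = "", ylab = "", main = "Sleep windows by cluster")
      th <- seq(0, 2 * pi, length.out = 200)
      graphics::lines(cos(th), sin(th), col = "grey70")
      for (h in seq(0, 21, by = 3)) {
        a <- pi / 2 - h * pi / 12     # midnight at top, clockwise
        graphics::text(1.18 * cos(a), 1.18 * sin(a), sprintf("%02d:00", h),
                       cex = 0.8)
      }
      sizeOf <- function(count) 0.8 + 2.2 * count / max(tab$count)
      gs <- unique(tab$group)
      cols <- grDevices::hcl.colors(max(2L, length(gs)), "Dark 3")
      for (i in seq_len(nrow(tab))) {
        aS <- pi / 2 - tab$sot_h[i] * pi / 12
        aW <- pi / 2 - tab$wt_h[i] * pi / 12
        col <- cols[match(tab$group[i], gs)]
        graphics::segments(cos(aS), sin(aS), cos(aW), sin(aW), col = col)
        graphics::points(cos(aS), sin(aS), pch = 16, col = col,
                         cex = sizeOf(tab$count[i]))
        graphics::points(cos(aW), sin(aW), pch = 1, col = col,
                         cex = sizeOf(tab$count[i]))
      }
      graphics::legend("bottomright", legend = gs, col = cols, pch = 16)
    })
  }
  invisible(written)
}
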