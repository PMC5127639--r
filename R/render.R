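# En face rendering of the TJ honeycomb as SVG (vector, text-only).
#
# Following the model's display convention, TJ-bearing cells are filled
# with three colours by height class (age terciles -- a rendering binning;
# the simulation state is continuous), bTJ seams are drawn green and tTJ
# seams purple; tricellular points at single-edged polygon vertices are not
# displayed.

.heightTercileFills <- c("#f8e71c", "#f5a623", "#4a90d9")  # low, mid, high

#' Render a honeycomb to an en face SVG
#'
#' @param graph a \linkS4class{TJGraph}.
#' @param file output path.
#' @param strokeWidth seam stroke width (um); default 0.8.
#' @return the file path, invisibly.
#' @export
renderEnFaceSVG <- function(graph, file, strokeWidth = 0.8) {
  pg <- graph@polygons
  zc <- pg$z
  br <- stats::quantile(zc, c(1, 2) / 3, names = FALSE)
  tier <- 1L + (zc > br[1]) + (zc > br[2])

  allxy <- do.call(rbind, lapply(graph@rings, function(P) P[, 1:2]))
  lo <- apply(allxy, 2, min) - 2; hi <- apply(allxy, 2, max) + 2
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="%.2f %.2f %.2f %.2f">',
    lo[1], lo[2], hi[1] - lo[1], hi[2] - lo[2]))

  ptsOf <- function(P) paste(sprintf("%.2f,%.2f", P[, 1], P[, 2]), collapse = " ")
  # fills first (drawing order: lower polygons beneath), then seams on top
  ord <- order(pg$z)
  for (i in ord)
    out <- c(out, sprintf('<polygon class="%s" points="%s" fill="%s" fill-opacity="0.55"/>',
                          pg$kind[i], ptsOf(graph@rings[[i]][, 1:2, drop = FALSE]),
                          .heightTercileFills[tier[i]]))
  sm <- graph@seams
  col <- ifelse(sm$class == "tTJ", "#7b2d8e", "#2e9e4f")
  out <- c(out, sprintf(
    '<line class="%s" x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="%.2f"/>',
    sm$class, sm$x1, sm$y1, sm$x2, sm$y2, col, strokeWidth))
  out <- c(out, "</svg>")
  writeLines(out, file)
  invisible(file)
}

#' Render a frame sequence of stored snapshots
#'
#' One SVG per stored snapshot in the requested interval (store snapshots
#' at the frame interval via \code{snapshotEvery = dtMinutes / 60} for a
#' movie-rate sequence).
#'
#' @param sim a \linkS4class{TurnoverSim}.
#' @param outDir output directory.
#' @param from,to time window (hr); defaults to the full stored range.
#' @return character vector of file paths, invisibly.
#' @export
renderFrames <- function(sim, outDir, from = -Inf, to = Inf) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ts <- snapshotTimes(sim)
  ts <- ts[ts >= from & ts < to]
  files <- character(0)
  for (k in seq_along(ts)) {
    f <- file.path(outDir, sprintf("frame_%05d.svg", k))
    renderEnFaceSVG(extractHoneycomb(sim, ts[k]), f)
    files <- c(files, f)
  }
  invisible(files)
}
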