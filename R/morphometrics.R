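# Measurement procedures applied identically to simulated and synthetic
# honeycombs: en face polygon areas (with the overlap convention used for
# single-edged polygons bordering an exterior polygon), vertex-average Z
# positions, relative Z over octets, random sampling windows and the
# double-edged percentage with across-assay SEM.

.shoelace <- function(P) abs(pracma::polyarea(P[, 1], P[, 2]))

# grid estimate of the en face intersection area of two rings
.gridIntersectArea <- function(A, B, n = 48L) {
  lo <- pmax(apply(A[, 1:2, drop = FALSE], 2, min), apply(B[, 1:2, drop = FALSE], 2, min))
  hi <- pmin(apply(A[, 1:2, drop = FALSE], 2, max), apply(B[, 1:2, drop = FALSE], 2, max))
  if (any(hi <= lo)) return(0)
  gx <- seq(lo[1], hi[1], length.out = n)
  gy <- seq(lo[2], hi[2], length.out = n)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  inA <- mgcv::in.out(rbind(A[, 1:2], A[1, 1:2]), pts)
  inB <- mgcv::in.out(rbind(B[, 1:2], B[1, 1:2]), pts)
  mean(inA & inB) * prod(hi - lo)
}

#' En face polygon area
#'
#' Shoelace area of the en face projection of a polygon's own outline.
#' Under \code{"include_overlap"} (the reporting convention for honeycomb
#' statistics) any region jointly claimed by a single-edged polygon and an
#' overhanging adjacent exterior polygon counts toward the single-edged
#' polygon, i.e. its own outline is integrated without clipping; under
#' \code{"plain"} the grid-estimated intersection with adjacent exterior
#' polygons is removed.  In meshes where the two outlines share their
#' boundary vertices exactly (all meshes produced by this package) the
#' conventions coincide.
#'
#' @param x a \linkS4class{TJGraph}, or a single ring coordinate matrix
#'   (columns x, y[, z]).
#' @param ids polygon ids (default: all).
#' @param convention \code{"include_overlap"} (default) or \code{"plain"}.
#' @return numeric areas, um^2 (named by polygon id for a TJGraph).
#' @examples
#' polygonArea(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))   # unit square -> 1
#' @export
polygonArea <- function(x, ids = NULL,
                        convention = c("include_overlap", "plain")) {
  convention <- match.arg(convention)
  if (is.matrix(x)) {
    if (nrow(x) < 3L) stop("a polygon needs at least 3 vertices")
    return(.shoelace(x))
  }
  if (!is(x, "TJGraph")) stop("x must be a TJGraph or a coordinate matrix")
  pg <- x@polygons
  if (is.null(ids)) ids <- pg$id
  a <- vapply(ids, function(id) .shoelace(x@rings[[match(id, pg$id)]]), 0)
  names(a) <- ids
  if (convention == "plain") {
    ext <- pg$id[pg$kind == "exterior"]
    for (k in seq_along(ids)) {
      id <- ids[k]
      if (pg$kind[match(id, pg$id)] != "single" || !length(ext)) next
      nb <- intersect(polygonNeighbors(x, id), ext)
      for (e in nb)
        a[k] <- a[k] - .gridIntersectArea(x@rings[[match(id, pg$id)]],
                                          x@rings[[match(e, pg$id)]])
    }
  }
  a
}

#' En face Z position of a polygon
#'
#' The Z position of a polygon is the average of the Z positions of its
#' vertices.
#'
#' @param x a \linkS4class{TJGraph} or a ring coordinate matrix with a z
#'   column.
#' @param ids polygon ids (default: all).
#' @return numeric Z (um), named by polygon id for a TJGraph.
#' @export
polygonZ <- function(x, ids = NULL) {
  if (is.matrix(x)) {
    if (nrow(x) < 1L) stop("empty polygon")
    return(mean(x[, 3]))
  }
  if (!is(x, "TJGraph")) stop("x must be a TJGraph or a coordinate matrix")
  pg <- x@polygons
  if (is.null(ids)) ids <- pg$id
  z <- pg$z[match(ids, pg$id)]
  names(z) <- ids
  z
}

#' Relative Z over a set of eight polygons
#'
#' Each polygon's Z minus the mean Z of the octet (one exterior, one
#' interior and their six adjacent single-edged polygons); the outputs sum
#' to zero by construction.
#'
#' @param z numeric vector of exactly 8 Z positions (um).
#' @return centred vector of relative Z (um).
#' @export
relativeZ <- function(z) {
  if (!is.numeric(z) || length(z) != 8L)
    stop("an octet has exactly 8 polygons")
  z - mean(z)
}

#' Relative-Z table over all octets of a honeycomb
#'
#' @param graph a \linkS4class{TJGraph}.
#' @return data.frame: octet, polygon_id, kind, rel_z (um).
#' @export
octetRelativeZ <- function(graph) {
  oc <- tjOctets(graph)
  out <- list()
  pg <- graph@polygons
  for (k in seq_along(oc)) {
    ids <- c(oc[[k]]$exterior, oc[[k]]$interior, oc[[k]]$singles)
    rz <- relativeZ(pg$z[match(ids, pg$id)])
    out[[k]] <- data.frame(octet = k, polygon_id = ids,
                           kind = pg$kind[match(ids, pg$id)], rel_z = rz)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(octet = integer(0), polygon_id = integer(0),
                  kind = character(0), rel_z = numeric(0))
}

#' Sample square en face windows and count polygons
#'
#' Random axis-aligned square fields of the given area; a polygon belongs
#' to a window when its en face centroid falls inside (a double-edged pair
#' is located by its exterior polygon's centroid and counted once).
#'
#' @param graph a \linkS4class{TJGraph}.
#' @param nWindows number of windows (default 20).
#' @param windowArea field area in um^2 (default 15376, a 124 um square).
#' @param origins optional nWindows x 2 matrix of window corners (um);
#'   random uniform over the domain otherwise.
#' @param wrap treat the domain as periodic when placing and evaluating
#'   windows (default: the graph's periodicity).  With \code{wrap = FALSE}
#'   membership is a plain box test, so a window covering the whole mesh
#'   returns the global counts.
#' @return data.frame: window, x0, y0, side_um, n_single, n_double.
#' @export
sampleWindows <- function(graph, nWindows = 20L, windowArea = 15376,
                          origins = NULL,
                          wrap = isTRUE(graph@domain$periodic)) {
  side <- sqrt(windowArea)
  lv <- graph@domain$latVec
  domArea <- abs(det(lv))
  if (wrap && windowArea > domArea)
    stop("window (", windowArea, " um^2) larger than the domain (",
         round(domArea), " um^2)")
  pg <- graph@polygons
  ctr <- t(vapply(graph@rings, function(P) colMeans(P[, 1:2, drop = FALSE]),
                  numeric(2)))
  singles <- which(pg$kind == "single")
  exts <- match(graph@pairs$exterior, pg$id)

  org <- if (is.null(origins)) matrix(stats::runif(2L * nWindows), nWindows) %*% lv
         else matrix(origins, ncol = 2)
  nWindows <- nrow(org)
  sh <- as.matrix(expand.grid(mi = -1:1, mj = -1:1)) %*% lv
  inWin <- function(p, o) {
    d <- p - o
    if (wrap) {
      d0 <- .wrapDelta0(d, lv)
      any(d0[1] + sh[, 1] >= 0 & d0[1] + sh[, 1] < side &
          d0[2] + sh[, 2] >= 0 & d0[2] + sh[, 2] < side)
    } else d[1] >= 0 && d[1] < side && d[2] >= 0 && d[2] < side
  }
  ns <- nd <- integer(nWindows)
  for (w in seq_len(nWindows)) {
    ns[w] <- sum(vapply(singles, function(k) inWin(ctr[k, ], org[w, ]), TRUE))
    nd[w] <- if (length(exts))
      sum(vapply(exts, function(k) inWin(ctr[k, ], org[w, ]), TRUE)) else 0L
  }
  data.frame(window = seq_len(nWindows), x0 = org[, 1], y0 = org[, 2],
             side_um = side, n_single = ns, n_double = nd)
}

# wrap a displacement into the fundamental cell, components in [0, period)
.wrapDelta0 <- function(d, lv) {
  frac <- solve(t(lv)) %*% d
  as.numeric(d - t(lv) %*% floor(frac))
}

#' Double-edged polygon percentage with across-assay SEM
#'
#' The per-assay percentage pools that assay's windows:
#' 100 * doubles / (doubles + singles); the summary is the mean and SEM
#' across assays (not across windows).
#'
#' @param counts data.frame with columns n_single, n_double and optionally
#'   assay (one assay assumed otherwise).
#' @return list: percent (per assay), mean, sem, n_assays.
#' @export
doubleEdgedPercent <- function(counts) {
  if (!all(c("n_single", "n_double") %in% names(counts)))
    stop("counts needs n_single and n_double columns")
  if (!nrow(counts)) stop("empty assay table")
  assay <- if ("assay" %in% names(counts)) counts$assay else rep(1L, nrow(counts))
  pct <- vapply(split(counts, assay), function(d) {
    tot <- sum(d$n_double) + sum(d$n_single)
    if (tot == 0) stop("assay with no polygons")
    100 * sum(d$n_double) / tot
  }, 0)
  list(percent = pct, mean = mean(pct),
       sem = if (length(pct) > 1L) stats::sd(pct) / sqrt(length(pct)) else NA_real_,
       n_assays = length(pct))
}

#' Calibrate the micrometre scale from single-edged polygon areas
#'
#' Returns the um-per-lattice-unit factor that brings the mean single-edged
#' polygon area of the honeycomb to the target (905.8 um^2 by default, the
#' reference steady-state mean).
#'
#' @param graph a \linkS4class{TJGraph}.
#' @param target target mean single-edged area (um^2).
#' @return scalar scale (um per lattice unit).
#' @export
calibrateScale <- function(graph, target = 905.8) {
  pg <- graph@polygons
  m <- mean(pg$area[pg$kind == "single"])
  if (!is.finite(m) || m <= 0) stop("no single-edged polygons to calibrate on")
  graph@scale * sqrt(target / m)
}

#' Morphometric summary of one or more simulated assays
#'
#' Treats each simulation (seed) as an independent assay: samples en face
#' windows on its extracted honeycombs for the double-edged percentage,
#' pools residence times, per-class polygon areas and octet relative-Z.
#'
#' @param sims a \linkS4class{TurnoverSim} or list of them.
#' @param nWindows windows per assay (default 20).
#' @param windowArea window area, um^2 (default 15376).
#' @param times snapshot times per sim (default: all post-burn-in stored
#'   snapshots).
#' @return data.frame: metric, class, mean, sem, n, units.
#' @export
summaryStats <- function(sims, nWindows = 20L, windowArea = 15376,
                         times = NULL) {
  if (is(sims, "TurnoverSim")) sims <- list(sims)
  winAll <- list(); areas <- list(); relz <- list(); res <- list()
  for (k in seq_along(sims)) {
    sim <- sims[[k]]
    tms <- if (is.null(times)) {
      ts <- snapshotTimes(sim); ts[ts > sim@config@burnIn]
    } else times
    perWin <- list()
    for (t in tms) {
      hc <- extractHoneycomb(sim, t)
      w <- sampleWindows(hc, nWindows = max(1L, ceiling(nWindows / length(tms))),
                         windowArea = windowArea)
      perWin[[length(perWin) + 1L]] <- w
      pg <- polygons(hc)
      areas[[length(areas) + 1L]] <- pg[, c("kind", "area")]
      oz <- octetRelativeZ(hc)
      if (nrow(oz)) relz[[length(relz) + 1L]] <- oz[, c("kind", "rel_z")]
    }
    w <- do.call(rbind, perWin); w$assay <- k
    winAll[[k]] <- w
    res[[k]] <- residenceTimes(sim)
  }
  dep <- doubleEdgedPercent(do.call(rbind, winAll))
  rr <- unlist(res)
  A <- do.call(rbind, areas)
  Z <- if (length(relz)) do.call(rbind, relz) else NULL

  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  rows <- list(
    data.frame(metric = "double_edged_percent", class = "all",
               mean = dep$mean, sem = dep$sem, n = dep$n_assays, units = "%"),
    data.frame(metric = "residence", class = "all",
               mean = mean(rr), sem = sem(rr), n = length(rr), units = "hr"))
  # single-edged class for reporting uses the overlap-inclusive convention,
  # which equals the stored own-outline area in these meshes
  for (kl in c("single", "exterior", "interior")) {
    v <- A$area[A$kind == kl]
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "area", class = kl, mean = mean(v), sem = sem(v),
      n = length(v), units = "um^2")
  }
  if (!is.null(Z)) for (kl in c("exterior", "single", "interior")) {
    v <- Z$rel_z[Z$kind == kl]
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "relative_z", class = kl, mean = mean(v), sem = sem(v),
      n = length(v), units = "um")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
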