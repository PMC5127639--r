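# En face TJ honeycomb extraction and classification.
#
# Each steady column contributes one single-edged polygon: the apical TJ
# ring of its SG2 cell, whose shape depends on which of the six lateral
# neighbours currently hold the higher of their two candidate cells.  A
# transitioning column contributes an exterior polygon (the exiting cell's
# pre-existing ring, the maximal cross-section circuit, since a cell only
# transitions when all six neighbours are lower) and an interior polygon
# (the apical hexagon of the freshly promoted cell, every edge of which is
# shared by three SG2 cells, hence tricellular).

# height of a column's top (TJ-bearing) cell, in units of the parity step
.topHeightSteps <- function(state, lattice) {
  lattice@parity - 3L * state$count
}

#' Check age/height consistency of a snapshot
#'
#' On the interdigitated lattice the SG2 cells of two adjacent columns must
#' sit one parity step apart (one up, or two down, toward a higher-parity
#' neighbour) and the higher cell must be the older one.  Violations mean
#' the snapshot has no geometric realization (e.g. after \code{init="iid"}).
#'
#' @param state engine state list.
#' @param lattice a \linkS4class{ColumnLattice}.
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
auditHeights <- function(state, lattice) {
  h <- .topHeightSteps(state, lattice)
  nbr <- lattice@nbr
  for (s in seq_len(6L)) {
    q <- nbr[, s]
    ok <- !is.na(q)
    dz <- h[q[ok]] - h[ok]
    up <- lattice@cell@sectors[[s]]$upParity
    valid <- if (up) dz == 1L | dz == -2L else dz == -1L | dz == 2L
    if (!all(valid))
      stop("height field violates the interdigitated packing at column ",
           which(ok)[!valid][1], ", sector ", s)
    older <- state$topEntry[q[ok]] < state$topEntry[ok]
    if (!all(older == (dz > 0)))
      stop("age order disagrees with height order at column ",
           which(ok)[older != (dz > 0)][1])
  }
  invisible(TRUE)
}

# canonical en face reduction of points to the fundamental torus cell,
# translating by whole period vectors chosen from the reference point
.reduceBy <- function(P, ref, latVec, Li = solve(t(latVec))) {
  frac <- Li %*% ref
  mn <- floor(frac + 1e-7)
  if (any(mn != 0)) {
    shift <- as.numeric(t(latVec) %*% mn)
    P[, 1] <- P[, 1] - shift[1]
    P[, 2] <- P[, 2] - shift[2]
  }
  P
}

# canonical keys for edges given as endpoint matrices A, B (n x 3), reduced
# by the edge midpoint and ordered lexicographically; fully vectorized
.edgePairKeys <- function(A, B, latVec, periodic, digits = 5,
                          Li = if (periodic) solve(t(latVec)) else NULL) {
  if (periodic) {
    mid <- (A[, 1:2, drop = FALSE] + B[, 1:2, drop = FALSE]) / 2
    mn <- floor(mid %*% t(Li) + 1e-7)
    if (any(mn != 0)) {
      shift <- mn %*% latVec
      A[, 1:2] <- A[, 1:2, drop = FALSE] - shift
      B[, 1:2] <- B[, 1:2, drop = FALSE] - shift
    }
  }
  A <- round(A, digits); B <- round(B, digits)
  swap <- A[, 1] > B[, 1] |
    (A[, 1] == B[, 1] & (A[, 2] > B[, 2] |
                         (A[, 2] == B[, 2] & A[, 3] > B[, 3])))
  if (any(swap)) {
    tmp <- A[swap, , drop = FALSE]
    A[swap, ] <- B[swap, , drop = FALSE]
    B[swap, ] <- tmp
  }
  paste(A[, 1], A[, 2], A[, 3], B[, 1], B[, 2], B[, 3], sep = ",")
}

.edgeKeys <- function(V, cyc, offset, latVec, periodic, digits = 5, Li = NULL) {
  P <- sweep(V[cyc, , drop = FALSE], 2, -offset)
  n <- nrow(P)
  nx2 <- c(2:n, 1L)
  if (periodic && is.null(Li)) Li <- solve(t(latVec))
  .edgePairKeys(P, P[nx2, , drop = FALSE], latVec, periodic, digits, Li)
}

.vertexKeys <- function(P, latVec, periodic, digits = 5,
                        Li = if (periodic) solve(t(latVec)) else NULL) {
  if (periodic) {
    mn <- floor(P[, 1:2, drop = FALSE] %*% t(Li) + 1e-7)
    if (any(mn != 0)) P[, 1:2] <- P[, 1:2, drop = FALSE] - mn %*% latVec
  }
  P <- round(P, digits)
  paste(P[, 1], P[, 2], P[, 3], sep = ",")
}

#' Extract the TJ honeycomb from a simulation snapshot
#'
#' @param sim a \linkS4class{TurnoverSim}.
#' @param time snapshot time (default: last stored snapshot).
#' @param scale micrometres per lattice unit (default: the lattice scale).
#' @return a \linkS4class{TJGraph}.
#' @examples
#' sim <- runTurnover(simConfig(nx = 6, ny = 6, duration = 48, burnIn = 24))
#' hc <- extractHoneycomb(sim)
#' table(polygons(hc)$kind)
#' @export
extractHoneycomb <- function(sim, time = NULL, scale = NULL) {
  if (!is(sim, "TurnoverSim")) stop("sim must be a TurnoverSim")
  if (is.null(time)) time <- max(snapshotTimes(sim))
  state <- snapshotAt(sim, time)
  .extractFromState(state, sim@lattice, scale = scale, time = time)
}

.extractFromState <- function(state, lattice, scale = NULL, time = NA_real_) {
  if (lattice@periodic && (lattice@nx %% 3L || lattice@ny %% 3L))
    stop("a flat periodic honeycomb requires nx and ny divisible by 3 ",
         "(the height phase advances one stack third per column step)")
  auditHeights(state, lattice)
  if (is.null(scale)) scale <- lattice@scale

  cell <- lattice@cell
  f <- cell@flattenRatio
  step <- .zPhaseStep(f); stackH <- .stackHeight(f)
  N <- nColumns(lattice)
  zTop <- .topHeightSteps(state, lattice) * step
  trans <- state$phase == .PHASE_TRANSITION

  # neighbour-higher configuration per column, from top-cell age order
  higher <- matrix(FALSE, N, 6L)
  for (s in seq_len(6L)) {
    q <- lattice@nbr[, s]
    higher[, s] <- !is.na(q) & state$topEntry[q] < state$topEntry
  }
  cfg <- 1L + as.integer(higher %*% 2^(0:5))

  # cells present in the TJ layer: every top cell, plus the incoming cell
  # of each transitioning column (one stack below the exiting one)
  cellCols <- c(seq_len(N), which(trans))
  cellZ <- c(zTop, zTop[trans] - stackH)

  # shared-edge and shared-vertex multiplicity over all SG2 cells
  VT <- cell@vertices
  Li <- if (lattice@periodic) solve(t(lattice@latVec)) else NULL
  ea <- cell@edges[, 1]; eb <- cell@edges[, 2]
  allEdgeKeys <- lapply(seq_along(cellCols), function(k) {
    off <- c(lattice@colPos[cellCols[k], ], cellZ[k])
    P <- sweep(VT, 2, -off)
    .edgePairKeys(P[ea, , drop = FALSE], P[eb, , drop = FALSE],
                  lattice@latVec, lattice@periodic, Li = Li)
  })
  edgeTab <- table(unlist(allEdgeKeys))

  vertKeysOf <- function(P) .vertexKeys(P, lattice@latVec, lattice@periodic, Li = Li)
  vertCellTab <- table(unlist(lapply(seq_along(cellCols), function(k) {
    off <- c(lattice@colPos[cellCols[k], ], cellZ[k])
    unique(vertKeysOf(sweep(VT, 2, -off)))
  })))

  polys <- list(); ringsL <- list(); seamsL <- list(); pairsL <- list()
  addPolygon <- function(column, kind, tmplIdx, zCenter) {
    idx <- cell@ringTemplates[[tmplIdx]]
    off <- c(lattice@colPos[column, ], zCenter)
    P <- sweep(VT[idx, , drop = FALSE], 2, -off)
    id <- length(polys) + 1L
    ekeys <- .edgeKeys(VT, idx, off, lattice@latVec, lattice@periodic, Li = Li)
    nshare <- as.integer(edgeTab[ekeys])
    vkeys <- vertKeysOf(P)
    nvshare <- as.integer(vertCellTab[vkeys])
    polys[[id]] <<- data.frame(
      id = id, column_id = column, kind = kind,
      area = abs(pracma::polyarea(P[, 1], P[, 2])) * scale^2,
      z = mean(P[, 3]) * scale,
      n_vertices = nrow(P),
      n_ttj_vertices = sum(nvshare >= 3L))
    ringsL[[id]] <<- P * scale
    n <- nrow(P)
    nx2 <- c(2:n, 1L)
    seamsL[[id]] <<- data.frame(
      polygon_id = id, key = ekeys,
      x1 = P[, 1] * scale, y1 = P[, 2] * scale, z1 = P[, 3] * scale,
      x2 = P[nx2, 1] * scale, y2 = P[nx2, 2] * scale, z2 = P[nx2, 3] * scale,
      n_share = nshare,
      class = ifelse(nshare >= 3L, "tTJ", "bTJ"))
    id
  }

  allHigher <- .ringTemplateIndex(rep(TRUE, 6L))
  for (c0 in seq_len(N)) {
    if (trans[c0]) {
      # exterior: the exiting cell's ring under the current neighbour-top
      # configuration -- the maximal circuit whenever no neighbour is also
      # transitioning (a cell only transitions once all six tops are lower),
      # pulled in toward a concurrently transitioning older neighbour
      eid <- addPolygon(c0, "exterior", cfg[c0], zTop[c0])
      iid <- addPolygon(c0, "interior", allHigher, zTop[c0] - stackH)
      pairsL[[length(pairsL) + 1L]] <-
        data.frame(column_id = c0, exterior = eid, interior = iid)
    } else {
      addPolygon(c0, "single", cfg[c0], zTop[c0])
    }
  }

  new("TJGraph",
      polygons = do.call(rbind, polys),
      rings = ringsL,
      seams = do.call(rbind, seamsL),
      pairs = if (length(pairsL)) do.call(rbind, pairsL)
              else data.frame(column_id = integer(0), exterior = integer(0),
                              interior = integer(0)),
      domain = list(periodic = lattice@periodic,
                    latVec = lattice@latVec * scale),
      scale = scale, time = time)
}

#' @rdname TJGraph-class
setMethod("polygons", "TJGraph", function(x) x@polygons)

#' @rdname TJGraph-class
setMethod("seams", "TJGraph", function(x) x@seams)

#' @rdname TJGraph-class
setMethod("rings", "TJGraph", function(x) x@rings)

#' @rdname TJGraph-class
setMethod("doubleEdgedPairs", "TJGraph", function(x) x@pairs)

setMethod("show", "TJGraph", function(object) {
  k <- table(object@polygons$kind)
  cat(sprintf("TJGraph: %d polygons (%s), %d seams (%d tTJ)%s\n",
              nrow(object@polygons),
              paste(names(k), as.integer(k), sep = ":", collapse = ", "),
              nrow(object@seams), sum(object@seams$class == "tTJ"),
              if (is.na(object@time)) "" else sprintf(", t = %g hr", object@time)))
})

# point-in-polygon with en face wrap: replicate polygon over the 9
# neighbouring period cells when periodic
.insideWrapped <- function(pts, ring2d, domain) {
  inside <- rep(FALSE, nrow(pts))
  shifts <- if (isTRUE(domain$periodic)) {
    g <- expand.grid(mi = -1:1, mj = -1:1)
    t(apply(g, 1, function(m) m[1] * domain$latVec[1, ] + m[2] * domain$latVec[2, ]))
  } else matrix(0, 1, 2)
  for (r in seq_len(nrow(shifts))) {
    bnd <- sweep(ring2d, 2, shifts[r, ], "+")
    sel <- pts[, 1] >= min(bnd[, 1]) & pts[, 1] <= max(bnd[, 1]) &
           pts[, 2] >= min(bnd[, 2]) & pts[, 2] <= max(bnd[, 2])
    if (any(sel))
      inside[sel] <- inside[sel] | mgcv::in.out(rbind(bnd, bnd[1, ]), pts[sel, , drop = FALSE])
  }
  inside
}

#' Audit barrier continuity of a honeycomb
#'
#' The TJ barrier is continuous when (i) every polygon is a closed seam
#' cycle, (ii) every seam is a true junction, i.e. the edge is shared by at
#' least two SG2 cells (a seam bordered by a single cell is an unsealed
#' boundary), and (iii) the en face union of the closed polygons covers the
#' periodic plane, tested on a sampling grid.
#'
#' @param graph a \linkS4class{TJGraph}.
#' @param gridN coverage sampling grid is gridN x gridN over the
#'   fundamental domain (default 40).
#' @param tol fraction of grid points allowed uncovered (default 0, with
#'   points snapped off seam lines).
#' @return list: ok (logical), open_polygons, unsealed_columns,
#'   uncovered_points (en face coordinates), coverage (fraction covered).
#' @export
barrierContinuity <- function(graph, gridN = 40L, tol = 0) {
  pg <- graph@polygons
  sm <- graph@seams
  cnt <- table(factor(sm$polygon_id, levels = pg$id))
  open <- pg$id[as.integer(cnt) < pg$n_vertices]

  unsealed <- sort(unique(pg$column_id[pg$id %in% sm$polygon_id[sm$n_share < 2L]]))

  # en face coverage on the periodic domain (offset grid avoids seam lines)
  lv <- graph@domain$latVec
  u <- (seq_len(gridN) - 0.382) / gridN
  gr <- as.matrix(expand.grid(u1 = u, u2 = u)) %*% lv
  covered <- rep(FALSE, nrow(gr))
  ok_ids <- setdiff(pg$id, open)
  testCover <- function(pts) {
    inside <- rep(FALSE, nrow(pts))
    for (id in ok_ids) {
      if (all(inside)) break
      r2 <- graph@rings[[id]][, 1:2, drop = FALSE]
      inside <- inside | .insideWrapped(pts, r2, graph@domain)
    }
    inside
  }
  covered <- testCover(gr)
  if (any(!covered)) {
    # points exactly on a seam line can fail either side's test; accept a
    # point if any tiny diagonal nudge of it is covered
    eps <- 1e-4 * sqrt(abs(det(lv)))
    for (dxy in list(c(eps, eps), c(-eps, eps), c(eps, -eps), c(-eps, -eps))) {
      miss <- which(!covered)
      if (!length(miss)) break
      covered[miss] <- testCover(sweep(gr[miss, , drop = FALSE], 2, -dxy))
    }
  }
  uncovered <- gr[!covered, , drop = FALSE]

  ok <- length(open) == 0L && length(unsealed) == 0L &&
        nrow(uncovered) <= tol * nrow(gr)
  list(ok = ok,
       open_polygons = open,
       unsealed_columns = unsealed,
       uncovered_points = uncovered,
       coverage = mean(covered))
}

#' Remove one seam from a polygon (for continuity counterexamples)
#'
#' @param graph a \linkS4class{TJGraph}.
#' @param polygonId polygon whose seam to delete.
#' @param seamIndex which of its seams (default 1).
#' @return modified TJGraph.
#' @export
dropSeam <- function(graph, polygonId, seamIndex = 1L) {
  rows <- which(graph@seams$polygon_id == polygonId)
  if (!length(rows)) stop("unknown polygon id ", polygonId)
  graph@seams <- graph@seams[-rows[seamIndex], ]
  graph
}

#' Detect double-edged (nested) polygon pairs geometrically
#'
#' A pair is double-edged when one ring lies entirely inside another in the
#' en face projection.  Detection uses geometry only (no stored labels), so
#' it can be scored against planted ground truth on synthetic meshes.  For
#' each detected pair the exterior must also be the upper and larger
#' polygon; a nested pair violating the area or Z ordering raises an error.
#'
#' @param graph a \linkS4class{TJGraph}.
#' @return data.frame: exterior, interior (polygon ids), area_ext,
#'   area_int, z_ext, z_int (um^2 / um).
#' @export
classifyDoubleEdged <- function(graph) {
  pg <- graph@polygons
  n <- nrow(pg)
  ctr <- t(vapply(graph@rings, function(P) colMeans(P[, 1:2, drop = FALSE]),
                  numeric(2)))
  out <- list()
  Li <- if (isTRUE(graph@domain$periodic)) solve(t(graph@domain$latVec)) else NULL
  # candidate exteriors: for each polygon, polygons whose centroid is close
  rad <- sqrt(max(pg$area))
  for (a in seq_len(n)) {
    A <- graph@rings[[a]][, 1:2, drop = FALSE]
    for (b in seq_len(n)) {
      if (a == b || pg$area[b] >= pg$area[a]) next
      d <- .wrapDelta(ctr[b, ] - ctr[a, ], graph@domain, Li)
      if (sqrt(sum(d^2)) > rad) next
      Bsh <- sweep(graph@rings[[b]][, 1:2, drop = FALSE], 2, (ctr[b, ] - ctr[a, ]) - d)
      if (all(mgcv::in.out(rbind(A, A[1, ]), Bsh))) {
        if (pg$z[b] >= pg$z[a])
          stop("nested pair with inverted Z ordering: polygons ",
               pg$id[a], ", ", pg$id[b])
        out[[length(out) + 1L]] <- data.frame(
          exterior = pg$id[a], interior = pg$id[b],
          area_ext = pg$area[a], area_int = pg$area[b],
          z_ext = pg$z[a], z_int = pg$z[b])
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(exterior = integer(0), interior = integer(0),
                  area_ext = numeric(0), area_int = numeric(0),
                  z_ext = numeric(0), z_int = numeric(0))
}

# minimal-image en face displacement on the periodic domain
.wrapDelta <- function(d, domain, Li = NULL) {
  if (!isTRUE(domain$periodic)) return(d)
  lv <- domain$latVec
  if (is.null(Li)) Li <- solve(t(lv))
  frac <- Li %*% d
  as.numeric(d - t(lv) %*% round(frac))
}

#' Polygons adjacent to a polygon
#'
#' Adjacency is sharing at least one seam or ring vertex (tricellular
#' corners count), computed from canonical wrapped vertex keys; in
#' addition, the nested members of a double-edged configuration are
#' adjacent to each other (the interior polygon floats below the exterior
#' without touching the surrounding seams in 3D).
#'
#' @param graph a \linkS4class{TJGraph}.
#' @param polygonId a polygon id (or vector of ids; the union of their
#'   neighbours, minus the query set, is returned).
#' @return integer vector of adjacent polygon ids.
#' @export
polygonNeighbors <- function(graph, polygonId) {
  pg <- graph@polygons
  if (!all(polygonId %in% pg$id)) stop("unknown polygon id ",
                                       polygonId[!polygonId %in% pg$id][1])
  vk <- .polygonVertexKeys(graph)
  q <- unique(unlist(vk[as.character(polygonId)]))
  hit <- vapply(vk, function(k) any(k %in% q), TRUE)
  ids <- pg$id[hit]
  # nesting adjacency: en face centroid containment either way
  ctr <- t(vapply(graph@rings, function(P) colMeans(P[, 1:2, drop = FALSE]),
                  numeric(2)))
  per <- isTRUE(graph@domain$periodic)
  lv <- graph@domain$latVec
  Li <- if (per) solve(t(lv)) else NULL
  rad2 <- max(pg$area)
  for (qid in polygonId) {
    qi <- match(qid, pg$id)
    A <- graph@rings[[qi]][, 1:2, drop = FALSE]
    d <- sweep(ctr, 2, ctr[qi, ])
    if (per) {
      frac <- d %*% t(Li)
      d <- d - round(frac) %*% lv
    }
    cand <- which(rowSums(d^2) <= rad2 & !(pg$id %in% ids) &
                  !(pg$id %in% polygonId))
    for (bi in cand) {
      Bc <- ctr[qi, ] + d[bi, ]
      B <- sweep(graph@rings[[bi]][, 1:2, drop = FALSE], 2,
                 (ctr[bi, ] - ctr[qi, ]) - d[bi, ])
      if (mgcv::in.out(rbind(A, A[1, ]), matrix(Bc, 1)) ||
          mgcv::in.out(rbind(B, B[1, ]), matrix(ctr[qi, ], 1)))
        ids <- c(ids, pg$id[bi])
    }
  }
  setdiff(ids, polygonId)
}

.polygonVertexKeys <- function(graph) {
  lv <- graph@domain$latVec
  per <- isTRUE(graph@domain$periodic)
  out <- lapply(graph@rings, function(P)
    .vertexKeys(P, lv, per, digits = 4))
  names(out) <- as.character(graph@polygons$id)
  out
}

#' Octets: isolated double-edged pairs with their six single neighbours
#'
#' Restricts to double-edged pairs whose neighbourhood is exactly six
#' single-edged polygons (pairs adjacent to another transitioning column
#' are skipped), the configuration used for relative-Z statistics.
#'
#' @param graph a \linkS4class{TJGraph}.
#' @return list of lists (exterior, interior, singles).
#' @export
tjOctets <- function(graph) {
  pg <- graph@polygons
  pr <- graph@pairs
  if (!nrow(pr)) return(list())
  # one shared-vertex incidence pass for all pairs
  vk <- .polygonVertexKeys(graph)
  inc <- data.frame(key = unlist(vk, use.names = FALSE),
                    id = rep(pg$id, lengths(vk)))
  byKey <- split(inc$id, inc$key)
  adjOf <- function(id) unique(unlist(byKey[unique(vk[[as.character(id)]])]))
  out <- list()
  for (k in seq_len(nrow(pr))) {
    nb <- setdiff(unique(c(adjOf(pr$exterior[k]), adjOf(pr$interior[k]))),
                  c(pr$exterior[k], pr$interior[k]))
    kinds <- pg$kind[match(nb, pg$id)]
    if (length(nb) == 6L && all(kinds == "single"))
      out[[length(out) + 1L]] <- list(exterior = pr$exterior[k],
                                      interior = pr$interior[k],
                                      singles = nb)
  }
  out
}
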