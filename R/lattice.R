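# The space-filling column lattice of f-TKD cells.
#
# Column centres form a triangular lattice spanned by the en face
# projections of two hexagon-contact offsets; the third projection is minus
# their sum.  Stacks interdigitate: height phase advances by one third of a
# stacking vector per (i + j) step, so the six lateral neighbours of any
# column alternate higher/lower around it.

# en face lattice basis (lattice units, unflattened xy)
.latticeBasis <- function() {
  R <- .tkdRotation()
  A <- .hexUpOffsets() %*% t(R)
  rbind(A[1, 1:2], A[2, 1:2])   # a1 -> (i+1), a2 -> (j+1)
}

# default en face scale: micrometres per lattice unit anchored so the ideal
# crystal's mean single-edged polygon area (the Voronoi tile, 16/sqrt(3))
# is the reference 905.8 um^2; refine with calibrateScale() on real output
.defaultScale <- function() sqrt(905.8 / (16 / sqrt(3)))

# height step between adjacent parity classes, and full stacking height
.zPhaseStep <- function(f) 2 / sqrt(3) * f
.stackHeight <- function(f) 2 * sqrt(3) * f

#' Build the interdigitated f-TKD column lattice
#'
#' Places f-TKD cells in the body-centred-cubic tessellation, realized as
#' vertical columns of cells (stacked via shared apical/basal hexagons) on a
#' triangular grid.  Every interior cell shares faces with 14 neighbours
#' (8 hexagons, 6 squares); every column has 6 lateral neighbour columns,
#' three holding their nearest cell higher and three lower.
#'
#' @param nx,ny column counts (>= 3 when periodic).
#' @param nLayers cell layers in the finite geometric realization (>= 2).
#' @param flattenRatio passed to \code{\link{makeCanonicalTKD}}.
#' @param periodic logical; toroidal en face boundaries (default).  The 3D
#'   structure is screw-periodic: translating by a full en face period
#'   raises the stack by (nx mod 3) height steps, so any nx, ny >= 3 tiles
#'   space, but a \emph{flat} periodic honeycomb (needed for en face
#'   statistics) additionally requires nx and ny divisible by 3.
#' @param scale micrometres per lattice unit; default anchors the crystal
#'   mean single-edged polygon area to 905.8 um^2.
#' @return a \linkS4class{ColumnLattice}.
#' @examples
#' lat <- buildLattice(6, 6)
#' nColumns(lat)
#' @export
buildLattice <- function(nx, ny, nLayers = 3L, flattenRatio = 0.25,
                         periodic = TRUE, scale = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny); nLayers <- as.integer(nLayers)
  if (periodic && (nx < 3L || ny < 3L))
    stop("periodic lattice needs nx, ny >= 3 so the 6 lateral neighbours are distinct")
  if (nx < 1L || ny < 1L) stop("nx, ny must be positive")
  if (nLayers < 2L) stop("nLayers must be >= 2")
  cell <- makeCanonicalTKD(flattenRatio)

  N <- nx * ny
  ii <- rep(0:(nx - 1L), times = ny)
  jj <- rep(0:(ny - 1L), each = nx)
  B <- .latticeBasis()
  colPos <- cbind(ii * B[1, 1] + jj * B[2, 1], ii * B[1, 2] + jj * B[2, 2])

  nbr <- matrix(NA_integer_, N, 6L)
  for (s in seq_len(6L)) {
    d <- cell@sectors[[s]]$dij
    i2 <- ii + d[1]; j2 <- jj + d[2]
    if (periodic) {
      nbr[, s] <- (j2 %% ny) * nx + (i2 %% nx) + 1L
    } else {
      ok <- i2 >= 0L & i2 < nx & j2 >= 0L & j2 < ny
      nbr[ok, s] <- j2[ok] * nx + i2[ok] + 1L
    }
  }

  new("ColumnLattice",
      nx = nx, ny = ny, nLayers = nLayers, periodic = periodic,
      cell = cell, nbr = nbr, parity = as.integer((ii + jj) %% 3L),
      colPos = colPos,
      latVec = rbind(nx * B[1, ], ny * B[2, ]),
      scale = if (is.null(scale)) .defaultScale() else scale)
}

#' @rdname ColumnLattice-class
#' @aliases nColumns,ColumnLattice-method
setMethod("nColumns", "ColumnLattice", function(x) x@nx * x@ny)

#' @rdname ColumnLattice-class
setMethod("neighborMap", "ColumnLattice", function(x) x@nbr)

#' @rdname ColumnLattice-class
setMethod("columnParity", "ColumnLattice", function(x) x@parity)

#' @rdname ColumnLattice-class
setMethod("columnPositions", "ColumnLattice", function(x) x@colPos)

setMethod("show", "ColumnLattice", function(object) {
  cat(sprintf("ColumnLattice: %d x %d columns (%s), %d layers, flatten %.3g, %.3g um/unit\n",
              object@nx, object@ny,
              if (object@periodic) "periodic" else "open",
              object@nLayers, object@cell@flattenRatio, object@scale))
})

setMethod("show", "FTKDCell", function(object) {
  cat(sprintf("FTKDCell: 24 vertices, 36 edges, 14 faces (8 hexagons, 6 squares), flatten %.3g\n",
              object@flattenRatio))
})

#' Cell centres of the finite geometric realization
#'
#' Columns are placed with unwrapped height phase (i + j) * step + layer *
#' stackHeight, which makes the realization exactly screw-periodic for any
#' lattice size.
#'
#' @param lattice a \linkS4class{ColumnLattice}.
#' @param layers integer layer indices (default all \code{nLayers}).
#' @return data.frame: column_id, layer, x, y, z (lattice units).
#' @export
cellCenters <- function(lattice, layers = seq_len(lattice@nLayers) - 1L) {
  f <- lattice@cell@flattenRatio
  ii <- rep(0:(lattice@nx - 1L), times = lattice@ny)
  jj <- rep(0:(lattice@ny - 1L), each = lattice@nx)
  phase <- (ii + jj) * .zPhaseStep(f)
  out <- NULL
  for (L in layers)
    out <- rbind(out, data.frame(
      column_id = seq_len(nColumns(lattice)), layer = L,
      x = lattice@colPos[, 1], y = lattice@colPos[, 2],
      z = phase + L * .stackHeight(f)))
  out
}

# canonical torus reduction of a point set: translate so the reference point
# (centroid) falls in the fundamental en face cell; screw-periodic z shift
.torusReduce <- function(P, lattice) {
  if (!lattice@periodic) return(P)
  f <- lattice@cell@flattenRatio
  Li <- solve(t(lattice@latVec))
  ctr <- colMeans(P[, 1:2, drop = FALSE])
  frac <- Li %*% ctr
  mn <- floor(frac + 1e-9)
  if (any(mn != 0)) {
    shift <- t(lattice@latVec) %*% mn
    P[, 1] <- P[, 1] - shift[1]
    P[, 2] <- P[, 2] - shift[2]
    P[, 3] <- P[, 3] - (mn[1] * lattice@nx + mn[2] * lattice@ny) * .zPhaseStep(f)
  }
  P
}

.faceKey <- function(P, digits = 6) {
  P <- round(P, digits)
  o <- do.call(order, as.data.frame(P))
  paste(apply(P[o, , drop = FALSE], 1, paste, collapse = ","), collapse = ";")
}

#' Count face-sharing neighbours of every cell
#'
#' Exhaustive geometric audit: every face of every placed cell is reduced to
#' a canonical representative modulo the (screw-)periodic domain and faces
#' occurring twice are contacts.  Interior cells of the space-filling
#' tessellation share all 14 faces.
#'
#' @param lattice a \linkS4class{ColumnLattice}.
#' @return data.frame: column_id, layer, n_contacts.
#' @export
countFaceNeighbors <- function(lattice) {
  cc <- cellCenters(lattice)
  cell <- lattice@cell
  keys <- vector("list", nrow(cc))
  for (r in seq_len(nrow(cc))) {
    off <- c(cc$x[r], cc$y[r], cc$z[r])
    ks <- character(14L)
    for (k in seq_len(14L)) {
      P <- sweep(cell@vertices[cell@faces[[k]], , drop = FALSE], 2, -off)
      P[, 1:2] <- P[, 1:2] + 0   # centred translation
      ks[k] <- .faceKey(.torusReduce(P, lattice))
    }
    keys[[r]] <- ks
  }
  all <- unlist(keys)
  tab <- table(all)
  n <- vapply(keys, function(ks) sum(tab[ks] == 2L), 0L)
  data.frame(column_id = cc$column_id, layer = cc$layer, n_contacts = as.integer(n))
}

#' Total en face area of the (periodic) domain
#'
#' @param lattice a \linkS4class{ColumnLattice}.
#' @param um convert to um^2 using the lattice scale (default TRUE).
#' @return scalar area.
#' @export
enFaceArea <- function(lattice, um = TRUE) {
  a <- abs(det(lattice@latVec))
  if (um) a * lattice@scale^2 else a
}
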