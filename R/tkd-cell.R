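# Construction of the flattened Kelvin tetrakaidecahedron and of the
# apical tight-junction ring templates.
#
# Canonical coordinates: all permutations of (0, +/-1, +/-2).  The stacking
# axis is the body diagonal (1,1,1)/sqrt(3); the rotation below maps it to
# +z, after which z is scaled by the flattening ratio.  Hexagonal faces lie
# on planes +/-x +/-y +/-z = 3, square faces on x_i = +/-2.

.tkdRotation <- function() {
  rbind(c(1, -1, 0) / sqrt(2),
        c(1, 1, -2) / sqrt(6),
        c(1, 1, 1) / sqrt(3))
}

# hexagonal-face offsets toward the three "upper" lateral neighbour columns
# (their cells sit one third of a stack higher); negatives are the lower ones
.hexUpOffsets <- function() rbind(c(2, 2, -2), c(2, -2, 2), c(-2, 2, 2))

.canonicalVertices <- function() {
  v <- NULL
  base <- c(0, 1, 2)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in seq_len(nrow(perms)))
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      x <- base[order(perms[p, ])]
      x[x == 1] <- s1; x[x == 2] <- 2 * s2
      v <- rbind(v, x)
    }
  unique(v)
}

# order a coplanar vertex set into a cycle around the face centroid
.orderFaceCycle <- function(idx, V, normal) {
  ctr <- colMeans(V[idx, , drop = FALSE])
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
  w <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3], n[1] * u[2] - n[2] * u[1])
  rel <- sweep(V[idx, , drop = FALSE], 2, ctr)
  ang <- atan2(rel %*% w, rel %*% u)
  idx[order(ang)]
}

.facePlanes <- function() {
  hex <- NULL
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1))
    hex <- rbind(hex, c(sx, sy, sz))
  list(normals = rbind(hex, diag(3), -diag(3)),
       rhs = c(rep(3, 8), rep(2, 6)),
       class = c(rep("hexagon", 8), rep("square", 6)))
}

.edgesFromFaces <- function(faces) {
  e <- NULL
  for (f in faces) {
    n <- length(f)
    e <- rbind(e, cbind(f, f[c(2:n, 1)]))
  }
  e <- t(apply(e, 1, sort))
  unique(e)
}

# apical edge of a face: the edge whose endpoint z-sum is maximal
.apicalEdge <- function(cycle, V) {
  n <- length(cycle)
  a <- cycle; b <- cycle[c(2:n, 1)]
  zs <- V[a, 3] + V[b, 3]
  k <- which.max(zs)
  c(a[k], b[k])
}

#' Construct the canonical (flattened) Kelvin tetrakaidecahedron
#'
#' Builds the truncated octahedron from all coordinate permutations of
#' (0, +/-1, +/-2), rotates a hexagonal-face normal onto the stacking axis
#' and scales along it by \code{flattenRatio}.  Faces are classified
#' (apical/basal hexagons, lateral-upper/lower hexagons and squares) and the
#' six lateral sectors with their apical TJ edges and 64 neighbour-
#' configuration ring templates are precomputed.
#'
#' @param flattenRatio scalar in (0, 1]; 1 is the unflattened truncated
#'   octahedron.  The default 0.25 gives the visibly flattened granular-cell
#'   profile; en face geometry is independent of this value.
#' @return an \linkS4class{FTKDCell}.
#' @examples
#' cell <- makeCanonicalTKD(1)
#' nrow(cell@vertices)   # 24
#' cellVolume(cell)      # 32
#' @export
makeCanonicalTKD <- function(flattenRatio = 0.25) {
  if (!is.numeric(flattenRatio) || length(flattenRatio) != 1L || flattenRatio <= 0)
    stop("flattenRatio must be a positive scalar")

  V0 <- .canonicalVertices()
  pl <- .facePlanes()
  R <- .tkdRotation()

  faces0 <- vector("list", 14L)
  for (k in seq_len(14L)) {
    on <- which(abs(V0 %*% pl$normals[k, ] - pl$rhs[k]) < 1e-9)
    faces0[[k]] <- .orderFaceCycle(on, V0, pl$normals[k, ])
  }

  V <- V0 %*% t(R)
  V[, 3] <- V[, 3] * flattenRatio
  normalsR <- pl$normals %*% t(R)

  # outward orientation: cycle normal must agree with the face plane normal
  faces <- faces0
  for (k in seq_len(14L)) {
    cyc <- faces[[k]]
    a <- V0[cyc[1], ]; b <- V0[cyc[2], ]; d <- V0[cyc[3], ]
    cr <- crossprod3(b - a, d - a)
    if (sum(cr * pl$normals[k, ]) < 0) faces[[k]] <- rev(cyc)
  }

  orient <- character(14L)
  for (k in seq_len(14L)) {
    nz <- normalsR[k, 3]
    if (pl$class[k] == "hexagon" && abs(abs(nz) - sqrt(sum(normalsR[k, ]^2))) < 1e-9) {
      orient[k] <- if (nz > 0) "apical" else "basal"
    } else {
      orient[k] <- if (nz > 0) "lateral-upper" else "lateral-lower"
    }
  }

  edges <- .edgesFromFaces(faces)
  storage.mode(edges) <- "integer"

  sectors <- .buildSectors(pl, faces, V)
  templates <- .buildRingTemplates(sectors, edges)

  new("FTKDCell",
      vertices = V, edges = edges, faces = faces,
      faceClass = pl$class, faceOrient = orient,
      flattenRatio = flattenRatio,
      sectors = sectors, ringTemplates = templates)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Identify, for each of the six lateral neighbour columns, the hexagonal and
# square contact faces, the apical TJ edge on each, and the boundary chains
# shared with the adjacent sectors.
.buildSectors <- function(pl, faces, V) {
  R <- .tkdRotation()
  hexUp <- .hexUpOffsets()
  # column directions: en face projections of the six hexagon offsets
  offs <- rbind(hexUp, -hexUp)
  dirs <- offs %*% t(R)            # rotated; columns 1:2 en face, 3 height
  ang <- atan2(dirs[, 2], dirs[, 1])
  ord <- order(ang)                # counter-clockwise en face

  # lattice (di, dj) offsets: +a1=(1,0), +a2=(0,1), +a3=(-1,-1)
  dij <- rbind(c(1, 0), c(0, 1), c(-1, -1), c(-1, 0), c(0, -1), c(1, 1))

  findFace <- function(normal, rhs) {
    for (k in seq_len(14L))
      if (all(abs(pl$normals[k, ] - normal) < 1e-9) && abs(pl$rhs[k] - rhs) < 1e-9)
        return(k)
    stop("internal: face not found")
  }

  sec <- vector("list", 6L)
  for (s in seq_len(6L)) {
    o <- offs[ord[s], ]
    up <- dirs[ord[s], 3] > 0      # hexagon contact is with the upper cell?
    hexFace <- findFace(o / 2, 3)
    sqOff <- if (up) o - c(2, 2, 2) else o + c(2, 2, 2)
    sqFace <- findFace(sqOff / 4, 2)
    upperFace <- if (up) hexFace else sqFace
    lowerFace <- if (up) sqFace else hexFace
    sec[[s]] <- list(
      dij = dij[ord[s], ], upParity = up,
      upperFace = upperFace, lowerFace = lowerFace,
      tjUpper = .apicalEdge(faces[[upperFace]], V),
      tjLower = .apicalEdge(faces[[lowerFace]], V),
      dir = dirs[ord[s], 1:2] / sqrt(sum(dirs[ord[s], 1:2]^2))
    )
  }

  # boundary chains between consecutive sectors: edges shared between a face
  # of sector s and a face of sector s+1, ordered apical -> basal
  edgeFaces <- function(f1, f2) intersect(faces[[f1]], faces[[f2]])
  for (s in seq_len(6L)) {
    s2 <- if (s == 6L) 1L else s + 1L
    vs <- unique(c(
      edgeFaces(sec[[s]]$upperFace, sec[[s2]]$upperFace),
      edgeFaces(sec[[s]]$upperFace, sec[[s2]]$lowerFace),
      edgeFaces(sec[[s]]$lowerFace, sec[[s2]]$upperFace),
      edgeFaces(sec[[s]]$lowerFace, sec[[s2]]$lowerFace)))
    sec[[s]]$chainNext <- vs[order(-V[vs, 3])]
  }
  sec
}

# Assemble the 64 ring templates.  Bit k of (config - 1) set means lateral
# neighbour k holds the higher of its two candidate cells, so the TJ runs
# along the apical edge of the upper contact face of sector k; otherwise
# along the apical edge of the lower face.  Consecutive TJ edges are joined
# by the unique monotone path on the shared sector-boundary chain.
.buildRingTemplates <- function(sectors, edges) {
  templates <- vector("list", 64L)
  for (cfg in 0:63) {
    bits <- bitwAnd(cfg, 2^(0:5)) > 0
    tj <- vector("list", 6L)
    for (s in seq_len(6L)) {
      e <- if (bits[s]) sectors[[s]]$tjUpper else sectors[[s]]$tjLower
      # orient: second endpoint must lie on the chain toward the next sector
      if (e[1] %in% sectors[[s]]$chainNext && !(e[2] %in% sectors[[s]]$chainNext))
        e <- rev(e)
      tj[[s]] <- e
    }
    ring <- integer(0)
    for (s in seq_len(6L)) {
      s2 <- if (s == 6L) 1L else s + 1L
      chain <- sectors[[s]]$chainNext
      a <- match(tj[[s]][2], chain)
      b <- match(tj[[s2]][1], chain)
      if (is.na(a) || is.na(b)) stop("internal: TJ edge endpoint off chain")
      between <- if (a == b) integer(0)
                 else if (a < b) chain[(a + 1):b] else chain[(a - 1):b]
      ring <- c(ring, tj[[s]], between)
    }
    ring <- ring[!duplicated(ring)]
    templates[[cfg + 1L]] <- as.integer(ring)
  }
  templates
}

#' Apical tight-junction ring for a neighbour configuration
#'
#' Returns the closed cycle of polyhedron edges along which the TJ runs,
#' given which of the six lateral neighbour columns currently hold their
#' higher candidate cell.  Toward a higher neighbour the ring follows the
#' apical edge of the upper contact face (a small, near-apical footprint);
#' toward a lower neighbour it follows the apical edge of the lower contact
#' face (the widest extent).  With all six neighbours lower the ring is the
#' cell's maximal cross-section circuit; with all six higher it is the
#' apical hexagon.
#'
#' @param cell an \linkS4class{FTKDCell}.
#' @param higher logical vector of length 6 (sector order, counter-clockwise
#'   en face): is the neighbour's SG2 cell higher than this cell?
#' @return matrix of ring vertex coordinates (cycle order, not closed).
#' @export
apicalTJRing <- function(cell, higher) {
  if (!is(cell, "FTKDCell")) stop("cell must be an FTKDCell")
  if (length(cell@sectors) != 6L) stop("cell has unclassified faces/sectors")
  higher <- as.logical(higher)
  if (length(higher) != 6L || anyNA(higher))
    stop("higher must be 6 logical values")
  idx <- .ringTemplateIndex(higher)
  cell@vertices[cell@ringTemplates[[idx]], , drop = FALSE]
}

.ringTemplateIndex <- function(higher) 1L + sum(2^(0:5) * higher)

#' Volume of an f-TKD cell
#'
#' Computed by the divergence theorem over the outward-oriented faces.  The
#' canonical cell (\code{flattenRatio = 1}) has volume 32 (half the volume
#' of the side-4 generating cube); flattening scales volume linearly.
#'
#' @param cell an \linkS4class{FTKDCell}.
#' @return scalar volume in lattice units cubed.
#' @export
cellVolume <- function(cell) {
  V <- cell@vertices
  vol <- 0
  for (cyc in cell@faces) {
    ctr <- colMeans(V[cyc, , drop = FALSE])
    n <- length(cyc)
    for (k in seq_len(n)) {
      a <- V[cyc[k], ]; b <- V[cyc[if (k == n) 1L else k + 1L], ]
      vol <- vol + det(rbind(ctr, a, b)) / 6
    }
  }
  abs(vol)
}

# en face (shoelace) area and mean z of a ring template, in lattice units
.templateStats <- function(cell) {
  n <- length(cell@ringTemplates)
  area <- numeric(n); zbar <- numeric(n)
  for (k in seq_len(n)) {
    P <- cell@vertices[cell@ringTemplates[[k]], , drop = FALSE]
    area[k] <- abs(pracma::polyarea(P[, 1], P[, 2]))
    zbar[k] <- mean(P[, 3])
  }
  list(area = area, z = zbar)
}
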