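# Synthetic microscopy-like honeycombs with planted ground truth.
#
# The generator emulates the data structure of en face whole-mount TJ
# images: a honeycomb mesh of polygon outlines with 3D vertex positions,
# a configurable share of double-edged (exterior/interior) polygon pairs,
# and Gaussian localization noise on vertices.  It does not synthesize
# pixel images; meshes are the measurement substrate.

#' Configuration for the synthetic honeycomb generator
#'
#' @param targetSingleArea target mean single-edged polygon area (um^2);
#'   default 905.8, the reference in vivo mean.
#' @param plantRate double-edged planting rate, percent of all polygons
#'   (pairs counted once); default 9.8.
#' @param jitterXY en face vertex jitter SD (um); default 0.
#' @param jitterZ Z vertex jitter SD (um); default 0.
#' @param zOffset named additional Z offsets (um) applied per polygon class
#'   (exterior, interior, single); default all 0 (the lattice geometry
#'   already separates the classes in Z).
#' @param nx,ny lattice size (multiples of 3); default 12 x 12.
#' @param seed integer seed.
#' @return validated list of class \code{ftkd_synth_config}.
#' @export
synthConfig <- function(targetSingleArea = 905.8, plantRate = 9.8,
                        jitterXY = 0, jitterZ = 0,
                        zOffset = c(exterior = 0, interior = 0, single = 0),
                        nx = 12L, ny = 12L, seed = 1L) {
  if (plantRate < 0 || plantRate > 100) stop("plantRate must be in [0, 100]")
  if (jitterXY < 0 || jitterZ < 0) stop("jitter SDs must be >= 0")
  if (targetSingleArea <= 0) stop("targetSingleArea must be positive")
  structure(list(targetSingleArea = targetSingleArea, plantRate = plantRate,
                 jitterXY = jitterXY, jitterZ = jitterZ, zOffset = zOffset,
                 nx = as.integer(nx), ny = as.integer(ny),
                 seed = as.integer(seed)),
            class = "ftkd_synth_config")
}

#' Generate a noisy honeycomb with planted double-edged pairs
#'
#' Starts from the ideal crystal honeycomb, converts the requested share of
#' columns to the double-edged configuration, calibrates the micrometre
#' scale so the single-edged mean area hits the target exactly (before
#' noise), then jitters every unique mesh vertex (shared vertices stay
#' shared, as they are one physical point).  Planting draws only from the
#' geometrically highest parity class, whose columns are never mutually
#' adjacent, so planted pairs are automatically isolated; rates above the
#' class share (one third) are rejected.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list: graph (a \linkS4class{TJGraph}), truth (data.frame
#'   polygon_id, column_id, kind), plantedColumns, realizedRate (percent).
#' @export
makeNoisyHoneycomb <- function(config = synthConfig()) {
  if (!inherits(config, "ftkd_synth_config")) stop("config must come from synthConfig()")
  set.seed(config$seed)
  lat <- buildLattice(config$nx, config$ny)
  N <- nColumns(lat)
  k <- round(config$plantRate / 100 * N)
  topClass <- which(lat@parity == 2L)
  if (k > length(topClass))
    stop("plantRate ", config$plantRate,
         "% too high: cannot plant more than one pair per three columns ",
         "while keeping pairs non-adjacent")

  st <- list(entry = -(lat@parity * 8) - drawWait(N, 4),
             phase = rep(.PHASE_STEADY, N),
             count = rep(0L, N), incoming = rep(NA_real_, N),
             deadline = rep(Inf, N))
  st$topEntry <- st$entry
  planted <- sort(sample(topClass, k))
  st$phase[planted] <- .PHASE_TRANSITION
  st$incoming[planted] <- 0

  hc <- .extractFromState(st, lat)
  sc <- calibrateScale(hc, config$targetSingleArea)
  hc <- .extractFromState(st, lat, scale = sc)

  # per-class Z offsets, then shared-vertex Gaussian jitter
  pg <- hc@polygons
  zoff <- config$zOffset[pg$kind]
  zoff[is.na(zoff)] <- 0
  for (i in seq_len(nrow(pg)))
    hc@rings[[i]][, 3] <- hc@rings[[i]][, 3] + zoff[i]
  if (config$jitterXY > 0 || config$jitterZ > 0)
    hc <- .jitterGraph(hc, config$jitterXY, config$jitterZ)
  hc <- .refreshGeometry(hc)

  list(graph = hc,
       truth = hc@polygons[, c("id", "column_id", "kind")],
       plantedColumns = planted,
       realizedRate = 100 * k / N)
}

# jitter unique mesh vertices; vertices shared between rings move together
.jitterGraph <- function(graph, sdXY, sdZ) {
  keys <- .polygonVertexKeys(graph)
  uk <- unique(unlist(keys))
  dx <- stats::rnorm(length(uk), 0, sdXY)
  dy <- stats::rnorm(length(uk), 0, sdXY)
  dz <- stats::rnorm(length(uk), 0, sdZ)
  names(dx) <- names(dy) <- names(dz) <- uk
  for (i in seq_along(graph@rings)) {
    kk <- keys[[i]]
    graph@rings[[i]][, 1] <- graph@rings[[i]][, 1] + dx[kk]
    graph@rings[[i]][, 2] <- graph@rings[[i]][, 2] + dy[kk]
    graph@rings[[i]][, 3] <- graph@rings[[i]][, 3] + dz[kk]
  }
  graph
}

# recompute polygon areas/Z and seam endpoint coordinates from rings
.refreshGeometry <- function(graph) {
  pg <- graph@polygons
  for (i in seq_len(nrow(pg))) {
    P <- graph@rings[[i]]
    pg$area[i] <- .shoelace(P)
    pg$z[i] <- mean(P[, 3])
    rows <- which(graph@seams$polygon_id == pg$id[i])
    n <- nrow(P); nx2 <- c(2:n, 1L)
    graph@seams[rows, c("x1", "y1", "z1")] <- P
    graph@seams[rows, c("x2", "y2", "z2")] <- P[nx2, ]
  }
  graph@polygons <- pg
  graph
}

#' Deterministic test fixtures
#'
#' \describe{
#'   \item{star7}{a 5 x 5 open lattice whose centre column is the locally
#'     highest/oldest of its 7-column star, ready to turn over.}
#'   \item{column_pair}{a 3 x 3 periodic lattice with exactly one column
#'     mid-transition (one exterior/interior pair).}
#'   \item{hexprism_strawman}{the hexagonal-prism comparison model: a flat
#'     honeycomb of identical hexagonal prisms in which one column has slid
#'     upward, tearing its TJ seams from the neighbours; returned both slid
#'     and aligned.}
#' }
#'
#' @param kind fixture name.
#' @param slide upward slide of the strawman column (um); default 2.
#' @return a list; see details per kind.
#' @export
makeFixture <- function(kind = c("star7", "column_pair", "hexprism_strawman"),
                        slide = 2) {
  kind <- match.arg(kind)
  if (kind == "star7") {
    lat <- buildLattice(5, 5, periodic = FALSE)
    N <- nColumns(lat)
    center <- 13L                     # (i, j) = (2, 2)
    count <- rep(0L, N)
    count[lat@nbr[center, ][lat@parity[lat@nbr[center, ]] == 2L]] <- 1L
    h <- lat@parity - 3L * count
    entry <- -8 * h - 0.01 * seq_len(N)
    st <- list(entry = entry, topEntry = entry,
               phase = rep(.PHASE_STEADY, N), deadline = rep(Inf, N),
               incoming = rep(NA_real_, N), count = count)
    return(list(kind = kind, lattice = lat, state = st, center = center))
  }
  if (kind == "column_pair") {
    lat <- buildLattice(3, 3)
    N <- 9L
    column <- 3L                      # (i, j) = (2, 0), parity 2
    entry <- -(lat@parity * 8) - 0.01 * seq_len(N)
    st <- list(entry = entry, topEntry = entry,
               phase = rep(.PHASE_STEADY, N), deadline = rep(Inf, N),
               incoming = rep(NA_real_, N), count = rep(0L, N))
    st$phase[column] <- .PHASE_TRANSITION
    st$incoming[column] <- 0
    st$entry[column] <- 0
    st$deadline[column] <- 2.4
    return(list(kind = kind, lattice = lat, state = st, column = column,
                graph = .extractFromState(st, lat)))
  }
  # hexprism_strawman
  lat <- buildLattice(6, 6)
  sc <- lat@scale
  N <- nColumns(lat)
  B <- lat@latVec * sc
  ctr <- lat@colPos * sc
  rad <- sqrt(sum((lat@latVec[1, ] / lat@nx)^2)) * sc / sqrt(3)
  hexAt <- function(cx, cy, z) {
    a <- (0:5) * pi / 3
    cbind(cx + rad * cos(a), cy + rad * sin(a), z)
  }
  buildGraph <- function(zcol) {
    ringsL <- vector("list", N); polys <- list(); seamsL <- list()
    for (c0 in seq_len(N)) {
      P <- hexAt(ctr[c0, 1], ctr[c0, 2], zcol[c0])
      ringsL[[c0]] <- P
      polys[[c0]] <- data.frame(id = c0, column_id = c0, kind = "single",
                                area = .shoelace(P), z = mean(P[, 3]),
                                n_vertices = 6L, n_ttj_vertices = 0L)
      n <- 6L; nx2 <- c(2:n, 1L)
      keys <- .edgeKeysRaw(P, B)
      seamsL[[c0]] <- data.frame(polygon_id = c0, key = keys,
                                 x1 = P[, 1], y1 = P[, 2], z1 = P[, 3],
                                 x2 = P[nx2, 1], y2 = P[nx2, 2], z2 = P[nx2, 3],
                                 n_share = NA_integer_, class = "bTJ")
    }
    sm <- do.call(rbind, seamsL)
    tab <- table(sm$key)
    sm$n_share <- as.integer(tab[sm$key])
    new("TJGraph", polygons = do.call(rbind, polys), rings = ringsL,
        seams = sm,
        pairs = data.frame(column_id = integer(0), exterior = integer(0),
                           interior = integer(0)),
        domain = list(periodic = TRUE, latVec = B), scale = sc,
        time = NA_real_)
  }
  column <- 8L
  z0 <- rep(0, N)
  zS <- z0; zS[column] <- slide
  list(kind = kind, graph = buildGraph(zS), aligned = buildGraph(z0),
       column = column)
}

# seam keys for externally built rings (canonical wrapped, rounded)
.edgeKeysRaw <- function(P, latVec, digits = 4) {
  n <- nrow(P); nx2 <- c(2:n, 1L)
  keys <- character(n)
  for (k in seq_len(n)) {
    E <- P[c(k, nx2[k]), , drop = FALSE]
    E <- .reduceBy(E, colMeans(E[, 1:2, drop = FALSE]), latVec)
    E <- round(E, digits)
    o <- order(E[, 1], E[, 2], E[, 3])
    keys[k] <- paste(t(E[o, ]), collapse = ",")
  }
  keys
}
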