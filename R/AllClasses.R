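#' @import methods
NULL

#' A flattened Kelvin tetrakaidecahedron (f-TKD) cell
#'
#' The truncated octahedron built from all coordinate permutations of
#' (0, +/-1, +/-2), rotated so that one hexagonal-face normal (a body
#' diagonal of the generating cube) points along the stacking axis (z), and
#' anisotropically scaled along z by \code{flattenRatio}.  The combinatorial
#' structure (24 vertices, 36 edges, 14 faces: 8 hexagons + 6 squares) is
#' independent of the flattening.
#'
#' Beyond the bare polyhedron the object carries the lateral \emph{sector}
#' decomposition used by the turnover model: each of the six lateral
#' neighbour columns touches the cell through one hexagonal and one square
#' face (one above, one below), and the tight-junction ring toward a
#' neighbour runs along the apical edge of whichever face contacts that
#' neighbour's SG2 cell.  Precomputed ring templates for all 64
#' higher/lower neighbour configurations make honeycomb extraction a table
#' lookup.
#'
#' @slot vertices 24 x 3 numeric matrix, lattice units (z flattened).
#' @slot edges 36 x 2 integer matrix of vertex indices.
#' @slot faces list of integer vertex cycles, outward-oriented.
#' @slot faceClass character, \code{"hexagon"} or \code{"square"}.
#' @slot faceOrient character: \code{"apical"}, \code{"basal"},
#'   \code{"lateral-upper"} or \code{"lateral-lower"}.
#' @slot flattenRatio scalar in (0, 1].
#' @slot sectors list describing the six lateral sectors (column offsets,
#'   parity, upper/lower contact faces, boundary chains, apical TJ edges).
#' @slot ringTemplates list of 64 integer vertex cycles indexed by the
#'   neighbour higher/lower bit pattern.
#' @export
setClass("FTKDCell",
  representation(
    vertices      = "matrix",
    edges         = "matrix",
    faces         = "list",
    faceClass     = "character",
    faceOrient    = "character",
    flattenRatio  = "numeric",
    sectors       = "list",
    ringTemplates = "list"
  )
)

setValidity("FTKDCell", function(object) {
  msg <- character(0)
  if (nrow(object@vertices) != 24L) msg <- c(msg, "expected 24 vertices")
  if (nrow(object@edges) != 36L)    msg <- c(msg, "expected 36 edges")
  if (length(object@faces) != 14L)  msg <- c(msg, "expected 14 faces")
  if (sum(object@faceClass == "hexagon") != 8L ||
      sum(object@faceClass == "square") != 6L)
    msg <- c(msg, "expected 8 hexagonal and 6 square faces")
  v <- nrow(object@vertices); e <- nrow(object@edges); f <- length(object@faces)
  if (v - e + f != 2L) msg <- c(msg, "Euler characteristic V - E + F != 2")
  if (length(object@flattenRatio) != 1L || object@flattenRatio <= 0)
    msg <- c(msg, "flattenRatio must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' A periodic triangular lattice of f-TKD cell columns
#'
#' Columns are indexed on a triangular grid (i, j); each column is an
#' infinite stack of f-TKD cells sharing apical/basal hexagons, and has six
#' lateral neighbour columns.  Columns fall into three height-parity classes
#' ((i + j) mod 3): the cell stack of a class-(p+1) column sits one third of
#' a stacking vector above a class-p column, so every column has three
#' lateral neighbours whose nearest cell is higher and three whose nearest
#' cell is lower -- the interdigitated packing.
#'
#' @slot nx,ny integer column counts.
#' @slot nLayers layers kept in the finite geometric realization (the
#'   turnover state itself treats each column as an unbounded stack).
#' @slot periodic logical; periodic (toroidal) boundaries.
#' @slot cell the shared \linkS4class{FTKDCell} geometry.
#' @slot nbr N x 6 integer matrix of lateral neighbour column ids (NA on the
#'   boundary of a non-periodic lattice), columns ordered as the cell's
#'   sectors (counter-clockwise en face).
#' @slot parity integer vector, height-parity class (0, 1, 2) per column.
#' @slot colPos N x 2 matrix of en face column positions (lattice units).
#' @slot latVec 2 x 2 matrix; rows are the en face torus period vectors.
#' @slot scale micrometres per lattice unit (en face).
#' @export
setClass("ColumnLattice",
  representation(
    nx = "integer", ny = "integer", nLayers = "integer",
    periodic = "logical",
    cell = "FTKDCell",
    nbr = "matrix", parity = "integer",
    colPos = "matrix", latVec = "matrix",
    scale = "numeric"
  )
)

setValidity("ColumnLattice", function(object) {
  msg <- character(0)
  N <- object@nx * object@ny
  if (nrow(object@nbr) != N || ncol(object@nbr) != 6L)
    msg <- c(msg, "neighbour map must be N x 6")
  if (object@periodic && anyNA(object@nbr))
    msg <- c(msg, "periodic lattice must have 6 neighbours everywhere")
  if (object@periodic && (object@nx < 3L || object@ny < 3L))
    msg <- c(msg, "periodic lattice needs nx, ny >= 3 for 6 distinct neighbours")
  if (length(object@scale) != 1L || object@scale <= 0)
    msg <- c(msg, "scale must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the stochastic SG2-layer turnover model.  Times are hours
#' except \code{dtMinutes}.  Defaults are the model's nominal calibration:
#' waiting time uniform on [0, 9.6] hr, TJ disappearance 2.4 hr
#' (= 24 hr x 9.8/100), frame interval 7.2 min.
#'
#' @slot waitMax upper bound of the uniform waiting time (hr).
#' @slot disappearance TJ disappearance duration of phase 1 (hr).
#' @slot dtMinutes frame interval (minutes).
#' @slot turnoverTarget nominal turnover time used for calibration
#'   reporting only (hr).
#' @slot burnIn discarded initial interval (hr).
#' @slot duration measured interval after burn-in (hr).
#' @slot seed integer RNG seed.
#' @slot nx,ny lattice dimensions (columns).
#' @slot periodic logical.
#' @slot flattenRatio cell flattening.
#' @slot init \code{"crystal"} (height-ordered by parity class; default) or
#'   \code{"iid"} (independent entry times; breaks the interdigitated height
#'   ordering and relaxes to a slower disordered regime).
#' @slot snapshotEvery interval between stored full state snapshots (hr).
#' @export
setClass("SimConfig",
  representation(
    waitMax = "numeric", disappearance = "numeric", dtMinutes = "numeric",
    turnoverTarget = "numeric", burnIn = "numeric", duration = "numeric",
    seed = "integer", nx = "integer", ny = "integer", periodic = "logical",
    flattenRatio = "numeric", init = "character", snapshotEvery = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  for (s in c("waitMax", "disappearance", "dtMinutes", "duration"))
    if (slot(object, s) < 0 || (s != "waitMax" && slot(object, s) <= 0))
      msg <- c(msg, paste(s, "must be positive"))
  if (object@dtMinutes / 60 > object@disappearance)
    msg <- c(msg, "dt must not exceed the disappearance duration")
  if (object@nx < 3L || object@ny < 3L)
    msg <- c(msg, "lattice needs nx, ny >= 3")
  if (!object@init %in% c("crystal", "iid"))
    msg <- c(msg, "init must be 'crystal' or 'iid'")
  if (length(msg)) msg else TRUE
})

#' A simulated turnover trajectory
#'
#' @slot config the \linkS4class{SimConfig} used.
#' @slot lattice the \linkS4class{ColumnLattice}.
#' @slot events data.frame (time_hr, column_id, event) with event one of
#'   \code{wait_start}, \code{transition_start}, \code{transition_end}.
#' @slot states list of full state snapshots (see \code{\link{snapshotAt}});
#'   each holds time, phase, entry, topEntry, count, incoming.
#' @slot fracSeries data.frame (time_hr, n_transition) per frame.
#' @export
setClass("TurnoverSim",
  representation(
    config = "SimConfig", lattice = "ColumnLattice",
    events = "data.frame", states = "list", fracSeries = "data.frame"
  )
)

#' The en face tight-junction honeycomb graph
#'
#' Closed TJ polygons (one per steady column; an exterior/interior pair per
#' transitioning column) with their seams classified as bicellular (bTJ,
#' shared by two SG2 cells) or tricellular (tTJ, shared by three).
#' Tricellular contact points at the vertices of single-edged polygons are
#' recorded in \code{polygons} metadata but are not seams.
#'
#' @slot polygons data.frame: id, column_id, kind
#'   (single/exterior/interior), area (en face, um^2), z (mean vertex Z,
#'   um), n_vertices.
#' @slot rings list of 3D coordinate matrices (um), parallel to
#'   \code{polygons}; rows are ring vertices in order, not closed.
#' @slot seams data.frame: seam endpoints (um), class (bTJ/tTJ), n_share
#'   (number of SG2 cells sharing the edge), polygon_id.
#' @slot pairs data.frame pairing exterior and interior polygon ids per
#'   transitioning column.
#' @slot domain list: periodic flag and en face period vectors (um).
#' @slot scale micrometres per lattice unit used at extraction.
#' @slot time snapshot time (hr), NA for synthetic meshes.
#' @export
setClass("TJGraph",
  representation(
    polygons = "data.frame", rings = "list", seams = "data.frame",
    pairs = "data.frame", domain = "list", scale = "numeric", time = "numeric"
  )
)

setValidity("TJGraph", function(object) {
  msg <- character(0)
  if (length(object@rings) != nrow(object@polygons))
    msg <- c(msg, "rings and polygons out of step")
  if (!all(object@polygons$kind %in% c("single", "exterior", "interior")))
    msg <- c(msg, "unknown polygon kind")
  if (nrow(object@pairs)) {
    k <- object@polygons$kind[match(object@pairs$exterior, object@polygons$id)]
    if (!all(k == "exterior")) msg <- c(msg, "pairs$exterior must be exterior polygons")
  }
  if (length(msg)) msg else TRUE
})
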