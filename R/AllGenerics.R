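#' @rdname ColumnLattice-class
#' @param x a ColumnLattice (or object containing one).
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname ColumnLattice-class
#' @export
setGeneric("neighborMap", function(x) standardGeneric("neighborMap"))

#' @rdname ColumnLattice-class
#' @export
setGeneric("columnParity", function(x) standardGeneric("columnParity"))

#' @rdname ColumnLattice-class
#' @export
setGeneric("columnPositions", function(x) standardGeneric("columnPositions"))

#' @rdname TJGraph-class
#' @param x a TJGraph.
#' @export
setGeneric("polygons", function(x) standardGeneric("polygons"))

#' @rdname TJGraph-class
#' @export
setGeneric("seams", function(x) standardGeneric("seams"))

#' @rdname TJGraph-class
#' @export
setGeneric("rings", function(x) standardGeneric("rings"))

#' @rdname TJGraph-class
#' @export
setGeneric("doubleEdgedPairs", function(x) standardGeneric("doubleEdgedPairs"))

#' @rdname TurnoverSim-class
#' @param x a TurnoverSim.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname TurnoverSim-class
#' @export
setGeneric("snapshotTimes", function(x) standardGeneric("snapshotTimes"))
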