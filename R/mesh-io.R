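# ASCII mesh export/import: OFF and PLY for cells and honeycomb rings.

#' Write f-TKD cells as an ASCII OFF mesh
#'
#' One merged mesh; a comment block lists, for every face, the owning cell
#' and its face class/orientation.
#'
#' @param lattice a \linkS4class{ColumnLattice} (all cells of its finite
#'   realization), or an \linkS4class{FTKDCell} (a single cell at the
#'   origin).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeOFF <- function(lattice, file) {
  m <- .asMesh(lattice)
  con <- file(file, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("# %s", m$comments), con)
  writeLines(sprintf("%d %d 0", nrow(m$vertices), length(m$faces)), con)
  writeLines(apply(format(m$vertices, digits = 10, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(vapply(m$faces, function(f)
    paste(c(length(f), f - 1L), collapse = " "), ""), con)
  invisible(file)
}

#' Write f-TKD cells as an ASCII PLY mesh
#'
#' Face classes are stored in an integer face property \code{face_class}
#' (0 apical, 1 basal, 2 lateral-upper, 3 lateral-lower).
#'
#' @inheritParams writeOFF
#' @return the file path, invisibly.
#' @export
writePLY <- function(lattice, file) {
  m <- .asMesh(lattice)
  cls <- match(m$faceOrient,
               c("apical", "basal", "lateral-upper", "lateral-lower")) - 1L
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment", m$comments[1]),
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", length(m$faces)),
               "property list uchar int vertex_indices",
               "property int face_class",
               "end_header"), con)
  writeLines(apply(format(m$vertices, digits = 10, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(vapply(seq_along(m$faces), function(k)
    paste(c(length(m$faces[[k]]), m$faces[[k]] - 1L, cls[k]), collapse = " "), ""), con)
  invisible(file)
}

.asMesh <- function(x) {
  if (is(x, "FTKDCell")) {
    return(list(vertices = x@vertices, faces = x@faces,
                faceOrient = x@faceOrient,
                comments = c("single f-TKD cell",
                             paste("face", seq_along(x@faces), x@faceClass,
                                   x@faceOrient))))
  }
  if (is(x, "ColumnLattice")) {
    cc <- cellCenters(x)
    cell <- x@cell
    nV <- nrow(cell@vertices)
    verts <- NULL; faces <- list(); orient <- character(0); cm <- character(0)
    for (r in seq_len(nrow(cc))) {
      off <- c(cc$x[r], cc$y[r], cc$z[r])
      verts <- rbind(verts, sweep(cell@vertices, 2, -off))
      base <- (r - 1L) * nV
      for (k in seq_along(cell@faces)) {
        faces[[length(faces) + 1L]] <- cell@faces[[k]] + base
        orient <- c(orient, cell@faceOrient[k])
        cm <- c(cm, paste("face", length(faces), "cell", cc$column_id[r],
                          "layer", cc$layer[r], cell@faceClass[k],
                          cell@faceOrient[k]))
      }
    }
    return(list(vertices = verts, faces = faces, faceOrient = orient,
                comments = c(sprintf("%d f-TKD cells", nrow(cc)), cm)))
  }
  if (is(x, "TJGraph")) {
    verts <- NULL; faces <- list(); cm <- character(0)
    for (i in seq_along(x@rings)) {
      P <- x@rings[[i]]
      faces[[i]] <- nrow(verts %||% matrix(0, 0, 3)) + seq_len(nrow(P))
      verts <- rbind(verts, P)
      cm <- c(cm, paste("ring", x@polygons$id[i], x@polygons$kind[i],
                        "column", x@polygons$column_id[i]))
    }
    return(list(vertices = verts, faces = faces,
                faceOrient = rep("apical", length(faces)),
                comments = c("TJ honeycomb rings", cm)))
  }
  stop("cannot export objects of class ", class(x)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ASCII OFF mesh
#'
#' @param file path to an OFF file.
#' @return list(vertices, faces) with 1-based face indices.
#' @export
readOFF <- function(file) {
  ln <- readLines(file)
  ln <- ln[!grepl("^#", ln)]
  if (trimws(ln[1]) != "OFF") stop("not an OFF file")
  hd <- scan(text = ln[2], quiet = TRUE)
  nv <- hd[1]; nf <- hd[2]
  verts <- do.call(rbind, lapply(ln[3:(2 + nv)],
                                 function(s) scan(text = s, quiet = TRUE)))
  faces <- lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    v <- scan(text = s, quiet = TRUE)
    as.integer(v[-1] + 1)
  })
  list(vertices = verts, faces = faces)
}
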