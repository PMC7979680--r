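# Minimal VTK legacy ASCII I/O: unstructured grids of hexahedra (cell type
# 12) with part_id / quality as cell data, and polydata polylines for fiber
# tracts.  Only the ASCII dialect is supported.

#' Write a hexahedral mesh as VTK legacy unstructured grid (ASCII)
#'
#' Cell data carry \code{part_id} and, optionally, the per-element scaled
#' Jacobian.
#'
#' @param mesh a [HexMesh-class].
#' @param path output file path (.vtk).
#' @param quality optional numeric vector of per-element quality values.
#' @export
writeVtkMesh <- function(mesh, path, quality = NULL) {
  nodes <- meshNodes(mesh)
  el <- meshElements(mesh) - 1L      # VTK is 0-based
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  write(t(nodes), con, ncolumns = 3L)
  m <- nrow(el)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  write(t(cbind(8L, el)), con, ncolumns = 9L)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  write(rep(12L, m), con, ncolumns = 1L)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS part_id int 1", "LOOKUP_TABLE default"), con)
  write(partId(mesh), con, ncolumns = 1L)
  if (!is.null(quality)) {
    writeLines(c("SCALARS scaled_jacobian double 1",
                 "LOOKUP_TABLE default"), con)
    write(quality, con, ncolumns = 1L)
  }
  invisible(path)
}

#' Read a hexahedral mesh from VTK legacy unstructured grid (ASCII)
#'
#' @param path input file path.
#' @return a [HexMesh-class]; a \code{scaled_jacobian} cell array, if
#'   present, is attached as attribute \code{"quality"}.
#' @export
readVtkMesh <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  findKw <- function(kw) grep(paste0("^", kw, "\\b"), lines)[1]
  if (!grepl("ASCII", lines[3], fixed = TRUE))
    stop("only ASCII VTK legacy files are supported")
  iPts <- findKw("POINTS")
  nPts <- as.integer(toks(lines[iPts])[2])
  numsFrom <- function(i0, count) {
    vals <- numeric(0); i <- i0
    while (length(vals) < count) {
      vals <- c(vals, as.numeric(toks(lines[i]))); i <- i + 1L
    }
    list(vals = vals[seq_len(count)], nextLine = i)
  }
  pts <- numsFrom(iPts + 1L, 3L * nPts)
  nodes <- matrix(pts$vals, ncol = 3L, byrow = TRUE)
  iCells <- findKw("CELLS")
  hdr <- toks(lines[iCells])
  nCells <- as.integer(hdr[2]); total <- as.integer(hdr[3])
  cl <- numsFrom(iCells + 1L, total)
  iTypes <- findKw("CELL_TYPES")
  ct <- numsFrom(iTypes + 1L, nCells)$vals
  # walk the flat connectivity list, keep hexahedra
  el <- matrix(0L, sum(ct == 12), 8L)
  pos <- 1L; row <- 0L
  for (c0 in seq_len(nCells)) {
    n <- cl$vals[pos]
    if (ct[c0] == 12) {
      if (n != 8L) stop("hexahedron cell with ", n, " points")
      row <- row + 1L
      el[row, ] <- as.integer(cl$vals[(pos + 1L):(pos + 8L)]) + 1L
    }
    pos <- pos + n + 1L
  }
  pid <- rep(1L, nrow(el)); qual <- NULL
  iCD <- findKw("CELL_DATA")
  if (!is.na(iCD)) {
    i <- iCD + 1L
    while (i <= length(lines)) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- toks(lines[i])[2]
        res <- numsFrom(i + 2L, nCells)   # skip LOOKUP_TABLE line
        if (nm == "part_id") pid <- as.integer(res$vals[ct == 12])
        if (nm == "scaled_jacobian") qual <- res$vals[ct == 12]
        i <- res$nextLine
      } else i <- i + 1L
    }
  }
  mesh <- hexMesh(nodes, el, pid)
  if (!is.null(qual)) attr(mesh, "quality") <- qual
  mesh
}

#' Write fiber tracts as VTK polydata polylines (ASCII)
#'
#' Point data carry the per-line mean FA replicated to the line's points.
#'
#' @param fibers a [FiberSet-class].
#' @param path output file path (.vtk).
#' @export
writeVtkPolylines <- function(fibers, path) {
  lines <- fibers@lines
  np <- vapply(lines, nrow, integer(1))
  pts <- do.call(rbind, lines)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fiber tracts", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", sum(np))), con)
  if (sum(np)) write(t(pts), con, ncolumns = 3L)
  writeLines(sprintf("LINES %d %d", length(lines), length(lines) + sum(np)),
             con)
  off <- 0L
  for (li in seq_along(lines)) {
    writeLines(paste(c(np[li], off:(off + np[li] - 1L)), collapse = " "), con)
    off <- off + np[li]
  }
  writeLines(c(sprintf("POINT_DATA %d", sum(np)),
               "SCALARS mean_fa double 1", "LOOKUP_TABLE default"), con)
  if (sum(np)) write(rep(fibers@meanFa, np), con, ncolumns = 1L)
  invisible(path)
}
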