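#' Read a CARP-style text mesh
#'
#' Reads the `.pts` / `.elem` (and optional `.lon`) plain-text dialect:
#' `.pts` has the vertex count on line 1 followed by `x y z` per line (mm);
#' `.elem` has the element count followed by `Tr v0 v1 v2 tag` (triangles)
#' or `Tt v0 v1 v2 v3 tag` (tetrahedra) with 0-based vertex indices;
#' `.lon` starts with the number of direction vectors per element (1 or 3)
#' followed by 3 or 9 numbers per element (fibre, or fibre + sheet +
#' sheet-normal). Indices are converted to the package's 1-based convention
#' on read.
#'
#' @param base path base: `base.pts`, `base.elem`, and optionally
#'   `base.lon` are read
#' @return a `dfe_mesh`
#' @export
read_carp_mesh <- function(base) {
  pts_file <- paste0(base, ".pts")
  elem_file <- paste0(base, ".elem")
  lon_file <- paste0(base, ".lon")
  if (!file.exists(pts_file)) stop("missing file: ", pts_file)
  if (!file.exists(elem_file)) stop("missing file: ", elem_file)

  pts_lines <- readLines(pts_file)
  np <- suppressWarnings(as.integer(trimws(pts_lines[1])))
  if (is.na(np)) stop(pts_file, ": line 1 is not a vertex count")
  if (length(pts_lines) < np + 1L)
    stop(pts_file, ": header announces ", np, " vertices but only ",
         length(pts_lines) - 1L, " coordinate lines follow (line ",
         length(pts_lines) + 1L, ")")
  coords <- utils::read.table(text = pts_lines[2:(np + 1L)],
                              col.names = c("x", "y", "z"),
                              colClasses = "numeric")
  vertices <- as.matrix(coords)

  el_lines <- readLines(elem_file)
  ne <- suppressWarnings(as.integer(trimws(el_lines[1])))
  if (is.na(ne)) stop(elem_file, ": line 1 is not an element count")
  if (length(el_lines) < ne + 1L)
    stop(elem_file, ": header announces ", ne, " elements but only ",
         length(el_lines) - 1L, " lines follow")
  toks <- strsplit(trimws(el_lines[2:(ne + 1L)]), "[[:space:]]+")
  types <- vapply(toks, `[[`, "", 1L)
  if (all(types == "Tr")) {
    k <- 3L
  } else if (all(types == "Tt")) {
    k <- 4L
  } else {
    bad <- which(!types %in% types[1])[1]
    stop(elem_file, ": mixed or unsupported element types (line ", bad + 1L,
         ": '", types[bad], "')")
  }
  lens <- lengths(toks)
  if (any(lens != k + 2L))
    stop(elem_file, ": malformed element line ",
         which(lens != k + 2L)[1] + 1L)
  num <- matrix(as.integer(unlist(lapply(toks, `[`, -1L))),
                ncol = k + 1L, byrow = TRUE)
  elements <- num[, seq_len(k), drop = FALSE] + 1L
  region <- num[, k + 1L]

  fibres <- sheets <- normals <- NULL
  if (file.exists(lon_file)) {
    lon_lines <- readLines(lon_file)
    ndir <- suppressWarnings(as.integer(trimws(lon_lines[1])))
    if (is.na(ndir) || !ndir %in% c(1L, 3L))
      stop(lon_file, ": line 1 must be 1 or 3 (directions per element)")
    lon <- as.matrix(utils::read.table(text = lon_lines[-1],
                                       colClasses = "numeric"))
    if (nrow(lon) != ne)
      stop(lon_file, ": expected ", ne, " orientation lines, found ",
           nrow(lon))
    fibres <- lon[, 1:3, drop = FALSE]
    if (ndir == 3L) {
      sheets <- lon[, 4:6, drop = FALSE]
      normals <- lon[, 7:9, drop = FALSE]
    }
  }
  dfe_mesh(vertices, elements, region = region,
           fibres = fibres, sheets = sheets, normals = normals)
}

#' Write a CARP-style text mesh
#'
#' Inverse of [read_carp_mesh()]: writes `base.pts`, `base.elem`, and (when
#' the mesh carries orientation triads) `base.lon` with 3 directions per
#' element. Coordinates are printed with 6 decimals; read-after-write
#' reproduces connectivity, tags and orientations exactly and coordinates
#' to the printed precision.
#'
#' @param mesh a `dfe_mesh`
#' @param base output path base
#' @return invisibly, the vector of files written
#' @export
write_carp_mesh <- function(mesh, base) {
  pts_file <- paste0(base, ".pts")
  elem_file <- paste0(base, ".elem")
  v <- mesh$vertices
  writeLines(c(sprintf("%d", nrow(v)),
               sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])), pts_file)
  el <- mesh$elements - 1L
  tag <- mesh$region
  if (ncol(el) == 3) {
    lines <- sprintf("Tr %d %d %d %d", el[, 1], el[, 2], el[, 3], tag)
  } else {
    lines <- sprintf("Tt %d %d %d %d %d", el[, 1], el[, 2], el[, 3],
                     el[, 4], tag)
  }
  writeLines(c(sprintf("%d", nrow(el)), lines), elem_file)
  written <- c(pts_file, elem_file)
  if (!is.null(mesh$fibres)) {
    lon_file <- paste0(base, ".lon")
    m <- cbind(mesh$fibres, mesh$sheets, mesh$normals)
    writeLines(c("3", apply(m, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " "))), lon_file)
    written <- c(written, lon_file)
  }
  invisible(written)
}

#' Export a mesh to legacy VTK (ASCII unstructured grid)
#'
#' Writes the mesh, with optional per-vertex and per-element scalar fields,
#' for visualization in ParaView and friends.
#'
#' @param mesh a `dfe_mesh`
#' @param file output path
#' @param point_data named list of per-vertex numeric vectors
#' @param cell_data named list of per-element numeric vectors; the region
#'   tag is always included as `region`
#' @return invisibly, `file`
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  v <- mesh$vertices
  el <- mesh$elements - 1L
  k <- ncol(el)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fibroDFE mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * (k + 1L)), con)
  writeLines(apply(cbind(k, el), 1L, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(as.character(rep(if (k == 3) 5L else 10L, nrow(el))), con)
  cell_data <- c(list(region = as.numeric(mesh$region)), cell_data)
  writeLines(sprintf("CELL_DATA %d", nrow(el)), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.6g", cell_data[[nm]]), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.6g", point_data[[nm]]), con)
    }
  }
  invisible(file)
}
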