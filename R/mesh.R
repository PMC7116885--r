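#' Simplex mesh for cardiac tissue simulation
#'
#' Constructs the basic mesh container used throughout the package: a
#' triangle (2D) or tetrahedral (3D) mesh with a per-element region tag and
#' an optional per-element orthonormal orientation triad (fibre, sheet,
#' sheet-normal). Coordinates are in millimetres. Vertex indices in
#' `elements` are 1-based; the on-disk CARP dialect (0-based) is converted
#' at the I/O boundary.
#'
#' @param vertices numeric matrix, one row per vertex. Two or three columns;
#'   a third zero column is added for 2D input.
#' @param elements integer matrix of 1-based vertex indices; 3 columns for
#'   triangles, 4 for tetrahedra.
#' @param region integer vector of per-element region tags (0 = normal,
#'   1 = LGE). Recycled if scalar.
#' @param fibres,sheets,normals optional per-element unit direction matrices
#'   (one row per element). If `fibres` is given without `sheets`/`normals`
#'   a completing orthonormal triad is constructed.
#' @return An object of class `dfe_mesh`: a list with components
#'   `vertices`, `elements`, `region`, `fibres`, `sheets`, `normals`, `dim`.
#' @examples
#' m <- dfe_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
#'               rbind(c(1, 2, 3), c(1, 3, 4)))
#' n_elements(m)
#' @export
dfe_mesh <- function(vertices, elements, region = 0L,
                     fibres = NULL, sheets = NULL, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) == 2) vertices <- cbind(vertices, 0)
  if (ncol(vertices) != 3) stop("vertices must have 2 or 3 columns")
  dimnames(vertices) <- NULL
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  if (!ncol(elements) %in% c(3L, 4L))
    stop("elements must have 3 (triangles) or 4 (tetrahedra) columns")
  if (anyNA(elements) || min(elements) < 1L || max(elements) > nrow(vertices))
    stop("element vertex indices out of range")
  dim <- ncol(elements) - 1L
  region <- as.integer(rep_len(region, nrow(elements)))

  mesh <- structure(
    list(vertices = vertices, elements = elements, region = region,
         fibres = NULL, sheets = NULL, normals = NULL, dim = dim),
    class = "dfe_mesh")

  meas <- element_measures(mesh)
  if (any(meas <= 0))
    stop("degenerate or inverted simplices (non-positive measure): elements ",
         paste(utils::head(which(meas <= 0), 5L), collapse = ", "))

  if (!is.null(fibres)) {
    fibres <- .unit_rows(as.matrix(fibres), nrow(elements), "fibres")
    if (is.null(sheets)) {
      triad <- .complete_triad(fibres)
      sheets <- triad$s
      normals <- triad$n
    } else {
      sheets <- .unit_rows(as.matrix(sheets), nrow(elements), "sheets")
      if (is.null(normals)) {
        normals <- .cross_rows(fibres, sheets)
      } else {
        normals <- .unit_rows(as.matrix(normals), nrow(elements), "normals")
      }
    }
    .check_triads(fibres, sheets, normals)
    mesh$fibres <- fibres
    mesh$sheets <- sheets
    mesh$normals <- normals
  }
  mesh
}

.unit_rows <- function(x, m, what) {
  dimnames(x) <- NULL
  if (ncol(x) == 2) x <- cbind(x, 0)
  if (nrow(x) == 1) x <- x[rep(1L, m), , drop = FALSE]
  if (nrow(x) != m) stop(what, " must have one row per element")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm < 1e-12)) stop(what, " contains zero vectors")
  x / nrm
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Deterministically complete f into an orthonormal (f, s, n) triad.
.complete_triad <- function(f) {
  ref <- matrix(rep(c(0, 0, 1), each = nrow(f)), ncol = 3)
  degen <- abs(f[, 3]) > 0.9
  ref[degen, ] <- matrix(rep(c(0, 1, 0), each = sum(degen)), ncol = 3)
  s <- .cross_rows(ref, f)
  s <- s / sqrt(rowSums(s^2))
  n <- .cross_rows(f, s)
  list(s = s, n = n)
}

.check_triads <- function(f, s, n, tol = 1e-8) {
  err <- max(abs(rowSums(f * s)), abs(rowSums(f * n)), abs(rowSums(s * n)),
             abs(rowSums(f^2) - 1), abs(rowSums(s^2) - 1),
             abs(rowSums(n^2) - 1))
  if (err > tol) stop("orientation triads not orthonormal (max error ",
                      signif(err, 3), ")")
  invisible(TRUE)
}

#' @export
print.dfe_mesh <- function(x, ...) {
  cat(sprintf("dfe_mesh: %d vertices, %d %s (%dD)%s\n",
              nrow(x$vertices), nrow(x$elements),
              if (x$dim == 2) "triangles" else "tetrahedra", x$dim,
              if (is.null(x$fibres)) "" else ", with orientation triads"))
  tab <- table(x$region)
  cat("  region tags:", paste(sprintf("%s:%d", names(tab), tab),
                              collapse = " "), "\n")
  invisible(x)
}

#' Number of vertices / elements
#' @param mesh a `dfe_mesh`
#' @return integer count
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_elements <- function(mesh) nrow(mesh$elements)

#' Signed element measures (area in 2D, volume in 3D), in mm^2 / mm^3
#' @param mesh a `dfe_mesh`
#' @return numeric vector, one entry per element
#' @export
element_measures <- function(mesh) {
  .element_measures(mesh$vertices, mesh$elements - 1L)
}

#' Element centroids (mm)
#' @param mesh a `dfe_mesh`
#' @return numeric matrix, one row per element
#' @export
element_centroids <- function(mesh) {
  k <- ncol(mesh$elements)
  out <- matrix(0, nrow(mesh$elements), 3)
  for (a in seq_len(k)) out <- out + mesh$vertices[mesh$elements[, a], , drop = FALSE]
  out / k
}

# ---- face keys ------------------------------------------------------------

# Canonical identity of a face: the sorted tuple of its vertex indices,
# encoded as a single string "a.b" (2D edge) or "a.b.c" (3D face).
.face_keys <- function(fmat) {
  # fmat: rows are faces; returns canonical keys after row-wise sort
  d <- ncol(fmat)
  if (d == 2) {
    lo <- pmin(fmat[, 1], fmat[, 2]); hi <- pmax(fmat[, 1], fmat[, 2])
    paste(lo, hi, sep = ".")
  } else {
    s <- t(apply(fmat, 1L, sort.int))
    paste(s[, 1], s[, 2], s[, 3], sep = ".")
  }
}

.key_to_face <- function(keys) {
  parts <- strsplit(keys, ".", fixed = TRUE)
  do.call(rbind, lapply(parts, as.integer))
}

# ---- adjacency ------------------------------------------------------------

#' Face and vertex adjacency index
#'
#' Enumerates the (d-1)-faces of every element (edges of triangles, triangle
#' faces of tetrahedra), classifies them as interior (shared by exactly two
#' elements) or boundary (one element), and records the star of every vertex
#' (the elements incident to it).
#'
#' @param mesh a `dfe_mesh`
#' @return An object of class `adjacency_index` with components:
#'   `keys` (canonical face key strings), `faces` (matrix of sorted vertex
#'   indices), `e1`, `e2` (adjacent element indices, `e2` is `NA` for
#'   boundary faces), `interior` (logical), and `star` (list: elements
#'   incident to each vertex).
#' @export
build_adjacency <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  k <- ncol(el)
  combs <- utils::combn(k, k - 1L)
  fl <- lapply(seq_len(ncol(combs)), function(ci)
    el[, combs[, ci], drop = FALSE])
  fmat <- do.call(rbind, fl)
  eid <- rep.int(seq_len(m), ncol(combs))
  keys <- .face_keys(fmat)

  o <- order(keys, method = "radix")
  ks <- keys[o]
  es <- eid[o]
  first <- !duplicated(ks)
  grp <- cumsum(first)
  cnt <- tabulate(grp)
  if (any(cnt > 2L)) {
    bad <- which(first)[which(cnt > 2L)[1L]]
    stop("non-manifold mesh: face ", ks[bad], " is shared by ", max(cnt),
         " elements")
  }
  ukeys <- ks[first]
  e1 <- es[first]
  e2 <- rep(NA_integer_, length(ukeys))
  second <- which(cnt == 2L)
  idx2 <- which(first)[second] + 1L
  e2[second] <- es[idx2]

  faces <- fmat[o[first], , drop = FALSE]
  faces <- t(apply(faces, 1L, sort.int))
  star <- split(rep.int(seq_len(m), k),
                factor(as.vector(el), levels = seq_len(nrow(mesh$vertices))))

  structure(list(keys = ukeys, faces = faces, e1 = e1, e2 = e2,
                 interior = !is.na(e2), star = star,
                 n_vertices = nrow(mesh$vertices)),
            class = "adjacency_index")
}

#' @export
print.adjacency_index <- function(x, ...) {
  cat(sprintf("adjacency_index: %d faces (%d interior, %d boundary)\n",
              length(x$keys), sum(x$interior), sum(!x$interior)))
  invisible(x)
}

#' Vertex star: elements incident to a vertex
#' @param adjacency an `adjacency_index`
#' @param vertex 1-based vertex index
#' @return integer vector of element indices
#' @export
vertex_star <- function(adjacency, vertex) adjacency$star[[vertex]]

# Unit normals of faces given by sorted vertex index rows. In 2D the
# "normal" of an edge is its in-plane perpendicular. Sign is arbitrary
# (faces are unoriented); callers must treat n and -n as equivalent.
.face_normals <- function(mesh, faces) {
  v <- mesh$vertices
  if (ncol(faces) == 2) {
    d <- v[faces[, 2], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
    n <- cbind(-d[, 2], d[, 1], 0)
  } else {
    a <- v[faces[, 2], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
    b <- v[faces[, 3], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
    n <- .cross_rows(a, b)
  }
  n / sqrt(rowSums(n^2))
}
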