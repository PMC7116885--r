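#' Structured triangular grid
#'
#' Builds an `n_boxes` x `n_boxes` square grid of boxes, each box divided
#' into two triangles by a diagonal running from left to right (bottom-left
#' to top-right by default). This is the geometry of the 2D fibrosis
#' topology test meshes: 38 boxes of 0.25 mm give a 9.5 mm x 9.5 mm sheet.
#'
#' @param n_boxes number of boxes per side (>= 1)
#' @param box_edge box edge length in mm
#' @param diagonal `"lr"` for bottom-left to top-right diagonals, `"rl"` for
#'   the mirrored orientation
#' @return a `dfe_mesh` with `(n_boxes+1)^2` vertices and `2 n_boxes^2`
#'   triangles; fibres along +x, sheet normals along +y (in plane)
#' @export
make_grid_2d <- function(n_boxes, box_edge = 0.25, diagonal = c("lr", "rl")) {
  diagonal <- match.arg(diagonal)
  if (n_boxes < 1 || box_edge <= 0)
    stop("n_boxes must be >= 1 and box_edge positive")
  .make_grid_rect(as.integer(n_boxes), as.integer(n_boxes), box_edge,
                  diagonal)
}

# rectangular variant (nx boxes wide, ny boxes tall); make_grid_2d is the
# square special case
.make_grid_rect <- function(nx, ny, box_edge, diagonal = "lr") {
  n <- nx
  vid <- function(i, j) j * (nx + 1L) + i + 1L   # i, j are 0-based
  ij <- expand.grid(i = 0:nx, j = 0:ny)
  vertices <- cbind(ij$i * box_edge, ij$j * box_edge, 0)
  box <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  v00 <- vid(box$i, box$j)
  v10 <- vid(box$i + 1L, box$j)
  v01 <- vid(box$i, box$j + 1L)
  v11 <- vid(box$i + 1L, box$j + 1L)
  if (diagonal == "lr") {
    tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  } else {
    tris <- rbind(cbind(v00, v10, v01), cbind(v10, v11, v01))
  }
  dfe_mesh(vertices, tris, region = 0L,
           fibres = matrix(c(1, 0, 0), 1),
           sheets = matrix(c(0, 0, 1), 1),   # out of plane
           normals = matrix(c(0, 1, 0), 1))  # sheet normal in plane
}

# 1-based vertex id of grid point (i, j), both 0-based, on an n-box grid
.grid_vid <- function(i, j, n) j * (n + 1L) + i + 1L

#' Structured tetrahedral slab
#'
#' Builds a box-shaped slab of hexahedral cells, each decomposed into 5
#' tetrahedra with alternating parity so that faces of neighbouring cells
#' match. Used as the synthetic stand-in for image-derived ventricular
#' tissue: the LGE-resolution meshes of the imaging pipeline use 0.25 mm
#' edges inside the enhanced zone and 0.4 mm outside, which this generator
#' reproduces on a rectangular geometry.
#'
#' @param dims lengths (mm) of the slab along x, y, z (length-3 vector)
#' @param target_edge requested cell edge length (mm); the actual edge is
#'   `dims / round(dims / target_edge)` per axis
#' @param orientation_rule either `NULL` (fibre +x, sheet +y, sheet-normal
#'   +z) or a function `f(centroid)` returning a list with unit vectors
#'   `f`, `s`, `n` for an element centred at `centroid` (mm)
#' @return a `dfe_mesh` of tetrahedra with orientation triads
#' @export
make_slab_3d <- function(dims, target_edge, orientation_rule = NULL) {
  dims <- rep_len(as.numeric(dims), 3L)
  if (any(dims <= 0)) stop("dims must be positive")
  if (target_edge <= 0 || target_edge > min(dims))
    stop("target_edge must be in (0, min(dims)]")
  nx <- max(1L, as.integer(round(dims[1] / target_edge)))
  ny <- max(1L, as.integer(round(dims[2] / target_edge)))
  nz <- max(1L, as.integer(round(dims[3] / target_edge)))
  hx <- dims[1] / nx; hy <- dims[2] / ny; hz <- dims[3] / nz

  vid <- function(i, j, k) (k * (ny + 1L) + j) * (nx + 1L) + i + 1L
  ijk <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  vertices <- cbind(ijk$i * hx, ijk$j * hy, ijk$k * hz)

  cell <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  # cube corners: a b c d on bottom (ccw), e f g h on top
  a <- vid(cell$i,      cell$j,      cell$k)
  b <- vid(cell$i + 1L, cell$j,      cell$k)
  cc <- vid(cell$i + 1L, cell$j + 1L, cell$k)
  d <- vid(cell$i,      cell$j + 1L, cell$k)
  e <- vid(cell$i,      cell$j,      cell$k + 1L)
  f <- vid(cell$i + 1L, cell$j,      cell$k + 1L)
  g <- vid(cell$i + 1L, cell$j + 1L, cell$k + 1L)
  h <- vid(cell$i,      cell$j + 1L, cell$k + 1L)
  even <- (cell$i + cell$j + cell$k) %% 2L == 0L

  # 5-tet decomposition; the odd-parity cells use the complementary cut so
  # that the diagonals of shared quad faces agree between neighbours.
  t_even <- function(a, b, cc, d, e, f, g, h)
    rbind(cbind(a, b, d, e),   # corner tets at a, c, f, h
          cbind(cc, b, g, d),
          cbind(f, b, e, g),
          cbind(h, d, g, e),
          cbind(b, d, e, g))   # central tet
  tets <- rbind(
    t_even(a[even], b[even], cc[even], d[even], e[even], f[even], g[even], h[even]),
    # complement: reflect the cube in x (a<->b, d<->c, e<->f, h<->g)
    t_even(b[!even], a[!even], d[!even], cc[!even], f[!even], e[!even],
           h[!even], g[!even]))

  # normalize tet orientation to positive volume
  meas <- .element_measures(vertices, tets - 1L)
  neg <- meas < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]

  if (is.null(orientation_rule)) {
    mesh <- dfe_mesh(vertices, tets, region = 0L,
                     fibres = matrix(c(1, 0, 0), 1),
                     sheets = matrix(c(0, 1, 0), 1),
                     normals = matrix(c(0, 0, 1), 1))
  } else {
    ctr <- matrix(0, nrow(tets), 3)
    for (aa in 1:4) ctr <- ctr + vertices[tets[, aa], , drop = FALSE]
    ctr <- ctr / 4
    tri <- lapply(seq_len(nrow(ctr)), function(i) orientation_rule(ctr[i, ]))
    mesh <- dfe_mesh(vertices, tets, region = 0L,
                     fibres = do.call(rbind, lapply(tri, `[[`, "f")),
                     sheets = do.call(rbind, lapply(tri, `[[`, "s")),
                     normals = do.call(rbind, lapply(tri, `[[`, "n")))
  }
  attr(mesh, "grid") <- list(n = c(nx, ny, nz), h = c(hx, hy, hz))
  mesh
}

#' 2D fibrosis-topology test case
#'
#' Builds the 38 x 38 box triangular test mesh (0.25 mm boxes, 9.5 mm x
#' 9.5 mm) with a horizontal row of 10 plus-shaped crosses of split edges at
#' mid height, spanning the full width with a one-element gap between the
#' arms of neighbouring crosses. Each cross consists of the four grid edges
#' incident to its centre vertex. With the connectivity-consistent splitting
#' each cross centre separates its surrounding elements into 4 groups
#' ("tight" topology); the "leaky" variant emulates naive per-edge node
#' doubling, in which diagonally opposite groups remain connected through a
#' shared node copy, leaving only 2 groups per centre.
#'
#' @param topology `"tight"` or `"leaky"`
#' @return a list with components `mesh`, `network` (a `fibrosis_network` of
#'   split edge keys, identical for both topologies), `centres` (vertex
#'   indices of the cross centres), `leaky_vertices` (vertices at which the
#'   degraded assignment is applied; empty for tight), and
#'   `expected_components` (4 or 2)
#' @export
make_cross_testcase <- function(topology = c("tight", "leaky")) {
  topology <- match.arg(topology)
  n <- 38L
  mesh <- make_grid_2d(n, 0.25)
  jrow <- 19L
  centres_i <- 1L + 4L * (0:9)
  centres <- .grid_vid(centres_i, jrow, n)
  edges <- NULL
  for (ci in centres_i) {
    v0 <- .grid_vid(ci, jrow, n)
    arms <- rbind(c(.grid_vid(ci - 1L, jrow, n), v0),
                  c(v0, .grid_vid(ci + 1L, jrow, n)),
                  c(.grid_vid(ci, jrow - 1L, n), v0),
                  c(v0, .grid_vid(ci, jrow + 1L, n)))
    edges <- rbind(edges, arms)
  }
  net <- fibrosis_network(.face_keys(edges), rho_max = NA_real_,
                          seed = NA_integer_)
  list(mesh = mesh, network = net, centres = centres,
       leaky_vertices = if (topology == "leaky") centres else integer(0),
       topology = topology,
       expected_components = if (topology == "tight") 4L else 2L)
}

#' Synthetic LGE-like intensity field
#'
#' Generates a smooth, radially decaying per-element intensity field that
#' emulates a late-gadolinium-enhanced zone embedded in normal tissue:
#' intensity is `I_max` at the centre, decays quadratically to the
#' reference (non-enhanced) intensity `I_ref` at `radius`, and equals
#' `I_ref` beyond. A small seeded jitter (scaled down towards the centre so
#' that the central element keeps intensity `I_max`) emulates image noise.
#'
#' @param mesh a `dfe_mesh`
#' @param centre centre of the enhanced zone (mm, length 3; a length-2
#'   vector is padded with 0)
#' @param radius radius of the enhanced zone (mm, > 0)
#' @param seed integer seed for the jitter; the field is deterministic
#'   given the seed
#' @param I_ref,I_max reference and maximum intensity (arbitrary image
#'   units, `I_max > I_ref`)
#' @param noise_sd jitter standard deviation in image units
#' @return an object of class `intensity_field`: list with `value` (one
#'   intensity per element), `I_ref`, `I_max`
#' @export
synthetic_lge_fixture <- function(mesh, centre, radius, seed,
                                  I_ref = 100, I_max = 200, noise_sd = 2) {
  if (radius <= 0) stop("radius must be positive")
  if (I_max <= I_ref) stop("I_max must exceed I_ref")
  centre <- c(rep_len(as.numeric(centre), 3L))
  if (length(centre) == 2) centre <- c(centre, 0)
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  if (any(centre < bb_lo - 1e-9) || any(centre > bb_hi + 1e-9))
    stop("centre lies outside the mesh bounding box")
  ctr <- element_centroids(mesh)
  d <- sqrt(rowSums((ctr - matrix(centre, nrow(ctr), 3, byrow = TRUE))^2))
  base <- I_ref + (I_max - I_ref) * pmax(0, 1 - (d / radius)^2)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  jit <- stats::rnorm(length(d), sd = noise_sd) * pmin(1, d / radius) *
    (d < radius)
  value <- pmin(pmax(base + jit, I_ref), I_max)
  value[which.min(d)] <- I_max
  structure(list(value = value, I_ref = I_ref, I_max = I_max),
            class = "intensity_field")
}

# save/restore .Random.seed so fixture generation does not disturb the
# caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Tag LGE elements from an intensity field
#'
#' Sets `region` to 1 for every element whose normalized intensity exceeds
#' `threshold` (0 marks everything brighter than the reference).
#'
#' @param mesh a `dfe_mesh`
#' @param field an `intensity_field`
#' @param threshold normalized intensity threshold in `[0, 1)`
#' @return the mesh with an updated `region` component
#' @export
set_region_from_intensity <- function(mesh, field, threshold = 0) {
  istar <- normalize_intensity(field$value, field$I_ref, field$I_max)
  mesh$region <- as.integer(istar > threshold)
  mesh
}
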