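# Shared fixtures and independent oracles, built in code.

# Fan of 5 triangles around a central vertex (index 6), rim vertices 1..5.
# Element e_i spans rim vertices (i, i+1 mod 5) and the centre.
pentagon_fan <- function() {
  ang <- (0:4) * 2 * pi / 5
  verts <- rbind(cbind(cos(ang), sin(ang)), c(0, 0))
  dfe_mesh(verts, cbind(1:5, c(2:5, 1), 6))
}

# Fan of 4 tetrahedra around the axis v6 (origin) - v4 (apex), rim vertices
# v5, v1, v2, v3 at in-plane angles 0, 60, 95, 190 degrees. The worked
# splitting example: face (4,5,6) separates e1 from e4, leaving them
# connected via e2, e3; among faces containing vertex 6, face (2,4,6) has
# the smallest |dot| of normals with face (4,5,6).
tet_fan <- function() {
  a <- c(0, 60, 95, 190) * pi / 180
  rim <- cbind(cos(a), sin(a), 0)          # rows: v5, v1, v2, v3
  verts <- rbind(rim[2, ], rim[3, ], rim[4, ], c(0, 0, 1), rim[1, ],
                 c(0, 0, 0))
  els <- rbind(c(5, 1, 6, 4), c(1, 2, 6, 4), c(2, 3, 6, 4), c(3, 5, 6, 4))
  dfe_mesh(verts, els)
}

# Brute-force O(m^2) face-matching oracle for the adjacency index.
brute_adjacency <- function(mesh) {
  el <- mesh$elements
  k <- ncol(el)
  m <- nrow(el)
  pairs <- NULL
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (length(intersect(el[i, ], el[j, ])) == k - 1L)
        pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs
}

# Brute-force components of the global element graph with split faces
# removed, restricted to the star of a vertex (induced subgraph).
brute_star_components <- function(mesh, vertex, network) {
  el <- mesh$elements
  k <- ncol(el)
  star <- which(rowSums(el == vertex) > 0)
  comp <- as.list(star)
  find <- function(e) which(vapply(comp, function(cc) e %in% cc,
                                   logical(1)))
  for (i in seq_along(star)) {
    for (j in seq_along(star)) {
      if (j <= i) next
      shared <- intersect(el[star[i], ], el[star[j], ])
      if (length(shared) != k - 1L) next
      keys <- paste(sort(shared), collapse = ".")
      if (keys %in% network$faces) next
      ci <- find(star[i]); cj <- find(star[j])
      if (ci != cj) {
        comp[[ci]] <- sort(c(comp[[ci]], comp[[cj]]))
        comp[[cj]] <- NULL
      }
    }
  }
  comp[order(vapply(comp, min, numeric(1)))]
}

# Number of full action-potential upstrokes in a vm trace: rises above
# 0 mV that start from below -40 mV.
count_upstrokes <- function(vm) {
  n <- 0L
  armed <- TRUE
  for (v in vm) {
    if (v < -40) armed <- TRUE
    else if (v >= 0 && armed) {
      n <- n + 1L
      armed <- FALSE
    }
  }
  n
}

# Straight full-width horizontal fence of split edges at grid row j on an
# n-box grid.
fence_network <- function(n, j) {
  e <- cbind(fibroDFE:::.grid_vid(0:(n - 1L), j, n),
             fibroDFE:::.grid_vid(1:n, j, n))
  fibrosis_network(fibroDFE:::.face_keys(e))
}

# Small 3D slab with a buried enhanced zone, for network sampling tests.
lge_slab <- function(dims = c(5, 5, 2.5), edge = 0.625,
                     centre = c(2.5, 2.5, 1.25), radius = 1.1, seed = 7) {
  slab <- make_slab_3d(dims, edge)
  field <- synthetic_lge_fixture(slab, centre, radius, seed)
  list(mesh = set_region_from_intensity(slab, field), field = field)
}
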