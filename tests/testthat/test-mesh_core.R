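test_that("grid generator produces the documented counts and extents", {
  m <- make_grid_2d(38, 0.25)
  expect_equal(n_vertices(m), 39^2)
  expect_equal(n_elements(m), 2 * 38^2)
  expect_equal(max(m$vertices[, 1]), 9.5)
  expect_equal(max(m$vertices[, 2]), 9.5)
  expect_true(all(element_measures(m) > 0))

  m1 <- make_grid_2d(1)
  expect_equal(n_vertices(m1), 4)
  expect_equal(n_elements(m1), 2)
  expect_error(make_grid_2d(0), "n_boxes")
  expect_error(make_grid_2d(3, -1), "positive")
})

test_that("grid satisfies the planar Euler formula on small instances", {
  for (n in 2:4) {
    m <- make_grid_2d(n, 0.5)
    adj <- build_adjacency(m)
    V <- n_vertices(m)
    E <- length(adj$keys)
    F <- n_elements(m)
    expect_equal(V - E + F, 1L)  # outer face not counted
  }
})

test_that("slab tetrahedralization has matching faces and exact counts", {
  s <- make_slab_3d(c(2, 2, 2), 1)
  expect_equal(n_elements(s), 8 * 5)
  expect_true(all(element_measures(s) > 0))
  adj <- build_adjacency(s)   # errors if any face is shared by > 2 elements
  expect_true(all(table(c(adj$e1, adj$e2[adj$interior])) <= 4))

  s2 <- make_slab_3d(c(4, 2.8, 1.2), 0.4)
  ncell <- prod(round(c(4, 2.8, 1.2) / 0.4))
  expect_equal(n_elements(s2), 5 * ncell)
  expect_equal(sum(element_measures(s2)), 4 * 2.8 * 1.2, tolerance = 1e-10)
  expect_error(make_slab_3d(c(2, 2, 2), 3), "target_edge")

  rule <- function(ctr) list(f = c(0, 0, 1), s = c(1, 0, 0), n = c(0, 1, 0))
  s3 <- make_slab_3d(c(2, 2, 1), 1, orientation_rule = rule)
  expect_true(all(s3$fibres[, 3] == 1))
})

test_that("adjacency matches a brute-force face-matching oracle", {
  for (mesh in list(make_grid_2d(4, 0.5), make_slab_3d(c(2, 2, 1), 0.7),
                    tet_fan())) {
    adj <- build_adjacency(mesh)
    oracle <- brute_adjacency(mesh)
    got <- cbind(pmin(adj$e1[adj$interior], adj$e2[adj$interior]),
                 pmax(adj$e1[adj$interior], adj$e2[adj$interior]))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(oracle))
    # stars cover all elements
    expect_setequal(unique(unlist(adj$star)), seq_len(n_elements(mesh)))
  }
})

test_that("adjacency classifies single and shared tet faces", {
  one <- dfe_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  matrix(c(1, 2, 3, 4), 1))
  adj <- build_adjacency(one)
  expect_equal(length(adj$keys), 4L)
  expect_true(all(!adj$interior))

  two <- dfe_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                        c(1, 1, 1)),
                  rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  adj2 <- build_adjacency(two)
  shared <- which(adj2$interior)
  expect_length(shared, 1L)
  expect_equal(adj2$keys[shared], "2.3.4")
  expect_setequal(c(adj2$e1[shared], adj2$e2[shared]), c(1L, 2L))

  pent <- pentagon_fan()
  expect_setequal(vertex_star(build_adjacency(pent), 6), 1:5)
})

test_that("carp i/o round-trips and reports malformed input", {
  dir <- withr::local_tempdir()
  m <- make_grid_2d(3, 0.25)
  m$region[1:4] <- 1L
  base <- file.path(dir, "grid")
  write_carp_mesh(m, base)
  m2 <- read_carp_mesh(base)
  expect_equal(m2$elements, m$elements)
  expect_equal(m2$region, m$region)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(m2$fibres, m$fibres, tolerance = 1e-6)

  big <- make_grid_2d(38, 0.25)
  base38 <- file.path(dir, "grid38")
  write_carp_mesh(big, base38)
  expect_equal(n_elements(read_carp_mesh(base38)), 2888L)

  writeLines(c("4", "0 0 0", "1 0 0", "0 1 0"), file.path(dir, "bad.pts"))
  writeLines(c("1", "Tr 0 1 2 0"), file.path(dir, "bad.elem"))
  expect_error(read_carp_mesh(file.path(dir, "bad")), "announces 4")

  writeLines(c("2", "Tr 0 1 2 0", "Tt 0 1 2 3 0"),
             file.path(dir, "mixed.elem"))
  writeLines(c("4", "0 0 0", "1 0 0", "0 1 0", "0 0 1"),
             file.path(dir, "mixed.pts"))
  expect_error(read_carp_mesh(file.path(dir, "mixed")), "mixed")

  vtk <- file.path(dir, "grid.vtk")
  write_vtk(m, vtk, point_data = list(v = rep(0, n_vertices(m))))
  expect_true(any(grepl("UNSTRUCTURED_GRID", readLines(vtk))))
})

test_that("mesh constructor validates indices, degeneracy and triads", {
  expect_error(dfe_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
                        matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(dfe_mesh(rbind(c(0, 0), c(1, 0), c(2, 0)),
                        matrix(c(1, 2, 3), 1)), "degenerate")
  expect_error(dfe_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
                        matrix(c(1, 2, 3), 1),
                        fibres = matrix(c(1, 0, 0), 1),
                        sheets = matrix(c(1, 0, 0), 1)),
               "orthonormal")
})

test_that("synthetic LGE fixture is deterministic, radial and bounded", {
  s <- make_slab_3d(c(4, 4, 2), 0.5)
  f1 <- synthetic_lge_fixture(s, c(2, 2, 1), 1.2, seed = 3)
  f2 <- synthetic_lge_fixture(s, c(2, 2, 1), 1.2, seed = 3)
  expect_identical(f1$value, f2$value)

  ctr <- element_centroids(s)
  d <- sqrt(rowSums((ctr - matrix(c(2, 2, 1), nrow(ctr), 3, TRUE))^2))
  istar <- normalize_intensity(f1$value, f1$I_ref, f1$I_max)
  expect_equal(max(istar[which.min(d)]), 1)        # centre element at I_max
  expect_true(all(istar[d > 1.2] == 0))            # zero beyond the radius
  expect_error(synthetic_lge_fixture(s, c(2, 2, 1), -1, 1), "radius")
  expect_error(synthetic_lge_fixture(s, c(99, 0, 0), 1, 1), "bounding box")
})

test_that("cross test case shares split edges across topologies", {
  tight <- make_cross_testcase("tight")
  leaky <- make_cross_testcase("leaky")
  expect_setequal(tight$network$faces, leaky$network$faces)
  expect_length(tight$network$faces, 40L)          # 10 crosses x 4 arms
  expect_length(tight$centres, 10L)
  expect_equal(tight$expected_components, 4L)
  expect_equal(leaky$expected_components, 2L)
  expect_length(tight$leaky_vertices, 0L)
  expect_setequal(leaky$leaky_vertices, leaky$centres)
})
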