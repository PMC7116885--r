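test_that("operators have the Neumann nullspace and partition of unity", {
  m <- make_grid_2d(5, 0.3)
  ops <- assemble_operators(m, conductivity_field(m, 2, 0.5))
  expect_lt(max(abs(ops$stiffness %*% rep(1, n_vertices(m)))), 1e-12)
  expect_equal(sum(ops$mass), (5 * 0.03)^2, tolerance = 1e-12)

  s <- make_slab_3d(c(2, 2, 1), 0.5)
  ops3 <- assemble_operators(s, conductivity_field(s, 3, 0.4))
  expect_lt(max(abs(ops3$stiffness %*% rep(1, n_vertices(s)))), 1e-12)
  expect_equal(sum(ops3$mass), 2 * 2 * 1 * 1e-3, tolerance = 1e-12)
})

test_that("a split fence decouples the energy inner product", {
  m <- make_grid_2d(8, 0.5)
  sp <- split_mesh(m, fence_network(8L, 4L))
  sm <- sp$mesh
  above <- element_centroids(sm)[, 2] > 2
  v <- numeric(n_vertices(sm))
  for (e in which(above)) v[sm$elements[e, ]] <- 1
  ops <- assemble_operators(sm, conductivity_field(sm, 1))
  expect_lt(abs(as.numeric(t(v) %*% ops$stiffness %*% v)), 1e-12)
})

test_that("resting tissue stays at rest without a stimulus", {
  m <- make_grid_2d(5, 0.4)
  run <- run_monodomain(m, conductivity_field(m, 2, 0.5), list(),
                        duration = 500, model = ionic_model("tt06"))
  expect_equal(nrow(run$activations), 0L)
  rs <- resting_state(ionic_model("tt06"))
  expect_lt(max(abs(run$state[, 1] - rs[["V"]])), 0.1)
})

test_that("LGE conductivity bands follow the intensity scheme", {
  sc <- lge_conductivity_bands(c(0, 0.10, 0.30, 0.60, 0.80, 1))
  expect_equal(sc[, "scale_fibre"], c(1, 1, 1, 0.75, 0.5, 0.5))
  expect_equal(sc[, "scale_transverse"], c(0.75, 0.75, 0.5, 0.5, 0.5, 0.5))
  # half-open band edges
  expect_equal(unname(lge_conductivity_bands(0.25)[1, ]), c(1, 0.5))
  expect_equal(unname(lge_conductivity_bands(0.75)[1, ]), c(0.5, 0.5))
  expect_error(lge_conductivity_bands(1.2), "I_star")
})

test_that("activation detection interpolates first upward crossings", {
  t <- 0:20
  v <- seq(-50, 50, by = 5)
  expect_equal(detect_activation_times(t, v), 10)
  v2 <- c(-10, -4, 2, 8)
  ta <- detect_activation_times(0:3, v2)
  expect_gt(ta, 1); expect_lt(ta, 2)
  expect_true(is.na(detect_activation_times(0:3, c(-10, -5, -2, -1))))
  expect_true(is.na(detect_activation_times(0:3, c(10, 5, -2, -4))))
})

test_that("activation maps bin events into beat windows", {
  run <- structure(list(activations = data.frame(
    node = c(1L, 1L, 2L, 2L, 3L),
    time = c(5, 105, 7, 30, 110)),
    state = matrix(0, 3, 1)), class = "monodomain_run")
  amap <- activation_map(run, c(0, 100))
  expect_equal(amap[1, ], c(5, 105))
  expect_equal(amap[2, ], c(7, NA))     # first event per window only
  expect_equal(amap[3, ], c(NA, 110))
})

test_that("measure_cv recovers a constructed slope and rejects sparse data", {
  m <- make_grid_2d(10, 0.5)
  act <- m$vertices[, 1] / 0.84          # t = x / (0.84 mm/ms)
  expect_equal(measure_cv(act, m, axis = c(1, 0, 0)), 84, tolerance = 1e-10)
  act2 <- rep(NA_real_, n_vertices(m))
  act2[1:2] <- 1:2
  expect_error(measure_cv(act2, m, axis = c(1, 0, 0)), "fewer than 3")
})

test_that("conduction velocity scales as the square root of conductivity", {
  mod <- ionic_model("ms")
  geo <- fibroDFE:::.strand_geometry("fibre", 0.5)
  cv1 <- fibroDFE:::.strand_cv(geo, 1.5, mod, 40)
  cv2 <- fibroDFE:::.strand_cv(geo, 3.0, mod, 60)
  expect_equal(cv2 / cv1, sqrt(2), tolerance = 0.05)
})

test_that("per-resolution tuning gives consistent velocity across meshes", {
  tun4 <- tune_conductivity(84, "fibre", 0.4)
  tun25 <- tune_conductivity(84, "fibre", 0.25)
  expect_false(isTRUE(all.equal(tun4$sigma, tun25$sigma, tolerance = 0.02)))
  expect_lt(abs(tun4$cv - tun25$cv) / 84, 0.05)
})

test_that("a wave cannot escape a fully enclosed split region", {
  n <- 12L
  m <- make_grid_2d(n, 0.5)
  # closed square fence: ring of grid edges around the centre
  lo <- 4L; hi <- 8L
  e <- rbind(
    cbind(fibroDFE:::.grid_vid(lo:(hi - 1L), lo, n),
          fibroDFE:::.grid_vid((lo + 1L):hi, lo, n)),
    cbind(fibroDFE:::.grid_vid(lo:(hi - 1L), hi, n),
          fibroDFE:::.grid_vid((lo + 1L):hi, hi, n)),
    cbind(fibroDFE:::.grid_vid(lo, lo:(hi - 1L), n),
          fibroDFE:::.grid_vid(lo, (lo + 1L):hi, n)),
    cbind(fibroDFE:::.grid_vid(hi, lo:(hi - 1L), n),
          fibroDFE:::.grid_vid(hi, (lo + 1L):hi, n)))
  net <- fibrosis_network(fibroDFE:::.face_keys(e))
  sp <- split_mesh(m, net)
  sm <- sp$mesh
  mod <- ionic_model("ms")
  cond <- conductivity_field(sm, 2)
  run <- run_monodomain(sm, cond,
                        stimulus(site = c(3, 3), onsets = 0, radius = 0.8),
                        duration = 60, model = mod)
  expect_gt(nrow(run$activations), 0)
  inside <- sm$vertices[, 1] > 2 & sm$vertices[, 1] < 4 &
    sm$vertices[, 2] > 2 & sm$vertices[, 2] < 4
  act_nodes <- unique(run$activations$node)
  # only vertices inside (or on) the enclosure activate
  outside <- sm$vertices[, 1] < 1.9 | sm$vertices[, 1] > 4.1 |
    sm$vertices[, 2] < 1.9 | sm$vertices[, 2] > 4.1
  expect_length(intersect(act_nodes, which(outside)), 0L)
  expect_gt(length(intersect(act_nodes, which(inside))), 0L)
})

test_that("stimuli require a non-empty capture region", {
  m <- make_grid_2d(4, 0.5)
  expect_error(
    run_monodomain(m, conductivity_field(m, 1),
                   stimulus(site = c(50, 50), onsets = 0, radius = 0.1),
                   duration = 5, model = ionic_model("ms")),
    "no vertices")
  expect_error(stimulus(onsets = 0), "site or nodes")
})
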