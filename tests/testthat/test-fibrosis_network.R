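test_that("intensity normalization clamps to the unit interval", {
  expect_equal(normalize_intensity(100, 100, 200), 0)
  expect_equal(normalize_intensity(200, 100, 200), 1)
  expect_equal(normalize_intensity(150, 100, 200), 0.5)
  expect_equal(normalize_intensity(c(50, 250), 100, 200), c(0, 1))
  expect_error(normalize_intensity(1, 5, 5), "I_max")
})

test_that("face probability follows the density-angle-intensity product", {
  expect_equal(face_probability(1, pi / 2, 1), 0, tolerance = 1e-12)
  expect_equal(face_probability(1, 0, 1), 1)
  expect_equal(face_probability(0.5, 0, 0.5), 0.25)
  # unoriented faces: theta and pi - theta are the same cleft
  expect_equal(face_probability(0.8, pi - 0.3, 0.6),
               face_probability(0.8, 0.3, 0.6))
  expect_error(face_probability(1.5, 0, 1), "I_star")
  expect_error(face_probability(0.5, 0, 2), "rho_max")
})

test_that("probability map covers only interior LGE faces within bounds", {
  fx <- lge_slab()
  pmap <- probability_map(fx$mesh, fx$field, rho_max = 0.7)
  expect_true(length(pmap$p) > 0)
  expect_true(all(pmap$p >= 0 & pmap$p <= 0.7))
  adj <- build_adjacency(fx$mesh)
  loc <- match(pmap$keys, adj$keys)
  expect_true(all(adj$interior[loc]))
  lge <- fx$mesh$region == 1L
  expect_true(all(lge[adj$e1[loc]] & lge[adj$e2[loc]]))
})

test_that("network sampling is Bernoulli per face and seed-reproducible", {
  fake <- structure(list(keys = sprintf("f%d", 1:10000),
                         p = rep(0.3, 10000), rho_max = 1),
                    class = "probability_map")
  net <- sample_network(fake, seed = 42)
  frac <- length(net) / 10000
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.3), 3 * se)
  expect_identical(sample_network(fake, 42)$faces, net$faces)

  none <- structure(list(keys = fake$keys, p = rep(0, 10000), rho_max = 1),
                    class = "probability_map")
  expect_length(sample_network(none, 1)$faces, 0L)
  all_in <- structure(list(keys = fake$keys, p = rep(1, 10000), rho_max = 1),
                      class = "probability_map")
  expect_length(sample_network(all_in, 1)$faces, 10000L)
})

test_that("expected network size grows with the density parameter", {
  fx <- lge_slab()
  adj <- build_adjacency(fx$mesh)
  mean_size <- vapply(c(0.2, 0.5, 0.9), function(rho) {
    pmap <- probability_map(fx$mesh, fx$field, rho, adjacency = adj)
    mean(vapply(1:5, function(s) length(sample_network(pmap, s)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_size) > 0))
  # and matches the mean probability within binomial tolerance
  pmap <- probability_map(fx$mesh, fx$field, 0.9, adjacency = adj)
  sizes <- vapply(1:20, function(s) length(sample_network(pmap, s)),
                  numeric(1))
  expect_lt(abs(mean(sizes) - sum(pmap$p)),
            4 * sqrt(sum(pmap$p * (1 - pmap$p)) / 20))
})

test_that("density sweep bookkeeping yields the full model set", {
  fx <- lge_slab()
  nets <- density_sweep(fx$mesh, fx$field, densities = c(1.0),
                        n_realizations = 1, base_seed = 5)
  expect_length(nets, 2L)
  expect_equal(nets[[2]]$rho_max, 0)
  expect_length(nets[[2]]$faces, 0L)

  nets_a <- density_sweep(fx$mesh, fx$field, densities = c(0.3, 0.6),
                          n_realizations = 3, base_seed = 9)
  nets_b <- density_sweep(fx$mesh, fx$field, densities = c(0.3, 0.6),
                          n_realizations = 3, base_seed = 9)
  expect_length(nets_a, 7L)
  expect_identical(lapply(nets_a, `[[`, "faces"),
                   lapply(nets_b, `[[`, "faces"))
  expect_error(density_sweep(fx$mesh, fx$field, densities = c(0, 0.5)),
               "densities")
})

test_that("network text serialization round-trips", {
  dir <- withr::local_tempdir()
  net <- fibrosis_network(c("3.7.9", "1.2.4"), rho_max = 0.4, seed = 12L)
  f <- file.path(dir, "net.txt")
  write_network(net, f)
  back <- read_network(f)
  expect_setequal(back$faces, net$faces)
  expect_equal(back$rho_max, 0.4)
  expect_equal(back$seed, 12L)
  empty <- fibrosis_network(character(0), 0, 1L)
  write_network(empty, f)
  expect_length(read_network(f)$faces, 0L)
})
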