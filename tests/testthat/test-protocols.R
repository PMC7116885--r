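test_that("ERP bisection converges against threshold oracles", {
  mk <- function(thr) function(ci) ci >= thr
  expect_equal(erp_binary_search(mk(310), c(200, 450), 10),
               c(fail = 300, capture = 310))
  expect_equal(erp_binary_search(mk(450), c(200, 450), 10),
               c(fail = 440, capture = 450))
  expect_equal(erp_binary_search(mk(201), c(200, 450), 10),
               c(fail = 200, capture = 210))
  expect_error(erp_binary_search(function(ci) TRUE, c(200, 450), 10),
               "lower bound")
  expect_error(erp_binary_search(function(ci) FALSE, c(200, 450), 10),
               "upper bound")
  # returned endpoints really bracket the oracle threshold
  for (thr in c(215, 342, 449)) {
    br <- erp_binary_search(mk(thr), c(200, 450), 10)
    expect_false(mk(thr)(br[["fail"]]))
    expect_true(mk(thr)(br[["capture"]]))
    expect_equal(br[["capture"]] - br[["fail"]], 10)
  }
})

test_that("new-wave detection applies the distance and latency window", {
  m <- make_grid_2d(10, 0.5)
  site <- c(0, 0)
  near <- which(m$vertices[, 1] < 2)[1]
  act <- function(node, time) data.frame(node = node, time = time)
  expect_false(detect_new_wave(act(integer(0), numeric(0)), m, site, 100))
  expect_true(detect_new_wave(act(near, 215), m, site, 100))
  expect_false(detect_new_wave(act(near, 225), m, site, 100))  # too late
  expect_false(detect_new_wave(act(near, 205), m, site, 100))  # too early
  far <- which.max(m$vertices[, 1])
  expect_false(detect_new_wave(act(far, 215), m, site, 100, radius = 3))
})

test_that("reentry detection requires a late activation near the site", {
  m <- make_grid_2d(10, 0.5)
  site <- c(0, 0)
  near <- which(rowSums(m$vertices^2) < 1)[1]
  act <- function(node, time) data.frame(node = node, time = time)
  expect_false(detect_reentry(act(near, 250), m, site, 0))
  expect_true(detect_reentry(act(near, 400), m, site, 0))
  far <- which.max(rowSums(m$vertices[, 1:2]^2))
  expect_false(detect_reentry(act(far, 400), m, site, 0, radius = 3))
})

test_that("programmed stimulation on homogeneous tissue finds no reentry", {
  mod <- ionic_model("ms")
  strip <- fibroDFE:::.make_grid_rect(48L, 6L, 0.5)
  tun <- tune_conductivity(17, "fibre", 0.5, model = mod)
  cond <- conductivity_field(strip, tun$sigma, tun$sigma)
  pes <- run_pes(strip, cond, pacing_site = c(1, 1.5), model = mod)
  expect_false(pes$reentry)
  expect_equal(pes$beats_delivered, 3L)
  expect_equal(nrow(pes$erp_brackets), 3L)
  expect_true(all(pes$erp_brackets[, "capture"] -
                    pes$erp_brackets[, "fail"] == 10))
  expect_true(all(pes$erp_brackets >= 200 & pes$erp_brackets <= 450))
  # protocol determinism
  pes2 <- run_pes(strip, cond, pacing_site = c(1, 1.5), model = mod)
  expect_identical(pes$erp_brackets, pes2$erp_brackets)
})

test_that("TAT protocol measures transit over the final three beats", {
  mod <- ionic_model("ms")
  slab <- make_slab_3d(c(4, 4, 3), 0.75)
  sig <- tune_conductivity(40, "fibre", 0.75, model = mod)$sigma
  cond <- conductivity_field(slab, sig, sig)
  rec <- run_tat_protocol(slab, cond, c(2, 2, 0), c(2, 2, 3), mod,
                          cis = c(600, 600, 600, 350, 270))
  expect_s3_class(rec, "tat_record")
  expect_equal(rec$ci, c(600, 350, 270))
  expect_false(anyNA(rec$tat))
  # homogeneous slab: roughly thickness / velocity for every beat
  expected <- 3 / (40 / 100)
  expect_true(all(rec$tat > 0.5 * expected & rec$tat < 2.5 * expected))
})
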