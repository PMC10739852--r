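test_that("quadrant gating assigns live/dead from stain intensities", {
  g <- gating_params(10, 50)
  r <- make_records(2, mean_live = c(100, 5), mean_dead = c(1, 100))
  out <- gate_viability(r, g)
  expect_identical(out$viability, c("live", "dead"))
  # bright in both stains is not live (high dead signal wins)
  r2 <- gate_viability(make_records(1, mean_live = 100, mean_dead = 100), g)
  expect_identical(r2$viability, "dead")
  # debris untouched
  r3 <- gate_viability(make_records(1, mean_live = 100, mean_dead = 1,
                                    ploidy_class = "debris"), g)
  expect_identical(r3$viability, "unassigned")
  # records without stains point at the time-lapse path
  r4 <- make_records(3, mean_live = NA_real_, mean_dead = NA_real_)
  expect_error(gate_viability(r4, g), "time-lapse")
})

test_that("auto gates split bimodal log-intensities and reject degenerates", {
  r <- make_records(100, mean_live = rep(c(10, 1000), each = 50),
                    mean_dead = rep(c(800, 8), each = 50))
  g <- auto_gates(r)
  expect_true(g$live_threshold > 10 && g$live_threshold < 1000)
  expect_true(g$dead_threshold > 8 && g$dead_threshold < 800)
  expect_identical(g$mode, "auto")
  # gating recovers the construction
  out <- gate_viability(r, g)
  expect_identical(out$viability, rep(c("dead", "live"), each = 50))
  expect_error(auto_gates(make_records(10)), "20")
  expect_error(auto_gates(make_records(30, mean_live = 5, mean_dead = 5)),
               "identical")
})

test_that("gate monotonicity: raising live_threshold never adds live cells", {
  set.seed(4)
  r <- make_records(200, mean_live = rlnorm(200, log(300), 1.5),
                    mean_dead = rlnorm(200, log(50), 1))
  n_live <- vapply(c(10, 50, 200, 1000, 5000), function(thr)
    sum(gate_viability(r, gating_params(thr, 100))$viability == "live"), 0L)
  expect_true(all(diff(n_live) <= 0))
})

test_that("area thresholds rescale with magnification squared", {
  expect_identical(threshold_for_magnification(300, 4, 10), 1875L)
  expect_identical(threshold_for_magnification(300, 4, 4), 300L)
  expect_identical(threshold_for_magnification(1875, 10, 4), 300L)
  expect_error(threshold_for_magnification(300, 0, 10), "positive")
})

test_that("threshold area converts to circle-equivalent diameter", {
  expect_equal(round(threshold_area_to_diameter(817)), 32)
  expect_equal(threshold_area_to_diameter(817), 2 * sqrt(817 / pi))
  expect_equal(threshold_area_to_diameter(817), 32.2527, tolerance = 1e-4)
  expect_equal(threshold_area_to_diameter(pi / 4), 1.0)
  expect_equal(threshold_area_to_diameter(100), 11.2838, tolerance = 1e-4)
  expect_error(threshold_area_to_diameter(0), "positive")
})

test_that("PGCC calling uses strict 'larger than' and spares dead cells", {
  cp <- class_params()  # 300 px at 4x -> 1875 px at 10x
  r <- make_records(3, area_px = c(1900L, 1875L, 5000L),
                    viability = c("live", "live", "dead"))
  out <- classify_pgcc(r, cp, magnification = 10)
  expect_identical(out$ploidy_class, c("pgcc", "non_pgcc", "unassigned"))
  expect_identical(out$viability[3], "dead")
  # physical mode ignores magnification, uses um^2 strictly
  cpp <- class_params("physical")
  rp <- make_records(2, area_um2 = c(817, 817.1), viability = "live")
  expect_identical(classify_pgcc(rp, cpp)$ploidy_class,
                   c("non_pgcc", "pgcc"))
  # errors: pixels mode without magnification; physical without pixel size
  expect_error(classify_pgcc(make_records(1, viability = "live"), cp),
               "magnification")
  expect_error(classify_pgcc(make_records(1, viability = "live"), cpp),
               "area_um2|pixel")
  # unassigned viability is a pipeline error unless assume_live
  expect_error(classify_pgcc(make_records(1), cp, magnification = 10),
               "viability")
  tl <- classify_pgcc(make_records(1, area_px = 2000L), cp,
                      magnification = 10, assume_live = TRUE)
  expect_identical(tl$viability, "live")
  expect_identical(tl$ploidy_class, "pgcc")
})

test_that("every non-debris record ends in exactly one terminal class", {
  sim <- simulate_field(small_sim(), seed = 8)
  recs <- segment_field(sim$field, seg_params(magnification = 10))
  recs <- gate_viability(recs, auto_gates(recs))
  recs <- classify_pgcc(recs, class_params(), magnification = 10)
  nd <- recs[recs$ploidy_class != "debris", ]
  is_dead <- nd$viability == "dead" & nd$ploidy_class == "unassigned"
  is_live <- nd$viability == "live" & nd$ploidy_class %in% c("pgcc", "non_pgcc")
  expect_true(all(xor(is_dead, is_live)))
})

test_that("raising the area threshold never increases the PGCC count", {
  set.seed(11)
  r <- make_records(300, area_px = as.integer(round(rlnorm(300, log(900), 0.8))),
                    viability = "live")
  n_pgcc <- vapply(c(100L, 300L, 900L, 1875L, 5000L), function(thr)
    sum(classify_pgcc(r, class_params(area_threshold_px = thr,
                                      reference_magnification = 10),
                      magnification = 10)$ploidy_class == "pgcc"), 0L)
  expect_true(all(diff(n_pgcc) <= 0))
})

test_that("pixel-mode classification is consistent across magnifications", {
  # same physical scene rendered at 4x and 10x: counts agree
  mk <- function(mag) sim_params(
    image_shape = c(512L, 512L), magnification = mag,
    n_non_pgcc = 15L, n_pgcc = 4L, n_dead = 2L, n_debris = 0L,
    include_ros = FALSE)
  counts <- lapply(c(4, 10), function(mag) {
    sim <- simulate_field(mk(mag), seed = 99)
    recs <- segment_field(sim$field, seg_params(magnification = mag))
    recs <- gate_viability(recs, auto_gates(recs))
    recs <- classify_pgcc(recs, class_params(), magnification = mag)
    s <- summarize_well(recs)
    c(s$n_non_pgcc, s$n_pgcc)
  })
  expect_identical(counts[[1]], counts[[2]])
})
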