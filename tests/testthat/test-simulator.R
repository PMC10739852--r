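test_that("simulation is deterministic and leaves the caller's RNG alone", {
  p <- small_sim()
  a <- simulate_field(p, seed = 5)
  set.seed(999); marker <- runif(1)
  b <- simulate_field(p, seed = 5)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
  # different seed differs
  c2 <- simulate_field(p, seed = 6)
  expect_false(identical(a$field$channels$nuclei, c2$field$channels$nuclei))
  # caller RNG stream unaffected by the simulation
  set.seed(999)
  expect_identical(runif(1), marker)
})

test_that("an empty scene renders pure background", {
  p <- sim_params(image_shape = c(128L, 128L), n_non_pgcc = 0L, n_pgcc = 0L,
                  n_dead = 0L, n_debris = 0L, include_ros = FALSE)
  sim <- simulate_field(p, seed = 1)
  expect_identical(nrow(sim$truth), 0L)
  # no nucleus: intensities stay near the background pedestal
  expect_lt(max(sim$field$channels$nuclei), 500)
})

test_that("rendered geometry matches the closed-form ellipse area", {
  p <- sim_params(image_shape = c(256L, 256L), n_non_pgcc = 0L, n_pgcc = 1L,
                  n_dead = 0L, n_debris = 0L, include_ros = FALSE,
                  pgcc_diameter_um = c(40, 1e-6), axis_ratio_range = c(1, 1))
  sim <- simulate_field(p, seed = 2)
  tr <- sim$truth
  expect_equal(tr$true_area_um2, pi * 20^2, tolerance = 1e-3)
  # rendered pixel count approximates the continuous area (quantization)
  expect_equal(tr$true_area_px, pi * (20 / 0.66)^2, tolerance = 0.02)
  expect_equal(tr$diameter_um, 40, tolerance = 1e-3)
})

test_that("placement honours minimum separation and the image border", {
  p <- sim_params(image_shape = c(512L, 512L), n_non_pgcc = 30L,
                  n_pgcc = 5L, n_dead = 0L, n_debris = 0L,
                  include_ros = FALSE, min_separation_um = 4)
  sim <- simulate_field(p, seed = 3)
  tr <- sim$truth
  px <- p$pixel_size_um
  a_px <- tr$diameter_um / 2 / sqrt(tr$axis_ratio) / px
  d <- as.matrix(dist(cbind(tr$centre_row, tr$centre_col)))
  req <- outer(a_px, a_px, "+") + 4 / px
  diag(d) <- Inf
  expect_true(all(d >= req - 1e-9))
  # an impossible request fails with advice
  bad <- sim_params(image_shape = c(128L, 128L), n_pgcc = 60L)
  expect_error(simulate_field(bad, seed = 1), "larger image")
})

test_that("plate simulation writes a readable plate whose manifest echoes the plan", {
  td <- withr::local_tempdir()
  compounds <- data.frame(compound = "pk", non_pgcc_mult = 1, pgcc_mult = 0.1)
  mp <- simulate_plate(file.path(td, "pl"), compounds,
                       base_params = small_sim(), n_replicates = 2L,
                       seed = 4)
  expect_true(file.exists(mp$layout_path))
  man <- mp$manifest
  expect_identical(length(man), 4L)  # 2 conditions x 2 replicates
  pk <- Filter(function(w) w$condition == "pk", man)
  for (w in pk) {
    expect_equal(w$pgcc_mult, 0.1)
    expect_equal(w$expected$pgcc, small_sim()$n_pgcc * 0.1)
  }
  entries <- read_plate(mp$layout_path, file.path(td, "pl"))
  expect_identical(length(entries), 4L)
  expect_identical(vapply(entries, `[[`, "", "well_id"),
                   sort(vapply(entries, `[[`, "", "well_id")))
  # plate regeneration is deterministic
  mp2 <- simulate_plate(file.path(td, "pl2"), compounds,
                        base_params = small_sim(), n_replicates = 2L,
                        seed = 4)
  f1 <- read_field(c(nuclei = file.path(td, "pl", "A01_nuclei.tif")), 10)
  f2 <- read_field(c(nuclei = file.path(td, "pl2", "A01_nuclei.tif")), 10)
  expect_identical(f1$channels, f2$channels)
})

test_that("scripted time-lapse transitions cross the threshold on schedule", {
  p <- sim_params(image_shape = c(448L, 448L), n_non_pgcc = 12L, n_pgcc = 0L,
                  n_dead = 0L, n_debris = 0L)
  sim <- simulate_timelapse(p, n_frames = 8L, n_transitions = 3L,
                            transition_frames = c(3L, 5L, 6L), seed = 7)
  expect_identical(nrow(sim$transitions), 3L)
  expect_identical(sort(sim$transitions$frame), c(3L, 5L, 6L))
  thr <- threshold_for_magnification(300, 4, 10)
  for (k in seq_len(3)) {
    id <- sim$transitions$id[k]; fc <- sim$transitions$frame[k]
    tr <- sim$truth[sim$truth$id == id, ]
    expect_true(all(tr$class[tr$frame < fc] == "non_pgcc"))
    expect_true(all(tr$class[tr$frame >= fc] == "pgcc"))
    # decisive crossing: areas clear the threshold by a wide margin
    expect_lt(max(tr$true_area_px[tr$frame < fc]), thr * 0.9)
    expect_gt(min(tr$true_area_px[tr$frame >= fc]), thr * 1.1)
  }
  # zero growth, zero motion -> all frames identical
  still <- simulate_timelapse(p, n_frames = 3L, n_transitions = 0L,
                              motion_sigma_um = 0, seed = 8)
  expect_identical(still$frames[[1]]$channels$rfp,
                   still$frames[[2]]$channels$rfp)
  expect_identical(still$frames[[2]]$channels$rfp,
                   still$frames[[3]]$channels$rfp)
})

test_that("death schedules remove cells from rendering", {
  p <- sim_params(image_shape = c(384L, 384L), n_non_pgcc = 6L, n_pgcc = 0L,
                  n_dead = 0L, n_debris = 0L)
  sim <- simulate_timelapse(p, n_frames = 4L, n_transitions = 0L,
                            death_frames = c(`2` = 3L),
                            motion_sigma_um = 0, seed = 9)
  tr <- sim$truth
  expect_identical(tr$class[tr$id == 2 & tr$frame >= 3], rep("gone", 2))
  expect_identical(tr$class[tr$id == 2 & tr$frame < 3], rep("non_pgcc", 2))
})
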