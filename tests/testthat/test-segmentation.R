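test_that("background correction flattens backgrounds and boosts contrast", {
  # constant image -> degenerate rescale maps to 0
  expect_equal(correct_background(matrix(7, 40, 40), 5),
               matrix(0, 40, 40))
  # radius must fit in the image
  expect_error(correct_background(matrix(1, 30, 30), 30), "radius")
  # bright disk on a linear ramp: contrast (disk mean / background mean)
  # must increase relative to the input, computed numerically here
  H <- 120; ramp <- outer(seq(100, 300, length.out = H), rep(1, H))
  disk <- matrix(0, H, H)
  cc <- as.matrix(expand.grid(r = 1:H, c = 1:H))
  inside <- (cc[, 1] - 60)^2 + (cc[, 2] - 60)^2 <= 8^2
  disk[cc[inside, ]] <- 400
  img <- ramp + disk
  out <- correct_background(img, 20)
  in_contrast <- mean(img[disk > 0]) / mean(img[disk == 0])
  out_contrast <- mean(out[disk > 0]) / max(mean(out[disk == 0]), 1e-9)
  expect_gt(out_contrast, in_contrast)
  expect_true(all(out >= 0 & out <= 1))
  expect_gt(mean(out[disk > 0]), mean(out[disk == 0]))
})

test_that("binarization thresholds two-level and fixed-threshold images", {
  sq <- matrix(0.1, 50, 50); sq[20:30, 20:30] <- 0.9
  expect_identical(binarize(sq, seg_params()), sq == 0.9)
  p <- seg_params(binarize_method = "fixed", fixed_threshold = 0.5)
  img <- matrix(c(0.4, 0.6), 10, 10)
  expect_identical(binarize(img, p), img == 0.6)
  expect_warning(m <- binarize(matrix(0.3, 20, 20), seg_params()),
                 "single-valued")
  expect_false(any(m))
})

test_that("labeling matches the flood-fill oracle on random masks", {
  p4 <- seg_params(connectivity = 4L, exclude_border = FALSE)
  p8 <- seg_params(connectivity = 8L, exclude_border = FALSE)
  set.seed(123)
  for (i in 1:100) {
    mask <- matrix(runif(256) < 0.4, 16, 16)
    for (p in list(p4, p8)) {
      got <- label_components(mask, p)
      want <- flood_label(mask, p$connectivity)
      expect_identical(canon_labels(got$labels), canon_labels(want))
      expect_identical(got$n_objects, max(want))
    }
  }
})

test_that("connectivity conventions agree on canonical shapes", {
  # two disjoint squares
  m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE; m[7:9, 7:9] <- TRUE
  expect_identical(label_components(m, seg_params(exclude_border = FALSE))$n_objects, 2L)
  # plus-shape is one object under both connectivities
  pl <- matrix(FALSE, 7, 7); pl[4, 3:5] <- TRUE; pl[3:5, 4] <- TRUE
  for (conn in c(4L, 8L))
    expect_identical(label_components(
      pl, seg_params(connectivity = conn, exclude_border = FALSE))$n_objects, 1L)
  # diagonal touch merges under 8 but not 4
  dg <- matrix(FALSE, 6, 6); dg[2, 2] <- TRUE; dg[3, 3] <- TRUE
  expect_identical(label_components(
    dg, seg_params(connectivity = 4L, exclude_border = FALSE))$n_objects, 2L)
  expect_identical(label_components(
    dg, seg_params(connectivity = 8L, exclude_border = FALSE))$n_objects, 1L)
  # empty mask
  expect_identical(label_components(matrix(FALSE, 5, 5),
                                    seg_params())$n_objects, 0L)
})

test_that("border exclusion and watershed splitting act as configured", {
  m <- matrix(FALSE, 12, 12); m[1:3, 5:7] <- TRUE; m[6:8, 5:7] <- TRUE
  expect_identical(label_components(m, seg_params(exclude_border = TRUE))$n_objects, 1L)
  expect_identical(label_components(m, seg_params(exclude_border = FALSE))$n_objects, 2L)
  # two overlapping discs form a low-solidity dumbbell; splitting recovers 2
  H <- 40; cc <- as.matrix(expand.grid(r = 1:H, c = 1:H))
  dumb <- matrix(FALSE, H, H)
  dumb[cc[(cc[, 1] - 20)^2 + (cc[, 2] - 13)^2 <= 49, ]] <- TRUE
  dumb[cc[(cc[, 1] - 20)^2 + (cc[, 2] - 27)^2 <= 49, ]] <- TRUE
  expect_identical(label_components(dumb, seg_params(split_touching = FALSE))$n_objects, 1L)
  split <- label_components(dumb, seg_params(split_touching = TRUE))
  expect_identical(split$n_objects, 2L)
})

test_that("record extraction measures area, centroid and channel means", {
  lab <- matrix(0L, 20, 20); lab[5:6, 5:9] <- 1L  # 10-px rectangle
  live <- matrix(7, 20, 20)
  f <- mc_field(list(nuclei = matrix(100, 20, 20), live = live),
                magnification = 10)
  r <- extract_records(list(labels = lab, n_objects = 1L), f)
  expect_identical(nrow(r), 1L)
  expect_identical(r$area_px, 10L)
  expect_equal(r$mean_live, 7)
  expect_equal(r$row, mean(c(4, 5)))   # 0-based centroid
  expect_equal(r$col, mean(4:8))
  expect_true(is.na(r$area_um2))      # no pixel size given
  expect_identical(r$viability, "unassigned")
  # physical area: 1875 px at 0.66 um/px -> 816.75 um^2
  f2 <- mc_field(list(nuclei = matrix(100, 50, 50)), magnification = 10,
                 pixel_size_um = 0.66)
  lab2 <- matrix(0L, 50, 50); lab2[which(lab2 == 0L)[1:1875]] <- 1L
  r2 <- extract_records(list(labels = lab2, n_objects = 1L), f2)
  expect_equal(r2$area_um2, 1875 * 0.66^2)
  expect_equal(r2$area_um2, 816.75)
  expect_error(extract_records(list(labels = lab, n_objects = 1L), f2),
               "shape")
})

test_that("debris flagging is a pure size rule", {
  r <- make_records(2, area_px = c(10L, 400L))
  p <- seg_params(min_area_px = 50L)
  out <- filter_debris(r, p)
  expect_identical(out$ploidy_class, c("debris", "unassigned"))
  out1 <- filter_debris(r, seg_params(min_area_px = 1L))
  expect_identical(out1$ploidy_class, c("unassigned", "unassigned"))
  # monotonicity: raising the cutoff never reduces the debris count
  set.seed(9)
  areas <- as.integer(sample(1:500, 60))
  recs <- make_records(60, area_px = areas)
  counts <- vapply(c(1L, 25L, 50L, 100L, 250L), function(m)
    sum(filter_debris(recs, seg_params(min_area_px = m))$ploidy_class ==
          "debris"), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("segmentation is translation-equivariant and conserves objects", {
  sim <- simulate_field(small_sim(), seed = 21)
  p <- seg_params(magnification = 10)
  recs <- segment_field(sim$field, p)
  expect_identical(nrow(recs),
                   sum(recs$ploidy_class == "debris") +
                     sum(recs$ploidy_class != "debris"))
  # shift all channels by (5, 3); centroids shift exactly, areas unchanged
  shift <- function(m, dr, dc) {
    out <- matrix(median(m), nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  chs <- lapply(sim$field$channels, shift, dr = 5, dc = 3)
  f2 <- mc_field(chs, magnification = 10, pixel_size_um = 0.66)
  recs2 <- segment_field(f2, p)
  ord1 <- order(recs$row, recs$col); ord2 <- order(recs2$row, recs2$col)
  expect_identical(nrow(recs), nrow(recs2))
  expect_equal(recs2$row[ord2], recs$row[ord1] + 5, tolerance = 1e-8)
  expect_equal(recs2$col[ord2], recs$col[ord1] + 3, tolerance = 1e-8)
  expect_identical(recs2$area_px[ord2], recs$area_px[ord1])
})

test_that("segmentation recovers simulated nuclei masks and areas", {
  sim <- simulate_field(sim_params(include_ros = FALSE), seed = 31)
  f <- sim$field
  corr <- correct_background(f$channels$nuclei, 50)
  mask <- binarize(corr, seg_params())
  # Jaccard against the true nucleus mask (rebuild from truth: all
  # non-debris ellipse pixels; debris too small to matter either way)
  recs <- segment_field(f, seg_params(magnification = 10))
  cells <- recs[recs$ploidy_class != "debris", ]
  truth <- sim$truth[sim$truth$class != "debris", ]
  # match each truth object to nearest record centroid
  d2 <- outer(truth$row, cells$row, "-")^2 + outer(truth$col, cells$col, "-")^2
  nearest <- apply(d2, 1, which.min)
  expect_identical(anyDuplicated(nearest), 0L)  # one-to-one
  rel_err <- abs(cells$area_px[nearest] - truth$true_area_px) /
    truth$true_area_px
  expect_gte(mean(rel_err <= 0.15), 0.95)
  # mask-level Jaccard via total areas of matched objects is implied by the
  # per-object bound; also check pixelwise against a rendered truth mask
  lab_true <- matrix(FALSE, nrow(f$channels$nuclei), ncol(f$channels$nuclei))
  px <- 0.66
  for (i in seq_len(nrow(truth))) {
    a <- truth$diameter_um[i] / 2 / sqrt(truth$axis_ratio[i]) / px
    b <- truth$diameter_um[i] / 2 * sqrt(truth$axis_ratio[i]) / px
    idx <- pgccscope:::ellipse_pixels(truth$centre_row[i] + 1,
                                      truth$centre_col[i] + 1,
                                      a, b, truth$theta[i], nrow(lab_true),
                                      ncol(lab_true))
    lab_true[idx] <- TRUE
  }
  jac <- sum(mask & lab_true) / sum(mask | lab_true)
  expect_gte(jac, 0.8)
})
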