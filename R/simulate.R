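#' Simulation parameters for synthetic fluorescence fields
#'
#' The simulator renders fields of elliptical nuclei with class-dependent
#' size and intensity distributions over a smooth background, blurred by a
#' Gaussian PSF, with optional Poisson shot noise and Gaussian read noise -
#' emulating a Hoechst / Calcein-AM / Ethidium-homodimer (/ CellROX) assay
#' on a 16-bit monochrome camera.
#'
#' Diameters are *area-equivalent* diameters (an ellipse with axis ratio q
#' gets semi-axes `d/2/sqrt(q)` and `d/2*sqrt(q)`, so its area is exactly
#' `pi (d/2)^2`). Class size distributions are log-normal, truncated away
#' from an ambiguity band around the 32 um threshold diameter (non-PGCC
#' below 28 um, PGCC above 36 um) so that ground-truth class labels are
#' well-defined; real populations overlap the threshold, which this
#' validation simulator deliberately does not model.
#'
#' @param image_shape `(H, W)` in pixels.
#' @param magnification objective magnification.
#' @param pixel_size_um physical pixel size; default is the magnification
#'   preset (0.66 um at 10x).
#' @param n_non_pgcc,n_pgcc,n_dead,n_debris object counts per class.
#' @param non_pgcc_diameter_um,pgcc_diameter_um `c(median, sdlog)` of the
#'   log-normal area-equivalent diameter (um) per class.
#' @param axis_ratio_range uniform range of the minor/major axis ratio.
#' @param min_separation_um minimum boundary-to-boundary gap between nuclei.
#' @param amp named list of `c(median, sdlog)` log-normal amplitudes
#'   (camera units above background): `nuclei`, `live_live` (Live channel,
#'   live cells), `live_dead`, `dead_dead`, `dead_live`, `ros`, `debris`.
#' @param debris_diameter_px uniform range of debris speck diameters
#'   (pixels; debris is rendered bright, like condensed chromatin
#'   fragments, and is excluded downstream purely by its size).
#' @param ros_fold_pgcc median ROS amplitude ratio, PGCC / non-PGCC.
#' @param psf_sigma_px Gaussian PSF sigma in pixels.
#' @param background `list(base, slope_max, blob_amplitude, blob_sigma_px)`;
#'   the background is `base + random plane + one low-frequency Gaussian
#'   blob`, per channel scaled by `channel_base_scale`.
#' @param read_noise_sd Gaussian read noise sd (camera units).
#' @param shot_noise apply Poisson shot noise.
#' @param amplitude_factor multiplies nuclear-stain amplitudes (emulates
#'   staining concentration).
#' @param gain_factor multiplies all channel intensities before noise
#'   (emulates exposure/gain).
#' @param include_ros render the ROS channel.
#' @param sensor_max clip level (16-bit camera).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(image_shape = c(1024L, 1024L),
                       magnification = 10,
                       pixel_size_um = pixel_size_preset(magnification),
                       n_non_pgcc = 90L, n_pgcc = 10L, n_dead = 5L,
                       n_debris = 10L,
                       non_pgcc_diameter_um = c(15, 0.15),
                       pgcc_diameter_um = c(40, 0.10),
                       axis_ratio_range = c(0.7, 1),
                       min_separation_um = 4,
                       amp = list(nuclei = c(3000, 0.15),
                                  live_live = c(2500, 0.2),
                                  live_dead = c(60, 0.2),
                                  dead_dead = c(2500, 0.2),
                                  dead_live = c(60, 0.2),
                                  ros = c(600, 0.25),
                                  debris = c(4000, 0.1)),
                       debris_diameter_px = c(3.5, 5),
                       ros_fold_pgcc = 3,
                       psf_sigma_px = 1.5,
                       background = list(base = 100, slope_max = 0.02,
                                         blob_amplitude = 30,
                                         blob_sigma_px = 150),
                       read_noise_sd = 5,
                       shot_noise = TRUE,
                       amplitude_factor = 1,
                       gain_factor = 1,
                       include_ros = TRUE,
                       sensor_max = 65535) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32),
            magnification > 0, pixel_size_um > 0,
            n_non_pgcc >= 0, n_pgcc >= 0, n_dead >= 0, n_debris >= 0,
            all(non_pgcc_diameter_um > 0), all(pgcc_diameter_um > 0),
            min_separation_um >= 0, ros_fold_pgcc > 0, psf_sigma_px > 0,
            amplitude_factor > 0, gain_factor > 0)
  structure(as.list(environment()), class = "sim_params")
}

# truncated log-normal draw (resample until inside (lo, hi))
rlnorm_trunc <- function(n, median, sdlog, lo = 0, hi = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rlnorm(length(need), meanlog = log(median), sdlog = sdlog)
    ok <- x > lo & x < hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Rejection-sampled, grid-accelerated placement of circles with per-object
# radius `r` (px), boundary gap `sep` (px) and border margin `margin` (px).
place_objects <- function(H, W, r, sep, margin, max_tries = 500L) {
  n <- length(r)
  cell <- max(2 * max(r) + sep, 1)
  gr <- ceiling(H / cell); gc <- ceiling(W / cell)
  grid <- vector("list", gr * gc)
  pos <- matrix(NA_real_, n, 2)
  ord <- order(r, decreasing = TRUE)  # place large objects first
  for (i in ord) {
    lo_r <- margin[i]; hi_r <- H - margin[i]
    lo_c <- margin[i]; hi_c <- W - margin[i]
    if (hi_r <= lo_r || hi_c <= lo_c)
      stop("image too small for an object of radius ", r[i], " px")
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      rr <- stats::runif(1, lo_r, hi_r); cc <- stats::runif(1, lo_c, hi_c)
      gi <- floor(rr / cell); gj <- floor(cc / cell)
      ok <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        ii <- gi + di; jj <- gj + dj
        if (ii < 0 || jj < 0 || ii >= gr || jj >= gc) next
        for (k in grid[[ii * gc + jj + 1L]]) {
          if (sqrt((rr - pos[k, 1])^2 + (cc - pos[k, 2])^2) <
              r[i] + r[k] + sep) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        pos[i, ] <- c(rr, cc)
        idx <- gi * gc + gj + 1L
        grid[[idx]] <- c(grid[[idx]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place object ", i, " after ", max_tries,
           " attempts; use a larger image or fewer/smaller objects")
  }
  pos
}

# Rasterize an ellipse; returns linear indices (column-major) of member
# pixels. Centre (cr, cc) in 1-based pixel coordinates.
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  rmax <- max(a, b)
  r0 <- max(1L, floor(cr - rmax)); r1 <- min(H, ceiling(cr + rmax))
  c0 <- max(1L, floor(cc - rmax)); c1 <- min(W, ceiling(cc + rmax))
  rs <- r0:r1; cs <- c0:c1
  dr <- rs - cr; dc <- cs - cc
  DR <- matrix(dr, length(rs), length(cs))
  DC <- matrix(dc, length(rs), length(cs), byrow = TRUE)
  u <- (DR * cos(theta) + DC * sin(theta)) / a
  v <- (-DR * sin(theta) + DC * cos(theta)) / b
  inside <- which(u * u + v * v <= 1)
  if (!length(inside)) return(integer(0))
  ri <- ((inside - 1L) %% length(rs)) + r0
  ci <- ((inside - 1L) %/% length(rs)) + c0
  (ci - 1L) * H + ri
}

# background model: base*scale + random plane + one Gaussian blob
render_background <- function(H, W, bg, scale = 1) {
  sx <- stats::runif(1, -bg$slope_max, bg$slope_max)
  sy <- stats::runif(1, -bg$slope_max, bg$slope_max)
  br <- stats::runif(1, 0.2 * H, 0.8 * H); bc <- stats::runif(1, 0.2 * W, 0.8 * W)
  amp <- bg$blob_amplitude * stats::runif(1, 0.5, 1.5)
  rowv <- (seq_len(H) - 1)
  colv <- (seq_len(W) - 1)
  plane <- outer(rowv * sy, colv * sx, "+") + bg$base * scale
  blob <- amp * outer(exp(-(rowv + 1 - br)^2 / (2 * bg$blob_sigma_px^2)),
                      exp(-(colv + 1 - bc)^2 / (2 * bg$blob_sigma_px^2)))
  plane + blob
}

apply_camera <- function(signal, p) {
  x <- signal * p$gain_factor
  x[x < 0] <- 0
  if (p$shot_noise) x <- matrix(stats::rpois(length(x), x), nrow(x))
  if (p$read_noise_sd > 0)
    x <- x + stats::rnorm(length(x), 0, p$read_noise_sd)
  matrix(pmin(pmax(round(x), 0), p$sensor_max), nrow(x))
}

#' Simulate one multichannel fluorescence field with ground truth
#'
#' Renders non-PGCC, PGCC and dead nuclei plus sub-debris-size specks (see
#' [sim_params] for the full generative model). Live-channel amplitudes are
#' bright for live cells and dim for dead cells, the Dead channel is the
#' reverse, and ROS amplitudes for PGCCs are `ros_fold_pgcc` times the
#' non-PGCC median. Identical parameters and seed give bit-identical output
#' (Mersenne-Twister / inversion sampling, fixed at call time).
#'
#' @param params a [sim_params].
#' @param seed integer RNG seed.
#' @param field_id identifier for the generated field.
#' @param nuclear_channel `"nuclei"` (screening) or `"rfp"` (time-lapse; no
#'   Live/Dead/ROS channels are rendered then).
#' @param timestamp optional field timestamp (minutes).
#' @return `list(field, truth)`: the [mc_field] and the per-object ground
#'   truth (`id`, `class`, `row`, `col` 0-based centre, `diameter_um`,
#'   `true_area_px` exact rendered mask area, `true_area_um2` continuous
#'   ellipse area, per-channel amplitudes).
#' @export
simulate_field <- function(params = sim_params(), seed = 1L,
                           field_id = "sim", nuclear_channel = "nuclei",
                           timestamp = NULL) {
  stopifnot(inherits(params, "sim_params"),
            nuclear_channel %in% c("nuclei", "rfp"))
  with_seed(seed, {
    scene <- sample_scene(params)
    render_scene(scene, params, field_id, nuclear_channel, timestamp)
  })
}

# Draw classes, sizes, shapes, positions and amplitudes (no rendering).
sample_scene <- function(params) {
  p <- params
  cls <- c(rep("non_pgcc", p$n_non_pgcc), rep("pgcc", p$n_pgcc),
           rep("dead", p$n_dead), rep("debris", p$n_debris))
  n <- length(cls)
  px <- p$pixel_size_um
  H <- p$image_shape[1]; W <- p$image_shape[2]
  d_um <- numeric(n)
  d_um[cls == "non_pgcc"] <- rlnorm_trunc(p$n_non_pgcc,
    p$non_pgcc_diameter_um[1], p$non_pgcc_diameter_um[2], hi = 28)
  d_um[cls == "dead"] <- rlnorm_trunc(p$n_dead,
    p$non_pgcc_diameter_um[1], p$non_pgcc_diameter_um[2], hi = 28)
  d_um[cls == "pgcc"] <- rlnorm_trunc(p$n_pgcc,
    p$pgcc_diameter_um[1], p$pgcc_diameter_um[2], lo = 36)
  d_um[cls == "debris"] <- stats::runif(p$n_debris, p$debris_diameter_px[1],
                                        p$debris_diameter_px[2]) * px
  q <- stats::runif(n, p$axis_ratio_range[1], p$axis_ratio_range[2])
  theta <- stats::runif(n, 0, pi)
  a <- (d_um / 2) / sqrt(q) / px   # semi-major, px
  b <- (d_um / 2) * sqrt(q) / px   # semi-minor, px
  blur_margin <- ceiling(3 * p$psf_sigma_px) + 3
  if (n > 0) {
    pos <- place_objects(H, W, r = a, sep = p$min_separation_um / px,
                         margin = a + blur_margin)
  } else pos <- matrix(numeric(0), 0, 2)
  amp_of <- function(spec, n) if (n > 0)
    stats::rlnorm(n, log(spec[1]), spec[2]) else numeric(0)
  amp_nuclei <- numeric(n)
  amp_nuclei[cls != "debris"] <- amp_of(p$amp$nuclei, sum(cls != "debris"))
  amp_nuclei[cls == "debris"] <- amp_of(p$amp$debris, sum(cls == "debris"))
  amp_nuclei <- amp_nuclei * p$amplitude_factor
  dead <- cls == "dead"
  amp_live <- numeric(n); amp_dead <- numeric(n)
  amp_live[!dead] <- amp_of(p$amp$live_live, sum(!dead))
  amp_live[dead] <- amp_of(p$amp$live_dead, sum(dead))
  amp_dead[dead] <- amp_of(p$amp$dead_dead, sum(dead))
  amp_dead[!dead] <- amp_of(p$amp$dead_live, sum(!dead))
  amp_ros <- amp_of(p$amp$ros, n)
  amp_ros[cls == "pgcc"] <- amp_ros[cls == "pgcc"] * p$ros_fold_pgcc
  list(cls = cls, d_um = d_um, q = q, theta = theta, a = a, b = b,
       pos = pos, amp_nuclei = amp_nuclei, amp_live = amp_live,
       amp_dead = amp_dead, amp_ros = amp_ros)
}

render_scene <- function(scene, params, field_id, nuclear_channel = "nuclei",
                         timestamp = NULL, alive = NULL) {
  p <- params
  H <- p$image_shape[1]; W <- p$image_shape[2]
  n <- length(scene$cls)
  if (is.null(alive)) alive <- rep(TRUE, n)
  nuc <- matrix(0, H, W)
  with_live <- nuclear_channel == "nuclei"
  if (with_live) { live <- matrix(0, H, W); deadm <- matrix(0, H, W) }
  if (with_live && p$include_ros) ros <- matrix(0, H, W)
  true_area_px <- integer(n)
  cen_r <- rep(NA_real_, n); cen_c <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    idx <- ellipse_pixels(scene$pos[i, 1], scene$pos[i, 2],
                          scene$a[i], scene$b[i], scene$theta[i], H, W)
    true_area_px[i] <- length(idx)
    if (!length(idx)) next
    ri <- ((idx - 1L) %% H) + 1L
    ci <- ((idx - 1L) %/% H) + 1L
    cen_r[i] <- mean(ri - 1L); cen_c[i] <- mean(ci - 1L)
    nuc[idx] <- nuc[idx] + scene$amp_nuclei[i]
    if (with_live) {
      live[idx] <- live[idx] + scene$amp_live[i]
      deadm[idx] <- deadm[idx] + scene$amp_dead[i]
      if (p$include_ros) ros[idx] <- ros[idx] + scene$amp_ros[i]
    }
  }
  blur <- function(m) EBImage::gblur(m, sigma = p$psf_sigma_px)
  channels <- list()
  channels[[nuclear_channel]] <- apply_camera(
    blur(nuc) + render_background(H, W, p$background, 1), p)
  if (with_live) {
    channels$live <- apply_camera(
      blur(live) + render_background(H, W, p$background, 0.8), p)
    channels$dead <- apply_camera(
      blur(deadm) + render_background(H, W, p$background, 0.8), p)
    if (p$include_ros)
      channels$ros <- apply_camera(
        blur(ros) + render_background(H, W, p$background, 0.9), p)
  }
  field <- mc_field(channels, magnification = p$magnification,
                    pixel_size_um = p$pixel_size_um, field_id = field_id,
                    timestamp = timestamp)
  truth <- data.frame(
    id = seq_len(n), class = scene$cls, row = cen_r, col = cen_c,
    diameter_um = scene$d_um, axis_ratio = scene$q, theta = scene$theta,
    centre_row = scene$pos[, 1] - 1, centre_col = scene$pos[, 2] - 1,
    true_area_px = true_area_px,
    true_area_um2 = pi * (scene$d_um / 2)^2,
    amp_nuclei = scene$amp_nuclei, amp_live = scene$amp_live,
    amp_dead = scene$amp_dead, amp_ros = scene$amp_ros,
    alive = alive, stringsAsFactors = FALSE)
  list(field = field, truth = truth)
}

#' Simulate a screening plate on disk
#'
#' Writes per-well channel TIFFs, a layout YAML readable by [read_plate],
#' and a JSON manifest with per-well ground truth. Per-well seeds are
#' derived deterministically from the master seed and well id, so plate
#' generation does not depend on iteration order.
#'
#' Compound effects are planted as multipliers on the expected class counts
#' (e.g. a PGCC-only killer has `pgcc_mult = 0.1`, `non_pgcc_mult = 1`);
#' realized per-well counts are Poisson draws around the scaled
#' expectations (well-to-well biological variability).
#'
#' @param out_dir output directory (created).
#' @param compounds data.frame with columns `compound`, `non_pgcc_mult`,
#'   `pgcc_mult` (and optionally `dead_mult`).
#' @param base_params [sim_params] for a control well; its counts are the
#'   control expectations.
#' @param n_replicates wells per condition (control included).
#' @param seed master seed.
#' @return invisibly, `list(layout_path, manifest_path, manifest)`.
#' @export
simulate_plate <- function(out_dir, compounds, base_params = sim_params(),
                           n_replicates = 3L, seed = 1L) {
  stopifnot(is.data.frame(compounds),
            all(c("compound", "non_pgcc_mult", "pgcc_mult") %in%
                  names(compounds)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- rbind(
    data.frame(compound = "control", non_pgcc_mult = 1, pgcc_mult = 1,
               dead_mult = 1, stringsAsFactors = FALSE),
    data.frame(compound = compounds$compound,
               non_pgcc_mult = compounds$non_pgcc_mult,
               pgcc_mult = compounds$pgcc_mult,
               dead_mult = compounds$dead_mult %||% rep(1, nrow(compounds)),
               stringsAsFactors = FALSE))
  n_wells <- nrow(conds) * n_replicates
  well_ids <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12)
  if (n_wells > 96)
    well_ids <- sprintf("W%03d", seq_len(n_wells))
  well_ids <- well_ids[seq_len(n_wells)]
  wells_yaml <- list(); manifest <- list()
  k <- 0L
  for (ci in seq_len(nrow(conds))) for (rep_i in seq_len(n_replicates)) {
    k <- k + 1L
    wid <- well_ids[k]
    wseed <- derive_seed(seed, wid)
    p <- base_params
    expected <- c(non_pgcc = p$n_non_pgcc * conds$non_pgcc_mult[ci],
                  pgcc = p$n_pgcc * conds$pgcc_mult[ci],
                  dead = p$n_dead * conds$dead_mult[ci])
    realized <- with_seed(derive_seed(wseed, "counts"), {
      stats::rpois(3, expected)
    })
    p$n_non_pgcc <- realized[1]; p$n_pgcc <- realized[2]
    p$n_dead <- realized[3]
    sim <- simulate_field(p, seed = wseed, field_id = wid)
    files <- c(nuclei = paste0(wid, "_nuclei.tif"),
               live = paste0(wid, "_live.tif"),
               dead = paste0(wid, "_dead.tif"))
    if (p$include_ros) files <- c(files, ros = paste0(wid, "_ros.tif"))
    write_field(sim$field, stats::setNames(file.path(out_dir, files),
                                           names(files)))
    wells_yaml[[k]] <- list(
      well = wid, condition = conds$compound[ci],
      compound = conds$compound[ci],
      concentration = if (conds$compound[ci] == "control") 0 else 1e-6,
      replicate = rep_i, images = as.list(files))
    manifest[[wid]] <- list(
      well = wid, condition = conds$compound[ci], seed = wseed,
      non_pgcc_mult = conds$non_pgcc_mult[ci],
      pgcc_mult = conds$pgcc_mult[ci],
      expected = as.list(expected),
      truth_counts = list(non_pgcc = realized[1], pgcc = realized[2],
                          dead = realized[3], debris = p$n_debris))
  }
  layout <- list(
    plate = list(magnification = base_params$magnification,
                 pixel_size_um = base_params$pixel_size_um,
                 control_condition = "control"),
    wells = wells_yaml)
  layout_path <- file.path(out_dir, "layout.yaml")
  yaml::write_yaml(layout, layout_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(layout_path = layout_path, manifest_path = manifest_path,
                 manifest = manifest))
}

#' Simulate count-level screening data (no imaging)
#'
#' Companion to [simulate_plate] for statistical validation at scale:
#' per-well class counts are drawn directly as Poisson variables around
#' control expectations scaled by planted compound multipliers, skipping
#' rendering and segmentation. Useful for null calibration of the
#' per-compound tests over thousands of simulated compounds.
#'
#' @param compounds data.frame (`compound`, `non_pgcc_mult`, `pgcc_mult`);
#'   multipliers of 1 everywhere give pure null compounds.
#' @param control_mean_non_pgcc,control_mean_pgcc control expectations.
#' @param n_replicates wells per condition.
#' @param seed RNG seed.
#' @return a per-well summary data.frame ready for [compare_conditions]
#'   (control condition is `"control"`).
#' @export
simulate_screen_counts <- function(compounds,
                                   control_mean_non_pgcc = 100,
                                   control_mean_pgcc = 25,
                                   n_replicates = 3L, seed = 1L) {
  conds <- rbind(data.frame(compound = "control", non_pgcc_mult = 1,
                            pgcc_mult = 1, stringsAsFactors = FALSE),
                 compounds[, c("compound", "non_pgcc_mult", "pgcc_mult")])
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(conds)), function(ci) {
      data.frame(
        well_id = sprintf("%s_r%d", conds$compound[ci],
                          seq_len(n_replicates)),
        condition = conds$compound[ci], compound = conds$compound[ci],
        concentration = if (conds$compound[ci] == "control") 0 else 1e-6,
        n_non_pgcc = stats::rpois(n_replicates,
                                  control_mean_non_pgcc * conds$non_pgcc_mult[ci]),
        n_pgcc = stats::rpois(n_replicates,
                              control_mean_pgcc * conds$pgcc_mult[ci]),
        n_dead = 0L, n_debris = 0L, pgcc_fraction = NA_real_,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Type-I error calibration of the per-compound tests
#'
#' Simulates inactive compounds - per compound, fresh control and treated
#' wells all drawn i.i.d. from the control count distribution - runs
#' [compare_conditions] on each, and reports the fraction of individual
#' endpoint tests (non-PGCC and PGCC count comparisons) rejecting at
#' `alpha`. For a calibrated procedure this fraction is close to `alpha`.
#' Controls are redrawn per compound: the rate measures the test procedure,
#' not one particular control draw.
#'
#' @param n_compounds number of simulated inactive compounds.
#' @param control_mean_non_pgcc,control_mean_pgcc Poisson means of the
#'   control well counts.
#' @param n_replicates wells per condition.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rejection_rate` (per-test), `flagged_rate`
#'   (compound-level, any non-inactive category) and the p-value matrix.
#' @export
null_calibration <- function(n_compounds = 1000L,
                             control_mean_non_pgcc = 100,
                             control_mean_pgcc = 25,
                             n_replicates = 3L, alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    res <- vapply(seq_len(n_compounds), function(i) {
      mk <- function(cond, conc) data.frame(
        well_id = paste0(cond, "_r", seq_len(n_replicates)),
        condition = cond, compound = cond, concentration = conc,
        n_non_pgcc = stats::rpois(n_replicates, control_mean_non_pgcc),
        n_pgcc = stats::rpois(n_replicates, control_mean_pgcc),
        n_dead = 0L, n_debris = 0L, pgcc_fraction = NA_real_,
        stringsAsFactors = FALSE)
      eff <- compare_conditions(rbind(mk("control", 0), mk("cmp", 1e-6)),
                                "control", alpha = alpha)
      c(eff$p_non_pgcc, eff$p_pgcc, as.numeric(eff$category != "inactive"))
    }, numeric(3))
    list(rejection_rate = mean(res[1:2, ] < alpha),
         flagged_rate = mean(res[3, ] > 0),
         p_values = t(res[1:2, , drop = FALSE]))
  })
}

#' Simulate a nuclear-RFP time-lapse sequence with scripted transitions
#'
#' Cells carry a nuclear-RFP label and are imaged at a fixed interval.
#' Scheduled cells cross the PGCC threshold by geometric growth of the
#' area-equivalent diameter (`d(f) = 32 * growth_factor^(f - f_cross + 1/2)`
#' um, clamped between the cell's initial diameter and `d_max_um`), so the
#' crossing frame is decisive: one frame before the scheduled crossing the
#' area is well below threshold, at the crossing frame well above. Centroids
#' take Gaussian steps per frame. Scheduled deaths remove the cell from
#' rendering.
#'
#' @param params a [sim_params]; `n_non_pgcc`/`n_pgcc` set the initial
#'   population (debris/dead are rendered static, usually 0 here).
#' @param n_frames number of frames.
#' @param interval_min acquisition interval in minutes.
#' @param n_transitions number of non-PGCCs scheduled to become PGCCs
#'   (crossing frames sampled uniformly over the middle of the sequence
#'   unless `transition_frames` is given).
#' @param transition_frames optional explicit crossing frames (1-based).
#' @param death_frames optional named/indexed vector: cell id -> frame at
#'   which the cell disappears.
#' @param motion_sigma_um per-frame centroid step sd (um).
#' @param growth_factor per-frame diameter growth through the crossing.
#' @param d_max_um diameter cap after transition.
#' @param seed RNG seed.
#' @return `list(frames, truth, transitions)`: the [mc_field] frames (rfp
#'   channel), per-frame truth (`frame`, `time`, `id`, `class` by true area
#'   vs. threshold, `row`, `col`, `true_area_px`), and the scheduled
#'   transitions (`id`, `frame`, `time`).
#' @export
simulate_timelapse <- function(params = sim_params(n_pgcc = 0L, n_dead = 0L,
                                                   n_debris = 0L),
                               n_frames = 48L, interval_min = 30,
                               n_transitions = 0L,
                               transition_frames = NULL,
                               death_frames = NULL,
                               motion_sigma_um = 0.3,
                               growth_factor = 1.25,
                               d_max_um = 48,
                               seed = 1L) {
  p <- params
  px <- p$pixel_size_um
  thr_px <- threshold_for_magnification(300L, 4, p$magnification)
  with_seed(seed, {
    scene <- sample_scene(p)
    n <- length(scene$cls)
    n_cand <- which(scene$cls == "non_pgcc")
    stopifnot(n_transitions <= length(n_cand))
    trans_ids <- if (n_transitions > 0)
      sort(sample(n_cand, n_transitions)) else integer(0)
    if (is.null(transition_frames)) {
      lo <- max(2L, ceiling(n_frames * 0.15))
      hi <- max(lo, floor(n_frames * 0.85))
      transition_frames <- if (n_transitions > 0)
        sample(lo:hi, n_transitions, replace = TRUE) else integer(0)
    }
    stopifnot(length(transition_frames) == n_transitions,
              all(transition_frames >= 1), all(transition_frames <= n_frames))
    f_cross <- rep(NA_integer_, n)
    f_cross[trans_ids] <- transition_frames
    dies <- rep(NA_integer_, n)
    if (!is.null(death_frames)) dies[as.integer(names(death_frames))] <-
      as.integer(death_frames)
    # grow the placement margin so transitioned cells stay inside the border
    grow_max <- (d_max_um / 2) / sqrt(min(p$axis_ratio_range)) / px
    blur_margin <- ceiling(3 * p$psf_sigma_px) + 3
    # re-place with margins for final size (transitioning cells only)
    r_final <- scene$a
    r_final[trans_ids] <- pmax(r_final[trans_ids], grow_max)
    scene$pos <- place_objects(p$image_shape[1], p$image_shape[2],
                               r = r_final, sep = p$min_separation_um / px,
                               margin = r_final + blur_margin)
    motion_px <- motion_sigma_um / px
    render_seed <- derive_seed(seed, "render")
    frames <- vector("list", n_frames)
    truth_rows <- vector("list", n_frames)
    pos0 <- scene$pos
    d0 <- scene$d_um
    for (f in seq_len(n_frames)) {
      if (f > 1L && motion_px > 0) {
        step <- matrix(stats::rnorm(2 * n, 0, motion_px), n, 2)
        newpos <- scene$pos + step
        lo <- r_final + blur_margin
        newpos[, 1] <- pmin(pmax(newpos[, 1], lo), p$image_shape[1] - lo)
        newpos[, 2] <- pmin(pmax(newpos[, 2], lo), p$image_shape[2] - lo)
        scene$pos <- newpos
      }
      d_f <- d0
      for (i in trans_ids) {
        d_f[i] <- min(d_max_um,
                      max(d0[i], 32 * growth_factor^(f - f_cross[i] + 0.5)))
      }
      scene$d_um <- d_f
      scene$a <- (d_f / 2) / sqrt(scene$q) / px
      scene$b <- (d_f / 2) * sqrt(scene$q) / px
      alive <- is.na(dies) | f < dies
      # frozen per-sequence render stream: the background/noise draw is
      # re-seeded identically each frame, so a static scene renders
      # bit-identical frames (noise is correlated across frames by design)
      sim <- with_seed(render_seed,
        render_scene(scene, p, field_id = sprintf("frame%03d", f),
                     nuclear_channel = "rfp",
                     timestamp = (f - 1) * interval_min, alive = alive))
      frames[[f]] <- sim$field
      tr <- sim$truth
      tr$frame <- f; tr$time <- (f - 1) * interval_min
      tr$class <- ifelse(!tr$alive, "gone",
                         ifelse(tr$class == "debris", "debris",
                                ifelse(tr$true_area_px > thr_px,
                                       "pgcc", "non_pgcc")))
      truth_rows[[f]] <- tr[, c("frame", "time", "id", "class", "row",
                                "col", "true_area_px")]
    }
    transitions <- data.frame(id = trans_ids,
                              frame = f_cross[trans_ids],
                              time = (f_cross[trans_ids] - 1) * interval_min)
    list(frames = frames, truth = do.call(rbind, truth_rows),
         transitions = transitions)
  })
}

#' Robustness sweep over staining amplitude and exposure gain
#'
#' Re-simulates the same scene under multiplicative perturbations of the
#' nuclear-stain amplitude and of the camera gain, runs the full
#' segmentation / gating / classification pipeline on each rendered field,
#' and reports recovered class counts per condition - mirroring the
#' experimental claim that the analysis is insensitive to staining
#' concentration and exposure.
#'
#' @param params base [sim_params].
#' @param amp_factors staining amplitude multipliers.
#' @param gain_factors exposure gain multipliers.
#' @param seed scene seed (the same scene is re-rendered per condition).
#' @param cparams a [class_params].
#' @return data.frame of recovered counts per (amp, gain) combination with
#'   percentage deviations from the unperturbed condition.
#' @export
robustness_sweep <- function(params = sim_params(),
                             amp_factors = c(0.5, 1, 2),
                             gain_factors = c(0.5, 1, 2),
                             seed = 1L, cparams = class_params()) {
  combos <- expand.grid(amp = amp_factors, gain = gain_factors)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    p <- params
    p$amplitude_factor <- combos$amp[k]
    p$gain_factor <- combos$gain[k]
    sim <- simulate_field(p, seed = seed)
    recs <- segment_field(sim$field,
                          seg_params(magnification = p$magnification))
    recs <- gate_viability(recs, auto_gates(recs))
    recs <- classify_pgcc(recs, cparams, magnification = p$magnification)
    s <- summarize_well(recs, well_id = sprintf("amp%g_gain%g",
                                                combos$amp[k], combos$gain[k]))
    cbind(data.frame(amp_factor = combos$amp[k],
                     gain_factor = combos$gain[k]),
          s[, c("n_non_pgcc", "n_pgcc", "n_dead", "n_debris")])
  })
  out <- do.call(rbind, rows)
  ref <- out[out$amp_factor == 1 & out$gain_factor == 1, ]
  if (nrow(ref) == 1L) {
    for (col in c("n_non_pgcc", "n_pgcc")) {
      out[[paste0("pct_change_", col)]] <-
        100 * (out[[col]] - ref[[col]]) / max(ref[[col]], 1L)
    }
  }
  out
}
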