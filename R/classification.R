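#' Viability gating parameters
#'
#' Quadrant gating on Live/Dead stain intensities: a cell is live iff its
#' Live-channel mean exceeds `live_threshold` and its Dead-channel mean does
#' not exceed `dead_threshold` (high Live and low Dead).
#'
#' @param live_threshold Live-channel threshold (camera units).
#' @param dead_threshold Dead-channel threshold (camera units).
#' @param mode `"fixed"` (user-supplied) or `"auto"` (from [auto_gates]).
#' @return a list of class `gating_params`.
#' @export
gating_params <- function(live_threshold, dead_threshold, mode = "fixed") {
  stopifnot(mode %in% c("fixed", "auto"))
  if (mode == "fixed" &&
      (!is.numeric(live_threshold) || live_threshold <= 0 ||
       !is.numeric(dead_threshold) || dead_threshold <= 0))
    stop("fixed gating thresholds must be positive")
  structure(list(live_threshold = live_threshold,
                 dead_threshold = dead_threshold, mode = mode),
            class = "gating_params")
}

#' Derive viability gates automatically
#'
#' Per-channel thresholds are the Otsu split of `log10(intensity + 1)`
#' across the supplied records (deterministic for fixed input). Intended to
#' be run on pooled control-well records; fixed gates override.
#'
#' @param records record table with `mean_live` and `mean_dead`.
#' @return a [gating_params] with `mode = "auto"`.
#' @export
auto_gates <- function(records) {
  validate_records(records)
  ok <- !is.na(records$mean_live) & !is.na(records$mean_dead)
  if (sum(ok) < 20L)
    stop("auto gating needs at least 20 records with Live/Dead ",
         "intensities; use fixed gates (gating_params()) instead")
  thr <- vapply(c("mean_live", "mean_dead"), function(ch) {
    t_log <- otsu_threshold(log10(records[[ch]][ok] + 1), nbins = 256L)
    if (is.na(t_log))
      stop("all ", ch, " intensities identical; no auto gate exists - ",
           "use fixed gates")
    10^t_log - 1
  }, 0)
  gating_params(thr[[1]], thr[[2]], mode = "auto")
}

#' Assign viability from Live/Dead intensities
#'
#' `viability = "live"` iff `mean_live > live_threshold` and
#' `mean_dead <= dead_threshold`; otherwise `"dead"`. Debris records are
#' untouched.
#'
#' @param records record table.
#' @param gates a [gating_params].
#' @return records with viability assigned.
#' @export
gate_viability <- function(records, gates) {
  validate_records(records)
  stopifnot(inherits(gates, "gating_params"))
  if (nrow(records) == 0L) return(records)
  if (all(is.na(records$mean_live)) || all(is.na(records$mean_dead)))
    stop("records carry no Live/Dead intensities; for time-lapse data ",
         "use count_frames()/classify_pgcc(assume_live = TRUE) instead")
  sel <- records$ploidy_class != "debris"
  live <- records$mean_live > gates$live_threshold &
    records$mean_dead <= gates$dead_threshold
  records$viability[sel] <- ifelse(live[sel], "live", "dead")
  records
}

#' PGCC classification parameters
#'
#' Two equivalent ways to express the nuclear-area threshold separating
#' PGCCs from non-PGCCs: a pixel area at a reference magnification
#' (300 px at 4x, equivalently 1875 px at 10x), rescaled to the working
#' magnification by [threshold_for_magnification]; or a physical area in
#' square micrometres (817 um^2, a circle of ~32 um diameter), which is
#' magnification-independent and preferred whenever the pixel size is known.
#'
#' @param threshold_mode `"pixels"` or `"physical"`.
#' @param area_threshold_px pixel-area threshold at `reference_magnification`.
#' @param reference_magnification magnification the pixel threshold refers to.
#' @param area_threshold_um2 physical-area threshold (um^2).
#' @return a list of class `class_params`.
#' @export
class_params <- function(threshold_mode = c("pixels", "physical"),
                         area_threshold_px = 300L,
                         reference_magnification = 4,
                         area_threshold_um2 = 817) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(area_threshold_px >= 1, reference_magnification > 0,
            area_threshold_um2 > 0)
  structure(list(threshold_mode = threshold_mode,
                 area_threshold_px = as.integer(area_threshold_px),
                 reference_magnification = reference_magnification,
                 area_threshold_um2 = area_threshold_um2),
            class = "class_params")
}

#' Rescale a pixel-area threshold between objective magnifications
#'
#' Areas scale with the square of the linear magnification ratio:
#' a 300-px threshold at 4x becomes `round(300 * (10/4)^2) = 1875` px at 10x.
#'
#' @param base_px pixel-area threshold at `base_mag`.
#' @param base_mag magnification `base_px` refers to.
#' @param target_mag magnification to convert to.
#' @return integer pixel-area threshold at `target_mag`.
#' @export
threshold_for_magnification <- function(base_px, base_mag, target_mag) {
  if (!all(c(base_px, base_mag, target_mag) > 0))
    stop("all arguments must be positive")
  as.integer(round(base_px * (target_mag / base_mag)^2))
}

#' Circle-equivalent diameter of an area threshold
#'
#' @param area_um2 area in square micrometres (> 0).
#' @return diameter (um) of the circle with that area, `2 * sqrt(area / pi)`.
#' @export
threshold_area_to_diameter <- function(area_um2) {
  if (!is.numeric(area_um2) || any(area_um2 <= 0))
    stop("area_um2 must be positive")
  2 * sqrt(area_um2 / pi)
}

#' Classify live cells as PGCC or non-PGCC by nuclear area
#'
#' Among live, non-debris records: `ploidy_class = "pgcc"` iff the nuclear
#' area strictly exceeds the resolved threshold ("larger than" - a nucleus
#' exactly at the threshold is a non-PGCC), else `"non_pgcc"`. Dead cells
#' are a terminal class: their nuclear size is never interpreted as ploidy.
#' Debris keeps its class.
#'
#' @param records record table with viability assigned (or
#'   `assume_live = TRUE`).
#' @param params a [class_params].
#' @param magnification working magnification (required in pixels mode).
#' @param assume_live treat all non-debris records as live (time-lapse mode,
#'   where viability staining is not used); sets their viability to "live".
#' @return records with ploidy class assigned.
#' @export
classify_pgcc <- function(records, params = class_params(),
                          magnification = NULL, assume_live = FALSE) {
  validate_records(records)
  stopifnot(inherits(params, "class_params"))
  if (nrow(records) == 0L) return(records)
  not_debris <- records$ploidy_class != "debris"
  if (assume_live) records$viability[not_debris] <- "live"
  if (any(not_debris & records$viability == "unassigned"))
    stop("records have unassigned viability; run gate_viability() first ",
         "or use assume_live = TRUE")
  if (params$threshold_mode == "pixels") {
    if (is.null(magnification))
      stop("pixels mode needs the working magnification")
    thr <- threshold_for_magnification(params$area_threshold_px,
                                       params$reference_magnification,
                                       magnification)
    area <- records$area_px
  } else {
    if (anyNA(records$area_um2[not_debris]))
      stop("physical mode needs area_um2 (pixel size unknown?)")
    thr <- params$area_threshold_um2
    area <- records$area_um2
  }
  live <- not_debris & records$viability == "live"
  records$ploidy_class[live] <- ifelse(area[live] > thr, "pgcc", "non_pgcc")
  records
}

# Resolve the working pixel-area threshold for a magnification (used by the
# time-lapse transition detector and the simulator's truth tables).
resolve_threshold_px <- function(params, magnification) {
  if (params$threshold_mode == "pixels")
    threshold_for_magnification(params$area_threshold_px,
                                params$reference_magnification, magnification)
  else stop("resolve_threshold_px applies to pixels mode")
}
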