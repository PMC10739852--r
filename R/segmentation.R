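#' Segmentation parameters
#'
#' Defaults are calibrated at 10x and scaled for other magnifications:
#' the top-hat/bottom-hat structuring-element radius scales linearly with
#' magnification (it must exceed the largest nucleus radius so whole nuclei
#' pass the top-hat), and the debris area cutoff scales with magnification
#' squared, like any area.
#'
#' @param tophat_radius_px structuring-element radius in pixels.
#' @param contrast_percentiles low/high percentiles mapped to \[0,1\] by the
#'   contrast adjustment after background correction.
#' @param binarize_method `"otsu"` (histogram between-class variance) or
#'   `"fixed"`.
#' @param fixed_threshold threshold in \[0,1\], required iff `binarize_method
#'   = "fixed"`.
#' @param min_area_px objects smaller than this are flagged as debris.
#' @param connectivity pixel connectivity for labeling, 4 or 8.
#' @param split_touching if `TRUE`, components with solidity < 0.9 are
#'   subdivided by a distance-transform watershed before labeling.
#' @param exclude_border drop components touching the image edge (partial
#'   nuclei bias area downward).
#' @param magnification objective magnification used to scale the defaults;
#'   explicit `tophat_radius_px`/`min_area_px` values override scaling.
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(tophat_radius_px = NULL,
                       contrast_percentiles = c(1, 99),
                       binarize_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       min_area_px = NULL,
                       connectivity = 8L,
                       split_touching = FALSE,
                       exclude_border = TRUE,
                       magnification = 10) {
  binarize_method <- match.arg(binarize_method)
  if (is.null(tophat_radius_px))
    tophat_radius_px <- max(1L, as.integer(round(50 * magnification / 10)))
  if (is.null(min_area_px))
    min_area_px <- max(1L, as.integer(round(50 * (magnification / 10)^2)))
  stopifnot(tophat_radius_px >= 1, min_area_px >= 1,
            length(contrast_percentiles) == 2L,
            contrast_percentiles[1] < contrast_percentiles[2],
            contrast_percentiles[1] >= 0, contrast_percentiles[2] <= 100,
            connectivity %in% c(4L, 8L))
  if (binarize_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold is required when binarize_method = 'fixed'")
  if (binarize_method == "otsu" && !is.null(fixed_threshold))
    stop("fixed_threshold is only meaningful with binarize_method = 'fixed'")
  structure(list(tophat_radius_px = as.integer(tophat_radius_px),
                 contrast_percentiles = as.numeric(contrast_percentiles),
                 binarize_method = binarize_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = as.integer(min_area_px),
                 connectivity = as.integer(connectivity),
                 split_touching = isTRUE(split_touching),
                 exclude_border = isTRUE(exclude_border)),
            class = "seg_params")
}

#' Background correction by top-hat / bottom-hat filtering
#'
#' Classic morphological contrast enhancement: the white top-hat (bright
#' features smaller than the structuring element) is added to the image and
#' the black bottom-hat (dark features) subtracted, flattening uneven
#' illumination while boosting nucleus-to-background contrast. The result is
#' then linearly rescaled so that the configured low/high intensity
#' percentiles map to \[0, 1\], and clipped. A constant image maps to all
#' zeros (the rescale is degenerate).
#'
#' @param img 2-D numeric matrix, raw camera units.
#' @param radius disc structuring-element radius in pixels (>= 1 and smaller
#'   than both image dimensions).
#' @param percentiles low/high percentiles for the contrast rescale.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
correct_background <- function(img, radius, percentiles = c(1, 99)) {
  stopifnot(is.matrix(img), length(img) > 0)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  if (radius >= min(dim(img)))
    stop("tophat radius (", radius, ") must be smaller than both image ",
         "dimensions (", paste(dim(img), collapse = "x"), ")")
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  enhanced <- img + EBImage::whiteTopHat(img, brush) -
    EBImage::blackTopHat(img, brush)
  qs <- stats::quantile(enhanced, probs = percentiles / 100, names = FALSE)
  if (qs[2] <= qs[1]) return(matrix(0, nrow(img), ncol(img)))
  clip01((enhanced - qs[1]) / (qs[2] - qs[1]))
}

#' Binarize a background-corrected image
#'
#' With `binarize_method = "otsu"` the threshold maximizes between-class
#' variance over a 256-bin histogram of the corrected image; with `"fixed"`
#' the configured threshold is applied directly. Foreground pixels are
#' nucleus candidates.
#'
#' @param img corrected image in \[0, 1\] (see [correct_background]).
#' @param params a [seg_params] object.
#' @return logical matrix (`TRUE` = foreground). A single-valued image under
#'   Otsu yields an all-background mask with a warning.
#' @export
binarize <- function(img, params = seg_params()) {
  stopifnot(is.matrix(img))
  if (params$binarize_method == "fixed")
    return(img > params$fixed_threshold)
  thr <- otsu_threshold(as.vector(img), nbins = 256L)
  if (is.na(thr)) {
    warning("image is single-valued; no Otsu threshold exists, ",
            "returning an all-background mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  img > thr
}

# Connected components at the requested connectivity. 4-connectivity is
# EBImage::bwlabel directly; 8-connectivity additionally merges labels that
# touch diagonally (components of the label-adjacency graph). Labels are
# renumbered 1..n in order of each component's smallest linear pixel index,
# which makes the output a pure function of the mask.
label_mask <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  n <- max(lab)
  if (n > 0L && connectivity == 8L) {
    edges <- integer(0)
    for (k in list(c(-1L, -1L), c(-1L, 1L))) {
      s <- shift_matrix(lab, k[1], k[2], fill = 0L)
      touch <- lab > 0L & s > 0L & lab != s
      if (any(touch)) edges <- c(edges, rbind(lab[touch], s[touch]))
    }
    if (length(edges)) {
      g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
      comp <- as.integer(igraph::components(g)$membership)
      lab[lab > 0L] <- comp[lab[lab > 0L]]
      n <- max(lab)
    }
  }
  if (n > 0L) {
    # canonical consecutive relabeling by first (column-major) pixel
    first_idx <- rep(NA_integer_, n)
    fg <- which(lab > 0L)
    l <- lab[fg]
    first_idx <- vapply(split(fg, l), min, 0L)
    ord <- order(as.integer(first_idx))
    remap <- integer(length(ord))
    remap[as.integer(names(first_idx))[ord]] <- seq_along(ord)
    lab[fg] <- remap[l]
    n <- length(ord)
  }
  storage.mode(lab) <- "integer"
  list(labels = lab, n_objects = as.integer(n))
}

solidity_of <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3L) return(1)
  pts <- cbind(cols, rows)
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  # hull over pixel centres underestimates the pixelated hull; clamp to (0,1]
  min(1, n / max(hull_area, n))
}

#' Label connected components of a nucleus mask
#'
#' Components are found under the configured connectivity. When
#' `split_touching` is set, components whose solidity falls below 0.9 (a
#' signature of merged nuclei) are subdivided by a watershed on the distance
#' transform. Components touching the image edge are removed when
#' `exclude_border` is set. Output labels are consecutive `1..n_objects`.
#'
#' @param mask logical matrix from [binarize].
#' @param params a [seg_params] object.
#' @return `list(labels, n_objects)` where `labels` is an integer matrix
#'   (0 = background).
#' @export
label_components <- function(mask, params = seg_params()) {
  li <- label_mask(mask, params$connectivity)
  lab <- li$labels
  if (params$split_touching && li$n_objects > 0L) {
    fg <- which(lab > 0L)
    coords <- arrayInd(fg, dim(lab))
    by_obj <- split(seq_along(fg), lab[fg])
    changed <- FALSE
    next_label <- li$n_objects
    for (ob in names(by_obj)) {
      sel <- by_obj[[ob]]
      sol <- solidity_of(coords[sel, 1], coords[sel, 2])
      if (sol < 0.9) {
        rr <- range(coords[sel, 1]); cc <- range(coords[sel, 2])
        sub <- matrix(0, rr[2] - rr[1] + 3L, cc[2] - cc[1] + 3L)
        sub[cbind(coords[sel, 1] - rr[1] + 2L,
                  coords[sel, 2] - cc[1] + 2L)] <- 1
        dm <- EBImage::distmap(sub)
        ws <- EBImage::watershed(dm, tolerance = 1)
        pieces <- ws[cbind(coords[sel, 1] - rr[1] + 2L,
                           coords[sel, 2] - cc[1] + 2L)]
        if (length(unique(pieces)) > 1L) {
          lab[fg[sel]] <- next_label + as.integer(pieces)
          next_label <- max(lab)
          changed <- TRUE
        }
      }
    }
    if (changed) {
      relab <- label_relabel(lab)
      lab <- relab$labels
    }
  }
  if (params$exclude_border && max(lab) > 0L) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                              lab[, 1], lab[, ncol(lab)]))
    border_labels <- border_labels[border_labels > 0L]
    if (length(border_labels)) {
      lab[lab %in% border_labels] <- 0L
      lab <- label_relabel(lab)$labels
    }
  }
  storage.mode(lab) <- "integer"
  list(labels = lab, n_objects = as.integer(max(lab)))
}

# renumber arbitrary positive labels to consecutive 1..n by first pixel index
label_relabel <- function(lab) {
  fg <- which(lab > 0L)
  if (!length(fg)) return(list(labels = lab, n_objects = 0L))
  l <- lab[fg]
  first_idx <- vapply(split(fg, l), min, 0L)
  ord <- order(as.integer(first_idx))
  remap <- integer(max(l))
  remap[as.integer(names(first_idx))[ord]] <- seq_along(ord)
  lab[fg] <- remap[l]
  list(labels = lab, n_objects = length(ord))
}

#' Extract per-nucleus records from a labeled field
#'
#' For every labeled object: pixel area, centroid (0-based mean of member
#' pixel row/col indices), physical area when the pixel size is known, mask
#' solidity, and the mean intensity of every available channel over the
#' object mask dilated by 2 px (the same dilated mask for all channels, so
#' nuclear-rim stain signal is captured consistently). Viability and ploidy
#' class start as `"unassigned"`.
#'
#' @param label_img `list(labels, n_objects)` from [label_components].
#' @param field the [mc_field] the labels were derived from.
#' @return a record table (see [empty_records]).
#' @export
extract_records <- function(label_img, field) {
  stopifnot(inherits(field, "mc_field"))
  lab <- label_img$labels
  if (!identical(dim(lab), dim(field$channels[[1]])))
    stop("label raster shape does not match channel shape")
  n <- label_img$n_objects
  if (n == 0L) return(empty_records())
  fg <- which(lab > 0L)
  l <- lab[fg]
  coords <- arrayInd(fg, dim(lab))
  area <- tabulate(l, n)
  # 0-based centroids
  cen_r <- rowsum(as.numeric(coords[, 1] - 1L), l)[, 1] / area
  cen_c <- rowsum(as.numeric(coords[, 2] - 1L), l)[, 1] / area
  sol <- vapply(seq_len(n), function(k) {
    sel <- l == k
    solidity_of(coords[sel, 1], coords[sel, 2])
  }, 0)
  dil <- dilate_labels(lab, 2L)
  fg2 <- which(dil > 0L)
  l2 <- dil[fg2]
  cnt2 <- tabulate(l2, n)
  means <- list(mean_nuclei = NA_real_, mean_live = NA_real_,
                mean_dead = NA_real_, mean_ros = NA_real_)
  nuc_channel <- if ("nuclei" %in% names(field$channels)) "nuclei" else "rfp"
  for (ch in names(field$channels)) {
    key <- if (ch == "rfp") "mean_nuclei" else paste0("mean_", ch)
    if (ch == "rfp" && "nuclei" %in% names(field$channels)) next
    means[[key]] <- rowsum(field$channels[[ch]][fg2], l2)[, 1] / cnt2
  }
  area_um2 <- if (!is.null(field$pixel_size_um))
    area * field$pixel_size_um^2 else rep(NA_real_, n)
  data.frame(field_id = rep(field$field_id, n), label = seq_len(n),
             row = cen_r, col = cen_c, area_px = as.integer(area),
             area_um2 = area_um2,
             mean_nuclei = rep_len(means$mean_nuclei, n),
             mean_live = rep_len(means$mean_live, n),
             mean_dead = rep_len(means$mean_dead, n),
             mean_ros = rep_len(means$mean_ros, n),
             viability = rep("unassigned", n),
             ploidy_class = rep("unassigned", n),
             solidity = sol, stringsAsFactors = FALSE)
}

#' Flag debris by size
#'
#' Records with `area_px < min_area_px` get `ploidy_class = "debris"` and are
#' excluded from downstream counts; all other records pass unchanged, order
#' preserved.
#'
#' @param records record table.
#' @param params a [seg_params] (supplies `min_area_px`).
#' @return the record table with debris flagged.
#' @export
filter_debris <- function(records, params = seg_params()) {
  validate_records(records)
  records$ploidy_class[records$area_px < params$min_area_px] <- "debris"
  records
}

#' Segment the nuclear channel of a field
#'
#' Convenience wrapper: background correction, binarization, labeling,
#' record extraction and debris flagging in one call. Uses the `nuclei`
#' channel when present, otherwise `rfp` (time-lapse mode).
#'
#' @param field an [mc_field].
#' @param params a [seg_params].
#' @return a record table with debris flagged.
#' @export
segment_field <- function(field, params = NULL) {
  stopifnot(inherits(field, "mc_field"))
  if (is.null(params)) params <- seg_params(magnification = field$magnification)
  nuc <- if ("nuclei" %in% names(field$channels)) "nuclei" else "rfp"
  corrected <- correct_background(field$channels[[nuc]],
                                  radius = params$tophat_radius_px,
                                  percentiles = params$contrast_percentiles)
  mask <- binarize(corrected, params)
  lab <- label_components(mask, params)
  filter_debris(extract_records(lab, field), params)
}
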