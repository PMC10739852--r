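CHANNEL_NAMES <- c("nuclei", "live", "dead", "ros", "rfp")

# Map common filter-set / stain synonyms onto the canonical channel names.
CHANNEL_SYNONYMS <- c(
  nuclei = "nuclei", hoechst = "nuclei", dapi = "nuclei", blue = "nuclei",
  live = "live", fitc = "live", calcein = "live", green = "live",
  dead = "dead", tritc = "dead", ethidium = "dead", red = "dead",
  ros = "ros", cy5 = "ros", cellrox = "ros", deepred = "ros",
  rfp = "rfp", dsred = "rfp", nucrfp = "rfp")

normalize_channel_name <- function(name) {
  key <- gsub("[^a-z0-9]", "", tolower(name))
  if (!key %in% names(CHANNEL_SYNONYMS))
    stop("unknown channel name '", name, "'; expected one of: ",
         paste(unique(names(CHANNEL_SYNONYMS)), collapse = ", "))
  unname(CHANNEL_SYNONYMS[key])
}

#' Construct a multichannel field
#'
#' A field is a set of co-registered single-plane channel rasters plus
#' acquisition metadata. Channel names are normalized to the canonical set
#' `nuclei`, `live`, `dead`, `ros`, `rfp` (stain/filter synonyms such as
#' "hoechst", "fitc", "tritc", "cy5" are accepted). Intensities are kept in
#' raw camera units; no rescaling happens at construction or load time so
#' that gating thresholds stay interpretable against the raw stains.
#'
#' @param channels named list of numeric matrices, all the same dimensions.
#' @param magnification objective magnification (e.g. 4 or 10).
#' @param pixel_size_um optional physical pixel side in micrometres.
#' @param field_id opaque identifier.
#' @param timestamp optional acquisition time in minutes.
#' @return an object of class `mc_field`.
#' @export
mc_field <- function(channels, magnification, pixel_size_um = NULL,
                     field_id = "field", timestamp = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  names(channels) <- vapply(names(channels), normalize_channel_name, "")
  if (anyDuplicated(names(channels)))
    stop("duplicate channel after name normalization")
  if (!any(c("nuclei", "rfp") %in% names(channels)))
    stop("a nuclear channel ('nuclei' or 'rfp') is required")
  if (!is.numeric(magnification) || length(magnification) != 1L ||
      magnification <= 0)
    stop("magnification must be a positive scalar")
  if (!is.null(pixel_size_um) &&
      (!is.numeric(pixel_size_um) || pixel_size_um <= 0))
    stop("pixel_size_um must be a positive scalar")
  ref <- dim(channels[[1]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop("channel '", nm, "' is not a numeric matrix")
    if (!identical(dim(ch), ref))
      stop("channel '", nm, "' has shape ", paste(dim(ch), collapse = "x"),
           " but expected ", paste(ref, collapse = "x"))
    if (any(ch < 0, na.rm = TRUE))
      stop("channel '", nm, "' contains negative intensities")
    storage.mode(channels[[nm]]) <- "double"
  }
  structure(list(channels = channels, magnification = magnification,
                 pixel_size_um = pixel_size_um, field_id = field_id,
                 timestamp = timestamp),
            class = "mc_field")
}

#' @export
print.mc_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<mc_field> ", x$field_id, ": ", d[1], "x", d[2], " px, ",
      length(x$channels), " channel(s) [",
      paste(names(x$channels), collapse = ", "), "], ",
      x$magnification, "x objective",
      if (!is.null(x$pixel_size_um))
        paste0(", ", x$pixel_size_um, " um/px"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.mc_field <- function(x) dim(x$channels[[1]])

#' Read a multichannel field from single-plane TIFF files
#'
#' Each channel is loaded at native bit depth and stored as a double matrix
#' without any intensity rescaling (`tiff::readTIFF(as.is = TRUE)`).
#'
#' @param paths named character vector or list, channel name -> TIFF path.
#' @param magnification objective magnification.
#' @param pixel_size_um optional physical pixel size (um).
#' @param field_id identifier attached to the field.
#' @param timestamp optional acquisition time in minutes.
#' @return an [mc_field] object.
#' @export
read_field <- function(paths, magnification, pixel_size_um = NULL,
                       field_id = "field", timestamp = NULL) {
  paths <- unlist(paths)
  stopifnot(length(paths) >= 1L, !is.null(names(paths)))
  channels <- list()
  for (nm in names(paths)) {
    p <- paths[[nm]]
    img <- tryCatch(tiff::readTIFF(p, as.is = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", p, "' (channel '", nm,
                           "'): ", conditionMessage(e), call. = FALSE))
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] != 1L)
        stop("TIFF '", p, "' is not single-plane grayscale")
      img <- img[, , 1]
    }
    storage.mode(img) <- "double"
    channels[[nm]] <- img
  }
  mc_field(channels, magnification = magnification,
           pixel_size_um = pixel_size_um, field_id = field_id,
           timestamp = timestamp)
}

#' Write a field's channels as 16-bit grayscale TIFFs
#'
#' Intensities are rounded, clipped to the 16-bit sensor range and written
#' one file per channel. Reading the files back with [read_field] reproduces
#' the (rounded) arrays exactly.
#'
#' @param field an [mc_field].
#' @param paths named vector, channel name -> destination path.
#' @return invisibly, the paths written.
#' @export
write_field <- function(field, paths) {
  stopifnot(inherits(field, "mc_field"))
  paths <- unlist(paths)
  for (nm in names(paths)) {
    cn <- normalize_channel_name(nm)
    if (!cn %in% names(field$channels))
      stop("field has no channel '", cn, "'")
    img <- pmin(pmax(round(field$channels[[cn]]), 0), 65535)
    tiff::writeTIFF(img / 65535, paths[[nm]], bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(paths)
}
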