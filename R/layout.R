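#' Read a plate layout file
#'
#' The layout is a human-editable YAML file with a `plate` block (shared
#' acquisition metadata) and a `wells` list, one entry per well:
#'
#' ```yaml
#' plate:
#'   magnification: 10
#'   pixel_size_um: 0.66          # optional
#'   control_condition: control
#' wells:
#'   - well: A01
#'     condition: control
#'     compound: DMSO
#'     concentration: 0           # molar; 0 for vehicle control
#'     replicate: 1
#'     images:
#'       nuclei: A01_nuclei.tif
#'       live:   A01_live.tif
#'       dead:   A01_dead.tif
#' ```
#'
#' @param path path to the layout YAML.
#' @return a list with `magnification`, `pixel_size_um`,
#'   `control_condition`, and `wells` (a data.frame with one row per well,
#'   images attached as a list-column of named channel -> path vectors).
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$plate) || is.null(y$wells))
    stop("layout must contain 'plate' and 'wells' blocks")
  plate <- y$plate
  if (is.null(plate$magnification) || plate$magnification <= 0)
    stop("plate.magnification must be a positive scalar")
  if (is.null(plate$control_condition))
    stop("plate.control_condition is required")
  wells <- y$wells
  ids <- vapply(wells, function(w) as.character(w$well %||% ""), "")
  if (any(ids == "")) stop("every well entry needs a 'well' id")
  if (anyDuplicated(ids))
    stop("duplicate well id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  conc <- vapply(wells, function(w) as.numeric(w$concentration %||% 0), 0)
  if (any(conc < 0)) stop("concentrations must be >= 0")
  df <- data.frame(
    well_id = ids,
    condition = vapply(wells, function(w) as.character(w$condition %||% w$compound %||% "unknown"), ""),
    compound = vapply(wells, function(w) as.character(w$compound %||% w$condition %||% "unknown"), ""),
    concentration = conc,
    replicate = vapply(wells, function(w) as.integer(w$replicate %||% 1L), 1L),
    stringsAsFactors = FALSE)
  df$images <- lapply(wells, function(w) {
    if (is.null(w$images) || !length(w$images))
      stop("well ", w$well, " has no images")
    unlist(w$images)
  })
  # deterministic iteration order: sorted well id
  df <- df[order(df$well_id), , drop = FALSE]
  rownames(df) <- NULL
  if (!plate$control_condition %in% df$condition)
    stop("control_condition '", plate$control_condition,
         "' appears in no well")
  all_paths <- unlist(lapply(seq_len(nrow(df)), function(i)
    paste(df$well_id[i], names(df$images[[i]]), df$images[[i]], sep = ":")))
  if (anyDuplicated(all_paths))
    stop("duplicate (well, channel, path) entries in layout")
  list(magnification = as.numeric(plate$magnification),
       pixel_size_um = if (!is.null(plate$pixel_size_um))
         as.numeric(plate$pixel_size_um) else NULL,
       control_condition = as.character(plate$control_condition),
       wells = df)
}

#' Read all fields of a plate
#'
#' Iterates wells in sorted well-id order (re-running on identical inputs
#' yields identical output ordering) and loads each well's channels.
#'
#' @param layout_path path to the layout YAML (see [read_layout]).
#' @param image_root directory that image paths in the layout are relative to.
#' @return a list of entries, each `list(well_id, condition, compound,
#'   concentration, replicate, field)`.
#' @export
read_plate <- function(layout_path, image_root) {
  layout <- read_layout(layout_path)
  wells <- layout$wells
  lapply(seq_len(nrow(wells)), function(i) {
    imgs <- wells$images[[i]]
    paths <- file.path(image_root, imgs)
    names(paths) <- names(imgs)
    missing <- !file.exists(paths)
    if (any(missing))
      stop("well ", wells$well_id[i], ": missing image file(s) for channel(s) ",
           paste(names(paths)[missing], collapse = ", "), call. = FALSE)
    field <- read_field(paths, magnification = layout$magnification,
                        pixel_size_um = layout$pixel_size_um,
                        field_id = wells$well_id[i])
    list(well_id = wells$well_id[i], condition = wells$condition[i],
         compound = wells$compound[i],
         concentration = wells$concentration[i],
         replicate = wells$replicate[i], field = field)
  })
}
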