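RECORD_COLUMNS <- c("field_id", "label", "row", "col", "area_px", "area_um2",
                    "mean_nuclei", "mean_live", "mean_dead", "mean_ros",
                    "viability", "ploidy_class", "solidity")

RECORD_CLASSES <- c(field_id = "character", label = "integer",
                    row = "numeric", col = "numeric", area_px = "integer",
                    area_um2 = "numeric", mean_nuclei = "numeric",
                    mean_live = "numeric", mean_dead = "numeric",
                    mean_ros = "numeric", viability = "character",
                    ploidy_class = "character", solidity = "numeric")

#' An empty per-nucleus record table
#'
#' One row per detected nucleus: label, centroid (0-based row/col of the
#' pixel-centre mean), area in pixels and (when the pixel size is known)
#' square micrometres, per-channel mean intensities over the 2-px-dilated
#' nucleus mask, viability (`live`/`dead`/`unassigned`), ploidy class
#' (`pgcc`/`non_pgcc`/`debris`/`unassigned`) and mask solidity.
#'
#' @return a zero-row data.frame with the canonical record columns.
#' @export
empty_records <- function() {
  df <- as.data.frame(
    stats::setNames(lapply(RECORD_CLASSES, function(cl) vector(cl, 0L)),
                    RECORD_COLUMNS),
    stringsAsFactors = FALSE)
  df
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing))
    stop("record table is missing columns: ", paste(missing, collapse = ", "))
  records
}

# Format numerics at full double precision so CSV round-trips are lossless.
fmt_full <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else x
}

write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out)) out[[nm]] <- fmt_full(out[[nm]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write per-nucleus records to CSV
#'
#' Floats are written at full precision; [read_records] reproduces the table
#' exactly (lossless round-trip).
#'
#' @param records a record table (see [empty_records] for the schema).
#' @param path destination CSV path.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  write_csv_full(records[, RECORD_COLUMNS], path)
}

#' Read per-nucleus records from CSV
#' @param path CSV written by [write_records].
#' @return record table with canonical column types.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, colClasses = RECORD_CLASSES,
                        stringsAsFactors = FALSE)
  validate_records(df)
}

SUMMARY_COLUMNS <- c("well_id", "condition", "compound", "concentration",
                     "n_non_pgcc", "n_pgcc", "n_dead", "n_debris",
                     "pgcc_fraction")

SUMMARY_CLASSES <- c(well_id = "character", condition = "character",
                     compound = "character", concentration = "numeric",
                     n_non_pgcc = "integer", n_pgcc = "integer",
                     n_dead = "integer", n_debris = "integer",
                     pgcc_fraction = "numeric")

#' Write per-well summaries to CSV (lossless round-trip)
#' @param summaries data.frame of [summarize_well] rows.
#' @param path destination CSV path.
#' @export
write_summaries <- function(summaries, path) {
  missing <- setdiff(SUMMARY_COLUMNS, names(summaries))
  if (length(missing))
    stop("summary table is missing columns: ", paste(missing, collapse = ", "))
  write_csv_full(summaries[, SUMMARY_COLUMNS], path)
}

#' Read per-well summaries from CSV
#' @param path CSV written by [write_summaries].
#' @export
read_summaries <- function(path) {
  utils::read.csv(path, colClasses = SUMMARY_CLASSES, stringsAsFactors = FALSE)
}
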