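#' Process a screening plate end to end
#'
#' For every well (in sorted well-id order): load channels, correct the
#' nuclear-channel background, binarize, label, extract records, flag
#' debris, gate viability, classify PGCCs, and summarize. Treated conditions
#' are then compared against control. Outputs are computed fully in memory
#' and written only after every well succeeded, so a failing well leaves no
#' partial outputs behind; errors carry the well id.
#'
#' Viability gates default to automatic Otsu gates derived from the pooled
#' control-well records; pass a fixed [gating_params] to override.
#'
#' @param layout_path plate layout YAML (see [read_layout]).
#' @param image_root directory containing the well images.
#' @param out_dir output directory; receives `records.csv`,
#'   `summaries.csv`, `effects.csv` and `run_metadata.json`.
#' @param params optional [seg_params] (default derives from the layout's
#'   magnification).
#' @param cparams a [class_params].
#' @param gates optional fixed [gating_params].
#' @param alpha significance level for [compare_conditions].
#' @param adjust `"none"` or `"BH"`.
#' @param seed recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return invisibly, `list(records, summaries, effects)`.
#' @export
process_plate <- function(layout_path, image_root, out_dir,
                          params = NULL, cparams = class_params(),
                          gates = NULL, alpha = 0.05,
                          adjust = c("none", "BH"), seed = NULL) {
  adjust <- match.arg(adjust)
  layout <- read_layout(layout_path)
  if (is.null(params)) params <- seg_params(magnification = layout$magnification)
  entries <- read_plate(layout_path, image_root)
  per_well <- lapply(entries, function(e) {
    tryCatch(segment_field(e$field, params),
             error = function(err)
               stop("well ", e$well_id, ": ", conditionMessage(err),
                    call. = FALSE))
  })
  if (is.null(gates)) {
    ctrl <- which(vapply(entries, function(e)
      e$condition == layout$control_condition, TRUE))
    pooled <- do.call(rbind, per_well[ctrl])
    gates <- auto_gates(pooled)
  }
  records <- list(); summaries <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    r <- tryCatch({
      r <- gate_viability(per_well[[i]], gates)
      classify_pgcc(r, cparams, magnification = layout$magnification)
    }, error = function(err)
      stop("well ", e$well_id, ": ", conditionMessage(err), call. = FALSE))
    records[[i]] <- r
    summaries[[i]] <- summarize_well(r, well_id = e$well_id,
                                     condition = e$condition,
                                     compound = e$compound,
                                     concentration = e$concentration)
  }
  records <- do.call(rbind, records)
  summaries <- do.call(rbind, summaries)
  effects <- compare_conditions(summaries, layout$control_condition,
                                alpha = alpha, adjust = adjust)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_records(records, file.path(out_dir, "records.csv"))
  write_summaries(summaries, file.path(out_dir, "summaries.csv"))
  write_csv_full(effects, file.path(out_dir, "effects.csv"))
  meta <- list(
    package = "pgccscope",
    version = as.character(utils::packageVersion("pgccscope")),
    layout = normalizePath(layout_path),
    magnification = layout$magnification,
    pixel_size_um = layout$pixel_size_um,
    seg_params = unclass(params),
    class_params = unclass(cparams),
    gates = unclass(gates),
    alpha = alpha, adjust = adjust, seed = seed)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(records = records, summaries = summaries,
                 effects = effects))
}
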