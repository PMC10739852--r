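#' Summarize a well's classified records
#'
#' Counts non-PGCCs, PGCCs, dead cells and debris. Any non-debris record
#' still carrying an unassigned viability or ploidy class is a pipeline
#' misuse and raises an error.
#'
#' @param records classified record table for one well.
#' @param well_id,condition,compound,concentration well annotation.
#' @return one-row data.frame with counts and `pgcc_fraction`
#'   (`n_pgcc / (n_pgcc + n_non_pgcc)`, `NA` when no live cells).
#' @export
summarize_well <- function(records, well_id = "well", condition = "unknown",
                           compound = condition, concentration = NA_real_) {
  validate_records(records)
  bad <- records$ploidy_class == "unassigned" |
    (records$ploidy_class != "debris" & records$viability == "unassigned")
  # dead records legitimately keep ploidy "unassigned"? no: dead is terminal,
  # ploidy stays "unassigned" only via classify_pgcc -> treat dead as valid
  bad <- bad & !(records$viability == "dead" & records$ploidy_class == "unassigned")
  if (any(bad))
    stop("well ", well_id, ": ", sum(bad), " record(s) with unassigned ",
         "class; run gate_viability() and classify_pgcc() first")
  n_debris <- sum(records$ploidy_class == "debris")
  dead <- records$viability == "dead" & records$ploidy_class != "debris"
  n_dead <- sum(dead)
  n_pgcc <- sum(records$ploidy_class == "pgcc")
  n_non <- sum(records$ploidy_class == "non_pgcc")
  data.frame(well_id = well_id, condition = condition, compound = compound,
             concentration = concentration,
             n_non_pgcc = as.integer(n_non), n_pgcc = as.integer(n_pgcc),
             n_dead = as.integer(n_dead), n_debris = as.integer(n_debris),
             pgcc_fraction = if (n_pgcc + n_non > 0)
               n_pgcc / (n_pgcc + n_non) else NA_real_,
             stringsAsFactors = FALSE)
}

# Pooled-variance two-sided t-test that degrades gracefully when both
# groups are (near-)constant: identical means -> p = 1, different -> p = 0.
lsd_t_test <- function(x, y) {
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  if (sp2 <= .Machine$double.eps * max(abs(c(x, y, 1)))^2) {
    return(list(p.value = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0,
                estimate = c(mean(x), mean(y))))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(p.value = ht$p.value, estimate = unname(ht$estimate))
}

#' Compare treated conditions against control (LSD-style)
#'
#' Per compound, two two-sided unpaired pooled-variance t-tests (Fisher's
#' LSD flavour: no multiplicity correction by default) compare non-PGCC and
#' PGCC counts against the control wells. The compound category combines the
#' directions of the significant differences:
#' significant decrease in both counts -> `kills_both`; in PGCCs only ->
#' `kills_pgcc_only`; a significant PGCC increase -> `induces_pgcc`;
#' a decrease in non-PGCCs only -> `kills_non_pgcc_only`; else `inactive`.
#'
#' @param summaries data.frame of per-well summaries (replicated wells).
#' @param control condition label of the control wells.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (LSD default) or `"BH"` for Benjamini-Hochberg
#'   within each endpoint family.
#' @return data.frame with one row per non-control condition: mean counts,
#'   control means, p-values and category.
#' @export
compare_conditions <- function(summaries, control, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(summaries),
            all(c("condition", "n_non_pgcc", "n_pgcc") %in% names(summaries)))
  if (!control %in% summaries$condition)
    stop("control condition '", control, "' not present in summaries")
  ctrl <- summaries[summaries$condition == control, ]
  if (nrow(ctrl) < 2L) stop("need >= 2 control replicates")
  conds <- setdiff(unique(summaries$condition), control)
  rows <- lapply(conds, function(cond) {
    trt <- summaries[summaries$condition == cond, ]
    if (nrow(trt) < 2L)
      stop("condition '", cond, "' has fewer than 2 replicates")
    t_non <- lsd_t_test(trt$n_non_pgcc, ctrl$n_non_pgcc)
    t_pgcc <- lsd_t_test(trt$n_pgcc, ctrl$n_pgcc)
    data.frame(compound = if ("compound" %in% names(trt)) trt$compound[1] else cond,
               condition = cond,
               mean_non_pgcc = mean(trt$n_non_pgcc),
               mean_pgcc = mean(trt$n_pgcc),
               control_non_pgcc = mean(ctrl$n_non_pgcc),
               control_pgcc = mean(ctrl$n_pgcc),
               p_non_pgcc = t_non$p.value, p_pgcc = t_pgcc$p.value,
               stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, rows)
  if (is.null(eff) || nrow(eff) == 0L) return(eff)
  if (adjust == "BH") {
    eff$p_non_pgcc <- stats::p.adjust(eff$p_non_pgcc, "BH")
    eff$p_pgcc <- stats::p.adjust(eff$p_pgcc, "BH")
  }
  sdn <- eff$p_non_pgcc < alpha & eff$mean_non_pgcc < eff$control_non_pgcc
  sinc <- eff$p_non_pgcc < alpha & eff$mean_non_pgcc > eff$control_non_pgcc
  sdp <- eff$p_pgcc < alpha & eff$mean_pgcc < eff$control_pgcc
  sip <- eff$p_pgcc < alpha & eff$mean_pgcc > eff$control_pgcc
  eff$category <- ifelse(sdp & sdn, "kills_both",
                  ifelse(sdp, "kills_pgcc_only",
                  ifelse(sip, "induces_pgcc",
                  ifelse(sdn, "kills_non_pgcc_only", "inactive"))))
  eff
}

#' Compare a per-cell intensity between PGCCs and non-PGCCs
#'
#' Default test: two-sided Welch t-test on `log10(intensity + 1)` (per-cell
#' fluorescence is approximately log-normal). A pooled-variance t-test or a
#' Mann-Whitney test can be selected instead. Group medians and quartiles
#' are returned for violin-style reporting, along with the median
#' fold-change of group A over group B on the raw scale.
#'
#' @param records classified record table.
#' @param channel intensity to compare (`"ros"`, `"nuclei"`, `"live"`,
#'   `"dead"`).
#' @param group_a,group_b ploidy classes to compare (defaults: PGCC vs
#'   non-PGCC).
#' @param method `"welch_log"`, `"t_log"` or `"wilcox"`.
#' @return list with `statistic`, `p_value`, `method`, `fold_median`
#'   (median A / median B), and `groups` (per-group n, median, quartiles).
#' @export
compare_intensity <- function(records, channel = "ros", group_a = "pgcc",
                              group_b = "non_pgcc",
                              method = c("welch_log", "t_log", "wilcox")) {
  method <- match.arg(method)
  validate_records(records)
  col <- paste0("mean_", channel)
  if (!col %in% names(records) || all(is.na(records[[col]])))
    stop("channel '", channel, "' not present in records")
  xa <- records[[col]][records$ploidy_class == group_a]
  xb <- records[[col]][records$ploidy_class == group_b]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (!length(xa)) stop("group '", group_a, "' is empty")
  if (!length(xb)) stop("group '", group_b, "' is empty")
  ht <- switch(method,
    welch_log = stats::t.test(log10(xa + 1), log10(xb + 1)),
    t_log = stats::t.test(log10(xa + 1), log10(xb + 1), var.equal = TRUE),
    wilcox = stats::wilcox.test(xa, xb, exact = FALSE))
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, fold_median = stats::median(xa) / stats::median(xb),
       groups = data.frame(group = c(group_a, group_b),
                           n = c(length(xa), length(xb)),
                           q1 = c(qs(xa)[1], qs(xb)[1]),
                           median = c(qs(xa)[2], qs(xb)[2]),
                           q3 = c(qs(xa)[3], qs(xb)[3]),
                           stringsAsFactors = FALSE))
}
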