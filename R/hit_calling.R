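activity_calls <- c("active", "inactive", "excluded_cytotoxic", "excluded_interference")

#' Classify compounds as active, inactive or excluded
#'
#' Applies the screen's hit-calling rule to per-compound assay results.
#' Exclusion takes precedence over activity, in the order:
#'
#' 1. `excluded_interference` if the compound distorts the glucose
#'    detection readout (counter assay) -- its suppression value is
#'    meaningless regardless of magnitude;
#' 2. `excluded_cytotoxic` if cell viability is strictly below
#'    `viability_threshold`;
#' 3. `active` if suppression of glucose production is at or above
#'    `inhibition_threshold` (inclusive);
#' 4. `inactive` otherwise.
#'
#' @param results A `data.frame` with columns `compound_id`, `condition`,
#'   `suppression` (percent), `viability` (percent) and `interference`
#'   (logical).
#' @param inhibition_threshold Minimum %suppression for an active call
#'   (default 60; the boundary is inclusive).
#' @param viability_threshold Viability below which a compound is excluded
#'   as cytotoxic (default 60; the boundary is strict, `< 60` excludes).
#' @return `results` with a `call` column (factor over the four call
#'   levels) appended; exactly one call per row.
#' @examples
#' res <- data.frame(compound_id = c("C1", "C2", "C3"),
#'                   condition = "compound_alone",
#'                   suppression = c(70, 70, 95),
#'                   viability = c(80, 50, 95),
#'                   interference = c(FALSE, FALSE, TRUE))
#' call_activity(res)$call
#' @export
call_activity <- function(results, inhibition_threshold = 60,
                          viability_threshold = 60) {
  needed <- c("compound_id", "condition", "suppression", "viability", "interference")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0L) {
    stop("screen table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!(inhibition_threshold > 0 && inhibition_threshold <= 100) ||
      !(viability_threshold > 0 && viability_threshold <= 100)) {
    stop("thresholds must lie in (0, 100]")
  }
  if (anyNA(results$suppression) || anyNA(results$viability)) {
    stop("incomplete record: missing suppression or viability value")
  }
  call <- ifelse(results$interference, "excluded_interference",
          ifelse(results$viability < viability_threshold, "excluded_cytotoxic",
          ifelse(results$suppression >= inhibition_threshold, "active",
                 "inactive")))
  results$call <- factor(call, levels = activity_calls)
  results
}

#' Flag detection interference from the counter assay
#'
#' The counter assay mixes each compound with a fixed glucose standard
#' (37.5 uM in the original assay) before the enzymatic readout; a compound
#' that shifts the measured signal away from the compound-free reference by
#' more than `tolerance` (relative) is flagged as interfering with the
#' detection chemistry.
#'
#' @param measured_signal Signal measured with compound present.
#' @param reference_signal Compound-free reference signal (> 0).
#' @param tolerance Maximum tolerated relative deviation (default 0.2).
#' @return Logical: `TRUE` if the compound interferes.
#' @export
counter_assay_flag <- function(measured_signal, reference_signal, tolerance = 0.2) {
  if (any(reference_signal <= 0)) {
    stop("invalid reference: counter-assay reference signal must be positive")
  }
  abs(measured_signal - reference_signal) / reference_signal > tolerance
}

#' Tally activity calls by category
#'
#' @param calls Output of [call_activity()] (or any data.frame with a
#'   `call` column over the standard call levels).
#' @return Named integer vector of counts over all four call categories
#'   (zero-filled); the counts sum to `nrow(calls)`.
#' @export
summarize_screen <- function(calls) {
  x <- factor(as.character(calls$call), levels = activity_calls)
  table(x, dnn = NULL)
}

#' Read a screen-results table
#'
#' TSV with columns `compound_id`, `condition`, `suppression`, `viability`,
#' `interference` (logical), one row per compound x condition.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of per-compound assay results.
#' @export
read_screen_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(compound_id = "character",
                                   condition = "character"))
}

#' Write activity calls
#'
#' @param calls Output of [call_activity()].
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble per-compound screen results from plate data
#'
#' Joins normalized plate wells with the viability and counter-assay
#' tables into the per-compound x condition table consumed by
#' [call_activity()]. Suppression is averaged over a compound's wells
#' within a condition.
#'
#' @param wells Well records (see [read_plates()]).
#' @param viability `data.frame` with `compound_id`, `viability` (percent
#'   of vehicle-well ATP signal).
#' @param counter_assay `data.frame` with `compound_id`,
#'   `measured_signal`, `reference_signal` from the glucose-standard
#'   counter assay.
#' @param tolerance Relative-deviation tolerance passed to
#'   [counter_assay_flag()].
#' @return A screen-results `data.frame` ready for [call_activity()].
#' @export
screen_results <- function(wells, viability, counter_assay, tolerance = 0.2) {
  norm <- normalize_wells(wells)
  agg <- stats::aggregate(percent_suppression ~ compound_id + condition,
                          data = norm, FUN = mean)
  names(agg)[names(agg) == "percent_suppression"] <- "suppression"
  vi <- match(agg$compound_id, viability$compound_id)
  if (anyNA(vi)) {
    stop("no viability result for compound(s): ",
         paste(unique(agg$compound_id[is.na(vi)]), collapse = ", "))
  }
  agg$viability <- viability$viability[vi]
  ci <- match(agg$compound_id, counter_assay$compound_id)
  if (anyNA(ci)) {
    stop("no counter-assay result for compound(s): ",
         paste(unique(agg$compound_id[is.na(ci)]), collapse = ", "))
  }
  agg$interference <- counter_assay_flag(counter_assay$measured_signal[ci],
                                         counter_assay$reference_signal[ci],
                                         tolerance)
  agg <- agg[order(agg$compound_id, agg$condition), ]
  rownames(agg) <- NULL
  agg
}
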