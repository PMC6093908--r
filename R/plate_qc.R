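#' Percent-of-control normalization
#'
#' Normalizes a raw well signal against the MAX (full glucose output:
#' vehicle plus gluconeogenic substrates) and MIN (basal output: vehicle,
#' no substrates) control means of the same plate:
#' \deqn{\%Control = 100 (Test - Min) / (Max - Min)}
#'
#' Values outside \[0, 100\] are retained, not clipped, so stimulated wells
#' (glucagon-like responses above MAX) remain representable.
#'
#' @param test Raw signal(s) of the test well(s) (absorbance units, A570).
#' @param max MAX-control level (typically the plate's MAX-well mean).
#' @param min MIN-control level (typically the plate's MIN-well mean).
#' @return Percent of control, same length as `test`.
#' @seealso [percent_suppression()], [plate_summary()]
#' @examples
#' percent_control(0.6, max = 1, min = 0.2)
#' @export
percent_control <- function(test, max, min) {
  stopifnot(is.numeric(test), is.numeric(max), is.numeric(min))
  if (any(max == min)) {
    stop("degenerate plate: MAX and MIN control levels are equal")
  }
  100 * (test - min) / (max - min)
}

#' Percent suppression of glucose production
#'
#' The screen's primary readout: \eqn{100 - \%Control}. A well at the MIN
#' level (glucose output fully suppressed) scores 100; a well at the MAX
#' level scores 0.
#'
#' @inheritParams percent_control
#' @return Percent suppression, same length as `test`.
#' @export
percent_suppression <- function(test, max, min) {
  100 - percent_control(test, max, min)
}

#' Coefficient of variation of replicate control wells
#'
#' CV in percent, using the sample (n-1) standard deviation.
#'
#' @param values Numeric vector of at least two replicate signals.
#' @return CV as a percentage.
#' @export
plate_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("insufficient replicates: CV needs at least 2 values")
  }
  m <- mean(values)
  if (m == 0) stop("undefined CV: mean of values is zero")
  100 * stats::sd(values) / m
}

#' Z'-factor of a plate's control separation
#'
#' The standard screening-window statistic
#' \deqn{Z' = 1 - 3 (\sigma_{max} + \sigma_{min}) / |\mu_{max} - \mu_{min}|}
#' Values near 1 indicate well-separated controls; widely overlapping
#' control bands can give negative values.
#'
#' @param max_values MAX-control replicate signals (>= 2 values).
#' @param min_values MIN-control replicate signals (>= 2 values).
#' @return Z' (dimensionless, <= 1).
#' @export
z_prime <- function(max_values, min_values) {
  if (length(max_values) < 2L || length(min_values) < 2L) {
    stop("insufficient replicates: Z' needs at least 2 values per control group")
  }
  mu_max <- mean(max_values)
  mu_min <- mean(min_values)
  if (mu_max == mu_min) stop("undefined Z': control means are equal")
  1 - 3 * (stats::sd(max_values) + stats::sd(min_values)) / abs(mu_max - mu_min)
}

well_roles <- c("MAX", "MIN", "TEST")
well_conditions <- c("compound_alone", "compound_plus_insulin")

#' Read a plate file
#'
#' Reads and validates a CSV of well records: one row per well with columns
#' `plate_id`, `well` (row-letter/column-number, e.g. "A01"), `role`
#' (MAX/MIN/TEST), `compound_id` (empty for control wells), `condition`
#' (`compound_alone` or `compound_plus_insulin`) and `raw_signal`
#' (non-negative absorbance).
#'
#' @param path Path to the plate CSV.
#' @return A validated `data.frame` of well records.
#' @export
read_plates <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(plate_id = "character",
                                          well = "character",
                                          role = "character",
                                          compound_id = "character",
                                          condition = "character"))
  validate_wells(wells)
}

#' @keywords internal
validate_wells <- function(wells) {
  needed <- c("plate_id", "well", "role", "compound_id", "condition", "raw_signal")
  missing_cols <- setdiff(needed, names(wells))
  if (length(missing_cols) > 0L) {
    stop("plate table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_role <- setdiff(unique(wells$role), well_roles)
  if (length(bad_role) > 0L) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "))
  }
  wells$compound_id[is.na(wells$compound_id)] <- ""
  ctrl <- wells$role != "TEST"
  if (any(nzchar(wells$compound_id[ctrl]))) {
    stop("MAX/MIN control wells must have an empty compound_id")
  }
  if (any(!is.finite(wells$raw_signal)) || any(wells$raw_signal < 0)) {
    stop("raw_signal must be finite and non-negative")
  }
  wells
}

#' Per-plate uniformity statistics
#'
#' Summarizes each plate's MAX/MIN control wells: means, standard
#' deviations, CVs and the Z'-factor. Mirrors a plate-validation report for
#' a high-throughput run.
#'
#' @param wells Well records as returned by [read_plates()].
#' @return A `data.frame` with one row per plate: `plate_id`, `max_mean`,
#'   `max_sd`, `min_mean`, `min_sd`, `cv_max`, `cv_min`, `z_prime`.
#' @export
plate_summary <- function(wells) {
  wells <- validate_wells(wells)
  plates <- unique(wells$plate_id)
  out <- lapply(plates, function(pid) {
    p <- wells[wells$plate_id == pid, ]
    mx <- p$raw_signal[p$role == "MAX"]
    mn <- p$raw_signal[p$role == "MIN"]
    if (length(mx) < 2L || length(mn) < 2L) {
      stop("plate ", pid, " has fewer than 2 MAX or MIN control wells")
    }
    data.frame(plate_id = pid,
               max_mean = mean(mx), max_sd = stats::sd(mx),
               min_mean = mean(mn), min_sd = stats::sd(mn),
               cv_max = plate_cv(mx), cv_min = plate_cv(mn),
               z_prime = z_prime(mx, mn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalize test wells against their own plate's controls
#'
#' Every TEST well is expressed as %Control and %Suppression relative to
#' the MAX/MIN control-well means of the plate it sits on (controls are
#' per-plate; no cross-plate pooling).
#'
#' @param wells Well records as returned by [read_plates()].
#' @return The TEST-well rows with `percent_control` and
#'   `percent_suppression` columns appended.
#' @export
normalize_wells <- function(wells) {
  wells <- validate_wells(wells)
  qc <- plate_summary(wells)
  test <- wells[wells$role == "TEST", ]
  idx <- match(test$plate_id, qc$plate_id)
  test$percent_control <- percent_control(test$raw_signal,
                                          qc$max_mean[idx], qc$min_mean[idx])
  test$percent_suppression <- 100 - test$percent_control
  rownames(test) <- NULL
  test
}

#' Write the per-plate QC report
#'
#' @param qc Output of [plate_summary()].
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
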