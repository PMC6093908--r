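#' Reference-normalized Ct
#'
#' `delta Ct = Ct(gene) - Ct(reference)` for one replicate; the
#' housekeeping-normalized quantity whose linear-scale transform
#' `2^(-dCt)` is the normalized expression level.
#'
#' @param ct_gene Threshold cycle of the gene of interest.
#' @param ct_ref Threshold cycle of the reference (housekeeping) signal in
#'   the same replicate.
#' @return delta Ct. Vectorized.
#' @export
delta_ct <- function(ct_gene, ct_ref) {
  ct_gene - ct_ref
}

#' Fold change from mean delta-Ct values
#'
#' `2^(-ddCt)` with `ddCt = mean dCt(treatment) - mean dCt(control)`:
#' normalized expression in the treated sample divided by normalized
#' expression in the control sample.
#'
#' @param mean_dct_control Mean delta Ct of the control arm.
#' @param mean_dct_treatment Mean delta Ct of the treatment arm.
#' @return Fold change (> 0).
#' @export
fold_change <- function(mean_dct_control, mean_dct_treatment) {
  2^(-(mean_dct_treatment - mean_dct_control))
}

#' Fold regulation
#'
#' Reports fold change symmetrically: values >= 1 are kept as-is
#' (up-regulation), values < 1 become the negative reciprocal
#' (down-regulation), so a halving and a doubling are both magnitude 2.
#'
#' @param fc Fold change (> 0). Vectorized.
#' @return Signed fold regulation with `|fold_regulation| >= 1`.
#' @export
fold_regulation <- function(fc) {
  if (any(fc <= 0)) stop("invalid ratio: fold change must be positive")
  ifelse(fc >= 1, fc, -1 / fc)
}

#' Per-gene Student's t-test on linear-scale expression
#'
#' Two-sided, pooled-variance (classic Student's) two-sample t-test on the
#' replicate `2^(-dCt)` values of the two arms.
#'
#' @param expr_control,expr_treatment Replicate linear-scale expression
#'   values (>= 2 per arm).
#' @return The p-value.
#' @export
gene_ttest <- function(expr_control, expr_treatment) {
  if (length(expr_control) < 2L || length(expr_treatment) < 2L) {
    stop("t-test needs at least 2 replicates per arm")
  }
  if (stats::var(expr_control) == 0 && stats::var(expr_treatment) == 0) {
    stop("degenerate test: both arms have zero variance")
  }
  stats::t.test(expr_control, expr_treatment, var.equal = TRUE)$p.value
}

#' Quantify a qPCR array by delta-delta-Ct
#'
#' Per-gene quantification from a long-format replicate table. Fold change
#' is computed from the arm means of delta Ct; the t-test is computed on
#' the replicate linear-scale `2^(-dCt)` values — the two scales the
#' standard array analysis distinguishes.
#'
#' @param ct Long-format `data.frame` with columns `gene_symbol`, `arm`
#'   (`control` / `treatment`), `replicate`, `ct_gene`, `ct_ref`.
#' @param fc_cutoff Fold-regulation magnitude that a gene must exceed to
#'   pass the filter (default 2).
#' @param p_cutoff p-value cutoff for the filter. Two conventional presets
#'   are exported as [qpcr_cutoffs]; default 0.05.
#' @return A `data.frame` with one row per gene: `gene_symbol`,
#'   `mean_dct_control`, `mean_dct_treatment`, `fold_change`,
#'   `fold_regulation`, `p_value`, `passes_filter`.
#' @export
analyze_qpcr <- function(ct, fc_cutoff = 2, p_cutoff = qpcr_cutoffs["heatmap"]) {
  needed <- c("gene_symbol", "arm", "replicate", "ct_gene", "ct_ref")
  missing_cols <- setdiff(needed, names(ct))
  if (length(missing_cols) > 0L) {
    stop("Ct table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_arm <- setdiff(unique(ct$arm), c("control", "treatment"))
  if (length(bad_arm) > 0L) stop("unknown arm(s): ", paste(bad_arm, collapse = ", "))
  if (any(!is.finite(ct$ct_gene)) || any(!is.finite(ct$ct_ref)) ||
      any(ct$ct_gene <= 0) || any(ct$ct_ref <= 0)) {
    stop("Ct values must be positive and finite")
  }
  ct$dct <- delta_ct(ct$ct_gene, ct$ct_ref)
  genes <- unique(ct$gene_symbol)
  rows <- lapply(genes, function(g) {
    dct_c <- ct$dct[ct$gene_symbol == g & ct$arm == "control"]
    dct_t <- ct$dct[ct$gene_symbol == g & ct$arm == "treatment"]
    if (length(dct_c) < 2L || length(dct_t) < 2L) {
      stop("gene ", g, " has fewer than 2 replicates in one arm")
    }
    fc <- fold_change(mean(dct_c), mean(dct_t))
    expr_c <- 2^(-dct_c); expr_t <- 2^(-dct_t)
    p <- if (stats::var(expr_c) == 0 && stats::var(expr_t) == 0) {
      NA_real_  # degenerate (e.g. noiseless simulation); no test possible
    } else {
      gene_ttest(expr_c, expr_t)
    }
    data.frame(gene_symbol = g,
               mean_dct_control = mean(dct_c),
               mean_dct_treatment = mean(dct_t),
               fold_change = fc,
               fold_regulation = fold_regulation(fc),
               p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$passes_filter <- !is.na(out$p_value) &
    abs(out$fold_regulation) > fc_cutoff & out$p_value < p_cutoff
  out
}

#' Conventional significance cutoffs for the array filter
#'
#' `stringent` (1e-6) is the table-grade cutoff; `heatmap` (0.05) the
#' display-grade one. Both are presets, not hard-coded into the analysis.
#'
#' @format Named numeric vector of length 2.
#' @export
qpcr_cutoffs <- c(stringent = 1e-6, heatmap = 0.05)

#' Filter regulated genes
#'
#' Keeps genes with `|fold_regulation| > fc_cutoff` and
#' `p_value < p_cutoff`.
#'
#' @param results Output of [analyze_qpcr()].
#' @param fc_cutoff Fold-regulation magnitude cutoff (default 2).
#' @param p_cutoff p-value cutoff.
#' @return The filtered rows.
#' @export
filter_regulated <- function(results, fc_cutoff = 2,
                             p_cutoff = qpcr_cutoffs["heatmap"]) {
  if (fc_cutoff <= 0 || p_cutoff <= 0) stop("cutoffs must be positive")
  results[abs(results$fold_regulation) > fc_cutoff &
            results$p_value < p_cutoff, , drop = FALSE]
}

#' Read a qPCR Ct replicate table
#'
#' TSV with columns `gene_symbol`, `arm`, `replicate`, `ct_gene`,
#' `ct_ref`.
#'
#' @param path Path to the TSV.
#' @return Long-format Ct `data.frame`.
#' @export
read_qpcr_ct <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene_symbol = "character", arm = "character"))
}

#' Write per-gene qPCR results
#'
#' @param results Output of [analyze_qpcr()].
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
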