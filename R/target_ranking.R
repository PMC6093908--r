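#' Ranking configuration
#'
#' Parameters of the target-deconvolution statistic.
#'
#' @param a Adjustment factor balancing the influence of the positive
#'   proportion against the amount of evidence (default 1).
#' @param confidence_level Confidence level of the Wilson interval whose
#'   width penalizes low-evidence targets (default 0.95).
#' @param b1_grid Balance-factor grid for the weighting sweep; strictly
#'   increasing values in (0, 1). The default, `seq(0.01, 0.99, by = 0.01)`,
#'   has 99 settings and covers the whole admissible range.
#' @param min_active_positives Eligibility rule: a target must have at
#'   least this many positive compounds in the active channel to be ranked
#'   (default 1).
#' @return An object of class `ranking_config`.
#' @export
ranking_config <- function(a = 1, confidence_level = 0.95,
                           b1_grid = seq(0.01, 0.99, by = 0.01),
                           min_active_positives = 1L) {
  if (!(a > 0)) stop("adjustment factor a must be positive")
  if (!(confidence_level > 0 && confidence_level < 1)) {
    stop("confidence_level must lie in (0, 1)")
  }
  if (length(b1_grid) < 1L || any(b1_grid <= 0) || any(b1_grid >= 1) ||
      is.unsorted(b1_grid, strictly = TRUE)) {
    stop("b1_grid must be strictly increasing with all values in (0, 1)")
  }
  structure(list(a = a, confidence_level = confidence_level,
                 b1_grid = b1_grid,
                 min_active_positives = as.integer(min_active_positives)),
            class = "ranking_config")
}

#' Width of the Wilson score interval
#'
#' Width (upper minus lower bound) of the Wilson score confidence interval
#' for a binomial proportion `k/n`. The width contracts as evidence
#' accumulates, which is what lets the evidence score reward targets with
#' more tested compounds at equal positive proportion.
#'
#' @param k Number of positive results, `0 <= k <= n`.
#' @param n Number of trials (tested compounds), `n >= 1`.
#' @param confidence_level Confidence level (default 0.95).
#' @return Interval width in (0, 1]. Vectorized over `k` and `n`.
#' @examples
#' wilson_width(5, 10)
#' wilson_width(5, 10) == wilson_width(5, 10, 0.95)
#' @export
wilson_width <- function(k, n, confidence_level = 0.95) {
  if (any(n < 1)) stop("no data: Wilson width needs n >= 1")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - confidence_level) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  2 * half
}

#' Evidence score of a target within one channel
#'
#' The per-target, per-channel score `S = p / (a * w)` where `p` is the
#' proportion of the target's tested compounds scoring positive and `w`
#' the Wilson-interval width of that proportion. At equal `p`, a target
#' tested with more compounds has a narrower interval and hence a higher
#' score.
#'
#' @param p Positive proportion in \[0, 1\].
#' @param w Wilson-interval width (> 0).
#' @param a Adjustment factor (> 0, default 1).
#' @return The evidence score (>= 0). Vectorized.
#' @export
evidence_score <- function(p, w, a = 1) {
  if (any(w <= 0) || any(a <= 0)) {
    stop("invalid parameter: w and a must be positive")
  }
  p / (a * w)
}

#' Standardize channel scores
#'
#' Centers and scales a channel's evidence scores to mean 0 and population
#' (divide-by-n) standard deviation 1, so that the two channels become
#' comparable despite very different tested-compound counts.
#'
#' @param scores Numeric vector of evidence scores for all eligible
#'   targets within one channel (length >= 2).
#' @return Standardized scores `(S - mu) / sigma`.
#' @export
standardize <- function(scores) {
  if (length(scores) < 2L) stop("standardization needs at least 2 targets")
  mu <- mean(scores)
  sigma <- sqrt(mean((scores - mu)^2))
  if (sigma == 0) stop("degenerate channel: all scores identical")
  (scores - mu) / sigma
}

#' Combined two-channel score
#'
#' Convex combination of the standardized active- and inactive-channel
#' scores, `I = b1 * Z1 + (1 - b1) * Z2`, with the balance factor `b1`
#' controlling the relative contribution of the active channel
#' (`b2 = 1 - b1`). `b1 = 0.5` is the neutral setting.
#'
#' @param Z1,Z2 Standardized channel scores (same length).
#' @param b1 Balance factor in (0, 1).
#' @return Combined score vector.
#' @export
combined_score <- function(Z1, Z2, b1) {
  if (!(b1 > 0 && b1 < 1)) stop("invalid balance factor: b1 must lie in (0, 1)")
  if (length(Z1) != length(Z2)) stop("Z1 and Z2 must have the same length")
  b1 * Z1 + (1 - b1) * Z2
}

#' Rank combined scores
#'
#' Rank 1 is the largest (best) combined score; ties receive the average
#' of the spanned ranks, which keeps the rank-versus-balance curve
#' continuous in the balance factor.
#'
#' @param I Combined-score vector.
#' @return Rank vector of the same length.
#' @export
rank_scores <- function(I) {
  if (length(I) < 1L) stop("rank_scores needs at least one target")
  rank(-I, ties.method = "average")
}

#' Rank matrix over the balance-factor sweep
#'
#' Computes the target ranking at every grid point of the balance factor.
#'
#' @param Z1,Z2 Standardized channel-score vectors (same length).
#' @param grid Balance-factor grid (nonempty, values in (0, 1)).
#' @return A targets x grid-points matrix of ranks; column `g` is
#'   `rank_scores(combined_score(Z1, Z2, grid[g]))`.
#' @export
balance_sweep <- function(Z1, Z2, grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(Z1) != length(Z2)) stop("Z1 and Z2 must have the same length")
  if (length(grid) < 1L) stop("balance grid must be nonempty")
  ranks <- vapply(grid, function(b1) rank_scores(combined_score(Z1, Z2, b1)),
                  numeric(length(Z1)))
  ranks <- matrix(ranks, nrow = length(Z1))
  colnames(ranks) <- formatC(grid, format = "f", digits = 2)
  ranks
}

#' Area under a target's rank-versus-balance curve
#'
#' Trapezoidal integral of the rank curve over the balance-factor grid.
#' A target ranked well across the whole sweep accumulates a small area;
#' the area rewards rankings that are robust to the channel weighting.
#'
#' @param grid Balance-factor grid (length >= 2).
#' @param ranks Either a rank vector for one target (same length as
#'   `grid`) or a targets x grid matrix as returned by [balance_sweep()].
#' @return The AUC (one value per target).
#' @export
rank_auc <- function(grid, ranks) {
  if (length(grid) < 2L) stop("insufficient grid: AUC needs at least 2 points")
  if (is.matrix(ranks)) {
    if (ncol(ranks) != length(grid)) stop("grid/rank length mismatch")
    return(apply(ranks, 1L, function(r) rank_auc(grid, r)))
  }
  if (length(ranks) != length(grid)) stop("grid/rank length mismatch")
  dx <- diff(grid)
  sum((ranks[-length(ranks)] + ranks[-1]) / 2 * dx)
}

#' Kendall rank correlation between two rankings
#'
#' Tie-adjusted Kendall tau-b, appropriate because tie-averaged ranks can
#' occur in either ranking.
#'
#' @param ranking_a,ranking_b Rank vectors of equal length (>= 2).
#' @return Correlation in \[-1, 1\].
#' @export
kendall_tau <- function(ranking_a, ranking_b) {
  if (length(ranking_a) != length(ranking_b)) {
    stop("rankings must have the same length")
  }
  if (length(ranking_a) < 2L) stop("Kendall tau needs at least 2 items")
  stats::cor(ranking_a, ranking_b, method = "kendall")
}

#' Assign compounds to evidence channels
#'
#' The default channel mapping: a compound's channel is decided by its
#' primary-screen call (no insulin), and its positivity within the channel
#' by whether its suppression was confirmed on top of insulin.
#'
#' * primary call `active` -> channel 1 (the "active assay"); positive if
#'   the `compound_plus_insulin` call is also `active`;
#' * primary call `inactive` -> channel 2 (the "inactive assay"); positive
#'   if the compound becomes `active` in the presence of insulin
#'   (insulin-potentiated suppression);
#' * excluded compounds (cytotoxic or detection interference, in either
#'   condition) contribute to neither channel.
#'
#' @param calls Output of [call_activity()] containing both conditions for
#'   every non-excluded compound.
#' @return A `data.frame` with one row per channel-assigned compound:
#'   `compound_id`, `channel` (1 or 2), `positive` (logical).
#' @export
default_channel_map <- function(calls) {
  calls$call <- as.character(calls$call)
  excluded <- unique(calls$compound_id[startsWith(calls$call, "excluded")])
  kept <- calls[!(calls$compound_id %in% excluded), ]
  alone <- kept[kept$condition == "compound_alone", c("compound_id", "call")]
  insulin <- kept[kept$condition == "compound_plus_insulin", c("compound_id", "call")]
  if (anyDuplicated(alone$compound_id) || anyDuplicated(insulin$compound_id)) {
    stop("more than one call per compound and condition")
  }
  idx <- match(alone$compound_id, insulin$compound_id)
  if (anyNA(idx)) {
    stop("missing compound_plus_insulin call for compound(s): ",
         paste(alone$compound_id[is.na(idx)], collapse = ", "))
  }
  data.frame(compound_id = alone$compound_id,
             channel = ifelse(alone$call == "active", 1L, 2L),
             positive = insulin$call[idx] == "active",
             stringsAsFactors = FALSE)
}

#' Tabulate per-target evidence counts
#'
#' Counts, for every annotated target and channel, the number of tested
#' compounds (`n_tested`) and the number of positives (`k_positive`). A
#' compound annotated to several targets contributes to all of them
#' (uniform fan-out).
#'
#' @param assignments Channel assignments, e.g. from
#'   [default_channel_map()]: `compound_id`, `channel`, `positive`.
#' @param annotations Annotation table: `compound_id`, `target_id` (and
#'   optionally `modulation_type`); no duplicate (compound, target) pairs.
#' @return A `data.frame` with columns `target_id`, `channel`, `n_tested`,
#'   `k_positive`, covering every annotated target in both channels
#'   (zero-filled where a target has no compounds in a channel).
#' @export
tabulate_evidence <- function(assignments, annotations) {
  if (anyDuplicated(annotations[, c("compound_id", "target_id")])) {
    stop("annotation table has duplicate (compound, target) pairs")
  }
  unannotated <- setdiff(assignments$compound_id, annotations$compound_id)
  if (length(unannotated) > 0L) {
    stop("missing annotation for compound(s): ",
         paste(unannotated, collapse = ", "))
  }
  merged <- merge(assignments, annotations[, c("compound_id", "target_id")],
                  by = "compound_id")
  targets <- sort(unique(annotations$target_id))
  grid <- expand.grid(target_id = targets, channel = c(1L, 2L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(merged$target_id, merged$channel)
  n <- table(factor(key, levels = paste(grid$target_id, grid$channel)))
  k <- table(factor(key[merged$positive],
                    levels = paste(grid$target_id, grid$channel)))
  grid$n_tested <- as.integer(n)
  grid$k_positive <- as.integer(k)
  grid[order(grid$target_id, grid$channel), ]
}

#' Eligible targets for the ranking
#'
#' Keeps the targets with at least `min_active_positives` positive
#' compounds in the active channel (channel 1); targets without any
#' positive active-assay evidence are not ranked.
#'
#' @param evidence Output of [tabulate_evidence()].
#' @param min_active_positives Minimum channel-1 positives (default 1).
#' @return Character vector of eligible target ids.
#' @export
filter_eligible <- function(evidence, min_active_positives = 1L) {
  ch1 <- evidence[evidence$channel == 1L, ]
  sort(ch1$target_id[ch1$k_positive >= min_active_positives])
}

#' Rank annotated targets from activity calls
#'
#' The full target-deconvolution statistic. For every eligible target and
#' each evidence channel the positive proportion `p = k/n` is penalized by
#' its Wilson-interval width `w` to give the score `S = p/(a w)`; scores
#' are standardized per channel; the standardized scores are combined as
#' `I = b1 Z1 + (1 - b1) Z2` across the balance-factor grid; targets are
#' ranked at every grid point and the area under each rank-versus-balance
#' curve is integrated; the final ordering is by ascending AUC (smaller
#' area = consistently better ranks).
#'
#' Targets with no tested compounds in the inactive channel cannot be
#' scored there; they are excluded from channel-2 standardization, carry
#' `Z2 = 0`, and are flagged in the output (`no_channel2_evidence`).
#'
#' @param calls Activity calls from [call_activity()] (both conditions).
#' @param annotations Compound-to-target annotation table.
#' @param config A [ranking_config()].
#' @param channel_map Function mapping calls to channel assignments
#'   (default [default_channel_map()]).
#' @return An object of class `target_ranking`: a list with `table` (one
#'   row per eligible target: counts, `p`, `w`, `S`, `Z` per channel,
#'   `neutral_rank`, `auc`, `final_rank`), `rank_matrix` (targets x grid),
#'   `grid`, and `config`. The table is sorted by `final_rank`.
#' @export
rank_targets <- function(calls, annotations, config = ranking_config(),
                         channel_map = default_channel_map) {
  stopifnot(inherits(config, "ranking_config"))
  assignments <- channel_map(calls)
  evidence <- tabulate_evidence(assignments, annotations)
  eligible <- filter_eligible(evidence, config$min_active_positives)
  if (length(eligible) < 2L) {
    stop("fewer than 2 eligible targets; nothing to rank")
  }
  ev <- evidence[evidence$target_id %in% eligible, ]
  ch1 <- ev[ev$channel == 1L, ][match(eligible, ev$target_id[ev$channel == 1L]), ]
  ch2 <- ev[ev$channel == 2L, ][match(eligible, ev$target_id[ev$channel == 2L]), ]

  p1 <- ch1$k_positive / ch1$n_tested
  w1 <- wilson_width(ch1$k_positive, ch1$n_tested, config$confidence_level)
  S1 <- evidence_score(p1, w1, config$a)
  Z1 <- standardize(S1)

  has2 <- ch2$n_tested > 0L
  p2 <- ifelse(has2, ch2$k_positive / ch2$n_tested, NA_real_)
  w2 <- rep(NA_real_, length(eligible))
  S2 <- rep(NA_real_, length(eligible))
  if (any(has2)) {
    w2[has2] <- wilson_width(ch2$k_positive[has2], ch2$n_tested[has2],
                             config$confidence_level)
    S2[has2] <- evidence_score(p2[has2], w2[has2], config$a)
  }
  Z2 <- numeric(length(eligible))          # no channel-2 evidence -> Z2 = 0
  if (sum(has2) >= 2L) Z2[has2] <- standardize(S2[has2])

  rank_matrix <- balance_sweep(Z1, Z2, config$b1_grid)
  rownames(rank_matrix) <- eligible
  neutral_rank <- rank_scores(combined_score(Z1, Z2, 0.5))
  auc <- rank_auc(config$b1_grid, rank_matrix)
  ord <- order(auc, neutral_rank, eligible)
  final_rank <- integer(length(eligible))
  final_rank[ord] <- seq_along(eligible)

  tab <- data.frame(target_id = eligible,
                    n1 = ch1$n_tested, k1 = ch1$k_positive, p1 = p1,
                    w1 = w1, S1 = S1, Z1 = Z1,
                    n2 = ch2$n_tested, k2 = ch2$k_positive, p2 = p2,
                    w2 = w2, S2 = S2, Z2 = Z2,
                    no_channel2_evidence = !has2,
                    neutral_rank = neutral_rank, auc = auc,
                    final_rank = final_rank,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$final_rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, rank_matrix = rank_matrix,
                 grid = config$b1_grid, config = config,
                 evidence = evidence),
            class = "target_ranking")
}

#' @export
print.target_ranking <- function(x, n = 10L, ...) {
  cat("Target ranking over", nrow(x$table), "eligible targets,",
      length(x$grid), "balance-factor settings\n")
  cat("Top targets by rank-curve AUC (smaller = more robustly top-ranked):\n")
  cols <- c("target_id", "n1", "k1", "n2", "k2", "neutral_rank", "auc", "final_rank")
  print(utils::head(x$table[, cols], n))
  invisible(x)
}

#' Plot rank-versus-balance curves
#'
#' Draws each selected target's rank across the balance-factor sweep
#' (rank 1 at the top), the visual used to judge how robust a target's
#' position is to the channel weighting.
#'
#' @param x A `target_ranking` object.
#' @param targets Target ids to draw (default: the top 5 by final rank).
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.target_ranking <- function(x, targets = NULL, ...) {
  if (is.null(targets)) targets <- utils::head(x$table$target_id, 5L)
  curves <- t(x$rank_matrix[targets, , drop = FALSE])
  graphics::matplot(x$grid, curves, type = "l", lty = 1,
                    xlab = "balance factor b1", ylab = "rank",
                    ylim = rev(range(curves)), ...)
  graphics::legend("bottomright", legend = targets, lty = 1,
                   col = seq_along(targets), cex = 0.8)
  invisible(x)
}

#' Read an annotation table
#'
#' TSV with columns `compound_id`, `target_id`, `modulation_type`.
#'
#' @param path Path to the TSV.
#' @return Annotation `data.frame`.
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(compound_id = "character",
                                   target_id = "character"))
}

#' Write the per-target ranking table
#'
#' @param ranking A `target_ranking` object.
#' @param path Destination TSV path.
#' @param curves Optional path for a long-format (target, b1, rank) export
#'   of the rank curves.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, curves = NULL) {
  utils::write.table(ranking$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(curves)) {
    long <- data.frame(target_id = rep(rownames(ranking$rank_matrix),
                                       times = length(ranking$grid)),
                       b1 = rep(ranking$grid, each = nrow(ranking$rank_matrix)),
                       rank = as.vector(ranking$rank_matrix))
    utils::write.table(long, curves, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
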