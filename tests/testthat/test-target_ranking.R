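test_that("Wilson width matches the closed form and its symmetry", {
  expect_equal(wilson_width(5, 10), naive_wilson_width(5, 10), tolerance = 1e-12)
  withr::with_seed(41, {
    for (i in 1:25) {
      n <- sample(1:200, 1); k <- sample(0:n, 1)
      expect_equal(wilson_width(k, n), naive_wilson_width(k, n),
                   tolerance = 1e-12)
      expect_equal(wilson_width(k, n), wilson_width(n - k, n))
    }
  })
  # evidence contracts the interval: same proportion, more compounds
  expect_lt(wilson_width(500, 1000), wilson_width(5, 10))
  expect_error(wilson_width(1, 0), "n >= 1")
  expect_error(wilson_width(5, 3), "0 <= k <= n")
})

test_that("the evidence score rewards proportion and evidence", {
  expect_equal(evidence_score(0, 0.5), 0)
  expect_equal(evidence_score(0.4, 0.2, a = 2),
               evidence_score(0.4, 0.2, a = 1) / 2)
  # equal p, larger n -> smaller Wilson width -> larger S
  s_small <- evidence_score(0.5, wilson_width(5, 10))
  s_large <- evidence_score(0.5, wilson_width(50, 100))
  expect_gt(s_large, s_small)
  expect_error(evidence_score(0.5, 0), "invalid parameter")
  expect_error(evidence_score(0.5, 0.1, a = -1), "invalid parameter")
})

test_that("standardization yields population mean 0 / sd 1 and absorbs scale", {
  expect_equal(standardize(c(0, 1)), c(-1, 1))
  withr::with_seed(42, {
    s <- rexp(178)
    z <- standardize(s)
    expect_equal(mean(z), 0)
    expect_equal(sqrt(mean(z^2)), 1)
    expect_equal(standardize(3.7 * s + 0.2), z)
  })
  expect_error(standardize(c(2, 2, 2)), "degenerate channel")
  expect_error(standardize(1), "at least 2")
})

test_that("combined score is the convex two-channel combination", {
  expect_equal(combined_score(2, 0, 0.5), 1)
  expect_equal(combined_score(c(1, -1), c(0.5, 2), 0.5), c(0.75, 0.5))
  # near the boundary the active channel dominates
  expect_equal(combined_score(2, -5, 1 - 1e-9), 2, tolerance = 1e-6)
  expect_error(combined_score(1, 1, 1), "invalid balance")
  expect_error(combined_score(1, 1, 0), "invalid balance")
  expect_error(combined_score(c(1, 2), 1, 0.5), "same length")
})

test_that("channel symmetry: swapping channels mirrors the balance factor", {
  withr::with_seed(43, {
    Z1 <- rnorm(8); Z2 <- rnorm(8)
    for (b1 in c(0.1, 0.33, 0.5, 0.9)) {
      expect_equal(combined_score(Z1, Z2, b1), combined_score(Z2, Z1, 1 - b1))
    }
  })
})

test_that("ranking gives rank 1 to the largest score and averages ties", {
  expect_equal(rank_scores(c(3.2, 1.1, 2.0)), c(1, 3, 2))
  expect_equal(rank_scores(c(5, 5)), c(1.5, 1.5))
  expect_equal(rank_scores(7), 1)
})

test_that("the balance sweep matches single-point recomputation per column", {
  withr::with_seed(44, {
    Z1 <- rnorm(5); Z2 <- rnorm(5)
    grid <- seq(0.01, 0.99, by = 0.01)
    m <- balance_sweep(Z1, Z2, grid)
    expect_equal(dim(m), c(5, 99))
    for (g in sample(seq_along(grid), 10)) {
      expect_equal(m[, g], naive_rank(grid[g] * Z1 + (1 - grid[g]) * Z2))
    }
    # every column is a tie-averaged permutation: sums to n(n+1)/2
    expect_true(all(colSums(m) == 15))
  })
})

test_that("identical channels give the same ranking at every balance factor", {
  withr::with_seed(45, {
    Z <- rnorm(7)
    m <- balance_sweep(Z, Z, seq(0.05, 0.95, by = 0.05))
    expect_true(all(m == m[, 1]))
  })
})

test_that("rank AUC is the trapezoidal integral over the grid", {
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_equal(rank_auc(grid, rep(5, 99)), 5 * 0.98)
  withr::with_seed(46, {
    curve <- sort(runif(99, 1, 50))
    expect_equal(rank_auc(grid, curve), naive_trapezoid(grid, curve))
    # pointwise-larger curve has larger area
    expect_gt(rank_auc(grid, curve + 1), rank_auc(grid, curve))
  })
  expect_error(rank_auc(0.5, 3), "insufficient grid")
})

test_that("Kendall tau matches brute-force pair counting", {
  expect_equal(kendall_tau(1:5, 1:5), 1)
  expect_equal(kendall_tau(1:5, 5:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6,
               tolerance = 1e-12)
  withr::with_seed(47, {
    a <- rank(rnorm(12), ties.method = "average")
    b <- rank(a + rnorm(12, 0, 2), ties.method = "average")
    expect_equal(kendall_tau(a, b), naive_kendall(a, b), tolerance = 1e-12)
  })
  expect_error(kendall_tau(1:3, 1:4), "same length")
})

test_that("evidence tabulation fans a compound out to all its targets", {
  assignments <- data.frame(compound_id = c("C1", "C2"),
                            channel = c(1L, 2L),
                            positive = c(TRUE, FALSE))
  ann <- data.frame(compound_id = c("C1", "C1", "C1", "C2"),
                    target_id = c("T1", "T2", "T3", "T1"))
  ev <- tabulate_evidence(assignments, ann)
  ch1 <- ev[ev$channel == 1, ]
  expect_equal(ch1$n_tested[match(c("T1", "T2", "T3"), ch1$target_id)],
               c(1L, 1L, 1L))
  expect_equal(ch1$k_positive[match(c("T1", "T2", "T3"), ch1$target_id)],
               c(1L, 1L, 1L))
  ch2 <- ev[ev$channel == 2, ]
  expect_equal(ch2$n_tested[ch2$target_id == "T1"], 1L)
  expect_equal(ch2$k_positive[ch2$target_id == "T1"], 0L)
})

test_that("evidence counts match an exhaustive pair tally", {
  withr::with_seed(48, {
    compounds <- sprintf("C%02d", 1:10)
    targets <- sprintf("T%d", 1:4)
    ann <- do.call(rbind, lapply(compounds, function(cp)
      data.frame(compound_id = cp, target_id = sample(targets, sample(1:3, 1)))))
    assignments <- data.frame(compound_id = compounds,
                              channel = sample(1:2, 10, replace = TRUE),
                              positive = runif(10) < 0.5)
    ev <- tabulate_evidence(assignments, ann)
    for (r in seq_len(nrow(ev))) {
      n_ref <- k_ref <- 0
      for (i in seq_len(nrow(ann))) {
        j <- match(ann$compound_id[i], assignments$compound_id)
        if (ann$target_id[i] == ev$target_id[r] &&
            assignments$channel[j] == ev$channel[r]) {
          n_ref <- n_ref + 1
          if (assignments$positive[j]) k_ref <- k_ref + 1
        }
      }
      expect_equal(ev$n_tested[r], n_ref)
      expect_equal(ev$k_positive[r], k_ref)
    }
  })
})

test_that("unannotated compounds are reported, not dropped", {
  assignments <- data.frame(compound_id = c("C1", "C2"), channel = 1L,
                            positive = TRUE)
  ann <- data.frame(compound_id = "C1", target_id = "T1")
  expect_error(tabulate_evidence(assignments, ann), "C2")
  dup <- data.frame(compound_id = c("C1", "C1"), target_id = c("T1", "T1"))
  expect_error(tabulate_evidence(assignments[1, ], dup), "duplicate")
})

test_that("eligibility keeps targets with enough active-channel positives", {
  ev <- data.frame(target_id = rep(c("T1", "T2", "T3"), each = 2),
                   channel = rep(1:2, 3),
                   n_tested = c(5L, 9L, 3L, 7L, 0L, 12L),
                   k_positive = c(1L, 4L, 0L, 3L, 0L, 6L))
  expect_equal(filter_eligible(ev), "T1")                 # k1 >= 1 inclusive
  expect_equal(filter_eligible(ev, 0L), c("T1", "T2", "T3"))
  expect_equal(filter_eligible(ev[0, ]), character(0))
})

test_that("the default channel map routes compounds by their primary call", {
  screen <- data.frame(
    compound_id = rep(c("C1", "C2", "C3", "C4"), each = 2),
    condition = rep(c("compound_alone", "compound_plus_insulin"), 4),
    # C1 active both arms; C2 active alone only; C3 inactive alone, active
    # with insulin; C4 cytotoxic
    suppression = c(80, 75, 70, 30, 40, 65, 90, 90),
    viability = c(95, 95, 95, 95, 95, 95, 20, 20),
    interference = FALSE)
  asg <- default_channel_map(call_activity(screen))
  expect_equal(asg$channel[match(c("C1", "C2", "C3"), asg$compound_id)],
               c(1L, 1L, 2L))
  expect_equal(asg$positive[match(c("C1", "C2", "C3"), asg$compound_id)],
               c(TRUE, FALSE, TRUE))
  expect_false("C4" %in% asg$compound_id)  # excluded compounds drop out
})

test_that("the full ranking chain equals the naive loop reimplementation", {
  for (seed in c(101, 102, 103)) {
    inst <- random_small_instance(seed)
    rk <- rank_targets(inst$calls, inst$annotations)
    ref <- naive_target_pipeline(inst$calls, inst$annotations)
    tab <- rk$table[order(rk$table$target_id), ]
    ord <- order(ref$eligible)
    expect_equal(tab$target_id, ref$eligible[ord])
    expect_equal(tab$S1, ref$S1[ord], tolerance = 1e-12)
    expect_equal(tab$Z1, ref$Z1[ord], tolerance = 1e-12)
    expect_equal(tab$Z2, ref$Z2[ord], tolerance = 1e-12)
    expect_equal(tab$auc, ref$auc[ord], tolerance = 1e-12)
    expect_equal(tab$final_rank, ref$final[ord])
    expect_equal(rk$rank_matrix[ref$eligible, ], unname(ref$rank_matrix),
                 ignore_attr = TRUE)
  }
})

test_that("rescaling a channel's scores leaves the ranking unchanged", {
  inst <- random_small_instance(104)
  # the adjustment factor multiplies every S in both channels; the
  # standardization must absorb it completely
  rk1 <- rank_targets(inst$calls, inst$annotations,
                      config = ranking_config(a = 1))
  rk5 <- rank_targets(inst$calls, inst$annotations,
                      config = ranking_config(a = 5))
  expect_equal(rk1$table$final_rank, rk5$table$final_rank)
  expect_equal(rk1$table$auc, rk5$table$auc, tolerance = 1e-10)
  expect_equal(rk1$rank_matrix, rk5$rank_matrix)
})

test_that("a target ranked well only at high b1 is demoted by the AUC", {
  # T_robust holds a good rank everywhere; T_fragile wins the neutral
  # setting on active-channel strength alone but collapses for b1 < 0.3,
  # so the whole-curve area demotes it
  Z1 <- c(T_fragile = 4.0, T_robust = 1.0, A = 0.5, B = 0.0, C = -1.0,
          D = -1.5, E = -2.0)
  Z2 <- c(T_fragile = -1.0, T_robust = 1.2, A = 0.6, B = 0.1, C = -0.8,
          D = -1.2, E = -1.8)
  grid <- seq(0.01, 0.99, by = 0.01)
  m <- balance_sweep(Z1, Z2, grid)
  auc <- rank_auc(grid, m)
  neutral <- rank_scores(combined_score(Z1, Z2, 0.5))
  final <- rank(auc, ties.method = "first")
  expect_gt(final[1], neutral[1])   # fragile target demoted vs neutral rank
  expect_lt(final[2], final[1])     # robust target ends ahead of it
})

test_that("ranking configuration validates its parameters", {
  expect_error(ranking_config(a = 0), "positive")
  expect_error(ranking_config(confidence_level = 1), "confidence")
  expect_error(ranking_config(b1_grid = c(0.5, 0.4)), "increasing")
  expect_error(ranking_config(b1_grid = c(0, 0.5)), "increasing|\\(0, 1\\)")
  expect_equal(length(ranking_config()$b1_grid), 99)
})

test_that("ranking tables round-trip to TSV with rank curves", {
  inst <- random_small_instance(105)
  rk <- rank_targets(inst$calls, inst$annotations)
  f <- withr::local_tempfile(fileext = ".tsv")
  fc <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(rk, f, curves = fc)
  back <- read.delim(f)
  expect_equal(back$auc, rk$table$auc, tolerance = 1e-9)
  curves <- read.delim(fc)
  expect_equal(nrow(curves), nrow(rk$rank_matrix) * length(rk$grid))
})
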