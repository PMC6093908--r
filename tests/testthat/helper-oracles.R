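# Independent, loop-based reimplementations used as oracles. These follow
# the formulas directly and share no code with the package internals.

naive_wilson_width <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  centre <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  (centre + half) - (centre - half)
}

# rank 1 = largest, ties get the average of the spanned ranks
naive_rank <- function(I) {
  vapply(seq_along(I), function(i) {
    sum(I > I[i]) + (sum(I == I[i]) + 1) / 2
  }, numeric(1))
}

naive_trapezoid <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + (y[i] + y[i + 1]) / 2 * (x[i + 1] - x[i])
  }
  total
}

# brute-force tau-b by counting concordant/discordant pairs
naive_kendall <- function(a, b) {
  nc <- nd <- ta <- tb <- 0
  n <- length(a)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      da <- a[i] - a[j]; db <- b[i] - b[j]
      if (da == 0 && db == 0) { ta <- ta + 1; tb <- tb + 1 }
      else if (da == 0) ta <- ta + 1
      else if (db == 0) tb <- tb + 1
      else if (da * db > 0) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - ta) * (n0 - tb))
}

# full chain from activity calls to final ranking, all explicit loops
naive_target_pipeline <- function(calls, annotations, a = 1, conf = 0.95,
                                  grid = seq(0.01, 0.99, by = 0.01)) {
  calls$call <- as.character(calls$call)
  compounds <- unique(calls$compound_id)
  chan <- pos <- setNames(rep(NA, length(compounds)), compounds)
  for (cp in compounds) {
    alone <- calls$call[calls$compound_id == cp &
                          calls$condition == "compound_alone"]
    insulin <- calls$call[calls$compound_id == cp &
                            calls$condition == "compound_plus_insulin"]
    if (grepl("^excluded", alone) || grepl("^excluded", insulin)) next
    chan[cp] <- if (alone == "active") 1 else 2
    pos[cp] <- insulin == "active"
  }
  targets <- sort(unique(annotations$target_id))
  n1 <- k1 <- n2 <- k2 <- setNames(rep(0, length(targets)), targets)
  for (r in seq_len(nrow(annotations))) {
    cp <- annotations$compound_id[r]; tg <- annotations$target_id[r]
    if (is.na(chan[cp])) next
    if (chan[cp] == 1) {
      n1[tg] <- n1[tg] + 1
      if (pos[cp]) k1[tg] <- k1[tg] + 1
    } else {
      n2[tg] <- n2[tg] + 1
      if (pos[cp]) k2[tg] <- k2[tg] + 1
    }
  }
  eligible <- targets[k1 >= 1]
  n1 <- n1[eligible]; k1 <- k1[eligible]; n2 <- n2[eligible]; k2 <- k2[eligible]
  S1 <- (k1 / n1) / (a * naive_wilson_width(k1, n1, conf))
  S2 <- rep(NA_real_, length(eligible))
  for (i in seq_along(eligible)) {
    if (n2[i] > 0) {
      S2[i] <- (k2[i] / n2[i]) / (a * naive_wilson_width(k2[i], n2[i], conf))
    }
  }
  pop_z <- function(x) {
    mu <- mean(x); sig <- sqrt(mean((x - mu)^2)); (x - mu) / sig
  }
  Z1 <- pop_z(S1)
  Z2 <- rep(0, length(eligible))
  has2 <- !is.na(S2)
  if (sum(has2) >= 2) Z2[has2] <- pop_z(S2[has2])
  rank_matrix <- matrix(NA_real_, length(eligible), length(grid))
  for (g in seq_along(grid)) {
    rank_matrix[, g] <- naive_rank(grid[g] * Z1 + (1 - grid[g]) * Z2)
  }
  auc <- apply(rank_matrix, 1, function(r) naive_trapezoid(grid, r))
  neutral <- naive_rank(0.5 * Z1 + 0.5 * Z2)
  ord <- order(auc, neutral, eligible)
  final <- integer(length(eligible)); final[ord] <- seq_along(eligible)
  list(eligible = unname(eligible), S1 = unname(S1), S2 = unname(S2),
       Z1 = unname(Z1), Z2 = unname(Z2), rank_matrix = unname(rank_matrix),
       auc = unname(auc), neutral = unname(neutral), final = unname(final))
}
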