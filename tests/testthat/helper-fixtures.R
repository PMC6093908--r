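# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# a tiny hand-laid plate: 3 MAX, 3 MIN, 2 TEST wells
tiny_plate <- function(max_sig = c(1.00, 1.02, 0.98),
                       min_sig = c(0.20, 0.21, 0.19),
                       test_sig = c(0.60, 0.28)) {
  data.frame(
    plate_id = "P1",
    well = c("A01", "B01", "C01", "A12", "B12", "C12", "A02", "B02"),
    role = rep(c("MAX", "MIN", "TEST"), times = c(3, 3, 2)),
    compound_id = c(rep("", 6), "C1", "C2"),
    condition = "compound_alone",
    raw_signal = c(max_sig, min_sig, test_sig),
    stringsAsFactors = FALSE)
}

# random screen-result rows (one condition) for hit-calling properties
random_screen_rows <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    compound_id = sprintf("C%03d", seq_len(n)),
    condition = "compound_alone",
    suppression = runif(n, -20, 120),
    viability = runif(n, 0, 120),
    interference = runif(n) < 0.1,
    stringsAsFactors = FALSE))
}

# random small ranking instance: calls for both conditions + annotations,
# redrawn until at least 2 eligible targets exist and neither channel is
# degenerate (all-equal scores), which the statistic rejects by design
random_small_instance <- function(seed, max_targets = 10, max_compounds = 50) {
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      n_t <- sample(4:max_targets, 1)
      n_c <- sample(20:max_compounds, 1)
      targets <- sprintf("T%02d", seq_len(n_t))
      compounds <- sprintf("C%03d", seq_len(n_c))
      ann <- do.call(rbind, lapply(compounds, function(cp) {
        data.frame(compound_id = cp,
                   target_id = sample(targets, sample(1:3, 1)),
                   stringsAsFactors = FALSE)
      }))
      screen <- expand.grid(compound_id = compounds,
                            condition = c("compound_alone",
                                          "compound_plus_insulin"),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      per_cpd_viab <- setNames(runif(n_c, 30, 110), compounds)
      per_cpd_intf <- setNames(runif(n_c) < 0.05, compounds)
      screen$suppression <- runif(nrow(screen), 0, 100)
      screen$viability <- per_cpd_viab[screen$compound_id]
      screen$interference <- per_cpd_intf[screen$compound_id]
      calls <- call_activity(screen)
      ok <- tryCatch({
        rk <- rank_targets(calls, ann)
        nrow(rk$table) >= 2
      }, error = function(e) FALSE)
      if (ok) return(list(calls = calls, annotations = ann))
    }
    stop("could not draw a non-degenerate instance")
  })
}

# small-but-complete simulated screen for pipeline tests
small_sim_config <- function(seed) {
  simulation_config(n_compounds = 160L, n_targets = 30L,
                    n_true_regulators = 3L, seed = seed)
}
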