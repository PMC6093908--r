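# Deterministic synthetic screen with planted ground truth. The defaults
# emulate the study conditions of an annotated-library gluconeogenesis
# screen: ~1,500 compounds annotated to 1-5 of ~200 targets, a small set
# of true regulator targets whose compounds are enriched for >=60%
# suppression, ~25% cytotoxic compounds, ~1% detection-interfering
# compounds, and 96-well plates whose control noise yields Z' roughly in
# the 0.4-0.8 band.

#' Simulation configuration
#'
#' Parameters of the synthetic-screen generator. Defaults reproduce the
#' scale of the study the pipeline was designed for: a 1,523-compound
#' annotated library over 200 targets, 10 true regulator targets, 60%
#' hit enrichment for regulator-hitting compounds against a 2% background
#' hit rate, 25% cytotoxic and 1% detection-interfering compounds.
#'
#' @param n_compounds Library size (default 1523).
#' @param n_targets Number of annotated targets (default 200).
#' @param targets_per_compound Inclusive range of annotations per compound
#'   (default 1--5).
#' @param n_true_regulators Number of planted regulator targets (default 10).
#' @param regulator_hit_rate Probability that a regulator-hitting compound
#'   truly suppresses >= 60% (default 0.6).
#' @param background_hit_rate Same probability for all other compounds
#'   (default 0.02).
#' @param cytotoxic_fraction Fraction of compounds with < 60% viability
#'   (default 0.25).
#' @param interference_fraction Fraction of compounds distorting the
#'   glucose detection readout (default 0.01).
#' @param plate_noise_sd Baseline well-level absorbance noise SD; each
#'   plate scales it by a random factor in \[0.75, 1.75\], giving the Z'
#'   spread of a realistic validation run (default 0.04).
#' @param insulin_effect Mean extra suppression (percentage points) that
#'   insulin adds for regulator-hitting compounds (default 12).
#' @param max_signal,min_signal Absorbance levels of the MAX and MIN
#'   controls (defaults 1.0 and 0.2 A570).
#' @param counter_reference Compound-free counter-assay signal at the
#'   fixed glucose standard (default 0.6).
#' @param annotation_shape Gamma shape of the per-target annotation
#'   weights; smaller values give stronger disparities in how many
#'   compounds each target is annotated to (default 2).
#' @param plate_rows,plate_cols Plate format (default 8 x 12, 96-well;
#'   controls sit in the first and last columns).
#' @param seed Integer seed; a fixed seed makes every emitter
#'   byte-identical across runs. `NULL` uses the session RNG.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 1523L, n_targets = 200L,
                              targets_per_compound = c(1L, 5L),
                              n_true_regulators = 10L,
                              regulator_hit_rate = 0.6,
                              background_hit_rate = 0.02,
                              cytotoxic_fraction = 0.25,
                              interference_fraction = 0.01,
                              plate_noise_sd = 0.04,
                              insulin_effect = 12,
                              max_signal = 1.0, min_signal = 0.2,
                              counter_reference = 0.6,
                              annotation_shape = 2,
                              plate_rows = 8L, plate_cols = 12L,
                              seed = NULL) {
  probs <- c(regulator_hit_rate, background_hit_rate, cytotoxic_fraction,
             interference_fraction)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_true_regulators > n_targets) {
    stop("n_true_regulators cannot exceed n_targets")
  }
  if (length(targets_per_compound) != 2L ||
      targets_per_compound[1] < 1L ||
      targets_per_compound[2] > n_targets ||
      targets_per_compound[1] > targets_per_compound[2]) {
    stop("targets_per_compound must be a valid range within 1..n_targets")
  }
  if (max_signal <= min_signal) stop("max_signal must exceed min_signal")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_targets = as.integer(n_targets),
                 targets_per_compound = as.integer(targets_per_compound),
                 n_true_regulators = as.integer(n_true_regulators),
                 regulator_hit_rate = regulator_hit_rate,
                 background_hit_rate = background_hit_rate,
                 cytotoxic_fraction = cytotoxic_fraction,
                 interference_fraction = interference_fraction,
                 plate_noise_sd = plate_noise_sd,
                 insulin_effect = insulin_effect,
                 max_signal = max_signal, min_signal = min_signal,
                 counter_reference = counter_reference,
                 annotation_shape = annotation_shape,
                 plate_rows = as.integer(plate_rows),
                 plate_cols = as.integer(plate_cols),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# truncated normal by inverse-CDF; lo/hi are hard bounds
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

modulation_types <- c("inhibitor", "antagonist", "agonist", "blocker", "other")

#' Simulate a compound-to-target annotation table
#'
#' Every compound is annotated to 1--5 targets drawn without replacement
#' with gamma-distributed per-target weights, producing the large
#' disparities in per-target tested-compound counts that real annotated
#' libraries show.
#'
#' @param config A [simulation_config()].
#' @return Annotation `data.frame` (`compound_id`, `target_id`,
#'   `modulation_type`), no duplicate pairs, every compound annotated.
#' @export
simulate_annotations <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  maybe_with_seed(config$seed, {
    targets <- sprintf("T%03d", seq_len(config$n_targets))
    compounds <- sprintf("C%04d", seq_len(config$n_compounds))
    weights <- stats::rgamma(config$n_targets, shape = config$annotation_shape)
    m <- sample(seq(config$targets_per_compound[1],
                    config$targets_per_compound[2]),
                config$n_compounds, replace = TRUE)
    picks <- lapply(m, function(k) sample(targets, k, prob = weights))
    ann <- data.frame(compound_id = rep(compounds, times = m),
                      target_id = unlist(picks),
                      stringsAsFactors = FALSE)
    ann$modulation_type <- sample(modulation_types, nrow(ann), replace = TRUE)
    ann
  })
}

#' Simulate screen plates with planted ground truth
#'
#' Emits 96-well plate data for both assay arms (compound alone and
#' compound plus 1 nM insulin), a viability table, a counter-assay table,
#' and the planted truth. Compounds annotated to at least one of the
#' planted regulator targets draw true suppression above the 60% activity
#' threshold with probability `regulator_hit_rate`; all others with
#' probability `background_hit_rate`. Near-miss regulator compounds
#' cluster just under the threshold and insulin adds a synergy shift, so
#' part of them cross 60% only in the insulin arm -- the signal the
#' inactive evidence channel picks up. Cytotoxic and interfering
#' compounds are planted at the configured fractions; interference is a
#' multiplicative distortion of the glucose signal applied identically in
#' the screen and in the counter assay, so the counter assay can detect it.
#'
#' @param config A [simulation_config()].
#' @param annotations Annotation table from [simulate_annotations()]
#'   (needed to decide which compounds hit regulator targets).
#' @return A list with `wells` (plate well records), `viability`,
#'   `counter_assay`, and `truth` (list: `regulator_targets`, per-compound
#'   `compounds` data.frame).
#' @export
simulate_plates <- function(config, annotations) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  maybe_with_seed(seed, {
    n <- config$n_compounds
    compounds <- sprintf("C%04d", seq_len(n))
    targets <- sprintf("T%03d", seq_len(config$n_targets))
    # true regulators are drawn from the mid-annotation band: not the
    # promiscuous library workhorses (which would flood the screen with
    # actives) nor the barely-annotated tail (untestable with 1-2
    # compounds); this keeps the active yield at the tens-per-1500 scale
    # such screens report while every regulator stays recoverable
    counts <- table(factor(annotations$target_id, levels = targets))
    band <- stats::quantile(counts, c(0.25, 0.75), type = 1)
    mid <- targets[counts >= band[1] & counts <= band[2]]
    regulators <- sort(sample(mid, config$n_true_regulators))
    hits_reg <- compounds %in%
      annotations$compound_id[annotations$target_id %in% regulators]

    cytotoxic <- stats::runif(n) < config$cytotoxic_fraction
    viability <- ifelse(cytotoxic, stats::runif(n, 5, 55),
                        pmax(61, pmin(115, stats::rnorm(n, 95, 8))))
    interfering <- stats::runif(n) < config$interference_fraction
    distort <- ifelse(interfering,
                      ifelse(stats::runif(n) < 0.5,
                             stats::runif(n, 0.3, 0.7),
                             stats::runif(n, 1.4, 1.9)),
                      1)

    hit <- stats::runif(n) < ifelse(hits_reg, config$regulator_hit_rate,
                                    config$background_hit_rate)
    supp_alone <- numeric(n)
    supp_alone[hit & hits_reg] <- rtnorm(sum(hit & hits_reg), 75, 12, 60.5, 100)
    supp_alone[!hit & hits_reg] <- rtnorm(sum(!hit & hits_reg), 45, 10, 0, 59.5)
    supp_alone[hit & !hits_reg] <- rtnorm(sum(hit & !hits_reg), 72, 8, 60.5, 100)
    supp_alone[!hit & !hits_reg] <- rtnorm(sum(!hit & !hits_reg), 15, 12, 0, 59.5)
    synergy <- ifelse(hits_reg, stats::rnorm(n, config$insulin_effect, 6),
                      stats::rnorm(n, 0, 5))
    supp_insulin <- pmin(100, pmax(0, supp_alone + synergy))

    wells <- rbind(
      render_plates(config, compounds, supp_alone, distort, "compound_alone"),
      render_plates(config, compounds, supp_insulin, distort,
                    "compound_plus_insulin")
    )
    counter <- data.frame(
      compound_id = compounds,
      measured_signal = config$counter_reference * distort *
        (1 + stats::rnorm(n, 0, 0.02)),
      reference_signal = config$counter_reference,
      stringsAsFactors = FALSE)

    truth <- list(
      regulator_targets = regulators,
      compounds = data.frame(compound_id = compounds,
                             hits_regulator = hits_reg,
                             true_suppression_alone = supp_alone,
                             true_suppression_insulin = supp_insulin,
                             viability = viability,
                             cytotoxic = cytotoxic,
                             interference = interfering,
                             interference_factor = distort,
                             stringsAsFactors = FALSE))
    list(wells = wells,
         viability = data.frame(compound_id = compounds, viability = viability,
                                stringsAsFactors = FALSE),
         counter_assay = counter,
         truth = truth)
  })
}

# lay compounds out on plates: controls in the first (MAX) and last (MIN)
# columns, test wells in between, one well per compound and condition
render_plates <- function(config, compounds, suppression, distort, condition) {
  rows <- LETTERS[seq_len(config$plate_rows)]
  test_cols <- seq(2L, config$plate_cols - 1L)
  per_plate <- length(rows) * length(test_cols)
  n_plates <- ceiling(length(compounds) / per_plate)
  span <- config$max_signal - config$min_signal
  tag <- if (condition == "compound_alone") "A" else "I"
  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    pid <- sprintf("P%s%02d", tag, p)
    idx <- seq((p - 1L) * per_plate + 1L, min(p * per_plate, length(compounds)))
    sd_p <- config$plate_noise_sd * stats::runif(1, 0.75, 1.75)
    ctrl_wells <- c(sprintf("%s%02d", rows, 1L),
                    sprintf("%s%02d", rows, config$plate_cols))
    ctrl <- data.frame(
      plate_id = pid,
      well = ctrl_wells,
      role = rep(c("MAX", "MIN"), each = length(rows)),
      compound_id = "",
      condition = condition,
      raw_signal = pmax(0, c(stats::rnorm(length(rows), config$max_signal, sd_p),
                             stats::rnorm(length(rows), config$min_signal, sd_p))),
      stringsAsFactors = FALSE)
    slots <- as.vector(outer(rows, test_cols, function(r, cc)
      sprintf("%s%02d", r, cc)))[seq_along(idx)]
    clean <- config$min_signal + (100 - suppression[idx]) / 100 * span
    test <- data.frame(
      plate_id = pid,
      well = slots,
      role = "TEST",
      compound_id = compounds[idx],
      condition = condition,
      raw_signal = pmax(0, (clean + stats::rnorm(length(idx), 0, sd_p)) *
                          distort[idx]),
      stringsAsFactors = FALSE)
    out[[p]] <- rbind(ctrl, test)
  }
  do.call(rbind, out)
}

#' Simulate a complete screen
#'
#' Convenience wrapper: annotations plus plates/viability/counter-assay
#' and ground truth from one configuration.
#'
#' @param config A [simulation_config()].
#' @return List with `annotations`, `wells`, `viability`, `counter_assay`,
#'   `truth`.
#' @export
simulate_screen <- function(config = simulation_config()) {
  annotations <- simulate_annotations(config)
  sim <- simulate_plates(config, annotations)
  c(list(annotations = annotations), sim)
}

#' Simulate a qPCR Ct replicate table with planted effects
#'
#' Generates control/treatment Ct replicates whose expected fold change
#' for gene `g` is exactly `2^(log2_effects[g])`: the treatment arm's
#' gene Ct is shifted down by the planted log2 effect. Reference
#' (housekeeping) Ct values are drawn per replicate and cancel exactly in
#' delta Ct; measurement noise is added to the gene Ct only, so the zero
#' noise limit reproduces the planted fold changes without error.
#'
#' @param genes Character vector of gene symbols, or a count (default 84,
#'   an insulin-signaling array's panel size).
#' @param log2_effects Planted log2 fold changes, recycled over genes
#'   (default 0).
#' @param noise_sd Ct measurement noise SD (default 0.15, a realistic
#'   technical-replicate spread).
#' @param replicates Replicates per arm (default 3).
#' @param seed Optional integer seed.
#' @return Long-format Ct `data.frame` as consumed by [analyze_qpcr()].
#' @export
simulate_qpcr <- function(genes = 84L, log2_effects = 0, noise_sd = 0.15,
                          replicates = 3L, seed = NULL) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("G%03d", seq_len(genes))
  }
  if (replicates < 2L) stop("need at least 2 replicates per arm")
  effects <- rep_len(log2_effects, length(genes))
  maybe_with_seed(seed, {
    base_dct <- stats::runif(length(genes), 2, 8)
    grid <- expand.grid(replicate = seq_len(replicates),
                        arm = c("control", "treatment"),
                        gene_symbol = genes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- match(grid$gene_symbol, genes)
    ct_ref <- stats::rnorm(nrow(grid), 20, 0.3)
    shift <- ifelse(grid$arm == "treatment", effects[g], 0)
    ct_gene <- ct_ref + base_dct[g] - shift +
      stats::rnorm(nrow(grid), 0, noise_sd)
    data.frame(gene_symbol = grid$gene_symbol, arm = grid$arm,
               replicate = grid$replicate,
               ct_gene = ct_gene, ct_ref = ct_ref,
               stringsAsFactors = FALSE)
  })
}
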