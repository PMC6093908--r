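#' Run the screen analysis chain in memory
#'
#' Chains plate QC, normalization, hit calling and target ranking on a
#' simulated (or loaded) screen: the in-memory equivalent of the staged
#' file pipeline in [run_pipeline()].
#'
#' @param sim A list with `wells`, `annotations`, `viability`,
#'   `counter_assay` (as produced by [simulate_screen()] or read from
#'   files).
#' @param inhibition_threshold,viability_threshold Hit-calling thresholds
#'   (default 60/60).
#' @param tolerance Counter-assay relative tolerance (default 0.2).
#' @param config A [ranking_config()].
#' @return List with `qc` (plate summary), `screen` (per-compound
#'   results), `calls`, and `ranking` (a `target_ranking`).
#' @export
analyze_screen <- function(sim, inhibition_threshold = 60,
                           viability_threshold = 60, tolerance = 0.2,
                           config = ranking_config()) {
  qc <- plate_summary(sim$wells)
  screen <- screen_results(sim$wells, sim$viability, sim$counter_assay,
                           tolerance = tolerance)
  calls <- call_activity(screen, inhibition_threshold, viability_threshold)
  ranking <- rank_targets(calls, sim$annotations, config = config)
  list(qc = qc, screen = screen, calls = calls, ranking = ranking)
}

#' Run the full staged pipeline and write a run manifest
#'
#' Simulates a screen (or loads one from `in_dir`), then runs every stage
#' -- plate QC, normalization, hit calling, target ranking, qPCR
#' quantification -- writing each stage's output as TSV/CSV under
#' `out_dir` together with a JSON manifest (configuration snapshot, file
#' digests, seed, timestamp). With a fixed seed, re-running reproduces
#' identical digests for every deterministic stage.
#'
#' @param out_dir Output directory (created if missing).
#' @param sim_config A [simulation_config()]; used when `in_dir` is NULL.
#' @param in_dir Optional directory containing `plates.csv`,
#'   `annotations.tsv`, `viability.tsv`, `counter_assay.tsv` (and
#'   optionally `qpcr_ct.tsv`) from a previous run or a real screen.
#' @param ranking A [ranking_config()].
#' @param qpcr_log2_effects Planted log2 effects for the simulated qPCR
#'   stage (ignored when `in_dir` supplies a Ct table).
#' @param inhibition_threshold,viability_threshold,tolerance Hit-calling
#'   parameters.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, sim_config = simulation_config(seed = 1L),
                         in_dir = NULL, ranking = ranking_config(),
                         qpcr_log2_effects = c(2, -2, rep(0, 82)),
                         inhibition_threshold = 60, viability_threshold = 60,
                         tolerance = 0.2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(in_dir)) {
    sim <- stage("simulate", simulate_screen(sim_config))
    qpcr_seed <- if (is.null(sim_config$seed)) NULL else sim_config$seed + 2L
    qpcr_ct <- stage("simulate", simulate_qpcr(
      log2_effects = qpcr_log2_effects, seed = qpcr_seed))
    utils::write.csv(sim$wells, file.path(out_dir, "plates.csv"),
                     row.names = FALSE, quote = FALSE)
    write_tsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv(sim$annotations, "annotations.tsv")
    write_tsv(sim$viability, "viability.tsv")
    write_tsv(sim$counter_assay, "counter_assay.tsv")
    write_tsv(qpcr_ct, "qpcr_ct.tsv")
    write_tsv(data.frame(target_id = sim$truth$regulator_targets), "truth_regulators.tsv")
    write_tsv(sim$truth$compounds, "truth_compounds.tsv")
  } else {
    need <- function(f) {
      p <- file.path(in_dir, f)
      if (!file.exists(p)) {
        stop("pipeline stage 'load' failed: missing input file ", f,
             call. = FALSE)
      }
      p
    }
    sim <- stage("load", list(
      wells = read_plates(need("plates.csv")),
      annotations = read_annotations(need("annotations.tsv")),
      viability = utils::read.delim(need("viability.tsv"),
                                    stringsAsFactors = FALSE),
      counter_assay = utils::read.delim(need("counter_assay.tsv"),
                                        stringsAsFactors = FALSE)))
    qpcr_path <- file.path(in_dir, "qpcr_ct.tsv")
    qpcr_ct <- if (file.exists(qpcr_path)) read_qpcr_ct(qpcr_path) else NULL
  }

  qc <- stage("plate_qc", plate_summary(sim$wells))
  write_qc_report(qc, file.path(out_dir, "qc.tsv"))
  screen <- stage("hit_calling", screen_results(
    sim$wells, sim$viability, sim$counter_assay, tolerance))
  calls <- stage("hit_calling", call_activity(
    screen, inhibition_threshold, viability_threshold))
  write_calls(calls, file.path(out_dir, "calls.tsv"))
  rk <- stage("target_ranking", rank_targets(calls, sim$annotations,
                                             config = ranking))
  write_ranking(rk, file.path(out_dir, "ranking.tsv"),
                curves = file.path(out_dir, "rank_curves.tsv"))
  if (!is.null(qpcr_ct)) {
    qpcr <- stage("qpcr_ddct", analyze_qpcr(qpcr_ct))
    write_qpcr_results(qpcr, file.path(out_dir, "qpcr_results.tsv"))
  }

  outputs <- list.files(out_dir, pattern = "\\.(tsv|csv)$", full.names = TRUE)
  manifest <- list(
    package = "chemrank",
    version = as.character(utils::packageVersion("chemrank")),
    seed = if (is.null(in_dir)) sim_config$seed else NULL,
    config = if (is.null(in_dir)) unclass(sim_config) else list(in_dir = in_dir),
    thresholds = list(inhibition = inhibition_threshold,
                      viability = viability_threshold,
                      counter_assay_tolerance = tolerance),
    n_plates = nrow(qc),
    call_summary = as.list(summarize_screen(calls)),
    n_ranked_targets = nrow(rk$table),
    file_digests = as.list(tools::md5sum(outputs)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
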