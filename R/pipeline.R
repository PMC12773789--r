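#' Run the full unpredictability analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage in order: simulate -> ingest (score, monthly
#' aggregation, eligibility) -> unpredictability statistics -> PCA +
#' composite -> descriptives (scale scores, correlations, group summaries)
#' -> balancing + weighted effect models on the outcome subsample. All
#' randomness flows from `config$seed`; rerunning with the same config
#' reproduces identical artifacts.
#'
#' @param config A [sim_config()]; validated before any stage runs.
#' @param output_dir Optional directory; when given, every stage's tables
#'   are written as CSV/JSON and a `run_report.json` with MD5 checksums is
#'   emitted.
#' @param penalty_rule,noise_transform Passed to [env_stats()].
#' @param k Components retained in the PCA composite.
#' @param methods Balancing methods searched per exposure.
#' @return List of class `hardship_run`: `cohort`, `series`, `eligibility`,
#'   `env_stats`, `pca`, `composite`, `scales`, `correlations`,
#'   `group_summaries`, `analysis`, `effects`, `config`.
#' @export
run_pipeline <- function(config = sim_config(), output_dir = NULL,
                         penalty_rule = "mbic", noise_transform = "negabs",
                         k = 2, methods = c("gps", "ebal")) {
  validate_sim_config(config)

  cohort <- simulate_cohort(config)

  scored <- score_responses(cohort$responses)
  series <- monthly_series(scored)
  eligible <- filter_eligible(series, min_months = config$min_months)
  elig_report <- eligibility_report(eligible)

  es <- env_stats(eligible, penalty_rule = penalty_rule,
                  noise_transform = noise_transform)

  pca <- fit_pca(es, k = k)
  comp <- composite_index(pca)

  scales <- score_scales(cohort$routines, cohort$quic)
  index_tbl <- es %>%
    dplyr::left_join(comp, by = "family_id") %>%
    dplyr::left_join(scales, by = "family_id")
  correlations <- pairwise_correlations(
    index_tbl,
    vars = c("severity", "cv", "n_cpt_mean", "n_cpt_var", "noise_unpred",
             "composite", "routines_mean", "quic_sum")
  )
  grp_data <- dplyr::inner_join(index_tbl, cohort$confounders, by = "family_id")
  groups <- dplyr::bind_rows(lapply(
    c("education", "income_fpl", "race_ethnicity"),
    function(g) group_summaries(
      grp_data, g,
      vars = c("cv", "n_cpt_mean", "n_cpt_var", "noise_unpred", "composite")
    )
  ))

  analysis <- cohort$outcome %>%
    dplyr::inner_join(index_tbl, by = "family_id") %>%
    dplyr::inner_join(cohort$confounders, by = "family_id")
  X <- confounder_design(analysis)
  effects <- effect_suite(analysis, X, outcome = "self_regulation",
                          methods = methods)

  run <- structure(list(
    cohort = cohort,
    series = series,
    eligibility = elig_report,
    env_stats = es,
    pca = pca,
    composite = comp,
    scales = scales,
    correlations = correlations,
    group_summaries = groups,
    analysis = analysis,
    effects = effects,
    config = config
  ), class = "hardship_run")

  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.hardship_run <- function(x, ...) {
  cat("<hardship_run> seed", x$config$seed, "\n")
  cat("  eligible families:", x$eligibility$n_eligible, "of",
      x$eligibility$n_total, "\n")
  cat(sprintf("  PC variance shares: %.2f%% / %.2f%%\n",
              100 * x$pca$variance_explained[1],
              100 * x$pca$variance_explained[2]))
  cat("  effects (ordered by |beta|):\n")
  print(as.data.frame(x$effects[, c("exposure", "B", "beta_std", "p_value",
                                    "ess", "method")]), digits = 3)
  invisible(x)
}

#' Write a pipeline run's tables and checksummed report to disk
#'
#' Emits the monthly series, index table, composite, scale scores,
#' correlations, group summaries and effects table as CSV, the PCA model as
#' JSON, and `run_report.json` with the seed and MD5 checksums of every
#' artifact.
#'
#' @param run A `hardship_run` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(tbl, name) {
    p <- file.path(dir, name)
    write.csv(tbl, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(run$series, "monthly_series.csv")
  wr(run$env_stats, "envstats.csv")
  wr(run$composite, "composite.csv")
  wr(run$scales, "scales.csv")
  wr(as_tibble(run$correlations), "correlations.csv")
  wr(run$group_summaries, "group_summaries.csv")
  wr(run$effects, "effects_table.csv")

  p <- file.path(dir, "pca_model.json")
  jsonlite::write_json(list(
    features = run$pca$features,
    center = run$pca$center,
    scale = run$pca$scale,
    loadings = run$pca$loadings,
    eigenvalues = run$pca$eigenvalues,
    variance_explained = run$pca$variance_explained,
    k = run$pca$k,
    sign_convention = "loading on n_cpt_var non-negative"
  ), p, auto_unbox = TRUE, digits = NA)
  paths[["pca_model.json"]] <- p

  checksums <- tools::md5sum(unlist(paths))
  names(checksums) <- names(paths)
  rp <- file.path(dir, "run_report.json")
  jsonlite::write_json(list(
    seed = run$config$seed,
    n_families = run$config$n_families,
    eligibility = as.list(run$eligibility),
    checksums = as.list(checksums)
  ), rp, auto_unbox = TRUE, digits = NA)
  invisible(c(unlist(paths), run_report = rp))
}
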