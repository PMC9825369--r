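# End-to-end orchestration: per-patient measure table, diagnostics for
# every measure x outcome definition, reflex summaries, propagation
# summary, all written as CSV with a JSON config echo. Deterministic for a
# fixed config.

# polarity registry: which direction of each measure predicts the positive
# outcome (declared before any ROC is run)
MEASURE_SPECS <- list(
  fr_rr = "higher_predicts_positive",
  rate_distance_diff = "lower_predicts_positive",
  distance_diff = "lower_predicts_positive",
  cpl_rr = "higher_predicts_positive",
  max_clust_unres = "higher_predicts_positive",
  mean_le_unres_pre = "higher_predicts_positive",
  mean_le_unres_post = "higher_predicts_positive"
)

default_measure_spec <- function(name) {
  pol <- MEASURE_SPECS[[name]]
  if (is.null(pol)) stop("no registered polarity for measure ", name,
                         call. = FALSE)
  measure_spec(name, pol)
}

#' All per-patient measures
#'
#' Runs the selection, spatial-network, and MI-network stages on one
#' patient and collects every scalar measure in a one-row data.frame.
#'
#' @inheritParams select_events
#' @return One-row data.frame: `patient_id`, `engel`, `n_events_selected`,
#'   `undersampled`, `soz_rr`, `soz_radius`, `unresected_soz_radius`,
#'   `fr_rr`, `rate_distance_diff`, `distance_diff`, `cpl_rr`,
#'   `max_clust_unres`, `mean_le_unres_pre`, `mean_le_unres_post`,
#'   `zero_le_pct_res`, `zero_le_pct_unres`, `indeterminate_reason`.
#' @export
patient_measures <- function(patient, rule = selection_rule("fr_gt350")) {
  rule <- as_rule(rule)
  soz <- soz_measures(patient)
  panel <- mi_metric_panel(patient, rule)
  data.frame(
    patient_id = patient$patient_id,
    engel = patient$engel,
    n_events_selected = nrow(select_events(patient, rule)),
    undersampled = as.logical(undersampling_flag(patient, rule)),
    soz_rr = soz$soz_rr,
    soz_radius = soz$soz_radius,
    unresected_soz_radius = soz$unresected_soz_radius,
    fr_rr = resection_ratio(patient, rule),
    rate_distance_diff = rate_distance_radius_difference(patient, rule),
    distance_diff = distance_radius_difference(patient, rule),
    cpl_rr = if (is.na(panel$indeterminate_reason)) panel$cpl_rr
             else NA_real_,
    max_clust_unres = panel$max_clust_unres,
    mean_le_unres_pre = panel$mean_le_unres_pre,
    mean_le_unres_post = panel$mean_le_unres_post,
    zero_le_pct_res = panel$zero_le_pct_res,
    zero_le_pct_unres = panel$zero_le_pct_unres,
    indeterminate_reason = if (is.na(panel$indeterminate_reason))
      NA_character_ else panel$indeterminate_reason,
    stringsAsFactors = FALSE
  )
}

#' Cohort measure table
#'
#' @param cohort An `fr_cohort`.
#' @inheritParams select_events
#' @return data.frame with one [patient_measures()] row per patient.
#' @export
cohort_measures <- function(cohort, rule = selection_rule("fr_gt350")) {
  do.call(rbind, lapply(cohort$patients, patient_measures, rule = rule))
}

#' Pipeline run configuration
#'
#' @param rule Selection-rule mode.
#' @param outcome_definitions Outcome label definitions to evaluate.
#' @param impute_rule Indeterminate-patient rule for confusion matrices.
#' @param alpha_propagation,window_ms Propagation sign-test settings.
#' @param reflex_measures Measures used to re-test `fr_rr` positives.
#' @param seed Integer seed (used by any stage that randomizes).
#' @return A `run_config` list.
#' @export
run_config <- function(rule = "fr_gt350",
                       outcome_definitions = c("seizure_free", "improved"),
                       impute_rule = "as_misclassified",
                       alpha_propagation = 0.005,
                       window_ms = 250,
                       reflex_measures = c("rate_distance_diff", "cpl_rr"),
                       seed = 1L) {
  structure(list(
    rule = rule,
    outcome_definitions = match.arg(outcome_definitions,
                                    c("seizure_free", "improved"),
                                    several.ok = TRUE),
    impute_rule = match.arg(impute_rule,
                            c("as_misclassified", "as_test_negative",
                              "exclude")),
    alpha_propagation = alpha_propagation,
    window_ms = window_ms,
    reflex_measures = reflex_measures,
    seed = as.integer(seed),
    rng_kind = "Mersenne-Twister"
  ), class = "run_config")
}

diagnostic_row <- function(dr, measure, definition) {
  m <- dr$metrics
  data.frame(
    measure = measure, outcome = definition, auc = dr$auc,
    youden_threshold = dr$youden_threshold, youden_j = dr$youden_j,
    tp = dr$confusion$tp, fp = dr$confusion$fp, fn = dr$confusion$fn,
    tn = dr$confusion$tn, n_indeterminate = dr$n_indeterminate,
    sensitivity = m$sensitivity$estimate,
    sensitivity_lo = m$sensitivity$ci_lo, sensitivity_hi = m$sensitivity$ci_hi,
    specificity = m$specificity$estimate,
    specificity_lo = m$specificity$ci_lo, specificity_hi = m$specificity$ci_hi,
    ppv = m$ppv$estimate, npv = m$npv$estimate,
    accuracy = m$accuracy$estimate,
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> per-patient measures -> Spearman + ROC diagnostics
#' for every measure and outcome definition -> reflex testing of FR RR
#' positives -> propagation summary. All tables are written to `out_dir`
#' as CSV together with a JSON echo of the configuration; a rerun with the
#' same cohort and config is byte-identical.
#'
#' @param cohort An `fr_cohort`.
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed; `NULL` skips
#'   writing.
#' @return List with `measures`, `spearman`, `diagnostics`, `reflex`,
#'   `propagation` tables (invisibly also on disk).
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "fr_cohort"), inherits(config, "run_config"))
  rule <- selection_rule(config$rule)
  measures <- cohort_measures(cohort, rule)

  measure_names <- names(MEASURE_SPECS)
  sp_rows <- lapply(measure_names, function(m) {
    sp <- spearman_outcome(measures[[m]], measures$engel)
    data.frame(measure = m, rho = sp$rho, p = sp$p, r2 = sp$r2, n = sp$n,
               stringsAsFactors = FALSE)
  })
  spearman <- do.call(rbind, sp_rows)

  diag_rows <- list()
  results_by <- list()
  for (def in config$outcome_definitions) {
    labels <- outcome_labels(measures$engel, def)
    for (m in measure_names) {
      vals <- measures[[m]]
      if (all(is.na(vals)) || length(unique(labels[!is.na(vals)])) < 2)
        next
      dr <- roc_analysis(vals, labels, default_measure_spec(m),
                         impute_rule = config$impute_rule)
      results_by[[paste(m, def, sep = ".")]] <- dr
      diag_rows[[length(diag_rows) + 1L]] <- diagnostic_row(dr, m, def)
    }
  }
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else NULL

  reflex_rows <- list()
  for (def in config$outcome_definitions) {
    prim_dr <- results_by[[paste("fr_rr", def, sep = ".")]]
    if (is.null(prim_dr)) next
    labels <- outcome_labels(measures$engel, def)
    for (rm in config$reflex_measures) {
      refl_dr <- results_by[[paste(rm, def, sep = ".")]]
      if (is.null(refl_dr)) next
      rt <- reflex_test(
        primary = list(values = measures$fr_rr,
                       threshold = prim_dr$youden_threshold,
                       spec = default_measure_spec("fr_rr")),
        reflex = list(values = measures[[rm]],
                      threshold = refl_dr$youden_threshold,
                      spec = default_measure_spec(rm)),
        labels = labels, impute_rule = config$impute_rule)
      reflex_rows[[length(reflex_rows) + 1L]] <- data.frame(
        outcome = def, reflex_measure = rm,
        misclass_before = rt$misclass_before,
        misclass_after = rt$misclass_after,
        misclass_rate_before = rt$misclass_rate_before,
        misclass_rate_after = rt$misclass_rate_after,
        stringsAsFactors = FALSE)
    }
  }
  reflex <- if (length(reflex_rows)) do.call(rbind, reflex_rows) else NULL

  propagation <- propagation_resection_summary(
    cohort, rule, alpha = config$alpha_propagation,
    window_ms = config$window_ms)

  out <- list(measures = measures, spearman = spearman,
              diagnostics = diagnostics, reflex = reflex,
              propagation = propagation)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (!is.null(df))
        write.csv(format_for_csv(df), file.path(out_dir, name),
                  row.names = FALSE, quote = TRUE, eol = "\n")
    }
    wr(out$measures, "measures.csv")
    wr(out$spearman, "spearman.csv")
    wr(out$diagnostics, "diagnostics.csv")
    wr(out$reflex, "reflex.csv")
    wr(out$propagation, "propagation.csv")
    echo <- c(unclass(config),
              list(package_version = as.character(
                utils::packageVersion("frnet"))))
    jsonlite::write_json(echo, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

format_for_csv <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- fmt_num(df[[nm]])
  df
}
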