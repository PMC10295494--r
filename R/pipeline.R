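#' Pipeline run configuration
#'
#' Collects every analysis choice in one validated object: seed, input
#' mode (simulate, or a cohort CSV path), BSA formula, stiffness-index
#' interpretation, correlation flavour, t-test variant, ROC
#' operating-point criterion, significance level, and an optional output
#' directory.
#'
#' @param seed Integer seed (simulation mode).
#' @param cohort_path Path to a cohort CSV, or `NULL` to simulate.
#' @param n Cohort size in simulation mode.
#' @param calibrate Run [calibrate_spec()] before generating.
#' @param bsa_method,stiffness,correlation,t_variant,roc_criterion
#'   Analysis options, see the per-stage functions.
#' @param alpha Significance level, in (0, 0.5].
#' @param output_dir Directory to write the report bundle into, or `NULL`
#'   to only return it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, cohort_path = NULL, n = 97,
                       calibrate = TRUE,
                       bsa_method = c("du_bois", "mosteller"),
                       stiffness = c("log_of_ratio", "classic_beta"),
                       correlation = c("pearson", "spearman"),
                       t_variant = c("pooled", "welch"),
                       roc_criterion = c("max_accuracy", "youden"),
                       alpha = 0.05, output_dir = NULL) {
  if (!(alpha > 0 && alpha <= 0.5)) {
    stop("alpha must lie in (0, 0.5]", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), cohort_path = cohort_path, n = n,
    calibrate = calibrate,
    bsa_method = match.arg(bsa_method),
    stiffness = match.arg(stiffness),
    correlation = match.arg(correlation),
    t_variant = match.arg(t_variant),
    roc_criterion = match.arg(roc_criterion),
    alpha = alpha, output_dir = output_dir
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, derives the per-patient indices, and
#' produces the complete report bundle: descriptive summary, the two
#' median-split subgroup tables (EAT outcomes split by aortic indices and
#' vice versa), the EAT-aorta correlation table, the 12-row ROC grid with
#' per-curve coordinates, and a machine-readable summary containing every
#' number in the rendered tables. Output is deterministic for a fixed
#' config.
#'
#' @param config A [run_config()] object.
#' @return The report bundle (a list), invisibly if written to disk.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (is.null(config$cohort_path)) {
      spec <- default_spec(n = config$n, seed = config$seed)
      if (config$calibrate) spec <- calibrate_spec(spec)
      generate_cohort(spec)
    } else {
      read_cohort(config$cohort_path)
    }
  })
  derived <- stage("derive", derive_indices(
    cohort, bsa_method = config$bsa_method, stiffness = config$stiffness))
  descriptive <- stage("describe", descriptive_table(derived))
  eat_by_aorta <- stage("subgroups", subgroup_table(
    derived,
    split_vars = c("ao_stiffness_index", "ao_strain", "ao_distensibility"),
    outcome_vars = c("eat_thickness", "eat_volume", "eat_thickness_index",
                     "eat_volume_index"),
    alpha = config$alpha, t_variant = config$t_variant))
  aorta_by_eat <- stage("subgroups", subgroup_table(
    derived,
    split_vars = c("eat_thickness", "eat_volume", "eat_thickness_index",
                   "eat_volume_index"),
    outcome_vars = c("ao_stiffness_index", "ao_strain", "ao_distensibility"),
    alpha = config$alpha, t_variant = config$t_variant))
  correlations <- stage("correlations",
                        correlation_table(derived, config$correlation))
  roc <- stage("roc", roc_report(derived, config$roc_criterion))
  n_tests <- nrow(eat_by_aorta) + nrow(aorta_by_eat)
  summary <- list(
    config = unclass(config)[c("seed", "n", "bsa_method", "stiffness",
                               "correlation", "t_variant", "roc_criterion",
                               "alpha")],
    n_records = nrow(derived),
    n_significance_tests = n_tests,
    descriptive = descriptive,
    subgroups_eat_by_aorta = eat_by_aorta,
    subgroups_aorta_by_eat = aorta_by_eat,
    correlations = as.data.frame(as.table(correlations),
                                 stringsAsFactors = FALSE),
    roc = roc[, setdiff(names(roc), "results")]
  )
  bundle <- list(cohort = cohort, derived = derived,
                 descriptive = descriptive,
                 subgroups_eat_by_aorta = eat_by_aorta,
                 subgroups_aorta_by_eat = aorta_by_eat,
                 correlations = correlations, roc = roc,
                 summary = summary)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    write_cohort(derived, out("derived_indices.csv"))
    utils::write.csv(render_descriptive(descriptive), out("table_descriptive.csv"),
                     row.names = FALSE)
    utils::write.csv(render_subgroups(eat_by_aorta),
                     out("table_eat_by_aortic_median.csv"), row.names = FALSE)
    utils::write.csv(render_subgroups(aorta_by_eat),
                     out("table_aortic_by_eat_median.csv"), row.names = FALSE)
    utils::write.csv(round(correlations, 2), out("table_correlations.csv"))
    utils::write.csv(render_roc(roc), out("table_roc.csv"), row.names = FALSE)
    curves <- attr(roc, "results")
    for (key in names(curves)) {
      utils::write.table(curves[[key]]$curve,
                         out(paste0("roc_", gsub("~", "_vs_", key), ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}

#' @keywords internal
render_descriptive <- function(descriptive) {
  q <- descriptive$quantitative
  q$mean <- round(q$mean, 2)
  q$sd <- round(q$sd, 2)
  q
}

#' @keywords internal
render_subgroups <- function(tab) {
  out <- tab
  for (col in c("split_median", "mean_ge", "sd_ge", "mean_lt", "sd_lt")) {
    out[[col]] <- round(out[[col]], 2)
  }
  out$p <- ifelse(tab$significant, "<0.05", "ns")
  out$p_value <- signif(tab$p_value, 3)
  out
}

#' @keywords internal
render_roc <- function(roc) {
  out <- roc
  for (col in c("auc", "sensitivity", "specificity", "accuracy")) {
    out[[col]] <- round(out[[col]], 3)
  }
  out$threshold <- signif(out$threshold, 4)
  out$outcome_median <- signif(out$outcome_median, 4)
  out
}
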