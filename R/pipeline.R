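# End-to-end orchestration: simulate (or load) cohorts, screen drivers,
# screen and rank events, call paired alterations, screen factors, stratify
# patients and compare survival, writing each stage's TSV plus a summary.

#' Run the whole screening pipeline
#'
#' Executes every stage in order on either freshly simulated cohorts (give
#' a [sim_config()]) or cohorts read from disk (give a directory). Outputs
#' are pure functions of (inputs, thresholds, seed): rerunning with the
#' same config gives identical results.
#'
#' @param config A [sim_config()], or a directory of bundles for
#'   [read_bundles()].
#' @param catalogue Driver catalogue (character vector). Defaults to the
#'   simulated driver genes when `config` is a `sim_config`.
#' @param factor_list Splicing-factor symbols; defaults analogously.
#' @param target_event Event id for the paired / factor / strata stages;
#'   defaults to the top-ranked event of the event screen.
#' @param top_n,quantified_frac,min_detected,min_n,alpha Screen thresholds
#'   (defaults 60, 0.80, 12, 10, 0.05).
#' @param paired_threshold Paired |delta PSI| alteration cut (default 0.15).
#' @param low_pct,marker_cut Stratification cuts (defaults 12, 1.75).
#' @param split_rule Expression split rule (default `"median"`).
#' @param survival_type Cancer type used for the stratified survival
#'   comparison (default: the first type).
#' @param arm Treatment arm for the survival contrast (default: first arm
#'   present).
#' @param out_dir Optional directory; when given every stage writes a TSV
#'   and a JSON run log with the thresholds echoed verbatim.
#' @return A `screen_report` list with each stage's tibble, the thresholds,
#'   and (for simulated input) the ground truth.
#' @export
run_screen_pipeline <- function(config,
                                catalogue = NULL,
                                factor_list = NULL,
                                target_event = NULL,
                                top_n = 60L,
                                quantified_frac = 0.80,
                                min_detected = 12L,
                                min_n = 10L,
                                alpha = 0.05,
                                paired_threshold = 0.15,
                                low_pct = 12,
                                marker_cut = 1.75,
                                split_rule = "median",
                                survival_type = NULL,
                                arm = NULL,
                                out_dir = NULL) {
  thresholds <- list(top_n = top_n, quantified_frac = quantified_frac,
                     min_detected = min_detected, min_n = min_n,
                     alpha = alpha, paired_threshold = paired_threshold,
                     low_pct = low_pct, marker_cut = marker_cut,
                     split_rule = split_rule)
  truth <- NULL
  if (inherits(config, "sim_config")) {
    gen <- generate_bundles(config)
    bundles <- gen$bundles
    truth <- gen$truth
    if (is.null(catalogue)) {
      catalogue <- unique(purrr::map(bundles,
                                     ~ unique(.x$psi$gene)) |> unlist())
    }
    if (is.null(factor_list)) {
      factors_all <- unique(bundles[[1]]$expr$gene)
      factor_list <- setdiff(factors_all,
                             c(catalogue, truth$marker_gene))
    }
    regulator <- truth$regulator
    marker <- truth$marker_gene
    target_gene <- truth$planted_gene
  } else {
    bundles <- read_bundles(config)
    if (is.null(catalogue)) {
      abort("run_screen_pipeline: a driver catalogue is required for cohorts read from disk")
    }
    if (is.null(factor_list)) {
      abort("run_screen_pipeline: a factor list is required for cohorts read from disk")
    }
    regulator <- NULL
    marker <- NULL
    target_gene <- NULL
  }
  tabs <- combine_bundles(bundles)

  # stage 1: driver compilation
  counts <- count_mutated_patients(tabs$mutations)
  top <- top_n_genes(counts, n = top_n)
  drivers <- compile_driver_set(top, catalogue)

  # stage 2: event screen over driver-gene events
  summaries <- summarize_events(
    filter(tabs$psi, gene %in% drivers$gene), tabs$samples, min_n = min_n)
  retained <- filter_events(summaries, quantified_frac = quantified_frac,
                            min_detected = min_detected, alpha = alpha)
  ranks <- rank_events(summaries, retained)
  if (is.null(target_event)) {
    if (nrow(ranks) == 0) abort("run_screen_pipeline: no events retained")
    target_event <- ranks$event_id[1]
  }

  # stage 3: paired alterations for the target event
  deltas <- patient_deltas(tabs$psi, tabs$samples, target_event,
                           threshold = paired_threshold)
  paired_freq <- alteration_frequency(deltas, threshold = paired_threshold)

  # stage 4: factor screen
  factor_ranks <- screen_factors(tabs$psi, tabs$expr, tabs$samples,
                                 target_event, factor_list, min_n = min_n)
  top_factor <- factor_ranks$factor_gene[1]
  cross <- cross_cancer_delta_correlation(
    filter(summaries, event_id == target_event),
    tabs$expr, tabs$samples, top_factor)

  # stage 5: stratification + survival in one cancer type
  if (is.null(survival_type)) survival_type <- bundles[[1]]$cancer_type
  b <- bundles[[survival_type]]
  if (is.null(b)) abort(paste0("run_screen_pipeline: no bundle for ",
                               survival_type))
  if (is.null(target_gene)) target_gene <- strsplit(target_event, "|",
                                                    fixed = TRUE)[[1]][1]
  strata <- classify_mut_status(b$mutations, b$expr, b$samples,
                                gene = target_gene, low_pct = low_pct)
  reg_split <- split_by_expression(b$expr, b$samples,
                                   gene = top_factor, rule = split_rule)
  strata <- strata |>
    left_join(reg_split, by = "patient_id") |>
    rename(regulator_group = group) |>
    mutate(functional_group = ifelse(
      mut_status == "WT" & regulator_group == "low", "high_E27", "low_E27"))
  if (!is.null(marker)) {
    marker_flags <- flag_marker_high(
      b$expr, b$samples, marker, cut = marker_cut,
      strata = select(strata, patient_id, stratum = mut_status))
  } else {
    marker_flags <- NULL
  }
  cli <- b$clinical |> inner_join(strata, by = "patient_id")
  if (is.null(arm)) arm <- sort(unique(cli$arm))[1]
  cli_arm <- cli |>
    filter(.data$arm == !!arm, mut_status != "LowExpr") |>
    mutate(group = functional_group)
  surv_test <- if (length(unique(cli_arm$group)) >= 2) {
    logrank_test(cli_arm)
  } else NULL
  km <- cli_arm |>
    group_by(group) |>
    group_map(~ km_estimate(.x))
  names(km) <- sort(unique(cli_arm$group))

  report <- structure(list(
    thresholds = thresholds,
    drivers = drivers,
    event_summaries = summaries,
    event_ranks = ranks,
    target_event = target_event,
    paired_deltas = deltas,
    paired_frequency = paired_freq,
    factor_ranks = factor_ranks,
    top_factor = top_factor,
    cross_cancer = cross,
    strata = strata,
    marker_flags = marker_flags,
    survival_arm = arm,
    survival_type = survival_type,
    logrank = surv_test,
    km = km,
    truth = truth
  ), class = "screen_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat("  drivers: ", nrow(x$drivers), " genes; events ranked: ",
      nrow(x$event_ranks), "\n", sep = "")
  cat("  top event: ", x$target_event, " (mean |dPSI| = ",
      signif(x$event_ranks$mean_abs_dpsi[1], 3), ")\n", sep = "")
  cat("  paired alteration frequency: ",
      signif(x$paired_frequency$frequency, 3), " (",
      x$paired_frequency$n_altered, "/", x$paired_frequency$n_evaluable,
      ")\n", sep = "")
  cat("  top factor: ", x$top_factor, " (median r = ",
      signif(x$factor_ranks$summary_r[1], 3), ")\n", sep = "")
  if (!is.null(x$logrank)) {
    cat("  log-rank (", x$survival_type, ", ", x$survival_arm, "): chi2 = ",
        signif(x$logrank$statistic, 4), ", p = ",
        format.pval(x$logrank$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(out_dir, name), progress = FALSE)
  }
  w(report$drivers, "drivers.tsv")
  w(report$event_summaries, "event_summaries.tsv")
  w(as_tibble(report$event_ranks), "event_ranks.tsv")
  w(report$paired_deltas, "paired_deltas.tsv")
  w(as_tibble(report$factor_ranks), "factor_ranks.tsv")
  w(report$strata, "strata.tsv")
  jsonlite::write_json(
    c(report$thresholds,
      list(target_event = report$target_event,
           top_factor = report$top_factor,
           paired_frequency = report$paired_frequency$frequency,
           logrank_p = if (!is.null(report$logrank))
             report$logrank$p_value else NA)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
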