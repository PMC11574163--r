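# Per-cancer event summaries, cross-cancer detection filters, and the mean
# |delta PSI| ranking.

#' Summarize splice events per cancer type
#'
#' For every (event, cancer type): mean PSI over non-missing tumor and
#' normal samples, `delta_psi = mean_psi_tumor - mean_psi_normal`, a pooled
#' two-tailed Student's t test, and a `quantified` flag requiring at least
#' `min_n` non-missing samples in each tissue group. Where an event is
#' unquantified its delta/t/p are reported as `NA`.
#'
#' @param psi Long PSI tibble (`event_id`, `sample_id`, `psi`, ...),
#'   with a `cancer_type` column or combined with `samples` carrying one.
#' @param samples Sample sheet (`sample_id`, `patient_id`, `cancer_type`,
#'   `tissue`).
#' @param events Optional character vector of event ids to restrict to.
#' @param min_n Minimum non-missing samples per tissue group (default 10).
#' @return A tibble with one row per (event, cancer type):
#'   `event_id`, `gene`, `cancer_type`, `mean_psi_tumor`, `mean_psi_normal`,
#'   `delta_psi`, `n_tumor`, `n_normal`, `t_stat`, `p_value`, `quantified`.
#' @export
summarize_events <- function(psi, samples, events = NULL, min_n = 10L) {
  if (!is.null(events)) {
    missing_ev <- setdiff(events, unique(psi$event_id))
    if (length(missing_ev) > 0) {
      abort(paste0("event(s) not in PSI table: ",
                   paste(head(missing_ev, 3), collapse = ", ")))
    }
    psi <- filter(psi, event_id %in% events)
  }
  joined <- psi |>
    select(-any_of("cancer_type")) |>
    inner_join(select(samples, sample_id, cancer_type, tissue),
               by = "sample_id")
  out <- joined |>
    group_by(event_id, gene, cancer_type) |>
    summarise(
      mean_psi_tumor = mean(psi[tissue == "tumor"], na.rm = TRUE),
      mean_psi_normal = mean(psi[tissue == "normal"], na.rm = TRUE),
      n_tumor = sum(tissue == "tumor" & !is.na(psi)),
      n_normal = sum(tissue == "normal" & !is.na(psi)),
      s2_tumor = var(psi[tissue == "tumor"], na.rm = TRUE),
      s2_normal = var(psi[tissue == "normal"], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      quantified = n_tumor >= min_n & n_normal >= min_n,
      delta_psi = ifelse(quantified, mean_psi_tumor - mean_psi_normal,
                         NA_real_)
    )
  sp2 <- ((out$n_tumor - 1) * out$s2_tumor +
            (out$n_normal - 1) * out$s2_normal) /
    (out$n_tumor + out$n_normal - 2)
  se <- sqrt(sp2 * (1 / out$n_tumor + 1 / out$n_normal))
  tval <- (out$mean_psi_tumor - out$mean_psi_normal) / se
  df <- out$n_tumor + out$n_normal - 2
  pval <- 2 * pt(-abs(tval), df)
  out$t_stat <- ifelse(out$quantified & is.finite(tval), tval, NA_real_)
  out$p_value <- ifelse(out$quantified & is.finite(tval), pval, NA_real_)
  out |>
    select(event_id, gene, cancer_type, mean_psi_tumor, mean_psi_normal,
           delta_psi, n_tumor, n_normal, t_stat, p_value, quantified)
}

#' Apply the cross-cancer detection filters
#'
#' An event is retained when it is quantified in at least `quantified_frac`
#' of the cancer types present and *detected* in at least `min_detected`
#' types, where detected means quantified with `p_value < alpha` or
#' `|delta_psi| > dpsi_floor`.
#'
#' @param summaries Output of [summarize_events()] covering all cancer
#'   types (unquantified rows included).
#' @param quantified_frac Minimum fraction of types quantified, in `(0, 1]`
#'   (default 0.80; the boundary is inclusive).
#' @param min_detected Minimum number of types detected (default 12).
#' @param alpha Detection significance level (default 0.05).
#' @param dpsi_floor Detection |delta PSI| floor (default 0.01).
#' @return A tibble of retained events with `event_id`, `gene`,
#'   `n_types_quantified`, `n_types_detected`, `n_types`.
#' @export
filter_events <- function(summaries, quantified_frac = 0.80,
                          min_detected = 12L, alpha = 0.05,
                          dpsi_floor = 0.01) {
  if (quantified_frac <= 0 || quantified_frac > 1) {
    abort("filter_events: quantified_frac must be in (0, 1]")
  }
  n_types <- length(unique(summaries$cancer_type))
  out <- summaries |>
    mutate(detected = quantified &
             ((!is.na(p_value) & p_value < alpha) |
                (!is.na(delta_psi) & abs(delta_psi) > dpsi_floor))) |>
    group_by(event_id, gene) |>
    summarise(n_types_quantified = sum(quantified),
              n_types_detected = sum(detected),
              .groups = "drop") |>
    mutate(n_types = n_types) |>
    filter(n_types_quantified / n_types >= quantified_frac,
           n_types_detected >= min_detected)
  as_tibble(out)
}

#' Rank events by mean |delta PSI| across quantified types
#'
#' The pan-cancer score is the mean of `|delta_psi|` over the types where
#' the event is quantified (unquantified types are omitted, not zero
#' imputed). Sort is descending with ties broken by `event_id`.
#'
#' @param summaries Output of [summarize_events()].
#' @param events Optional tibble from [filter_events()] (or a character
#'   vector of event ids) restricting the ranking to retained events.
#' @return A `pan_cancer_rank` tibble: `event_id`, `gene`, `mean_abs_dpsi`,
#'   `n_types_quantified`, `rank`; the per-type delta profile is kept in the
#'   `"by_type"` attribute for plotting.
#' @export
rank_events <- function(summaries, events = NULL) {
  if (!is.null(events)) {
    ids <- if (is.data.frame(events)) events$event_id else events
    summaries <- filter(summaries, event_id %in% ids)
  }
  if (nrow(summaries) == 0) {
    warn("rank_events: no events to rank")
    return(structure(tibble(event_id = character(0), gene = character(0),
                            mean_abs_dpsi = numeric(0),
                            n_types_quantified = integer(0),
                            rank = integer(0)),
                     class = c("pan_cancer_rank", "tbl_df", "tbl",
                               "data.frame")))
  }
  out <- summaries |>
    filter(quantified) |>
    group_by(event_id, gene) |>
    summarise(mean_abs_dpsi = mean(abs(delta_psi)),
              n_types_quantified = n(),
              .groups = "drop") |>
    arrange(desc(mean_abs_dpsi), event_id) |>
    mutate(rank = row_number())
  attr(out, "by_type") <- summaries |>
    select(event_id, cancer_type, delta_psi, quantified)
  class(out) <- c("pan_cancer_rank", class(out))
  out
}
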