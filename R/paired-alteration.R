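# Per-patient tumor-vs-adjacent-normal delta PSI and the supra-threshold
# alteration frequency.

#' Per-patient paired delta PSI for one event
#'
#' For every patient sampled in both tissues, `delta_psi = tumor PSI -
#' normal PSI`. Patients with a missing PSI on either side are
#' `unevaluable`. Calls at threshold `t`: `included` if `delta > t`,
#' `excluded` if `delta < -t`, otherwise `unchanged` (strict inequalities).
#'
#' @param psi Long PSI tibble.
#' @param samples Sample sheet; patients contribute once per cancer type.
#' @param event Event id to evaluate.
#' @param threshold Call threshold (default 0.15).
#' @return A tibble with `cancer_type`, `patient_id`, `psi_tumor`,
#'   `psi_normal`, `delta_psi`, `call`.
#' @export
patient_deltas <- function(psi, samples, event, threshold = 0.15) {
  pv <- psi |>
    filter(event_id == event) |>
    select(sample_id, psi) |>
    inner_join(select(samples, sample_id, patient_id, cancer_type, tissue),
               by = "sample_id")
  # first sample in sheet order per (patient, tissue)
  pv <- pv |>
    group_by(cancer_type, patient_id, tissue) |>
    slice(1) |>
    ungroup()
  wide <- pv |>
    select(cancer_type, patient_id, tissue, psi) |>
    pivot_wider(names_from = tissue, values_from = psi,
                names_prefix = "psi_")
  for (col in c("psi_tumor", "psi_normal")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  # dually sampled = patient appears with both tissue rows (even if the PSI
  # value itself is missing)
  both <- pv |>
    distinct(cancer_type, patient_id, tissue) |>
    count(cancer_type, patient_id) |>
    filter(n == 2) |>
    select(cancer_type, patient_id)
  out <- inner_join(both, wide, by = c("cancer_type", "patient_id")) |>
    mutate(
      delta_psi = psi_tumor - psi_normal,
      call = case_when(
        is.na(delta_psi) ~ "unevaluable",
        delta_psi > threshold ~ "included",
        delta_psi < -threshold ~ "excluded",
        TRUE ~ "unchanged"
      )
    )
  if (nrow(out) == 0) warn("patient_deltas: no dually sampled patients")
  as_tibble(out)
}

#' Paired alteration frequency at a |delta PSI| threshold
#'
#' The fraction of evaluable dually-sampled patients whose `|delta_psi|`
#' strictly exceeds the threshold; unevaluable patients are excluded from
#' the denominator. A delta of exactly the threshold is not altered.
#'
#' @param deltas Output of [patient_deltas()].
#' @param threshold Alteration threshold (default 0.15, strict `>`).
#' @return A one-row tibble with `n_altered`, `n_evaluable`, `frequency`.
#' @export
alteration_frequency <- function(deltas, threshold = 0.15) {
  ev <- deltas$delta_psi[!is.na(deltas$delta_psi)]
  if (length(ev) == 0) {
    abort("alteration_frequency: no evaluable paired deltas")
  }
  n_alt <- sum(abs(ev) > threshold)
  tibble(n_altered = n_alt, n_evaluable = length(ev),
         frequency = n_alt / length(ev))
}
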