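# Driver-gene compilation: per-cancer mutation-frequency ranking intersected
# with a curated driver catalogue.

#' Count mutated patients per gene
#'
#' "Most frequently mutated" is counted as the number of distinct patients
#' carrying at least one qualifying mutation in the gene; multiple hits in
#' one patient count once, and silent mutations do not qualify by default.
#'
#' @param mutations Tibble with `patient_id`, `gene`, `variant_class`, and
#'   optionally `cancer_type` (counts are per cancer type when present).
#' @param include_silent Count silent mutations too (default `FALSE`).
#' @return A tibble with `cancer_type` (if supplied), `gene`,
#'   `n_patients_mutated`.
#' @export
count_mutated_patients <- function(mutations, include_silent = FALSE) {
  has_ct <- "cancer_type" %in% names(mutations)
  keys <- if (has_ct) c("cancer_type", "gene") else "gene"
  out <- mutations |>
    filter(include_silent | variant_class != "silent") |>
    distinct(across(all_of(c(keys, "patient_id")))) |>
    count(across(all_of(keys)), name = "n_patients_mutated")
  as_tibble(out)
}

#' Rank genes by mutated-patient count and take the top n
#'
#' Sort is by count descending with ties broken by gene symbol ascending;
#' exactly the first `n` are returned (no tie expansion), so the result is
#' deterministic and independent of input row order.
#'
#' @param counts Output of [count_mutated_patients()].
#' @param n Number of genes to keep per cancer type (default 60).
#' @return `counts` with a dense 1-based `rank` column, truncated to the top
#'   `n` per cancer type.
#' @export
top_n_genes <- function(counts, n = 60L) {
  if (n <= 0) abort("top_n_genes: n must be positive")
  has_ct <- "cancer_type" %in% names(counts)
  grouped <- if (has_ct) group_by(counts, cancer_type) else counts
  out <- grouped |>
    arrange(desc(n_patients_mutated), gene, .by_group = has_ct) |>
    mutate(rank = row_number()) |>
    filter(rank <= n) |>
    ungroup()
  as_tibble(out)
}

#' Compile the driver set from per-cancer top lists and a catalogue
#'
#' The union of the per-cancer top-`n` gene lists is intersected with the
#' driver catalogue; each retained gene is annotated with the cancer types
#' that contributed it.
#'
#' @param top_genes Output of [top_n_genes()] (with `cancer_type`), or any
#'   tibble with `cancer_type` and `gene`.
#' @param catalogue Character vector of catalogued driver genes (non-empty).
#' @return A tibble with `gene`, `n_types` and `cancer_types`
#'   (comma-collapsed), sorted by gene.
#' @export
compile_driver_set <- function(top_genes, catalogue) {
  if (length(catalogue) == 0) {
    abort("compile_driver_set: empty driver catalogue")
  }
  if (!"cancer_type" %in% names(top_genes)) {
    top_genes <- mutate(top_genes, cancer_type = "all")
  }
  out <- top_genes |>
    filter(gene %in% catalogue) |>
    distinct(gene, cancer_type) |>
    group_by(gene) |>
    summarise(n_types = n(),
              cancer_types = paste(sort(cancer_type), collapse = ","),
              .groups = "drop") |>
    arrange(gene)
  if (nrow(out) == 0) {
    warn("compile_driver_set: catalogue is disjoint from all top lists")
  }
  as_tibble(out)
}
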