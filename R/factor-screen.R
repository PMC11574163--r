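# Splicing-factor screen: per-cancer Pearson correlation of event PSI with
# factor expression (tumor samples only), a cross-type ranking, and the
# cross-cancer delta-PSI vs delta-expression correlation.

#' Correlate one PSI series with one expression series
#'
#' Expression is transformed `log2(FPKM + 1)` (configurable off) and
#' correlated with PSI by Pearson's r with a two-tailed p-value; pairs with
#' a missing value on either side are dropped. Below `min_n` complete pairs
#' (or with a constant series) the correlation is reported as unevaluated
#' (`NA` with a `reason`).
#'
#' @param psi_values Numeric PSI vector.
#' @param expr_values Numeric FPKM vector, same sample order.
#' @param min_n Minimum complete pairs (default 10).
#' @param log_transform Apply log2(FPKM+1) before correlating (default
#'   `TRUE`).
#' @return A one-row tibble: `r`, `p_value`, `n`, `reason` (`NA` when
#'   evaluated).
#' @export
correlate_factor <- function(psi_values, expr_values, min_n = 10L,
                             log_transform = TRUE) {
  if (length(psi_values) != length(expr_values)) {
    abort("correlate_factor: series differ in length")
  }
  e <- if (log_transform) log2(expr_values + 1) else expr_values
  keep <- !is.na(psi_values) & !is.na(e)
  x <- psi_values[keep]
  y <- e[keep]
  if (length(x) < min_n) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                  reason = "too few pairs"))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                  reason = "constant series"))
  }
  ct <- pearson_test(x, y)
  tibble(r = ct$estimate, p_value = ct$p_value, n = ct$n,
         reason = NA_character_)
}

#' Per-(factor, cancer type) correlations of event PSI with expression
#'
#' Tumor samples only. Vectorized over factors and cancer types.
#'
#' @param psi Long PSI tibble.
#' @param expr Long expression tibble.
#' @param samples Sample sheet with `cancer_type`.
#' @param event Event id whose PSI is screened.
#' @param factors Character vector of factor symbols.
#' @param min_n Minimum complete pairs per correlation (default 10).
#' @param log_transform Apply log2(FPKM+1) (default `TRUE`).
#' @return A tibble: `factor_gene`, `cancer_type`, `r`, `p_value`, `n`.
#' @export
factor_correlations <- function(psi, expr, samples, event, factors,
                                min_n = 10L, log_transform = TRUE) {
  if (length(factors) == 0) abort("factor_correlations: empty factor list")
  tum <- samples |> filter(tissue == "tumor")
  ev <- psi |>
    filter(event_id == event) |>
    select(sample_id, psi) |>
    inner_join(select(tum, sample_id, cancer_type), by = "sample_id")
  fx <- expr |>
    select(-any_of("cancer_type")) |>
    filter(gene %in% factors, sample_id %in% tum$sample_id)
  if (log_transform) fx$fpkm <- log2(fx$fpkm + 1)
  # per-type matrix correlation of the PSI vector against all factors
  types <- sort(unique(ev$cancer_type))
  rows <- lapply(types, function(ct) {
    evc <- ev[ev$cancer_type == ct, ]
    m <- fx |>
      filter(sample_id %in% evc$sample_id) |>
      pivot_wider(names_from = gene, values_from = fpkm) |>
      arrange(match(sample_id, evc$sample_id))
    x <- evc$psi[match(m$sample_id, evc$sample_id)]
    mm <- as.matrix(m[, setdiff(names(m), "sample_id"), drop = FALSE])
    if (ncol(mm) == 0 || nrow(mm) == 0) {
      return(tibble(factor_gene = character(0), cancer_type = character(0),
                    r = numeric(0), p_value = numeric(0), n = integer(0)))
    }
    n_j <- colSums(!is.na(x) & !is.na(mm))
    r_j <- suppressWarnings(as.vector(stats::cor(
      x, mm, use = "pairwise.complete.obs")))
    ok <- n_j >= max(min_n, 3L) & !is.na(r_j)
    r_out <- ifelse(ok, r_j, NA_real_)
    tval <- r_out * sqrt((n_j - 2) / pmax(1 - r_out^2, .Machine$double.eps))
    p_out <- 2 * pt(-abs(tval), n_j - 2)
    p_out[ok & abs(r_out) >= 1] <- 0
    tibble(factor_gene = colnames(mm), cancer_type = ct,
           r = r_out, p_value = p_out, n = as.integer(n_j))
  })
  list_rbind(rows) |> arrange(factor_gene, cancer_type)
}

#' Screen splicing factors against an event
#'
#' Ranks factors by the median Pearson r across the cancer types with a
#' reported correlation (most negative first, ties by symbol). The count of
#' types with `r` below `negative_cut` is reported alongside, and a
#' Benjamini-Hochberg column over the factor family can be added.
#'
#' @inheritParams factor_correlations
#' @param negative_cut Count types with `r` below this value (default -0.3).
#' @param bh Add a Benjamini-Hochberg adjusted minimum p per factor
#'   (default `FALSE`; the screen itself reports raw r/p).
#' @return A `factor_ranking` tibble: `factor_gene`, `summary_r`,
#'   `n_types`, `n_types_negative`, `rank`; per-type correlations are kept
#'   in the `"correlations"` attribute.
#' @export
screen_factors <- function(psi, expr, samples, event, factors,
                           min_n = 10L, log_transform = TRUE,
                           negative_cut = -0.3, bh = FALSE) {
  corrs <- factor_correlations(psi, expr, samples, event, factors,
                               min_n = min_n, log_transform = log_transform)
  if (all(is.na(corrs$r))) {
    abort("screen_factors: no factor evaluable in any cancer type")
  }
  out <- corrs |>
    filter(!is.na(r)) |>
    group_by(factor_gene) |>
    summarise(summary_r = median(r),
              n_types = n(),
              n_types_negative = sum(r < negative_cut),
              min_p = min(p_value),
              .groups = "drop") |>
    arrange(summary_r, factor_gene) |>
    mutate(rank = row_number())
  if (bh) {
    out$p_bh <- stats::p.adjust(out$min_p, method = "BH")
  }
  out$min_p <- NULL
  attr(out, "correlations") <- corrs
  class(out) <- c("factor_ranking", class(out))
  out
}

#' Cross-cancer correlation of event delta PSI with factor delta expression
#'
#' One point per cancer type: the event's tumor-minus-normal delta PSI
#' against the factor's tumor-minus-normal change in mean log2(FPKM+1).
#' Needs at least 3 types with both deltas.
#'
#' @param summaries Output of [summarize_events()] for the event (its
#'   quantified per-type `delta_psi` supplies the x coordinates).
#' @param expr Long expression tibble.
#' @param samples Sample sheet.
#' @param factor_gene Factor symbol.
#' @return A one-row tibble: `r`, `p_value`, `n_types`; `NA` with a reason
#'   when fewer than 3 types are evaluable.
#' @export
cross_cancer_delta_correlation <- function(summaries, expr, samples,
                                           factor_gene) {
  fg <- factor_gene
  de <- expr |>
    select(-any_of("cancer_type")) |>
    filter(gene == fg) |>
    inner_join(select(samples, sample_id, cancer_type, tissue),
               by = "sample_id") |>
    group_by(cancer_type) |>
    summarise(
      delta_expr = mean(log2(fpkm[tissue == "tumor"] + 1), na.rm = TRUE) -
        mean(log2(fpkm[tissue == "normal"] + 1), na.rm = TRUE),
      .groups = "drop"
    )
  pts <- summaries |>
    filter(quantified, !is.na(delta_psi)) |>
    select(cancer_type, delta_psi) |>
    inner_join(de, by = "cancer_type") |>
    filter(is.finite(delta_expr))
  if (nrow(pts) < 3) {
    return(tibble(r = NA_real_, p_value = NA_real_, n_types = nrow(pts),
                  reason = "fewer than 3 cancer types"))
  }
  ct <- pearson_test(pts$delta_psi, pts$delta_expr)
  tibble(r = ct$estimate, p_value = ct$p_value, n_types = ct$n,
         reason = NA_character_)
}
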