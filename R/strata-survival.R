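# Rule-based patient stratification and survival comparison: mutation /
# low-expression classes, expression splits, marker flags, group tests,
# the Kaplan-Meier product-limit estimator and the log-rank test.

first_tumor_expr <- function(expr, samples, gene_symbol) {
  tum <- samples |>
    filter(tissue == "tumor") |>
    group_by(cancer_type, patient_id) |>
    slice(1) |>
    ungroup()
  expr |>
    select(-any_of("cancer_type")) |>
    filter(gene == gene_symbol) |>
    inner_join(select(tum, sample_id, patient_id, cancer_type),
               by = "sample_id") |>
    select(cancer_type, patient_id, fpkm)
}

ensure_cancer_type <- function(samples) {
  if (!"cancer_type" %in% names(samples)) {
    samples$cancer_type <- "all"
  }
  samples
}

#' Classify patients as WT / Mut / LowExpr for a target gene
#'
#' `Mut`: at least one non-silent mutation in the gene (precedence over the
#' expression rule). `LowExpr`: non-mutant with tumor FPKM below the
#' `low_pct`-th percentile of non-mutant tumors (per cancer type).
#' Everyone else is `WT`.
#'
#' @param mutations Mutation tibble (`patient_id`, `gene`, `variant_class`).
#' @param expr Long expression tibble.
#' @param samples Sample sheet.
#' @param gene Target gene symbol.
#' @param low_pct Percentile cut in 0-100 (default 12, i.e. "below 12%").
#' @return A tibble `patient_id`, `mut_status`.
#' @export
classify_mut_status <- function(mutations, expr, samples, gene,
                                low_pct = 12) {
  samples <- ensure_cancer_type(samples)
  ev <- first_tumor_expr(expr, samples, gene)
  if (nrow(ev) == 0) {
    abort(paste0("classify_mut_status: gene ", gene,
                 " absent from expression matrix"))
  }
  mut_pats <- unique(mutations$patient_id[
    mutations$gene == gene & mutations$variant_class != "silent"])
  out <- ev |>
    mutate(mutated = patient_id %in% mut_pats) |>
    group_by(cancer_type) |>
    mutate(cut = quantile(fpkm[!mutated], probs = low_pct / 100,
                          na.rm = TRUE, names = FALSE)) |>
    ungroup() |>
    mutate(mut_status = case_when(
      mutated ~ "Mut",
      fpkm < cut ~ "LowExpr",
      TRUE ~ "WT"
    )) |>
    select(patient_id, mut_status)
  as_tibble(out)
}

#' Split patients into high/low expression groups
#'
#' `median` rule: values at or above the median are `high` (ties to high).
#' `tertile` rule: top third `high`, bottom third `low`, middle
#' `unassigned`. `threshold` rule: strictly above the given FPKM is `high`.
#' Cuts are computed per cancer type on tumor samples.
#'
#' @param expr Long expression tibble.
#' @param samples Sample sheet.
#' @param gene Gene symbol to split on.
#' @param rule One of `"median"`, `"tertile"`, `"threshold"`.
#' @param threshold FPKM cut, required for `rule = "threshold"`.
#' @return A tibble `patient_id`, `group` (`high`/`low`/`unassigned`).
#' @export
split_by_expression <- function(expr, samples, gene,
                                rule = c("median", "tertile", "threshold"),
                                threshold = NULL) {
  rule <- match.arg(rule)
  samples <- ensure_cancer_type(samples)
  ev <- first_tumor_expr(expr, samples, gene) |> filter(!is.na(fpkm))
  if (nrow(ev) == 0) abort("split_by_expression: no expression values")
  if (rule == "threshold" && is.null(threshold)) {
    abort("split_by_expression: rule = 'threshold' needs a threshold")
  }
  out <- ev |>
    group_by(cancer_type) |>
    mutate(group = switch(
      rule,
      median = ifelse(fpkm >= median(fpkm), "high", "low"),
      tertile = {
        lo <- quantile(fpkm, 1 / 3, names = FALSE)
        hi <- quantile(fpkm, 2 / 3, names = FALSE)
        case_when(fpkm >= hi ~ "high", fpkm <= lo ~ "low",
                  TRUE ~ "unassigned")
      },
      threshold = ifelse(fpkm > threshold, "high", "low")
    )) |>
    ungroup()
  if (rule == "median" && any(tapply(ev$fpkm, ev$cancer_type,
                                     function(v) sd(v) == 0))) {
    warn("split_by_expression: constant expression; all patients 'high' under the median rule")
  }
  select(out, patient_id, group)
}

#' Flag marker-high patients at a strict FPKM cut
#'
#' `flag = (value > cut)`, strict: a value exactly at the cut is not
#' flagged. When strata are supplied, per-stratum percentages with their
#' numerators/denominators are attached as the `"by_stratum"` attribute.
#'
#' @param expr Long (normalized) expression tibble.
#' @param samples Sample sheet.
#' @param marker Marker gene symbol.
#' @param cut Normalized-FPKM cut (default 1.75).
#' @param strata Optional tibble `patient_id`, `stratum`.
#' @return A tibble `patient_id`, `fpkm`, `flag`.
#' @export
flag_marker_high <- function(expr, samples, marker, cut = 1.75,
                             strata = NULL) {
  samples <- ensure_cancer_type(samples)
  ev <- first_tumor_expr(expr, samples, marker)
  if (nrow(ev) == 0) {
    abort(paste0("flag_marker_high: marker ", marker,
                 " absent from expression matrix"))
  }
  out <- ev |>
    mutate(flag = fpkm > cut) |>
    select(patient_id, fpkm, flag)
  if (!is.null(strata)) {
    by_stratum <- out |>
      inner_join(strata, by = "patient_id") |>
      group_by(stratum = .data$stratum) |>
      summarise(n_flagged = sum(flag), n = n(),
                pct_flagged = 100 * sum(flag) / n(), .groups = "drop")
    attr(out, "by_stratum") <- by_stratum
  }
  out
}

#' Compare a marker between patient groups
#'
#' Two groups: two-tailed pooled Student's t. More than two: one-way ANOVA
#' with Bonferroni-adjusted pairwise contrasts on the pooled within-group
#' variance.
#'
#' @param data Tibble with a value column and a group column.
#' @param value,group Column names (strings) of the response and grouping.
#' @return A `group_comparison` list: `test` (`"t"` or
#'   `"anova_bonferroni"`), `group_means`, `overall` (tidy test row), and
#'   `contrasts` (per-pair tibble with raw and adjusted p).
#' @export
compare_marker_by_group <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  ns <- table(g)
  if (length(ns) < 2) abort("compare_marker_by_group: need at least 2 groups")
  small <- names(ns)[ns < 2]
  if (length(small) > 0) {
    abort(paste0("compare_marker_by_group: group '", small[1],
                 "' has fewer than 2 patients"))
  }
  means <- tapply(v, g, mean)
  if (length(ns) == 2) {
    labs <- names(ns)
    tt <- t_test_two_sample(v[g == labs[1]], v[g == labs[2]])
    contrasts <- tibble(group1 = labs[1], group2 = labs[2],
                        estimate = unname(means[labs[1]] - means[labs[2]]),
                        statistic = tt$statistic,
                        p.raw = tt$p_value, p.adj = tt$p_value)
    res <- list(test = "t", group_means = means, overall = tidy.ss_test(tt),
                contrasts = contrasts)
  } else {
    av <- anova_oneway(v, g)
    labs <- names(means)
    pairs <- utils::combn(labs, 2)
    nsv <- tapply(v, g, length)
    df <- av$df[[2]]
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]
      b2 <- pairs[2, j]
      se <- sqrt(av$ms_within * (1 / nsv[[a]] + 1 / nsv[[b2]]))
      tv <- if (se == 0) 0 else (means[[a]] - means[[b2]]) / se
      tibble(group1 = a, group2 = b2, estimate = means[[a]] - means[[b2]],
             statistic = tv, p.raw = if (se == 0) 1 else 2 * pt(-abs(tv), df))
    })
    contrasts <- list_rbind(rows)
    contrasts$p.adj <- adjust_bonferroni(contrasts$p.raw)
    res <- list(test = "anova_bonferroni", group_means = means,
                overall = tidy.ss_test(av), contrasts = contrasts)
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test, "; groups: ",
      paste(names(x$group_means), collapse = ", "), "\n", sep = "")
  print(x$contrasts)
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(0) = 1`; the curve steps only at event times. Censorings tied with an
#' event time leave the risk set after the step at that time (events are
#' processed before censorings).
#'
#' @param clinical Tibble with `time` (> 0) and `event` (1 death / 0
#'   censored).
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, one row per distinct observed time, preceded by the `t = 0`
#'   row.
#' @export
km_estimate <- function(clinical) {
  t <- clinical$time
  d <- clinical$event
  if (length(t) == 0) abort("km_estimate: no records")
  if (any(is.na(t)) || any(t <= 0)) {
    abort("km_estimate: survival times must be positive")
  }
  if (!all(d %in% c(0, 1))) abort("km_estimate: event must be 0/1")
  ut <- sort(unique(t))
  n_event <- vapply(ut, function(u) sum(t == u & d == 1), numeric(1))
  n_censor <- vapply(ut, function(u) sum(t == u & d == 0), numeric(1))
  n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble(
    time = c(0, ut),
    n_risk = c(length(t), n_risk),
    n_event = c(0, n_event),
    n_censor = c(0, n_censor),
    surv = c(1, surv)
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank test between survival groups
#'
#' Standard observed-vs-expected chi-square over the pooled event times
#' with the hypergeometric variance; `df = #groups - 1`.
#'
#' @param clinical Tibble with `time`, `event` and a grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return An `ss_test` with `statistic` (chi-square), `df`, `p_value`, and
#'   per-group observed/expected counts.
#' @export
logrank_test <- function(clinical, group = "group") {
  g <- as.character(clinical[[group]])
  t <- clinical$time
  d <- clinical$event
  labs <- sort(unique(g))
  k <- length(labs)
  if (k < 2) abort("logrank_test: need at least 2 groups")
  if (any(tabulate(factor(g, labs)) == 0)) {
    abort("logrank_test: empty group")
  }
  ut <- sort(unique(t[d == 1]))
  O <- setNames(numeric(k), labs)
  E <- setNames(numeric(k), labs)
  V <- matrix(0, k, k, dimnames = list(labs, labs))
  for (u in ut) {
    at_risk <- t >= u
    n <- sum(at_risk)
    dj <- sum(t == u & d == 1)
    ng <- vapply(labs, function(l) sum(at_risk & g == l), numeric(1))
    og <- vapply(labs, function(l) sum(t == u & d == 1 & g == l), numeric(1))
    O <- O + og
    E <- E + dj * ng / n
    if (n > 1) {
      cov_t <- dj * (n - dj) / (n - 1) *
        (diag(ng / n) - tcrossprod(ng / n))
      V <- V + cov_t
    }
  }
  idx <- seq_len(k - 1)
  u_vec <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  chi2 <- tryCatch(
    drop(t(u_vec) %*% solve(Vsub, u_vec)),
    error = function(e) {
      # singular variance (e.g. no events): no evidence against the null
      0
    }
  )
  p <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  new_ss_test("log-rank", chi2, k - 1, p,
              observed = list(O), expected = list(E))
}

#' @rdname km_estimate
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
glance.km_curve <- function(x, ...) {
  n <- x$n_risk[1]
  med <- suppressWarnings(min(x$time[x$surv <= 0.5]))
  tibble(n = n, events = sum(x$n_event),
         median_survival = if (is.finite(med)) med else NA_real_)
}
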