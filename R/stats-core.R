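# Statistical primitives used throughout the screens. The test statistics are
# computed here from first principles; only the reference distribution
# functions (t, F, chi-square) are delegated to stats::.

new_ss_test <- function(method, statistic, df, p_value, ...) {
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = p_value, ...),
    class = "ss_test"
  )
}

#' @export
print.ss_test <- function(x, ...) {
  cat("<ss_test> ", x$method, "\n", sep = "")
  cat("  statistic = ", format(x$statistic, digits = 6),
      ", df = ", paste(format(x$df, digits = 6), collapse = "/"),
      ", p = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Turn a test result into a one-row tibble
#'
#' @param x An `ss_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `df` (or `df1`/`df2`),
#'   `p.value`, and any extra scalar fields the test carries (e.g. `estimate`
#'   for the Pearson correlation).
#' @export
tidy.ss_test <- function(x, ...) {
  out <- tibble(method = x$method, statistic = x$statistic)
  if (length(x$df) == 2L) {
    out$df1 <- x$df[[1]]
    out$df2 <- x$df[[2]]
  } else {
    out$df <- x$df
  }
  out$p.value <- x$p_value
  extra <- x[setdiff(names(x), c("method", "statistic", "df", "p_value"))]
  extra <- extra[vapply(extra, function(e) is.atomic(e) && length(e) == 1L,
                        logical(1))]
  if (length(extra) > 0) out <- bind_cols(out, as_tibble(extra))
  out
}

#' Two-sample Student's t test
#'
#' Pooled-variance two-sample t test (two-tailed), the test used for the
#' per-cancer tumor-versus-normal PSI comparisons. A Welch variant is
#' available via `pooled = FALSE`.
#'
#' @param x,y Numeric vectors (NAs dropped), each of length >= 2.
#' @param pooled Use the pooled-variance statistic with
#'   `df = n_x + n_y - 2` (default) rather than Welch's approximation.
#' @return An `ss_test` with fields `statistic` (t), `df`, `p_value`, and the
#'   two group means.
#' @export
t_test_two_sample <- function(x, y, pooled = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) {
    abort("t_test_two_sample: each sample needs at least 2 non-missing values")
  }
  vx <- var(x)
  vy <- var(y)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 <= 0) abort("t_test_two_sample: zero pooled variance")
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
    method <- "two-sample t (pooled)"
  } else {
    if (vx <= 0 && vy <= 0) abort("t_test_two_sample: zero variance in both samples")
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    method <- "two-sample t (Welch)"
  }
  tval <- (mean(x) - mean(y)) / se
  p <- 2 * pt(-abs(tval), df)
  new_ss_test(method, tval, df, p,
              mean_x = mean(x), mean_y = mean(y), n_x = nx, n_y = ny)
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with any NA are dropped.
#' @return An `ss_test` with `estimate` (r), `statistic` (t), `df`, `p_value`
#'   and `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("pearson_test: x and y differ in length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("pearson_test: need at least 3 complete pairs")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) abort("pearson_test: constant input series")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    tval <- sign(r) * Inf
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), n - 2)
  }
  new_ss_test("Pearson correlation", tval, n - 2, p, estimate = r, n = n)
}

#' One-way analysis of variance
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @return An `ss_test` with `statistic` (F), `df` = c(between, within),
#'   `p_value`, and the group means.
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  tab <- split(values, groups)
  k <- length(tab)
  if (k < 2L) abort("anova_oneway: need at least 2 groups")
  ns <- lengths(tab)
  if (any(ns < 2L)) abort("anova_oneway: every group needs n >= 2")
  gm <- mean(values)
  means <- vapply(tab, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(tab, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- length(values) - k
  if (ssw == 0 && ssb == 0) abort("anova_oneway: all observations identical")
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- msb / msw
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  new_ss_test("one-way ANOVA", f, c(df1, df2), p,
              ms_within = msw, group_means = list(means), group_n = list(ns))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m = length(p)` unless given.
#'
#' @param p Vector of raw p-values.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("adjust_bonferroni: p outside [0,1]")
  pmin(1, m * p)
}

#' Dunnett many-to-one contrasts with Monte-Carlo adjustment
#'
#' Compares every treatment group against the control group using the pooled
#' within-group variance, and adjusts each contrast p-value for the family by
#' the distribution of the maximum absolute statistic under the null. That
#' null distribution is estimated by seeded Monte-Carlo simulation of group
#' means and the pooled variance, so the reported p carries a Monte-Carlo
#' standard error.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param control Label of the control group.
#' @param mc_reps Number of Monte-Carlo draws (default 200000).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return A tibble with one row per non-control group: `group`, `estimate`
#'   (mean difference vs control), `statistic`, `p.value` (Dunnett-adjusted),
#'   `p.raw` (unadjusted two-tailed t), `mc_se`.
#' @export
dunnett_contrasts <- function(values, groups, control, mc_reps = 200000L,
                              seed = 1L) {
  groups <- as.character(groups)
  if (!control %in% groups) abort("dunnett_contrasts: control group not found")
  av <- anova_oneway(values, groups)
  means <- av$group_means[[1]]
  ns <- av$group_n[[1]]
  msw <- av$ms_within
  if (msw == 0) abort("dunnett_contrasts: zero within-group variance")
  df <- av$df[[2]]
  others <- setdiff(names(means), control)
  tvals <- vapply(others, function(g) {
    (means[[g]] - means[[control]]) / sqrt(msw * (1 / ns[[g]] + 1 / ns[[control]]))
  }, numeric(1))

  # Null: group means ~ N(0, msw/n_g), pooled s^2 ~ msw * chisq_df / df;
  # simulate max |t| across the same contrasts.
  k <- length(others)
  old <- .Random.seed_exists()
  set.seed(seed)
  z0 <- rnorm(mc_reps, sd = sqrt(1 / ns[[control]]))
  zs <- matrix(rnorm(mc_reps * k), ncol = k)
  zs <- sweep(zs, 2, sqrt(1 / ns[others]), `*`)
  s2 <- stats::rchisq(mc_reps, df) / df
  tmat <- (zs - z0) / sqrt(outer(s2, 1 / ns[others] + 1 / ns[[control]]))
  maxabs <- apply(abs(tmat), 1, max)
  .Random.seed_restore(old)

  padj <- vapply(tvals, function(t0) mean(maxabs >= abs(t0)), numeric(1))
  mc_se <- sqrt(padj * (1 - padj) / mc_reps)
  praw <- 2 * pt(-abs(tvals), df)
  tibble(
    group = others,
    estimate = unname(means[others] - means[[control]]),
    statistic = unname(tvals),
    p.value = unname(padj),
    p.raw = unname(praw),
    mc_se = unname(mc_se)
  )
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
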