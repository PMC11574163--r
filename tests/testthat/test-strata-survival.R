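test_that("mutation status classification applies Mut > LowExpr > WT", {
  co <- tiny_cohort()
  st <- classify_mut_status(co$mutations, co$expr, co$samples, "PBRM1",
                            low_pct = 12)
  # P01 has a frameshift: Mut regardless of its (lowest) expression
  expect_identical(st$mut_status[st$patient_id == "P01"], "Mut")
  # P02's PBRM1 mutation is silent: does not confer Mut
  expect_false(st$mut_status[st$patient_id == "P02"] == "Mut")
  # the lowest-expressed non-mutant falls below the 12th percentile
  nonmut <- st$patient_id[st$mut_status != "Mut"]
  expr_nm <- co$expr$fpkm[co$expr$gene == "PBRM1"][match(
    nonmut, sprintf("P%02d", 1:10))]
  lowest <- nonmut[which.min(expr_nm)]
  expect_identical(st$mut_status[st$patient_id == lowest], "LowExpr")
  expect_error(classify_mut_status(co$mutations, co$expr, co$samples,
                                   "GHOST"), "absent")
})

test_that("classification matches a brute-force rule oracle on synthetic patients", {
  cfg <- sim_config(n_cancer_types = 1, planted_n_types = 1, n_tumor = 100,
                    n_normal = 20, n_paired = 0, n_driver_genes = 4,
                    n_passenger_genes = 2, n_factors = 5, seed = 55)
  g <- generate_bundles(cfg)
  b <- g$bundles[[1]]
  st <- classify_mut_status(b$mutations, b$expr, b$samples, "PBRM1",
                            low_pct = 12)
  # oracle: independent evaluation of the stated rule
  tum <- b$samples[b$samples$tissue == "tumor", ]
  ev <- b$expr[b$expr$gene == "PBRM1" &
                 b$expr$sample_id %in% tum$sample_id, ]
  val <- setNames(ev$fpkm, tum$patient_id[match(ev$sample_id,
                                                tum$sample_id)])
  mut <- unique(b$mutations$patient_id[b$mutations$gene == "PBRM1" &
                                         b$mutations$variant_class != "silent"])
  cut <- quantile(val[setdiff(names(val), mut)], 0.12, names = FALSE)
  oracle <- ifelse(names(val) %in% mut, "Mut",
                   ifelse(val < cut, "LowExpr", "WT"))
  expect_identical(st$mut_status[match(names(val), st$patient_id)],
                   unname(oracle))
})

test_that("expression splits follow the median, tertile and threshold rules", {
  samples <- tibble::tibble(sample_id = paste0("S", 1:4),
                            patient_id = paste0("P", 1:4),
                            cancer_type = "X", tissue = "tumor")
  expr <- tibble::tibble(gene = "G", sample_id = paste0("S", 1:4),
                         fpkm = c(1, 2, 3, 4))
  sp <- split_by_expression(expr, samples, "G", rule = "median")
  expect_identical(sp$group, c("low", "low", "high", "high"))
  # constant expression: everyone high, with a warning
  expr_c <- dplyr::mutate(expr, fpkm = 5)
  expect_warning(spc <- split_by_expression(expr_c, samples, "G"),
                 "constant")
  expect_true(all(spc$group == "high"))
  # tertile on 9 distinct values gives a 3/3/3 partition matching the sort
  samples9 <- tibble::tibble(sample_id = paste0("S", 1:9),
                             patient_id = paste0("P", 1:9),
                             cancer_type = "X", tissue = "tumor")
  set.seed(61)
  v <- sample(c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  expr9 <- tibble::tibble(gene = "G", sample_id = paste0("S", 1:9), fpkm = v)
  sp9 <- split_by_expression(expr9, samples9, "G", rule = "tertile")
  expect_identical(sp9$group[order(v)],
                   rep(c("low", "unassigned", "high"), each = 3))
  spt <- split_by_expression(expr, samples, "G", rule = "threshold",
                             threshold = 2)
  expect_identical(spt$group, c("low", "low", "high", "high"))
  expect_error(split_by_expression(expr, samples, "G", rule = "threshold"),
               "threshold")
})

test_that("marker flags use a strict cut and report per-stratum percentages", {
  samples <- tibble::tibble(sample_id = paste0("S", 1:4),
                            patient_id = paste0("P", 1:4),
                            cancer_type = "X", tissue = "tumor")
  expr <- tibble::tibble(gene = "PDL1", sample_id = paste0("S", 1:4),
                         fpkm = c(1.75, 1.76, 0.2, 3.0))
  fl <- flag_marker_high(expr, samples, "PDL1", cut = 1.75)
  expect_identical(fl$flag, c(FALSE, TRUE, FALSE, TRUE))
  strata <- tibble::tibble(patient_id = paste0("P", 1:4),
                           stratum = c("WT", "WT", "Mut", "Mut"))
  fl2 <- flag_marker_high(expr, samples, "PDL1", strata = strata)
  bs <- attr(fl2, "by_stratum")
  expect_equal(bs$pct_flagged[bs$stratum == "WT"], 50)
  expect_error(flag_marker_high(expr, samples, "GHOST"), "absent")
})

test_that("marker expression separates PSI groups in WT but not Mut patients", {
  # construction check: the marker couples to PSI only without a planted-gene
  # mutation, so the high/low PSI contrast is significant in WT strata only
  hits_wt <- 0
  hits_mut <- 0
  for (seed in 1:8) {
    cfg <- sim_config(n_cancer_types = 1, planted_n_types = 1,
                      n_tumor = 120, n_normal = 20, n_paired = 0,
                      n_driver_genes = 4, n_passenger_genes = 0,
                      n_factors = 5, missing_frac = 0, seed = seed)
    g <- generate_bundles(cfg)
    b <- g$bundles[[1]]
    tum <- b$samples[b$samples$tissue == "tumor", ]
    psi <- b$psi[b$psi$event_id == cfg$planted_event_id &
                   b$psi$sample_id %in% tum$sample_id, ]
    marker <- b$expr[b$expr$gene == cfg$marker_gene &
                       b$expr$sample_id %in% tum$sample_id, ]
    st <- classify_mut_status(b$mutations, b$expr, b$samples, "PBRM1")
    dat <- tibble::tibble(
      patient_id = tum$patient_id,
      psi = psi$psi[match(tum$sample_id, psi$sample_id)],
      value = marker$fpkm[match(tum$sample_id, marker$sample_id)]
    ) |>
      dplyr::inner_join(st, by = "patient_id") |>
      dplyr::mutate(group = ifelse(psi >= median(psi), "high", "low"))
    p_wt <- compare_marker_by_group(
      dplyr::filter(dat, mut_status == "WT"))$contrasts$p.adj
    p_mut <- compare_marker_by_group(
      dplyr::filter(dat, mut_status == "Mut"))$contrasts$p.adj
    hits_wt <- hits_wt + (p_wt < 0.05)
    hits_mut <- hits_mut + (p_mut < 0.05)
  }
  expect_gte(hits_wt, 6)
  expect_lte(hits_mut, 2)
})

test_that("group comparisons reduce to t for two groups and ANOVA beyond", {
  d2 <- tibble::tibble(value = c(1.1, 1.9, 1.4, 3.2, 2.8, 3.9),
                       group = rep(c("a", "b"), each = 3))
  gc <- compare_marker_by_group(d2)
  ref <- stats::t.test(value ~ group, data = d2, var.equal = TRUE)
  expect_equal(gc$contrasts$p.raw, ref$p.value, tolerance = 1e-12)
  expect_identical(gc$test, "t")
  # identical values across groups: family-wide p = 1
  same <- tibble::tibble(value = rep(c(1, 2), 3),
                         group = rep(c("a", "b", "c"), each = 2))
  gs <- compare_marker_by_group(same)
  expect_true(all(gs$contrasts$p.adj == 1))
  expect_equal(gs$overall$p.value, 1)
  # a singleton group is an error naming the group
  bad <- tibble::tibble(value = 1:4, group = c("a", "a", "a", "b"))
  expect_error(compare_marker_by_group(bad), "'b'")
})

test_that("Kaplan-Meier matches the hand product-limit and survfit", {
  # all censored: flat at 1
  km0 <- km_estimate(tibble::tibble(time = c(2, 5, 9), event = c(0, 0, 0)))
  expect_true(all(km0$surv == 1))
  # worked instance: events at 1 and 3, censor at 2
  km <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km$surv, c(1, 2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3, 3, 2, 1))
  # invariants: S(0)=1, non-increasing, within [0,1]
  set.seed(71)
  cli <- tibble::tibble(time = rexp(100, 1 / 300),
                        event = rbinom(100, 1, 0.7))
  kmr <- km_estimate(cli)
  expect_equal(kmr$surv[1], 1)
  expect_true(all(diff(kmr$surv) <= 1e-15))
  expect_true(all(kmr$surv >= 0 & kmr$surv <= 1))
  # equals the survival-package estimate at every event time
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = cli)
  at <- kmr$time[kmr$n_event > 0]
  expect_equal(kmr$surv[match(at, kmr$time)],
               summary(sf, times = at)$surv, tolerance = 1e-10)
  # with no censoring KM equals the empirical survival function
  cli2 <- tibble::tibble(time = rexp(80, 1 / 100), event = 1L)
  km2 <- km_estimate(cli2)
  emp <- vapply(km2$time, function(u) mean(cli2$time > u), numeric(1))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  expect_error(km_estimate(tibble::tibble(time = -1, event = 1L)),
               "positive")
})

test_that("KM recovers the exponential rate without censoring", {
  # the sample median of 200 exponentials has ~10% relative error, so the
  # rate is read off as the average over three independent draws
  set.seed(72)
  lambda <- 1 / 250
  est <- vapply(1:3, function(i) {
    km <- km_estimate(tibble::tibble(time = rexp(200, lambda), event = 1L))
    -log(0.5) / glance(km)$median_survival
  }, numeric(1))
  expect_lt(abs(mean(est) - lambda) / lambda, 0.15)
})

test_that("log-rank matches hand-tabulated risk sets and survdiff", {
  # identical groups: no evidence
  cli <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1L,
                        group = rep(c("a", "b"), each = 3))
  lr <- logrank_test(cli)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  # small worked instance, n = 6: brute-force O-E over pooled event times
  cli6 <- tibble::tibble(time = c(1, 3, 4, 2, 5, 6),
                         event = c(1, 1, 0, 1, 1, 1),
                         group = rep(c("a", "b"), each = 3))
  lr6 <- logrank_test(cli6)
  O <- c(a = 0, b = 0); E <- c(a = 0, b = 0); V <- 0
  for (u in sort(unique(cli6$time[cli6$event == 1]))) {
    at <- cli6$time >= u
    d <- sum(cli6$time == u & cli6$event == 1)
    n <- sum(at)
    for (gr in c("a", "b")) {
      ng <- sum(at & cli6$group == gr)
      O[gr] <- O[gr] + sum(cli6$time == u & cli6$event == 1 &
                             cli6$group == gr)
      E[gr] <- E[gr] + d * ng / n
    }
    na <- sum(at & cli6$group == "a")
    if (n > 1) V <- V + d * (n - d) / (n - 1) * (na / n) * (1 - na / n)
  }
  expect_equal(lr6$statistic, (O[["a"]] - E[["a"]])^2 / V, tolerance = 1e-12)
  ref <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = cli6)
  expect_equal(lr6$statistic, ref$chisq, tolerance = 1e-10)
  # three-group agreement with survdiff
  set.seed(73)
  cli3 <- tibble::tibble(time = rexp(90, 1 / 100),
                         event = rbinom(90, 1, 0.8),
                         group = rep(c("a", "b", "c"), 30))
  lr3 <- logrank_test(cli3)
  ref3 <- survival::survdiff(survival::Surv(time, event) ~ group,
                             data = cli3)
  expect_equal(lr3$statistic, ref3$chisq, tolerance = 1e-8)
  expect_equal(lr3$df, 2)
})

test_that("log-rank is invariant to time rescaling and label swaps", {
  set.seed(74)
  cli <- tibble::tibble(time = rexp(60, 1 / 100),
                        event = rbinom(60, 1, 0.7),
                        group = rep(c("a", "b"), 30))
  base <- logrank_test(cli)$statistic
  scaled <- dplyr::mutate(cli, time = time * 7.3)
  expect_equal(logrank_test(scaled)$statistic, base, tolerance = 1e-12)
  swapped <- dplyr::mutate(cli, group = ifelse(group == "a", "b", "a"))
  expect_equal(logrank_test(swapped)$statistic, base, tolerance = 1e-12)
  expect_error(logrank_test(dplyr::mutate(cli, group = "a")), "2 groups")
})
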