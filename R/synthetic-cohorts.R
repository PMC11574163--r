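# Synthetic multi-cohort generator. Emits per-cancer-type bundles (samples,
# PSI, expression, mutations, clinical) with known planted structure: one
# differentially spliced event, one anti-correlated regulator among the
# splicing factors, a marker gene whose expression couples to event PSI in
# planted-gene wild-type patients only, and a survival hazard raised for the
# susceptible stratum in one treatment arm.

#' Simulation configuration
#'
#' All knobs of the synthetic cohort generator, with defaults describing the
#' study conditions the screens are validated under: 15 cancer types with
#' 60 tumor / 30 normal samples each (15 patients dually sampled), 36
#' catalogued driver genes x 3 exon-skipping events, 172 splicing factors,
#' a planted event shifted by -0.2 PSI in 12 of 15 types, a regulator
#' coupled to tumor PSI at Pearson r = -0.6, and an exponential survival
#' model with hazard ratio 2.5 for the susceptible stratum.
#'
#' @param n_cancer_types Number of cancer types.
#' @param n_tumor,n_normal Tumor / normal sample counts per type.
#' @param n_paired Patients per type sampled in both tissues
#'   (`n_paired <= min(n_tumor, n_normal)`).
#' @param n_driver_genes Catalogued driver genes carrying splice events.
#' @param n_passenger_genes Mutated genes absent from the catalogue.
#' @param n_events_per_gene Exon-skipping events per driver gene.
#' @param n_factors Splicing factors (the regulator is one of them).
#' @param planted_gene,planted_event_id The differentially spliced event.
#' @param planted_delta Tumor-minus-normal PSI shift planted in
#'   `planted_n_types` types, in `[-1, 1]`.
#' @param planted_n_types Number of cancer types carrying the shift.
#' @param planted_psi_mean Baseline PSI mean of the planted event.
#' @param regulator Symbol of the planted regulator factor.
#' @param regulator_r Target Pearson correlation between tumor PSI of the
#'   planted event and log2(FPKM+1) of the regulator.
#' @param regulator_expr_shift Log2-units added to tumor-sample regulator
#'   expression in planted types (drives the cross-cancer
#'   delta-PSI-vs-delta-expression signal without touching delta-PSI, since
#'   the PSI coupling standardizes the realized expression within each type).
#' @param psi_noise_sd Gaussian PSI noise SD for the planted event.
#' @param beta_concentration Concentration of the Beta baseline for decoys.
#' @param frac_altered_patients Target probability that a dually sampled
#'   patient's paired |delta PSI| exceeds `alteration_threshold` (planted
#'   types only; requires `planted_delta != 0`).
#' @param alteration_threshold Paired-alteration threshold used for that
#'   calibration (default 0.15).
#' @param mutation_rate_planted Per-patient mutation probability of the
#'   planted gene.
#' @param mutation_rate_range Range of per-gene mutation probabilities for
#'   the other genes (drawn once per gene).
#' @param silent_frac Fraction of mutation records that are silent.
#' @param marker_gene Marker symbol (the PD-L1 role).
#' @param marker_baseline,marker_baseline_sd Baseline marker FPKM mean / SD.
#' @param marker_effect Additive marker FPKM per unit of planted-event tumor
#'   PSI, applied only to patients without a non-silent planted-gene
#'   mutation.
#' @param expr_log2_mean,expr_log2_sd Mean / SD of log2(FPKM+1) for ordinary
#'   gene expression.
#' @param baseline_hazard Exponential event hazard per day.
#' @param survival_hazard_ratio Hazard multiplier for patients who are
#'   planted-gene WT, regulator-low, and in the first treatment arm.
#' @param censor_rate Target censoring fraction (uniform censoring window
#'   solved from the baseline hazard).
#' @param arms Two treatment-arm labels; the hazard ratio applies to the
#'   first.
#' @param low_pct Percentile (0-100) below which non-mutant planted-gene
#'   expression removes a patient from the WT stratum.
#' @param missing_frac Fraction of PSI cells set missing at random.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cancer_types = 15L,
                       n_tumor = 60L,
                       n_normal = 30L,
                       n_paired = 15L,
                       n_driver_genes = 36L,
                       n_passenger_genes = 24L,
                       n_events_per_gene = 3L,
                       n_factors = 172L,
                       planted_gene = "PBRM1",
                       planted_event_id = "PBRM1|ES|27|25|28",
                       planted_delta = -0.2,
                       planted_n_types = 12L,
                       planted_psi_mean = 0.75,
                       regulator = "RBFOX2",
                       regulator_r = -0.6,
                       regulator_expr_shift = 0.8,
                       psi_noise_sd = 0.08,
                       beta_concentration = 30,
                       frac_altered_patients = 0.5,
                       alteration_threshold = 0.15,
                       mutation_rate_planted = 0.4,
                       mutation_rate_range = c(0.02, 0.3),
                       silent_frac = 0.1,
                       marker_gene = "PDL1",
                       marker_baseline = 0.8,
                       marker_baseline_sd = 0.25,
                       marker_effect = 1.5,
                       expr_log2_mean = 5,
                       expr_log2_sd = 1,
                       baseline_hazard = log(2) / 800,
                       survival_hazard_ratio = 2.5,
                       censor_rate = 0.3,
                       arms = c("nivolumab", "everolimus"),
                       low_pct = 12,
                       missing_frac = 0.02,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_cancer_types", "n_tumor", "n_normal", "n_driver_genes",
              "n_events_per_gene", "n_factors")
  for (f in counts) {
    if (cfg[[f]] < 1) abort(paste0("sim_config: ", f, " must be positive"))
  }
  if (n_paired < 0 || n_paired > min(n_tumor, n_normal)) {
    abort("sim_config: n_paired must be in [0, min(n_tumor, n_normal)]")
  }
  if (planted_n_types > n_cancer_types) {
    abort("sim_config: planted_n_types must not exceed n_cancer_types")
  }
  for (f in c("frac_altered_patients", "silent_frac", "censor_rate",
              "missing_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("sim_config: ", f, " must be in [0, 1]"))
    }
  }
  if (abs(planted_delta) > 1) abort("sim_config: planted_delta must be in [-1, 1]")
  if (abs(regulator_r) >= 1) {
    abort("sim_config: |regulator_r| must be < 1 (perfect coupling is not representable with noise)")
  }
  if (psi_noise_sd <= 0 && regulator_r != 0) {
    abort("sim_config: regulator coupling needs psi_noise_sd > 0; with zero noise only regulator_r = 0 is feasible")
  }
  if (length(arms) != 2L) abort("sim_config: exactly two treatment arms")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cancer_types, " cancer types, ",
      x$n_tumor, "T/", x$n_normal, "N per type (", x$n_paired, " paired)\n",
      "  planted: ", x$planted_event_id, " delta=", x$planted_delta,
      " in ", x$planted_n_types, " types; regulator ", x$regulator,
      " r=", x$regulator_r, "; seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# PSI coupling slope giving correlation r against a standardized covariate
# when the residual SD is `sd`: r = b / sqrt(b^2 + sd^2).
coupling_slope <- function(r, sd) {
  if (r == 0) return(0)
  sign(r) * abs(r) * sd / sqrt(1 - r^2)
}

# Shift m such that P(|N(m, s)| > thr) = frac; sign of m follows `direction`.
calibrate_paired_shift <- function(frac, thr, s, direction) {
  if (direction == 0) return(0)
  floor_frac <- 2 * stats::pnorm(-thr / s)
  if (frac < floor_frac - 1e-12) {
    abort(paste0("frac_altered_patients = ", frac,
                 " is below the noise floor ", signif(floor_frac, 3),
                 " implied by psi_noise_sd and the alteration threshold"))
  }
  f <- function(m) {
    stats::pnorm((-thr - m) / s) + stats::pnorm((m - thr) / s) - frac
  }
  lo <- 0
  hi <- sign(direction) * (thr + 10 * s)
  if (direction < 0) uniroot(f, c(hi, lo), tol = 1e-10)$root
  else uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Uniform censoring upper bound u with P(C < T) = rate for exponential(T).
censor_window <- function(lambda, rate) {
  if (rate <= 0) return(Inf)
  f <- function(u) (1 - exp(-lambda * u)) / (lambda * u) - rate
  uniroot(f, c(1e-8 / lambda, 1e6 / lambda), tol = 1e-10)$root
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate synthetic cohort bundles with ground truth
#'
#' See [sim_config()] for the generative model. All randomness derives from
#' the single config seed; each cancer type draws from its own sub-stream so
#' adding types does not reshuffle earlier ones.
#'
#' @param cfg A [sim_config()].
#' @return A list with `bundles` (named list of `cohort_bundle`s) and
#'   `truth` (a `ground_truth` list: `planted_event_id`, `regulator`,
#'   `per_type` tibble of true per-type deltas, `patients` tibble of
#'   per-patient flags/strata/hazards, and the config).
#' @export
generate_bundles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_exists()
  on.exit(.Random.seed_restore(old), add = TRUE)

  types <- sprintf("C%02d", seq_len(cfg$n_cancer_types))
  planted_types <- types[seq_len(cfg$planted_n_types)]

  # global (type-independent) structure
  set.seed(cfg$seed)
  driver_genes <- c(cfg$planted_gene,
                    sprintf("DRV%02d", seq_len(cfg$n_driver_genes - 1L)))
  passenger_genes <- if (cfg$n_passenger_genes > 0) {
    sprintf("PSG%02d", seq_len(cfg$n_passenger_genes))
  } else character(0)
  factors <- c(cfg$regulator,
               sprintf("SF%03d", seq_len(cfg$n_factors - 1L)))
  events <- make_event_table(driver_genes, cfg$n_events_per_gene,
                             cfg$planted_gene, cfg$planted_event_id)
  mu <- runif(nrow(events), 0.1, 0.9)
  mu[events$event_id == cfg$planted_event_id] <- cfg$planted_psi_mean
  events$mu <- mu
  mut_genes <- c(driver_genes, passenger_genes)
  mut_rates <- runif(length(mut_genes), cfg$mutation_rate_range[1],
                     cfg$mutation_rate_range[2])
  names(mut_rates) <- mut_genes
  mut_rates[cfg$planted_gene] <- cfg$mutation_rate_planted

  b <- coupling_slope(cfg$regulator_r, cfg$psi_noise_sd)
  s_paired <- sqrt(b^2 + 2 * cfg$psi_noise_sd^2)
  m_shift <- if (cfg$planted_delta != 0 && cfg$n_paired > 0) {
    calibrate_paired_shift(cfg$frac_altered_patients,
                           cfg$alteration_threshold, s_paired,
                           sign(cfg$planted_delta))
  } else 0
  u_censor <- censor_window(cfg$baseline_hazard, cfg$censor_rate)

  expr_genes <- c(driver_genes, factors, cfg$marker_gene)

  bundles <- vector("list", length(types))
  truth_pat <- vector("list", length(types))
  names(bundles) <- types
  for (i in seq_along(types)) {
    set.seed(cfg$seed + 1000L * i)
    g <- generate_type(cfg, types[i], types[i] %in% planted_types, events,
                       expr_genes, mut_genes, mut_rates, b, m_shift,
                       u_censor)
    bundles[[i]] <- g$bundle
    truth_pat[[i]] <- g$patients
  }

  truth <- structure(list(
    planted_event_id = cfg$planted_event_id,
    planted_gene = cfg$planted_gene,
    regulator = cfg$regulator,
    marker_gene = cfg$marker_gene,
    per_type = tibble(
      cancer_type = types,
      planted = types %in% planted_types,
      true_delta = ifelse(types %in% planted_types, cfg$planted_delta, 0),
      regulator_r = cfg$regulator_r
    ),
    patients = list_rbind(truth_pat),
    config = unclass(cfg)
  ), class = "ground_truth")

  list(bundles = bundles, truth = truth)
}

make_event_table <- function(driver_genes, n_events_per_gene, planted_gene,
                             planted_event_id) {
  planted <- parse_event_id(planted_event_id)
  rows <- lapply(driver_genes, function(g) {
    base <- if (g == planted_gene) {
      as.integer(planted$event_exons[[1]][1])
    } else {
      10L
    }
    k <- seq_len(n_events_per_gene)
    exon <- base + 3L * (k - 1L)
    ids <- format_event_id(g, "ES", as.list(as.character(exon)),
                           as.character(exon - 1L), as.character(exon + 1L))
    if (g == planted_gene) ids[1] <- planted_event_id
    parse_event_id(ids)
  })
  out <- list_rbind(rows)
  out$event_exons <- vapply(out$event_exons, paste, character(1),
                            collapse = ":")
  out
}

generate_type <- function(cfg, ct, is_planted, events, expr_genes,
                          mut_genes, mut_rates, b, m_shift, u_censor) {
  n_t <- cfg$n_tumor
  n_n <- cfg$n_normal
  n_p <- cfg$n_paired
  tumor_pats <- sprintf("%s-P%03d", ct, seq_len(n_t))
  paired_pats <- tumor_pats[seq_len(n_p)]
  normal_only <- sprintf("%s-P%03d", ct, n_t + seq_len(n_n - n_p))
  normal_pats <- c(paired_pats, normal_only)
  tumor_ids <- paste0(tumor_pats, "-T")
  normal_ids <- paste0(normal_pats, "-N")
  samples <- tibble(
    sample_id = c(tumor_ids, normal_ids),
    patient_id = c(tumor_pats, normal_pats),
    cancer_type = ct,
    tissue = rep(c("tumor", "normal"), c(n_t, n_n))
  )

  # expression: log2(FPKM + 1) ~ N(mean, sd); regulator tumor shift in
  # planted types
  n_g <- length(expr_genes)
  n_s <- n_t + n_n
  x <- matrix(rnorm(n_g * n_s, cfg$expr_log2_mean, cfg$expr_log2_sd),
              nrow = n_g, dimnames = list(expr_genes, c(tumor_ids, normal_ids)))
  if (is_planted && cfg$regulator_expr_shift != 0) {
    x[cfg$regulator, tumor_ids] <- x[cfg$regulator, tumor_ids] +
      cfg$regulator_expr_shift
  }
  z <- x[cfg$regulator, tumor_ids]
  z <- (z - mean(z)) / sd(z)

  # PSI: decoys Beta-distributed around their event mean; planted event
  # built from the regulator coupling plus the planted shift
  c0 <- cfg$beta_concentration
  psi_mat <- matrix(rbeta(nrow(events) * n_s,
                          rep(events$mu * c0, n_s),
                          rep((1 - events$mu) * c0, n_s)),
                    nrow = nrow(events),
                    dimnames = list(events$event_id, c(tumor_ids, normal_ids)))
  pe <- cfg$planted_event_id
  mu_p <- events$mu[events$event_id == pe]
  delta_c <- if (is_planted) cfg$planted_delta else 0
  m_c <- if (is_planted) m_shift else 0
  eps_t <- rnorm(n_t, 0, cfg$psi_noise_sd)
  eps_n <- rnorm(n_n, 0, cfg$psi_noise_sd)
  tumor_shift <- rep(delta_c, n_t)
  if (n_p > 0) tumor_shift[seq_len(n_p)] <- m_c
  psi_mat[pe, tumor_ids] <- clamp01(mu_p + tumor_shift + b * z + eps_t)
  psi_mat[pe, normal_ids] <- clamp01(mu_p + eps_n)

  paired_delta <- if (n_p > 0) {
    psi_mat[pe, paste0(paired_pats, "-T")] -
      psi_mat[pe, paste0(paired_pats, "-N")]
  } else numeric(0)

  # mutations: per-gene Bernoulli over tumor patients, one record each
  mut_list <- lapply(mut_genes, function(g) {
    hit <- runif(n_t) < mut_rates[[g]]
    if (!any(hit)) return(NULL)
    tibble(patient_id = tumor_pats[hit], gene = g)
  })
  mutations <- list_rbind(mut_list[!vapply(mut_list, is.null, logical(1))])
  if (nrow(mutations) > 0) {
    nonsilent <- c("missense", "nonsense", "frameshift", "splice_site",
                   "in_frame")
    w <- c(0.62, 0.12, 0.14, 0.06, 0.06) * (1 - cfg$silent_frac)
    mutations$variant_class <- sample(
      c(nonsilent, "silent"), nrow(mutations), replace = TRUE,
      prob = c(w, cfg$silent_frac))
  } else {
    mutations <- tibble(patient_id = character(0), gene = character(0),
                        variant_class = character(0))
  }

  # marker expression couples to planted-event tumor PSI in patients without
  # a non-silent planted-gene mutation
  mut_pl <- unique(mutations$patient_id[
    mutations$gene == cfg$planted_gene &
      mutations$variant_class != "silent"])
  baseline <- pmax(0, rnorm(n_s, cfg$marker_baseline, cfg$marker_baseline_sd))
  marker <- baseline
  is_wt_tumor <- !(tumor_pats %in% mut_pl)
  marker[seq_len(n_t)][is_wt_tumor] <- baseline[seq_len(n_t)][is_wt_tumor] +
    cfg$marker_effect * psi_mat[pe, tumor_ids][is_wt_tumor]
  x[cfg$marker_gene, ] <- log2(marker + 1)

  expr <- tibble(
    gene = rep(expr_genes, n_s),
    sample_id = rep(c(tumor_ids, normal_ids), each = n_g),
    fpkm = as.vector(2^x - 1)
  )
  # numeric guard: 2^log2(v+1)-1 can dip an epsilon below zero
  expr$fpkm <- pmax(expr$fpkm, 0)

  # strata via the same rules the analysis applies downstream
  expr_tbl <- expr
  samples_tbl <- samples
  mut_status <- classify_mut_status(mutations, expr_tbl, samples_tbl,
                                    gene = cfg$planted_gene,
                                    low_pct = cfg$low_pct)
  reg_split <- split_by_expression(expr_tbl, samples_tbl,
                                   gene = cfg$regulator, rule = "median")
  strata <- tibble(patient_id = tumor_pats) |>
    left_join(mut_status, by = "patient_id") |>
    left_join(reg_split, by = "patient_id") |>
    mutate(high_e27 = mut_status == "WT" & group == "low")

  arm <- sample(cfg$arms, n_t, replace = TRUE)
  hazard <- cfg$baseline_hazard *
    ifelse(strata$high_e27 & arm == cfg$arms[1], cfg$survival_hazard_ratio, 1)
  t_event <- rexp(n_t, rate = hazard)
  c_time <- runif(n_t, 0, u_censor)
  clinical <- tibble(
    patient_id = tumor_pats,
    time = pmax(pmin(t_event, c_time), 1e-3),
    event = as.integer(t_event <= c_time),
    arm = arm
  )

  # PSI long table with random missingness
  psi_long <- tibble(
    event_id = rep(events$event_id, n_s),
    gene = rep(events$gene, n_s),
    as_type = rep(events$as_type, n_s),
    event_exons = rep(events$event_exons, n_s),
    upstream_exon = rep(events$upstream_exon, n_s),
    downstream_exon = rep(events$downstream_exon, n_s),
    sample_id = rep(c(tumor_ids, normal_ids), each = nrow(events)),
    psi = round(as.vector(psi_mat), 4)
  )
  if (cfg$missing_frac > 0) {
    drop <- runif(nrow(psi_long)) < cfg$missing_frac
    psi_long$psi[drop] <- NA_real_
  }

  bundle <- cohort_bundle(ct, samples, psi_long, expr, mutations, clinical)

  patients <- tibble(
    cancer_type = ct,
    patient_id = tumor_pats,
    paired = tumor_pats %in% paired_pats,
    altered = NA,
    mut_planted = tumor_pats %in% mut_pl,
    mut_status = strata$mut_status,
    regulator_group = strata$group,
    functional_group = ifelse(strata$high_e27, "high_E27", "low_E27"),
    arm = arm,
    hazard = hazard
  )
  if (n_p > 0) {
    patients$altered[seq_len(n_p)] <-
      abs(paired_delta) > cfg$alteration_threshold
  }
  list(bundle = bundle, patients = patients)
}

#' Write cohort bundles and the ground-truth manifest to disk
#'
#' Creates one sub-directory per cancer type (five TSV tables each), a
#' `ground_truth.json` manifest and a `run_log.json` recording the seed.
#'
#' @param bundles Named list of `cohort_bundle`s.
#' @param truth A `ground_truth` object (or `NULL` to skip the manifest).
#' @param out_dir Output directory (created if needed).
#' @return A character vector of all files written (the manifest), invisibly.
#' @export
write_bundles <- function(bundles, truth, out_dir) {
  if (length(bundles) == 0) abort("write_bundles: empty bundle list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (b in bundles) {
    d <- file.path(out_dir, b$cancer_type)
    dir.create(d, showWarnings = FALSE)
    files <- c(files,
               write_samples(b$samples, file.path(d, "samples.tsv")),
               write_psi_table(b$psi, file.path(d, "psi.tsv")),
               write_expr_table(b$expr, file.path(d, "expr.tsv")),
               write_mutations(b$mutations, file.path(d, "mutations.tsv")),
               write_clinical(b$clinical, file.path(d, "clinical.tsv")))
  }
  if (!is.null(truth)) {
    mf <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(ground_truth_to_list(truth), mf, digits = NA,
                         auto_unbox = TRUE, null = "null")
    files <- c(files, mf)
  }
  lg <- file.path(out_dir, "run_log.json")
  seed <- if (!is.null(truth)) truth$config$seed else NA
  jsonlite::write_json(list(seed = seed, n_bundles = length(bundles)),
                       lg, auto_unbox = TRUE)
  files <- c(files, lg)
  invisible(files)
}

ground_truth_to_list <- function(truth) {
  cfg <- truth$config
  cfg$arms <- as.list(cfg$arms)
  cfg$mutation_rate_range <- as.list(cfg$mutation_rate_range)
  list(
    planted_event_id = truth$planted_event_id,
    planted_gene = truth$planted_gene,
    regulator = truth$regulator,
    marker_gene = truth$marker_gene,
    per_type = truth$per_type,
    patients = truth$patients,
    config = cfg
  )
}

#' Read a ground-truth manifest back from disk
#'
#' @param path Path to `ground_truth.json` as written by [write_bundles()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    planted_event_id = raw$planted_event_id,
    planted_gene = raw$planted_gene,
    regulator = raw$regulator,
    marker_gene = raw$marker_gene,
    per_type = as_tibble(raw$per_type),
    patients = as_tibble(raw$patients),
    config = raw$config
  ), class = "ground_truth")
}
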