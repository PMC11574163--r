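# Small in-code fixtures shared across the suite.

# A two-event, three-sample PSI file in the SpliceSeq-style dialect.
write_tiny_psi_file <- function(path, cell_21 = "NA") {
  lines <- c(
    "symbol\tsplice_type\texons\tfrom_exon\tto_exon\tS1\tS2\tS3",
    "PBRM1\tES\t27\t25\t28\t0.8000\t0.6000\t0.7000",
    paste("GENE2\tES\t5\t4\t6\t0.1000", cell_21, "0.2000", sep = "\t")
  )
  writeLines(lines, path)
  path
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    patient_id = c("P1", "P2", "P3"),
    cancer_type = "KIRC",
    tissue = c("tumor", "tumor", "normal")
  )
}

# Long PSI tibble from explicit tumor / normal value vectors for one event.
psi_from_groups <- function(tumor, normal, event = "GENE1|ES|10|9|11",
                            cancer_type = "C01") {
  n_t <- length(tumor)
  n_n <- length(normal)
  ids <- c(sprintf("T%02d", seq_len(n_t)), sprintf("N%02d", seq_len(n_n)))
  ev <- splicescreen::parse_event_id(event)
  psi <- tibble::tibble(
    event_id = event, gene = ev$gene, as_type = ev$as_type,
    event_exons = paste(ev$event_exons[[1]], collapse = ":"),
    upstream_exon = ev$upstream_exon, downstream_exon = ev$downstream_exon,
    sample_id = ids, psi = c(tumor, normal)
  )
  samples <- tibble::tibble(
    sample_id = ids,
    patient_id = paste0("P", ids),
    cancer_type = cancer_type,
    tissue = rep(c("tumor", "normal"), c(n_t, n_n))
  )
  list(psi = psi, samples = samples)
}

# Per-type event summaries with prescribed quantified / detected patterns.
summaries_from_pattern <- function(quantified, detected, delta = 0.2,
                                   event = "E1", gene = "G1") {
  n <- length(quantified)
  tibble::tibble(
    event_id = event, gene = gene,
    cancer_type = sprintf("C%02d", seq_len(n)),
    mean_psi_tumor = 0.5 + ifelse(quantified, delta, NA),
    mean_psi_normal = 0.5,
    delta_psi = ifelse(quantified, delta, NA_real_),
    n_tumor = ifelse(quantified, 30L, 2L),
    n_normal = ifelse(quantified, 30L, 2L),
    t_stat = ifelse(quantified, 5, NA_real_),
    # detected = quantified & (p < alpha | |dPSI| > floor); drive via p
    p_value = dplyr::case_when(
      !quantified ~ NA_real_,
      detected ~ 0.001,
      TRUE ~ 0.9
    ),
    quantified = quantified
  ) |>
    dplyr::mutate(delta_psi = dplyr::case_when(
      !quantified ~ NA_real_,
      detected ~ delta,
      TRUE ~ 0.0  # undetected: null delta below the floor
    ))
}

# Tiny deterministic cohort for strata tests.
tiny_cohort <- function() {
  n <- 10L
  pats <- sprintf("P%02d", seq_len(n))
  samples <- tibble::tibble(
    sample_id = paste0(pats, "-T"), patient_id = pats,
    cancer_type = "KIRC", tissue = "tumor"
  )
  expr <- tibble::tibble(
    gene = rep(c("PBRM1", "RBFOX2", "PDL1"), each = n),
    sample_id = rep(samples$sample_id, 3),
    fpkm = c(seq(1, 10), seq(10, 1), rep(c(1, 2), 5))
  )
  mutations <- tibble::tibble(
    patient_id = c("P01", "P02", "P03"),
    gene = c("PBRM1", "PBRM1", "VHL"),
    variant_class = c("frameshift", "silent", "missense")
  )
  list(samples = samples, expr = expr, mutations = mutations)
}
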