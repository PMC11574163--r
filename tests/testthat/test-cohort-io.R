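test_that("event ids round-trip through parse and format", {
  set.seed(11)
  for (i in 1:50) {
    gene <- paste0("G", sample(1000, 1))
    type <- sample(c("ES", "AA", "AD", "RI"), 1)
    exons <- as.character(sample(50, sample(1:3, 1)))
    exons <- ifelse(runif(length(exons)) < 0.3,
                    paste0(exons, ".", sample(3, length(exons),
                                              replace = TRUE)), exons)
    up <- "4"
    down <- "9.1"
    id <- format_event_id(gene, type, exons, up, down)
    back <- parse_event_id(id)
    expect_identical(back$gene, gene)
    expect_identical(back$as_type, type)
    expect_identical(back$event_exons[[1]], exons)
    expect_identical(
      format_event_id(back$gene, back$as_type, back$event_exons[[1]],
                      back$upstream_exon, back$downstream_exon), id)
  }
  expect_error(parse_event_id("PBRM1|ES|27"), "malformed")
  expect_error(format_event_id("G", "XX", "1", "0", "2"), "AS type")
})

test_that("PSI tables parse with missing cells kept missing, not zero", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_psi_file(f)
  psi <- read_psi_table(f)
  expect_equal(nrow(psi), 6)
  expect_equal(sum(is.na(psi$psi)), 1)
  expect_equal(psi$psi[psi$event_id == "GENE2|ES|5|4|6" &
                         psi$sample_id == "S1"], 0.1)
  expect_setequal(unique(psi$event_id),
                  c("PBRM1|ES|27|25|28", "GENE2|ES|5|4|6"))
})

test_that("out-of-range and malformed PSI cells give located errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_psi_file(f, cell_21 = "1.2")
  expect_error(read_psi_table(f), "1\\.2.*GENE2.*S2|GENE2.*S2.*1\\.2")
  # fuzzed malformed cells never coerce silently
  for (bad in c("-0.1", "abc", "0.5.5", "1.0001")) {
    write_tiny_psi_file(f, cell_21 = bad)
    expect_error(read_psi_table(f))
  }
  # header validation names the missing column
  writeLines(c("symbol\tsplice_type\texons\tfrom_exon\tS1", "A\tES\t1\t0\t0.5"), f)
  expect_error(read_psi_table(f), "to_exon")
})

test_that("PSI write -> read is the identity at 4-decimal precision", {
  sim <- generate_bundles(sim_config(
    n_cancer_types = 1, planted_n_types = 1, n_tumor = 12, n_normal = 12,
    n_paired = 6, n_driver_genes = 4, n_passenger_genes = 2, seed = 42))
  psi <- sim$bundles[[1]]$psi
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psi_table(psi, f)
  back <- read_psi_table(f)
  merged <- dplyr::inner_join(psi, back, by = c("event_id", "sample_id"))
  expect_equal(nrow(merged), nrow(psi))
  expect_equal(merged$psi.x, merged$psi.y, tolerance = 1e-12)
})

test_that("MAF spellings normalize to the variant-class enum", {
  expect_identical(normalize_variant_class("Frame_Shift_Ins"), "frameshift")
  expect_identical(normalize_variant_class("Missense_Mutation"), "missense")
  expect_warning(out <- normalize_variant_class("Weird_Thing"), "other")
  expect_identical(out, "other")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Tumor_Sample_Barcode\tHugo_Symbol\tVariant_Classification",
               "P1\tTP53\tFrame_Shift_Ins"), f)
  m <- read_mutations(f)
  expect_identical(m$variant_class, "frameshift")
  expect_identical(m$patient_id, "P1")
})

test_that("expression and clinical validation reject bad values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "A\t-1.5\t2"), f)
  expect_error(read_expr_table(f), "negative FPKM")
  writeLines(c("patient_id\ttime_days\tevent\tarm",
               "P1\t0\t1\tnivolumab"), f)
  expect_error(read_clinical(f), "non-positive")
  writeLines(c("patient_id\ttime_days\tevent\tarm",
               "P1\t10\t2\tnivolumab"), f)
  expect_error(read_clinical(f), "0.*1|censored")
})

test_that("tissue is inferred from TCGA barcodes by the 01-19 code split", {
  expect_identical(infer_tissue_from_barcode("TCGA-XX-0001-01"), "tumor")
  expect_identical(infer_tissue_from_barcode("TCGA-XX-0001-11"), "normal")
  expect_identical(
    infer_tissue_from_barcode(c("TCGA-A-1-01A", "TCGA-A-2-10B")),
    c("tumor", "normal"))
  expect_error(infer_tissue_from_barcode("S1"), "tissue column")
})

test_that("bundle write -> read reproduces every table field-for-field", {
  for (seed in c(7, 8)) {
    sim <- generate_bundles(sim_config(
      n_cancer_types = 2, planted_n_types = 2, n_tumor = 14, n_normal = 12,
      n_paired = 6, n_driver_genes = 3, n_passenger_genes = 1,
      n_factors = 4, seed = seed))
    d <- withr::local_tempfile()
    write_bundles(sim$bundles, sim$truth, d)
    back <- read_bundles(d)
    expect_setequal(names(back), names(sim$bundles))
    for (ct in names(sim$bundles)) {
      orig <- sim$bundles[[ct]]
      got <- back[[ct]]
      expect_equal(got$samples, orig$samples)
      expect_equal(
        dplyr::arrange(got$mutations, patient_id, gene),
        dplyr::arrange(orig$mutations, patient_id, gene))
      expect_equal(got$clinical$time, orig$clinical$time, tolerance = 1e-9)
      eo <- dplyr::arrange(orig$expr, gene, sample_id)
      eg <- dplyr::arrange(got$expr, gene, sample_id)
      expect_equal(eg$fpkm, eo$fpkm, tolerance = 1e-9)
      po <- dplyr::arrange(orig$psi, event_id, sample_id)
      pg <- dplyr::arrange(got$psi, event_id, sample_id)
      expect_equal(pg$psi, po$psi, tolerance = 1e-12)
    }
    truth_back <- read_ground_truth(file.path(d, "ground_truth.json"))
    expect_identical(truth_back$planted_event_id, sim$truth$planted_event_id)
    expect_equal(as.data.frame(truth_back$per_type),
                 as.data.frame(sim$truth$per_type))
    expect_equal(truth_back$patients$functional_group,
                 sim$truth$patients$functional_group)
  }
})

test_that("bundle validation rejects stray samples and patients", {
  p <- psi_from_groups(c(0.5, 0.6), c(0.4, 0.5))
  expr <- tibble::tibble(gene = "A", sample_id = "T01", fpkm = 1)
  muts <- tibble::tibble(patient_id = "PT01", gene = "A",
                         variant_class = "missense")
  cli <- tibble::tibble(patient_id = "PT01", time = 10, event = 1L,
                        arm = "a")
  expect_s3_class(
    cohort_bundle("C01", p$samples, p$psi, expr, muts, cli),
    "cohort_bundle")
  bad_psi <- dplyr::mutate(p$psi,
                           sample_id = replace(sample_id, 1, "GHOST"))
  expect_error(cohort_bundle("C01", p$samples, bad_psi, expr, muts, cli),
               "GHOST")
  bad_cli <- dplyr::mutate(cli, patient_id = "NOBODY")
  expect_error(cohort_bundle("C01", p$samples, p$psi, expr, muts, bad_cli),
               "NOBODY")
})
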