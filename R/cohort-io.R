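# Readers/writers for the pipeline's tabular dialect: UTF-8 TSV, "." decimal
# separator, missing cells written as "" or "NA", PSI serialized to 4
# decimals. Exon labels are opaque SpliceSeq-style strings ("27", "14.2"),
# never genomic coordinates.

PSI_ID_COLS <- c("symbol", "splice_type", "exons", "from_exon", "to_exon")
AS_TYPES <- c("ES", "AA", "AD", "RI")
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice_site",
                     "in_frame", "silent", "other")

# MAF Variant_Classification spellings -> normalized enum
MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Nonstop_Mutation  = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift",
  Splice_Site       = "splice_site",
  Splice_Region     = "splice_site",
  In_Frame_Del      = "in_frame",
  In_Frame_Ins      = "in_frame",
  Silent            = "silent"
)

#' Compose / parse canonical splice-event identifiers
#'
#' The canonical form is `"GENE|TYPE|event|up|down"`, e.g.
#' `"PBRM1|ES|27|25|28"`. Multiple event exons are joined with `:`.
#'
#' @param gene Gene symbol.
#' @param as_type One of `"ES"`, `"AA"`, `"AD"`, `"RI"`.
#' @param event_exons Character vector of event exon labels.
#' @param upstream_exon,downstream_exon Flanking exon labels.
#' @return `format_event_id()`: the canonical string. `parse_event_id()`: a
#'   tibble with columns `event_id`, `gene`, `as_type`, `event_exons`
#'   (list-column), `upstream_exon`, `downstream_exon`.
#' @export
format_event_id <- function(gene, as_type, event_exons, upstream_exon,
                            downstream_exon) {
  if (!all(as_type %in% AS_TYPES)) {
    abort(paste0("unknown AS type; expected one of ",
                 paste(AS_TYPES, collapse = ", ")))
  }
  exons <- if (is.list(event_exons)) {
    vapply(event_exons, paste, character(1), collapse = ":")
  } else {
    paste(event_exons, collapse = ":")
  }
  paste(gene, as_type, exons, upstream_exon, downstream_exon, sep = "|")
}

#' @rdname format_event_id
#' @param event_id Canonical event identifier string(s).
#' @export
parse_event_id <- function(event_id) {
  parts <- strsplit(event_id, "|", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) {
    abort(paste0("malformed event_id: ", event_id[bad][1]))
  }
  m <- do.call(rbind, parts)
  out <- tibble(
    event_id = event_id,
    gene = m[, 1],
    as_type = m[, 2],
    event_exons = strsplit(m[, 3], ":", fixed = TRUE),
    upstream_exon = m[, 4],
    downstream_exon = m[, 5]
  )
  if (!all(out$as_type %in% AS_TYPES)) {
    abort(paste0("unknown AS type in event_id: ",
                 out$event_id[!out$as_type %in% AS_TYPES][1]))
  }
  out
}

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"), ...)
}

#' Read a SpliceSeq-style PSI table
#'
#' Expects five event-identity columns (`symbol`, `splice_type`, `exons`,
#' `from_exon`, `to_exon`) followed by one column per sample. Empty cells and
#' `"NA"` are recorded as missing (never as zero); any value outside `[0, 1]`
#' raises a validation error naming the offending cell.
#'
#' @param path Path to a TSV file.
#' @return A long tibble with columns `event_id`, `gene`, `as_type`,
#'   `event_exons`, `upstream_exon`, `downstream_exon`, `sample_id`, `psi`.
#' @export
read_psi_table <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(PSI_ID_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("PSI table ", path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  sample_cols <- setdiff(names(raw), PSI_ID_COLS)
  if (length(sample_cols) == 0) abort("PSI table has no sample columns")
  long <- raw |>
    pivot_longer(all_of(sample_cols), names_to = "sample_id",
                 values_to = "psi_chr")
  vals <- suppressWarnings(as.numeric(long$psi_chr))
  bad_num <- !is.na(long$psi_chr) & is.na(vals)
  bad_rng <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad_num) || any(bad_rng)) {
    i <- which(bad_num | bad_rng)[1]
    abort(paste0("invalid PSI value '", long$psi_chr[i], "' for event ",
                 long$symbol[i], " (", long$splice_type[i], " ",
                 long$exons[i], "), sample ", long$sample_id[i],
                 ": must be a number in [0, 1]"))
  }
  tibble(
    event_id = format_event_id(long$symbol, long$splice_type,
                               strsplit(long$exons, ":", fixed = TRUE),
                               long$from_exon, long$to_exon),
    gene = long$symbol,
    as_type = long$splice_type,
    event_exons = long$exons,
    upstream_exon = long$from_exon,
    downstream_exon = long$to_exon,
    sample_id = long$sample_id,
    psi = vals
  )
}

#' Write a PSI table in the SpliceSeq-style wide dialect
#'
#' PSI is serialized to 4 decimals; missing values become `"NA"`.
#'
#' @param psi Long PSI tibble as returned by [read_psi_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psi_table <- function(psi, path) {
  wide <- psi |>
    mutate(psi = ifelse(is.na(psi), NA_character_, sprintf("%.4f", psi))) |>
    select(symbol = gene, splice_type = as_type, exons = event_exons,
           from_exon = upstream_exon, to_exon = downstream_exon,
           sample_id, psi) |>
    pivot_wider(names_from = sample_id, values_from = psi)
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write an FPKM expression table
#'
#' Wide format: a `gene` column followed by one column per sample. Negative
#' FPKM values are a validation error.
#'
#' @param path Path to a TSV file.
#' @return A long tibble with columns `gene`, `sample_id`, `fpkm`.
#' @export
read_expr_table <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(
    gene = "c", .default = "d"))
  if (!"gene" %in% names(raw)) abort("expression table missing 'gene' column")
  long <- raw |>
    pivot_longer(-gene, names_to = "sample_id", values_to = "fpkm")
  bad <- !is.na(long$fpkm) & long$fpkm < 0
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("negative FPKM ", long$fpkm[i], " for gene ", long$gene[i],
                 ", sample ", long$sample_id[i]))
  }
  long
}

#' @rdname read_expr_table
#' @param expr Long expression tibble (`gene`, `sample_id`, `fpkm`).
#' @export
write_expr_table <- function(expr, path) {
  wide <- expr |>
    select(gene, sample_id, fpkm) |>
    pivot_wider(names_from = sample_id, values_from = fpkm)
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a minimal MAF-style somatic mutation table
#'
#' Accepts either minimal MAF headers (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`) or the pipeline's own (`patient_id`, `gene`,
#' `variant_class`). MAF variant-class spellings are normalized to
#' `missense`, `nonsense`, `frameshift`, `splice_site`, `in_frame`,
#' `silent`; unknown spellings map to `other` with a warning.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `patient_id`, `gene`, `variant_class`.
#' @export
read_mutations <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (all(c("Tumor_Sample_Barcode", "Hugo_Symbol",
            "Variant_Classification") %in% names(raw))) {
    out <- tibble(patient_id = raw$Tumor_Sample_Barcode,
                  gene = raw$Hugo_Symbol,
                  variant_class = raw$Variant_Classification)
  } else if (all(c("patient_id", "gene", "variant_class") %in% names(raw))) {
    out <- raw |> select(patient_id, gene, variant_class)
  } else {
    abort("mutation table needs MAF columns (Tumor_Sample_Barcode, Hugo_Symbol, Variant_Classification) or (patient_id, gene, variant_class)")
  }
  out$variant_class <- normalize_variant_class(out$variant_class)
  out
}

#' Normalize MAF variant-classification spellings
#'
#' @param x Character vector of variant classifications.
#' @return Character vector over the normalized enum; unknown values become
#'   `"other"` with a warning.
#' @export
normalize_variant_class <- function(x) {
  out <- ifelse(x %in% VARIANT_CLASSES, x, unname(MAF_CLASS_MAP[x]))
  unknown <- is.na(out)
  if (any(unknown)) {
    warn(paste0("unknown variant class(es) mapped to 'other': ",
                paste(unique(x[unknown]), collapse = ", ")))
    out[unknown] <- "other"
  }
  out
}

#' @rdname read_mutations
#' @param mutations Tibble with `patient_id`, `gene`, `variant_class`.
#' @export
write_mutations <- function(mutations, path) {
  readr::write_tsv(select(mutations, patient_id, gene, variant_class),
                   path, progress = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' Columns `patient_id`, `time_days` (> 0), `event` (0 censored / 1 death)
#' and `arm` (free-text treatment label).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `patient_id`, `time`, `event`, `arm`.
#' @export
read_clinical <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(
    patient_id = "c", time_days = "d", event = "i", arm = "c"))
  need <- c("patient_id", "time_days", "event", "arm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_t <- is.na(raw$time_days) | raw$time_days <= 0
  if (any(bad_t)) {
    abort(paste0("non-positive or missing survival time for patient ",
                 raw$patient_id[which(bad_t)[1]]))
  }
  if (!all(raw$event %in% c(0L, 1L))) {
    abort("clinical 'event' must be 0 (censored) or 1 (death)")
  }
  tibble(patient_id = raw$patient_id, time = raw$time_days,
         event = raw$event, arm = raw$arm)
}

#' @rdname read_clinical
#' @param clinical Tibble with `patient_id`, `time`, `event`, `arm`.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(
    tibble(patient_id = clinical$patient_id, time_days = clinical$time,
           event = clinical$event, arm = clinical$arm),
    path, progress = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' @param path Path to a TSV with columns `sample_id`, `patient_id`,
#'   `cancer_type`, `tissue`.
#' @return A tibble with those columns; `tissue` validated to
#'   `tumor`/`normal`, `sample_id` to uniqueness.
#' @export
read_samples <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  need <- c("sample_id", "patient_id", "cancer_type", "tissue")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_samples(raw[need])
}

#' @rdname read_samples
#' @param samples Sample tibble.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(
    select(samples, sample_id, patient_id, cancer_type, tissue),
    path, progress = FALSE)
  invisible(path)
}

validate_samples <- function(samples) {
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  bad <- !samples$tissue %in% c("tumor", "normal")
  if (any(bad)) {
    abort(paste0("tissue must be 'tumor' or 'normal'; got '",
                 samples$tissue[bad][1], "'"))
  }
  as_tibble(samples)
}

#' Infer tissue from a TCGA-style barcode
#'
#' TCGA sample-type codes 01-09 denote tumor and 10-19 normal; the code is
#' the final two-digit field of the barcode.
#'
#' @param sample_id Character vector of barcodes ending in a two-digit code.
#' @return Character vector of `"tumor"`/`"normal"`.
#' @export
infer_tissue_from_barcode <- function(sample_id) {
  code <- regmatches(sample_id, regexpr("([0-9]{2})[A-Z]?$", sample_id))
  code_num <- suppressWarnings(as.integer(substr(code, 1, 2)))
  ok <- lengths(regmatches(sample_id, gregexpr("-", sample_id))) >= 1 &
    !is.na(code_num)
  out <- rep(NA_character_, length(sample_id))
  out[ok & code_num >= 1 & code_num <= 9] <- "tumor"
  out[ok & code_num >= 10 & code_num <= 19] <- "normal"
  if (anyNA(out)) {
    abort(paste0("cannot infer tissue from sample_id '",
                 sample_id[is.na(out)][1],
                 "'; supply an explicit tissue column instead"))
  }
  out
}

#' Read a one-symbol-per-line gene list
#'
#' Used for the driver catalogue and the splicing-factor list.
#'
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return Character vector of unique symbols (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' @rdname read_gene_list
#' @param genes Character vector of gene symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Assemble and validate a cohort bundle
#'
#' A bundle links one cancer type's sample sheet, PSI table, expression
#' table, mutations and clinical records. Validation checks that all
#' sample ids in the PSI/expression tables appear in the sample sheet and
#' that all patient ids in mutations/clinical belong to the cohort. When a
#' patient carries multiple tumor samples the first in sheet order is kept
#' for per-patient analyses (a notice is emitted).
#'
#' @param cancer_type Short cohort code (e.g. `"KIRC"`).
#' @param samples,psi,expr,mutations,clinical Component tibbles as produced
#'   by the `read_*` functions.
#' @return A `cohort_bundle` (a validated list of the component tibbles).
#' @export
cohort_bundle <- function(cancer_type, samples, psi, expr, mutations,
                          clinical) {
  samples <- validate_samples(samples)
  stray_psi <- setdiff(unique(psi$sample_id), samples$sample_id)
  if (length(stray_psi) > 0) {
    abort(paste0("PSI sample(s) not in sample sheet: ",
                 paste(head(stray_psi, 3), collapse = ", ")))
  }
  stray_expr <- setdiff(unique(expr$sample_id), samples$sample_id)
  if (length(stray_expr) > 0) {
    abort(paste0("expression sample(s) not in sample sheet: ",
                 paste(head(stray_expr, 3), collapse = ", ")))
  }
  pats <- unique(samples$patient_id)
  stray_mut <- setdiff(unique(mutations$patient_id), pats)
  if (length(stray_mut) > 0) {
    abort(paste0("mutation patient(s) not in cohort: ",
                 paste(head(stray_mut, 3), collapse = ", ")))
  }
  stray_cli <- setdiff(unique(clinical$patient_id), pats)
  if (length(stray_cli) > 0) {
    abort(paste0("clinical patient(s) not in cohort: ",
                 paste(head(stray_cli, 3), collapse = ", ")))
  }
  dup <- samples |>
    filter(tissue == "tumor") |>
    count(patient_id) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    inform(paste0(nrow(dup), " patient(s) with multiple tumor samples; ",
                  "first sample in sheet order is used"))
  }
  structure(
    list(cancer_type = cancer_type, samples = samples, psi = psi,
         expr = expr, mutations = mutations, clinical = clinical),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", x$cancer_type, "\n", sep = "")
  cat("  samples: ", nrow(x$samples),
      " (", sum(x$samples$tissue == "tumor"), " tumor / ",
      sum(x$samples$tissue == "normal"), " normal)\n", sep = "")
  cat("  events: ", length(unique(x$psi$event_id)),
      " | genes: ", length(unique(x$expr$gene)),
      " | mutations: ", nrow(x$mutations),
      " | clinical: ", nrow(x$clinical), "\n", sep = "")
  invisible(x)
}

#' Read or write a directory of cohort bundles
#'
#' The on-disk layout is one sub-directory per cancer type holding
#' `samples.tsv`, `psi.tsv`, `expr.tsv`, `mutations.tsv`, `clinical.tsv`.
#'
#' @param dir Directory containing one sub-directory per cancer type.
#' @return `read_bundles()`: a named list of `cohort_bundle`s.
#' @export
read_bundles <- function(dir) {
  types <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  if (length(types) == 0) abort(paste0("no cohort directories under ", dir))
  bundles <- lapply(types, function(ct) {
    d <- file.path(dir, ct)
    cohort_bundle(
      cancer_type = ct,
      samples = read_samples(file.path(d, "samples.tsv")),
      psi = read_psi_table(file.path(d, "psi.tsv")),
      expr = read_expr_table(file.path(d, "expr.tsv")),
      mutations = read_mutations(file.path(d, "mutations.tsv")),
      clinical = read_clinical(file.path(d, "clinical.tsv"))
    )
  })
  setNames(bundles, types)
}

#' Combine a list of cohort bundles into pan-cancer long tables
#'
#' @param bundles Named list of `cohort_bundle`s.
#' @return A list of five tibbles (`samples`, `psi`, `expr`, `mutations`,
#'   `clinical`), each carrying a `cancer_type` column.
#' @export
combine_bundles <- function(bundles) {
  grab <- function(field) {
    purrr::map(bundles, function(b) {
      mutate(b[[field]], cancer_type = b$cancer_type)
    }) |> list_rbind()
  }
  out <- lapply(c(samples = "samples", psi = "psi", expr = "expr",
                  mutations = "mutations", clinical = "clinical"), grab)
  # samples already carry cancer_type; drop the duplicate column if created
  out$samples <- out$samples[, c("sample_id", "patient_id", "cancer_type",
                                 "tissue")]
  out
}
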