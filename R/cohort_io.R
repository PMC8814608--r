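#' @import data.table
#' @importFrom stats setNames
NULL

# Required MAF columns (GDC v1.0 names). Everything else is optional and kept.
MAF_REQUIRED <- c(
  "Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome", "Start_Position",
  "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification",
  "Variant_Type"
)

# MAF Variant_Classification -> internal variant class vocabulary.
VARIANT_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Silent            = "silent",
  Splice_Site       = "splice_site",
  Frame_Shift_Ins   = "frame_shift_ins",
  Frame_Shift_Del   = "frame_shift_del",
  In_Frame_Ins      = "in_frame_ins",
  In_Frame_Del      = "in_frame_del"
)

VARIANT_CLASS_LEVELS <- c(unname(VARIANT_CLASS_MAP), "other")
VARIANT_TYPE_LEVELS <- c("SNP", "DNP", "INS", "DEL", "OTHER")

# Classes counted as nonsynonymous coding SNVs (everything coding but silent).
NONSYN_CLASSES <- setdiff(VARIANT_CLASS_LEVELS, c("silent", "other"))

#' Read a MAF-format somatic mutation table
#'
#' Reads a tab-separated MAF file (GDC column names, `#` comment lines
#' allowed), validates the required columns, normalises variant types and
#' classes to the package vocabulary, and deduplicates identical records.
#'
#' Only eight columns are required (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Chromosome`, `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Variant_Classification`, `Variant_Type`); the optional columns
#' `Protein_Change` (or `HGVSp_Short`), `Context_5prime` and `Context_3prime`
#' are picked up when present so that signature catalogs can be built without
#' a reference genome. Unknown `Variant_Classification` values are mapped to
#' `"other"` with a warning; unknown `Variant_Type` values to `"OTHER"`.
#'
#' @param path path to a tab-separated MAF file.
#' @param cohort_label label recorded in the `cohort` column of the result.
#' @return a `data.table` of mutation records with columns `sample_id`,
#'   `cohort`, `gene`, `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `variant_type`, `variant_class`, `protein_change`, `context5`,
#'   `context3`.
#' @export
read_maf <- function(path, cohort_label = "cohort1") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           na.strings = c("", "NA", "."))
  if (nrow(raw) == 0L) stop("empty MAF file (no records): ", path)
  missing_cols <- setdiff(MAF_REQUIRED, names(raw))
  if (length(missing_cols) > 0L) {
    stop("MAF format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  as_mutation_table(raw, cohort_label)
}

# Normalise a raw MAF data.table into the internal mutation-record layout.
as_mutation_table <- function(raw, cohort_label) {
  dt <- data.table::data.table(
    sample_id  = raw[["Tumor_Sample_Barcode"]],
    cohort     = cohort_label,
    gene       = raw[["Hugo_Symbol"]],
    chrom      = as.character(raw[["Chromosome"]]),
    pos        = as.integer(raw[["Start_Position"]]),
    ref_allele = toupper(raw[["Reference_Allele"]]),
    alt_allele = toupper(raw[["Tumor_Seq_Allele2"]])
  )
  vt <- toupper(raw[["Variant_Type"]])
  bad_vt <- !(vt %in% c("SNP", "DNP", "INS", "DEL"))
  if (any(bad_vt)) {
    warning(sum(bad_vt), " record(s) with nonstandard Variant_Type (",
            paste(unique(vt[bad_vt]), collapse = ", "), ") mapped to OTHER")
    vt[bad_vt] <- "OTHER"
  }
  dt[, variant_type := vt]
  vc_raw <- raw[["Variant_Classification"]]
  vc <- unname(VARIANT_CLASS_MAP[vc_raw])
  unknown <- is.na(vc)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unmapped Variant_Classification (",
            paste(unique(vc_raw[unknown]), collapse = ", "),
            ") mapped to 'other'")
    vc[unknown] <- "other"
  }
  dt[, variant_class := vc]
  pc <- if ("Protein_Change" %in% names(raw)) raw[["Protein_Change"]]
        else if ("HGVSp_Short" %in% names(raw)) raw[["HGVSp_Short"]]
        else NA_character_
  dt[, protein_change := pc]
  dt[, context5 := if ("Context_5prime" %in% names(raw))
        toupper(raw[["Context_5prime"]]) else NA_character_]
  dt[, context3 := if ("Context_3prime" %in% names(raw))
        toupper(raw[["Context_3prime"]]) else NA_character_]
  if (any(!is.na(dt$pos) & dt$pos < 1L)) stop("Start_Position must be >= 1")
  snp_same <- dt$variant_type == "SNP" & dt$ref_allele == dt$alt_allele
  if (any(snp_same)) stop("SNP records with ref == alt: ", sum(snp_same))
  # MAF uses "-" for the absent allele in indels; keep that convention.
  dt[variant_type == "INS" & (is.na(ref_allele) | ref_allele == ""), ref_allele := "-"]
  dt[variant_type == "DEL" & (is.na(alt_allele) | alt_allele == ""), alt_allele := "-"]
  n0 <- nrow(dt)
  dt <- unique(dt)
  if (nrow(dt) < n0) {
    message(n0 - nrow(dt), " duplicate identical record(s) removed")
  }
  dt[]
}

#' Write a mutation table back to MAF format
#'
#' Emits the eight required GDC columns plus `Protein_Change`,
#' `Context_5prime` and `Context_3prime`. `read_maf(write_maf(x))`
#' round-trips all record fields.
#'
#' @param mutations a mutation `data.table` as returned by [read_maf()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  out <- data.table::data.table(
    Hugo_Symbol            = mutations$gene,
    Chromosome             = mutations$chrom,
    Start_Position         = mutations$pos,
    Reference_Allele       = mutations$ref_allele,
    Tumor_Seq_Allele2      = mutations$alt_allele,
    Variant_Classification = names(VARIANT_CLASS_MAP)[match(mutations$variant_class,
                                                            VARIANT_CLASS_MAP)],
    Variant_Type           = mutations$variant_type,
    Tumor_Sample_Barcode   = mutations$sample_id,
    Protein_Change         = mutations$protein_change,
    Context_5prime         = mutations$context5,
    Context_3prime         = mutations$context3
  )
  out[is.na(Variant_Classification), Variant_Classification := "Unknown"]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

# Controlled vocabularies for the clinical table.
CLIN_LEVELS <- list(
  gender    = c("male", "female"),
  smoking   = c("yes", "no"),
  drinking  = c("yes", "no"),
  n_lymph   = c("yes", "no"),
  t_stage   = paste0("T", 1:4),
  tnm_stage = paste0("S", 1:4),
  m_stage   = c("M0", "M1"),
  grade     = paste0("G", 1:4),
  location  = c("upper", "middle", "lower")
)

normalize_clin_factor <- function(x, field) {
  x <- tolower(trimws(as.character(x)))
  lv <- CLIN_LEVELS[[field]]
  if (field %in% c("t_stage", "tnm_stage", "grade", "m_stage")) {
    # accept "T2", "t2", "2", "S III", roman numerals
    prefix <- substr(lv[1], 1, 1)
    x <- gsub("[[:space:]]", "", x)
    x <- sub(paste0("^", tolower(prefix)), "", x)
    roman <- c(i = "1", ii = "2", iii = "3", iv = "4")
    x <- ifelse(x %in% names(roman), roman[x], x)
    x <- paste0(prefix, x)
    x <- ifelse(toupper(x) %in% lv, toupper(x), "unknown")
    return(x)
  }
  if (field %in% c("smoking", "drinking", "n_lymph")) {
    x[x %in% c("yes", "y", "1", "true", "positive", "pos")] <- "yes"
    x[x %in% c("no", "n", "0", "false", "negative", "neg")] <- "no"
  }
  ifelse(x %in% lv, x, "unknown")
}

#' Read and vocabulary-normalise a clinical table
#'
#' Reads a tab-separated clinical table keyed by `sample_id` and normalises
#' every recognised column to the package vocabulary (`gender`, `smoking`,
#' `drinking`, `n_lymph` as yes/no, `t_stage` T1--T4, `tnm_stage` S1--S4,
#' `m_stage` M0/M1, `grade` G1--G4, `location` upper/middle/lower, numeric
#' `age`, `os_time` in days, `os_event` 0/1). Unparseable cells become
#' `"unknown"` (or `NA` for numerics); unrecognised columns are kept as-is.
#'
#' @param path path to a tab-separated clinical table with a `sample_id`
#'   column.
#' @return a `data.table`, one row per sample.
#' @export
read_clinical <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!"sample_id" %in% names(raw)) {
    stop("clinical format error: missing required column: sample_id")
  }
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id in clinical table: ",
         paste(unique(dup), collapse = ", "))
  }
  dt <- data.table::copy(raw)
  for (f in intersect(names(CLIN_LEVELS), names(dt))) {
    data.table::set(dt, j = f, value = normalize_clin_factor(dt[[f]], f))
  }
  for (f in intersect(c("age", "os_time", "os_event"), names(dt))) {
    data.table::set(dt, j = f, value = suppressWarnings(as.numeric(dt[[f]])))
  }
  if ("os_time" %in% names(dt) && any(!is.na(dt$os_time) & dt$os_time < 0)) {
    stop("os_time must be >= 0")
  }
  if ("os_event" %in% names(dt) &&
      !all(is.na(dt$os_event) | dt$os_event %in% c(0, 1))) {
    stop("os_event must be 0/1")
  }
  dt[]
}

#' Merge per-cohort mutation and clinical tables into one cohort
#'
#' Concatenates mutation tables (each labelled with a distinct cohort) and
#' clinical tables into a single analysis-ready cohort object. The same
#' `sample_id` appearing in more than one cohort is an error rather than a
#' silent merge.
#'
#' @param mutation_tables list of mutation `data.table`s from [read_maf()].
#' @param clinical_tables list of clinical `data.table`s from
#'   [read_clinical()], parallel to `mutation_tables` (or a single table
#'   covering all cohorts).
#' @return an object of class `mutscape_cohort`: a list with elements
#'   `mutations` and `clinical`.
#' @export
merge_cohorts <- function(mutation_tables, clinical_tables) {
  if (data.table::is.data.table(mutation_tables)) {
    mutation_tables <- list(mutation_tables)
  }
  if (data.table::is.data.table(clinical_tables)) {
    clinical_tables <- list(clinical_tables)
  }
  stopifnot(length(mutation_tables) >= 1L)
  labels <- vapply(mutation_tables, function(m) m$cohort[1], character(1))
  if (anyDuplicated(labels)) stop("cohort labels must be distinct")
  per_cohort_samples <- lapply(mutation_tables, function(m) unique(m$sample_id))
  all_samples <- unlist(per_cohort_samples)
  if (anyDuplicated(all_samples)) {
    stop("sample_id collision across cohorts: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  }
  clin <- data.table::rbindlist(clinical_tables, fill = TRUE)
  dupc <- clin$sample_id[duplicated(clin$sample_id)]
  if (length(dupc) > 0L) {
    stop("sample_id collision across clinical tables: ",
         paste(unique(dupc), collapse = ", "))
  }
  mut <- data.table::rbindlist(mutation_tables, fill = TRUE)
  orphans <- setdiff(unique(mut$sample_id), clin$sample_id)
  if (length(orphans) > 0L) {
    warning(length(orphans),
            " mutated sample(s) missing from the clinical table")
  }
  structure(list(mutations = mut, clinical = clin),
            class = "mutscape_cohort")
}

#' @export
print.mutscape_cohort <- function(x, ...) {
  cat("mutscape cohort:",
      length(unique(x$mutations$sample_id)), "mutated samples,",
      nrow(x$clinical), "clinical records,",
      nrow(x$mutations), "mutation records,",
      length(unique(x$mutations$cohort)), "cohort(s)\n")
  invisible(x)
}
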