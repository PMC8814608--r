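# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files these helpers write.

maf_header <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                "Reference_Allele", "Tumor_Seq_Allele2",
                "Variant_Classification", "Variant_Type",
                "Tumor_Sample_Barcode", "Context_5prime", "Context_3prime")

# write a MAF file from a list of row vectors (in maf_header order)
write_maf_fixture <- function(rows, path = tempfile(fileext = ".maf"),
                              header = maf_header) {
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

maf_row <- function(gene = "TP53", chrom = "17", pos = 7577120,
                    ref = "C", alt = "A", class = "Missense_Mutation",
                    type = "SNP", sample = "S1", ctx5 = "A", ctx3 = "A") {
  c(gene, chrom, pos, ref, alt, class, type, sample, ctx5, ctx3)
}

write_clinical_fixture <- function(dt, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  path
}

# a minimal cohort built directly from record vectors
make_cohort <- function(sample_id, gene, variant_type = "SNP",
                        variant_class = "missense", clinical = NULL) {
  n <- max(length(sample_id), length(gene))
  mut <- data.table::data.table(
    sample_id = rep_len(sample_id, n), cohort = "test",
    gene = rep_len(gene, n), chrom = "1", pos = seq_len(n),
    ref_allele = "C", alt_allele = "A",
    variant_type = rep_len(variant_type, n),
    variant_class = rep_len(variant_class, n),
    protein_change = NA_character_,
    context5 = "A", context3 = "A")
  if (is.null(clinical)) {
    clinical <- data.table::data.table(sample_id = unique(mut$sample_id))
  }
  structure(list(mutations = mut, clinical = clinical),
            class = "mutscape_cohort")
}

# peptide record builder
peptide_rows <- function(n, sample_id = "S1", gene = "G1",
                         bind_level = "SB", wild_score = 500,
                         mutant_score = 50, percent_rank = NA_real_) {
  data.table::data.table(
    sample_id = rep_len(sample_id, n), gene = rep_len(gene, n),
    mutant_peptide = replicate(n, paste(
      sample(strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]], 9, TRUE),
      collapse = "")),
    wild_peptide = ifelse(is.na(rep_len(wild_score, n)), NA_character_,
                          "WILDPEPT"),
    wild_score = rep_len(wild_score, n),
    mutant_score = rep_len(mutant_score, n),
    percent_rank = rep_len(percent_rank, n),
    bind_level = rep_len(bind_level, n))
}

# two-sided Fisher p by direct hypergeometric enumeration (independent of
# stats::fisher.test): P(tables at least as extreme as observed)
fisher_p_enum <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0L, k - nn); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
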