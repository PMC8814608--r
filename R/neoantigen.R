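# Neoantigen burden and binding-ratio scoring from epitope prediction
# tables (pVACtools-style export). Candidates are the strong/weak binders;
# each candidate peptide scores log2(wild-type/mutant binding ratio), with
# unpaired (frameshift-derived) peptides assigned the fixed ratio 15.

#' Read a peptide binding table
#'
#' Tab-separated with columns `sample_id`, `gene`, `mutant_peptide` and any
#' of `wild_peptide`, `mutant_score`, `wild_score`, `percent_rank`,
#' `bind_level`. Empty strings become `NA`.
#'
#' @param path TSV path.
#' @return data.table of peptide records.
#' @export
read_binding_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"))
  need <- c("sample_id", "gene", "mutant_peptide")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L) {
    stop("binding table missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  dt[]
}

#' Filter peptides down to candidate neoantigens
#'
#' Keeps strong (SB) and weak (WB) binders. When `bind_level` is missing
#' for a record it is derived from `percent_rank` using the NetMHC
#' convention: SB at rank <= `sb_rank`, WB at rank <= `wb_rank`, NB
#' otherwise.
#'
#' @param peptides data.table of peptide records.
#' @param sb_rank,wb_rank percent-rank thresholds for strong/weak binders
#'   (defaults 0.5 and 2.0).
#' @return the candidate subset, with a filled `bind_level` column.
#' @export
filter_candidates <- function(peptides, sb_rank = 0.5, wb_rank = 2.0) {
  dt <- data.table::copy(data.table::as.data.table(peptides))
  if (!"bind_level" %in% names(dt)) dt[, bind_level := NA_character_]
  derivable <- "percent_rank" %in% names(dt)
  need_derive <- is.na(dt$bind_level)
  if (any(need_derive)) {
    if (!derivable) {
      stop("records without bind_level or percent_rank at row(s): ",
           paste(utils::head(which(need_derive), 5), collapse = ", "))
    }
    pr <- dt$percent_rank
    bad <- need_derive & is.na(pr)
    if (any(bad)) {
      stop("records without bind_level or percent_rank at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
    lvl <- ifelse(pr <= sb_rank, "SB", ifelse(pr <= wb_rank, "WB", "NB"))
    dt[need_derive, bind_level := lvl[need_derive]]
  }
  dt[bind_level %in% c("SB", "WB")]
}

#' Peptide binding-ratio score
#'
#' `log2(W / M)` for peptides with a matched wild-type binding score `W`
#' and mutant score `M` (IC50-like, lower = stronger binding); for
#' unpaired peptides (no wild-type counterpart, e.g. frameshift products)
#' the wild-to-mutant ratio is fixed at `unpaired_ratio`, giving
#' `log2(unpaired_ratio)` by default. `unpaired_mode = "literal"` instead
#' returns `unpaired_ratio` itself as the score.
#'
#' @param W wild-type binding score(s), `NA` when unpaired; must be > 0
#'   otherwise.
#' @param M mutant binding score(s), > 0.
#' @param unpaired_ratio assumed W/M ratio for unpaired peptides
#'   (default 15).
#' @param unpaired_mode `"log2_ratio"` (default) or `"literal"`.
#' @return numeric score(s).
#' @export
aascore <- function(W, M, unpaired_ratio = 15,
                    unpaired_mode = c("log2_ratio", "literal")) {
  unpaired_mode <- match.arg(unpaired_mode)
  if (any(is.na(M)) || any(M <= 0)) stop("mutant score M must be > 0")
  if (any(!is.na(W) & W <= 0)) stop("wild score W must be > 0 when present")
  unpaired_value <- if (unpaired_mode == "literal") unpaired_ratio
                    else log2(unpaired_ratio)
  ifelse(is.na(W), unpaired_value, log2(W / M))
}

#' Per-gene neoantigen score
#'
#' Sum of [aascore()] over one gene's candidate peptides in one sample;
#' zero when the gene has no candidates.
#'
#' @param candidates candidate peptide records of a single gene/sample
#'   (with `wild_score`, `mutant_score` columns).
#' @param ... passed to [aascore()].
#' @return a single numeric score.
#' @export
gscore <- function(candidates, ...) {
  if (nrow(candidates) == 0L) return(0)
  sum(aascore(candidates$wild_score, candidates$mutant_score, ...))
}

#' Per-sample neoantigen burden and score
#'
#' Filters to candidate neoantigens, then computes for every sample the
#' tumor neoantigen burden (TNB, the candidate count) and tumor
#' neoantigen score (TNS, the sum over genes of the per-gene score, which
#' equals the sum of [aascore()] over all candidate peptides).
#'
#' @param peptides data.table of peptide records (all samples).
#' @param sb_rank,wb_rank binder thresholds, see [filter_candidates()].
#' @param unpaired_ratio,unpaired_mode see [aascore()].
#' @return list with `scores` (data.table `sample_id`, `TNB`, `TNS`) and
#'   `gene_scores` (data.table `sample_id`, `gene`, `Gscore`). Samples
#'   with no candidates get TNB = TNS = 0.
#' @export
sample_scores <- function(peptides, sb_rank = 0.5, wb_rank = 2.0,
                          unpaired_ratio = 15,
                          unpaired_mode = c("log2_ratio", "literal")) {
  unpaired_mode <- match.arg(unpaired_mode)
  peptides <- data.table::as.data.table(peptides)
  cand <- filter_candidates(peptides, sb_rank = sb_rank, wb_rank = wb_rank)
  all_samples <- unique(peptides$sample_id)
  if (nrow(cand) == 0L) {
    return(list(
      scores = data.table::data.table(sample_id = all_samples, TNB = 0L, TNS = 0),
      gene_scores = data.table::data.table(sample_id = character(0),
                                           gene = character(0),
                                           Gscore = numeric(0))))
  }
  cand[, aa := aascore(wild_score, mutant_score,
                       unpaired_ratio = unpaired_ratio,
                       unpaired_mode = unpaired_mode)]
  gene_scores <- cand[, .(Gscore = sum(aa)), by = .(sample_id, gene)]
  scores <- cand[, .(TNB = .N, TNS = sum(aa)), by = sample_id]
  missing <- setdiff(all_samples, scores$sample_id)
  if (length(missing) > 0L) {
    scores <- rbind(scores,
                    data.table::data.table(sample_id = missing, TNB = 0L, TNS = 0))
  }
  data.table::setorder(scores, sample_id)
  list(scores = scores[], gene_scores = gene_scores[])
}

#' Cross-patient neoantigen sharing spectrum
#'
#' Groups distinct candidate mutant peptides by the number of patients
#' carrying them and reports, for each multiplicity, how many distinct
#' peptides are shared by exactly that many patients and the fraction of
#' all distinct peptides.
#'
#' @param candidates candidate peptide records (already filtered).
#' @param by_allele if `TRUE`, peptide identity is the
#'   (peptide, HLA allele) pair; default counts peptide strings only.
#' @return data.table: `n_patients`, `n_peptides`, `fraction` (sums to 1);
#'   empty for empty input.
#' @export
sharing_spectrum <- function(candidates, by_allele = FALSE) {
  candidates <- data.table::as.data.table(candidates)
  if (nrow(candidates) == 0L) {
    return(data.table::data.table(n_patients = integer(0),
                                  n_peptides = integer(0),
                                  fraction = numeric(0)))
  }
  key <- if (by_allele && "hla_allele" %in% names(candidates)) {
    paste(candidates$mutant_peptide, candidates$hla_allele, sep = "|")
  } else {
    candidates$mutant_peptide
  }
  per_pep <- data.table::data.table(pep = key, sample_id = candidates$sample_id)
  mult <- per_pep[, .(n_patients = data.table::uniqueN(sample_id)), by = "pep"]
  spec <- mult[, .(n_peptides = .N), by = n_patients]
  data.table::setorder(spec, n_patients)
  spec[, fraction := n_peptides / sum(n_peptides)]
  spec[]
}
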