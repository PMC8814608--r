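# Tumor mutational burden over a fixed 30-Mb coding footprint.
# Two statistics per sample: aTMB counts every coding SNV (synonymous
# included) plus indels; fTMB keeps only nonsynonymous SNVs plus indels.

TMB_DENOMINATOR_MB <- 30

#' Compute per-sample tumor mutational burden
#'
#' For each sample, counts coding single-nucleotide variants (total and
#' nonsynonymous), and insertions/deletions, then converts to mutations
#' per megabase over a fixed 30-Mb coding denominator:
#' `aTMB = (n_snv_total + n_indel) / 30` and
#' `fTMB = (n_snv_nonsynonymous + n_indel) / 30`.
#' Nonsynonymous covers every coding class except `silent` (splice-site
#' SNVs count as nonsynonymous); records with class `other` are excluded
#' from both SNV counts; indels count regardless of frame. Samples present
#' in the clinical table but without mutations get burden 0.
#'
#' @param cohort a `mutscape_cohort` or mutation `data.table`.
#' @param include_synonymous_in_ftmb if `TRUE`, applies the literal
#'   alternative reading in which fTMB instead removes the nonsynonymous
#'   SNVs (keeping synonymous ones). Default `FALSE`.
#' @return data.table: `sample_id`, `n_snv_total`, `n_snv_nonsynonymous`,
#'   `n_indel`, `aTMB`, `fTMB`.
#' @export
compute_burden <- function(cohort, include_synonymous_in_ftmb = FALSE) {
  if (inherits(cohort, "mutscape_cohort")) {
    mut <- cohort$mutations
    samples <- union(cohort$clinical$sample_id, unique(mut$sample_id))
  } else {
    mut <- cohort
    samples <- unique(mut$sample_id)
  }
  snv <- mut[mut$variant_type == "SNP" & mut$variant_class != "other", ]
  indel <- mut[mut$variant_type %in% c("INS", "DEL"), ]
  cnt <- function(dt) {
    as.integer(table(factor(dt$sample_id, levels = samples)))
  }
  out <- data.table::data.table(
    sample_id = samples,
    n_snv_total = cnt(snv),
    n_snv_nonsynonymous = cnt(snv[snv$variant_class %in% NONSYN_CLASSES, ]),
    n_indel = cnt(indel))
  out[, aTMB := (n_snv_total + n_indel) / TMB_DENOMINATOR_MB]
  f_snv <- if (include_synonymous_in_ftmb) {
    out$n_snv_total - out$n_snv_nonsynonymous
  } else {
    out$n_snv_nonsynonymous
  }
  out[, fTMB := (f_snv + n_indel) / TMB_DENOMINATOR_MB]
  out[]
}

#' Concordance between the two burden statistics
#'
#' Pearson and Spearman correlation between aTMB and fTMB across samples,
#' plus a paired two-sided t-test on the per-sample differences.
#'
#' @param burdens output of [compute_burden()].
#' @return list with `pearson`, `spearman`, `mean_difference`,
#'   `t_statistic`, `p` (paired t-test; `NA` when the differences are
#'   constant), `n`.
#' @export
burden_concordance <- function(burdens) {
  if (nrow(burdens) < 3L) stop("need at least 3 samples for concordance")
  a <- burdens$aTMB; f <- burdens$fTMB
  d <- a - f
  tt <- if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    stats::t.test(a, f, paired = TRUE)
  }
  pear <- if (stats::sd(a) == 0 || stats::sd(f) == 0) NA_real_
          else stats::cor(a, f, method = "pearson")
  spear <- if (stats::sd(a) == 0 || stats::sd(f) == 0) NA_real_
           else stats::cor(a, f, method = "spearman")
  list(pearson = pear, spearman = spear,
       mean_difference = mean(d),
       t_statistic = unname(tt$statistic), p = tt$p.value,
       n = nrow(burdens))
}
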