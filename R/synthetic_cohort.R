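# Synthetic cohort generator. Produces MAF-format mutations with flanking
# context drawn from known signature mixtures, clinically structured
# covariates, survival times with a planted hazard threshold, and peptide
# binding tables with paired (missense) and unpaired (frameshift)
# records -- everything downstream modules consume, with the latent truth
# recorded for recovery testing. All outputs are deterministic given the
# config seed.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]

# Two synthetic SBS-96 signatures with disjoint channel support: one flat
# over the C>T channels (deamination-flavoured), one flat over the C>A
# channels (oxidative-damage-flavoured). Flat blocks carry no internal
# substructure, so the pair is exactly rank-2. Labelled synthetic: these
# are constructions, not COSMIC signatures.
default_signatures <- function() {
  ch <- sbs96_channels()
  s1 <- rep(0, 96); names(s1) <- ch
  s1[grepl("\\[C>T\\]", ch)] <- 1
  s2 <- rep(0, 96); names(s2) <- ch
  s2[grepl("\\[C>A\\]", ch)] <- 1
  cbind(synthSig1 = s1 / sum(s1), synthSig2 = s2 / sum(s2))
}

#' Build a simulation configuration
#'
#' Defaults emulate the scale of a pooled squamous-carcinoma WES cohort:
#' negative-binomial mutation counts with median total burden around
#' 3.6/Mb over a 30-Mb footprint, a 24% synonymous fraction among SNVs,
#' male-dominant demographics, lymph-node metastasis odds raised by
#' smoking, exponential survival with a planted hazard step on total
#' burden, and a Poisson neoantigen yield per nonsynonymous mutation so
#' neoantigen burden tracks nonsilent burden.
#'
#' @param n_samples cohort size (default 120).
#' @param seed integer seed; every draw derives from it.
#' @param signatures channels x k column-stochastic SBS-96 matrix
#'   (default: two disjoint-support synthetic signatures).
#' @param mixture_alpha Dirichlet concentration for per-sample signature
#'   weights (default 0.5 per signature: sparse mixtures in which most
#'   samples are dominated by one process, as in real exposure profiles).
#' @param mutation_mean,mutation_size negative-binomial mean/size of the
#'   per-sample total mutation count (defaults 129 and 2.5).
#' @param silent_fraction fraction of SNVs that are synonymous (0.24).
#' @param indel_fraction,dbs_fraction fractions of total mutations that
#'   are indels (0.08) / doublet substitutions (0.02).
#' @param frameshift_fraction fraction of indels that shift frame (0.7).
#' @param n_genes background gene pool size (default 400).
#' @param hmg_genes,lmg_genes named numeric-list configs of planted
#'   lymph-associated genes: each entry `c(rate_met, rate_nonmet)`.
#' @param smoking_lymph_or odds ratio of lymph metastasis for smokers
#'   (default 2).
#' @param survival list: `baseline_median` days, `hr` hazard ratio above
#'   the planted burden threshold, `threshold_quantile` of aTMB where the
#'   hazard steps, `censor_horizon` days.
#' @param neoantigen list: `peptides_per_nonsyn` Poisson mean, `rank_meanlog`,
#'   `rank_sdlog` of the lognormal percent-rank, `mutant_score_meanlog`,
#'   `mutant_score_sdlog`, `log2_ratio_mean`, `log2_ratio_sd` of the
#'   wild/mutant score ratio, `shared_peptides` list of
#'   `list(peptide =, n_patients =)` plants.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 120L, seed = 1L,
                       signatures = default_signatures(),
                       mixture_alpha = NULL,
                       mutation_mean = 129, mutation_size = 2.5,
                       silent_fraction = 0.24,
                       indel_fraction = 0.08, dbs_fraction = 0.02,
                       frameshift_fraction = 0.7,
                       n_genes = 400L,
                       hmg_genes = list(HMG01 = c(0.35, 0.10),
                                        HMG02 = c(0.35, 0.10),
                                        HMG03 = c(0.30, 0.08)),
                       lmg_genes = list(LMG01 = c(0.05, 0.25),
                                        LMG02 = c(0.08, 0.30)),
                       smoking_lymph_or = 2.0,
                       survival = list(baseline_median = 730, hr = 2.5,
                                       threshold_quantile = 0.6,
                                       censor_horizon = 2000),
                       neoantigen = list(peptides_per_nonsyn = 0.2,
                                         rank_meanlog = 0, rank_sdlog = 1.2,
                                         mutant_score_meanlog = log(200),
                                         mutant_score_sdlog = 1,
                                         log2_ratio_mean = 1.5,
                                         log2_ratio_sd = 1.5,
                                         shared_peptides = list(
                                           list(peptide = "SYNTHSHRDPEP1",
                                                n_patients = 3)))) {
  signatures <- as.matrix(signatures)
  if (any(signatures < 0)) stop("signature probabilities must be >= 0")
  if (any(abs(colSums(signatures) - 1) > 1e-8)) {
    stop("signature columns must sum to 1")
  }
  if (is.null(mixture_alpha)) mixture_alpha <- rep(0.5, ncol(signatures))
  if (length(mixture_alpha) != ncol(signatures)) {
    stop("mixture_alpha length must equal the number of signatures")
  }
  fr <- c(silent_fraction, indel_fraction, dbs_fraction, frameshift_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (indel_fraction + dbs_fraction >= 1) {
    stop("indel_fraction + dbs_fraction must leave room for SNVs")
  }
  structure(list(
    n_samples = as.integer(n_samples), seed = as.integer(seed),
    signatures = signatures, mixture_alpha = mixture_alpha,
    mutation_mean = mutation_mean, mutation_size = mutation_size,
    silent_fraction = silent_fraction, indel_fraction = indel_fraction,
    dbs_fraction = dbs_fraction, frameshift_fraction = frameshift_fraction,
    n_genes = as.integer(n_genes), hmg_genes = hmg_genes,
    lmg_genes = lmg_genes, smoking_lymph_or = smoking_lymph_or,
    survival = survival, neoantigen = neoantigen), class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# decode SBS-96 channels into ref/alt plus single-base flanks,
# emitting either strand with equal probability (vectorised)
decode_sbs96 <- function(channel) {
  f5 <- substr(channel, 1, 1); ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5); f3 <- substr(channel, 7, 7)
  flip <- stats::runif(length(channel)) < 0.5
  data.table::data.table(
    ref = ifelse(flip, unname(COMPLEMENT[ref]), ref),
    alt = ifelse(flip, unname(COMPLEMENT[alt]), alt),
    context5 = ifelse(flip, unname(COMPLEMENT[f3]), f5),
    context3 = ifelse(flip, unname(COMPLEMENT[f5]), f3))
}

rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# random bases whose head/tail avoids extending a run of `avoid`
rand_flank <- function(n, avoid) {
  first <- sample(setdiff(BASES, avoid), 1)
  paste0(first, rand_bases(n - 1L))
}

# construct an indel with a controlled homopolymer/repeat context and
# return its record fields; channel truth is recovered by the classifier
simulate_indel <- function(frameshift_fraction) {
  is_del <- stats::runif(1) < 0.5
  len <- if (stats::runif(1) < 0.8) 1L else sample(2:4, 1)
  if (len %% 3L == 0L) is_frameshift <- FALSE
  else is_frameshift <- stats::runif(1) < frameshift_fraction
  if (!is_frameshift && len %% 3L != 0L) len <- 3L
  seq <- rand_bases(len)
  extra <- sample(0:4, 1, prob = c(0.35, 0.3, 0.15, 0.12, 0.08))
  ctx3 <- paste0(strrep(seq, extra), rand_flank(10L, substr(seq, 1, 1)))
  ctx5 <- rev_flank <- paste0(rand_bases(9L),
                              sample(setdiff(BASES, substr(seq, len, len)), 1))
  cls <- if (is_del) {
    if (len %% 3L == 0L) "in_frame_del" else "frame_shift_del"
  } else {
    if (len %% 3L == 0L) "in_frame_ins" else "frame_shift_ins"
  }
  list(ref = if (is_del) seq else "-", alt = if (is_del) "-" else seq,
       type = if (is_del) "DEL" else "INS", class = cls,
       context5 = ctx5, context3 = ctx3)
}

#' Simulate a synthetic mutation cohort with known truth
#'
#' Draws per-sample mutation counts (negative binomial), assigns each SNV
#' a latent signature from the sample's mixture weights and a channel
#' from that signature, decodes channels into alleles plus flanking
#' context, adds indels/doublets and planted lymph-associated gene
#' mutations, simulates clinical covariates and exponential survival with
#' a hazard step above a planted total-burden threshold, and returns the
#' cohort together with the full latent truth.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `cohort.maf`,
#'   `clinical.tsv` and `truth.json`.
#' @return list: `cohort` (a `mutscape_cohort`), `truth` (list with
#'   per-sample mixture weights, per-mutation latent signatures and
#'   channels, planted gene rates, the survival threshold and hazard
#'   ratio, and the seed).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sids <- sprintf("SYN%04d", seq_len(n))
  k <- ncol(config$signatures)
  channels <- rownames(config$signatures)
  if (is.null(channels)) channels <- sbs96_channels()
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))

  ## clinical covariates -----------------------------------------------
  age <- round(stats::rnorm(n, 60, 9))
  gender <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.8, 0.2))
  smoking <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.6, 0.4))
  drinking <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.55, 0.45))
  base_logodds <- stats::qlogis(0.45)
  p_lymph <- stats::plogis(base_logodds +
                             log(config$smoking_lymph_or) * (smoking == "yes"))
  n_lymph <- ifelse(stats::runif(n) < p_lymph, "yes", "no")
  t_stage <- sample(paste0("T", 1:4), n, replace = TRUE,
                    prob = c(0.1, 0.3, 0.45, 0.15))
  tnm_stage <- sample(paste0("S", 1:4), n, replace = TRUE,
                      prob = c(0.15, 0.35, 0.4, 0.1))
  m_stage <- sample(c("M0", "M1"), n, replace = TRUE, prob = c(0.995, 0.005))
  grade <- sample(paste0("G", 1:4), n, replace = TRUE,
                  prob = c(0.15, 0.45, 0.3, 0.1))
  location <- sample(c("upper", "middle", "lower"), n, replace = TRUE,
                     prob = c(0.15, 0.55, 0.3))

  ## mutations ----------------------------------------------------------
  weights <- t(vapply(seq_len(n), function(i) rdirichlet1(config$mixture_alpha),
                      numeric(k)))
  colnames(weights) <- colnames(config$signatures)
  rownames(weights) <- sids
  totals <- stats::rnbinom(n, size = config$mutation_size,
                           mu = config$mutation_mean)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- totals[i]
    if (m == 0L) next
    u <- stats::runif(m)
    kind <- ifelse(u < config$indel_fraction, "indel",
            ifelse(u < config$indel_fraction + config$dbs_fraction,
                   "dbs", "snv"))
    dt <- data.table::data.table(
      gene = sample(genes, m, replace = TRUE),
      ref_allele = NA_character_, alt_allele = NA_character_,
      variant_type = NA_character_, variant_class = NA_character_,
      context5 = NA_character_, context3 = NA_character_,
      true_channel = NA_character_, true_signature = NA_character_)
    m_snv <- sum(kind == "snv")
    if (m_snv > 0L) {
      s <- sample.int(k, m_snv, replace = TRUE, prob = weights[i, ])
      ch <- character(m_snv)
      for (sg in unique(s)) {
        ch[s == sg] <- sample(channels, sum(s == sg), replace = TRUE,
                              prob = config$signatures[, sg])
      }
      dec <- decode_sbs96(ch)
      cls <- ifelse(stats::runif(m_snv) < config$silent_fraction, "silent",
                    sample(c("missense", "nonsense", "splice_site"), m_snv,
                           replace = TRUE, prob = c(0.85, 0.08, 0.07)))
      w <- which(kind == "snv")
      data.table::set(dt, w, c("ref_allele", "alt_allele", "context5",
                               "context3", "variant_type", "variant_class",
                               "true_channel", "true_signature"),
                      list(dec$ref, dec$alt, dec$context5, dec$context3,
                           "SNP", cls, ch, colnames(weights)[s]))
    }
    m_dbs <- sum(kind == "dbs")
    if (m_dbs > 0L) {
      ch <- sample(DBS78_TABLE, m_dbs, replace = TRUE)
      ref <- substr(ch, 1, 2); alt <- substr(ch, 4, 5)
      flip <- stats::runif(m_dbs) < 0.5
      ref[flip] <- revcomp(ref[flip]); alt[flip] <- revcomp(alt[flip])
      w <- which(kind == "dbs")
      data.table::set(dt, w, c("ref_allele", "alt_allele", "context5",
                               "context3", "variant_type", "variant_class",
                               "true_channel"),
                      list(ref, alt, sample(BASES, m_dbs, replace = TRUE),
                           sample(BASES, m_dbs, replace = TRUE),
                           "DNP", "missense", ch))
    }
    for (w in which(kind == "indel")) {
      ind <- simulate_indel(config$frameshift_fraction)
      data.table::set(dt, w, c("ref_allele", "alt_allele", "variant_type",
                               "variant_class", "context5", "context3"),
                      list(ind$ref, ind$alt, ind$type, ind$class,
                           ind$context5, ind$context3))
    }
    dt[, sample_id := sids[i]]
    rows[[i]] <- dt
  }
  mut <- data.table::rbindlist(rows)

  ## planted lymph-associated genes -------------------------------------
  planted <- c(config$hmg_genes, config$lmg_genes)
  planted_rows <- list()
  for (g in names(planted)) {
    rate <- planted[[g]]
    p <- ifelse(n_lymph == "yes", rate[1], rate[2])
    hit <- stats::runif(n) < p
    if (!any(hit)) next
    m <- sum(hit)
    dec <- decode_sbs96(sample(channels, m, replace = TRUE,
                               prob = rowMeans(config$signatures)))
    planted_rows[[g]] <- data.table::data.table(
      gene = g,
      ref_allele = dec$ref, alt_allele = dec$alt,
      variant_type = "SNP", variant_class = "missense",
      context5 = dec$context5, context3 = dec$context3,
      true_channel = NA_character_, true_signature = NA_character_,
      sample_id = sids[hit])
  }
  if (length(planted_rows) > 0L) {
    mut <- rbind(mut, data.table::rbindlist(planted_rows))
  }
  nm <- nrow(mut)
  mut[, chrom := as.character(sample(1:22, nm, replace = TRUE))]
  mut[, pos := sample.int(5e7, nm, replace = TRUE)]
  mut[, cohort := "synthetic"]
  mut[, protein_change := ifelse(
    variant_class == "missense",
    paste0("p.", sample(AA_LETTERS, nm, replace = TRUE),
           sample.int(800, nm, replace = TRUE),
           sample(AA_LETTERS, nm, replace = TRUE)),
    NA_character_)]
  truth_channels <- mut[, c("sample_id", "true_channel", "true_signature"),
                        with = FALSE]
  mut[, true_channel := NULL]; mut[, true_signature := NULL]
  data.table::setcolorder(mut, c("sample_id", "cohort", "gene", "chrom",
                                 "pos", "ref_allele", "alt_allele",
                                 "variant_type", "variant_class",
                                 "protein_change", "context5", "context3"))

  ## survival: hazard step above a planted aTMB threshold ---------------
  burden_now <- compute_burden(mut)
  atmb <- stats::setNames(burden_now$aTMB, burden_now$sample_id)[sids]
  atmb[is.na(atmb)] <- 0
  sv <- config$survival
  theta <- stats::quantile(atmb, sv$threshold_quantile, names = FALSE)
  lambda0 <- log(2) / sv$baseline_median
  lambda <- lambda0 * ifelse(atmb > theta, sv$hr, 1)
  t_true <- stats::rexp(n, rate = lambda)
  os_time <- pmax(1, round(pmin(t_true, sv$censor_horizon)))
  os_event <- as.integer(t_true <= sv$censor_horizon)

  clinical <- data.table::data.table(
    sample_id = sids, age = age, gender = gender, smoking = smoking,
    drinking = drinking, t_stage = t_stage, n_lymph = n_lymph,
    tnm_stage = tnm_stage, m_stage = m_stage, grade = grade,
    location = location, os_time = as.numeric(os_time), os_event = os_event)

  cohort <- structure(list(mutations = mut, clinical = clinical),
                      class = "mutscape_cohort")
  truth <- list(
    seed = config$seed,
    mixture_weights = weights,
    signatures = config$signatures,
    mutation_truth = truth_channels,
    hmg_genes = names(config$hmg_genes),
    lmg_genes = names(config$lmg_genes),
    planted_gene_rates = planted,
    survival_threshold = theta,
    survival_hr = sv$hr,
    totals = stats::setNames(totals, sids))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_maf(mut, file.path(out_dir, "cohort.maf"))
    data.table::fwrite(clinical, file.path(out_dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(seed = truth$seed, hmg_genes = truth$hmg_genes,
           lmg_genes = truth$lmg_genes,
           survival_threshold = truth$survival_threshold,
           survival_hr = truth$survival_hr),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, truth = truth)
}

rand_peptides <- function(n, len = 9L) {
  vapply(seq_len(n), function(i)
    paste(sample(AA_LETTERS, len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate a peptide binding table for a cohort
#'
#' Per nonsynonymous SNV, draws a Poisson number of candidate peptide
#' records with lognormal percent ranks (binned into SB/WB/NB) and paired
#' wild-type/mutant binding scores; frameshift indels yield unpaired
#' peptides (no wild-type score). Configured shared peptides are planted
#' into the stated number of patients as strong binders.
#'
#' @param config a [sim_config()].
#' @param cohort a `mutscape_cohort` from [simulate_cohort()].
#' @param seed optional seed override (defaults to `config$seed + 1`).
#' @return list: `peptides` (data.table with `sample_id`, `gene`,
#'   `mutant_peptide`, `wild_peptide`, `mutant_score`, `wild_score`,
#'   `percent_rank`, `bind_level`, `hla_allele`), `truth` (planted shared
#'   peptides).
#' @export
simulate_binding_table <- function(config, cohort, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  np <- config$neoantigen
  mut <- cohort$mutations
  nonsyn_snv <- mut[mut$variant_type == "SNP" &
                      mut$variant_class %in% NONSYN_CLASSES, ]
  fs_indel <- mut[mut$variant_class %in% c("frame_shift_ins",
                                           "frame_shift_del"), ]
  src <- rbind(
    data.table::data.table(sample_id = nonsyn_snv$sample_id,
                           gene = nonsyn_snv$gene, paired = TRUE),
    data.table::data.table(sample_id = fs_indel$sample_id,
                           gene = fs_indel$gene, paired = FALSE))
  if (nrow(src) == 0L) {
    warning("cohort has no nonsynonymous mutations: empty binding table")
    return(list(peptides = data.table::data.table(), truth = list()))
  }
  n_pep <- stats::rpois(nrow(src), np$peptides_per_nonsyn)
  idx <- rep(seq_len(nrow(src)), n_pep)
  total <- length(idx)
  hla_pool <- c("HLA-A*02:01", "HLA-A*11:01", "HLA-B*15:01", "HLA-C*07:02")
  peptides <- if (total > 0L) {
    rank <- stats::rlnorm(total, np$rank_meanlog, np$rank_sdlog)
    M <- stats::rlnorm(total, np$mutant_score_meanlog, np$mutant_score_sdlog)
    ratio <- 2^stats::rnorm(total, np$log2_ratio_mean, np$log2_ratio_sd)
    paired <- src$paired[idx]
    data.table::data.table(
      sample_id = src$sample_id[idx],
      gene = src$gene[idx],
      mutant_peptide = rand_peptides(total),
      wild_peptide = ifelse(paired, rand_peptides(total), NA_character_),
      mutant_score = M,
      wild_score = ifelse(paired, M * ratio, NA_real_),
      percent_rank = rank,
      bind_level = ifelse(rank <= 0.5, "SB",
                          ifelse(rank <= 2, "WB", "NB")),
      hla_allele = sample(hla_pool, total, replace = TRUE))
  } else data.table::data.table()
  plant_truth <- list()
  samples <- unique(cohort$clinical$sample_id)
  for (pl in np$shared_peptides) {
    who <- sample(samples, min(pl$n_patients, length(samples)))
    M <- stats::rlnorm(length(who), np$mutant_score_meanlog, 0.2)
    plant <- data.table::data.table(
      sample_id = who, gene = "GENE0001",
      mutant_peptide = pl$peptide,
      wild_peptide = rand_peptides(1L),
      mutant_score = M, wild_score = M * 4,
      percent_rank = 0.2, bind_level = "SB",
      hla_allele = hla_pool[1])
    peptides <- rbind(peptides, plant, fill = TRUE)
    plant_truth[[pl$peptide]] <- who
  }
  list(peptides = peptides[], truth = list(shared = plant_truth))
}

#' Simulate survival records with a planted hazard threshold on a score
#'
#' Lightweight generator for cutpoint-recovery experiments: scores are
#' standard normal, survival is exponential with the hazard multiplied by
#' `hr` for samples whose score exceeds the `threshold_quantile` quantile,
#' with administrative censoring at `censor_horizon`.
#'
#' @param n number of samples.
#' @param hr hazard ratio above the threshold (default 3).
#' @param threshold_quantile quantile of the score where the hazard steps
#'   (default 0.5).
#' @param baseline_median median survival below the threshold, days
#'   (default 730).
#' @param censor_horizon administrative censoring time, days
#'   (default 2000).
#' @param seed integer seed.
#' @return list: `records` (data.table `sample_id`, `time`, `event`,
#'   `score`), `threshold` (the planted score threshold).
#' @export
simulate_survival_scores <- function(n, hr = 3, threshold_quantile = 0.5,
                                     baseline_median = 730,
                                     censor_horizon = 2000, seed = 1L) {
  set.seed(seed)
  score <- stats::rnorm(n)
  theta <- stats::quantile(score, threshold_quantile, names = FALSE)
  lambda0 <- log(2) / baseline_median
  t_true <- stats::rexp(n, rate = lambda0 * ifelse(score > theta, hr, 1))
  list(records = data.table::data.table(
    sample_id = sprintf("SYN%04d", seq_len(n)),
    time = pmin(t_true, censor_horizon),
    event = as.integer(t_true <= censor_horizon),
    score = score),
    threshold = theta)
}
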