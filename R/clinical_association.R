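# Gene-clinical association: cohort grouping conventions (including exact
# 1-D k-means dichotomisation of age), per-gene Fisher exact tests with BH
# FDR, higher/lower-mutated-gene classification for lymph-node metastasis,
# pairwise mutual exclusivity / co-occurrence, and driver-gene consensus
# across external caller result tables.

#' Exact 1-D k-means split
#'
#' Optimal k-cluster partition of a numeric vector minimising
#' within-cluster sum of squares. In one dimension optimal clusters are
#' contiguous in sorted order, so the exact optimum is found by exhaustive
#' search over contiguous splits (k = 2) or dynamic programming over split
#' positions (k > 2).
#'
#' @param x numeric vector (e.g. ages).
#' @param k number of clusters (default 2).
#' @return list: `labels` (1 = lowest cluster), `boundaries` (k-1
#'   midpoints between adjacent clusters), `withinss` (total
#'   within-cluster sum of squares).
#' @export
kmeans1d_split <- function(x, k = 2L) {
  if (anyNA(x)) stop("missing values in x")
  if (length(unique(x)) < k) stop("fewer distinct values than clusters")
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  wss <- function(v) if (length(v) <= 1L) 0 else sum((v - mean(v))^2)
  if (k == 2L) {
    # all contiguous splits after position i
    costs <- vapply(seq_len(n - 1L), function(i)
      wss(xs[1:i]) + wss(xs[(i + 1L):n]), numeric(1))
    # avoid zero-width boundaries between tied values
    valid <- xs[seq_len(n - 1L)] < xs[2:n]
    costs[!valid] <- Inf
    i <- which.min(costs)
    splits <- i
  } else {
    # DP over prefix costs: cost[i,j] = wss of xs[i..j]
    csum <- cumsum(xs); csq <- cumsum(xs^2)
    seg <- function(i, j) {
      s <- csum[j] - if (i > 1) csum[i - 1] else 0
      q <- csq[j] - if (i > 1) csq[i - 1] else 0
      q - s^2 / (j - i + 1)
    }
    D <- matrix(Inf, k, n); B <- matrix(0L, k, n)
    for (j in 1:n) D[1, j] <- seg(1, j)
    for (kk in 2:k) {
      for (j in kk:n) {
        for (i in kk:j) {
          cand <- D[kk - 1, i - 1] + seg(i, j)
          if (cand < D[kk, j]) { D[kk, j] <- cand; B[kk, j] <- i }
        }
      }
    }
    splits <- integer(k - 1L); j <- n
    for (kk in k:2) { splits[kk - 1L] <- B[kk, j] - 1L; j <- B[kk, j] - 1L }
  }
  labels_sorted <- rep(seq_len(k), diff(c(0L, splits, n)))
  labels <- integer(n); labels[ord] <- labels_sorted
  boundaries <- (xs[splits] + xs[splits + 1L]) / 2
  list(labels = labels, boundaries = boundaries,
       withinss = sum(vapply(seq_len(k), function(c)
         wss(x[labels == c]), numeric(1))))
}

#' Build the standard clinical groupings
#'
#' Emits the cohort's binary grouping conventions: T stage (T1-T2 vs
#' T3-T4), TNM stage (S1-S2 vs S3-S4), gender, lymph-node metastasis,
#' smoking, drinking, tumor grade (G1-G2 vs G3-G4), plus the three-level
#' tumor location and two age splits (fixed threshold 60 years and an
#' exact 1-D k-means split). M stage is never emitted (too few M1
#' samples to test). Unknown values become `NA` and are excluded from
#' downstream tests; a grouping whose source column is missing is omitted
#' with a warning.
#'
#' @param clinical clinical data.table from [read_clinical()].
#' @param age_threshold fixed age split (default 60 years).
#' @return named list of per-sample factors (names = sample ids). Binary
#'   groupings use levels `A`/`B` with the convention A = first-named arm
#'   (e.g. T1-T2, metastasis yes, age <= threshold).
#' @export
build_groupings <- function(clinical, age_threshold = 60) {
  sid <- clinical$sample_id
  out <- list()
  two_level <- function(x, a_levels, b_levels) {
    f <- ifelse(x %in% a_levels, "A", ifelse(x %in% b_levels, "B", NA))
    stats::setNames(factor(f, levels = c("A", "B")), sid)
  }
  specs <- list(
    t_stage  = list(col = "t_stage", a = c("T1", "T2"), b = c("T3", "T4")),
    tnm      = list(col = "tnm_stage", a = c("S1", "S2"), b = c("S3", "S4")),
    gender   = list(col = "gender", a = "male", b = "female"),
    lymph    = list(col = "n_lymph", a = "yes", b = "no"),
    smoking  = list(col = "smoking", a = "yes", b = "no"),
    drinking = list(col = "drinking", a = "yes", b = "no"),
    grade    = list(col = "grade", a = c("G1", "G2"), b = c("G3", "G4")))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (!sp$col %in% names(clinical)) {
      warning("clinical column '", sp$col, "' missing: grouping '", nm,
              "' omitted")
      next
    }
    out[[nm]] <- two_level(clinical[[sp$col]], sp$a, sp$b)
  }
  if ("location" %in% names(clinical)) {
    loc <- clinical$location
    loc[!loc %in% c("upper", "middle", "lower")] <- NA
    out$location <- stats::setNames(
      factor(loc, levels = c("upper", "middle", "lower")), sid)
  } else {
    warning("clinical column 'location' missing: grouping omitted")
  }
  if ("age" %in% names(clinical)) {
    age <- clinical$age
    f60 <- ifelse(is.na(age), NA, ifelse(age <= age_threshold, "A", "B"))
    out$age60 <- stats::setNames(factor(f60, levels = c("A", "B")), sid)
    ok <- !is.na(age)
    if (sum(ok) >= 2L && length(unique(age[ok])) >= 2L) {
      km <- kmeans1d_split(age[ok], 2L)
      fkm <- rep(NA_character_, length(age))
      fkm[ok] <- c("A", "B")[km$labels]
      g <- stats::setNames(factor(fkm, levels = c("A", "B")), sid)
      attr(g, "boundary") <- km$boundaries
      out$age_kmeans <- g
    }
  } else {
    warning("clinical column 'age' missing: age groupings omitted")
  }
  out
}

# per-gene mutation status matrix over the cohort's samples
mutation_status <- function(cohort, genes = NULL) {
  mut <- if (inherits(cohort, "mutscape_cohort")) cohort$mutations else cohort
  if (is.null(genes)) genes <- sort(unique(mut$gene))
  samples <- if (inherits(cohort, "mutscape_cohort")) {
    cohort$clinical$sample_id
  } else {
    sort(unique(mut$sample_id))
  }
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  hit <- unique(mut[mut$gene %in% genes & mut$sample_id %in% samples,
                    c("sample_id", "gene"), with = FALSE])
  m[cbind(hit$sample_id, hit$gene)] <- TRUE
  m
}

#' Per-gene Fisher association with a binary clinical grouping
#'
#' For each gene mutated in at least `min_mutated` tested samples, builds
#' the 2x2 table of mutation status against the grouping and runs a
#' two-sided Fisher exact test; Benjamini-Hochberg FDR is applied across
#' the genes of the grouping. Mutation rates per arm and the direction of
#' the effect are reported so that downstream classification (e.g.
#' HMG/LMG) can use them.
#'
#' @param cohort a `mutscape_cohort`.
#' @param grouping per-sample two-level factor (names = sample ids).
#' @param min_mutated minimum mutated tested samples per gene (default 3).
#' @return data.table: `gene`, table cells `n_mut_A`, `n_mut_B`,
#'   `n_wild_A`, `n_wild_B`, `rate_A`, `rate_B`, `odds_ratio`, `p`, `fdr`,
#'   `direction` (`higher_in_A`/`higher_in_B`).
#' @export
gene_group_fisher <- function(cohort, grouping, min_mutated = 3L) {
  grouping <- grouping[!is.na(grouping)]
  if (length(unique(grouping)) != 2L) stop("grouping must have two nonempty arms")
  status <- mutation_status(cohort)
  samples <- intersect(rownames(status), names(grouping))
  if (length(samples) == 0L) stop("no samples shared between cohort and grouping")
  status <- status[samples, , drop = FALSE]
  grp <- factor(grouping[samples])
  lev <- levels(grp)
  keep <- colSums(status) >= min_mutated
  status <- status[, keep, drop = FALSE]
  nA <- sum(grp == lev[1]); nB <- sum(grp == lev[2])
  rows <- lapply(colnames(status), function(g) {
    mutA <- sum(status[, g] & grp == lev[1])
    mutB <- sum(status[, g] & grp == lev[2])
    tab <- matrix(c(mutA, nA - mutA, mutB, nB - mutB), 2,
                  dimnames = list(c("mut", "wild"), lev))
    ft <- stats::fisher.test(tab)
    data.table::data.table(
      gene = g, n_mut_A = mutA, n_mut_B = mutB,
      n_wild_A = nA - mutA, n_wild_B = nB - mutB,
      rate_A = mutA / nA, rate_B = mutB / nB,
      odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) return(out)
  out[, fdr := stats::p.adjust(p, method = "BH")]
  out[, direction := ifelse(rate_A >= rate_B, "higher_in_A", "higher_in_B")]
  out[]
}

#' Per-gene Welch t-test against a numeric variable
#'
#' Tests, for each gene with at least two mutated and two wild-type
#' values, whether a numeric per-sample variable (age, burden, ...)
#' differs between mutated and wild-type samples (two-sided Welch t-test).
#'
#' @param cohort a `mutscape_cohort`.
#' @param values named numeric vector (names = sample ids).
#' @param min_mutated minimum mutated samples (default 3).
#' @return data.table: `gene`, `n_mut`, `n_wild`, `mean_mut`, `mean_wild`,
#'   `t`, `p`, `fdr`, `skipped` (arm with < 2 values).
#' @export
gene_numeric_ttest <- function(cohort, values, min_mutated = 3L) {
  values <- values[!is.na(values)]
  status <- mutation_status(cohort)
  samples <- intersect(rownames(status), names(values))
  status <- status[samples, , drop = FALSE]
  v <- values[samples]
  keep <- colSums(status) >= min_mutated
  status <- status[, keep, drop = FALSE]
  rows <- lapply(colnames(status), function(g) {
    vm <- v[status[, g]]; vw <- v[!status[, g]]
    skip <- length(vm) < 2L || length(vw) < 2L ||
      (stats::sd(vm) == 0 && stats::sd(vw) == 0)
    if (skip) {
      return(data.table::data.table(
        gene = g, n_mut = length(vm), n_wild = length(vw),
        mean_mut = mean(vm), mean_wild = mean(vw),
        t = NA_real_, p = NA_real_, skipped = TRUE))
    }
    tt <- stats::t.test(vm, vw)
    data.table::data.table(
      gene = g, n_mut = length(vm), n_wild = length(vw),
      mean_mut = mean(vm), mean_wild = mean(vw),
      t = unname(tt$statistic), p = tt$p.value, skipped = FALSE)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) return(out)
  out[, fdr := NA_real_]
  out[skipped == FALSE, fdr := stats::p.adjust(p, method = "BH")]
  out[]
}

#' Classify genes as higher/lower-mutated in the metastasis arm
#'
#' Applies the HMG/LMG rule to a [gene_group_fisher()] result computed on
#' the lymph-node-metastasis grouping (arm A = metastasis): genes with
#' `p < alpha` are HMG when their mutation rate is higher in the
#' metastasis arm and LMG when lower; all other genes are `none`.
#'
#' @param assoc result of [gene_group_fisher()] on the lymph grouping.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param use_fdr classify on the FDR column instead of raw p.
#' @return the input with an added `class` column in
#'   `{"HMG", "LMG", "none"}`.
#' @export
hmg_lmg_classify <- function(assoc, alpha = 0.05, use_fdr = FALSE) {
  out <- data.table::copy(assoc)
  pv <- if (use_fdr) out$fdr else out$p
  out[, class := ifelse(pv < alpha & rate_A > rate_B, "HMG",
                 ifelse(pv < alpha & rate_A < rate_B, "LMG", "none"))]
  out[]
}

#' Pairwise mutual exclusivity / co-occurrence of mutated genes
#'
#' For each pair among the `top_n` most frequently mutated genes, tests
#' the 2x2 table of joint mutation status with a two-sided Fisher exact
#' test and classifies significant pairs by the odds ratio: < 1 mutually
#' exclusive, > 1 co-occurring.
#'
#' @param cohort a `mutscape_cohort`.
#' @param top_n number of top genes (default 25).
#' @param alpha significance threshold (default 0.05).
#' @return data.table: `gene1`, `gene2`, `n_both`, `n_g1_only`,
#'   `n_g2_only`, `n_neither`, `odds_ratio`, `p`, `classification`
#'   (`mutually_exclusive` / `co_occurring` / `none`).
#' @export
pairwise_interactions <- function(cohort, top_n = 25L, alpha = 0.05) {
  mut <- cohort$mutations
  freq <- sort(table(unique(mut[, c("sample_id", "gene"),
                                with = FALSE])$gene), decreasing = TRUE)
  genes <- names(freq)[seq_len(min(top_n, length(freq)))]
  status <- mutation_status(cohort, genes)
  pairs <- utils::combn(genes, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    a <- status[, g1]; b <- status[, g2]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2)
    ft <- stats::fisher.test(tab)
    or <- unname(ft$estimate)
    cls <- if (ft$p.value < alpha) {
      if (or < 1) "mutually_exclusive" else "co_occurring"
    } else "none"
    data.table::data.table(
      gene1 = g1, gene2 = g2,
      n_both = tab[1, 1], n_g1_only = tab[2, 1],
      n_g2_only = tab[1, 2], n_neither = tab[2, 2],
      odds_ratio = or, p = ft$p.value, classification = cls)
  })
  data.table::rbindlist(rows)[]
}

# thresholds under which each external caller flags a gene
DRIVER_TOOL_THRESHOLDS <- list(
  MutSigCV       = list(column = "fdr", threshold = 0.05),
  driverml       = list(column = "p", threshold = 0.01),
  OncodriveFML   = list(column = "fdr", threshold = 0.05),
  OncodriveCLUSTL = list(column = "fdr", threshold = 0.05)
)

#' Driver-gene consensus across external caller results
#'
#' Each tool's result table (columns `gene` plus `p` or `fdr`) is
#' thresholded at its convention -- p < 0.01 for driverml, FDR < 0.05 for
#' MutSigCV, OncodriveFML and OncodriveCLUSTL -- and a gene is called a
#' driver when flagged by at least `min_tools` tools.
#'
#' @param tool_tables named list of data.frames, names drawn from
#'   `MutSigCV`, `driverml`, `OncodriveFML`, `OncodriveCLUSTL`.
#' @param min_tools support threshold (default 2).
#' @return data.table: `gene`, one logical flag column per supplied tool,
#'   `n_tools_supporting`, `is_driver`; empty input gives an empty table.
#' @export
driver_consensus <- function(tool_tables, min_tools = 2L) {
  if (length(tool_tables) == 0L) {
    return(data.table::data.table(gene = character(0),
                                  n_tools_supporting = integer(0),
                                  is_driver = logical(0)))
  }
  unknown <- setdiff(names(tool_tables), names(DRIVER_TOOL_THRESHOLDS))
  if (length(unknown) > 0L) {
    stop("unknown driver tool(s): ", paste(unknown, collapse = ", "))
  }
  flags <- lapply(names(tool_tables), function(tool) {
    tt <- data.table::as.data.table(tool_tables[[tool]])
    spec <- DRIVER_TOOL_THRESHOLDS[[tool]]
    if (!spec$column %in% names(tt)) {
      stop("tool ", tool, " table lacks required column '", spec$column, "'")
    }
    data.table::data.table(gene = tt$gene,
                           flag = tt[[spec$column]] < spec$threshold,
                           tool = tool)
  })
  long <- data.table::rbindlist(flags)
  wide <- data.table::dcast(long, gene ~ tool, value.var = "flag", fill = FALSE)
  flag_cols <- setdiff(names(wide), "gene")
  wide[, n_tools_supporting := rowSums(.SD), .SDcols = flag_cols]
  wide[, is_driver := n_tools_supporting >= min_tools]
  data.table::setorder(wide, -n_tools_supporting, gene)
  wide[]
}
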