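test_that("1-D k-means finds the optimal contiguous split", {
  km <- kmeans1d_split(c(50, 55, 58, 62, 65, 70))
  expect_equal(sort(unique(km$labels[1:3])), 1L)
  expect_equal(sort(unique(km$labels[4:6])), 2L)
  expect_gt(km$boundaries, 58); expect_lt(km$boundaries, 62)

  km2 <- kmeans1d_split(c(40, 40, 40, 80, 80, 80))
  expect_equal(km2$labels, rep(c(1L, 2L), each = 3))
  expect_gt(km2$boundaries, 40); expect_lt(km2$boundaries, 80)

  expect_error(kmeans1d_split(rep(5, 10)), "distinct")
})

test_that("1-D k-means equals exhaustive search and stats::kmeans optima", {
  set.seed(50)
  for (i in 1:5) {
    x <- c(rnorm(40, 50, 6), rnorm(30, 72, 5))
    km <- kmeans1d_split(x, 2L)
    # exhaustive oracle over all contiguous splits in sorted order
    xs <- sort(x)
    wss <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
    best <- min(vapply(1:(length(xs) - 1), function(i)
      wss(xs[1:i]) + wss(xs[-(1:i)]), numeric(1)))
    expect_equal(km$withinss, best, tolerance = 1e-9)
    # never worse than multi-start Lloyd
    kk <- stats::kmeans(x, 2, nstart = 25)
    expect_lte(km$withinss, kk$tot.withinss + 1e-9)
  }
  # k = 3 dynamic program vs brute force over split pairs
  set.seed(51)
  x <- c(rnorm(15, 10), rnorm(15, 30), rnorm(15, 60))
  km3 <- kmeans1d_split(x, 3L)
  xs <- sort(x); n <- length(xs)
  wss <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  combs <- utils::combn(n - 1, 2)
  brute <- min(apply(combs, 2, function(s)
    wss(xs[1:s[1]]) + wss(xs[(s[1] + 1):s[2]]) + wss(xs[(s[2] + 1):n])))
  expect_equal(km3$withinss, brute, tolerance = 1e-9)
})

test_that("groupings follow the cohort's dichotomisation conventions", {
  clin <- data.table::data.table(
    sample_id = paste0("s", 1:6),
    age = c(50, 55, 58, 62, 65, 70),
    gender = c("male", "female", "male", "male", "female", "male"),
    smoking = c("yes", "no", "yes", "unknown", "no", "yes"),
    drinking = "yes",
    t_stage = c("T1", "T2", "T3", "T4", "T2", "unknown"),
    n_lymph = c("yes", "no", "yes", "no", "yes", "no"),
    tnm_stage = c("S1", "S2", "S3", "S4", "S3", "S1"),
    m_stage = "M0",
    grade = c("G1", "G2", "G3", "G4", "G2", "G1"),
    location = c("upper", "middle", "lower", "middle", "middle", "lower"))
  g <- build_groupings(clin)
  expect_equal(unname(g$t_stage[c("s1", "s2", "s3")]),
               factor(c("A", "A", "B"), levels = c("A", "B"))[c(1, 2, 3)])
  expect_true(is.na(g$t_stage[["s6"]]))
  expect_equal(as.character(g$tnm[c("s1", "s3")]), c("A", "B"))
  expect_equal(as.character(g$gender[1:2]), c("A", "B"))
  expect_true(is.na(g$smoking[["s4"]]))
  # M stage never emitted
  expect_false(any(grepl("m_stage|^m$", names(g))))
  # both age groupings present; k-means boundary separates the two blocks
  expect_setequal(as.character(g$age60[1:3]), "A")
  expect_true(!is.null(attr(g$age_kmeans, "boundary")))
  # missing grade column drops that grouping with a warning
  expect_warning(g2 <- build_groupings(clin[, !"grade"]), "grade")
  expect_false("grade" %in% names(g2))
})

test_that("gene-group Fisher tests match enumeration and stay symmetric", {
  # 10/50 mutated in each arm: OR 1, p 1
  samples <- paste0("s", 1:100)
  grp <- stats::setNames(factor(rep(c("A", "B"), each = 50)), samples)
  mutated <- c(samples[1:10], samples[51:60])
  co <- make_cohort(mutated, "G1",
                    clinical = data.table::data.table(sample_id = samples))
  res <- gene_group_fisher(co, grp)
  expect_equal(res$p, 1)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-9)

  # [[8,2],[2,8]]: p equals the hypergeometric enumeration oracle
  samples2 <- paste0("t", 1:20)
  grp2 <- stats::setNames(factor(rep(c("A", "B"), each = 10)), samples2)
  mutated2 <- c(samples2[1:8], samples2[11:12])
  co2 <- make_cohort(mutated2, "G1",
                     clinical = data.table::data.table(sample_id = samples2))
  res2 <- gene_group_fisher(co2, grp2)
  expect_equal(res2$p, fisher_p_enum(8, 2, 2, 8), tolerance = 1e-12)
  # swapping arm labels leaves p unchanged
  grp2_swapped <- stats::setNames(
    factor(ifelse(grp2 == "A", "B", "A")), names(grp2))
  res2s <- gene_group_fisher(co2, grp2_swapped)
  expect_equal(res2s$p, res2$p, tolerance = 1e-12)

  # genes below the mutated-sample floor are skipped
  co3 <- make_cohort(samples2[1:2], "RARE",
                     clinical = data.table::data.table(sample_id = samples2))
  expect_equal(nrow(gene_group_fisher(co3, grp2, min_mutated = 3)), 0L)
})

test_that("per-gene t-tests follow the Welch formula and skip tiny arms", {
  samples <- paste0("s", 1:6)
  co <- make_cohort(samples[1:3], "G1",
                    clinical = data.table::data.table(sample_id = samples))
  vals <- stats::setNames(c(1, 2, 3, 4, 5, 6), samples)
  res <- gene_numeric_ttest(co, vals, min_mutated = 2)
  # Welch t for {1,2,3} vs {4,5,6}
  t_manual <- (mean(1:3) - mean(4:6)) / sqrt(var(1:3) / 3 + var(4:6) / 3)
  expect_equal(res$t, t_manual, tolerance = 1e-12)

  co1 <- make_cohort(samples[1], "G1",
                     clinical = data.table::data.table(sample_id = samples))
  res1 <- gene_numeric_ttest(co1, vals, min_mutated = 1)
  expect_true(res1$skipped)
})

test_that("HMG/LMG classification is exhaustive and direction-aware", {
  assoc <- data.table::data.table(
    gene = c("g1", "g2", "g3"),
    rate_A = c(0.30, 0.05, 0.30), rate_B = c(0.10, 0.20, 0.10),
    p = c(0.01, 0.01, 0.2), fdr = c(0.04, 0.04, 0.4))
  cl <- hmg_lmg_classify(assoc)
  expect_equal(cl$class, c("HMG", "LMG", "none"))
  expect_true(all(cl$class %in% c("HMG", "LMG", "none")))
})

test_that("pairwise interactions classify exclusivity and co-occurrence", {
  samples <- paste0("s", 1:20)
  clin <- data.table::data.table(sample_id = samples)
  # perfectly exclusive: 10 samples A-only, 10 B-only
  mut <- rbind(make_cohort(samples[1:10], "GA", clinical = clin)$mutations,
               make_cohort(samples[11:20], "GB", clinical = clin)$mutations)
  co <- structure(list(mutations = mut, clinical = clin),
                  class = "mutscape_cohort")
  res <- pairwise_interactions(co, top_n = 2)
  expect_equal(res$classification, "mutually_exclusive")
  expect_equal(res$odds_ratio, 0)

  # perfectly co-occurring: 10 both, 10 neither
  mut2 <- rbind(make_cohort(samples[1:10], "GA", clinical = clin)$mutations,
                make_cohort(samples[1:10], "GB", clinical = clin)$mutations)
  co2 <- structure(list(mutations = mut2, clinical = clin),
                   class = "mutscape_cohort")
  res2 <- pairwise_interactions(co2, top_n = 2)
  expect_equal(res2$classification, "co_occurring")
  expect_equal(res2$odds_ratio, Inf)
})

test_that("driver consensus applies per-tool thresholds and the 2-tool rule", {
  tabs <- list(
    MutSigCV = data.frame(gene = c("TP53", "GX"), fdr = c(0.01, 0.2)),
    driverml = data.frame(gene = c("TP53", "GY"), p = c(0.005, 0.5)),
    OncodriveFML = data.frame(gene = "GZ", fdr = 0.001))
  dc <- driver_consensus(tabs)
  expect_true(dc[gene == "TP53", is_driver])
  expect_equal(dc[gene == "TP53", n_tools_supporting], 2)
  # one tool is not enough
  expect_false(dc[gene == "GZ", is_driver])
  expect_false(dc[gene == "GX", is_driver])

  # boundary: FDR exactly at threshold does not flag
  dc2 <- driver_consensus(list(
    MutSigCV = data.frame(gene = "g", fdr = 0.05),
    driverml = data.frame(gene = "g", p = 0.01)))
  expect_equal(dc2$n_tools_supporting, 0)

  expect_error(driver_consensus(list(badtool = data.frame(gene = "g", p = 1))),
               "unknown driver tool")
  expect_equal(nrow(driver_consensus(list())), 0L)
})
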