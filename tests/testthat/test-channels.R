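test_that("SBS-96 classification follows the pyrimidine-strand convention", {
  expect_equal(classify_sbs96("C", "A", "A", "A"), "A[C>A]A")
  # purine reference: reverse-complement, flanks swap and complement
  expect_equal(classify_sbs96("G", "T", "A", "C"), "G[C>A]T")
  expect_error(classify_sbs96("N", "A", "A", "A"), "non-ACGT")
  expect_error(classify_sbs96("C", "C", "A", "A"), "not a substitution")
  # longer context strings: only the adjacent base counts
  expect_equal(classify_sbs96("C", "T", "GGA", "GTT"), "A[C>T]G")
})

test_that("SBS-96 labels are closed over the 96-channel set and strand-invariant", {
  set.seed(42)
  channels <- sbs96_channels()
  expect_length(channels, 96L)
  expect_false(anyDuplicated(channels) > 0)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:300) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    f5 <- sample(c("A", "C", "G", "T"), 1)
    f3 <- sample(c("A", "C", "G", "T"), 1)
    lab <- classify_sbs96(ref, alt, f5, f3)
    expect_true(lab %in% channels)
    # classifying the reverse-complement strand gives the same channel
    lab_rc <- classify_sbs96(comp[ref], comp[alt], comp[f3], comp[f5])
    expect_identical(lab_rc, lab)
  }
})

test_that("DBS-78 canonicalisation collapses reverse complements", {
  expect_equal(classify_dbs78("GG", "TT"), "CC>AA")
  expect_equal(classify_dbs78("CC", "AA"), "CC>AA")
  expect_error(classify_dbs78("AC", "AG"), "fewer than two positions")
  set.seed(7)
  channels <- dbs78_channels()
  expect_length(channels, 78L)
  for (i in 1:200) {
    ref <- paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")
    alts <- expand.grid(a = setdiff(c("A", "C", "G", "T"), substr(ref, 1, 1)),
                        b = setdiff(c("A", "C", "G", "T"), substr(ref, 2, 2)))
    j <- sample(nrow(alts), 1)
    alt <- paste0(alts$a[j], alts$b[j])
    lab <- classify_dbs78(ref, alt)
    expect_true(lab %in% channels)
    # strand invariance
    rc <- function(x) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
    expect_identical(classify_dbs78(rc(ref), rc(alt)), lab)
  }
})

test_that("ID-83 classification follows the indel decision tree", {
  # 1-bp T deletion inside a run of 5 T's: homopolymer length 5 (index 4)
  expect_equal(classify_id83("T", "-", "AGCTT", "TTGCA"), "1:Del:T:4")
  # 1-bp C insertion with no adjacent C
  expect_equal(classify_id83("-", "C", "AGTAT", "TGAGA"), "1:Ins:C:0")
  # 3-bp deletion, no full extra copy, 2 flanking bases match the deleted
  # suffix -> microhomology channel of length 2
  # deleted CTA; context5 ends ...TA (suffix match of length 2); context3
  # shares no prefix
  expect_equal(classify_id83("CTA", "-", "GGGTA", "GGGGG"), "3:Del:M:2")
  # a full extra copy takes precedence over microhomology
  expect_equal(classify_id83("CTA", "-", "GGGGG", "CTAGG"), "3:Del:R:1")
  # 1-bp A deletion normalises to T
  expect_equal(classify_id83("A", "-", "GGGGC", "CGGGG"), "1:Del:T:0")
  expect_error(classify_id83("T", "-", NA, "TT"), "context")
})

test_that("ID-83 labels are closed over the 83-channel set", {
  channels <- id83_channels()
  expect_length(channels, 83L)
  set.seed(11)
  for (i in 1:200) {
    ind <- mutscape:::simulate_indel(0.7)
    lab <- classify_id83(ind$ref, ind$alt, ind$context5, ind$context3)
    expect_true(lab %in% channels)
  }
})

test_that("build_catalog counts classifiable mutations and skips the rest", {
  co <- make_cohort(sample_id = "S1", gene = paste0("G", 1:3))
  cat1 <- build_catalog(co, "SBS96")
  expect_equal(unname(cat1$counts["S1", "A[C>A]A"]), 3L)
  expect_equal(sum(cat1$counts), 3L)

  # indel-only sample yields an all-zero SBS row
  co2 <- make_cohort(sample_id = "S2", gene = "G1", variant_type = "DEL",
                     variant_class = "frame_shift_del")
  co2$mutations[, ref_allele := "T"]; co2$mutations[, alt_allele := "-"]
  cat2 <- build_catalog(co2, "SBS96")
  expect_true(all(cat2$counts == 0))

  # missing context -> skipped with warning, bookkeeping preserved
  co3 <- make_cohort(sample_id = "S1", gene = paste0("G", 1:4))
  co3$mutations[1:2, context5 := NA_character_]
  expect_warning(cat3 <- build_catalog(co3, "SBS96"), "skipped")
  expect_equal(sum(cat3$counts) + cat3$skipped, 4L)
})

test_that("catalog row sums equal classifiable mutations from the generator", {
  cfg <- sim_config(n_samples = 5, seed = 3, mutation_mean = 100,
                    mutation_size = 10, indel_fraction = 0,
                    dbs_fraction = 0, hmg_genes = list(), lmg_genes = list())
  sim <- simulate_cohort(cfg)
  cat <- build_catalog(sim$cohort, "SBS96")
  per_sample <- table(sim$cohort$mutations$sample_id)
  expect_equal(rowSums(cat$counts)[names(per_sample)],
               stats::setNames(as.numeric(per_sample), names(per_sample)))
  # channel truth matches the catalog count per channel
  truth_counts <- table(sim$truth$mutation_truth$true_channel)
  expect_equal(sum(cat$counts), sum(truth_counts))
})
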