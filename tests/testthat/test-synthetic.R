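test_that("the generator is deterministic and its outputs pass the readers", {
  cfg <- sim_config(n_samples = 15, seed = 9, mutation_mean = 30,
                    mutation_size = 3)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulate_cohort(cfg, out_dir = d1)
  s2 <- simulate_cohort(cfg, out_dir = d2)
  expect_identical(s1$cohort$mutations, s2$cohort$mutations)
  expect_identical(s1$cohort$clinical, s2$cohort$clinical)
  expect_identical(readLines(file.path(d1, "cohort.maf")),
                   readLines(file.path(d2, "cohort.maf")))

  # round trip through the readers, without warnings
  expect_no_warning({
    mut <- read_maf(file.path(d1, "cohort.maf"), "synthetic")
    clin <- read_clinical(file.path(d1, "clinical.tsv"))
    merge_cohorts(list(mut), list(clin))
  })
  expect_equal(nrow(mut), nrow(s1$cohort$mutations))
})

test_that("config validation rejects inconsistent settings", {
  bad_sig <- matrix(c(0.5, 0.4), 2)  # does not sum to 1
  expect_error(sim_config(signatures = bad_sig), "sum to 1")
  expect_error(sim_config(indel_fraction = 0.9, dbs_fraction = 0.2),
               "leave room")
  expect_error(sim_config(silent_fraction = 1.5), "0, 1")
})

test_that("zero silent fraction forces fTMB to equal aTMB downstream", {
  cfg <- sim_config(n_samples = 10, seed = 2, mutation_mean = 50,
                    mutation_size = 5, silent_fraction = 0,
                    hmg_genes = list(), lmg_genes = list())
  b <- compute_burden(simulate_cohort(cfg)$cohort)
  expect_equal(b$aTMB, b$fTMB)
})

test_that("channel frequencies follow the configured signature mixture", {
  # near-degenerate Dirichlet pins weights at (0.7, 0.3)
  cfg <- sim_config(n_samples = 20, seed = 13, mutation_mean = 300,
                    mutation_size = 100, mixture_alpha = c(0.7, 0.3) * 1e6,
                    indel_fraction = 0, dbs_fraction = 0,
                    hmg_genes = list(), lmg_genes = list())
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$mutation_truth
  # empirical channel distribution: C>T block should carry ~70% of SNVs
  frac_ct <- mean(grepl("\\[C>T\\]", truth$true_channel))
  n <- nrow(truth)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(frac_ct - 0.7), 2.6 * se)   # 99% band
})

test_that("planted lymph-associated genes mutate at the configured rates", {
  cfg <- sim_config(n_samples = 400, seed = 21, mutation_mean = 20,
                    mutation_size = 3)
  sim <- simulate_cohort(cfg)
  clin <- sim$cohort$clinical
  status <- mutscape:::mutation_status(sim$cohort, "HMG01")
  met <- clin$n_lymph == "yes"
  rate_met <- mean(status[clin$sample_id[met], 1])
  rate_non <- mean(status[clin$sample_id[!met], 1])
  expect_gt(rate_met, rate_non)
  # within 3 binomial SDs of the configured rates
  expect_lt(abs(rate_met - 0.35), 3 * sqrt(0.35 * 0.65 / sum(met)))
  expect_lt(abs(rate_non - 0.10), 3 * sqrt(0.1 * 0.9 / sum(!met)))
})

test_that("binding tables honour pairing rules and degenerate settings", {
  # all indels frameshift, no SNVs -> every peptide unpaired
  cfg <- sim_config(n_samples = 10, seed = 4, mutation_mean = 30,
                    mutation_size = 5, indel_fraction = 0.98,
                    dbs_fraction = 0.01, frameshift_fraction = 1,
                    hmg_genes = list(), lmg_genes = list(),
                    neoantigen = list(peptides_per_nonsyn = 1,
                                      rank_meanlog = 0, rank_sdlog = 1,
                                      mutant_score_meanlog = log(200),
                                      mutant_score_sdlog = 1,
                                      log2_ratio_mean = 1, log2_ratio_sd = 1,
                                      shared_peptides = list()))
  sim <- simulate_cohort(cfg)
  # keep only frameshift records to make every source unpaired
  sim$cohort$mutations <- sim$cohort$mutations[
    variant_class %in% c("frame_shift_ins", "frame_shift_del")]
  bt <- simulate_binding_table(cfg, sim$cohort)
  expect_true(all(is.na(bt$peptides$wild_score)))

  # candidate rate 0 -> TNB 0 everywhere
  cfg0 <- sim_config(n_samples = 5, seed = 4, mutation_mean = 20,
                     mutation_size = 5,
                     neoantigen = list(peptides_per_nonsyn = 0,
                                       rank_meanlog = 0, rank_sdlog = 1,
                                       mutant_score_meanlog = log(200),
                                       mutant_score_sdlog = 1,
                                       log2_ratio_mean = 1, log2_ratio_sd = 1,
                                       shared_peptides = list()))
  sim0 <- simulate_cohort(cfg0)
  bt0 <- simulate_binding_table(cfg0, sim0$cohort)
  if (nrow(bt0$peptides) > 0) {
    sc <- sample_scores(bt0$peptides)
    expect_true(all(sc$scores$TNB == 0))
  } else {
    expect_equal(nrow(bt0$peptides), 0L)
  }
})

test_that("neoantigen burden tracks nonsilent burden on synthetic cohorts", {
  cfg <- sim_config(n_samples = 60, seed = 17)
  sim <- simulate_cohort(cfg)
  bt <- simulate_binding_table(cfg, sim$cohort)
  sc <- sample_scores(bt$peptides)
  b <- compute_burden(sim$cohort)
  m <- merge(b, sc$scores, by = "sample_id")
  expect_gt(stats::cor(m$TNB, m$fTMB), 0.8)
})
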