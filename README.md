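# mutscape

Integrative somatic-mutation landscape analysis for pooled cancer
cohorts, built for studies of the kind performed on merged esophageal
squamous cell carcinoma (ESCC) sequencing cohorts: many MAF-format
mutation tables and one clinical table in, and out come mutational
signatures, tumor mutational burden, neoantigen scores, survival
cutpoints, and gene–clinical associations — every stage also runnable on
a built-in synthetic cohort with known ground truth.

It is aimed at cancer-genomics analysts who have variant calls (MAF),
clinical annotations, and optionally epitope-prediction output, and who
want the downstream statistics reproducible and tested rather than
scattered across one-off scripts.

## What it computes

- **Mutation catalogs and signatures.** SBS-96 / DBS-78 / ID-83 channel
  classification under the COSMIC conventions, de-novo signature
  extraction by NMF (Frobenius objective, multiplicative updates,
  multi-restart, seeded), rank selection by bootstrap stability
  (Poisson-resampled catalogs, one-to-one signature matching, mean
  silhouette ≥ 0.8), cosine annotation against a reference set, and
  per-sample exposures by nonnegative least squares.
- **Tumor mutational burden.** Two statistics over a fixed 30-Mb coding
  footprint: `aTMB = (SNV + indel)/30` (synonymous included) and
  `fTMB = (nonsynonymous SNV + indel)/30`, plus their concordance
  (Pearson/Spearman r, paired t-test).
- **Neoantigen scoring.** From pVACtools-style binding tables: candidates
  are strong/weak binders; each candidate scores
  `AAscore = log2(W/M)` (wild-type over mutant binding score), with
  unpaired frameshift peptides fixed at `log2(15)`; per-gene `Gscore` is
  the sum over the gene's candidates, per-sample `TNS` the sum over
  genes, and `TNB` the candidate count. A sharing spectrum reports how
  many patients carry each distinct peptide.
- **Survival.** Kaplan–Meier curves, a native two-group log-rank test
  (cross-checked against `survival::survdiff`), and optimal
  dichotomisation of any continuous score by maximally selected rank
  statistics (`surv_cutpoint`-style scan, `minprop = 0.1`, high group
  `score > cutpoint`), with the unadjusted log-rank p plus a
  Lausen–Schumacher-adjusted diagnostic p.
- **Gene–clinical association.** The standard cohort groupings (T stage,
  TNM, gender, lymph-node metastasis, smoking, drinking, grade,
  location, and age both at 60 years and by exact 1-D k-means), per-gene
  two-sided Fisher tests with BH FDR, HMG/LMG classification for the
  metastasis grouping, pairwise mutual exclusivity / co-occurrence, and
  driver-gene consensus across MutSigCV / driverml / OncodriveFML /
  OncodriveCLUSTL result tables (driver ⇔ flagged by ≥ 2 tools).
- **Synthetic cohorts.** `sim_config()` + `simulate_cohort()` +
  `simulate_binding_table()` generate MAF/clinical/binding inputs with
  planted signatures, lymph-associated genes, a survival hazard
  threshold, and shared peptides — all recorded as ground truth.

## Worked example

```r
library(mutscape)

cfg <- sim_config(n_samples = 80, seed = 11)
sim <- simulate_cohort(cfg)
sim$cohort
#> mutscape cohort: 80 mutated samples, 80 clinical records, 9708 mutation records, 1 cohort(s)

burden <- compute_burden(sim$cohort)
burden[1:3]
#>    sample_id n_snv_total n_snv_nonsynonymous n_indel     aTMB     fTMB
#> 1:   SYN0001          74                  61       6 2.666667 2.233333
#> 2:   SYN0002         131                 102      13 4.800000 3.833333
#> 3:   SYN0003         108                  78      11 3.966667 2.966667
conc <- burden_concordance(burden)
cat(sprintf("aTMB vs fTMB: Pearson r = %.3f, mean difference = %.2f/Mb\n",
            conc$pearson, conc$mean_difference))
#> aTMB vs fTMB: Pearson r = 0.997, mean difference = 0.90/Mb

catalog <- build_catalog(sim$cohort, "SBS96")
sel <- select_k(catalog, k_range = 1:4, seed = 11, n_restarts = 6)
sel$k
#> chosen rank: 2
fit <- extract_signatures(catalog, k = sel$k, seed = 11)
round(cosine_similarity(fit$signatures, sim$truth$signatures), 3)
#>    synthSig1 synthSig2
#> S1     0.998     0.016
#> S2     0.080     0.990

surv <- merge(sim$cohort$clinical[, .(sample_id, time = os_time, event = os_event)],
              burden[, .(sample_id, score = aTMB)], by = "sample_id")
oc <- optimal_cutpoint(surv, minprop = 0.1)
#> optimal aTMB cutpoint 4.33 (planted 3.99): z = 3.20, logrank p = 0.0014, groups 26/54
```

The cohort was simulated with a hazard step planted at aTMB 3.99 (the
60th percentile); the scan recovers a cutpoint of 4.33 with a clearly
significant split — the kind of agreement the seeded recovery tests
assert systematically. The two extracted signatures match the planted
ones at cosine 0.998 and 0.990, and aTMB/fTMB track each other at
r = 0.997 with the mean 0.90/Mb offset coming from the synonymous and
excluded-class load.

Gene-level association on the same cohort recovers the planted
lymph-metastasis genes:

```r
groupings <- build_groupings(sim$cohort$clinical)
assoc <- gene_group_fisher(sim$cohort, groupings$lymph)
hmg_lmg_classify(assoc)[gene %in% c("HMG01", "HMG02", "LMG01"),
                        .(gene, rate_A, rate_B, p, class)]
#>      gene    rate_A     rate_B            p class
#> 1:  HMG01 0.4042553 0.18181818 4.965742e-02   HMG
#> 2:  HMG02 0.3829787 0.03030303 1.535382e-04   HMG
#> 3:  LMG01 0.0000000 0.30303030 5.621712e-05   LMG
```

`rate_A`/`rate_B` are the mutation rates in the metastasis / 
no-metastasis arms; HMG01/HMG02 were planted at 35% vs 10% and LMG01 at
5% vs 25%.

The whole pipeline can also run from one config
(`run_pipeline(list(inputs = ..., params = ..., out_dir = ...))` or a
YAML file; see `?run_pipeline`), writing per-stage TSVs and a manifest.
A thin command-line wrapper lives at `inst/cli/mutscape.R`.

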