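---
title: "Methods and design of the mutscape pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mutscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mutscape re-implements, as a tested and reusable pipeline, an integrative
somatic-mutation analysis of the kind applied to pooled esophageal squamous
cell carcinoma (ESCC) cohorts: mutational-signature extraction, two tumor
mutational burden (TMB) statistics, neoantigen burden and scoring from
epitope-prediction tables, survival comparison with optimally selected
cutpoints, gene–clinical association with higher/lower-mutated-gene
classification, mutual-exclusivity testing, and driver-gene consensus.
This vignette documents the statistical models, the tunable parameters,
and the design decisions that were genuinely open.

## Cohort ingestion

Mutations are consumed in MAF format (GDC column names). Only eight
columns are required; everything else is optional, because pooled cohorts
converted from heterogeneous sources rarely agree beyond the core fields.
Coordinates are 1-based inclusive; insertions and deletions use the MAF
dash convention for the absent allele. `Tumor_Sample_Barcode` is taken
verbatim — no barcode truncation — and the same sample id appearing in
two cohorts is an error rather than a silent merge, since there is no
defensible automatic reconciliation of conflicting clinical records.

Variant vocabulary: *synonymous* means `Silent`; *nonsynonymous* means
every other coding class, including splice-site SNVs; *indel* means
`Variant_Type` INS or DEL regardless of frame. Unmapped classification
strings become `other` with a warning and are excluded from SNV-based
burden counts. Doublet substitutions (DNP) are counted in neither TMB
statistic: the defining formulas are written in terms of SNVs and indels
only.

## Tumor mutational burden

Two statistics per sample, both over a fixed 30-Mb coding footprint:

- `aTMB = (SNV_total + indel) / 30` — synonymous variants included;
- `fTMB = (SNV_nonsynonymous + indel) / 30` — synonymous excluded.

Filtered-TMB definitions in the literature vary in which class they
drop; we define fTMB as *excluding synonymous* mutations — the only
reading under which the filtered value is at most the total value — and
expose the inverted alternative (keep only synonymous SNVs) behind
`include_synonymous_in_ftmb = TRUE`. The 30-Mb denominator is fixed for
both WES and WGS-coding inputs; capture-region-aware denominators are
out of scope.

## Mutation catalogs and signatures

Catalogs follow the COSMIC channel conventions:

- **SBS-96** — pyrimidine-strand trinucleotide labels `X[R>A]Y`;
  purine-reference substitutions are reverse-complemented, flanks
  included. Strand invariance (`classify(x) == classify(revcomp(x))`) is
  asserted property-style in the test suite.
- **DBS-78** — the canonical reverse-complement-collapsed doublet table,
  hard-coded (it is a convention, not a computation).
- **ID-83** — the COSMIC indel decision tree: 1-bp events by
  pyrimidine-normalised base and homopolymer length, longer events by
  length and tandem-copy count, deletions without a full extra copy but
  with partial flanking homology into the microhomology channels. When a
  full extra repeat copy exists, the repeat channel wins over
  microhomology (the COSMIC tie-break).

Flanking context comes from the MAF's optional context columns or from
the synthetic generator. The package deliberately performs no
reference-genome fetching, which keeps it download-free; context
extraction from a genome is an extension point, not a feature.

### NMF extraction

De-novo signatures are extracted by non-negative matrix factorisation
with the Frobenius objective and multiplicative updates: defaults are 20
random restarts, relative-improvement tolerance 1e-6, at most 2000
iterations, deterministic given a seed. The per-iteration objective is
recorded and asserted non-increasing in the tests. Signatures are
column-normalised to sum to one with the scale pushed into exposures, so
per-sample exposures stay on the mutation-count scale; for well-fit
synthetic catalogs the exposure row sums conserve the catalog row sums
to within 5%.

### Choosing the number of signatures

`select_k()` scores each candidate rank by bootstrap stability: each
restart factorises a Poisson-resampled replicate of the catalog, every
replicate's signatures are matched **one-to-one** (greedy
maximum-cosine assignment) to a reference fit on the original catalog,
and the clustering is scored by mean silhouette width under cosine
distance. Two details matter and were learned the hard way:

- resampling is essential — repeated factorisations of the *identical*
  noisy matrix converge to the same noise-driven components and make any
  rank look stable;
- the one-to-one constraint is essential — nearest-column assignment
  lets the near-duplicate signatures produced when the rank exceeds the
  data rank merge into a single cluster, hiding the degeneracy.

The chosen rank is the largest one with mean silhouette at least 0.8
(configurable); rank 1 is a single perfect cluster by convention.
Reconstruction error per rank is reported alongside for diagnostics.

### Annotation and exposures

Extracted signatures are annotated against a COSMIC-style reference
matrix by maximal cosine similarity; matches below 0.75 are reported as
`novel`. Exposures to a fixed signature set are per-sample nonnegative
least squares (`pracma::lsqnonneg`), with the Euclidean residual
reported. "Enrichment" of a sample in a signature is defined as the
argmax of relative exposure — published analyses often plot survival by
signature "enrichment" without defining it, so this explicit,
reproducible definition is our choice. Signature–clinical association uses two-sided
Fisher exact tests on (dominant vs not) × (binary grouping), with
Benjamini–Hochberg FDR across all performed tests.

## Neoantigen scoring

Inputs are per-sample peptide binding records in the shape of
pVACtools epitope output. Candidates are strong and weak binders; when
`bind_level` is absent it is derived from percent rank at the NetMHC
thresholds (SB ≤ 0.5, WB ≤ 2.0, both configurable). Per candidate
peptide,

`AAscore = log2(W / M)`,

with `W` and `M` the wild-type and mutant binding scores (IC50-like,
lower = stronger). Peptides without a wild-type counterpart (frameshift
products) take the fixed wild-to-mutant ratio 15, i.e. `log2(15) ≈ 3.91`
by default; because the constant can also be read as the score itself
rather than the ratio, `unpaired_mode = "literal"` implements that
alternative. The per-gene `Gscore` is the sum of its candidates'
AAscores; the per-sample tumor neoantigen score TNS is the sum of
Gscores over genes (equivalently, of AAscores over peptides — the
additivity is asserted in the tests); the tumor neoantigen burden TNB is
the candidate count. Peptide identity for the cross-patient sharing
spectrum is the exact mutant peptide string, ignoring the HLA allele
(configurable to peptide–allele pairs).

## Survival analysis

Kaplan–Meier estimation delegates to `survival::survfit`. The two-group
log-rank statistic is computed natively from the O/E/V decomposition
(hypergeometric variance with ties), because the cutpoint scan needs the
standardized statistic at every candidate split; it is cross-checked
against `survival::survdiff` in the tests, and three or more groups are
delegated to `survdiff` directly.

`optimal_cutpoint()` implements maximally selected rank statistics in
the style of survminer's `surv_cutpoint`: every observed score value
whose split keeps at least `minprop = 0.1` (the survminer default) of
samples on each side is a candidate; the candidate maximising the
absolute standardized log-rank statistic wins, ties going to the smaller
value. The high group is `score > cutpoint` — strictly greater, the
usual "high > threshold" convention. The reported p-value at the
selected cutpoint is the **unadjusted** log-rank p, as such analyses
conventionally report it; because maximisation makes it anti-conservative
under the null, the per-candidate table is returned in full and a
Lausen–Schumacher-adjusted p is reported alongside as a diagnostic. No
multiplicity correction is applied to the selected p itself.

## Clinical association

Groupings follow the usual ESCC cohort conventions: T1–T2 vs T3–T4,
TNM S1–S2 vs S3–S4, gender, lymph node metastasis, smoking, drinking,
grade G1–G2 vs G3–G4, three-level tumor location, and two age splits — a
fixed threshold at 60 years and an exact 1-D k-means split. M stage is
never emitted: distant metastases are so rare in resected ESCC cohorts
that the test is never informative. The 1-D k-means is exact:
optimal clusters in one dimension are contiguous in sorted order, so
k = 2 is an exhaustive scan over splits and k > 2 a dynamic program;
equivalence with brute force is asserted in the tests.

Per-gene association with a binary grouping is a two-sided Fisher exact
test on mutated/wild × arm, with BH FDR within the grouping. Genes
mutated in fewer than `min_mutated = 3` tested samples are skipped to
avoid degenerate tables — a floor we chose, documented and configurable.
Both raw p and FDR are reported; `hmg_lmg_classify()` gates on the raw
p-value by default (`use_fdr = TRUE` switches) — p below alpha with a higher
mutation rate in the metastasis arm is HMG, lower is LMG, everything
else none (an exhaustive, exclusive partition).

Pairwise mutual exclusivity among the top `top_n = 25` most mutated
genes uses the same two-sided Fisher machinery on joint mutation status,
classifying significant pairs by odds ratio (< 1 exclusive, > 1
co-occurring), matching the semantics of maftools'
`somaticInteractions`. Driver consensus thresholds external caller
tables at their conventions (driverml p < 0.01; MutSigCV, OncodriveFML,
OncodriveCLUSTL FDR < 0.05) and calls a gene a driver when at least two
tools agree. Running those callers is explicitly out of scope; their
result tables are inputs.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate everything the pipeline
consumes with recorded ground truth. What it emulates, and why the
defaults are what they are:

- **Mutation counts** — negative binomial (mean 129, size 2.5): TMB
  distributions are overdispersed, and these values put the cohort
  median total burden near 3.6/Mb over the fixed 30-Mb footprint, the
  scale of the pooled ESCC cohorts this pipeline targets.
- **Composition** — 24% of SNVs synonymous (echoing the gap between the
  published mean aTMB and fTMB), 8% of mutations indels, 2% doublets,
  70% of indels frameshift.
- **Signatures** — SNV channels drawn from per-sample mixtures of two
  flat, disjoint-support synthetic signatures (C>T block and C>A
  block). Flat blocks carry no internal substructure, so the planted
  truth is exactly rank 2; a peaked design would itself be a mixture and
  make the "true" rank ambiguous. Mixture weights are Dirichlet(0.5):
  sparse exposures — most samples dominated by one process — are both
  the realistic regime and the regime in which NMF is identifiable
  (separability requires near-pure samples). Channels are decoded into
  alleles and flanking bases on a random strand, exercising the
  classifiers' strand invariance.
- **Clinical structure** — male-dominant demographics, smoking raising
  the lymph-node-metastasis odds (OR 2 by default), and planted genes
  whose mutation probability differs between metastasis arms (the
  ground truth for HMG/LMG recovery).
- **Survival** — exponential baseline (median 730 days) with the hazard
  multiplied by 2.5 above the cohort's 60th aTMB percentile and
  administrative censoring at 2000 days; simple, and sufficient to
  exercise log-rank and cutpoint recovery. A lighter generator,
  `simulate_survival_scores()`, plants a hazard step on a standard
  normal score for cutpoint-recovery experiments.
- **Binding tables** — Poisson(0.2) peptide records per nonsynonymous
  mutation (so neoantigen burden tracks nonsilent burden, as observed
  in real cohorts), lognormal percent ranks binned into SB/WB/NB,
  lognormal mutant scores with a lognormal wild/mutant ratio, unpaired
  records for frameshift products, and configurable peptides planted
  into a stated number of patients for sharing-spectrum bookkeeping.

What it does **not** emulate: real genome coordinates, gene lengths and
local mutability, germline contamination, subclonal structure,
signature–clinical correlations beyond the planted genes, and
non-exponential hazards. Passing recovery tests on these cohorts
demonstrates that the estimators recover what was planted under the
stated models — not that the models capture everything in real data.

## Numerical choices and degenerate inputs

- NMF guards divisions with machine epsilon; all-zero catalogs and
  out-of-range ranks are errors; all-zero samples get zero exposures and
  an `NA` dominant signature.
- Constant scores, splits violating `minprop`, and thresholds emptying
  an arm are errors in the cutpoint/dichotomisation code, not silent
  degeneracies.
- Cutpoint ties in |z| resolve to the smaller candidate; 1-D k-means
  never places a boundary between tied values.
- Fisher tests on groupings with an empty arm are skipped and flagged
  rather than fabricated; t-tests require two values per arm.
- The log-rank chi-square approximation is mildly anti-conservative in
  small samples; the test suite checks its size at n = 100 per
  simulation, inside the asymptotic regime the approximation is meant
  for.
- Problem sizes in the test suite are chosen for desk-scale runs:
  signature recovery uses 50 samples × ~2000 mutations, cutpoint
  recovery 100 replicates of n = 300, the null-calibration simulations
  1000 replicates each.

## Known limitations

Contexts must be supplied (no reference-genome lookup); DNPs are outside
both TMB statistics; the Lausen–Schumacher adjustment is an
approximation, reported as a diagnostic only; driver consensus trusts
the external callers' own statistics; and the pipeline's signature
stage extracts one catalog kind per run (SBS-96 by default) — DBS-78 and
ID-83 catalogs are built with the same functions but orchestrated by the
user.
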