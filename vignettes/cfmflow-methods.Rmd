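---
title: "Methods: contaminant-controlled detection of cell-free microbial DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contaminant-controlled detection of cell-free microbial DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plasma contains very little microbial DNA. A 16S rRNA gene library prepared
from plasma yields read counts comparable to those of its DNA-extraction
negative controls (DENCs), and most of what it sequences is reagent-derived
contaminant DNA (the "kitome"). Contaminants are introduced per extraction
kit unit, so they track DNA-extraction batch (DEB), extraction day and
sequencing run; naive analyses then discover "biology" that is really batch
structure. `cfmflow` implements a decontamination framework that exploits
three properties genuine cell-free microbial DNA (cfmDNA) should have and
reagent DNA should not:

* its abundance does not follow technical batch variables;
* it is detected more consistently in true samples than in pure-water
  controls;
* it is re-detected when the same patient's sample is extracted again in a
  different batch.

A fourth, knowledge-based filter removes taxa that are documented reagent
contaminants and keeps taxa with documented commensal or pathogen biology.

# Data model

An `asv_table` is a non-negative integer matrix (ASV × sample). A
`study_design` carries per-sample factors with validated nesting: extraction
day within DEB within sequencing run, and replicate groups that link one
patient's re-extractions across exactly two batches. Taxonomy is an ordered
six-rank lineage (domain … genus); empty ranks may only trail named ones.

# Preprocessing

1. ASVs whose lineage names eukaryota, mitochondria or chloroplast at any
   rank are removed (off-target amplification).
2. PCR replicates of one biological sample are merged by summing counts.
3. Within each sample-type stratum, an ASV below 0.01 % of the stratum's
   reads is zeroed there (strictly below; an ASV can stay in one stratum and
   be removed from another). The floor (0.01 %) is distinct from the
   abundance *classes* used in reporting (low < 0.1 %, medium 0.1–1 %,
   high > 1 % of mean plasma relative abundance).
4. Comparative diversity analyses rarefy to even depth first. Rarefaction is
   a multivariate-hypergeometric subsample without replacement, seeded per
   (global seed, sample id) so per-sample draws do not depend on column
   order. Counts for the batch screen (criterion i) and prevalence screen
   (criterion ii) are *not* rarefied.

# Diversity and community structure

Alpha diversity: richness (observed ASVs) and inverse Simpson `1/Σp²`.
Beta diversity: Bray–Curtis on rarefied, square-root-transformed counts
(the transform is a documented preset, not hard-wired), and the Aitchison
distance — Euclidean distance of centred log-ratio (CLR) vectors of
`counts + 1` on non-rarefied counts — to respect the compositional nature of
the data. UPGMA (unweighted average linkage) gives ultrametric dendrograms;
ties in the minimal inter-cluster distance are broken by the lexicographic
order of the smaller cluster's first leaf so results are reproducible.

PERMANOVA partitions the Gower-centred inner-product matrix
`G = −½CAC` (A = squared dissimilarities) by sequential (Type I)
projections in the user's term order, as the classical `adonis` convention
does; interactions enter after their main effects. The p-value counts
permuted pseudo-F values at least as large as the observed one, with the
identity permutation always in the null set:
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so `p ≥ 1/(n_perm + 1)`. For repeated
measurements (patients extracted in two DEBs), the repeated-measures-aware
variant draws permutations that shuffle labels only within each subject
block; with blocks of size one only the identity permutation exists and
p = 1. Ties with the observed statistic count as exceedances (conservative).

# Criterion (i): batch differential abundance

Library sizes are normalised by trimmed-mean-of-M-values (TMM): per sample,
a doubly trimmed (30 % by M, 5 % by A), inverse-asymptotic-variance-weighted
mean of log2 ratios against a reference sample, rescaled to geometric mean
one. Counts become `log2` CPM with a 0.5 prior over TMM-effective library
sizes. The per-ASV residual sqrt-standard-deviation is smoothed against mean
log-CPM (lowess, span 0.5) and observation weights are the inverse of the
predicted variance at each observation's fitted scale. Because extraction
day is nested in DEB and DEB in run, the linear model has day as its only
factor and all technical variables are tested as contrasts of day means:
every DEB pair, every run pair, and day pairs *within* a DEB only.

Two aspects deserve note:

* **Sparsity.** Zero-heavy ASVs understate their variance: an all-zero
  design group contributes residuals of exactly zero. ASVs detected in
  fewer than three samples are excluded from trend fitting (they would drag
  the trend to the floor), and each ASV's residual df is reduced by its
  number of all-zero design groups before empirical-Bayes shrinkage.
* **Shrinkage.** The prior `(d₀, s₀²)` is estimated by moment matching of
  `log s²` against its scaled-F sampling theory (digamma/trigamma
  corrections, trigamma inverse by Newton iteration); if the moment
  estimator is infeasible the prior degenerates to `d₀ = ∞` with
  `s₀² = mean(s²)`. Moderated t uses `d₀ + d` degrees of freedom. Setting
  `d₀ = 0` recovers the ordinary weighted-least-squares t exactly, which
  the tests verify against an independent `lm(weights=)` oracle.

When patients recur across batches, a consensus within-patient residual
correlation is estimated per ASV, pooled by a 15 %-trimmed mean on Fisher's
z scale, and incorporated through generalised least squares with a
block-equicorrelated covariance.

BH adjustment pools, per technical variable, all of that variable's
contrasts across all ASVs into one family — the simplest choice consistent
with "adjusted per variable", and stricter than per-contrast families. An
ASV with FDR ≤ 0.05 in any contrast of any variable is batch-affected.
DENCs are excluded from the model by default (the criterion asks whether
abundance among *plasma* samples follows technical variables); a
configuration switch can include them.

# Criterion (ii): prevalence against negative controls

For each DEB independently, the ASV's presence/absence counts in plasma vs
plasma-DENCs form a 2×2 table. The score is the chi-square (1 df, no
continuity correction) two-sided tail probability folded to one side: `t/2`
when the control prevalence fraction exceeds the sample fraction, `1 − t/2`
otherwise, so that *small scores mean contaminant-like*. When any expected
cell is below 5 or the total below 20, the one-sided hypergeometric tail of
seeing at least the observed control presences replaces it (the exact
analogue of the same orientation). Batches where the ASV never occurs, and
batches without controls, contribute no score. Per-batch scores combine by
their plain minimum — one control-dominated batch is enough to condemn an
ASV — and classification uses a strict `combined < 0.55` threshold.

# Criterion (iii): replicate-extraction agreement

For the batch pair linked by replicate groups, detection (≥ 1 read) of each
ASV is compared across each patient's matched pair. Cohen's kappa
`κ = (p_o − p_e)/(1 − p_e)` is tested with the large-sample null standard
error of Fleiss; p is two-sided (the direction of agreement is not assumed).
The criterion passes with κ > 0.4 and p < 0.05, thresholds strict as
written. Applicability follows the wider reading of the framework: the
criterion is evaluated for every ASV *observed* in the replicated batches
(not only those exclusive to them); ASVs never seen there are judged on the
other criteria alone, and degenerate tables (chance agreement 1, e.g.
detected in every pair) are marked not applicable.

# Criterion (iv): taxonomy evidence

The consensus lineage of two classifications is their deepest agreeing rank
prefix (case-insensitive, bracketed synonyms normalised). Matching against
the contaminant blocklist and the commensal/pathogen evidence list is exact
on normalised names, at genus first then family — no fuzzy matching, so
every hit is auditable. The 2×3 category scheme crosses blocklist
membership with evidence status; "likely contaminant" (blocklisted, no
evidence) and "no evidence" (classifiable at family/genus, matching
neither list) are discarded; lineages resolvable only above family rank are
kept as potentially novel. The six labels are configurable; the discard
rule is the contract.

# ddPCR quantification and group tests

A reaction with `k` positive of `n` droplets has
`λ = −ln(1 − k/n)` mean template molecules per droplet and concentration
`λ / v_d` copies/µl with droplet volume `v_d = 8.5 × 10⁻⁴` µl — the
platform's nominal partition volume, configurable since it rescales every
concentration. Copies per ml of source fluid are
`conc × elution volume (µl) / source volume (ml)`, by default 50 µl eluate
from 2 ml plasma. Detection requires ≥ 2 template molecules summed across
duplicate reactions (at the relevant dilutions, molecules and positive
droplets coincide). Saturated reactions (`k = n`) return the `k = n − 1`
value as a flagged lower bound.

Group differences in concentration or alpha diversity use Gaussian
generalised estimating equations with an exchangeable working correlation
over patients (sample type, DEB and their interaction as terms), robust
sandwich standard errors, and Wald tests of user-specified linear
hypotheses. With singleton clusters or an independence working correlation,
the estimates equal ordinary least squares, which the tests assert.

# The synthetic cohort generator

The generator exists so the whole framework can be exercised with known
ground truth. Its default configuration encodes the study design the
framework targets: five DEBs of 12 plasma samples and 8 DENCs, the second
batch a replicate extraction of the first batch's patients, two sequencing
runs (batches 1–2 and 3–5), two extraction days per batch, 120 shared and
80 batch-specific contaminant ASVs, 20 true ASVs, and log-normal depth
around 40,000 reads.

Choices made once, with their reasoning:

* **Kitome abundance distribution**: log-normal with `sdlog = 3`. Real
  low-biomass kitomes are heavy-tailed — a few taxa dominate and most ASVs
  are rare; this setting puts roughly 80–90 % of ASVs in the < 0.1 %
  abundance class, matching the abundance-class structure reported for
  plasma cohorts.
* **Batch effects**: shared contaminants get per-batch log-normal
  multipliers with `sdlog = 1` (typical 2–4-fold between-batch changes),
  reproducing the DEB-dominated clustering seen in real plasma data;
  batch-specific contaminants occur only in their batch's samples *and its
  DENCs*.
* **Contaminant suppression in true samples** (`contaminant_plasma_dropout
  = 0.3`): each contaminant is independently undetectable in a given plasma
  extraction with probability 0.3, while DENCs always receive the full
  kitome. Genuine DNA competes with trace reagent DNA during amplification
  — the same phenomenon that makes contaminant proportion rise along a
  target dilution series — and it is the asymmetry that prevalence-based
  scoring fundamentally requires. A perfectly symmetric kitome would make
  criterion (ii) undecidable by construction.
* **True signal**: each true ASV is carried by half the patients (carriage
  is a patient property), at a relative abundance drawn log-uniformly from
  0.1–1 %, never in DENCs, and re-detected in the replicate batch minus a
  10 % dropout. Patient-level carriage means replicate extractions agree
  (high kappa) while per-batch carriage fractions vary binomially — the
  honest noise floor for criterion (i).
* Reads are multinomial at log-normal depth; a negative-binomial generator
  (`simulate_nb_counts`) provides overdispersed single-factor designs for
  error-control and power studies of the batch screen.

What the generator does *not* emulate: taxonomic correlation structure
(phylogenetically clustered contaminants), compositional interactions
beyond renormalisation, index hopping or cross-talk between samples,
sequencing error or chimeras (the pipeline consumes denoised ASV tables),
and DNA-concentration-dependent contaminant fractions within one cohort.
Passing recovery tests therefore demonstrates that the statistical
machinery discriminates the planted structure — not that any particular
real cohort will reach the same sensitivity.

# Numerical conventions

* All randomness flows from explicit integer seeds; sub-seeds stay below
  2³¹. User RNG state is saved and restored around internal draws.
* Permutation p-values include the identity permutation; ties count as
  exceedances.
* Thresholds follow their stated inequalities exactly: abundance floor
  strictly below; prevalence classification strictly below 0.55; kappa
  strictly above 0.4 with p strictly below 0.05; FDR flag at ≤ 0.05.
* UPGMA ties and all report orderings are lexicographic; pipeline outputs
  are byte-deterministic for fixed inputs and seed.
* The chi-square/Fisher switch in criterion (ii) triggers when any expected
  cell is < 5 or the total is < 20 (the conventional validity rule, since
  "few samples" is otherwise undefined).
* Degenerate inputs fail loudly: zero library sizes, strata without reads,
  saturated ddPCR wells, singular designs and single-level factors raise
  errors or flagged warnings rather than silently degrading.

# Validation strategy and problem sizes

The test suite checks every statistic against an independent oracle:
kappa against the exhaustive 2×2 formula for all tables with n ≤ 20;
the prevalence score against brute-force hypergeometric tails for all
tables with totals ≤ 30; moderated t with `d₀ = 0` against `lm` with
weights; TMM against `edgeR::calcNormFactors`; the moderated pipeline
against `limma::voom`/`eBayes`; PERMANOVA against `vegan::adonis2` and an
exact enumeration of 3-vs-3 assignments; blocked permutations against a
10⁴-draw block-integrity sweep; GEE against OLS limits and
parameter-recovery simulations. Error-control studies use 500-replicate
permutation nulls (12 samples, 99 permutations) and 20-seed
negative-binomial nulls (500 ASVs × 3 batches × 12 samples); end-to-end
recovery uses the default cohort (220 ASVs × 100 samples). These sizes keep
the full suite under a few minutes on one CPU while leaving Monte-Carlo
bands (±3 s.e.) tight enough to detect calibration failures.

# Known limitations

* Criterion (i) is a conservative screen: with many contrasts and a family
  saturated by genuine batch effects, the BH threshold is liberal, and
  sparse ASVs whose carriage fraction happens to differ between batches can
  be flagged without a systematic batch effect. This is inherent to
  "flag if significant anywhere" screens.
* Criterion (ii) cannot condemn an ASV present in every sample and every
  control (the sparse-table tail is 1 by construction); such ubiquitous
  contaminants are left to criteria (i), (iii) and (iv).
* The GEE implementation covers the Gaussian family with
  exchangeable/independence working correlation only, matching its use for
  concentrations and alpha diversity.
* Criterion (iv) is only as good as its lists; the packaged lists are
  synthetic stand-ins matched to the simulator's name pools, and real
  analyses must supply curated ones.
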