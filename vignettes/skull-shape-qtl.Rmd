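---
title: "From skull landmarks to candidate causal variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From skull landmarks to candidate causal variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

skullqtl implements the full inference chain used to map a large-effect
craniofacial QTL in dogs: landmark morphometrics produce allometry-corrected
shape phenotypes; a kinship-aware mixed model scans the genome; phased
haplotypes of the most extreme (brachycephalic) animals define a critical
interval by recombination counting; and identity-by-descent logic filters
resequencing variants inside that interval down to a handful of candidates,
whose phenotypic and transcriptional effects are then modelled. This
vignette explains each model, the tunable parameters, the synthetic-data
generator used for validation, and the design decisions taken where the
procedure was genuinely under-determined.

## Morphometrics

**Generalized Procrustes analysis.** Configurations of k landmarks in d
dimensions (d = 2 or 3) are superimposed by iterating three steps: centre
each configuration and scale it to unit centroid size (the square root of
summed squared deviations of landmarks from their centroid); rotate each
onto the current consensus using the proper-rotation solution of the
cross-covariance SVD (determinant +1, so reflections are never introduced);
and update the consensus as the re-normalised mean. Iteration stops when
the consensus moves less than `tol` (default 1e-10 in root-summed-squared
coordinates, typically 3-6 iterations). Pre-alignment centroid sizes are
retained: the neurocranium centroid size is the pipeline's body-size proxy.

Two refinements make the output fully deterministic. Initialisation uses
the plain mean of the scaled configurations (not an arbitrary reference
specimen), and the converged solution is rotated so the consensus
principal axes coincide with the coordinate axes with deterministic signs.
Without this canonicalisation GPA output is only defined up to a global
rotation; with it, alignment is invariant (to 1e-8) under permutation of
specimens and under arbitrary similarity transforms of any input.

**Allometric correction.** Shape depends strongly on size in a species
whose size range exceeds 40-fold, so aligned shape coordinates are
regressed on a size predictor (by default an external vector — in the
standard analysis the *neurocranium* centroid size, deliberately not the
substructure's own size). The percentage of pooled shape variance
explained is tested by permutation of the predictor across specimens
(default 10,000 permutations, seed mandatory;
p = (1 + #{perm ≥ obs}) / (n_perm + 1)). The predictor is used as given —
no log transform is applied by the package; callers can pass log sizes if
they prefer. Note a structural subtlety validated in the tests: if the
generative allometry is log-linear in size, a linear fit on raw size
removes it only approximately, and in small samples a chance correlation
between size and genotype lets the fitted slope absorb a little of the QTL
signal. This is a property of the published procedure itself, not of the
implementation.

**Shape PCA.** The covariance matrix of the regression residuals is
decomposed (via SVD of the centred residual matrix, which is numerically
equivalent and stabler than forming the covariance explicitly). Component
signs are fixed by making the largest-magnitude loading element positive;
`orient_pc()` then flips a component so a designated reference group (the
brachycephalic animals) scores negative, matching the field convention
that short, broad rostra sit at negative PC1. Descriptions of this
procedure sometimes speak of decomposing a distance matrix where a
covariance matrix was computed; this package implements covariance PCA,
the interpretation consistent with reported percent-variance figures.

An optional object-symmetry step (`symmetrize_landmarks()`) reflects,
relabels via a left/right pairing map, re-superimposes and averages. It is
off by default because pairing maps are rarely published; all results here
use asymmetric configurations.

## Mixed-model association scan

The scan fits, marker by marker, y = Wα + xβ + u + ε with u ~ (0, σ²g K)
and ε ~ (0, σ²e I). K is the centred genomic relationship matrix
ZZᵀ/m (Z the column-centred dosage matrix) — the default kinship of the
standard mixed-model GWAS tools; residual missing dosages are mean-imputed
per marker. K is eigendecomposed once, the model is rotated to diagonal
covariance, and for each marker the variance ratio λ = σ²g/σ²e is profiled
by 1-D REML optimisation (Brent search on log λ over [1e-5, 1e5], relative
tolerance 1e-6), followed by a Wald t test of β. This is exact per-marker
optimisation, not re-use of a null variance ratio. REML and the Wald test
are the conventional defaults where the original tooling does not state
its settings. When K = I the machinery collapses algebraically to ordinary
least squares; the tests verify agreement with `lm()` at 1e-6 and the
suite's null calibration (polygenic phenotypes drawn from K) checks
type-I error 0.05 ± 0.013 at α = 0.05 and genomic inflation λ ∈ [0.9, 1.1].

Scan QC mirrors standard practice: genomic inflation is the median
1-df chi-square quantile of the p-values over 0.4549364; the significance
threshold is Bonferroni (with 139,260 tests, −log10(0.05/139,260) = 6.44,
p ≈ 3.6 × 10⁻⁷). Covariates are an intercept plus caller-chosen columns —
typically sex and up to ten genotype principal components (eigenvectors of
K scaled by root eigenvalue); the component count is a configuration knob,
not hard-coded. After a scan, `ld_prune_rescan()` removes each
chromosome's index SNP and all markers with r² > 0.2 to it (strict
inequality) so a re-scan can confirm that no residual stratification
remains.

On the default synthetic study the scan's λ deflates to ~0.65: the
kinship matrix is estimated from only 1,000 markers that include the
strong causal block, so the random effect over-absorbs (proximal
contamination). At real panel sizes (139k markers) this effect is small —
the published λ range is 0.954-1.000 — and the null-calibration suite,
where no causal marker exists, recovers λ ≈ 1.

## Haplotype fine mapping

**Sliding windows.** Ten-marker windows step across the region; within a
window, distinct haplotypes among all chromosome copies are enumerated,
haplotypes carried by fewer than 5 copies are pooled into a "rare" class
(an omnibus test needs a rare-class policy; the source procedure does not
state its test, so one-way ANOVA with pooling is the documented stand-in),
and the per-copy phenotype (each animal contributing its value once per
chromosome copy) is compared across classes by one-way ANOVA.

**Cases, consensus, interval.** Cases are animals with oriented
viscerocranium PC1 at or below −0.2 — the threshold is stated variously as
≤ and < in the source material, so the rule is configurable with `"le"`
as default. The consensus haplotype is the per-marker majority allele over
case chromosome copies (ties break toward the copy with the most negative
phenotype). For the critical interval, each case copy is reduced to its
maximal consensus-matching run containing the index SNP; copies that
mismatch at the index itself are non-carriers and are excluded and
reported (the "variant haplotype" homozygotes of the original analysis).
Walking outward from the index, each boundary is the first inter-marker
gap at which the cumulative count of distinct recombinant *copies* (not
animals — chromosomes are the natural unit) reaches `min_recomb` = 3 per
side; requiring the count per side, rather than in total, is the stricter
reading and is adopted. The interval spans the markers strictly inside
the two boundary gaps, and its length uses the end − start convention
(56,037,676 − 55,850,299 = 187,377 bp, the published arithmetic). If a
side never accumulates enough breakpoints the interval runs to the panel
edge and is flagged rather than failing.

**Core haplotype and carriers.** The published 12-SNP haplotype is not
accompanied by a selection rule, so the core haplotype is defined as the
consensus restricted to interval markers that are themselves strongly
associated: single-marker p below the scan threshold, or r² with the
index above the pruning threshold (0.2). A chromosome copy is a carrier
iff it matches the core at every defining marker; frequencies are reported
per phenotype group as exact count ratios rendered to one decimal
(63/74 → 85.1%), and carrier-bearing versus carrier-free animals are
compared by a two-sided Student's t test.

## Identity-by-descent variant filtering

Five assumptions drive the filter: (1) haplotype-homozygous cases carry
the causal variant; (2) identity-by-descent means they are *fixed* for the
same allele; (3) because the reference assembly derives from a
haplotype-fixed brachycephalic breed, the causal allele may be the
REFERENCE allele; (4) the causal variant is derived, hence absent from
wild canids; (5) haplotype-free dolichocephalic controls cannot carry it.
Operationally: a record's candidate allele is the single allele for which
every non-missing case sample is homozygous (REF or ALT); the record is
eliminated if any non-missing wild or control sample carries that allele
(het or hom). Missing genotypes are non-informative — absence of a call at
14-33× coverage must not count as absence of the allele — so they never
eliminate a record; a `strict` mode additionally requires at least one
informative wild and control call. Eliminations are tallied by first
failing rule in the fixed order; multi-allelic sites are represented as
one biallelic record per ALT. Surviving variants are checked for complete
pairwise LD of carrier status (r² = 1 within 1e-9) over an extended
cohort. Conservation-based ranking of survivors is out of scope (it needs
external alignments); survivors are reported unranked.

## Effect modelling

Per-genotype-class comparisons (homozygous ancestral / heterozygous /
homozygous derived) use two-sided Mann-Whitney-Wilcoxon and
Kolmogorov-Smirnov tests; the MWW null is exact for combined n ≤ 20
(closed-form Wilcoxon distribution without ties, exhaustive enumeration
with ties) and a tie-corrected normal approximation above; the additive
trend is a linear regression on dosage. Per-locus
proportion-of-variance-explained is the raw R² of the single-predictor
model times 100 — these are maximum potential contributions and are not
additive — while the joint model is built by forward stepwise selection
under AIC (BIC and adjusted R² are options; "stepwise" alone does not pin
down a criterion, and AIC is the conventional default). Expression ratios
use the efficiency-corrected (Pfaffl) formula with per-assay efficiencies
in (1, 2]; allelic-imbalance counts become integer percentage pairs by
largest-remainder rounding so printed pairs always total 100; cryptic
splice-acceptor scanning reports the dinucleotide preceding each observed
junction (AG being the near-invariant mammalian acceptor context) and
enumerates all AG-preceded positions; and `naive_fold_change()` is a
deliberately transparent median-of-ratios-normalised group mean ratio —
a descriptive summary, not a dispersion-modelled differential-expression
method, and labelled as such.

## The synthetic-data generator

`simulate_study()` produces cohorts with known ground truth that exhibit
the statistical structure every downstream stage assumes:

* **Breed structure.** Balding-Nichols allele frequencies: per LD block an
  ancestral frequency ~ Uniform(0.1, 0.9) and per-breed frequencies from
  the beta model with variance scaled by `fst` (default 0.15, a typical
  between-breed divergence). Blocks of `ld_block_len` (default 10) markers
  are built from two complementary founder haplotypes copied with a 1%
  per-marker mutation rate — enough to generate realistic r² structure and
  recombination-like breakpoints without a coalescent simulator.
* **The planted haplotype.** A contiguous run of 12 markers carries the
  causal haplotype at frequency 0.90 on case-breed chromosomes and 0.03
  elsewhere, emulating the observed 85.1% vs 4.2% carrier chromosomes;
  case breeds are ~15% of breeds, matching the cohort's brachycephalic
  share. The run's markers are modelled as the haplotype's own tag
  variants: derived allele on the IBD segment, sporadic background
  frequency Uniform(0.01, 0.08) per marker. This matters: if the planted
  pattern were a random background pattern, background chromosomes would
  match the consensus at the index by chance and generate spurious
  breakpoints inside the run, which is not how tag SNPs of a derived
  haplotype behave.
* **Landmarks.** Specimen i is s·R(M + log(s)·a·A + d·q·V + E) + t: a fixed
  unit-centroid-size template M; a unit allometry direction A with slope
  `allometry_slope` (default 0.3 shape units per log-size unit);
  a unit QTL direction V confined to the viscerocranium mask with effect
  `qtl_effect` (default 0.15 shape units per derived allele — a
  large-effect locus, as in the motivating study where this locus alone
  explains ~36% of facial variation); iid Gaussian noise (`noise_sd`
  0.01); and random rotation (uniform, det +1), translation and log-normal
  scale so the Procrustes fit is genuinely exercised. With these defaults
  homozygous-derived animals land below oriented PC1 = −0.2, so the
  study's case-selection rule applies unchanged. Substructure masks follow
  the published 18:25:30 neurocranium:viscerocranium:mandible proportions.
* **Variant tables.** Exactly the requested number of planted records
  satisfy all five filtering assumptions (including at least one whose
  candidate is the REFERENCE allele); every other record violates at least
  one rule, with violations cycled across case-fixation, case-concordance,
  wild-carrier, control-carrier and all-case-missing classes. Wild-canid
  genotypes never carry planted candidate alleles, satisfying the
  derived-variant assumption by construction.

What the generator does *not* emulate: coalescent LD decay (blocks are
exchangeable, so there is no r² continuum into the flanks and no
recombination map), genotyping or phasing error, imputation artefacts,
sequencing reads, and breed-specific morphological covariance beyond the
single allometry axis. Passing tests therefore demonstrate correctness of
the inference machinery under the stated generative model — recovery of
planted truth, calibration under the null — not robustness to every
pathology of real array and resequencing data.

## Numerical choices and degenerate inputs

Rotation solving is constrained to det +1 throughout (no reflections).
Degenerate landmark configurations (all points identical) are rejected at
construction. Monomorphic markers get missing p-values rather than
failures; monomorphic survivors in the LD check are marked
not-assessable. Consensus ties break toward the most-affected copy.
PCA retains components above a relative singular-value floor of 1e-12.
The REML search interval [1e-5, 1e5] covers heritabilities from ~0 to ~1
at the panel sizes used. Exact-test enumeration switches to the normal
approximation above combined n = 20 (the classical boundary).

## Problem sizes used for validation

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in about a minute: the published-arithmetic checks are
exact; null calibration uses 200 animals × 2,000 markers with polygenic
phenotypes; end-to-end recovery uses 50 studies of 150 dogs × 300 markers
with the default effect sizes (the acceptance script reports 20);
variance-explained recovery uses 30 replicates at the cohort size of 374;
and the analysis drivers under `analysis/` run one full default-sized
study (374 dogs, 1,000 markers, 10,000 allometry permutations)
end to end.

## Known limitations

The package consumes called, phased genotypes and called variant tables:
phasing, imputation, variant calling and annotation are explicitly out of
scope. The sliding-window test statistic and the core-haplotype selection
rule are documented reconstructions of under-specified steps. λ estimates
on small synthetic panels deflate for the structural reason described
above. `naive_fold_change()` is not a substitute for a dispersion-modelled
differential-expression analysis.
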