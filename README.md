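# skullqtl

Mapping the genetics of skull shape in dogs — from raw landmark
coordinates to a short list of candidate causal variants — in one tested R
package. It is aimed at quantitative geneticists and morphometricians who
work with cohorts of individually phenotyped and genotyped animals and
want the complete inference chain, plus a synthetic-study generator with
known ground truth to validate every stage.

The pipeline implements, end to end:

1. **Morphometrics** — generalized Procrustes superimposition of landmark
   configurations (centroid sizes `CS = sqrt(Σᵢ ‖xᵢ − x̄‖²)` as the size
   phenotype), multivariate regression of shape on size to remove
   allometry (permutation-tested), and PCA of the residuals. Oriented
   viscerocranium PC1 is the brachycephaly phenotype: short, broad rostra
   score negative.
2. **Association** — per-marker linear mixed models
   `y = Wα + xβ + u + ε`, `u ~ N(0, σ²g K)`, with the centred genomic
   relationship matrix `K = ZZᵀ/m`, exact per-marker REML profiling of
   `σ²g/σ²e` after a single eigendecomposition of `K`, Wald tests, genomic
   inflation λ, Bonferroni thresholds, and LD pruning (r² > 0.2) with
   re-scan.
3. **Fine mapping** — ten-SNP sliding-window haplotype ANOVA, consensus
   haplotype over case chromosomes (PC1 ≤ −0.2), and a critical interval
   bounded where at least three case chromosomes recombine on each side
   of the index SNP; carrier statistics per chromosome group.
4. **Variant filtering** — the five identity-by-descent assumptions:
   haplotype-homozygous cases are fixed for a shared candidate allele
   (which may be the *reference* allele, the assembly being derived from a
   haplotype-fixed breed), wild canids and haplotype-free controls must
   not carry it; survivors checked for complete pairwise LD.
5. **Effect modelling** — genotype-class tests (exact Mann-Whitney-
   Wilcoxon, Kolmogorov-Smirnov, additive trend), single-locus and
   forward-stepwise proportion of variance explained, efficiency-corrected
   (Pfaffl) expression ratios, allelic-imbalance percentage ratios,
   cryptic splice-acceptor (AG) scanning, and a naive median-of-ratios
   fold change.

The methods vignette (`vignettes/skull-shape-qtl.Rmd`) documents every
model, default and design decision.

## Worked example

The `analysis/` directory holds the numbered drivers of the full study;
run them in order from the repository root. Abridged output of an actual
run (fixed study seed):

```sh
$ Rscript analysis/01_simulate.R
Simulated 374 dogs across 12 breeds; 1000 markers with a 12-marker causal
haplotype at markers 495-506
Causal dosage distribution: 0=285 1=34 2=55

$ Rscript analysis/02_morphometrics.R
Allometry: size predicts 9.4% of viscerocranium shape variance (permutation p = 0.0001, 10000 permutations)
Shape PCA: PC1 carries 66.4%, PC2 2.9% of residual variance
Oriented PC1 means by causal dosage: d0=0.094 d1=-0.177 d2=-0.380
|cor(PC1, causal dosage)| = 0.988

$ Rscript analysis/03_gwas.R
Index SNP snp00502 at 1:56002000 (p = 8.39e-155); lambda = 0.646; -log10 threshold = 4.30

$ Rscript analysis/04_finemap.R
60 brachycephalic-type cases (PC1 <= -0.2) of 374 dogs
critical_interval: 1:55988000-56010000 (22,000 bp), defined by 51 left / 54 right recombinant copies
Core associated haplotype: 12 SNPs within the interval
  case: 115 of 120 chromosomes (95.8%)
  control: 29 of 628 chromosomes (4.6%)

$ Rscript analysis/05_varfilter.R
  Pre-filtering       3,674        162
  Post-filtering          4          1
Survivors in complete pairwise LD: TRUE (min r2 = 1.000)

$ Rscript analysis/06_effects.R
Additive trend: -0.241 PC1 units per derived allele (p = 4.19e-301)
  selected (AIC): smoc2_line1; joint PVE = 97.5%
Allele percentile ratios: ancestral het 46:54; insertion het 75:25
Naive RNA-seq fold change (non-carrier / carrier) at the target gene: 3.15
```

Reading the numbers: the planted 12-marker haplotype sits at markers
495–506; after Procrustes alignment and allometric correction, oriented
PC1 tracks the causal dosage almost perfectly (|r| = 0.988), the scan's
index SNP lands inside the planted run, the recombination-count interval
recovers exactly the planted region, and the five-rule filter reduces
3,674 + 162 variant records to the 4 + 1 planted candidates. The deflated
λ on this panel is expected — the kinship matrix is estimated from only
1,000 markers that include the causal block (see the vignette).

Every stage is also available programmatically; `run_study_pipeline()`
chains simulation through carrier statistics in one call.

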