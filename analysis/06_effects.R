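#!/usr/bin/env Rscript

# Stage 6: downstream effect modelling of the candidate insertion.
# Genotype-class tests of PC1 by causal dosage, stepwise
# proportion-of-variance-explained against decoy loci, efficiency-corrected
# qPCR-style expression ratios, allelic-imbalance ratios, cryptic
# splice-acceptor scanning and a naive RNA-seq fold change.

suppressMessages(library(skullqtl))

seed <- 20170605L
pheno <- utils::read.delim("results/phenotypes.tsv")
truth <- jsonlite::read_json("results/simdata/truth.json", simplifyVector = TRUE)
pc1 <- pheno$viscerocranium_pc1
dosage <- truth$causal_dosage

## genotype-class distribution tests (AA vs AD vs DD) and additive trend
gt <- genotype_class_tests(pc1, dosage)
cat("Genotype-class tests on viscerocranium PC1:\n")
print(cbind(gt$pairs[, 1:2],
            mww_p = signif(gt$pairs$mww_p, 3),
            ks_p = signif(gt$pairs$ks_p, 3)))
cat(sprintf("Additive trend: %.3f PC1 units per derived allele (p = %.3g)\n",
            gt$trend$slope, gt$trend$p.value))

## stepwise PVE: the causal dosage plus four decoy loci
set.seed(seed)
n <- length(pc1)
X <- cbind(smoc2_line1 = dosage,
           decoy_cfa30 = rbinom(n, 2, 0.3),
           decoy_bmp3 = rbinom(n, 2, 0.2),
           decoy_igf1 = rbinom(n, 2, 0.4),
           decoy_stc2 = rbinom(n, 2, 0.25))
pve <- stepwise_pve(pc1, X)
print(pve)

## efficiency-corrected expression ratios at both transcript ends
eff <- c(target = 1.92, ref = 1.87)
ratios <- vapply(c(AA = 0, AD = 1.2, DD = 2.4), function(shift)
  pfaffl_ratio(25 + shift, 25, 22, 22, eff["target"], eff["ref"]), numeric(1))
cat(sprintf("Relative expression by genotype (Pfaffl, calibrator = AA): AA=%.2f AD=%.2f DD=%.2f (~%.1f-fold reduction in DD)\n",
            ratios["AA"], ratios["AD"], ratios["DD"], 1 / ratios["DD"]))

## allelic imbalance at the exon-8 C/T reporter SNP
anc <- simulate_ase_counts(100000, 0.46, seed = seed)
het <- simulate_ase_counts(100000, 0.75, seed = seed + 1L)
r_anc <- allele_ratio(anc["a"], anc["b"])
r_het <- allele_ratio(het["a"], het["b"])
cat(sprintf("Allele percentile ratios: ancestral het %d:%d; insertion het %d:%d\n",
            r_anc[1], r_anc[2], r_het[1], r_het[2]))

## cryptic splice acceptors in a synthetic intron-8-like sequence
set.seed(seed + 2L)
intron <- paste(sample(c("A", "C", "G", "T"), 400, TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
# the observed isoform junctions all sit at AG-preceded positions
junctions <- sort(sample(scan_acceptor_sites(intron)$candidate_acceptors, 3))
sc <- scan_acceptor_sites(intron, junctions)
cat(sprintf("Splice scan: %d/%d observed junctions AG-preceded; %d candidate acceptor positions in %d nt\n",
            sum(sc$junctions$is_ag), nrow(sc$junctions),
            length(sc$candidate_acceptors), nchar(intron)))

## naive fold change with a planted ~3.1-fold reduction in carriers
set.seed(seed + 3L)
mu <- runif(200, 50, 500)
mu_non <- mu; mu_non[1] <- mu[1] * 3.1
carr <- sapply(1:3, function(i) rpois(200, mu))
nonc <- sapply(1:3, function(i) rpois(200, mu_non))
fc <- naive_fold_change(carr, nonc)
cat(sprintf("Naive RNA-seq fold change (non-carrier / carrier) at the target gene: %.2f\n",
            fc[1]))

jsonlite::write_json(
  list(trend_slope = gt$trend$slope, trend_p = gt$trend$p.value,
       pve_single = as.list(round(pve$single, 1)), pve_joint = pve$joint,
       expression_ratio_DD = unname(ratios["DD"]),
       ase_ancestral = as.list(r_anc), ase_insertion_het = as.list(r_het),
       fold_change = unname(fc[1])),
  "results/effects.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/effects.json\n")
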