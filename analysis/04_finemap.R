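#!/usr/bin/env Rscript

# Stage 4: haplotype fine mapping.  Ten-SNP sliding-window association
# around the index SNP, case selection at oriented PC1 <= -0.2, consensus
# haplotype over case chromosomes, critical interval bounded by >= 3
# recombinant chromosomes per side, the core associated haplotype within
# it, and carrier statistics.

suppressMessages(library(skullqtl))

panel <- read_phased_vcf("results/simdata/phased.vcf")
pheno <- utils::read.delim("results/phenotypes.tsv")
scan_df <- utils::read.delim("results/scan.tsv")
qcj <- jsonlite::read_json("results/scan_qc.json", simplifyVector = TRUE)
pc1 <- pheno$viscerocranium_pc1

# restrict the panel columns to the scanned (QC-surviving) markers
keep <- match(scan_df$id, panel$map$id)
panel <- haplotype_panel(panel$alleles[, keep], panel$sample_ids,
                         panel$map[keep, ])
scan <- structure(list(result = scan_df, lambda = qcj$lambda,
                       threshold_p = qcj$threshold_p, n_tests = qcj$n_tests),
                  class = "assoc_scan")
index <- which.min(scan_df$p)

win <- window_haplotype_assoc(panel, pc1, window = 10)
best <- win[which.min(win$p), ]
cat(sprintf("Sliding windows: best 10-SNP window starts at marker %d (pos %d), p = %.3g\n",
            best$start_index, best$pos, best$p))

cases <- select_cases(pc1, threshold = -0.2, rule = "le")
cat(sprintf("%d brachycephalic-type cases (PC1 <= -0.2) of %d dogs\n",
            length(cases), length(pc1)))
rows <- skullqtl:::case_copy_rows(cases)
case_copies <- panel$alleles[rows, , drop = FALSE]
cons <- consensus_haplotype(case_copies, rep(pc1, each = 2)[rows])

iv <- critical_interval(case_copies, cons, index, panel$map, min_recomb = 3)
print(iv)
cat(sprintf("Interval length: %s bp\n",
            format(interval_length(iv), big.mark = ",")))

G <- panel_to_genotypes(panel)
core <- core_haplotype(iv, cons, scan, G, index)
cat(sprintf("Core associated haplotype: %d SNPs within the interval\n",
            length(core$markers)))

cstats <- carrier_stats(panel, core, pc1, threshold = -0.2)
print(cstats)

write_interval_bed(iv, "results/critical_interval.bed")
utils::write.table(
  data.frame(marker = panel$map$id[core$markers],
             pos = panel$map$pos[core$markers], allele = core$alleles,
             support = cons$support[core$markers]),
  "results/core_haplotype.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(win, "results/window_assoc.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Wrote results/critical_interval.bed, core_haplotype.tsv, window_assoc.tsv\n")
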