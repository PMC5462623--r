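#!/usr/bin/env Rscript

# Stage 5: identity-by-descent variant filtering.  Applies the five logical
# assumptions to the critical-interval variant table: haplotype-homozygous
# cases are fixed for the shared candidate allele (which may be the
# reference allele), and neither wild canids nor haplotype-free controls
# may carry it.  Survivors are checked for complete pairwise LD.

suppressMessages(library(skullqtl))

raw <- utils::read.delim("results/simdata/variants.tsv",
                         check.names = FALSE, stringsAsFactors = FALSE)
rec_cols <- c("chrom", "pos", "ref", "alt", "vtype")
records <- raw[, rec_cols]
records$chrom <- as.character(records$chrom)
genos <- as.matrix(raw[, setdiff(names(raw), rec_cols)])
tab <- variant_table(records, genos,
                     region = list(chrom = "1", start = 55850299L,
                                   end = 56037676L))
groups <- read_sample_map("results/simdata/sample_map.tsv")

rep <- filter_variants(tab, groups)
print(rep)

ld <- complete_ld_check(rep$survivors,
                        tab$genotypes[rep$survivors$index, , drop = FALSE])
cat(sprintf("Survivors in complete pairwise LD: %s (min r2 = %.3f)\n",
            ld$complete_ld, min(ld$r2[upper.tri(ld$r2)], na.rm = TRUE)))

jsonlite::write_json(
  list(pre = as.list(rep$pre), post = as.list(rep$post),
       eliminated = as.list(rep$eliminated), no_data = rep$no_data,
       complete_ld = ld$complete_ld),
  "results/filter_report.json", auto_unbox = TRUE, digits = NA)
utils::write.table(rep$survivors, "results/candidate_variants.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/filter_report.json and candidate_variants.tsv\n")
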