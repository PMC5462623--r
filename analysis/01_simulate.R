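#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study -- a breed-structured cohort with a
# planted 12-SNP causal haplotype, landmark configurations carrying size,
# allometry and QTL shape effects, and a variant table in which exactly
# 4 SNVs/INDELs + 1 SV satisfy the identity-by-descent filtering
# assumptions.  Everything downstream works from the files written here.

suppressMessages(library(skullqtl))

out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20170605L                       # fixed study seed

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)

write_landmarks(study$landmarks$landmarks, file.path(out, "landmarks.csv"))
write_phased_vcf(study$genotypes$panel, file.path(out, "phased.vcf"))

vsim <- simulate_variant_table(c(case_hom = 8, control = 20, wild = 10),
                               n_snvs = 3674, n_svs = 162,
                               n_true_snvs = 4, n_true_svs = 1, seed = seed)
write_sample_map(vsim$groups, file.path(out, "sample_map.tsv"))
saveRDS_free <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE)
saveRDS_free(list(causal_idx = study$genotypes$truth$causal_idx,
                  planted_alleles = study$genotypes$truth$planted_alleles,
                  causal_dosage = study$genotypes$truth$causal_dosage,
                  breed = as.list(study$genotypes$breed),
                  case_breeds = study$genotypes$case_breeds,
                  variant_truth_idx = vsim$truth$true_idx),
             file.path(out, "truth.json"))
# per-record variant fixture kept as TSV so stage 5 reloads it exactly
utils::write.table(cbind(vsim$table$records, vsim$table$genotypes),
                   file.path(out, "variants.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", cfg$n_dogs, "dogs across", cfg$n_breeds, "breeds;",
    cfg$n_snps, "markers with a", cfg$causal_markers,
    "-marker causal haplotype at markers",
    min(study$genotypes$truth$causal_idx), "-",
    max(study$genotypes$truth$causal_idx), "\n")
cat("Causal dosage distribution:",
    paste(names(table(study$genotypes$truth$causal_dosage)),
          table(study$genotypes$truth$causal_dosage),
          sep = "=", collapse = " "), "\n")
cat("Variant fixture: 3674 SNVs/INDELs + 162 SVs with 4 + 1 planted causal",
    "candidates\nOutputs in", out, "\n")
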