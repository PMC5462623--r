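#' Run the full synthetic-study analysis chain
#'
#' Chains the pipeline stages on a [simulate_study()] output: generalized
#' Procrustes fits (neurocranium for the size proxy, viscerocranium for
#' shape), allometric regression of viscerocranium shape on neurocranium
#' centroid size, shape PCA oriented so high-dosage (case-breed-like)
#' specimens score negative, a kinship LMM scan of oriented PC1, case
#' selection at the PC1 threshold, consensus haplotype, recombination-count
#' critical interval, core haplotype and carrier statistics.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param n_perm allometry permutation count (default 1000 here; the
#'   one-off published-scale analysis uses 10,000 via
#'   [allometric_regression()] directly).
#' @param n_pcs genotype-PC covariates for the scan (default 5).
#' @param case_threshold,case_rule case definition on oriented PC1.
#' @param min_recomb breakpoints per interval side (default 3).
#' @param seed seed for the permutation draw.
#' @return list with `phenotypes` (data.frame: specimen, neurocranium
#'   centroid size, oriented viscerocranium PC1), `gpa_neuro`,
#'   `gpa_viscero`, `allometry`, `pca`, `scan`, `index_marker`, `cases`,
#'   `consensus`, `interval`, `core`, `carriers`.
#' @export
run_study_pipeline <- function(study, n_perm = 1000L, n_pcs = 5L,
                               case_threshold = -0.2,
                               case_rule = "le", min_recomb = 3L,
                               seed = study$config$seed) {
  stopifnot(inherits(study, "synthetic_study"))
  lms <- study$landmarks$landmarks
  gpa_neuro <- gpa(lms, mask = "neurocranium")
  gpa_visc <- gpa(lms, mask = "viscerocranium")
  size <- gpa_neuro$centroid_sizes
  allo <- allometric_regression(gpa_visc, size, n_perm = n_perm, seed = seed)
  pca <- shape_pca(allo)
  dosage <- study$genotypes$truth$causal_dosage
  pca <- orient_pc(pca, reference = dosage == max(dosage), component = 1L)
  pc1 <- pca$scores[, 1L]

  G <- genotype_matrix(study$genotypes$dosages, study$genotypes$panel$map)
  K <- kinship(G)
  covars <- genotype_pcs(K, min(n_pcs, nrow(G$dosages) - 2L))
  scan <- lmm_scan(pc1, G, K, covariates = covars)
  index_marker <- which.min(scan$result$p)

  cases <- select_cases(pc1, threshold = case_threshold, rule = case_rule)
  rows <- case_copy_rows(cases)
  case_copies <- study$genotypes$panel$alleles[rows, , drop = FALSE]
  copy_pheno <- rep(pc1, each = 2L)[rows]
  cons <- consensus_haplotype(case_copies, copy_pheno)
  interval <- suppressWarnings(
    critical_interval(case_copies, cons, index_marker, G$map,
                      min_recomb = min_recomb))
  core <- core_haplotype(interval, cons, scan, G, index_marker)
  carriers <- carrier_stats(study$genotypes$panel, core, pc1,
                            threshold = case_threshold, rule = case_rule)
  list(phenotypes = data.frame(specimen = names(size),
                               neurocranium_cs = unname(size),
                               viscerocranium_pc1 = unname(pc1)),
       gpa_neuro = gpa_neuro, gpa_viscero = gpa_visc, allometry = allo,
       pca = pca, scan = scan, index_marker = index_marker, cases = cases,
       consensus = cons, interval = interval, core = core,
       carriers = carriers)
}
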