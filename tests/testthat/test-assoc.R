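make_G <- function(n = 30, m = 40, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  dos <- sapply(maf, function(p) rbinom(n, 2, p))
  map <- data.frame(chrom = "1", pos = 100L * seq_len(m),
                    id = sprintf("m%03d", seq_len(m)), ref = "A", alt = "G")
  genotype_matrix(dos, map)
}

test_that("qc_filter applies strict boundary rules and matches a recount", {
  dos <- cbind(rep(c(0, 1), 25),                  # MAF 0.25 -> retained
               c(rep(1, 4), rep(0, 46)),          # MAF 0.04 -> dropped
               c(rep(1, 5), rep(0, 45)),          # MAF 0.05 -> retained (strict <)
               rep(0, 50))                        # monomorphic -> dropped
  map <- data.frame(chrom = "1", pos = 1:4, id = paste0("m", 1:4),
                    ref = "A", alt = "G")
  G <- genotype_matrix(dos, map)
  out <- qc_filter(G)
  expect_identical(colnames(out$genotypes$dosages), c("m1", "m3"))

  # sample missingness boundary: 11% dropped, 10% retained (strict >)
  set.seed(2)
  dos2 <- matrix(rbinom(20 * 100, 2, 0.4), 20, 100)
  dos2[1, 1:11] <- NA                              # 11% missing
  dos2[2, 1:10] <- NA                              # 10% missing
  G2 <- genotype_matrix(dos2, data.frame(chrom = "1", pos = 1:100,
                                         id = paste0("m", 1:100),
                                         ref = "A", alt = "G"))
  out2 <- qc_filter(G2)
  expect_identical(out2$report$samples_dropped_missingness, 1L)
  expect_identical(nrow(out2$genotypes$dosages), 19L)

  # random fixture vs brute-force recount
  G3 <- make_G(40, 60, seed = 3, maf = runif(60, 0.01, 0.5))
  out3 <- qc_filter(G3)
  keep_manual <- apply(G3$dosages, 2, function(x) {
    f <- mean(x) / 2; min(f, 1 - f) >= 0.05
  })
  expect_identical(ncol(out3$genotypes$dosages), sum(keep_manual))
})

test_that("kinship matches its definition and permutes with samples", {
  G <- make_G(25, 50, seed = 4)
  K <- kinship(G)
  Z <- scale(G$dosages, center = TRUE, scale = FALSE)
  expect_equal(unclass(K), tcrossprod(Z) / 50, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(K - t(K))), 1e-10)
  # duplicated samples: off-diagonal entry equals both diagonals
  dd <- G$dosages
  dd[2, ] <- dd[1, ]
  K2 <- kinship(genotype_matrix(dd, G$map))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-10)
  expect_equal(K2[1, 2], K2[2, 2], tolerance = 1e-10)
  # sample permutation permutes rows/cols identically
  perm <- sample(25)
  Kp <- kinship(genotype_matrix(G$dosages[perm, ], G$map))
  expect_equal(unclass(Kp), unclass(K)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("genotype PCs separate simulated breeds and are orthogonal", {
  cfg <- sim_config(n_dogs = 80, n_breeds = 2, fst = 0.4, n_snps = 300,
                    causal_freq_case_breeds = 0, causal_freq_other = 0,
                    seed = 6)
  g <- simulate_genotypes(cfg)
  G <- genotype_matrix(g$dosages, g$panel$map)
  sc <- genotype_pcs(G, 4)
  lbl <- as.numeric(factor(g$breed))
  expect_gt(abs(cor(sc[, 1], lbl)), 0.9)
  Gram <- crossprod(sc)
  expect_lt(max(abs(Gram - diag(diag(Gram)))), 1e-6 * max(diag(Gram)))
  expect_error(genotype_pcs(G, 80), "sample count")
  expect_error(genotype_pcs(G, 0), "positive")
})

test_that("LMM collapses to OLS when K = I", {
  G <- make_G(40, 30, seed = 7)
  set.seed(8)
  y <- rnorm(40)
  covar <- cbind(sex = rbinom(40, 1, 0.5))
  scan <- lmm_scan(y, G, K = diag(40), covariates = covar)
  for (j in c(1, 7, 19)) {
    fit <- summary(lm(y ~ covar + G$dosages[, j]))$coefficients
    expect_equal(scan$result$p[j], fit[3, 4], tolerance = 1e-6)
    expect_equal(scan$result$beta[j], fit[3, 1], tolerance = 1e-6)
  }
})

test_that("LMM scan is invariant to marker order and flags monomorphic markers", {
  G <- make_G(30, 25, seed = 9)
  dos <- G$dosages
  dos[, 5] <- 1                                  # monomorphic
  G <- genotype_matrix(dos, G$map)
  set.seed(10)
  y <- rnorm(30)
  K <- kinship(G)
  s1 <- lmm_scan(y, G, K)
  expect_true(is.na(s1$result$p[5]))
  perm <- sample(25)
  Gp <- genotype_matrix(dos[, perm],
                        within(G$map[perm, ], pos <- sort(pos)))
  s2 <- lmm_scan(y, Gp, K)
  expect_equal(s2$result$beta, s1$result$beta[perm], tolerance = 1e-8)
  expect_equal(s2$result$p, s1$result$p[perm], tolerance = 1e-8)
})

test_that("LMM scan localises a strong planted haplotype", {
  cfg <- sim_config(n_dogs = 120, n_breeds = 8, n_snps = 200, seed = 12)
  g <- simulate_genotypes(cfg)
  set.seed(13)
  y <- -0.5 * g$truth$causal_dosage + rnorm(120, 0, 0.3)
  G <- genotype_matrix(g$dosages, g$panel$map)
  scan <- lmm_scan(y, G, kinship(G))
  expect_true(which.min(scan$result$p) %in% g$truth$causal_idx)
})

test_that("genomic inflation behaves on known inputs", {
  n <- 1001
  grid <- (seq_len(n) - 0.5) / n
  expect_equal(genomic_inflation(grid), 1, tolerance = 1e-3)
  expect_gt(genomic_inflation(grid / 2), 1)
  set.seed(14)
  expect_lt(abs(genomic_inflation(runif(10000)) - 1), 0.05)
  expect_error(genomic_inflation(numeric(0)), "no finite")
})

test_that("Bonferroni threshold reproduces published arithmetic", {
  thr <- bonferroni_threshold(139260)
  expect_equal(round(thr$neglog10, 2), 6.44)
  expect_equal(signif(thr$p_threshold, 2), 3.6e-7)
  expect_equal(bonferroni_threshold(1)$p_threshold, 0.05)
  expect_equal(bonferroni_threshold(20)$p_threshold, 2.5e-3)
  ths <- vapply(c(10, 100, 1000), function(n)
    bonferroni_threshold(n)$p_threshold, numeric(1))
  expect_true(all(diff(ths) < 0))
  expect_error(bonferroni_threshold(10, alpha = 1.5), "alpha")
})

test_that("ld_r2 equals squared dosage correlation", {
  G <- make_G(50, 10, seed = 15)
  expect_equal(ld_r2(G, 3, 3), 1.0, tolerance = 1e-12)
  dos <- G$dosages
  dos[, 2] <- 2 - dos[, 1]                        # complement
  G2 <- genotype_matrix(dos, G$map)
  expect_equal(ld_r2(G2, 1, 2), 1.0, tolerance = 1e-12)
  expect_equal(ld_r2(G, 4, 9), cor(G$dosages[, 4], G$dosages[, 9])^2,
               tolerance = 1e-12)
  dos[, 5] <- 0
  expect_error(ld_r2(genotype_matrix(dos, G$map), 5, 1), "monomorphic")
})

test_that("LD pruning removes the index and its linked block", {
  set.seed(16)
  n <- 60
  block <- rbinom(n, 2, 0.4)
  dos <- cbind(block, block, block,                       # perfect LD block
               replicate(5, rbinom(n, 2, 0.3)))
  map <- data.frame(chrom = "1", pos = 1:8, id = paste0("m", 1:8),
                    ref = "A", alt = "G")
  G <- genotype_matrix(dos, map)
  y <- block * 2 + rnorm(n, 0, 0.5)                       # strong signal
  scan <- lmm_scan(y, G, diag(n))
  pr <- ld_prune_rescan(scan, G)
  expect_true(all(c("m1", "m2", "m3") %in% pr$removed))
  # r2_threshold = 1: nothing exceeds 1 strictly, only the index goes
  pr1 <- ld_prune_rescan(scan, G, r2_threshold = 1.0)
  expect_length(pr1$removed, 1L)
  expect_identical(pr1$removed, pr1$index)
  # no significant markers: untouched with a note
  set.seed(17)
  scan0 <- lmm_scan(rnorm(n), G, diag(n))
  pr0 <- ld_prune_rescan(scan0, G)
  expect_identical(pr0$kept, G$map$id)
  expect_match(pr0$note, "no significant")
})
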