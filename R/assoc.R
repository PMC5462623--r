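#' Genotype dosage matrix with a genomic map
#'
#' @param dosages samples x markers matrix with values 0/1/2 or `NA`.
#' @param map data.frame with columns `chrom`, `pos` (1-based,
#'   non-decreasing within chromosome), `id`, and optionally `ref`, `alt`.
#' @param sample_ids character vector (defaults to rownames).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (nrow(map) != ncol(dosages)) stop("map length must equal marker count")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(nrow(dosages)))
  bad <- unlist(tapply(map$pos, map$chrom, function(p) any(diff(p) < 0)))
  if (any(bad)) stop("positions must be non-decreasing within chromosome")
  ok <- dosages[!is.na(dosages)]
  if (length(ok) && (any(ok < 0) || any(ok > 2)))
    stop("dosages must lie in [0,2]")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- map$id
  structure(list(dosages = dosages, map = map, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "markers\n")
  invisible(x)
}

#' Marker and sample quality control
#'
#' Drops samples whose missing-genotype fraction strictly exceeds
#' `sample_missing_max`, then markers whose minor-allele frequency
#' (computed on the retained samples) is strictly below `maf_min`.
#'
#' @param G a [genotype_matrix].
#' @param maf_min minimum minor-allele frequency retained (default 0.05).
#' @param sample_missing_max maximum tolerated per-sample missingness
#'   (default 0.1).
#' @return list with the filtered `genotypes` and a `report` of counts
#'   dropped per rule.
#' @export
qc_filter <- function(G, maf_min = 0.05, sample_missing_max = 0.1) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- rowMeans(is.na(G$dosages))
  keep_s <- miss <= sample_missing_max
  if (!any(keep_s)) stop("all samples dropped by missingness filter")
  dos <- G$dosages[keep_s, , drop = FALSE]
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  keep_m <- maf >= maf_min
  out <- genotype_matrix(dos[, keep_m, drop = FALSE],
                         G$map[keep_m, , drop = FALSE],
                         G$sample_ids[keep_s])
  list(genotypes = out,
       report = list(samples_dropped_missingness = sum(!keep_s),
                     markers_dropped_maf = sum(!keep_m),
                     samples_retained = sum(keep_s),
                     markers_retained = sum(keep_m)))
}

## Per-marker mean imputation of residual missing dosages.
.impute_mean <- function(dos) {
  nas <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(dos, na.rm = TRUE)
    dos[nas] <- mu[nas[, 2L]]
  }
  dos
}

#' Centred genomic relationship (kinship) matrix
#'
#' `K = Z Z' / m` with `Z` the column-centred dosage matrix and `m` the
#' marker count; residual missing genotypes are mean-imputed per marker.
#'
#' @param G a [genotype_matrix] (or a plain dosage matrix).
#' @return symmetric samples x samples matrix of class `kinship_matrix`.
#' @export
kinship <- function(G) {
  dos <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (ncol(dos) == 0L) stop("zero markers: kinship undefined")
  Z <- scale(.impute_mean(dos), center = TRUE, scale = FALSE)
  K <- tcrossprod(Z) / ncol(Z)
  structure(K, class = c("kinship_matrix", "matrix"))
}

#' Genotype principal-component covariates
#'
#' Top eigenvectors of the kinship matrix scaled by root-eigenvalue;
#' standard population-structure covariates for the mixed-model scan.
#'
#' @param G a [genotype_matrix] or a precomputed [kinship] matrix.
#' @param n_components number of components, `0 < n < sample count`.
#' @return samples x `n_components` score matrix.
#' @export
genotype_pcs <- function(G, n_components) {
  K <- if (inherits(G, "kinship_matrix")) unclass(G) else unclass(kinship(G))
  n <- nrow(K)
  if (n_components <= 0L) stop("n_components must be positive")
  if (n_components >= n) stop("n_components must be < sample count")
  e <- eigen(K, symmetric = TRUE)
  idx <- seq_len(n_components)
  sc <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[idx], 0)), n_components)
  rownames(sc) <- rownames(K)
  colnames(sc) <- sprintf("PC%d", idx)
  sc
}

## REML criterion (-2 log restricted likelihood up to constants) for the
## rotated model with weights w = lambda * d + 1; minimised over log-lambda.
.reml_crit <- function(loglam, yr, Xr, d) {
  w <- exp(loglam) * d + 1
  Xw <- Xr / w
  XtX <- crossprod(Xr, Xw)
  Xty <- crossprod(Xw, yr)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), Xty))
  r <- yr - Xr %*% beta
  rss <- sum(r^2 / w)
  nq <- length(yr) - ncol(Xr)
  nq * log(rss) + sum(log(w)) + 2 * sum(log(diag(ch)))
}

## GLS fit at a given lambda; returns beta, se and t df for the LAST column.
.gls_wald <- function(lam, yr, Xr, d) {
  w <- lam * d + 1
  Xw <- Xr / w
  XtX <- crossprod(Xr, Xw)
  Xty <- crossprod(Xw, yr)
  XtXi <- solve(XtX)
  beta <- XtXi %*% Xty
  r <- yr - Xr %*% beta
  nq <- length(yr) - ncol(Xr)
  s2 <- sum(r^2 / w) / nq
  j <- ncol(Xr)
  se <- sqrt(s2 * XtXi[j, j])
  list(beta = beta[j], se = se, df = nq)
}

#' Univariate linear-mixed-model association scan
#'
#' Fits `y = W a + x b + u + e` per marker with `u ~ (0, s2_g K)` and
#' `e ~ (0, s2_e I)`.  The kinship matrix is eigendecomposed once; for every
#' marker the variance ratio `lambda = s2_g / s2_e` is profiled by 1-D REML
#' optimisation on the rotated model (Brent search on the log scale over
#' `[1e-5, 1e5]`) and the marker effect is tested by a Wald t test -- exact
#' per-marker optimisation, not a reused null ratio.  With `K = I` the model
#' collapses to ordinary least squares exactly.
#'
#' @param y numeric phenotype, length = sample count.
#' @param G a [genotype_matrix]; residual missing dosages are mean-imputed.
#' @param K a [kinship] matrix (computed from `G` if omitted).
#' @param covariates optional samples x c matrix (sex, genotype PCs, ...);
#'   an intercept is always included.
#' @param alpha significance level for the Bonferroni scan threshold.
#' @return object of class `assoc_scan`: data.frame `result` with per-marker
#'   `chrom`, `pos`, `id`, `beta`, `se`, `p` (monomorphic markers get `NA`),
#'   plus scan QC `lambda` (genomic inflation), `threshold_p`, `n_tests`.
#' @export
lmm_scan <- function(y, G, K = NULL, covariates = NULL, alpha = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- .impute_mean(G$dosages)
  n <- nrow(dos)
  if (length(y) != n) stop("phenotype length must equal sample count")
  if (is.null(K)) K <- kinship(G)
  K <- unclass(K)
  W <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(W)$rank < ncol(W)) stop("singular covariate matrix")

  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  yr <- drop(crossprod(U, y))
  Wr <- crossprod(U, W)
  Gr <- crossprod(U, dos)

  m <- ncol(dos)
  beta <- se <- p <- rep(NA_real_, m)
  mono <- apply(dos, 2L, function(x) stats::sd(x) == 0)
  for (j in seq_len(m)) {
    if (mono[j]) next
    Xr <- cbind(Wr, Gr[, j])
    opt <- stats::optimize(.reml_crit, c(log(1e-5), log(1e5)),
                           yr = yr, Xr = Xr, d = d, tol = 1e-6)
    fit <- .gls_wald(exp(opt$minimum), yr, Xr, d)
    beta[j] <- fit$beta
    se[j] <- fit$se
    tstat <- fit$beta / fit$se
    p[j] <- 2 * stats::pt(-abs(tstat), fit$df)
  }
  n_tests <- sum(!mono)
  thr <- bonferroni_threshold(max(n_tests, 1L), alpha)
  structure(list(result = data.frame(chrom = G$map$chrom, pos = G$map$pos,
                                     id = G$map$id, beta = beta, se = se,
                                     p = p, stringsAsFactors = FALSE),
                 lambda = genomic_inflation(p[!is.na(p)]),
                 threshold_p = thr$p_threshold,
                 n_tests = n_tests),
            class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("assoc_scan: %d markers tested; lambda = %.3f; Bonferroni p threshold = %.3g\n",
              x$n_tests, x$lambda, x$threshold_p))
  top <- x$result[order(x$result$p), ][1L, ]
  cat(sprintf("  top marker %s at %s:%d, p = %.3g\n",
              top$id, top$chrom, top$pos, top$p))
  invisible(x)
}

#' Genomic inflation factor
#'
#' Lambda: the median of the 1-df chi-square quantile transform of the
#' observed p-values divided by the null median (0.4549364).  Values near 1
#' indicate a well-calibrated scan.
#'
#' @param pvals numeric p-values (NAs dropped); at least one finite value.
#' @return scalar lambda.
#' @export
genomic_inflation <- function(pvals) {
  pvals <- pvals[is.finite(pvals)]
  if (!length(pvals)) stop("no finite p-values")
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate in (0,1), default 0.05.
#' @return list with `p_threshold = alpha / n_tests` and its
#'   `neglog10` transform.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  p <- alpha / n_tests
  list(p_threshold = p, neglog10 = -log10(p))
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of the dosages of two markers over
#' pairwise-complete samples.
#'
#' @param G a [genotype_matrix].
#' @param marker_i,marker_j marker indices or ids.
#' @return r-squared in `[0,1]`.
#' @export
ld_r2 <- function(G, marker_i, marker_j) {
  stopifnot(inherits(G, "genotype_matrix"))
  ix <- if (is.character(marker_i)) match(marker_i, G$map$id) else marker_i
  jx <- if (is.character(marker_j)) match(marker_j, G$map$id) else marker_j
  xi <- G$dosages[, ix]
  xj <- G$dosages[, jx]
  ok <- !is.na(xi) & !is.na(xj)
  if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0)
    stop("monomorphic marker: r-squared undefined")
  stats::cor(xi[ok], xj[ok])^2
}

#' LD pruning of index-SNP neighbourhoods for re-scanning
#'
#' Takes the lowest-p significant marker per chromosome as the index SNP
#' and removes it together with all markers whose r-squared with it
#' strictly exceeds `r2_threshold`; the surviving marker set is intended
#' for a fresh [lmm_scan()] (QQ-plot concordance check).
#'
#' @param scan an [lmm_scan] result.
#' @param G the [genotype_matrix] the scan was run on (same markers).
#' @param r2_threshold LD pruning threshold (default 0.2, strict `>`).
#' @return list with `kept` and `removed` marker ids, `index` ids, and a
#'   `note` when no marker reached significance (input returned unchanged).
#' @export
ld_prune_rescan <- function(scan, G, r2_threshold = 0.2) {
  stopifnot(inherits(scan, "assoc_scan"), inherits(G, "genotype_matrix"))
  res <- scan$result
  if (!identical(res$id, G$map$id)) stop("scan and genotypes share no marker order")
  sig <- which(!is.na(res$p) & res$p < scan$threshold_p)
  if (!length(sig))
    return(list(kept = res$id, removed = character(0), index = character(0),
                note = "no significant markers; nothing pruned"))
  removed <- integer(0)
  index <- integer(0)
  for (ch in unique(res$chrom[sig])) {
    on_ch <- sig[res$chrom[sig] == ch]
    idx <- on_ch[which.min(res$p[on_ch])]
    index <- c(index, idx)
    partners <- which(vapply(seq_len(nrow(res)), function(j) {
      if (j == idx) return(FALSE)
      sdj <- stats::sd(G$dosages[, j], na.rm = TRUE)
      if (is.na(sdj) || sdj == 0) return(FALSE)
      ld_r2(G, idx, j) > r2_threshold
    }, logical(1)))
    removed <- c(removed, idx, partners)
  }
  removed <- sort(unique(removed))
  list(kept = res$id[-removed], removed = res$id[removed],
       index = res$id[index], note = NULL)
}
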