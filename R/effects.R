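#' Normalize linear measurements by centroid size
#'
#' Elementwise ratio of a linear skull measurement to a per-specimen
#' centroid size (size proxy), yielding unitless size-corrected values.
#'
#' @param measurements numeric vector.
#' @param centroid_sizes positive numeric vector, same length.
#' @return numeric vector of ratios.
#' @export
normalize_by_centroid <- function(measurements, centroid_sizes) {
  if (length(measurements) != length(centroid_sizes))
    stop("lengths must match")
  if (any(centroid_sizes <= 0)) stop("centroid sizes must be positive")
  measurements / centroid_sizes
}

#' Exact / approximate Mann-Whitney-Wilcoxon test
#'
#' Two-sided two-sample rank test.  For combined sample sizes up to
#' `exact_max` the null distribution is exact: from the closed-form
#' Wilcoxon distribution when the data carry no ties, and from exhaustive
#' enumeration of all group assignments when they do.  Above `exact_max`
#' the tie-corrected normal approximation (no continuity correction) is
#' used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined n for which the exact null is used
#'   (default 20).
#' @return list with `statistic` (the U statistic of `x`), `p.value`,
#'   `method`.
#' @export
mww_test <- function(x, y, exact_max = 20L) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (nx + ny <= exact_max) {
    if (!ties) {
      ## exact Wilcoxon null (min of the two one-sided tails, doubled)
      p_le <- stats::pwilcox(U, nx, ny)
      p_ge <- 1 - stats::pwilcox(U - 1, nx, ny)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact"
    } else {
      ## enumerate all assignments of the pooled ranks to group x
      cmb <- utils::combn(nx + ny, nx)
      usum <- colSums(matrix(r[cmb], nx)) - nx * (nx + 1) / 2
      p_le <- mean(usum <= U)
      p_ge <- mean(usum >= U)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact (ties, enumeration)"
    }
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sig2 <- nx * ny / 12 *
      (nx + ny + 1 - sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = U, p.value = p, method = method)
}

#' Per-genotype-class distribution tests and additive trend
#'
#' For each pair of genotype classes (homozygous ancestral 0, heterozygous
#' 1, homozygous derived 2) present with at least two observations, a
#' two-sided Mann-Whitney-Wilcoxon test ([mww_test]) and a
#' Kolmogorov-Smirnov test are run; an additive-trend linear regression of
#' the values on the dosage gives the per-allele slope and its p-value.
#'
#' @param values numeric phenotype per sample.
#' @param classes integer dosage in `{0,1,2}` per sample.
#' @return list with `pairs` (data.frame of pairwise `mww_p`, `ks_p`,
#'   skipped pairs carry `NA` and a note) and `trend` (`slope`, `p.value`).
#' @export
genotype_class_tests <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  classes <- as.integer(classes)
  present <- sort(unique(classes))
  if (length(present) < 2L) stop("need at least two genotype classes")
  combs <- utils::combn(present, 2L)
  pairs <- data.frame(class_a = combs[1L, ], class_b = combs[2L, ],
                      mww_p = NA_real_, ks_p = NA_real_,
                      note = NA_character_)
  for (i in seq_len(ncol(combs))) {
    va <- values[classes == combs[1L, i]]
    vb <- values[classes == combs[2L, i]]
    if (length(va) < 2L || length(vb) < 2L) {
      pairs$note[i] <- "skipped: fewer than 2 observations in a class"
      next
    }
    pairs$mww_p[i] <- mww_test(va, vb)$p.value
    pairs$ks_p[i] <- suppressWarnings(stats::ks.test(va, vb)$p.value)
  }
  fit <- summary(stats::lm(values ~ classes))
  list(pairs = pairs,
       trend = list(slope = fit$coefficients["classes", "Estimate"],
                    p.value = fit$coefficients["classes", "Pr(>|t|)"]))
}

#' Stepwise proportion of variance explained by genotypes
#'
#' Per-locus PVE is 100 times the R-squared of the single-predictor linear
#' model -- the maximum potential (non-additive) contribution of each
#' genotype.  A forward stepwise selection (AIC by default; BIC and
#' adjusted R-squared available) then builds the joint model, whose
#' R-squared is the joint PVE.
#'
#' @param phenotype numeric response.
#' @param dosage_matrix samples x loci numeric matrix (column names are the
#'   locus labels); samples with any missing dosage are dropped listwise.
#' @param criterion `"AIC"` (default), `"BIC"` or `"adjR2"`.
#' @return object of class `pve_result` with `single` (named per-locus PVE,
#'   percent), `selected` (locus names in selection order), `joint`
#'   (percent), `path` (data.frame of the selection trace).
#' @export
stepwise_pve <- function(phenotype, dosage_matrix, criterion = c("AIC", "BIC", "adjR2")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(dosage_matrix)
  if (is.null(colnames(X))) colnames(X) <- sprintf("locus%d", seq_len(ncol(X)))
  keep <- stats::complete.cases(cbind(phenotype, X))
  y <- phenotype[keep]; X <- X[keep, , drop = FALSE]
  if (stats::sd(y) == 0) stop("constant phenotype")

  ## exact fits trigger a harmless precision warning from summary.lm
  r2 <- function(fit) suppressWarnings(summary(fit)$r.squared)
  single <- vapply(seq_len(ncol(X)), function(j)
    100 * r2(stats::lm(y ~ X[, j])), numeric(1))
  names(single) <- colnames(X)

  score <- function(fit) switch(criterion,
    AIC = stats::AIC(fit), BIC = stats::BIC(fit),
    adjR2 = -summary(fit)$adj.r.squared)      # lower is better throughout
  selected <- character(0)
  dat <- data.frame(y = y, X, check.names = FALSE)
  cur <- stats::lm(y ~ 1, data = dat)
  cur_score <- score(cur)
  path <- data.frame(step = 0L, added = NA_character_,
                     joint_pve = 0, score = cur_score)
  repeat {
    rest <- setdiff(colnames(X), selected)
    if (!length(rest)) break
    cand <- vapply(rest, function(v) {
      f <- stats::reformulate(c(selected, v, "1"), response = "y")
      score(stats::lm(f, data = dat))
    }, numeric(1))
    best <- names(cand)[which.min(cand)]
    if (min(cand) >= cur_score) break         # minimum-improvement stop
    selected <- c(selected, best)
    cur <- stats::lm(stats::reformulate(c(selected, "1"), "y"), data = dat)
    cur_score <- min(cand)
    path <- rbind(path, data.frame(step = length(selected), added = best,
                                   joint_pve = 100 * r2(cur),
                                   score = cur_score))
  }
  joint <- if (length(selected)) 100 * r2(cur) else 0
  structure(list(single = single, selected = selected, joint = joint,
                 path = path, n = length(y), criterion = criterion),
            class = "pve_result")
}

#' @export
print.pve_result <- function(x, ...) {
  cat("pve_result: single-locus PVE (%):\n")
  print(round(x$single, 1))
  cat(sprintf("  selected (%s): %s; joint PVE = %.1f%%\n", x$criterion,
              paste(x$selected, collapse = " + "), x$joint))
  invisible(x)
}

#' Efficiency-corrected relative expression ratio (Pfaffl)
#'
#' `ratio = E_target^(Ct_target_calibrator - Ct_target_sample) /
#'          E_ref^(Ct_ref_calibrator - Ct_ref_sample)`
#' with amplification efficiencies in fold-per-cycle units (2 = perfect
#' doubling).
#'
#' @param ct_target_sample,ct_target_calibrator target-assay Ct values.
#' @param ct_ref_sample,ct_ref_calibrator reference-assay Ct values.
#' @param eff_target,eff_ref efficiencies in `(1, 2]`.
#' @return fold ratio (> 0); vectorised over Ct inputs.
#' @export
pfaffl_ratio <- function(ct_target_sample, ct_target_calibrator,
                         ct_ref_sample, ct_ref_calibrator,
                         eff_target = 2, eff_ref = 2) {
  for (e in c(eff_target, eff_ref))
    if (e <= 1 || e > 2) stop("efficiencies must lie in (1, 2]")
  eff_target^(ct_target_calibrator - ct_target_sample) /
    eff_ref^(ct_ref_calibrator - ct_ref_sample)
}

#' Allele percentage ratio with largest-remainder rounding
#'
#' Converts an allele count pair to integer percentages that always sum to
#' exactly 100 (largest-remainder correction).
#'
#' @param count_a,count_b non-negative counts, not both zero.
#' @return integer vector `c(a, b)` summing to 100.
#' @export
allele_ratio <- function(count_a, count_b) {
  tot <- count_a + count_b
  if (tot <= 0) stop("counts must not both be zero")
  raw <- 100 * c(count_a, count_b) / tot
  fl <- floor(raw)
  rem <- 100L - sum(fl)
  ord <- order(raw - fl, decreasing = TRUE)
  out <- as.integer(fl)
  if (rem > 0) out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  stats::setNames(out, c("a", "b"))
}

#' Scan a sequence for splice-acceptor context
#'
#' Mammalian 3' splice acceptors are almost invariantly preceded by the
#' dinucleotide AG.  For each observed junction (0-based offset of the
#' first base after the splice) the preceding dinucleotide is reported
#' with an `is_ag` flag, and every position in the sequence that could act
#' as an acceptor (preceded by AG) is enumerated.
#'
#' @param sequence character string over `A/C/G/T/N`.
#' @param junctions integer vector of 0-based junction offsets; offsets
#'   below 2 are flagged not-assessable.
#' @return object of class `splice_scan` with `junctions` (data.frame:
#'   `offset`, `dinucleotide`, `is_ag`, `assessable`) and
#'   `candidate_acceptors` (0-based offsets).
#' @export
scan_acceptor_sites <- function(sequence, junctions = integer(0)) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over A/C/G/T/N")
  n <- nchar(sequence)
  if (any(junctions > n)) stop("junction outside sequence bounds")
  din <- ifelse(junctions >= 2L,
                substring(sequence, junctions - 1L, junctions), NA_character_)
  jt <- data.frame(offset = junctions, dinucleotide = din,
                   is_ag = !is.na(din) & din == "AG",
                   assessable = junctions >= 2L)
  starts <- gregexpr("AG", sequence, fixed = TRUE)[[1L]]
  cand <- if (starts[1L] == -1L) integer(0) else as.integer(starts) + 1L
  structure(list(junctions = jt,
                 candidate_acceptors = cand[cand <= n],
                 sequence = sequence),
            class = "splice_scan")
}

#' Naive between-group fold change with median-of-ratios normalization
#'
#' Library sizes are normalized by the median-of-ratios method (per-sample
#' median of counts over the per-gene geometric mean, computed on genes
#' with all-positive counts); the fold change is the mean normalized count
#' of group 2 over group 1 per gene (orientation: non-carrier over
#' carrier when quantifying an expression reduction).  A transparent
#' descriptive summary, not a dispersion-modelled differential-expression
#' inference.
#'
#' @param counts_group1,counts_group2 genes x samples count matrices with
#'   identical gene order.
#' @return numeric vector of per-gene fold changes (group2 / group1).
#' @export
naive_fold_change <- function(counts_group1, counts_group2) {
  c1 <- as.matrix(counts_group1); c2 <- as.matrix(counts_group2)
  if (nrow(c1) != nrow(c2)) stop("gene sets must match")
  if (ncol(c1) < 1L || ncol(c2) < 1L) stop("need >= 1 sample per group")
  all_counts <- cbind(c1, c2)
  if (any(colSums(all_counts) == 0)) stop("zero library size")
  pos <- rowSums(all_counts > 0) == ncol(all_counts)
  if (!any(pos)) stop("no gene with all-positive counts for normalization")
  geo <- exp(rowMeans(log(all_counts[pos, , drop = FALSE])))
  sf <- apply(all_counts[pos, , drop = FALSE], 2L,
              function(col) stats::median(col / geo))
  norm <- sweep(all_counts, 2L, sf, "/")
  i1 <- seq_len(ncol(c1)); i2 <- ncol(c1) + seq_len(ncol(c2))
  fc <- rowMeans(norm[, i2, drop = FALSE]) / rowMeans(norm[, i1, drop = FALSE])
  stats::setNames(fc, rownames(c1))
}
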