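#' Phased haplotype panel
#'
#' Two chromosome copies per diploid sample, binary alleles, plus a genomic
#' map.  Copy ids are `<sample>_A` / `<sample>_B` and copies are stored
#' sample-major (A then B).
#'
#' @param alleles copies x markers 0/1 matrix (`2n` rows).
#' @param sample_ids length-`n` character vector.
#' @param map data.frame with `chrom`, `pos` (1-based), `id` per marker.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sample_ids, map) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("need exactly two chromosome copies per sample")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be binary 0/1")
  if (nrow(map) != ncol(alleles)) stop("map length must equal marker count")
  copy_ids <- as.vector(rbind(paste0(sample_ids, "_A"),
                              paste0(sample_ids, "_B")))
  rownames(alleles) <- copy_ids
  colnames(alleles) <- map$id
  structure(list(alleles = alleles, copy_ids = copy_ids,
                 sample_ids = sample_ids,
                 copy_sample = rep(sample_ids, each = 2L), map = map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$sample_ids), "samples (",
      nrow(x$alleles), "copies) x", ncol(x$alleles), "markers\n")
  invisible(x)
}

#' Collapse a phased panel to a dosage genotype matrix
#'
#' @param panel a [haplotype_panel].
#' @return a [genotype_matrix] with dosage = sum of the two copies.
#' @export
panel_to_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  n <- length(panel$sample_ids)
  dos <- a[seq(1L, 2L * n, 2L), , drop = FALSE] +
    a[seq(2L, 2L * n, 2L), , drop = FALSE]
  genotype_matrix(dos, panel$map, panel$sample_ids)
}

#' Sliding-window haplotype association
#'
#' For each window of `window` consecutive markers the distinct haplotypes
#' among all chromosome copies are enumerated; haplotypes carried by fewer
#' than `min_copies` copies are pooled into a "rare" class, and a one-way
#' ANOVA of the per-copy phenotype (each sample contributes its phenotype
#' once per copy) across haplotype classes gives the window p-value.
#' Windows with fewer than two classes after pooling get `NA`.
#'
#' @param panel a [haplotype_panel].
#' @param phenotype per-sample phenotype (panel sample order).
#' @param window window width in markers (default 10).
#' @param step window step (default 1).
#' @param min_copies rare-haplotype pooling threshold (default 5 copies).
#' @return data.frame with `start_index`, `pos` (first-marker coordinate),
#'   `n_classes`, `p`.
#' @export
window_haplotype_assoc <- function(panel, phenotype, window = 10L, step = 1L,
                                   min_copies = 5L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- ncol(panel$alleles)
  if (window > m) stop("window exceeds marker count")
  if (length(phenotype) != length(panel$sample_ids))
    stop("phenotype must be per sample")
  y <- rep(phenotype, each = 2L)
  starts <- seq(1L, m - window + 1L, by = step)
  p <- rep(NA_real_, length(starts))
  ncl <- integer(length(starts))
  for (s in seq_along(starts)) {
    cols <- starts[s]:(starts[s] + window - 1L)
    hap <- apply(panel$alleles[, cols, drop = FALSE], 1L, paste, collapse = "")
    tab <- table(hap)
    cls <- ifelse(tab[hap] < min_copies, "rare", hap)
    ncl[s] <- length(unique(cls))
    if (ncl[s] < 2L) next
    fit <- stats::oneway.test(y ~ factor(cls), var.equal = TRUE)
    p[s] <- fit$p.value
  }
  data.frame(start_index = starts, pos = panel$map$pos[starts],
             n_classes = ncl, p = p)
}

#' Select case samples by a phenotype threshold
#'
#' @param phenotype named or plain numeric vector.
#' @param threshold case threshold (default -0.2, the conventional shape
#'   PC1 cut for brachycephalic skulls).
#' @param rule `"le"` (default, `<=` threshold) or `"lt"` (`<`).
#' @return integer indices of the case samples.
#' @export
select_cases <- function(phenotype, threshold = -0.2, rule = c("le", "lt")) {
  rule <- match.arg(rule)
  idx <- if (rule == "le") which(phenotype <= threshold)
  else which(phenotype < threshold)
  if (!length(idx)) stop("no samples fall below the case threshold")
  idx
}

## Rows of the panel allele matrix belonging to the given sample indices.
case_copy_rows <- function(sample_idx) {
  as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
}

#' Consensus haplotype over case chromosome copies
#'
#' Per-marker majority allele over the case copies.  Exact ties are broken
#' toward the allele of the copy with the most-negative phenotype when one
#' is supplied, otherwise toward the first copy's allele.
#'
#' @param case_copies copies x markers 0/1 matrix (case chromosomes only).
#' @param copy_phenotype optional per-copy phenotype used for tie-breaking.
#' @return object of class `consensus_haplotype` with `alleles` and
#'   `support` (fraction of case copies matching, in `[0.5, 1]`).
#' @export
consensus_haplotype <- function(case_copies, copy_phenotype = NULL) {
  H <- as.matrix(case_copies)
  if (!nrow(H)) stop("need at least one case chromosome copy")
  nc <- nrow(H)
  ones <- colSums(H)
  cons <- as.integer(ones > nc / 2)
  tie <- which(ones * 2L == nc)
  if (length(tie)) {
    ref_copy <- if (is.null(copy_phenotype)) 1L else which.min(copy_phenotype)
    cons[tie] <- H[ref_copy, tie]
  }
  support <- ifelse(cons == 1L, ones, nc - ones) / nc
  structure(list(alleles = cons, support = support, n_copies = nc),
            class = "consensus_haplotype")
}

#' Critical interval by recombination counting
#'
#' Each case chromosome copy is reduced to its maximal run of consecutive
#' consensus-matching markers containing the index marker; copies that
#' mismatch the consensus at the index itself are non-carriers and are
#' excluded (and reported).  A copy's left breakpoint is the inter-marker
#' gap just left of its run, its right breakpoint the gap just right of it.
#' Walking outward from the index, each boundary is placed at the first gap
#' where the cumulative count of distinct recombinant copies reaches
#' `min_recomb`; the interval spans the markers strictly inside the two
#' boundary gaps, and the reported coordinates are those of the outermost
#' included markers.  If a side never accumulates `min_recomb` breakpoints
#' the interval runs to the panel edge and is flagged.
#'
#' @param case_copies copies x markers 0/1 matrix of case chromosomes.
#' @param consensus a [consensus_haplotype] covering the same markers.
#' @param index_marker index (column) of the association index SNP.
#' @param map marker map (`chrom`, `pos`) aligned with the columns.
#' @param min_recomb breakpoint count required per side (default 3).
#' @return object of class `critical_interval` with `chrom`, `start_pos`,
#'   `end_pos`, `start_index`, `end_index`, `left_breakpoints`,
#'   `right_breakpoints` (cumulative counts at the boundaries),
#'   `non_carrier_copies`, `edge_warning` (per side).
#' @export
critical_interval <- function(case_copies, consensus, index_marker, map,
                              min_recomb = 3L) {
  H <- as.matrix(case_copies)
  m <- ncol(H)
  if (index_marker < 1L || index_marker > m) stop("index marker outside map")
  cons <- if (inherits(consensus, "consensus_haplotype")) consensus$alleles
  else as.integer(consensus)
  if (length(cons) != m) stop("consensus must cover all markers")

  match_mat <- H == matrix(rep(cons, each = nrow(H)), nrow(H), m)
  non_carrier <- !match_mat[, index_marker]
  carriers <- which(!non_carrier)
  left_bp <- integer(0)   # gap g = between markers g and g+1
  right_bp <- integer(0)
  for (i in carriers) {
    run_start <- index_marker
    while (run_start > 1L && match_mat[i, run_start - 1L]) run_start <- run_start - 1L
    run_end <- index_marker
    while (run_end < m && match_mat[i, run_end + 1L]) run_end <- run_end + 1L
    if (run_start > 1L) left_bp <- c(left_bp, run_start - 1L)
    if (run_end < m) right_bp <- c(right_bp, run_end)
  }

  ## walk outward: cumulative distinct-copy breakpoints per gap
  left_boundary <- NA_integer_
  if (index_marker > 1L) {
    cum <- 0L
    for (g in (index_marker - 1L):1L) {
      cum <- cum + sum(left_bp == g)
      if (cum >= min_recomb) { left_boundary <- g; break }
    }
  }
  right_boundary <- NA_integer_
  if (index_marker < m) {
    cum <- 0L
    for (g in index_marker:(m - 1L)) {
      cum <- cum + sum(right_bp == g)
      if (cum >= min_recomb) { right_boundary <- g; break }
    }
  }
  edge <- c(left = is.na(left_boundary), right = is.na(right_boundary))
  if (any(edge))
    warning("breakpoint count never reached min_recomb on the ",
            paste(names(edge)[edge], collapse = " and "),
            " side; interval extends to the panel edge")
  si <- if (is.na(left_boundary)) 1L else left_boundary + 1L
  ei <- if (is.na(right_boundary)) m else right_boundary
  structure(list(chrom = map$chrom[si],
                 start_pos = map$pos[si], end_pos = map$pos[ei],
                 start_index = si, end_index = ei,
                 left_breakpoints = if (edge["left"]) length(left_bp)
                   else sum(left_bp >= left_boundary),
                 right_breakpoints = if (edge["right"]) length(right_bp)
                   else sum(right_bp <= right_boundary),
                 non_carrier_copies = which(non_carrier),
                 edge_warning = edge),
            class = "critical_interval")
}

#' @export
print.critical_interval <- function(x, ...) {
  cat(sprintf("critical_interval: %s:%d-%d (%s bp), defined by %d left / %d right recombinant copies\n",
              x$chrom, x$start_pos, x$end_pos,
              format(interval_length(x), big.mark = ","),
              x$left_breakpoints, x$right_breakpoints))
  if (any(x$edge_warning)) cat("  [extends to panel edge]\n")
  invisible(x)
}

#' Length of a critical interval in base pairs
#'
#' Uses the end - start convention (e.g. 56,037,676 - 55,850,299 =
#' 187,377).
#'
#' @param interval a [critical_interval], or anything with `start_pos` and
#'   `end_pos`.
#' @return integer length in bp.
#' @export
interval_length <- function(interval) {
  as.integer(interval$end_pos) - as.integer(interval$start_pos)
}

#' Core associated haplotype within the critical interval
#'
#' Restricts the consensus to the interval markers that are themselves
#' strongly associated: those whose single-marker p passes the scan's
#' significance threshold OR whose r-squared with the index SNP exceeds
#' the pruning threshold.
#'
#' @param interval a [critical_interval].
#' @param consensus a [consensus_haplotype] over the full marker set.
#' @param scan an [lmm_scan] result over the same markers.
#' @param G the [genotype_matrix] used for r-squared.
#' @param index_marker index-SNP column.
#' @param r2_threshold LD threshold (default 0.2).
#' @return object of class `core_haplotype` with `markers` (indices) and
#'   `alleles`.
#' @export
core_haplotype <- function(interval, consensus, scan, G, index_marker,
                           r2_threshold = 0.2) {
  idx <- interval$start_index:interval$end_index
  keep <- vapply(idx, function(j) {
    sig <- !is.na(scan$result$p[j]) && scan$result$p[j] < scan$threshold_p
    if (sig) return(TRUE)
    if (j == index_marker) return(TRUE)
    sdj <- stats::sd(G$dosages[, j], na.rm = TRUE)
    if (is.na(sdj) || sdj == 0) return(FALSE)
    ld_r2(G, index_marker, j) > r2_threshold
  }, logical(1))
  structure(list(markers = idx[keep],
                 alleles = consensus$alleles[idx[keep]]),
            class = "core_haplotype")
}

#' Carrier statistics for a core haplotype
#'
#' A chromosome copy is a carrier iff it matches the core haplotype at
#' every defining marker.  Counts and frequencies are reported for the
#' case (phenotype at or below the threshold, per `rule`) and control
#' chromosome groups, and the per-sample phenotype is compared between
#' carrier-bearing samples (at least one carrier copy) and non-carriers by
#' a two-sided Student's t test.
#'
#' @param panel a [haplotype_panel].
#' @param core a [core_haplotype] (or list with `markers`, `alleles`).
#' @param phenotype per-sample phenotype.
#' @param threshold,rule case definition (see [select_cases()]).
#' @return object of class `carrier_stats` with a per-group table
#'   (`carriers`, `total`, `frequency_pct`) and `t_test`
#'   (`statistic`, `p.value`) or a note when it cannot be computed.
#' @export
carrier_stats <- function(panel, core, phenotype, threshold = -0.2,
                          rule = c("le", "lt")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  rule <- match.arg(rule)
  sub <- panel$alleles[, core$markers, drop = FALSE]
  is_carrier <- rowSums(sub == matrix(rep(core$alleles, each = nrow(sub)),
                                      nrow(sub), length(core$alleles))) ==
    length(core$alleles)
  copy_pheno <- rep(phenotype, each = 2L)
  is_case_copy <- if (rule == "le") copy_pheno <= threshold else copy_pheno < threshold

  grp <- function(sel) {
    cnt <- sum(is_carrier[sel]); tot <- sum(sel)
    c(carriers = cnt, total = tot,
      frequency_pct = if (tot) 100 * cnt / tot else NA_real_)
  }
  tab <- rbind(case = grp(is_case_copy), control = grp(!is_case_copy))

  n <- length(panel$sample_ids)
  sample_carrier <- is_carrier[seq(1L, 2L * n, 2L)] | is_carrier[seq(2L, 2L * n, 2L)]
  t_test <- NULL; note <- NULL
  if (sum(sample_carrier) >= 2L && sum(!sample_carrier) >= 2L) {
    ht <- stats::t.test(phenotype[sample_carrier], phenotype[!sample_carrier],
                        var.equal = TRUE)
    t_test <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  } else note <- "carrier t test skipped: fewer than 2 samples in a class"
  structure(list(table = tab, t_test = t_test, note = note,
                 copy_carrier = is_carrier, sample_carrier = sample_carrier),
            class = "carrier_stats")
}

#' @export
print.carrier_stats <- function(x, ...) {
  for (g in rownames(x$table))
    cat(sprintf("  %s: %d of %d chromosomes (%.1f%%)\n", g,
                x$table[g, "carriers"], x$table[g, "total"],
                x$table[g, "frequency_pct"]))
  if (!is.null(x$t_test))
    cat(sprintf("  carrier vs non-carrier t = %.3f, p = %.3g\n",
                x$t_test$statistic, x$t_test$p.value))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}
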