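#' Multi-sample variant table
#'
#' Variant records (SNV/INDEL/SV) over a genomic region with per-sample
#' genotype calls coded `hom_ref` / `het` / `hom_alt` / `missing`.
#' Multi-allelic sites are represented as one biallelic record per ALT
#' allele, so each record's candidate allele is either its REF or its ALT.
#'
#' @param records data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `vtype` in `{"SNV","INDEL","SV"}`.
#' @param genotypes records x samples character matrix of codes.
#' @param region list with `chrom`, `start`, `end` bounding the records.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(records, genotypes, region) {
  genotypes <- as.matrix(genotypes)
  if (nrow(records) != nrow(genotypes))
    stop("records and genotype rows must match")
  if (!all(genotypes %in% c("hom_ref", "het", "hom_alt", "missing")))
    stop("genotype codes must be hom_ref/het/hom_alt/missing")
  if (!all(records$vtype %in% c("SNV", "INDEL", "SV")))
    stop("vtype must be SNV, INDEL or SV")
  bad <- records$vtype == "SNV" &
    (nchar(records$ref) != 1L | nchar(records$alt) != 1L)
  if (any(bad)) stop("SNV records must have single-base ref and alt alleles")
  if (any(records$pos < region$start | records$pos > region$end))
    stop("record positions fall outside the region")
  structure(list(records = records, genotypes = genotypes, region = region),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d records (%d SNV/INDEL, %d SV) over %s:%d-%d, %d samples\n",
              nrow(x$records), sum(x$records$vtype != "SV"),
              sum(x$records$vtype == "SV"), x$region$chrom,
              x$region$start, x$region$end, ncol(x$genotypes)))
  invisible(x)
}

#' Sample group labels for identity-by-descent filtering
#'
#' @param case_hom samples homozygous for the associated haplotype.
#' @param control haplotype-free (dolichocephalic) samples.
#' @param wild wild canid samples.
#' @return object of class `sample_groups`; groups must be disjoint and
#'   non-empty.
#' @export
sample_groups <- function(case_hom, control, wild) {
  g <- list(case_hom = case_hom, control = control, wild = wild)
  if (any(lengths(g) == 0L)) stop("all three groups must be non-empty")
  if (anyDuplicated(unlist(g))) stop("groups must be disjoint")
  structure(g, class = "sample_groups")
}

#' Candidate allele of a record under the identity-by-descent assumptions
#'
#' Haplotype-homozygous case genomes are assumed to carry, and be fixed
#' for, the same inherited causal allele; the candidate allele is therefore
#' the single allele for which every non-missing case sample is homozygous.
#' It may be the REFERENCE allele (the assembly derives from a
#' haplotype-fixed brachycephalic breed) or the ALT.  Missing calls are
#' non-informative.
#'
#' @param genotypes named character vector of codes for one record.
#' @param groups a [sample_groups].
#' @return list with `candidate` (`"REF"`/`"ALT"`) or `NULL` plus `reason`
#'   (`"ok"`, `"no_data"`, `"case_not_fixed"`).
#' @export
assign_candidate_allele <- function(genotypes, groups) {
  g <- genotypes[groups$case_hom]
  g <- g[g != "missing"]
  if (!length(g)) return(list(candidate = NULL, reason = "no_data"))
  if (all(g == "hom_alt")) return(list(candidate = "ALT", reason = "ok"))
  if (all(g == "hom_ref")) return(list(candidate = "REF", reason = "ok"))
  list(candidate = NULL, reason = "case_not_fixed")
}

## Does a genotype code carry the given candidate allele?
.carries <- function(code, candidate) {
  if (candidate == "ALT") code %in% c("het", "hom_alt")
  else code %in% c("het", "hom_ref")
}

#' Filter variants by the five identity-by-descent assumptions
#'
#' A record survives iff (i) a single candidate allele can be assigned
#' (every non-missing haplotype-homozygous case sample homozygous for it,
#' REF or ALT); (ii) no non-missing wild canid carries the candidate
#' allele (the causal variant is derived, hence absent from wolves);
#' (iii) no non-missing haplotype-free control carries it.  Missing
#' genotypes never eliminate a record (absence of a call is not absence of
#' the allele) unless `strict = TRUE`, which additionally requires at
#' least one non-missing wild and control call.  Eliminations are tallied
#' by the first failing rule in the order (i), (ii), (iii).
#'
#' @param table a [variant_table].
#' @param groups a [sample_groups].
#' @param strict require informative wild and control calls (default
#'   `FALSE`).
#' @return object of class `filter_report` with `pre` / `post` counts by
#'   variant class (SNV/INDEL pooled vs SV), per-rule `eliminated`
#'   tallies, `no_data` exclusions, `survivors` (record indices with
#'   candidate alleles).
#' @export
filter_variants <- function(table, groups, strict = FALSE) {
  stopifnot(inherits(table, "variant_table"), inherits(groups, "sample_groups"))
  n <- nrow(table$records)
  cls <- ifelse(table$records$vtype == "SV", "SV", "SNV/INDEL")
  pre <- c(`SNV/INDEL` = sum(cls == "SNV/INDEL"), SV = sum(cls == "SV"))
  status <- character(n)
  cand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    gi <- table$genotypes[i, ]
    a <- assign_candidate_allele(gi, groups)
    if (a$reason != "ok") { status[i] <- a$reason; next }
    gw <- gi[groups$wild]; gc <- gi[groups$control]
    if (strict && (all(gw == "missing") || all(gc == "missing"))) {
      status[i] <- "no_data"; next
    }
    if (any(.carries(gw[gw != "missing"], a$candidate))) {
      status[i] <- "wild_carrier"; next
    }
    if (any(.carries(gc[gc != "missing"], a$candidate))) {
      status[i] <- "control_carrier"; next
    }
    status[i] <- "pass"
    cand[i] <- a$candidate
  }
  surv <- which(status == "pass")
  post <- c(`SNV/INDEL` = sum(cls[surv] == "SNV/INDEL"),
            SV = sum(cls[surv] == "SV"))
  structure(list(pre = pre, post = post,
                 eliminated = c(case_not_fixed = sum(status == "case_not_fixed"),
                                wild_carrier = sum(status == "wild_carrier"),
                                control_carrier = sum(status == "control_carrier")),
                 no_data = sum(status == "no_data"),
                 survivors = data.frame(index = surv,
                                        table$records[surv, , drop = FALSE],
                                        candidate = cand[surv],
                                        row.names = NULL),
                 status = status),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filtering within the critical interval\n")
  cat(sprintf("  %-14s %10s %10s\n", "", "SNVs/INDELs", "SVs"))
  cat(sprintf("  %-14s %10s %10s\n", "Pre-filtering",
              format(x$pre[1L], big.mark = ","), format(x$pre[2L], big.mark = ",")))
  cat(sprintf("  %-14s %10d %10d\n", "Post-filtering", x$post[1L], x$post[2L]))
  cat("  eliminated:", paste(sprintf("%s=%d", names(x$eliminated), x$eliminated),
                             collapse = ", "),
      sprintf("; no_data=%d\n", x$no_data))
  invisible(x)
}

#' Pairwise complete-LD check among surviving variants
#'
#' Computes carrier status (any copy of the candidate allele) for every
#' sample of an extended cohort and declares two survivors in complete
#' linkage disequilibrium iff the squared correlation of their carrier
#' vectors is 1 within 1e-9.  Monomorphic survivors are marked
#' not-assessable (`NA`).
#'
#' @param survivors data.frame as returned in `filter_report$survivors`
#'   (needs a `candidate` column) -- or a logical carrier matrix
#'   (survivors x samples) directly.
#' @param genotypes records x samples genotype-code matrix over the
#'   extended cohort, rows aligned with `survivors$index` (ignored when a
#'   carrier matrix is given).
#' @return list with `r2` (pairwise matrix) and `complete_ld` (single
#'   logical: all assessable pairs at r-squared 1).
#' @export
complete_ld_check <- function(survivors, genotypes = NULL) {
  if (is.matrix(survivors) && is.logical(survivors)) {
    carr <- survivors
  } else {
    if (nrow(survivors) < 2L) stop("need at least 2 surviving records")
    carr <- t(vapply(seq_len(nrow(survivors)), function(i) {
      gi <- genotypes[i, ]
      out <- rep(NA, length(gi))
      ok <- gi != "missing"
      out[ok] <- .carries(gi[ok], survivors$candidate[i])
      out
    }, logical(ncol(genotypes))))
  }
  ns <- nrow(carr)
  if (ns < 2L) stop("need at least 2 surviving records")
  r2 <- matrix(NA_real_, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    ok <- !is.na(carr[i, ]) & !is.na(carr[j, ])
    xi <- as.numeric(carr[i, ok]); xj <- as.numeric(carr[j, ok])
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # not assessable
    r2[i, j] <- stats::cor(xi, xj)^2
  }
  off <- r2[upper.tri(r2)]
  list(r2 = r2,
       complete_ld = length(off[!is.na(off)]) > 0 &&
         all(abs(off[!is.na(off)] - 1) < 1e-9))
}
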