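# Shared fixture builders; everything is generated in code at test time.

# Small random landmark set with optional planted structure.
make_landmarks <- function(n = 8, k = 10, d = 2, noise = 0.05, seed = 1) {
  set.seed(seed)
  M <- skullqtl:::.template_shape(k, d)
  coords <- array(NA_real_, c(n, k, d))
  for (i in seq_len(n))
    coords[i, , ] <- M + matrix(rnorm(k * d, 0, noise), k, d)
  landmark_set(coords)
}

# Apply a random similarity transform (rotation, scale, translation) to one
# specimen of a landmark set.
transform_specimen <- function(lms, i, seed = 1) {
  set.seed(seed)
  d <- lms$d
  R <- skullqtl:::.random_rotation(d)
  s <- exp(rnorm(1, 0, 0.5))
  tr <- runif(d, -10, 10)
  ci <- matrix(lms$coords[i, , ], lms$k, d)
  lms$coords[i, , ] <- sweep(s * ci %*% R, 2, tr, "+")
  lms
}

# Constructed phased panel: n_samples, m markers, all-zero background.
make_panel <- function(alleles, map = NULL) {
  n <- nrow(alleles) / 2
  if (is.null(map))
    map <- data.frame(chrom = "1", pos = 1000L * seq_len(ncol(alleles)),
                      id = sprintf("m%03d", seq_len(ncol(alleles))),
                      ref = "A", alt = "G")
  haplotype_panel(alleles, sprintf("s%03d", seq_len(n)), map)
}

# Small random variant table with known genotype codes.
random_variant_table <- function(n_rec = 20, n_case = 4, n_ctrl = 5,
                                 n_wild = 4, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("case%02d", 1:n_case), sprintf("ctrl%02d", 1:n_ctrl),
               sprintf("wild%02d", 1:n_wild))
  region <- list(chrom = "1", start = 100L, end = 100000L)
  codes <- c("hom_ref", "het", "hom_alt", "missing")
  G <- matrix(sample(codes, n_rec * length(samples), TRUE,
                     prob = c(0.45, 0.2, 0.25, 0.1)),
              n_rec, length(samples), dimnames = list(NULL, samples))
  rec <- data.frame(chrom = "1", pos = sort(sample(100:100000, n_rec)),
                    ref = "A", alt = "G",
                    vtype = sample(c("SNV", "SV"), n_rec, TRUE, c(0.9, 0.1)))
  list(table = variant_table(rec, G, region),
       groups = sample_groups(samples[1:n_case],
                              samples[n_case + 1:n_ctrl],
                              samples[n_case + n_ctrl + 1:n_wild]))
}

# Independent brute-force oracle for the five-assumption filter: literal
# nested-loop restatement of the rules, separate from the implementation.
oracle_filter_status <- function(table, groups) {
  status <- character(nrow(table$records))
  for (i in seq_len(nrow(table$records))) {
    g <- table$genotypes[i, ]
    case <- g[groups$case_hom]
    case <- case[case != "missing"]
    if (length(case) == 0) { status[i] <- "no_data"; next }
    cand <- NULL
    if (length(unique(case)) == 1 && unique(case) == "hom_alt") cand <- "ALT"
    if (length(unique(case)) == 1 && unique(case) == "hom_ref") cand <- "REF"
    if (is.null(cand)) { status[i] <- "case_not_fixed"; next }
    bad_codes <- if (cand == "ALT") c("het", "hom_alt") else c("het", "hom_ref")
    hit <- FALSE
    for (w in groups$wild)
      if (g[w] != "missing" && g[w] %in% bad_codes) hit <- TRUE
    if (hit) { status[i] <- "wild_carrier"; next }
    hit <- FALSE
    for (ct in groups$control)
      if (g[ct] != "missing" && g[ct] %in% bad_codes) hit <- TRUE
    if (hit) { status[i] <- "control_carrier"; next }
    status[i] <- "pass"
  }
  status
}

# Brute-force two-sided exact MWW p by explicit enumeration of group
# assignments, computing the U statistic by pairwise comparisons.
oracle_mww_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  U <- u_of(x, y)
  cmb <- utils::combn(nx + ny, nx)
  us <- apply(cmb, 2, function(ix) u_of(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(us <= U), mean(us >= U)))
}
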