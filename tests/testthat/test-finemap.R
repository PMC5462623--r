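# Brute-force oracle for the critical interval: for each side, scan every
# gap outward from the index and accumulate per-copy breakpoints computed
# from scratch.
oracle_interval <- function(H, cons, index, min_recomb) {
  m <- ncol(H)
  runs <- lapply(seq_len(nrow(H)), function(i) {
    if (H[i, index] != cons[index]) return(NULL)      # non-carrier
    lo <- index
    while (lo > 1 && H[i, lo - 1] == cons[lo - 1]) lo <- lo - 1
    hi <- index
    while (hi < m && H[i, hi + 1] == cons[hi + 1]) hi <- hi + 1
    c(lo, hi)
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  lb <- NA
  if (index > 1) for (g in (index - 1):1) {
    cnt <- sum(vapply(runs, function(r) r[1] - 1 >= g && r[1] > 1, logical(1)))
    if (cnt >= min_recomb) { lb <- g; break }
  }
  rb <- NA
  if (index < m) for (g in index:(m - 1)) {
    cnt <- sum(vapply(runs, function(r) r[2] <= g && r[2] < m, logical(1)))
    if (cnt >= min_recomb) { rb <- g; break }
  }
  c(start = if (is.na(lb)) 1 else lb + 1, end = if (is.na(rb)) m else rb)
}

test_that("window haplotype association flags the discriminating window", {
  # panel where one 10-marker haplotype perfectly partitions the phenotype
  set.seed(21)
  n <- 40; m <- 30
  H <- matrix(rbinom(2 * n * m, 1, 0.5), 2 * n, m)
  carrier <- rep(c(TRUE, FALSE), each = n)          # copies of samples 1..20
  pattern <- rep(c(1L, 0L), 5)
  H[carrier, 11:20] <- matrix(pattern, sum(carrier), 10, byrow = TRUE)
  # perturb any non-carrier copy that reproduces the pattern by chance
  clash <- !carrier & rowSums(H[, 11:20] ==
                                matrix(pattern, 2 * n, 10, byrow = TRUE)) == 10
  H[clash, 11] <- 1L - pattern[1]
  panel <- make_panel(H)
  pheno <- ifelse(carrier[seq(1, 2 * n, 2)] | carrier[seq(2, 2 * n, 2)], -1, 1) +
    rnorm(n, 0, 0.1)
  res <- window_haplotype_assoc(panel, pheno, window = 10)
  expect_true(which.min(res$p) %in% 2:20)           # overlaps the planted run
  # identical phenotypes: no window discriminates
  flat <- window_haplotype_assoc(panel, rep(1, n), window = 10)
  expect_true(all(is.na(flat$p) | flat$p > 0.999))
  # the haplotype window beats the best single marker in it
  G <- panel_to_genotypes(panel)
  scan <- lmm_scan(pheno, G, diag(n))
  expect_lt(res$p[11], min(scan$result$p[11:20], na.rm = TRUE))
})

test_that("case selection respects threshold boundary and rule", {
  ph <- c(-0.3, -0.2, -0.1)
  expect_identical(select_cases(ph), 1:2)
  expect_identical(select_cases(ph, rule = "lt"), 1L)
  expect_error(select_cases(ph, threshold = -1), "no samples")
})

test_that("consensus haplotype equals brute-force column majority", {
  all_same <- matrix(1L, 5, 8)
  cs <- consensus_haplotype(all_same)
  expect_identical(cs$alleles, rep(1L, 8))
  expect_identical(cs$support, rep(1, 8))
  # 3 copies, 2 share allele 1 at a marker
  H3 <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L))
  cs3 <- consensus_haplotype(H3)
  expect_identical(cs3$alleles, c(1L, 1L))
  expect_equal(cs3$support, c(2 / 3, 2 / 3))
  # random odd panel vs per-column majority
  set.seed(22)
  H <- matrix(rbinom(9 * 30, 1, 0.5), 9, 30)
  cs9 <- consensus_haplotype(H)
  manual <- apply(H, 2, function(col) as.integer(sum(col) > 4.5))
  expect_identical(cs9$alleles, manual)
  expect_true(all(cs9$support >= 0.5 & cs9$support <= 1))
  # exact tie broken toward the most-negative-phenotype copy
  Ht <- rbind(c(1L, 0L), c(0L, 1L))
  cst <- consensus_haplotype(Ht, copy_phenotype = c(0.5, -0.5))
  expect_identical(cst$alleles, c(0L, 1L))
})

test_that("critical interval matches a hand-constructed breakpoint layout", {
  # 20 markers, index at 10; 3 copies recombine at gap 5 (left) and 3 at
  # gap 15 (right); remaining copies match full length
  m <- 20; idx <- 10
  cons <- rep(1L, m)
  H <- matrix(1L, 12, m)
  for (i in 1:3) H[i, 1:5] <- 0L          # left breakpoint at gap 5
  for (i in 4:6) H[i, 16:m] <- 0L         # right breakpoint at gap 15
  map <- data.frame(chrom = "1", pos = 100L * seq_len(m))
  ci <- critical_interval(H, cons, idx, map, min_recomb = 3)
  expect_identical(ci$start_index, 6L)
  expect_identical(ci$end_index, 15L)
  expect_identical(ci$start_pos, 600L)
  expect_identical(ci$end_pos, 1500L)
  expect_identical(unname(ci$left_breakpoints), 3L)
  expect_identical(unname(ci$right_breakpoints), 3L)
  expect_false(any(ci$edge_warning))
  # brute-force oracle agreement
  or <- oracle_interval(H, cons, idx, 3)
  expect_identical(c(ci$start_index, ci$end_index), as.integer(or))
})

test_that("critical interval handles edges, monotonicity and permutations", {
  m <- 15; idx <- 8
  cons <- rep(1L, m)
  # all copies fully match: interval spans the panel with a warning
  Hfull <- matrix(1L, 6, m)
  map <- data.frame(chrom = "1", pos = 10L * seq_len(m))
  expect_warning(ci <- critical_interval(Hfull, cons, idx, map), "panel edge")
  expect_identical(c(ci$start_index, ci$end_index), c(1L, 15L))
  expect_true(all(ci$edge_warning))
  # random panels: min_recomb=1 interval within min_recomb=3 interval,
  # index always inside, copy order irrelevant, oracle agreement
  set.seed(23)
  for (r in 1:25) {
    H <- matrix(rbinom(16 * m, 1, 0.8), 16, m)
    H[, idx] <- 1L                                  # all carriers at index
    ci1 <- suppressWarnings(critical_interval(H, cons, idx, map, 1))
    ci3 <- suppressWarnings(critical_interval(H, cons, idx, map, 3))
    expect_gte(ci1$start_index, ci3$start_index)
    expect_lte(ci1$end_index, ci3$end_index)
    expect_true(ci3$start_index <= idx && idx <= ci3$end_index)
    or <- oracle_interval(H, cons, idx, 3)
    expect_identical(c(ci3$start_index, ci3$end_index), as.integer(or))
    perm <- sample(16)
    cip <- suppressWarnings(critical_interval(H[perm, ], cons, idx, map, 3))
    expect_identical(c(cip$start_index, cip$end_index),
                     c(ci3$start_index, ci3$end_index))
  }
})

test_that("recombinant-rich case panels recover the planted run", {
  # constructed strong-effect regime: full carriers plus >= 5 planted
  # recombinants per side; recovered interval must contain the run
  set.seed(24)
  m <- 60
  run <- 26:37
  ok <- 0
  for (r in 1:20) {
    cons <- rep(1L, m)
    H <- matrix(1L, 30, m)
    # background outside the run diverges from consensus randomly
    for (i in 1:30) {
      flip <- which(runif(m) < 0.15)
      flip <- setdiff(flip, run)
      H[i, flip] <- 0L
    }
    # 6 recombinants per side breaking exactly at the run edges
    for (i in 1:6) H[i, 1:(min(run) - 1)] <- 0L
    for (i in 7:12) H[i, (max(run) + 1):m] <- 0L
    map <- data.frame(chrom = "1", pos = 50L * seq_len(m))
    ci <- suppressWarnings(
      critical_interval(H, cons, sample(run, 1), map, min_recomb = 3))
    if (ci$start_index <= min(run) && ci$end_index >= max(run)) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})

test_that("interval length uses the end-minus-start convention", {
  iv <- list(start_pos = 55850299, end_pos = 56037676)
  expect_identical(interval_length(iv), 187377L)
  expect_identical(interval_length(list(start_pos = 5, end_pos = 5)), 0L)
  shift <- list(start_pos = 55850299 + 1e6, end_pos = 56037676 + 1e6)
  expect_identical(interval_length(shift), 187377L)
})

test_that("carrier statistics count matching chromosomes exactly", {
  # 6 samples; core haplotype 1,1 at markers 2-3
  H <- matrix(0L, 12, 5)
  carriers <- c(1, 2, 3, 7)                       # copy rows carrying the core
  H[carriers, 2:3] <- 1L
  panel <- make_panel(H)
  core <- list(markers = 2:3, alleles = c(1L, 1L))
  pheno <- c(-0.5, -0.4, -0.3, 0.1, 0.2, 0.3)
  cs <- carrier_stats(panel, core, pheno)
  # case copies: samples 1-3 -> 6 copies, carriers among them: rows 1,2,3 -> wait
  # rows 1,2 are sample 1; rows 3,4 sample 2; row 7 is sample 4 (control)
  expect_identical(unname(cs$table["case", c("carriers", "total")]), c(3, 6))
  expect_identical(unname(cs$table["control", c("carriers", "total")]), c(1, 6))
  expect_equal(unname(cs$table["case", "frequency_pct"]), 50)
  # no copy matches: zero frequency and skipped t test
  none <- carrier_stats(panel, list(markers = 4:5, alleles = c(1L, 1L)), pheno)
  expect_identical(unname(none$table[, "carriers"]), c(0, 0))
  expect_match(none$note, "skipped")
})

test_that("published carrier-frequency arithmetic reproduces to one decimal", {
  # fixture with the published counts: 63 of 74 case chromosomes, 28 of 674
  n_case <- 37; n_ctrl <- 337
  H <- matrix(0L, 2 * (n_case + n_ctrl), 3)
  case_rows <- seq_len(2 * n_case)
  ctrl_rows <- 2 * n_case + seq_len(2 * n_ctrl)
  H[case_rows[1:63], ] <- 1L
  H[ctrl_rows[1:28], ] <- 1L
  panel <- make_panel(H)
  pheno <- c(rep(-0.5, n_case), rep(0.5, n_ctrl))
  cs <- carrier_stats(panel, list(markers = 1:3, alleles = rep(1L, 3)), pheno)
  expect_identical(unname(cs$table["case", c("carriers", "total")]), c(63, 74))
  expect_identical(unname(cs$table["control", c("carriers", "total")]), c(28, 674))
  expect_equal(round(cs$table["case", "frequency_pct"], 1), 85.1)
  expect_equal(round(cs$table["control", "frequency_pct"], 1), 4.2)
})
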