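#' Configuration for a synthetic skull-QTL study
#'
#' Bundles the parameters of the generative model: a breed-structured
#' diploid panel (Balding-Nichols allele frequencies, founder-haplotype LD
#' blocks) carrying a planted multi-marker causal haplotype, and landmark
#' configurations with isometric size variation, an allometric shape trend
#' and an additive QTL shape displacement confined to the facial skeleton.
#'
#' Defaults emulate the study design this pipeline targets: 374 dogs across
#' 12 breeds of which ~15% are "case" (brachycephalic-type) breeds, a 12-marker
#' causal haplotype at frequency 0.90 on case-breed chromosomes and 0.03
#' elsewhere, and a QTL shape effect large enough that homozygous-derived
#' animals fall below the conventional PC1 case threshold of -0.2.
#'
#' @param n_dogs number of diploid samples.
#' @param n_breeds number of breeds; the first `max(1, round(0.15*n_breeds))`
#'   are case breeds.
#' @param fst Balding-Nichols divergence parameter in (0,1).
#' @param n_snps number of markers.
#' @param ld_block_len markers per LD block.
#' @param causal_markers length of the planted contiguous causal haplotype.
#' @param causal_freq_case_breeds,causal_freq_other planted-haplotype
#'   frequency on case-breed / other chromosomes, in `[0,1]`.
#' @param n_landmarks,dims landmark count and dimension (2 or 3).
#' @param allometry_slope shape change per log-size unit.
#' @param qtl_effect shape displacement per causal-dosage unit, in
#'   unit-centroid-size shape units.
#' @param noise_sd per-coordinate landmark noise SD.
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_dogs = 374L, n_breeds = 12L, fst = 0.15,
                       n_snps = 1000L, ld_block_len = 10L,
                       causal_markers = 12L,
                       causal_freq_case_breeds = 0.90,
                       causal_freq_other = 0.03,
                       n_landmarks = 30L, dims = 3L,
                       allometry_slope = 0.3, qtl_effect = 0.15,
                       noise_sd = 0.01, seed = 1L) {
  cfg <- list(n_dogs = as.integer(n_dogs), n_breeds = as.integer(n_breeds),
              fst = fst, n_snps = as.integer(n_snps),
              ld_block_len = as.integer(ld_block_len),
              causal_markers = as.integer(causal_markers),
              causal_freq_case_breeds = causal_freq_case_breeds,
              causal_freq_other = causal_freq_other,
              n_landmarks = as.integer(n_landmarks), dims = as.integer(dims),
              allometry_slope = allometry_slope, qtl_effect = qtl_effect,
              noise_sd = noise_sd, seed = as.integer(seed))
  with(cfg, {
    if (n_dogs < 2L || n_breeds < 1L) stop("need >= 2 dogs and >= 1 breed")
    if (fst <= 0 || fst >= 1) stop("fst must lie in (0,1)")
    if (causal_markers > n_snps)
      stop("causal_markers exceeds n_snps: invalid configuration")
    for (f in c(causal_freq_case_breeds, causal_freq_other))
      if (f < 0 || f > 1) stop("haplotype frequencies must lie in [0,1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  })
  structure(cfg, class = "sim_config")
}

## Balding-Nichols breed allele frequency given ancestral p0 and fst.
.bn_freq <- function(p0, fst, n) {
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  stats::rbeta(n, a, b)
}

#' Simulate a breed-structured phased genotype panel
#'
#' Chromosome copies are built block-by-block: each LD block has an
#' ancestral haplotype frequency drawn Uniform(0.1, 0.9), per-breed
#' frequencies drawn from the Balding-Nichols beta model with variance
#' scaled by `fst`, and two complementary founder haplotypes copied with a
#' 1% per-marker mutation rate (so markers within a block share a haplotype
#' frequency and show high r-squared without a coalescent simulator).  A
#' contiguous run of `causal_markers` markers is overwritten with the
#' planted haplotype on carrier chromosomes drawn at breed-specific carrier
#' frequencies; a non-carrier chromosome that happens to match the planted
#' alleles is perturbed at the first causal marker so degenerate-frequency
#' configurations behave exactly.
#'
#' @param config a [sim_config].
#' @return list of class `genotype_sim` with `panel` (a [haplotype_panel]),
#'   `dosages` (samples x markers, 0/1/2), `breed` (per-sample labels),
#'   `case_breeds`, and `truth` (`causal_idx`, `planted_alleles`,
#'   `causal_dosage` per sample, `carrier` per copy).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_dogs
  nc <- 2L * n
  m <- config$n_snps
  breeds <- sprintf("breed%02d", seq_len(config$n_breeds))
  breed <- breeds[1L + (seq_len(n) - 1L) %% config$n_breeds]
  case_breeds <- breeds[seq_len(max(1L, round(config$n_breeds * 0.15)))]
  copy_breed <- rep(breed, each = 2L)

  blocks <- split(seq_len(m), (seq_len(m) - 1L) %/% config$ld_block_len)
  H <- matrix(0L, nc, m)
  mu <- 0.01                                    # founder mutation rate
  for (bl in blocks) {
    p0 <- stats::runif(1L, 0.1, 0.9)
    pb <- stats::setNames(.bn_freq(p0, config$fst, config$n_breeds), breeds)
    hA <- stats::rbinom(length(bl), 1L, 0.5)
    hB <- 1L - hA
    pick <- stats::rbinom(nc, 1L, pb[copy_breed]) == 1L
    blk <- matrix(rep(hB, each = nc), nc, length(bl))
    blk[pick, ] <- matrix(rep(hA, each = sum(pick)), sum(pick), length(bl))
    flips <- matrix(stats::rbinom(nc * length(bl), 1L, mu), nc, length(bl))
    H[, bl] <- (blk + flips) %% 2L
  }

  ## plant the causal haplotype on a centred contiguous run.  The run's
  ## markers are the haplotype's own tag variants: derived (allele 1) on the
  ## IBD segment, present only at low sporadic frequency in the background,
  ## as expected for a derived haplotype shared identical-by-descent
  cm <- config$causal_markers
  start <- max(1L, (m - cm) %/% 2L + 1L)
  causal_idx <- start:(start + cm - 1L)
  eps <- stats::runif(cm, 0.01, 0.08)
  H[, causal_idx] <- matrix(stats::rbinom(nc * cm, 1L, rep(eps, each = nc)),
                            nc, cm)
  planted <- rep(1L, cm)
  freq <- ifelse(copy_breed %in% case_breeds,
                 config$causal_freq_case_breeds, config$causal_freq_other)
  carrier <- stats::rbinom(nc, 1L, freq) == 1L
  H[carrier, causal_idx] <- matrix(rep(planted, each = sum(carrier)),
                                   sum(carrier), cm)
  if (any(!carrier)) {
    clash <- !carrier &
      rowSums(H[, causal_idx, drop = FALSE] ==
                matrix(rep(planted, each = nc), nc, cm)) == cm
    H[clash, causal_idx[1L]] <- 1L - planted[1L]
  }

  map <- data.frame(chrom = "1", pos = 55000000L + (seq_len(m) - 1L) * 2000L,
                    id = sprintf("snp%05d", seq_len(m)),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  sample_ids <- sprintf("dog%03d", seq_len(n))
  panel <- haplotype_panel(H, sample_ids, map)
  dos <- H[seq(1L, nc, 2L), , drop = FALSE] + H[seq(2L, nc, 2L), , drop = FALSE]
  rownames(dos) <- sample_ids
  colnames(dos) <- map$id
  cd <- as.integer(carrier[seq(1L, nc, 2L)]) + as.integer(carrier[seq(2L, nc, 2L)])
  structure(list(panel = panel, dosages = dos,
                 breed = stats::setNames(breed, sample_ids),
                 case_breeds = case_breeds,
                 truth = list(causal_idx = causal_idx,
                              planted_alleles = planted,
                              causal_dosage = stats::setNames(cd, sample_ids),
                              carrier = carrier)),
            class = "genotype_sim")
}

## Deterministic template mean shape with unit centroid size: points on an
## anisotropic ellipse (2D) / spiralled ellipsoid (3D), so no two landmarks
## coincide and all three substructure masks span distinct regions.
.template_shape <- function(k, d) {
  t <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  M <- if (d == 2L) cbind(1.3 * cos(t), 0.9 * sin(t))
  else cbind(1.3 * cos(t), 0.9 * sin(t), 0.6 * sin(2 * t + 0.5))
  M <- sweep(M, 2, colMeans(M), "-")
  M / centroid_size(M)
}

## Random proper rotation (det +1): 2D by angle, 3D via QR of a Gaussian
## matrix with sign fix.
.random_rotation <- function(d) {
  if (d == 2L) {
    th <- stats::runif(1, 0, 2 * pi)
    return(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L))
  }
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Simulate landmark configurations with a planted QTL shape effect
#'
#' Specimen `i` is built as `s_i * R_i (M + log(s_i) * a * A + d_i * q * V + E_i) + t_i`
#' where `M` is a fixed unit-centroid-size mean shape, `A` a unit-norm
#' allometry direction (`a = allometry_slope`), `V` a unit-norm QTL
#' displacement direction confined to the viscerocranium mask
#' (`q = qtl_effect`, `d_i` the causal dosage), `E_i` iid Gaussian noise,
#' and `R_i`, `t_i`, `s_i` random rotation / translation / scale -- so the
#' Procrustes fit downstream is genuinely exercised.  Substructure masks
#' (neurocranium : viscerocranium : mandible, proportioned 18:25:30) are
#' attached, and the generative truth is recorded.
#'
#' @param dosage per-sample causal dosage in `{0,1,2}` (length `n_dogs`).
#' @param config a [sim_config].
#' @return list of class `landmark_sim` with `landmarks` (a
#'   [landmark_set]) and `truth` (`sizes`, `A`, `V`, `dosage`).
#' @export
simulate_landmarks <- function(dosage, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_dogs
  if (length(dosage) != n) stop("dosage length must equal n_dogs")
  set.seed(config$seed + 1L)
  k <- config$n_landmarks
  d <- config$dims
  M <- .template_shape(k, d)

  ## masks proportioned like the published substructures (18:25:30)
  w <- c(neurocranium = 18, viscerocranium = 25, mandible = 30)
  cuts <- round(cumsum(w / sum(w)) * k)
  masks <- list(neurocranium = seq_len(cuts[1L]),
                viscerocranium = (cuts[1L] + 1L):cuts[2L],
                mandible = (cuts[2L] + 1L):k)

  A <- matrix(stats::rnorm(k * d), k, d)
  A <- A / sqrt(sum(A^2))
  V <- matrix(0, k, d)
  V[masks$viscerocranium, ] <- stats::rnorm(length(masks$viscerocranium) * d)
  V <- V / sqrt(sum(V^2))

  sizes <- exp(stats::rnorm(n, 0, 0.25))
  coords <- array(NA_real_, c(n, k, d))
  for (i in seq_len(n)) {
    shp <- M + log(sizes[i]) * config$allometry_slope * A +
      dosage[i] * config$qtl_effect * V +
      matrix(stats::rnorm(k * d, 0, config$noise_sd), k, d)
    R <- .random_rotation(d)
    tr <- stats::runif(d, -5, 5)
    coords[i, , ] <- sweep(sizes[i] * shp %*% R, 2, tr, "+")
  }
  lms <- landmark_set(coords, sprintf("dog%03d", seq_len(n)), masks)
  structure(list(landmarks = lms,
                 truth = list(sizes = sizes, A = A, V = V, dosage = dosage)),
            class = "landmark_sim")
}

#' Simulate a multi-sample variant table with planted causal candidates
#'
#' Builds a variant table over a critical-interval-sized region in which
#' exactly `n_true_snvs + n_true_svs` planted records satisfy all five
#' identity-by-descent filtering assumptions (including at least one whose
#' candidate allele is the REFERENCE allele, the boxer-reference situation),
#' while every other record violates at least one assumption, with
#' violations cycled across the case-fixation, case-concordance, wild-canid
#' and control rules plus all-case-missing exclusions.
#'
#' @param groups_spec named integer vector or list giving sample counts for
#'   `case_hom`, `control`, `wild` (all must be positive).
#' @param n_snvs,n_svs total SNV/INDEL and structural-variant record counts.
#' @param n_true_snvs,n_true_svs planted-true counts (`<=` totals).
#' @param seed integer seed.
#' @param region chrom/start/end of the interval (defaults to the canonical
#'   187,377-bp interval coordinates used throughout the examples).
#' @return list of class `variant_sim` with `table` (a [variant_table]),
#'   `groups` (a [sample_groups]), `truth` (`true_idx`, `violation` per
#'   non-true record).
#' @export
simulate_variant_table <- function(groups_spec, n_snvs, n_svs,
                                   n_true_snvs, n_true_svs, seed,
                                   region = list(chrom = "1",
                                                 start = 55850299L,
                                                 end = 56037676L)) {
  gs <- unlist(groups_spec)
  need <- c("case_hom", "control", "wild")
  if (!all(need %in% names(gs)) || any(gs[need] < 1L))
    stop("groups_spec must give a positive count for case_hom, control and wild")
  if (n_true_snvs > n_snvs || n_true_svs > n_svs)
    stop("planted-true counts exceed totals")
  set.seed(seed)

  ids <- list(case_hom = sprintf("case%02d", seq_len(gs["case_hom"])),
              control = sprintf("ctrl%02d", seq_len(gs["control"])),
              wild = sprintf("wild%02d", seq_len(gs["wild"])))
  samples <- unlist(ids, use.names = FALSE)
  groups <- sample_groups(ids$case_hom, ids$control, ids$wild)

  n_rec <- n_snvs + n_svs
  pos <- sort(sample(seq(region$start, region$end), n_rec, replace = FALSE))
  vtype <- c(ifelse(stats::runif(n_snvs) < 0.9, "SNV", "INDEL"),
             rep("SV", n_svs))
  true_idx <- c(if (n_true_snvs > 0) sample(seq_len(n_snvs), n_true_snvs),
                if (n_true_svs > 0) n_snvs + sample(seq_len(n_svs), n_true_svs))
  true_idx <- as.integer(sort(true_idx))

  G <- matrix("hom_ref", n_rec, length(samples),
              dimnames = list(NULL, samples))
  viol <- rep(NA_character_, n_rec)
  rules <- c("case_not_fixed", "case_discordant", "wild_carrier",
             "control_carrier", "no_data")
  r <- 0L
  ref_candidate_done <- FALSE
  for (i in seq_len(n_rec)) {
    ci <- ids$case_hom; co <- ids$control; wi <- ids$wild
    if (i %in% true_idx) {
      if (!ref_candidate_done) {
        ## candidate allele IS the reference allele: the causal allele sits
        ## in the assembly, so cases are hom_ref and everyone else carries ALT
        G[i, ci] <- "hom_ref"
        G[i, co] <- "hom_alt"
        G[i, wi] <- "hom_alt"
        ref_candidate_done <- TRUE
      } else {
        G[i, ci] <- "hom_alt"
        G[i, co] <- sample(c("hom_ref", "missing"), length(co), TRUE,
                           prob = c(0.9, 0.1))
        G[i, wi] <- sample(c("hom_ref", "missing"), length(wi), TRUE,
                           prob = c(0.9, 0.1))
      }
    } else {
      r <- r + 1L
      rule <- rules[1L + (r - 1L) %% length(rules)]
      viol[i] <- rule
      switch(rule,
        case_not_fixed = {                       # one case heterozygous
          G[i, ci] <- "hom_alt"
          G[i, ci[1L]] <- "het"
        },
        case_discordant = {                      # cases split over alleles
          G[i, ci] <- "hom_alt"
          G[i, ci[1L]] <- "hom_ref"
          if (length(ci) < 2L) G[i, ci[1L]] <- "het"
        },
        wild_carrier = {
          G[i, ci] <- "hom_alt"
          G[i, wi[1L]] <- sample(c("het", "hom_alt"), 1L)
        },
        control_carrier = {
          G[i, ci] <- "hom_alt"
          G[i, co[1L]] <- sample(c("het", "hom_alt"), 1L)
        },
        no_data = {
          G[i, ci] <- "missing"
          G[i, co[1L]] <- "het"
        })
    }
  }

  refs <- sample(c("A", "C", "G", "T"), n_rec, TRUE)
  alts <- vapply(refs, function(r_) sample(setdiff(c("A", "C", "G", "T"), r_), 1L), "")
  alts[vtype == "INDEL"] <- paste0(refs[vtype == "INDEL"], "T")
  alts[vtype == "SV"] <- "<INS>"
  records <- data.frame(chrom = region$chrom, pos = pos, ref = refs,
                        alt = alts, vtype = vtype, stringsAsFactors = FALSE)
  tab <- variant_table(records, G, region)
  structure(list(table = tab, groups = groups,
                 truth = list(true_idx = true_idx, violation = viol)),
            class = "variant_sim")
}

#' Simulate allele-specific read counts
#'
#' Binomial split of a read total between two alleles, emulating the
#' transcript-level allele counting that underpins allelic-imbalance
#' ratios.
#'
#' @param total_reads positive read total.
#' @param allele_fraction expected fraction of reads from allele A, in
#'   `[0,1]`.
#' @param seed integer seed.
#' @return integer vector `c(a, b)` summing to `total_reads`.
#' @export
simulate_ase_counts <- function(total_reads, allele_fraction, seed) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (allele_fraction < 0 || allele_fraction > 1)
    stop("allele_fraction must lie in [0,1]")
  set.seed(seed)
  a <- stats::rbinom(1L, total_reads, allele_fraction)
  c(a = a, b = as.integer(total_reads) - a)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_landmarks()] into one object with shared truth, the input the
#' end-to-end analyses start from.
#'
#' @param config a [sim_config].
#' @return list of class `synthetic_study` with `genotypes` (a
#'   `genotype_sim`), `landmarks` (a `landmark_sim`) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  gsim <- simulate_genotypes(config)
  lsim <- simulate_landmarks(gsim$truth$causal_dosage, config)
  structure(list(genotypes = gsim, landmarks = lsim, config = config),
            class = "synthetic_study")
}
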