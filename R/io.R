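#' Write landmarks to CSV
#'
#' One row per specimen: `id`, then `x1,y1[,z1],x2,...` coordinate columns.
#'
#' @param landmarks a [landmark_set].
#' @param path output file.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  k <- landmarks$k; d <- landmarks$d
  ax <- c("x", "y", "z")[seq_len(d)]
  cols <- as.vector(t(outer(seq_len(k), ax, function(i, a) paste0(a, i))))
  flat <- flatten_shapes(landmarks$coords)
  df <- data.frame(id = landmarks$specimen_ids, flat, check.names = FALSE)
  names(df) <- c("id", cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmarks from CSV or TPS
#'
#' CSV dialect: header `id,x1,y1[,z1],...`, one row per specimen.  TPS
#' dialect: `LM=k` (2D) or `LM3=k` (3D) blocks of coordinate lines with
#' optional `ID=` lines.
#'
#' @param path input file.
#' @param format `"csv"` or `"tps"` (default guessed from the extension).
#' @param masks optional named list of landmark-index masks to attach.
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path, format = NULL, masks = list()) {
  if (is.null(format))
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  format <- match.arg(format, c("csv", "tps"))
  if (format == "csv") .read_landmarks_csv(path, masks)
  else .read_landmarks_tps(path, masks)
}

.read_landmarks_csv <- function(path, masks) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ax <- sub("[0-9]+$", "", names(df)[-1L])
  d <- length(unique(ax))
  if (!d %in% 2:3 || (ncol(df) - 1L) %% d != 0L)
    stop("malformed landmark CSV header")
  k <- (ncol(df) - 1L) %/% d
  n <- nrow(df)
  coords <- array(NA_real_, c(n, k, d))
  for (i in seq_len(n))
    coords[i, , ] <- matrix(as.numeric(df[i, -1L]), k, d, byrow = TRUE)
  landmark_set(coords, as.character(df[[1L]]), masks)
}

.read_landmarks_tps <- function(path, masks) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  specs <- list(); ids <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    hdr <- regmatches(lines[i], regexec("^LM(3?)\\s*=\\s*(\\d+)$", lines[i]))[[1L]]
    if (!length(hdr)) stop("expected an LM=/LM3= header at line ", i)
    d <- if (hdr[2L] == "3") 3L else 2L
    k <- as.integer(hdr[3L])
    block <- lines[(i + 1L):(i + k)]
    co <- t(vapply(strsplit(block, "\\s+"),
                   function(x) as.numeric(x[seq_len(d)]), numeric(d)))
    if (anyNA(co)) stop("malformed coordinate line in TPS block starting at line ", i)
    i <- i + k + 1L
    id <- sprintf("spec%03d", length(specs) + 1L)
    while (i <= length(lines) && grepl("=", lines[i]) &&
           !grepl("^LM", lines[i])) {
      kv <- strsplit(lines[i], "=")[[1L]]
      if (toupper(kv[1L]) == "ID") id <- trimws(kv[2L])
      i <- i + 1L
    }
    specs[[length(specs) + 1L]] <- co
    ids <- c(ids, id)
  }
  ks <- vapply(specs, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("inconsistent landmark counts across specimens (offender: ",
         ids[which(ks != ks[1L])[1L]], ")")
  ds <- vapply(specs, ncol, integer(1))
  if (length(unique(ds)) != 1L) stop("mixed 2D/3D TPS blocks")
  coords <- array(NA_real_, c(length(specs), ks[1L], ds[1L]))
  for (j in seq_along(specs)) coords[j, , ] <- specs[[j]]
  landmark_set(coords, ids, masks)
}

#' Write a phased haplotype panel as VCF
#'
#' Plain-text VCF 4.2 with contig header lines, 1-based POS and
#' `|`-separated GT fields.
#'
#' @param panel a [haplotype_panel].
#' @param path output file.
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  map <- panel$map
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(map$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  n <- length(panel$sample_ids)
  a1 <- panel$alleles[seq(1L, 2L * n, 2L), , drop = FALSE]
  a2 <- panel$alleles[seq(2L, 2L * n, 2L), , drop = FALSE]
  body <- vapply(seq_len(nrow(map)), function(j) {
    gt <- paste0(a1[, j], "|", a2[, j])
    paste(c(map$chrom[j], map$pos[j], map$id[j], map$ref[j], map$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires fully phased (`|`-separated) GT fields; parsing is done with
#' the vcfR package.
#'
#' @param path VCF file (plain text or gzipped).
#' @return a [haplotype_panel].
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes ('/' separator) found: phased VCF required")
  fx <- vcfR::getFIX(v)
  map <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                    id = fx[, "ID"], ref = fx[, "REF"], alt = fx[, "ALT"],
                    stringsAsFactors = FALSE)
  samples <- colnames(gt)
  n <- length(samples); m <- nrow(map)
  H <- matrix(0L, 2L * n, m)
  sp <- strsplit(as.vector(gt), "|", fixed = TRUE)   # gt is markers x samples
  a1 <- as.integer(vapply(sp, `[`, "", 1L))
  a2 <- as.integer(vapply(sp, `[`, "", 2L))
  for (s in seq_len(n)) {
    H[2L * s - 1L, ] <- a1[(s - 1L) * m + seq_len(m)]
    H[2L * s, ] <- a2[(s - 1L) * m + seq_len(m)]
  }
  haplotype_panel(H, samples, map)
}

#' Read an unphased VCF into a genotype matrix
#'
#' Accepts `0/1` and `0|1` GT dialects; missing calls (`./.` or `.`)
#' become `NA` dosages.
#'
#' @param path VCF file.
#' @return a [genotype_matrix].
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fx <- vcfR::getFIX(v)
  map <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                    id = fx[, "ID"], ref = fx[, "REF"], alt = fx[, "ALT"],
                    stringsAsFactors = FALSE)
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1L]]))
  })
  genotype_matrix(t(dos), map, colnames(gt))
}

#' Write a sample map TSV
#'
#' Columns: `sample_id`, `group` (`case_hom` / `control` / `wild`),
#' `breed`, `sex`.
#'
#' @param groups a [sample_groups].
#' @param path output file.
#' @param breed,sex optional named vectors keyed by sample id.
#' @export
write_sample_map <- function(groups, path, breed = NULL, sex = NULL) {
  stopifnot(inherits(groups, "sample_groups"))
  ids <- unlist(groups, use.names = FALSE)
  grp <- rep(names(groups), lengths(groups))
  df <- data.frame(sample_id = ids, group = grp,
                   breed = if (is.null(breed)) "NA" else breed[ids],
                   sex = if (is.null(sex)) "NA" else sex[ids])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample map TSV into sample groups
#'
#' @param path TSV with `sample_id` and `group` columns.
#' @return a [sample_groups].
#' @export
read_sample_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_groups(df$sample_id[df$group == "case_hom"],
                df$sample_id[df$group == "control"],
                df$sample_id[df$group == "wild"])
}

#' Write an association scan as TSV
#'
#' @param scan an [lmm_scan] result.
#' @param path output file.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "assoc_scan"))
  utils::write.table(scan$result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a critical interval as BED
#'
#' Converts the internal 1-based inclusive marker coordinates to the
#' 0-based half-open BED convention: `start0 = start_pos - 1`,
#' `end0 = end_pos`.
#'
#' @param interval a [critical_interval].
#' @param path output file.
#' @param name feature name (default `"critical_interval"`).
#' @export
write_interval_bed <- function(interval, path, name = "critical_interval") {
  line <- paste(interval$chrom, interval$start_pos - 1L, interval$end_pos,
                name, sep = "\t")
  writeLines(line, path)
  invisible(path)
}
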