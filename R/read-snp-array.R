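#' Read genotypes from a folder of per-individual SNP-array files
#'
#' SNP-array genotyping is typically exported as one text file per individual,
#' listing the SNP name and the two allele calls after a block of comment and
#' header lines (12 by default). Coordinates are not carried in those files;
#' they are joined in from a separate SNP map file giving the chromosome and
#' position of each array SNP (see [read_snp_map()]).
#'
#' Allele calls are converted to dosages using, for each SNP, the first allele
#' seen across the files (in lexicographic file order) as the reference
#' orientation; since r-squared is invariant to allele relabeling, this choice
#' cannot affect downstream LD results. Calls containing `-`, `N` or empty
#' fields are recorded as missing. SNPs showing more than two distinct alleles
#' across files are excluded with a logged count.
#'
#' @param folder directory containing one `.txt` file per individual; the
#'   sample identifier is the file name without the `.txt` extension.
#' @param snp_map path to the SNP map file (columns: SNP name, chromosome,
#'   position; a header line is auto-detected).
#' @param maf_min minor-allele-frequency floor in `[0, 0.5]`.
#' @param skip_lines number of comment/header lines preceding the data in each
#'   per-individual file (default 12).
#' @return A [genotype_matrix()] with attribute `excluded` (counts of
#'   `multiallelic` and `low_maf` exclusions).
#' @export
read_snp_array <- function(folder, snp_map, maf_min = 0, skip_lines = 12L) {
  if (!dir.exists(folder)) stop(sprintf("SNP-array folder not found: '%s'", folder))
  files <- sort(list.files(folder, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("no per-individual .txt files found in '%s'", folder))
  }
  map <- read_snp_map(snp_map)

  read_one <- function(f) {
    lines <- readLines(f)
    if (length(lines) <= skip_lines) {
      stop(sprintf("'%s': expected %d header lines followed by data, but file has only %d lines",
                   f, skip_lines, length(lines)))
    }
    body <- lines[-seq_len(skip_lines)]
    body <- body[nzchar(trimws(body))]
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      bad <- which(nf < 3L)[1]
      stop(sprintf("'%s' line %d: expected >= 3 tab-separated columns (SNP name, allele1, allele2), found %d",
                   f, skip_lines + bad, nf[bad]))
    }
    nm <- vapply(fields, `[`, "", 1L)
    if (anyDuplicated(nm)) {
      stop(sprintf("'%s': SNP name '%s' listed more than once", f,
                   nm[duplicated(nm)][1]))
    }
    data.frame(name = nm,
               a1 = toupper(vapply(fields, `[`, "", 2L)),
               a2 = toupper(vapply(fields, `[`, "", 3L)),
               stringsAsFactors = FALSE)
  }

  per <- lapply(files, read_one)
  snp_names <- per[[1]]$name
  key <- sort(snp_names)
  for (i in seq_along(per)[-1]) {
    if (!identical(sort(per[[i]]$name), key)) {
      stop(sprintf("'%s' lists a different SNP set than '%s': per-individual files must genotype the same SNPs",
                   files[i], files[1]))
    }
  }

  missing_names <- setdiff(snp_names, map$name)
  if (length(missing_names)) {
    stop(sprintf("SNP name(s) absent from the SNP map '%s': %s%s (first seen in '%s')",
                 snp_map, paste(head(missing_names, 5), collapse = ", "),
                 if (length(missing_names) > 5) sprintf(" and %d more", length(missing_names) - 5) else "",
                 files[1]))
  }

  ns <- length(files)
  nv <- length(snp_names)
  valid_base <- c("A", "C", "G", "T")
  A1 <- matrix(NA_character_, ns, nv)
  A2 <- matrix(NA_character_, ns, nv)
  for (i in seq_along(per)) {
    m <- match(snp_names, per[[i]]$name)
    a1 <- per[[i]]$a1[m]; a2 <- per[[i]]$a2[m]
    a1[!a1 %in% valid_base] <- NA_character_
    a2[!a2 %in% valid_base] <- NA_character_
    A1[i, ] <- a1
    A2[i, ] <- a2
  }

  ## first-seen allele per SNP (file-major scan order) fixes the orientation
  ref_allele <- rep(NA_character_, nv)
  for (i in seq_len(ns)) {
    take <- is.na(ref_allele) & !is.na(A1[i, ])
    ref_allele[take] <- A1[i, take]
    take2 <- is.na(ref_allele) & !is.na(A2[i, ])
    ref_allele[take2] <- A2[i, take2]
  }

  n_alleles <- vapply(seq_len(nv), function(j) {
    length(unique(c(A1[, j], A2[, j])[!is.na(c(A1[, j], A2[, j]))]))
  }, 0L)
  multi <- n_alleles > 2L
  n_multi <- sum(multi)

  dos <- (A1 != matrix(ref_allele, ns, nv, byrow = TRUE)) +
         (A2 != matrix(ref_allele, ns, nv, byrow = TRUE))
  dos[is.na(A1) | is.na(A2)] <- NA
  keep <- !multi
  coords <- map[match(snp_names, map$name), ]

  gm <- genotype_matrix(dos[, keep, drop = FALSE],
                        chrom = coords$chrom[keep],
                        pos = coords$pos[keep],
                        vid = snp_names[keep],
                        ref = ref_allele[keep],
                        samples = sub("\\.txt$", "", basename(files)))
  gm <- filter_maf(gm, maf_min)
  n_low_maf <- attr(gm, "n_low_maf")
  if (nrow(gm$variants) == 0L) {
    stop(sprintf("no variants remain from '%s' after filtering", folder))
  }
  attr(gm, "excluded") <- c(multiallelic = n_multi, low_maf = n_low_maf)
  attr(gm, "n_low_maf") <- NULL
  message(sprintf(
    "read_snp_array: kept %d SNPs x %d individuals from '%s' (excluded: %d multi-allelic, %d low-MAF)",
    nrow(gm$variants), length(gm$samples), folder, n_multi, n_low_maf))
  gm
}

#' Read a SNP map file
#'
#' Tab-separated text with columns SNP name, chromosome, position. A header
#' line is auto-detected (first line whose position column does not parse as a
#' number is skipped).
#'
#' @param path path to the SNP map file.
#' @return data.frame with columns `name`, `chrom`, `pos`.
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("SNP map file not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("SNP map '%s' is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("SNP map '%s' line %d: expected 3 tab-separated columns (name, chromosome, position)",
                 path, which(nf < 3L)[1]))
  }
  third <- vapply(fields, `[`, "", 3L)
  start <- if (is.na(suppressWarnings(as.numeric(third[1])))) 2L else 1L
  if (start > length(fields)) stop(sprintf("SNP map '%s' has a header but no data rows", path))
  idx <- start:length(fields)
  pos <- suppressWarnings(as.numeric(third[idx]))
  if (any(is.na(pos))) {
    bad <- idx[which(is.na(pos))[1]]
    stop(sprintf("SNP map '%s' line %d: position '%s' is not a number", path, bad, third[bad]))
  }
  out <- data.frame(name = vapply(fields[idx], `[`, "", 1L),
                    chrom = vapply(fields[idx], `[`, "", 2L),
                    pos = pos, stringsAsFactors = FALSE)
  if (anyDuplicated(out$name)) {
    stop(sprintf("SNP map '%s': duplicated SNP name '%s'", path,
                 out$name[duplicated(out$name)][1]))
  }
  out
}
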