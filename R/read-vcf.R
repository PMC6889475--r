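#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (GT field required) into a [genotype_matrix()],
#' keeping only biallelic SNPs. Multi-allelic records, non-SNP records
#' (indels, symbolic alleles) and variants below the MAF floor are excluded,
#' with counts reported via a message and stored in the `"excluded"`
#' attribute. Genotypes containing any missing allele (`./.`, `0/.`, `.`) are
#' recorded as missing; phased separators (`|`) are treated as unphased.
#'
#' @param path path to a VCF file (uncompressed or gzipped).
#' @param maf_min minor-allele-frequency floor in `[0, 0.5]`; variants with
#'   MAF below this are dropped. Default 0 (no filtering).
#' @return A [genotype_matrix()] with attribute `excluded`, a named integer
#'   vector with counts of `multiallelic`, `non_snp` and `low_maf` exclusions.
#' @export
read_vcf <- function(path, maf_min = 0) {
  if (!file.exists(path)) stop(sprintf("VCF file not found: '%s'", path))
  if (maf_min < 0 || maf_min > 0.5) stop("'maf_min' must be in [0, 0.5]")
  check_vcf_header(path)

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop(sprintf("no variant records in '%s'", path))
  if (ncol(vcf@gt) < 2L) {
    stop(sprintf("'%s' has no sample genotype columns (GT field is required)", path))
  }
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) stop(sprintf(
                   "cannot extract GT genotypes from '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  is_snp <- !multi & toupper(ref) %in% bases & toupper(alt) %in% bases
  n_multi <- sum(multi)
  n_non_snp <- sum(!multi & !is_snp)
  keep <- is_snp
  if (!any(keep)) {
    stop(sprintf("no biallelic SNPs found in '%s' (%d multi-allelic, %d non-SNP records excluded)",
                 path, n_multi, n_non_snp))
  }

  g <- gsub("|", "/", gt[keep, , drop = FALSE], fixed = TRUE)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  d <- lut[g]
  dim(d) <- dim(g)

  gm <- genotype_matrix(t(d),
                        chrom = fix[keep, "CHROM"],
                        pos = as.numeric(fix[keep, "POS"]),
                        vid = fix[keep, "ID"],
                        ref = ref[keep], alt = alt[keep],
                        samples = colnames(gt))
  gm <- filter_maf(gm, maf_min)
  n_low_maf <- attr(gm, "n_low_maf")
  if (nrow(gm$variants) == 0L) {
    stop(sprintf("no variants remain in '%s' after MAF >= %g filtering", path, maf_min))
  }
  attr(gm, "excluded") <- c(multiallelic = n_multi, non_snp = n_non_snp,
                            low_maf = n_low_maf)
  attr(gm, "n_low_maf") <- NULL
  message(sprintf(
    "read_vcf: kept %d biallelic SNPs x %d samples from '%s' (excluded: %d multi-allelic, %d non-SNP, %d low-MAF)",
    nrow(gm$variants), length(gm$samples), path, n_multi, n_non_snp, n_low_maf))
  gm
}

## Validate the two structural header requirements before delegating the
## record parsing: line 1 must declare ##fileformat and a #CHROM row with the
## eight fixed columns plus FORMAT and >= 1 sample must precede the records.
check_vcf_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lineno <- 0L
  first <- readLines(con, n = 1L)
  lineno <- lineno + 1L
  if (!length(first) || !startsWith(first, "##fileformat")) {
    stop(sprintf("malformed VCF header in '%s' at line 1: first line must start with '##fileformat'",
                 path))
  }
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) {
      stop(sprintf("malformed VCF header in '%s': no '#CHROM' header row found (read %d lines)",
                   path, lineno))
    }
    lineno <- lineno + 1L
    if (startsWith(l, "##")) next
    if (!startsWith(l, "#CHROM")) {
      stop(sprintf("malformed VCF header in '%s' at line %d: expected '#CHROM' header row before records",
                   path, lineno))
    }
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    want <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT")
    if (length(f) < 10L || !identical(f[1:9], want)) {
      stop(sprintf("malformed VCF header in '%s' at line %d: '#CHROM' row must list %s plus at least one sample",
                   path, lineno, paste(want, collapse = " ")))
    }
    return(invisible(TRUE))
  }
}
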