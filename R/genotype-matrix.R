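#' Construct a genotype matrix
#'
#' The central container for all LD computation: an individuals-by-variants
#' matrix of alternate-allele dosages (0, 1, 2 or `NA` for missing) together
#' with per-variant metadata. Variants are stored strictly sorted by
#' chromosome, then position.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param chrom character vector of chromosome names, one per variant.
#' @param pos integer-valued vector of 1-based positions (bp), one per variant.
#' @param vid optional variant identifiers; missing or `"."` entries are
#'   synthesized as `"<chrom>_<pos>"`.
#' @param ref,alt optional reference/alternate allele strings per variant.
#' @param samples optional sample identifiers; defaults to the row names of
#'   `dosages` or `sample1, sample2, ...`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (matrix), `variants` (data.frame with columns `chrom`, `pos`,
#'   `vid`, `ref`, `alt`) and `samples` (character).
#' @export
genotype_matrix <- function(dosages, chrom, pos, vid = NULL, ref = NULL,
                            alt = NULL, samples = NULL) {
  dosages <- as.matrix(dosages)
  nv <- ncol(dosages)
  ns <- nrow(dosages)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) != nv || length(pos) != nv) {
    stop("'chrom' and 'pos' must have one entry per dosage column")
  }
  if (any(is.na(pos)) || any(pos < 1) || any(pos != floor(pos))) {
    stop("positions must be integers >= 1 (1-based bp)")
  }
  vals <- dosages[!is.na(dosages)]
  if (!all(vals %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA (missing)")
  }
  if (is.null(samples)) {
    samples <- rownames(dosages) %||% paste0("sample", seq_len(ns))
  }
  samples <- as.character(samples)
  if (length(samples) != ns) stop("'samples' must have one entry per dosage row")
  if (is.null(vid)) vid <- rep(NA_character_, nv)
  vid <- as.character(vid)
  synth <- is.na(vid) | vid == "." | vid == ""
  vid[synth] <- paste(chrom[synth], format(pos[synth], scientific = FALSE,
                                           trim = TRUE), sep = "_")
  ref <- as.character(ref %||% rep(NA_character_, nv))
  alt <- as.character(alt %||% rep(NA_character_, nv))

  ord <- order(chrom, pos, method = "radix")
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(samples, vid[ord])
  structure(
    list(
      dosages = dosages,
      variants = data.frame(chrom = chrom[ord], pos = pos[ord],
                            vid = vid[ord], ref = ref[ord], alt = alt[ord],
                            stringsAsFactors = FALSE),
      samples = samples
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  tab <- table(x$variants$chrom)
  cat(sprintf("chromosomes (%d): %s\n", length(tab),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Minor allele frequency of a dosage vector
#'
#' Computes `min(p, 1 - p)` where `p` is the alternate-allele frequency
#' `sum(dosages) / (2 * n)` over non-missing samples.
#'
#' @param dosages vector of allele dosages (0, 1, 2 or `NA`).
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("MAF is undefined: all genotypes are missing")
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

## Drop variants below a MAF floor; returns the matrix plus an exclusion count.
filter_maf <- function(gm, maf_min) {
  if (maf_min <= 0) {
    attr(gm, "n_low_maf") <- 0L
    return(gm)
  }
  nm <- colSums(!is.na(gm$dosages))
  s <- colSums(gm$dosages, na.rm = TRUE)
  p <- ifelse(nm > 0, s / (2 * nm), NA_real_)
  mafv <- pmin(p, 1 - p)
  keep <- !is.na(mafv) & mafv >= maf_min
  out <- genotype_matrix(gm$dosages[, keep, drop = FALSE],
                         chrom = gm$variants$chrom[keep],
                         pos = gm$variants$pos[keep],
                         vid = gm$variants$vid[keep],
                         ref = gm$variants$ref[keep],
                         alt = gm$variants$alt[keep],
                         samples = gm$samples)
  attr(out, "n_low_maf") <- sum(!keep)
  out
}

## Accept either a genotype_matrix or a bare variants data.frame (chrom, pos).
as_variant_table <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$variants)
  if (is.data.frame(x) && all(c("chrom", "pos") %in% names(x))) return(x)
  stop("expected a genotype_matrix or a data.frame with columns 'chrom' and 'pos'")
}
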