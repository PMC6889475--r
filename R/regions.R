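#' Dataset-wide average distance between linked SNPs
#'
#' Mean base-pair separation of all retained variant pairs whose r-squared is
#' at or above the given threshold, across all chromosomes. This average is
#' later used to delineate a region around candidates that have no linked
#' genotyped SNP ("alone" candidates), and to broadly estimate genome
#' coverage; it is a rough summary, since r-squared varies along the genome
#' and the distance distribution need not be Gaussian.
#'
#' @param pairs pair table from [pairwise_ld()].
#' @param threshold user r-squared threshold; must be at least the base
#'   threshold the pair table was computed with.
#' @return An object of class `ld_summary`: list with `threshold`,
#'   `average_distance` (bp; `NA` with a warning when no pair qualifies) and
#'   `n_pairs`.
#' @export
average_linked_distance <- function(pairs, threshold) {
  bt <- attr(pairs, "base_threshold")
  if (!is.null(bt) && threshold < bt) {
    stop(sprintf("threshold (%g) is below the base threshold (%g) the pair table was computed at; pairs below it were never retained",
                 threshold, bt))
  }
  sel <- pairs$r2 >= threshold
  n <- sum(sel)
  if (n == 0L) {
    warning(sprintf("no variant pairs with r^2 >= %g: average linked distance is undefined and 'alone' regions will degenerate to the candidate position itself",
                    threshold), call. = FALSE)
    avg <- NA_real_
  } else {
    avg <- mean(pairs$pos_b[sel] - pairs$pos_a[sel])
  }
  structure(list(threshold = threshold, average_distance = avg, n_pairs = n),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("ld_summary: %d pair(s) with r^2 >= %g; average linked distance %s bp\n",
              x$n_pairs, x$threshold,
              if (is.na(x$average_distance)) "undefined" else
                format(round(x$average_distance, 1), scientific = FALSE)))
  invisible(x)
}

#' Delineate the region linked to one candidate SNP
#'
#' Collects every variant linked to the candidate with r-squared at or above
#' the threshold and takes the foremost upstream and downstream linked
#' positions as the region bounds (the candidate's own position is always
#' included, so the region is never empty). When no variant is linked, the
#' region falls back to the candidate position plus/minus the dataset-wide
#' average linked distance, the `alone` flag is set, and the candidate's
#' identifier carries an `"_alone"` suffix in output files.
#'
#' @param candidate one-row data.frame or list with `chrom`, `pos`, `sid`.
#' @param pairs pair table from [pairwise_ld()].
#' @param threshold user r-squared threshold.
#' @param fallback an `ld_summary` from [average_linked_distance()], used for
#'   alone candidates.
#' @return One-row data.frame with columns `chrom`, `sid`, `pos`, `start`,
#'   `end`, `alone`, `n_linked`.
#' @export
build_region <- function(candidate, pairs, threshold, fallback) {
  ch <- as.character(candidate$chrom)
  p <- as.numeric(candidate$pos)
  on_chrom <- pairs$chrom == ch & pairs$r2 >= threshold
  hit <- on_chrom & (pairs$pos_a == p | pairs$pos_b == p)
  other <- ifelse(pairs$pos_a[hit] == p, pairs$pos_b[hit], pairs$pos_a[hit])
  n_linked <- length(other)
  if (n_linked > 0L) {
    start <- min(other, p)
    end <- max(other, p)
    alone <- FALSE
  } else {
    d <- if (is.null(fallback) || is.na(fallback$average_distance)) 0 else
      round(fallback$average_distance)
    if (d == 0) {
      warning(sprintf("candidate '%s' has no linked SNP and no average distance is available: region degenerates to the candidate position itself",
                      candidate$sid), call. = FALSE)
    }
    start <- max(1, p - d)
    end <- p + d
    alone <- TRUE
  }
  data.frame(chrom = ch, sid = as.character(candidate$sid), pos = p,
             start = start, end = end, alone = alone, n_linked = n_linked,
             stringsAsFactors = FALSE)
}

#' Delineate regions for all candidate SNPs
#'
#' Applies [build_region()] to each candidate. When `variants` is supplied,
#' each candidate position is first checked against the genotyped variants:
#' with `on_missing = "error"` (default) an ungenotyped candidate is an
#' error; with `"nearest"` the closest genotyped variant on the same
#' chromosome within `window_bp` is substituted for the linkage lookup (the
#' reported region still includes the candidate's own position).
#'
#' @param candidates data.frame from [read_candidates()] (canonical
#'   chromosome names).
#' @param pairs pair table from [pairwise_ld()].
#' @param threshold user r-squared threshold.
#' @param fallback optional `ld_summary`; computed from `pairs` at
#'   `threshold` when `NULL`.
#' @param variants optional [genotype_matrix()] or variants data.frame used
#'   for the candidate-position check.
#' @param on_missing policy for candidates absent from the genotyped
#'   variants: `"error"` or `"nearest"`.
#' @param window_bp search window for `"nearest"` substitution.
#' @return data.frame of regions, one row per candidate, in candidate order.
#' @export
build_regions <- function(candidates, pairs, threshold, fallback = NULL,
                          variants = NULL, on_missing = c("error", "nearest"),
                          window_bp = 1e6) {
  on_missing <- match.arg(on_missing)
  if (is.null(fallback)) fallback <- average_linked_distance(pairs, threshold)
  vt <- if (!is.null(variants)) as_variant_table(variants)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    p_query <- cand$pos
    if (!is.null(vt)) {
      chr_pos <- vt$pos[vt$chrom == cand$chrom]
      if (!any(chr_pos == cand$pos)) {
        if (on_missing == "error") {
          stop(sprintf("candidate '%s' at %s:%s is not a genotyped variant; check the candidate list or rerun with on_missing = \"nearest\"",
                       cand$sid, cand$chrom,
                       format(cand$pos, scientific = FALSE)), call. = FALSE)
        }
        if (!length(chr_pos)) {
          stop(sprintf("candidate '%s': no genotyped variants on chromosome %s",
                       cand$sid, cand$chrom), call. = FALSE)
        }
        dmin <- min(abs(chr_pos - cand$pos))
        if (dmin > window_bp) {
          stop(sprintf("candidate '%s' at %s:%s: nearest genotyped variant is %s bp away, beyond the %s bp window",
                       cand$sid, cand$chrom, format(cand$pos, scientific = FALSE),
                       format(dmin, scientific = FALSE),
                       format(window_bp, scientific = FALSE)), call. = FALSE)
        }
        p_query <- chr_pos[which.min(abs(chr_pos - cand$pos))]
        message(sprintf("build_regions: candidate '%s' is not genotyped; substituting nearest variant at %s:%s (%s bp away)",
                        cand$sid, cand$chrom, format(p_query, scientific = FALSE),
                        format(dmin, scientific = FALSE)))
      }
    }
    r <- build_region(list(chrom = cand$chrom, pos = p_query, sid = cand$sid),
                      pairs, threshold, fallback)
    ## region is anchored at the resolved variant but always contains the
    ## candidate's own position
    r$pos <- cand$pos
    r$start <- min(r$start, cand$pos)
    r$end <- max(r$end, cand$pos)
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "average_distance") <- fallback$average_distance
  out
}

#' Broad genome-coverage estimate from the average linked distance
#'
#' For every genotyped variant an interval of plus/minus the average linked
#' distance is formed, clipped to the chromosome, and overlapping intervals
#' are merged; coverage is the total merged length divided by the summed
#' chromosome lengths. Interval lengths are 1-based inclusive
#' (`end - start + 1`). This is a broad estimate of how much of the genome the
#' genotyped SNPs interrogate at the chosen r-squared threshold.
#'
#' @param genotypes a [genotype_matrix()] or variants data.frame.
#' @param summary an `ld_summary` from [average_linked_distance()].
#' @param chrom_lengths named numeric vector (or two-column data.frame) of
#'   per-chromosome lengths in bp.
#' @return Fraction of the genome covered, in `[0, 1]`.
#' @export
genome_coverage <- function(genotypes, summary, chrom_lengths) {
  v <- as_variant_table(genotypes)
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(as.numeric(chrom_lengths[[2]]),
                              as.character(chrom_lengths[[1]]))
  }
  d <- summary$average_distance
  if (is.na(d)) stop("average linked distance is undefined (no qualifying pairs); genome coverage cannot be estimated")
  d <- round(d)
  chroms <- unique(v$chrom)
  miss <- setdiff(chroms, names(chrom_lengths))
  if (length(miss)) {
    stop(sprintf("no chromosome length provided for '%s' (genotyped variants present there)",
                 miss[1]))
  }
  total <- 0
  for (ch in chroms) {
    L <- chrom_lengths[[ch]]
    pos <- v$pos[v$chrom == ch]
    s <- pmin(pmax(pos - d, 1), L)
    e <- pmax(pmin(pos + d, L), 1)
    ir <- IRanges::reduce(IRanges::IRanges(start = as.integer(s), end = as.integer(e)))
    total <- total + sum(as.numeric(IRanges::width(ir)))
  }
  total / sum(chrom_lengths)
}

#' Read a chromosome-lengths file
#'
#' Two-column tab-separated text: chromosome name, length in bp. A header
#' line is auto-detected.
#'
#' @param path path to the file.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  if (!file.exists(path)) stop(sprintf("chromosome-lengths file not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("'%s' line %d: expected 2 tab-separated columns (chromosome, length-bp)",
                 path, which(nf < 2L)[1]))
  }
  second <- vapply(fields, `[`, "", 2L)
  start <- if (is.na(suppressWarnings(as.numeric(second[1])))) 2L else 1L
  idx <- start:length(fields)
  len <- suppressWarnings(as.numeric(second[idx]))
  if (any(is.na(len) | len <= 0)) {
    stop(sprintf("'%s': chromosome lengths must be positive numbers", path))
  }
  setNames(len, vapply(fields[idx], `[`, "", 1L))
}

#' Export candidate regions as BED
#'
#' Writes regions as a BED file; coordinates are converted from the internal
#' 1-based inclusive convention to BED's 0-based half-open convention at
#' write time.
#'
#' @param regions data.frame from [build_regions()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_regions_bed <- function(regions, path) {
  sid <- ifelse(regions$alone, paste0(regions$sid, "_alone"), regions$sid)
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = sid, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
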