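#' Read annotation features of one type from a GFF/GTF/GFF3 file
#'
#' Reads a 9-column tab-separated annotation file (any of the gff-like
#' dialects), keeping only records whose third column equals `ftype` exactly
#' (case-sensitive). Coordinates are kept 1-based inclusive as in the file and
#' the attributes column is passed through verbatim. Exact duplicate records
#' (same chromosome, type, coordinates and attributes) are dropped with a
#' logged count.
#'
#' @param path path to a GFF/GTF/GFF3 file; comment lines start with `#`.
#' @param ftype feature type to keep (e.g. `"gene"`, `"mRNA"`, `"CDS"`).
#' @return data.frame with columns `chrom`, `ftype`, `start`, `end`,
#'   `attributes`, and attribute `n_duplicates` (count of exact duplicates
#'   removed).
#' @export
read_annotations <- function(path, ftype) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: '%s'", path))
  if (!is.character(ftype) || length(ftype) != 1L || !nzchar(ftype)) {
    stop("'ftype' must be a single non-empty feature type string")
  }
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) stop(sprintf("annotation file '%s' has no records", path))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- which(nf < 9L)[1]
    stop(sprintf("'%s' line %d: expected >= 9 tab-separated columns (gff/gtf/gff3), found %d",
                 path, lineno[bad], nf[bad]))
  }
  types <- vapply(fields, `[`, "", 3L)
  sel <- types == ftype
  if (!any(sel)) {
    stop(sprintf("feature type not found: no '%s' records in '%s'; types present: %s",
                 ftype, path, paste(sort(unique(types)), collapse = ", ")))
  }
  f <- fields[sel]
  start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4L)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5L)))
  if (any(is.na(start)) || any(is.na(end))) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("'%s' line %d: start/end positions are not numbers", path,
                 lineno[sel][bad]))
  }
  if (any(start > end)) {
    bad <- which(start > end)[1]
    stop(sprintf("'%s' line %d: start (%s) greater than end (%s)", path,
                 lineno[sel][bad], start[bad], end[bad]))
  }
  out <- data.frame(chrom = vapply(f, `[`, "", 1L),
                    ftype = ftype,
                    start = start, end = end,
                    attributes = vapply(f, `[`, "", 9L),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out)
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (n_dup > 0) {
    message(sprintf("read_annotations: dropped %d exact duplicate '%s' record(s) from '%s'",
                    n_dup, ftype, path))
  }
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Read a candidate SNP list
#'
#' Plain text, whitespace- or tab-separated, with chromosome in the first
#' column, 1-based position in the second, and an optional SNP identifier in
#' the third. When the identifier is absent it is synthesized as
#' `"<chrom>_<pos>"`.
#'
#' @param path path to the candidate list file.
#' @return data.frame with columns `chrom`, `pos`, `sid`, in file order.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop(sprintf("candidate list file not found: '%s'", path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) stop(sprintf("candidate list '%s' is empty", path))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1]
    stop(sprintf("'%s' line %d: expected >= 2 columns (chromosome, position)",
                 path, lineno[bad]))
  }
  pos_chr <- vapply(fields, `[`, "", 2L)
  pos <- suppressWarnings(as.numeric(pos_chr))
  if (any(is.na(pos) | pos < 1 | pos != floor(pos))) {
    bad <- which(is.na(pos) | pos < 1 | pos != floor(pos))[1]
    stop(sprintf("'%s' line %d: position '%s' is not a positive integer",
                 path, lineno[bad], pos_chr[bad]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  sid <- vapply(fields, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
  synth <- is.na(sid) | sid == ""
  sid[synth] <- paste(chrom[synth],
                      format(pos[synth], scientific = FALSE, trim = TRUE), sep = "_")
  data.frame(chrom = chrom, pos = pos, sid = sid, stringsAsFactors = FALSE)
}

#' Normalize a chromosome name for cross-file comparison
#'
#' Strips a single leading `chr`/`Chr`/`CHR` prefix; no other aliasing is
#' performed.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Check chromosome-name consistency across input files
#'
#' Chromosome naming must be consistent across the genotype, annotation and
#' candidate files; in practice the most common discrepancy is a `chr` prefix
#' present in one file and absent in another. Names are compared after
#' stripping that prefix, and a mapping from each file's raw names to the
#' genotype file's (canonical) names is returned. A candidate chromosome with
#' no genotyped counterpart is an error (no LD can ever be computed there);
#' annotation chromosomes without genotyped variants only trigger a warning,
#' since features there can never be hit.
#'
#' @param genotypes a [genotype_matrix()] or a variants data.frame.
#' @param features optional data.frame from [read_annotations()].
#' @param candidates optional data.frame from [read_candidates()].
#' @param genotype_label,feature_label,candidate_label labels (typically file
#'   names) used in error messages.
#' @return An object of class `chrom_map`: list with named character vectors
#'   `candidates` and `features` mapping raw names to canonical names (`NA`
#'   for unmatched annotation chromosomes) and `canonical`, the genotype
#'   chromosome names.
#' @export
check_chromosome_consistency <- function(genotypes, features = NULL,
                                         candidates = NULL,
                                         genotype_label = "genotype input",
                                         feature_label = "annotation file",
                                         candidate_label = "candidate file") {
  v <- as_variant_table(genotypes)
  canon <- unique(v$chrom)
  norm <- normalize_chrom(canon)

  map_names <- function(raw, label, fatal) {
    if (is.null(raw)) return(NULL)
    u <- unique(as.character(raw))
    m <- canon[match(normalize_chrom(u), norm)]
    bad <- u[is.na(m)]
    if (length(bad) && fatal) {
      stop(sprintf(
        "chromosome '%s' in %s matches no chromosome in %s (which has: %s%s); probable cause: a 'chr' prefix present in one file but not the other, or the files describe different assemblies",
        bad[1], label, genotype_label, paste(head(canon, 10), collapse = ", "),
        if (length(canon) > 10) ", ..." else ""))
    }
    if (length(bad) && !fatal) {
      warning(sprintf(
        "%d chromosome name(s) in %s (%s%s) have no genotyped variants; features there can never overlap a candidate region",
        length(bad), label, paste(head(bad, 5), collapse = ", "),
        if (length(bad) > 5) ", ..." else ""), call. = FALSE)
    }
    setNames(m, u)
  }

  structure(
    list(candidates = map_names(candidates$chrom, candidate_label, fatal = TRUE),
         features = map_names(features$chrom, feature_label, fatal = FALSE),
         canonical = canon),
    class = "chrom_map")
}

#' Apply a chromosome-name mapping to a table
#'
#' Rewrites the `chrom` column to canonical names; rows whose chromosome has
#' no canonical counterpart (possible for annotation features) are dropped.
#'
#' @param x data.frame with a `chrom` column.
#' @param map named character vector from [check_chromosome_consistency()].
#' @return `x` with canonical chromosome names.
#' @export
apply_chrom_map <- function(x, map) {
  if (is.null(map)) return(x)
  x$chrom <- unname(map[x$chrom])
  x <- x[!is.na(x$chrom), , drop = FALSE]
  rownames(x) <- NULL
  x
}
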