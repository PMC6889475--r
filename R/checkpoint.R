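## Checkpointing: the pairwise-LD table is by far the most expensive pipeline
## stage, and it only depends on the genotype input and the LD parameters --
## not on the user threshold, the feature type, or the annotation/candidate
## files. The checkpoint stores the pair table at the base threshold together
## with a fingerprint of its inputs and the kept variant positions, so a rerun
## at any threshold >= base can skip genotype parsing and LD computation
## entirely while producing byte-identical results.

ld_fingerprint <- function(genotype_paths, params, maf_min) {
  files <- sort(normalizePath(genotype_paths, mustWork = TRUE))
  md5 <- unname(tools::md5sum(files))
  list(version = 1L,
       geno_md5 = paste(md5, collapse = ""),
       estimator = params$estimator,
       base_threshold = params$base_threshold,
       window_bp = params$window_bp,
       min_informative = params$min_informative,
       maf_min = maf_min)
}

checkpoint_paths <- function(dir) {
  list(pairs = file.path(dir, "ld_pairs.tsv"),
       variants = file.path(dir, "ld_variants.tsv"),
       meta = file.path(dir, "checkpoint.json"))
}

#' Save an LD checkpoint
#'
#' Serializes the pair table (at the base threshold), the kept variant
#' positions and a fingerprint of the genotype input and LD parameters into a
#' human-inspectable versioned TSV + JSON sidecar pair.
#'
#' @param dir checkpoint directory (created if needed).
#' @param pairs pair table from [pairwise_ld()].
#' @param variants variants data.frame of the genotype matrix used.
#' @param fingerprint fingerprint list (internal).
#' @param extra named list of additional run metadata to store (e.g. sample
#'   count, exclusion counts).
#' @return Invisibly, `dir`.
#' @keywords internal
save_checkpoint <- function(dir, pairs, variants, fingerprint, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- checkpoint_paths(dir)
  df <- pairs
  df$r2 <- sprintf("%.17g", df$r2)  # full double precision, round-trips exactly
  for (f in c("pairs", "variants", "meta")) {
    tmp <- paste0(p[[f]], ".tmp")
    if (f == "pairs") {
      write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (f == "variants") {
      vv <- variants[, c("chrom", "pos", "vid")]
      vv$pos <- format(vv$pos, scientific = FALSE, trim = TRUE)
      write.table(vv, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      meta <- c(fingerprint,
                list(created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     n_pairs = nrow(pairs)),
                extra)
      jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA)
    }
    file.rename(tmp, p[[f]])
  }
  invisible(dir)
}

#' Load an LD checkpoint if it is valid for this run
#'
#' A checkpoint is reused only when its fingerprint (genotype file content
#' and LD parameters excluding the user threshold) matches and the requested
#' threshold is at least the stored base threshold; otherwise `NULL` is
#' returned and the caller recomputes.
#'
#' @param dir checkpoint directory.
#' @param fingerprint fingerprint of the current run (internal).
#' @param threshold requested user threshold.
#' @return `NULL`, or a list with `pairs`, `variants` and `meta`.
#' @keywords internal
load_checkpoint <- function(dir, fingerprint, threshold) {
  p <- checkpoint_paths(dir)
  if (!all(vapply(p, file.exists, TRUE))) return(NULL)
  meta <- tryCatch(jsonlite::read_json(p$meta, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta)) return(NULL)
  keys <- c("version", "geno_md5", "estimator", "base_threshold", "window_bp",
            "min_informative", "maf_min")
  if (!all(keys %in% names(meta))) return(NULL)
  same <- vapply(keys, function(k) {
    a <- meta[[k]]; b <- fingerprint[[k]]
    if (is.numeric(b)) isTRUE(a == b) else identical(as.character(a), as.character(b))
  }, TRUE)
  if (!all(same)) return(NULL)
  if (threshold < as.numeric(meta$base_threshold)) return(NULL)

  pairs <- read.table(p$pairs, header = TRUE, sep = "\t",
                      colClasses = c(chrom = "character", pos_a = "numeric",
                                     pos_b = "numeric", vid_a = "character",
                                     vid_b = "character", r2 = "character"))
  pairs$r2 <- as.numeric(pairs$r2)
  attr(pairs, "base_threshold") <- as.numeric(meta$base_threshold)
  attr(pairs, "estimator") <- as.character(meta$estimator)
  variants <- read.table(p$variants, header = TRUE, sep = "\t",
                         colClasses = c(chrom = "character", pos = "numeric",
                                        vid = "character"))
  list(pairs = pairs, variants = variants, meta = meta)
}
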