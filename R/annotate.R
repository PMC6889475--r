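#' Build a per-chromosome interval index over annotation features
#'
#' @param features data.frame from [read_annotations()].
#' @return An object of class `feature_index` supporting fast interval
#'   (stabbing) queries per chromosome.
#' @export
feature_index <- function(features) {
  by_chrom <- lapply(split(seq_len(nrow(features)), features$chrom), function(i) {
    f <- features[i, , drop = FALSE]
    list(ranges = IRanges::IRanges(start = as.integer(f$start),
                                   end = as.integer(f$end)),
         features = f)
  })
  structure(list(by_chrom = by_chrom, n = nrow(features)), class = "feature_index")
}

#' Features overlapping one candidate region
#'
#' Closed-interval overlap on the region's chromosome: a feature is reported
#' when `feature$start <= region$end` and `feature$end >= region$start`
#' (a single shared base pair suffices; adjacency is not overlap).
#'
#' @param region one-row data.frame from [build_regions()].
#' @param features a `feature_index` or the features data.frame.
#' @return data.frame of overlapping features sorted by `start` (possibly
#'   zero rows).
#' @export
overlapping_features <- function(region, features) {
  if (!inherits(features, "feature_index")) features <- feature_index(features)
  fx <- features$by_chrom[[as.character(region$chrom)]]
  empty <- data.frame(chrom = character(0), ftype = character(0),
                      start = numeric(0), end = numeric(0),
                      attributes = character(0), stringsAsFactors = FALSE)
  if (is.null(fx)) return(empty)
  q <- IRanges::IRanges(start = as.integer(region$start),
                        end = as.integer(region$end))
  hits <- IRanges::findOverlaps(q, fx$ranges)
  if (length(hits) == 0L) return(empty)
  res <- fx$features[S4Vectors::subjectHits(hits), , drop = FALSE]
  res <- res[order(res$start, res$end, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate all candidate regions
#'
#' Intersects every candidate region with the feature index and emits one row
#' per (candidate, overlapping feature) pair. A candidate linked to several
#' features therefore appears on several rows, and one feature linked to
#' several candidates appears under each of them; candidates overlapping no
#' feature contribute no rows but are counted in the attached summary.
#'
#' @param regions data.frame from [build_regions()].
#' @param features a `feature_index` or features data.frame (canonical
#'   chromosome names).
#' @param id_column if `TRUE`, additionally extract the `ID=` key from the
#'   attributes column into a `feature_id` column (convenience only; the
#'   attributes column itself is always passed through verbatim).
#' @return data.frame with columns `chrom`, `snp_id` (suffixed `"_alone"` for
#'   alone candidates), `snp_pos`, `region_start`, `region_end`,
#'   `feature_start`, `feature_end`, `attributes`, sorted by
#'   (`chrom`, `snp_pos`, `feature_start`); attributes `n_candidates`,
#'   `n_candidates_hit` and `n_candidates_no_hit` summarize the run.
#' @export
annotate_all <- function(regions, features, id_column = FALSE) {
  if (!inherits(features, "feature_index")) features <- feature_index(features)
  rows <- vector("list", nrow(regions))
  n_hit <- 0L
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    of <- overlapping_features(rg, features)
    if (nrow(of) == 0L) next
    n_hit <- n_hit + 1L
    rows[[i]] <- data.frame(
      chrom = rg$chrom,
      snp_id = if (rg$alone) paste0(rg$sid, "_alone") else rg$sid,
      snp_pos = rg$pos,
      region_start = rg$start, region_end = rg$end,
      feature_start = of$start, feature_end = of$end,
      attributes = of$attributes, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), snp_id = character(0),
               snp_pos = numeric(0), region_start = numeric(0),
               region_end = numeric(0), feature_start = numeric(0),
               feature_end = numeric(0), attributes = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$snp_pos, out$feature_start, method = "radix"),
             , drop = FALSE]
  rownames(out) <- NULL
  if (id_column) {
    out$feature_id <- NA_character_
    has <- grepl("(?:^|;)\\s*ID=", out$attributes)
    out$feature_id[has] <- sub("^;?\\s*ID=", "",
                               regmatches(out$attributes,
                                          regexpr("(?:^|;)\\s*ID=[^;]+",
                                                  out$attributes)))
  }
  attr(out, "n_candidates") <- nrow(regions)
  attr(out, "n_candidates_hit") <- n_hit
  attr(out, "n_candidates_no_hit") <- nrow(regions) - n_hit
  out
}

#' Write the annotation-hit table
#'
#' Tab-separated output with a header row and one row per
#' (candidate, overlapping feature) pair: chromosome, candidate SNP ID
#' (suffixed `"_alone"` where applicable), candidate position, region start
#' and end, feature start and end, and the feature's attributes verbatim.
#' Rows are ordered by (chromosome, candidate position, feature start). A run
#' with zero hits produces a header-only file.
#'
#' @param hits data.frame from [annotate_all()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_hits <- function(hits, path) {
  cols <- c("chrom", "snp_id", "snp_pos", "region_start", "region_end",
            "feature_start", "feature_end", "attributes")
  if (!all(cols %in% names(hits))) {
    stop(sprintf("hits table is missing column(s): %s",
                 paste(setdiff(cols, names(hits)), collapse = ", ")))
  }
  out <- hits[, cols, drop = FALSE]
  for (nc in c("snp_pos", "region_start", "region_end", "feature_start", "feature_end")) {
    out[[nc]] <- format(out[[nc]], scientific = FALSE, trim = TRUE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
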