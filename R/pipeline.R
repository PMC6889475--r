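#' Run the full candidate-SNP annotation pipeline
#'
#' Orchestrates the whole analysis: format checks, genotype parsing (VCF file
#' or SNP-array folder + SNP map), pairwise LD at the base threshold (0.4,
#' the lowest threshold a user may select), dataset-wide average linked
#' distance at the user threshold, region delineation around each candidate
#' SNP, feature overlap, and output writing. When `checkpoint_dir` is given,
#' the LD table is cached so a rerun with a different threshold or feature
#' type skips genotype parsing and LD computation; the rerun's results are
#' identical to a cold run. The output file is written atomically (temporary
#' file + rename), so a failed run never leaves a partial output behind.
#'
#' @param genotypes path to a VCF file, or to a folder of per-individual
#'   SNP-array files (in which case `snp_map` is required).
#' @param annotations path to a GFF/GTF/GFF3 file.
#' @param candidates path to the candidate SNP list.
#' @param ftype feature type to extract (e.g. `"gene"`).
#' @param threshold user r-squared threshold; must be at least the base
#'   threshold (0.4 by default).
#' @param output path of the tab-separated output table (see [write_hits()]).
#' @param snp_map path to the SNP map file (SNP-array input only).
#' @param params an [ld_params()] object.
#' @param maf_min minor-allele-frequency floor applied when reading genotypes.
#' @param chrom_lengths optional named vector, data.frame or file path of
#'   per-chromosome lengths (bp); when given, a genome-coverage estimate is
#'   included in the summary.
#' @param checkpoint_dir optional directory for the LD checkpoint.
#' @param on_missing_candidate policy when a candidate position is not a
#'   genotyped variant: `"error"` (default) or `"nearest"`.
#' @param id_column if `TRUE`, add a `feature_id` column extracted from the
#'   `ID=` attribute.
#' @param quiet suppress progress messages.
#' @return An object of class `ld_run` summarizing the run (counts of
#'   variants kept and excluded, pairs retained, skip classes, average linked
#'   distance, candidates with/without overlapping features, alone candidates,
#'   coverage when lengths were supplied) with the `regions` and `hits`
#'   tables attached.
#' @export
ld_annotate <- function(genotypes, annotations, candidates, ftype, threshold,
                        output, snp_map = NULL, params = ld_params(),
                        maf_min = 0, chrom_lengths = NULL,
                        checkpoint_dir = NULL,
                        on_missing_candidate = c("error", "nearest"),
                        id_column = FALSE, quiet = FALSE) {
  on_missing_candidate <- match.arg(on_missing_candidate)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (threshold < params$base_threshold) {
    stop(sprintf("threshold %g is below the base r^2 threshold %g: pairwise LD is only retained at r^2 >= %g, the lowest threshold a user may select",
                 threshold, params$base_threshold, params$base_threshold))
  }

  is_folder <- dir.exists(genotypes)
  if (is_folder && is.null(snp_map)) {
    stop("'snp_map' is required when 'genotypes' is a folder of SNP-array files")
  }
  geno_paths <- if (is_folder) {
    c(list.files(genotypes, pattern = "\\.txt$", full.names = TRUE), snp_map)
  } else {
    genotypes
  }
  if (!length(geno_paths) || !all(file.exists(geno_paths))) {
    stop(sprintf("genotype input not found: '%s'", genotypes))
  }

  fp <- ld_fingerprint(geno_paths, params, maf_min)
  ckpt <- if (!is.null(checkpoint_dir)) load_checkpoint(checkpoint_dir, fp, threshold)
  checkpoint_used <- !is.null(ckpt)

  if (checkpoint_used) {
    say("ld_annotate: reusing LD checkpoint in '%s' (fingerprint match); skipping genotype parsing and LD computation",
        checkpoint_dir)
    pairs <- ckpt$pairs
    variants <- ckpt$variants
    n_samples <- ckpt$meta$n_samples %||% NA_integer_
    excluded <- unlist(ckpt$meta$excluded %||% list())
    ld_counts <- c(n_tested = ckpt$meta$n_tested %||% NA_integer_,
                   low_informative = ckpt$meta$n_skipped_low_informative %||% NA_integer_,
                   monomorphic = ckpt$meta$n_skipped_monomorphic %||% NA_integer_)
  } else {
    gm <- if (is_folder) {
      if (quiet) suppressMessages(read_snp_array(genotypes, snp_map, maf_min = maf_min))
      else read_snp_array(genotypes, snp_map, maf_min = maf_min)
    } else {
      if (quiet) suppressMessages(read_vcf(genotypes, maf_min = maf_min))
      else read_vcf(genotypes, maf_min = maf_min)
    }
    say("ld_annotate: computing pairwise LD (estimator %s, base threshold %g)",
        params$estimator, params$base_threshold)
    pairs <- pairwise_ld(gm, params)
    variants <- gm$variants
    n_samples <- length(gm$samples)
    excluded <- attr(gm, "excluded")
    ld_counts <- c(n_tested = attr(pairs, "n_tested"),
                   low_informative = attr(pairs, "n_skipped_low_informative"),
                   monomorphic = attr(pairs, "n_skipped_monomorphic"))
    if (!is.null(checkpoint_dir)) {
      save_checkpoint(checkpoint_dir, pairs, variants, fp,
                      extra = list(n_samples = n_samples,
                                   excluded = as.list(excluded),
                                   n_tested = attr(pairs, "n_tested"),
                                   n_skipped_low_informative = attr(pairs, "n_skipped_low_informative"),
                                   n_skipped_monomorphic = attr(pairs, "n_skipped_monomorphic")))
      say("ld_annotate: wrote LD checkpoint to '%s'", checkpoint_dir)
    }
  }

  ann <- if (quiet) suppressMessages(read_annotations(annotations, ftype))
         else read_annotations(annotations, ftype)
  cand <- read_candidates(candidates)

  cmap <- withCallingHandlers(
    check_chromosome_consistency(variants, features = ann, candidates = cand,
                                 genotype_label = sprintf("'%s'", genotypes),
                                 feature_label = sprintf("'%s'", annotations),
                                 candidate_label = sprintf("'%s'", candidates)),
    warning = function(w) {
      if (quiet) invokeRestart("muffleWarning")
    })
  ann <- apply_chrom_map(ann, cmap$features)
  cand <- apply_chrom_map(cand, cmap$candidates)

  fb <- withCallingHandlers(
    average_linked_distance(pairs, threshold),
    warning = function(w) if (quiet) invokeRestart("muffleWarning"))
  say("ld_annotate: %d pair(s) at r^2 >= %g; average linked distance %s bp",
      fb$n_pairs, threshold,
      if (is.na(fb$average_distance)) "undefined"
      else format(round(fb$average_distance, 1), scientific = FALSE))

  regions <- if (quiet) {
    suppressMessages(suppressWarnings(
      build_regions(cand, pairs, threshold, fallback = fb, variants = variants,
                    on_missing = on_missing_candidate,
                    window_bp = if (params$window_bp == 0) Inf else params$window_bp)))
  } else {
    build_regions(cand, pairs, threshold, fallback = fb, variants = variants,
                  on_missing = on_missing_candidate,
                  window_bp = if (params$window_bp == 0) Inf else params$window_bp)
  }

  hits <- annotate_all(regions, ann, id_column = id_column)

  coverage <- NULL
  if (!is.null(chrom_lengths)) {
    if (is.character(chrom_lengths) && length(chrom_lengths) == 1L) {
      chrom_lengths <- read_chrom_lengths(chrom_lengths)
    }
    coverage <- genome_coverage(variants, fb, chrom_lengths)
  }

  tmp <- paste0(output, ".tmp-", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_hits(hits, tmp)
  if (!file.rename(tmp, output)) stop(sprintf("cannot write output file '%s'", output))
  say("ld_annotate: wrote %d hit row(s) to '%s'", nrow(hits), output)

  structure(list(
    output = output,
    threshold = threshold,
    params = params,
    maf_min = maf_min,
    ftype = ftype,
    n_samples = n_samples,
    n_variants = nrow(variants),
    excluded = excluded,
    n_pairs_base = nrow(pairs),
    ld_skips = ld_counts,
    summary = fb,
    n_candidates = nrow(regions),
    n_alone = sum(regions$alone),
    n_candidates_hit = attr(hits, "n_candidates_hit"),
    n_candidates_no_hit = attr(hits, "n_candidates_no_hit"),
    n_hits = nrow(hits),
    coverage = coverage,
    checkpoint_used = checkpoint_used,
    regions = regions,
    hits = hits
  ), class = "ld_run")
}

#' @export
print.ld_run <- function(x, ...) {
  cat("LD region annotation run\n")
  cat(sprintf("  genotypes: %s samples x %d variants (r^2 estimator: %s)\n",
              ifelse(is.na(x$n_samples), "?", x$n_samples), x$n_variants,
              x$params$estimator))
  if (length(x$excluded)) {
    cat(sprintf("  excluded variants: %s\n",
                paste(sprintf("%s=%s", names(x$excluded), x$excluded), collapse = ", ")))
  }
  cat(sprintf("  LD pairs at base r^2 >= %g: %d (skipped: %s low-informative, %s monomorphic)\n",
              x$params$base_threshold, x$n_pairs_base,
              x$ld_skips[["low_informative"]], x$ld_skips[["monomorphic"]]))
  cat(sprintf("  user threshold r^2 >= %g: %d pair(s), average linked distance %s bp\n",
              x$threshold, x$summary$n_pairs,
              if (is.na(x$summary$average_distance)) "undefined"
              else format(round(x$summary$average_distance, 1), scientific = FALSE)))
  cat(sprintf("  candidates: %d (%d with >= 1 overlapping %s, %d with none, %d alone)\n",
              x$n_candidates, x$n_candidates_hit, x$ftype,
              x$n_candidates_no_hit, x$n_alone))
  cat(sprintf("  output rows: %d -> %s%s\n", x$n_hits, x$output,
              if (x$checkpoint_used) " (LD stage from checkpoint)" else ""))
  if (!is.null(x$coverage)) {
    cat(sprintf("  estimated genome coverage at r^2 >= %g: %.1f%%\n",
                x$threshold, 100 * x$coverage))
  }
  invisible(x)
}

#' @export
summary.ld_run <- function(object, ...) {
  out <- object[c("threshold", "n_samples", "n_variants", "n_pairs_base",
                  "n_candidates", "n_alone", "n_candidates_hit",
                  "n_candidates_no_hit", "n_hits", "checkpoint_used")]
  out$average_distance <- object$summary$average_distance
  out$n_pairs_at_threshold <- object$summary$n_pairs
  out$coverage <- object$coverage
  out
}

#' Validate pipeline inputs without running the analysis
#'
#' Runs every input parser in validation mode plus the chromosome-name
#' consistency check, and reports per-file status with probable causes for
#' failures.
#'
#' @inheritParams ld_annotate
#' @return An object of class `ld_validation`: list with `issues` (data.frame
#'   of file, check, status, message) and `ok`.
#' @export
validate_inputs <- function(genotypes, annotations, candidates, ftype,
                            snp_map = NULL, maf_min = 0) {
  issues <- list()
  note <- function(file, check, status, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, check = check, status = status, message = msg,
      stringsAsFactors = FALSE)
  }
  run_check <- function(file, check, expr) {
    tryCatch({
      r <- suppressMessages(suppressWarnings(expr))
      note(file, check, "ok", "")
      r
    }, error = function(e) {
      note(file, check, "error", conditionMessage(e))
      NULL
    })
  }

  is_folder <- dir.exists(genotypes)
  gm <- if (is_folder) {
    if (is.null(snp_map)) {
      note(genotypes, "genotypes", "error",
           "'snp_map' is required when genotypes are a folder of SNP-array files")
      NULL
    } else {
      run_check(genotypes, "genotypes",
                read_snp_array(genotypes, snp_map, maf_min = maf_min))
    }
  } else {
    run_check(genotypes, "genotypes", read_vcf(genotypes, maf_min = maf_min))
  }
  ann <- run_check(annotations, "annotations", read_annotations(annotations, ftype))
  cand <- run_check(candidates, "candidates", read_candidates(candidates))

  if (!is.null(gm) && !is.null(cand)) {
    run_check(paste(genotypes, candidates, sep = " + "), "chromosome naming",
              check_chromosome_consistency(
                gm, features = ann, candidates = cand,
                genotype_label = sprintf("'%s'", genotypes),
                feature_label = sprintf("'%s'", annotations),
                candidate_label = sprintf("'%s'", candidates)))
  }

  issues <- do.call(rbind, issues)
  structure(list(issues = issues, ok = !any(issues$status == "error")),
            class = "ld_validation")
}

#' @export
print.ld_validation <- function(x, ...) {
  cat(sprintf("input validation: %s\n", if (x$ok) "all checks passed" else "FAILED"))
  for (i in seq_len(nrow(x$issues))) {
    r <- x$issues[i, ]
    cat(sprintf("  [%s] %s (%s)%s\n", r$status, r$check, r$file,
                if (nzchar(r$message)) paste0(": ", r$message) else ""))
  }
  invisible(x)
}
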