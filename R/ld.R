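#' LD computation parameters
#'
#' @param base_threshold r-squared floor below which pairs are never retained;
#'   0.4 is the lowest threshold a user may later select, so the pair table
#'   computed at this floor can serve any higher user threshold.
#' @param window_bp maximum inter-variant distance (bp) at which a pair is
#'   considered; `0` (or `Inf`) means unlimited. The default 1 Mb bounds the
#'   quadratic pair count on dense whole-genome inputs.
#' @param estimator `"dosage_correlation"` (squared Pearson correlation of
#'   allele dosages; the default) or `"em_haplotype"` (gametic r-squared from
#'   EM-estimated haplotype frequencies).
#' @param min_informative minimum number of samples non-missing at both
#'   variants for a pair to be evaluated.
#' @return An object of class `ld_params`.
#' @export
ld_params <- function(base_threshold = 0.4, window_bp = 1e6,
                      estimator = c("dosage_correlation", "em_haplotype"),
                      min_informative = 4L) {
  estimator <- match.arg(estimator)
  if (!is.numeric(base_threshold) || base_threshold <= 0 || base_threshold > 1) {
    stop("'base_threshold' must be in (0, 1]")
  }
  if (!is.numeric(window_bp) || window_bp < 0) stop("'window_bp' must be >= 0 (0 = unlimited)")
  min_informative <- as.integer(min_informative)
  if (min_informative < 2L) stop("'min_informative' must be >= 2")
  structure(list(base_threshold = base_threshold, window_bp = window_bp,
                 estimator = estimator, min_informative = min_informative),
            class = "ld_params")
}

#' @export
print.ld_params <- function(x, ...) {
  cat(sprintf("ld_params: estimator=%s, base_threshold=%g, window_bp=%s, min_informative=%d\n",
              x$estimator, x$base_threshold,
              if (x$window_bp == 0) "unlimited" else format(x$window_bp, scientific = FALSE),
              x$min_informative))
  invisible(x)
}

#' r-squared from allele-dosage correlation
#'
#' Squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples. Returns `NA` (with a `"reason"` attribute of
#' `"low_informative"` or `"monomorphic"`) when fewer than `min_informative`
#' samples are complete or either locus is monomorphic among them; such pairs
#' are skipped, not errors.
#'
#' @param x,y dosage vectors (0, 1, 2 or `NA`) of equal length.
#' @param min_informative minimum complete-sample count.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
r2_dosage <- function(x, y, min_informative = 4L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_informative) return(structure(NA_real_, reason = "low_informative"))
  xc <- x[ok]; yc <- y[ok]
  sx <- sum(xc); sy <- sum(yc)
  vx <- sum(xc * xc) - sx * sx / n
  vy <- sum(yc * yc) - sy * sy / n
  if (vx <= 0 || vy <= 0) return(structure(NA_real_, reason = "monomorphic"))
  cxy <- sum(xc * yc) - sx * sy / n
  clamp_r2((cxy * cxy) / (vx * vy))
}

## restrict to [0, 1]; values within 1e-12 of 1 are snapped to exactly 1 so
## that complete LD (identical or allele-flipped dosage vectors) survives an
## inclusive cut at threshold 1 despite floating-point rounding
clamp_r2 <- function(r2) {
  r2 <- min(max(r2, 0), 1)
  if (1 - r2 < 1e-12) 1 else r2
}

#' Gametic r-squared from EM haplotype-frequency estimation
#'
#' Estimates the four haplotype frequencies (pAB, pAb, paB, pab) from unphased
#' diploid genotypes by expectation-maximization under Hardy-Weinberg
#' equilibrium: genotypes other than the double heterozygote determine their
#' two gametes; double heterozygotes contribute fractionally to AB/ab versus
#' Ab/aB according to the current frequency estimates. Iteration stops when
#' every frequency changes by less than `tol` (default 1e-10) or after
#' `max_iter` iterations (a warning is emitted and the last iterate used).
#' Returns `D^2 / (pA pa pB pb)` with `D = pAB - pA pB`.
#'
#' Allele frequencies are conserved by the EM update, so the estimate differs
#' from [r2_dosage()] only through the haplotype-phase model.
#'
#' @inheritParams r2_dosage
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter maximum EM iterations.
#' @return r-squared in `[0, 1]`, or `NA` (see [r2_dosage()] for skip reasons).
#' @export
r2_em <- function(x, y, min_informative = 4L, tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_informative) return(structure(NA_real_, reason = "low_informative"))
  xc <- x[ok]; yc <- y[ok]
  if (var(xc) == 0 || var(yc) == 0) return(structure(NA_real_, reason = "monomorphic"))

  N <- table(factor(xc, levels = 0:2), factor(yc, levels = 0:2))
  N <- matrix(as.numeric(N), 3, 3)      # N[gx+1, gy+1]
  n2 <- 2 * n
  ndh <- N[2, 2]                        # double heterozygotes
  ## gamete contributions fixed by all other genotype classes
  kAB <- 2 * N[3, 3] + N[3, 2] + N[2, 3]
  kAb <- 2 * N[3, 1] + N[3, 2] + N[2, 1]
  kaB <- 2 * N[1, 3] + N[1, 2] + N[2, 3]
  kab <- 2 * N[1, 1] + N[1, 2] + N[2, 1]

  pA <- sum(xc) / n2
  pB <- sum(yc) / n2
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    den <- h[1] * h[4] + h[2] * h[3]
    w <- if (den > 0) h[1] * h[4] / den else 0.5
    hn <- c(kAB + w * ndh, kAb + (1 - w) * ndh,
            kaB + (1 - w) * ndh, kab + w * ndh) / n2
    if (max(abs(hn - h)) < tol) {
      h <- hn
      converged <- TRUE
      break
    }
    h <- hn
  }
  if (!converged) {
    warning(sprintf("EM haplotype estimation did not converge in %d iterations; using last iterate",
                    max_iter), call. = FALSE)
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den <= 0) return(structure(NA_real_, reason = "monomorphic"))
  D <- h[1] - pA * pB
  clamp_r2(D * D / den)
}

#' Pairwise LD across a genotype matrix
#'
#' Computes r-squared for every pair of variants on the same chromosome whose
#' inter-variant distance is within `window_bp`, and retains pairs with
#' r-squared at or above the base threshold. Retention is inclusive (`>=`).
#'
#' @param genotypes a [genotype_matrix()].
#' @param params an [ld_params()] object.
#' @return data.frame with columns `chrom`, `pos_a`, `pos_b` (`pos_a < pos_b`),
#'   `vid_a`, `vid_b`, `r2`, sorted by (`chrom`, `pos_a`, `pos_b`); attributes
#'   `base_threshold`, `estimator`, `n_tested`, `n_skipped_low_informative`
#'   and `n_skipped_monomorphic` summarize the scan.
#' @export
pairwise_ld <- function(genotypes, params = ld_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(params, "ld_params"))
  v <- genotypes$variants
  D <- genotypes$dosages
  window <- if (params$window_bp == 0) Inf else params$window_bp
  est <- switch(params$estimator,
                dosage_correlation = r2_dosage,
                em_haplotype = r2_em)

  chunks <- list()
  n_tested <- 0L; skip_low <- 0L; skip_mono <- 0L
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (length(idx) < 2L) next
    pos <- v$pos[idx]
    ia <- integer(0); ib <- integer(0); rr <- numeric(0)
    for (a in seq_len(length(idx) - 1L)) {
      xa <- D[, idx[a]]
      for (b in (a + 1L):length(idx)) {
        if (pos[b] - pos[a] > window) break
        n_tested <- n_tested + 1L
        r2 <- est(xa, D[, idx[b]], min_informative = params$min_informative)
        if (is.na(r2)) {
          if (identical(attr(r2, "reason"), "low_informative")) {
            skip_low <- skip_low + 1L
          } else {
            skip_mono <- skip_mono + 1L
          }
          next
        }
        if (r2 >= params$base_threshold) {
          ia <- c(ia, a); ib <- c(ib, b); rr <- c(rr, as.numeric(r2))
        }
      }
    }
    if (length(ia)) {
      chunks[[ch]] <- data.frame(chrom = ch,
                                 pos_a = pos[ia], pos_b = pos[ib],
                                 vid_a = v$vid[idx[ia]], vid_b = v$vid[idx[ib]],
                                 r2 = rr, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(chunks)) do.call(rbind, unname(chunks)) else
    data.frame(chrom = character(0), pos_a = numeric(0), pos_b = numeric(0),
               vid_a = character(0), vid_b = character(0), r2 = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "base_threshold") <- params$base_threshold
  attr(out, "estimator") <- params$estimator
  attr(out, "n_tested") <- n_tested
  attr(out, "n_skipped_low_informative") <- skip_low
  attr(out, "n_skipped_monomorphic") <- skip_mono
  out
}
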