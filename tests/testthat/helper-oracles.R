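## Independent oracles used to cross-check the package's own implementations.
## These deliberately take the naive route (stats::cor, brute-force double
## loops, exhaustive likelihood grids) rather than sharing any code with the
## functions they check.

## squared Pearson correlation over pairwise-complete samples, via stats::cor
oracle_r2 <- function(x, y, min_informative = 4L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_informative) return(NA_real_)
  xc <- x[ok]; yc <- y[ok]
  if (var(xc) == 0 || var(yc) == 0) return(NA_real_)
  stats::cor(xc, yc)^2
}

## naive all-pairs LD scan with the same window/threshold semantics
oracle_pairwise <- function(gm, params) {
  v <- gm$variants
  D <- gm$dosages
  window <- if (params$window_bp == 0) Inf else params$window_bp
  rows <- list()
  n <- nrow(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (v$chrom[i] != v$chrom[j]) next
      if (abs(v$pos[j] - v$pos[i]) > window) next
      r2 <- oracle_r2(D[, i], D[, j], params$min_informative)
      if (!is.na(r2) && min(max(r2, 0), 1) >= params$base_threshold) {
        a <- if (v$pos[i] <= v$pos[j]) i else j
        b <- if (v$pos[i] <= v$pos[j]) j else i
        rows[[length(rows) + 1]] <- data.frame(
          chrom = v$chrom[a], pos_a = v$pos[a], pos_b = v$pos[b],
          vid_a = v$vid[a], vid_b = v$vid[b], r2 = min(max(r2, 0), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos_a = numeric(0), pos_b = numeric(0),
               vid_a = character(0), vid_b = character(0), r2 = numeric(0))
  out <- out[order(out$chrom, out$pos_a, out$pos_b, method = "radix"), ]
  rownames(out) <- NULL
  out
}

## brute-force closed-interval overlap of regions x features
oracle_overlap <- function(regions, features) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    for (j in seq_len(nrow(features))) {
      f <- features[j, ]
      if (f$chrom == rg$chrom && f$start <= rg$end && f$end >= rg$start) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = rg$chrom,
          snp_id = if (rg$alone) paste0(rg$sid, "_alone") else rg$sid,
          snp_pos = rg$pos, region_start = rg$start, region_end = rg$end,
          feature_start = f$start, feature_end = f$end,
          attributes = f$attributes, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), snp_id = character(0),
               snp_pos = numeric(0), region_start = numeric(0),
               region_end = numeric(0), feature_start = numeric(0),
               feature_end = numeric(0), attributes = character(0))
  out <- out[order(out$chrom, out$snp_pos, out$feature_start, method = "radix"), ]
  rownames(out) <- NULL
  out
}

## direct haplotype counting; valid only when no sample is heterozygous at
## both loci (phase is then fully determined by the genotypes)
oracle_hap_count_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  xc <- x[ok]; yc <- y[ok]
  stopifnot(!any(xc == 1 & yc == 1))
  split2 <- function(g) if (g == 0) c(0, 0) else if (g == 1) c(1, 0) else c(1, 1)
  nAB <- nAb <- naB <- nab <- 0
  for (i in seq_along(xc)) {
    gx <- split2(xc[i]); gy <- split2(yc[i])
    ## pairing is unique as a multiset when not both heterozygous
    for (k in 1:2) {
      if (gx[k] == 1 && gy[k] == 1) nAB <- nAB + 1
      if (gx[k] == 1 && gy[k] == 0) nAb <- nAb + 1
      if (gx[k] == 0 && gy[k] == 1) naB <- naB + 1
      if (gx[k] == 0 && gy[k] == 0) nab <- nab + 1
    }
  }
  tot <- nAB + nAb + naB + nab
  pAB <- nAB / tot
  pA <- (nAB + nAb) / tot
  pB <- (nAB + naB) / tot
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## exhaustive 1-D multinomial-likelihood grid over the free haplotype
## frequency pAB (allele frequencies are fixed at their marginal MLEs)
oracle_em_grid_r2 <- function(x, y, step = 1e-5) {
  ok <- !is.na(x) & !is.na(y)
  xc <- x[ok]; yc <- y[ok]
  n <- length(xc)
  N <- table(factor(xc, levels = 0:2), factor(yc, levels = 0:2))
  N <- matrix(as.numeric(N), 3, 3)
  pA <- sum(xc) / (2 * n)
  pB <- sum(yc) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  g <- unique(c(seq(lo, hi, by = step), hi))
  hAB <- g; hAb <- pA - g; haB <- pB - g; hab <- 1 - pA - pB + g
  logp <- function(p) {
    out <- rep(-Inf, length(p))
    ok <- p > 0
    out[ok] <- log(p[ok])
    out
  }
  ll <- N[1, 1] * logp(hab^2)          + N[1, 2] * logp(2 * hab * haB) +
        N[1, 3] * logp(haB^2)          + N[2, 1] * logp(2 * hab * hAb) +
        N[2, 2] * logp(2 * (hAB * hab + hAb * haB)) +
        N[2, 3] * logp(2 * haB * hAB)  + N[3, 1] * logp(hAb^2) +
        N[3, 2] * logp(2 * hAb * hAB)  + N[3, 3] * logp(hAB^2)
  ll[is.nan(ll)] <- -Inf
  best <- g[which.max(ll)]
  D <- best - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## random dosage matrix generator for oracle-equivalence fixtures
random_genotypes <- function(n_samples, n_variants, n_chrom = 2,
                             missing_rate = 0.05, correlated = TRUE) {
  chrom <- sort(as.character(sample(seq_len(n_chrom), n_variants, replace = TRUE)))
  pos <- unlist(lapply(split(seq_len(n_variants), chrom), function(i) {
    sort(sample.int(1e6, length(i)))
  }), use.names = FALSE)
  D <- matrix(NA_real_, n_samples, n_variants)
  base <- rbinom(n_samples, 2, runif(1, 0.2, 0.8))
  for (j in seq_len(n_variants)) {
    if (correlated && runif(1) < 0.5) {
      ## partially copy a shared vector so some pairs clear the threshold
      keep <- runif(n_samples) < runif(1, 0.5, 1)
      D[, j] <- ifelse(keep, base, rbinom(n_samples, 2, runif(1, 0.1, 0.9)))
    } else {
      D[, j] <- rbinom(n_samples, 2, runif(1, 0.05, 0.95))
    }
  }
  if (missing_rate > 0) D[runif(length(D)) < missing_rate] <- NA
  genotype_matrix(D, chrom = chrom, pos = pos)
}
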