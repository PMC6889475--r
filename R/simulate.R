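#' Configuration for the synthetic genotype simulator
#'
#' Describes a diploid study population with block-wise LD structure. LD is
#' induced by founder-gamete copying: within a `"hard"` block every variant
#' carries an exact copy of the block's founder gametes (optionally
#' allele-flipped), guaranteeing pairwise r-squared of 1 before missingness;
#' within a `"decay"` block each variant's gametes copy the previous
#' variant's, with each gamete independently resampled from the founder
#' allele frequency with probability `rate`, so haplotype correlation decays
#' as `(1 - rate)^distance` in variant steps. Variants outside blocks are
#' drawn independently.
#'
#' @param n_samples number of diploid individuals (default 50, a typical
#'   breeding-population or pedigree genotyping scale).
#' @param n_chromosomes number of chromosomes (named `"1"`, `"2"`, ...).
#' @param chrom_length_bp chromosome length in bp; variant positions are
#'   evenly spaced along it.
#' @param n_variants_per_chrom variants per chromosome.
#' @param blocks list of blocks, each a list with `chrom` (name), `from`,
#'   `to` (variant indices within the chromosome, inclusive), `kind`
#'   (`"hard"` or `"decay"`) and, for decay blocks, `rate` (per-step gamete
#'   resampling probability in `[0, 1]`).
#' @param maf_range range the per-founder minor allele frequency is drawn
#'   uniformly from.
#' @param missing_rate probability that any single genotype is missing.
#' @param seed integer seed; a fixed seed yields byte-identical fixtures.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 50, n_chromosomes = 2,
                       chrom_length_bp = 1e6, n_variants_per_chrom = 60,
                       blocks = list(
                         list(chrom = "1", from = 11, to = 20, kind = "hard"),
                         list(chrom = "1", from = 36, to = 50, kind = "decay", rate = 0.02),
                         list(chrom = "2", from = 11, to = 20, kind = "hard"),
                         list(chrom = "2", from = 36, to = 50, kind = "decay", rate = 0.02)),
                       maf_range = c(0.1, 0.5), missing_rate = 0, seed = 1) {
  stopifnot(n_samples >= 2, n_chromosomes >= 1, n_variants_per_chrom >= 2,
            chrom_length_bp >= n_variants_per_chrom,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate <= 1)
  chroms <- as.character(seq_len(n_chromosomes))
  for (b in blocks) {
    if (!all(c("chrom", "from", "to", "kind") %in% names(b))) {
      stop("each block needs 'chrom', 'from', 'to' and 'kind'")
    }
    if (!b$chrom %in% chroms) {
      stop(sprintf("block chromosome '%s' is not among the simulated chromosomes", b$chrom))
    }
    if (b$from < 1 || b$to > n_variants_per_chrom || b$from > b$to) {
      stop(sprintf("block %d..%d on chromosome %s lies outside 1..%d",
                   b$from, b$to, b$chrom, n_variants_per_chrom))
    }
    if (identical(b$kind, "decay") &&
        (is.null(b$rate) || b$rate < 0 || b$rate > 1)) {
      stop("decay blocks need a 'rate' in [0, 1]")
    }
    if (!b$kind %in% c("hard", "decay")) stop("block 'kind' must be 'hard' or 'decay'")
  }
  ## blocks on the same chromosome must not overlap
  for (ch in chroms) {
    bb <- Filter(function(b) b$chrom == ch, blocks)
    if (length(bb) > 1) {
      iv <- do.call(rbind, lapply(bb, function(b) c(b$from, b$to)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
        stop(sprintf("overlapping blocks on chromosome %s", ch))
      }
    }
  }
  structure(list(n_samples = n_samples, n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 n_variants_per_chrom = n_variants_per_chrom,
                 blocks = blocks, maf_range = maf_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype matrix with known LD-block structure
#'
#' @param config a [sim_config()].
#' @return An object of class `ld_sim`: list with `genotypes` (a
#'   [genotype_matrix()]), `blocks` (data.frame of the true block map with
#'   columns `chrom`, `from`, `to`, `start_bp`, `end_bp`, `kind`, `rate`) and
#'   `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_samples
  nv <- config$n_variants_per_chrom
  chroms <- as.character(seq_len(config$n_chromosomes))

  draw_p <- function() {
    m <- runif(1, config$maf_range[1], config$maf_range[2])
    if (runif(1) < 0.5) m else 1 - m
  }
  draw_polymorphic_gametes <- function() {
    for (try in 1:100) {
      p <- draw_p()
      g1 <- rbinom(ns, 1, p)
      g2 <- rbinom(ns, 1, p)
      if (var(g1 + g2) > 0) return(list(p = p, g1 = g1, g2 = g2))
    }
    stop("could not draw a polymorphic founder in 100 attempts; widen 'maf_range' or increase 'n_samples'")
  }

  all_dos <- NULL
  all_chrom <- character(0)
  all_pos <- numeric(0)
  all_vid <- character(0)
  block_rows <- list()

  for (ch in chroms) {
    pos <- round(seq_len(nv) * config$chrom_length_bp / (nv + 1))
    block_id <- integer(nv)
    bb <- Filter(function(b) b$chrom == ch, config$blocks)
    for (k in seq_along(bb)) block_id[bb[[k]]$from:bb[[k]]$to] <- k

    H1 <- matrix(0L, ns, nv)
    H2 <- matrix(0L, ns, nv)
    for (j in which(block_id == 0L)) {
      f <- draw_polymorphic_gametes()
      H1[, j] <- f$g1
      H2[, j] <- f$g2
    }
    for (k in seq_along(bb)) {
      b <- bb[[k]]
      f <- draw_polymorphic_gametes()
      cur1 <- f$g1; cur2 <- f$g2
      for (j in b$from:b$to) {
        if (identical(b$kind, "decay") && j > b$from) {
          m1 <- runif(ns) < b$rate
          m2 <- runif(ns) < b$rate
          cur1[m1] <- rbinom(sum(m1), 1, f$p)
          cur2[m2] <- rbinom(sum(m2), 1, f$p)
        }
        if (identical(b$kind, "hard") && runif(1) < 0.5) {
          H1[, j] <- 1L - cur1   # allele relabeling; r^2 is invariant
          H2[, j] <- 1L - cur2
        } else {
          H1[, j] <- cur1
          H2[, j] <- cur2
        }
      }
      block_rows[[length(block_rows) + 1L]] <-
        data.frame(chrom = ch, from = b$from, to = b$to,
                   start_bp = pos[b$from], end_bp = pos[b$to],
                   kind = b$kind, rate = b$rate %||% NA_real_,
                   stringsAsFactors = FALSE)
    }

    dos <- H1 + H2
    all_dos <- cbind(all_dos, dos)
    all_chrom <- c(all_chrom, rep(ch, nv))
    all_pos <- c(all_pos, pos)
    all_vid <- c(all_vid, paste0("snp", ch, "_", seq_len(nv)))
  }

  if (config$missing_rate > 0) {
    miss <- runif(length(all_dos)) < config$missing_rate
    all_dos[miss] <- NA
  }

  gm <- genotype_matrix(all_dos, chrom = all_chrom, pos = all_pos,
                        vid = all_vid,
                        ref = rep("A", length(all_pos)),
                        alt = rep("G", length(all_pos)),
                        samples = sprintf("ind%03d", seq_len(ns)))
  blocks <- if (length(block_rows)) do.call(rbind, block_rows) else
    data.frame(chrom = character(0), from = integer(0), to = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               kind = character(0), rate = numeric(0))
  structure(list(genotypes = gm, blocks = blocks, config = config),
            class = "ld_sim")
}

#' Write a genotype matrix as a VCF file
#'
#' Minimal VCF 4.2 rendering (GT field only) of a [genotype_matrix()], used by
#' the fixture generator; [read_vcf()] on the result reproduces the matrix
#' exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  ref <- ifelse(is.na(v$ref), "A", v$ref)
  alt <- ifelse(is.na(v$alt), "G", v$alt)
  gt_lut <- c("0/0", "0/1", "1/1")
  gts <- apply(gm$dosages, 2, function(col) {
    out <- rep("./.", length(col))
    ok <- !is.na(col)
    out[ok] <- gt_lut[col[ok] + 1L]
    out
  })  # samples x variants
  if (is.null(dim(gts))) gts <- matrix(gts, nrow = 1)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=ldregion synthetic fixture generator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(j) {
      paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE, trim = TRUE),
              v$vid[j], ref[j], alt[j], ".", "PASS", ".", "GT", gts[, j]),
            collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a genotype matrix as a SNP-array folder plus SNP map
#'
#' Renders the matrix as one per-individual text file (12 comment/header
#' lines, then SNP name and two allele calls per row) plus a SNP map file, the
#' input pair accepted by [read_snp_array()].
#'
#' @param gm a [genotype_matrix()].
#' @param dir output folder for the per-individual files (created).
#' @param map_path output path for the SNP map.
#' @return Invisibly, `dir`.
#' @export
write_snp_array <- function(gm, dir, map_path) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- gm$variants
  ref <- ifelse(is.na(v$ref), "A", v$ref)
  alt <- ifelse(is.na(v$alt), "G", v$alt)
  header <- c(sprintf("# synthetic SNP-array export, sample %%s"),
              rep("# (header filler line)", 10),
              "SNP Name\tAllele1\tAllele2")
  for (i in seq_along(gm$samples)) {
    d <- gm$dosages[i, ]
    a1 <- ifelse(is.na(d), "-", ifelse(d >= 1, alt, ref))
    a2 <- ifelse(is.na(d), "-", ifelse(d == 2, alt, ref))
    hdr <- header
    hdr[1] <- sprintf(hdr[1], gm$samples[i])
    writeLines(c(hdr, paste(v$vid, a1, a2, sep = "\t")),
               file.path(dir, paste0(gm$samples[i], ".txt")))
  }
  writeLines(c("Name\tChromosome\tPosition",
               paste(v$vid, v$chrom,
                     format(v$pos, scientific = FALSE, trim = TRUE), sep = "\t")),
             map_path)
  invisible(dir)
}

#' Write a complete fixture bundle for end-to-end pipeline tests
#'
#' Emits every input format the pipeline accepts -- a VCF, a SNP-array folder
#' with SNP map, a GFF3 annotation, a candidate list and a chromosome-lengths
#' file -- all derived from one simulated genotype matrix, plus a JSON
#' manifest of ground truth for assertions. Genes (each with a matching mRNA
#' line) are placed fully inside each block, overlapping each block's
#' downstream edge, and between blocks. Candidates are placed at the middle
#' variant of each block and at one between-block ("lone") variant per
#' chromosome; candidate chromosomes are written with a `chr` prefix to
#' exercise name normalization.
#'
#' @param sim an `ld_sim` from [simulate_genotypes()].
#' @param dir output directory (created).
#' @return Invisibly, a list with the file `paths` and the `manifest`.
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "ld_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- sim$genotypes
  cfg <- sim$config
  v <- gm$variants
  paths <- list(vcf = file.path(dir, "geno.vcf"),
                snp_array = file.path(dir, "snp_array"),
                snp_map = file.path(dir, "SNP_Map.txt"),
                gff3 = file.path(dir, "annot.gff3"),
                candidates = file.path(dir, "candidates.txt"),
                chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
                manifest = file.path(dir, "manifest.json"))

  write_vcf(gm, paths$vcf)
  write_snp_array(gm, paths$snp_array, paths$snp_map)

  ## genes relative to blocks: one inside, one overlapping the right edge;
  ## plus one gene between blocks per chromosome
  genes <- list()
  gid <- 0L
  add_gene <- function(chrom, start, end) {
    gid <<- gid + 1L
    genes[[gid]] <<- data.frame(chrom = chrom, start = max(1, round(start)),
                                end = min(cfg$chrom_length_bp, round(end)),
                                id = sprintf("gene%03d", gid),
                                stringsAsFactors = FALSE)
    genes[[gid]]$id
  }
  blocks <- sim$blocks
  blocks$gene_inside <- NA_character_
  blocks$gene_edge <- NA_character_
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    w <- b$end_bp - b$start_bp
    blocks$gene_inside[i] <- add_gene(b$chrom, b$start_bp + w / 4, b$end_bp - w / 4)
    blocks$gene_edge[i] <- add_gene(b$chrom, b$end_bp - w / 8, b$end_bp + 2000)
  }
  for (ch in unique(v$chrom)) {
    bb <- blocks[blocks$chrom == ch, ]
    gap_start <- if (nrow(bb)) max(bb$end_bp) + 5000 else 1
    add_gene(ch, gap_start + 20000, gap_start + 22000)
  }
  genes <- do.call(rbind, genes)

  gff <- c("##gff-version 3",
           unlist(lapply(seq_len(nrow(genes)), function(i) {
             g <- genes[i, ]
             s <- format(g$start, scientific = FALSE, trim = TRUE)
             e <- format(g$end, scientific = FALSE, trim = TRUE)
             c(paste(g$chrom, "sim", "gene", s, e, ".", "+", ".",
                     sprintf("ID=%s;Name=%s", g$id, toupper(g$id)), sep = "\t"),
               paste(g$chrom, "sim", "mRNA", s, e, ".", "+", ".",
                     sprintf("ID=%s.t1;Parent=%s", g$id, g$id), sep = "\t"))
           })))
  writeLines(gff, paths$gff3)

  ## candidates: block middles + one lone between-block variant per chromosome
  cand <- list()
  add_cand <- function(chrom, pos, sid) {
    cand[[length(cand) + 1L]] <<- data.frame(chrom = chrom, pos = pos, sid = sid,
                                             stringsAsFactors = FALSE)
  }
  hard_expected <- list()
  alone_sids <- character(0)
  decay_sids <- character(0)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    mid_idx <- (b$from + b$to) %/% 2
    pos <- v$pos[v$chrom == b$chrom][mid_idx]
    sid <- sprintf("cand_%s_%s_%d", b$kind, b$chrom, i)
    add_cand(b$chrom, pos, sid)
    if (b$kind == "hard") {
      span_genes <- genes$id[genes$chrom == b$chrom &
                             genes$start <= b$end_bp & genes$end >= b$start_bp]
      hard_expected[[sid]] <- list(chrom = b$chrom, pos = pos,
                                   region_start = b$start_bp,
                                   region_end = b$end_bp,
                                   feature_ids = span_genes)
    } else {
      decay_sids <- c(decay_sids, sid)
    }
  }
  for (ch in unique(v$chrom)) {
    bb <- blocks[blocks$chrom == ch, ]
    free <- setdiff(seq_len(cfg$n_variants_per_chrom),
                    unlist(lapply(seq_len(nrow(bb)), function(k) bb$from[k]:bb$to[k])))
    ## pick the free variant farthest from any block
    pos_ch <- v$pos[v$chrom == ch]
    dist_to_block <- vapply(free, function(j) {
      if (!nrow(bb)) return(Inf)
      min(abs(pos_ch[j] - bb$start_bp), abs(pos_ch[j] - bb$end_bp))
    }, 0)
    lone_idx <- free[which.max(dist_to_block)]
    sid <- sprintf("cand_lone_%s", ch)
    add_cand(ch, pos_ch[lone_idx], sid)
    alone_sids <- c(alone_sids, sid)
  }
  cand <- do.call(rbind, cand)
  writeLines(paste(paste0("chr", cand$chrom),
                   format(cand$pos, scientific = FALSE, trim = TRUE),
                   cand$sid, sep = "\t"),
             paths$candidates)

  writeLines(c("chrom\tlength_bp",
               paste(unique(v$chrom),
                     format(cfg$chrom_length_bp, scientific = FALSE, trim = TRUE),
                     sep = "\t")),
             paths$chrom_lengths)

  manifest <- list(seed = cfg$seed,
                   n_samples = cfg$n_samples,
                   n_variants = nrow(v),
                   missing_rate = cfg$missing_rate,
                   files = lapply(paths, basename),
                   hard_candidates = hard_expected,
                   decay_candidates = decay_sids,
                   alone_candidates = alone_sids)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest))
}
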