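test_that("average_linked_distance is the mean separation of qualifying pairs", {
  p <- pairs_table("1", c(100, 100, 100), c(200, 300, 400),
                   r2 = c(0.95, 0.8, 0.5))
  s <- average_linked_distance(p, 0.5)
  expect_equal(s$average_distance, 200)
  expect_equal(s$n_pairs, 3L)
  s9 <- average_linked_distance(p, 0.9)
  expect_equal(s9$average_distance, 100)
  expect_equal(s9$n_pairs, 1L)
  expect_warning(s_none <- average_linked_distance(p, 0.99), "undefined")
  expect_true(is.na(s_none$average_distance))
  expect_equal(s_none$n_pairs, 0L)
  expect_error(average_linked_distance(p, 0.2), "base threshold")
})

test_that("build_region spans the foremost up- and downstream linked SNPs", {
  p <- pairs_table("1", c(400, 700, 1000, 1000), c(1000, 1000, 1500, 2000),
                   r2 = c(0.9, 0.95, 0.85, 0.5))
  fb <- average_linked_distance(p, 0.7)
  r <- build_region(list(chrom = "1", pos = 1000, sid = "c1"), p, 0.7, fb)
  expect_equal(r$start, 400)
  expect_equal(r$end, 1500)    # the 2000 bp SNP is below threshold
  expect_false(r$alone)
  expect_equal(r$n_linked, 3L)
})

test_that("candidates with no linked SNP fall back to the average distance", {
  p <- pairs_table("1", c(5000, 5400), c(5200, 5800), r2 = c(0.9, 0.9))
  fb <- average_linked_distance(p, 0.7)   # mean(200, 400) = 300
  expect_equal(fb$average_distance, 300)
  r <- build_region(list(chrom = "1", pos = 1000, sid = "c"), p, 0.7, fb)
  expect_true(r$alone)
  expect_equal(c(r$start, r$end), c(700, 1300))
  expect_equal(r$n_linked, 0L)
  ## lower bound clamps at 1
  r2 <- build_region(list(chrom = "1", pos = 50, sid = "c"), p, 0.7, fb)
  expect_equal(c(r2$start, r2$end), c(1, 350))
  ## no average available -> region degenerates to the candidate position
  expect_warning(fb0 <- average_linked_distance(p, 0.99), "undefined")
  expect_warning(
    r3 <- build_region(list(chrom = "1", pos = 1000, sid = "c"), p, 0.99, fb0),
    "degenerates")
  expect_equal(c(r3$start, r3$end), c(1000, 1000))
})

test_that("alone flag is true exactly when no SNP is linked", {
  p <- pairs_table("1", c(100, 5000), c(300, 5100), r2 = c(0.9, 0.6))
  fb <- average_linked_distance(p, 0.5)
  cands <- data.frame(chrom = "1", pos = c(100, 5000, 9000),
                      sid = c("a", "b", "lone"), stringsAsFactors = FALSE)
  rg <- build_regions(cands, p, 0.5, fallback = fb)
  expect_equal(rg$alone, c(FALSE, FALSE, TRUE))
  expect_true(all((rg$n_linked == 0) == rg$alone))
  expect_true(all(rg$start <= rg$pos & rg$pos <= rg$end))
})

test_that("ungenotyped candidates follow the on_missing policy", {
  d <- c(0, 1, 2, 2, 0, 1)
  gm <- genotype_matrix(cbind(d, d, d), chrom = rep("1", 3),
                        pos = c(100, 500, 900))
  p <- pairwise_ld(gm, ld_params())
  fb <- average_linked_distance(p, 0.7)
  cands <- data.frame(chrom = "1", pos = 510, sid = "c",
                      stringsAsFactors = FALSE)
  expect_error(build_regions(cands, p, 0.7, fb, variants = gm),
               "not a genotyped variant")
  rg <- suppressMessages(
    build_regions(cands, p, 0.7, fb, variants = gm, on_missing = "nearest"))
  expect_equal(c(rg$start, rg$end), c(100, 900))  # anchored at the 500 bp SNP
  expect_equal(rg$pos, 510)                       # candidate position preserved
  far <- data.frame(chrom = "1", pos = 9e6, sid = "far", stringsAsFactors = FALSE)
  expect_error(suppressMessages(
    build_regions(far, p, 0.7, fb, variants = gm, on_missing = "nearest",
                  window_bp = 1000)), "beyond")
})

test_that("raising the threshold never enlarges regions nor reduces alone counts", {
  set.seed(77)
  sim <- simulate_genotypes(sim_config(seed = 77))
  gm <- sim$genotypes
  pairs <- pairwise_ld(gm, ld_params())
  cands <- data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
                      sid = gm$variants$vid, stringsAsFactors = FALSE)
  cands <- cands[seq(1, nrow(cands), by = 7), ]
  prev <- NULL
  prev_alone <- -1
  for (thr in c(0.4, 0.6, 0.8, 0.95)) {
    fb <- suppressWarnings(average_linked_distance(pairs, thr))
    rg <- suppressWarnings(build_regions(cands, pairs, thr, fallback = fb))
    if (!is.null(prev)) {
      cmp <- !rg$alone & !prev$alone
      expect_true(all(rg$start[cmp] >= prev$start[cmp]))
      expect_true(all(rg$end[cmp] <= prev$end[cmp]))
      expect_true(sum(rg$alone) >= prev_alone)
    }
    prev <- rg
    prev_alone <- sum(rg$alone)
  }
})

test_that("non-alone region bounds are genotyped positions linked to the candidate", {
  set.seed(88)
  sim <- simulate_genotypes(sim_config(seed = 88))
  gm <- sim$genotypes
  pairs <- pairwise_ld(gm, ld_params())
  cands <- data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
                      sid = gm$variants$vid, stringsAsFactors = FALSE)[c(15, 40, 75), ]
  fb <- average_linked_distance(pairs, 0.7)
  rg <- build_regions(cands, pairs, 0.7, fallback = fb)
  for (i in which(!rg$alone)) {
    ## brute-force scan over the pair list for this candidate
    sel <- pairs$chrom == rg$chrom[i] & pairs$r2 >= 0.7 &
      (pairs$pos_a == rg$pos[i] | pairs$pos_b == rg$pos[i])
    linked <- c(ifelse(pairs$pos_a[sel] == rg$pos[i],
                       pairs$pos_b[sel], pairs$pos_a[sel]), rg$pos[i])
    expect_equal(rg$start[i], min(linked))
    expect_equal(rg$end[i], max(linked))
    expect_true(all(c(rg$start[i], rg$end[i]) %in%
                      gm$variants$pos[gm$variants$chrom == rg$chrom[i]]))
  }
})

test_that("genome_coverage reproduces hand-computed merged-interval fractions", {
  mk <- function(pos) data.frame(chrom = "1", pos = pos)
  s <- structure(list(threshold = 0.7, average_distance = 100, n_pairs = 2L),
                 class = "ld_summary")
  lens <- c("1" = 1000)
  ## disjoint intervals [150,350] and [650,850]: 2 x 201 bp inclusive
  expect_equal(genome_coverage(mk(c(250, 750)), s, lens), 402 / 1000)
  ## overlapping intervals [300,500] and [400,600] merge to [300,600]
  expect_equal(genome_coverage(mk(c(400, 500)), s, lens), 301 / 1000)
  ## radius at least the chromosome length -> full coverage
  s2 <- structure(list(threshold = 0.7, average_distance = 1000, n_pairs = 1L),
                  class = "ld_summary")
  expect_equal(genome_coverage(mk(c(400, 500)), s2, lens), 1.0)
  ## missing chromosome length -> error naming the chromosome
  expect_error(genome_coverage(mk(100), s, c("2" = 1000)), "'1'")
})

test_that("genome_coverage is bounded and non-decreasing in the average distance", {
  set.seed(99)
  v <- data.frame(chrom = sample(c("1", "2"), 40, replace = TRUE),
                  pos = sample.int(1e5, 40))
  lens <- c("1" = 1e5, "2" = 1e5)
  covs <- vapply(c(10, 100, 1000, 1e4, 1e5), function(d) {
    s <- structure(list(threshold = 0.7, average_distance = d, n_pairs = 1L),
                   class = "ld_summary")
    genome_coverage(v, s, lens)
  }, 0)
  expect_true(all(covs >= 0 & covs <= 1))
  expect_true(all(diff(covs) >= 0))
})

test_that("hard LD blocks are recovered exactly as candidate regions", {
  sim <- simulate_genotypes(sim_config(seed = 123, missing_rate = 0))
  gm <- sim$genotypes
  pairs <- pairwise_ld(gm, ld_params())
  hard <- sim$blocks[sim$blocks$kind == "hard", ]
  for (thr in c(0.4, 0.7, 0.9, 1.0)) {
    fb <- average_linked_distance(pairs, thr)
    for (i in seq_len(nrow(hard))) {
      b <- hard[i, ]
      pos_ch <- gm$variants$pos[gm$variants$chrom == b$chrom]
      for (idx in c(b$from, (b$from + b$to) %/% 2, b$to)) {
        cand <- data.frame(chrom = b$chrom, pos = pos_ch[idx], sid = "c",
                           stringsAsFactors = FALSE)
        rg <- build_regions(cand, pairs, thr, fallback = fb)
        expect_equal(rg$start, b$start_bp)
        expect_equal(rg$end, b$end_bp)
        expect_false(rg$alone)
      }
    }
  }
})

test_that("regions export to BED with 0-based half-open coordinates", {
  rg <- rbind(region_row("1", "a", 150, 100, 200),
              region_row("2", "b", 70, 50, 90, alone = TRUE, n_linked = 0L))
  f <- tempfile(fileext = ".bed")
  write_regions_bed(rg, f)
  lines <- readLines(f)
  expect_equal(lines[1], "1\t99\t200\ta")
  expect_equal(lines[2], "2\t49\t90\tb_alone")
})
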