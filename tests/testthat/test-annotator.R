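test_that("closed-interval overlap includes 1-bp contact but not adjacency", {
  rg <- region_row("1", "c", 1000, 400, 1500)
  expect_equal(nrow(overlapping_features(rg, features_df("1", 1400, 1600))), 1L)
  expect_equal(nrow(overlapping_features(rg, features_df("1", 1501, 1600))), 0L)
  expect_equal(nrow(overlapping_features(rg, features_df("1", 1500, 1600))), 1L)
  expect_equal(nrow(overlapping_features(rg, features_df("1", 300, 400))), 1L)
  expect_equal(nrow(overlapping_features(rg, features_df("1", 300, 399))), 0L)
  expect_equal(nrow(overlapping_features(rg, features_df("2", 400, 1500))), 0L)
})

test_that("overlapping features are returned sorted by start position", {
  rg <- region_row("1", "c", 500, 1, 1000)
  feats <- features_df("1", start = c(800, 100, 400), end = c(900, 200, 600))
  of <- overlapping_features(rg, feats)
  expect_equal(of$start, c(100, 400, 800))
})

test_that("many-to-many candidate/feature relations produce one row per pair", {
  feats <- features_df("1", start = c(100, 900), end = c(600, 1400),
                       attributes = c("ID=gA", "ID=gB"))
  regions <- rbind(
    region_row("1", "c1", 500, 200, 1000),   # overlaps both genes
    region_row("1", "c2", 550, 500, 650))    # overlaps gA only
  hits <- annotate_all(regions, feats)
  expect_equal(nrow(hits), 3L)
  expect_equal(sum(hits$attributes == "ID=gA"), 2L)  # one gene, two candidates
  expect_equal(sum(hits$snp_id == "c1"), 2L)         # one candidate, two genes
  expect_equal(attr(hits, "n_candidates_hit"), 2L)
  expect_equal(attr(hits, "n_candidates_no_hit"), 0L)
})

test_that("annotate_all equals the brute-force double loop on random fixtures", {
  set.seed(321)
  for (i in 1:20) {
    n_r <- sample(10:40, 1)
    n_f <- sample(20:80, 1)
    starts <- sample.int(10000, n_r)
    regions <- do.call(rbind, lapply(seq_len(n_r), function(k) {
      e <- starts[k] + sample.int(500, 1)
      region_row(sample(c("1", "2", "3"), 1), paste0("c", k), starts[k],
                 starts[k], e, alone = runif(1) < 0.2,
                 n_linked = sample(0:3, 1))
    }))
    regions$alone <- regions$n_linked == 0
    fs <- sample.int(10000, n_f)
    feats <- features_df(sample(c("1", "2", "3"), n_f, replace = TRUE),
                         start = fs, end = fs + sample.int(400, n_f),
                         attributes = paste0("ID=f", seq_len(n_f)))
    got <- annotate_all(regions, feats)
    want <- oracle_overlap(regions, feats)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
  }
})

test_that("candidate counts are conserved between hits and no-hit summary", {
  set.seed(654)
  regions <- do.call(rbind, lapply(1:30, function(k) {
    s <- sample.int(5000, 1)
    region_row("1", paste0("c", k), s, s, s + sample.int(200, 1))
  }))
  fs <- sample.int(5000, 15)
  feats <- features_df("1", start = fs, end = fs + 100)
  hits <- annotate_all(regions, feats)
  expect_equal(attr(hits, "n_candidates_hit") + attr(hits, "n_candidates_no_hit"),
               nrow(regions))
  per <- table(hits$snp_id)
  expect_equal(sum(per), nrow(hits))
  expect_equal(length(per), attr(hits, "n_candidates_hit"))
})

test_that("lowering the user threshold never removes a hit pair", {
  sim <- simulate_genotypes(sim_config(seed = 555))
  gm <- sim$genotypes
  pairs <- pairwise_ld(gm, ld_params())
  ## candidates restricted to block variants so none goes alone at 0.9
  blocks <- sim$blocks
  cands <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    idx <- (b$from + b$to) %/% 2
    pos <- gm$variants$pos[gm$variants$chrom == b$chrom][idx]
    data.frame(chrom = b$chrom, pos = pos, sid = paste0("c", i),
               stringsAsFactors = FALSE)
  }))
  fs <- seq(1e4, 9.9e5, by = 3e4)
  feats <- features_df(rep(c("1", "2"), each = length(fs)),
                       start = rep(fs, 2), end = rep(fs + 8000, 2),
                       attributes = paste0("ID=f", seq_len(2 * length(fs))))
  key <- NULL
  for (thr in c(0.9, 0.7, 0.5)) {
    fb <- average_linked_distance(pairs, thr)
    rg <- build_regions(cands, pairs, thr, fallback = fb)
    expect_false(any(rg$alone))
    hits <- annotate_all(rg, feats)
    k <- paste(hits$snp_id, hits$feature_start, hits$feature_end)
    if (!is.null(key)) expect_true(all(key %in% k))
    key <- k
  }
})

test_that("the ID attribute can be extracted into its own column", {
  feats <- features_df("1", 100, 200, attributes = "ID=geneX;Name=GX")
  hits <- annotate_all(region_row("1", "c", 150, 100, 200), feats,
                       id_column = TRUE)
  expect_equal(hits$feature_id, "geneX")
  expect_equal(hits$attributes, "ID=geneX;Name=GX")  # verbatim pass-through
})
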