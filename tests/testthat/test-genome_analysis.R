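make_contig_genome <- function(gaps, strands) {
  nt <- strrep("ATGGCA", 10)   # 60 bp
  pos <- 0L
  rows <- list()
  for (i in seq_along(strands)) {
    if (i > 1) pos <- pos + gaps[i - 1]
    rows[[i]] <- data.frame(gene_id = sprintf("t%02d", i), contig_id = "c1",
                            start = pos, end = pos + 60L, strand = strands[i])
    pos <- pos + 60L
  }
  genes <- do.call(rbind, rows)
  seq <- strrep("A", pos + 20L)
  for (i in seq_along(strands)) {
    substr(seq, genes$start[i] + 1, genes$end[i]) <- nt
  }
  new_genome("toy", c(c1 = seq), genes)
}

test_that("TU boundaries follow the 30-bp inclusive gap and strand rules", {
  g <- make_contig_genome(gaps = c(20L, 31L), strands = c(1L, 1L, 1L))
  tus <- call_tus(g)
  expect_equal(tus$n_genes, c(2L, 1L))
  expect_equal(tus$genes[[1]], c("t01", "t02"))
  # gap of exactly 30 stays in one TU ("30 bp or less")
  g30 <- make_contig_genome(gaps = c(30L), strands = c(1L, 1L))
  expect_equal(call_tus(g30)$n_genes, 2L)
  # abutting genes on opposite strands split
  gflip <- make_contig_genome(gaps = c(0L), strands = c(1L, -1L))
  expect_equal(call_tus(gflip)$n_genes, c(1L, 1L))
})

test_that("TU calling matches the enumerate-runs oracle on random contigs", {
  for (seed in 1:100) {
    g <- random_contig_genome(seed)
    tus <- call_tus(g)
    expect_identical(unclass(unname(tus$genes)), tu_oracle(g$genes))
    # every gene in exactly one TU, order preserved
    expect_identical(unlist(tus$genes), g$genes$gene_id)
  }
})

test_that("TU log-odds is the maximum over member genes", {
  g <- make_contig_genome(gaps = c(10L, 10L), strands = c(1L, 1L, 1L))
  preds <- data.frame(gene_id = c("t01", "t02", "t03"),
                      log_odds = c(-1, 5.5, 2))
  tus <- call_tus(g, predictions = preds)
  expect_equal(tus$tu_log_odds, 5.5)
})

test_that("context flags apply the island window and interval overlaps", {
  # defense gene at rank 10: rank 20 is inside the +/-10 window, 21 is not
  strands <- rep(1L, 22)
  g <- make_contig_genome(gaps = rep(200L, 21), strands = strands)
  def_id <- "t11"   # rank 10
  ctx <- annotate_context(list(g), def_id, boot_reps = 5, seed = 1)
  fl <- ctx$flags
  expect_true(fl$in_island[fl$gene_id == "t21"])    # rank 20
  expect_false(fl$in_island[fl$gene_id == "t22"])   # rank 21
  # the defense gene itself needs another defense gene nearby
  expect_false(fl$in_island[fl$gene_id == def_id])
  # >= 1 bp interval overlap flags prophage membership
  iv <- data.frame(genome_id = "toy", contig_id = "c1",
                   start = g$genes$end[1] - 1L, end = g$genes$end[1] + 50L,
                   type = "prophage")
  ctx2 <- annotate_context(list(g), def_id, intervals = iv, boot_reps = 5, seed = 1)
  expect_true(ctx2$flags$in_prophage[1])
  expect_false(any(ctx2$flags$in_prophage[-1]))
  expect_error(annotate_context(list(g), def_id,
                                intervals = transform(iv, contig_id = "nope"),
                                boot_reps = 5, seed = 1),
               class = "shieldscan_validation_error")
  # bootstrap CIs are seeded
  ctx3 <- annotate_context(list(g), def_id, intervals = iv, boot_reps = 5, seed = 1)
  expect_identical(ctx2$frequencies, ctx3$frequencies)
})

test_that("accumulation curves are monotone and exact at the extremes", {
  co <- tiny_cohort()
  gt <- data.frame(gene_id = co$gene_meta$gene_id, genome_id = co$gene_meta$genome_id)
  cat_map <- stats::setNames(co$gene_meta$label, co$gene_meta$gene_id)
  for (seed in 1:5) {
    ac <- accumulation_curve(gt, co$cluster_map, cat_map, step = 1, reps = 4,
                             seed = seed)
    for (ct in unique(ac$category)) {
      expect_true(all(diff(ac$mean_clusters[ac$category == ct]) >= 0))
    }
  }
  # at n = all genomes the mean equals the exact unique count
  ac <- accumulation_curve(gt, co$cluster_map, cat_map, step = 1, reps = 3, seed = 1)
  full <- ac[ac$n_genomes == length(unique(gt$genome_id)), ]
  gt2 <- gt; gt2$cl <- co$cluster_map[gt2$gene_id]; gt2$ct <- cat_map[gt2$gene_id]
  for (i in seq_len(nrow(full))) {
    expect_equal(full$mean_clusters[i],
                 length(unique(gt2$cl[gt2$ct == full$category[i]])))
  }
  # identical cluster content in both genomes -> flat curve
  gt3 <- data.frame(gene_id = c("a", "b"), genome_id = c("g1", "g2"))
  cm3 <- c(a = "c1", b = "c1"); cat3 <- c(a = "x", b = "x")
  ac3 <- accumulation_curve(gt3, cm3, cat3, step = 1, reps = 2, seed = 1)
  expect_true(all(ac3$mean_clusters == 1))
})

test_that("occupancy counts drive accessory and core flags", {
  gt <- data.frame(gene_id = sprintf("q%02d", 1:12),
                   genome_id = rep(sprintf("G%d", 1:6), each = 2))
  cm <- stats::setNames(c("one", rep("all", 6), rep("six", 5)), gt$gene_id)
  # cluster "one": genome G1 only; "all": genomes G1..G4 (rows 2..7);
  # recompute explicitly instead
  cm <- stats::setNames(rep("", 12), gt$gene_id)
  cm[1] <- "solo"
  cm[c(2, 4, 6, 8, 10, 12)] <- "everywhere"
  cm[c(3, 5, 7, 9, 11)] <- "most"
  occ <- occupancy_histogram(gt, cm)
  expect_equal(occ$n_genomes[occ$cluster_id == "solo"], 1L)
  expect_true(occ$accessory[occ$cluster_id == "solo"])
  expect_true(occ$core[occ$cluster_id == "everywhere"])
  expect_false(occ$core[occ$cluster_id == "most"])      # 5 of 6 genomes
  expect_true(occ$accessory[occ$cluster_id == "most"])  # <= 5 genomes
})

test_that("validation-rate curve uses inclusive windows and seeded bootstraps", {
  vr <- validation_rate_curve(c(0, 1, 5), c(FALSE, TRUE, TRUE),
                              boot_reps = 100, seed = 2)
  expect_equal(vr$curve$rate, c(0.5, 0.5, 1))   # window +/-2 captures {0,1}, {0,1}, {5}
  expect_gt(vr$pearson_r, 0.9)
  vr2 <- validation_rate_curve(c(0, 1, 5), c(FALSE, TRUE, TRUE),
                               boot_reps = 100, seed = 2)
  expect_identical(vr, vr2)
  expect_warning(vrc <- validation_rate_curve(c(0, 5), c(TRUE, TRUE),
                                              boot_reps = 10, seed = 1),
                 "constant")
  expect_true(is.na(vrc$pearson_r))
  expect_true(all(vrc$curve$rate == 1))
  expect_error(validation_rate_curve(1, TRUE), class = "shieldscan_validation_error")
})
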