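test_that("deduplication keeps the top-scoring entry per group deterministically", {
  sc <- data.frame(id = c("a", "b", "c", "d"),
                   score = c(0.9, 0.2, 0.7, 0.7),
                   label = c(1, 0, 1, 0),
                   dedup_group = c("g", "g", "h", "h"))
  dd <- dedup_top_per_group(sc)
  expect_equal(dd$id[dd$dedup_group == "g"], "a")
  expect_equal(dd$id[dd$dedup_group == "h"], "c")   # tie -> smallest id
  # singleton (empty) groups pass through
  sc$dedup_group <- ""
  expect_equal(nrow(dedup_top_per_group(sc)), 4L)
  # dedup never increases positives and keeps the retained entry's label
  withr::with_seed(11, for (i in 1:20) {
    n <- sample(5:40, 1)
    sc <- data.frame(id = sprintf("e%02d", 1:n), score = runif(n),
                     label = rbinom(n, 1, 0.3),
                     dedup_group = sample(letters[1:5], n, replace = TRUE))
    dd <- dedup_top_per_group(sc)
    expect_lte(sum(dd$label), sum(sc$label))
    m <- merge(dd, sc, by = "id")
    expect_equal(m$label.x, m$label.y)
  })
})

test_that("AP and AUROC match brute-force oracles on random rankings", {
  # the spec-style worked example: labels [1,0,1,0] in score order
  ev <- pr_curve_and_ap(data.frame(id = letters[1:4], score = c(4, 3, 2, 1),
                                   label = c(1, 0, 1, 0)))
  expect_equal(ev$AP, (1 + 2 / 3) / 2)
  # perfect and inverted rankings
  perfect <- data.frame(id = letters[1:6], score = 6:1, label = c(1, 1, 1, 0, 0, 0))
  evp <- pr_curve_and_ap(perfect)
  expect_equal(evp$AP, 1); expect_equal(evp$AUROC, 1)
  inverted <- perfect; inverted$label <- rev(perfect$label)
  expect_equal(pr_curve_and_ap(inverted)$AUROC, 0)
  expect_error(pr_curve_and_ap(data.frame(id = "a", score = 1, label = 1)),
               class = "shieldscan_validation_error")
  # 200 random rankings with distinct scores
  withr::with_seed(2024, for (i in 1:200) {
    n <- sample(5:50, 1)
    score <- sample(seq_len(1000), n)
    label <- rbinom(n, 1, 0.4)
    if (sum(label) == 0 || sum(label) == n) next
    d <- data.frame(id = sprintf("x%02d", 1:n), score = score, label = label)
    ev <- pr_curve_and_ap(d)
    expect_equal(ev$AP, ap_oracle(score, label), tolerance = 1e-12)
    expect_equal(ev$AUROC, auroc_oracle(score, label), tolerance = 1e-12)
  })
  # tied scores: AUROC still matches the half-credit pair count
  d <- data.frame(id = letters[1:5], score = c(2, 2, 2, 1, 1), label = c(1, 0, 1, 0, 1))
  expect_equal(pr_curve_and_ap(d)$AUROC, auroc_oracle(d$score, d$label))
  expect_true(all(diff(pr_curve_and_ap(d)$recall) >= 0))
})

test_that("top-k precision follows the deterministic tie rules", {
  d <- data.frame(id = c("a", "b", "c"), score = c(3, 2, 1), label = c(1, 1, 0))
  expect_equal(top_k_precision(d, 2), 1)
  d2 <- data.frame(id = c("a", "b", "c"), score = c(3, 2, 1), label = c(1, 0, 0))
  expect_equal(top_k_precision(d2, 3), 1 / 3)
  expect_equal(top_k_precision(d2, 1), 1)
  expect_warning(p <- top_k_precision(d2, 10), "full list")
  expect_equal(p, 1 / 3)
  expect_error(top_k_precision(d2, 0), class = "shieldscan_validation_error")
})

test_that("cosine nearest-neighbour baseline signs scores by the neighbour label", {
  ref <- rbind(def = c(1, 0, 0), ctl = c(0, 1, 0))
  labs <- c(def = 1, ctl = 0)
  q <- rbind(q1 = c(1, 0, 0),      # identical to the defense reference
             q2 = c(0, 1, 0),      # identical to the control reference
             q3 = c(0, 0, 1))      # orthogonal to both
  s <- cosine_nn_baseline(q, ref, labs)
  expect_equal(unname(s["q1"]), 1)
  expect_equal(unname(s["q2"]), -1)
  expect_equal(abs(unname(s["q3"])), 0)
  # tie between defense and control neighbours prefers defense
  qt <- rbind(qt = c(1, 1, 0) / sqrt(2))
  st <- cosine_nn_baseline(qt, ref, labs)
  expect_gt(unname(st["qt"]), 0)
  expect_warning(sz <- cosine_nn_baseline(rbind(z = c(0, 0, 0)), ref, labs),
                 "zero-vector")
  expect_equal(unname(sz["z"]), 0)
})

test_that("signed best-hit baseline signs by the best hit's label", {
  hits <- data.frame(query = c("q1", "q1", "q2", "q3", "q3"),
                     target = c("d1", "c1", "c1", "d1", "c2"),
                     bit_score = c(100, 90, 80, 50, 50))
  labs <- c(d1 = 1, c1 = 0, c2 = 0)
  s <- signed_best_hit_baseline(hits, labs, query_ids = c("q1", "q2", "q3", "q4"))
  expect_equal(unname(s["q1"]), 100)
  expect_equal(unname(s["q2"]), -80)
  expect_equal(unname(s["q3"]), 50)    # bit tie -> defense target first
  expect_equal(unname(s["q4"]), 0)     # no hit
})

test_that("Fisher enrichment p equals the hypergeometric tail", {
  expect_equal(shieldscan:::fisher_p_greater(8, 2, 2, 8), 2126 / 184756,
               tolerance = 1e-12)
  expect_equal(shieldscan:::fisher_p_greater(0, 10, 10, 0), 1)
  # exhaustive check for all tables with row margins <= 12
  for (r1 in 0:12) for (r2 in 0:12) {
    if (r1 + r2 == 0) next
    for (a in 0:r1) for (c in 0:r2) {
      expect_equal(shieldscan:::fisher_p_greater(a, r1 - a, c, r2 - c),
                   fisher_oracle(a, r1 - a, c, r2 - c), tolerance = 1e-9)
    }
  }
  # sampled larger tables with margins <= 30
  withr::with_seed(8, for (i in 1:300) {
    r1 <- sample(1:30, 1); r2 <- sample(1:30, 1)
    a <- sample(0:r1, 1); c <- sample(0:r2, 1)
    expect_equal(shieldscan:::fisher_p_greater(a, r1 - a, c, r2 - c),
                 fisher_oracle(a, r1 - a, c, r2 - c), tolerance = 1e-9)
  })
})

test_that("guilt-by-association applies the window and exclusion rules", {
  co <- tiny_cohort()
  gba <- guilt_by_association(co$genomes, co$cluster_map, co$labels, window = 10)
  expect_true(all(gba$p_value > 0 & gba$p_value <= 1))
  expect_true(!is.unsorted(gba$p_value))
  # cluster sizes are conserved: a + b equals the cluster size
  sizes <- table(co$cluster_map)
  expect_equal(gba$a + gba$b, as.integer(sizes[gba$cluster_id]))
  expect_error(guilt_by_association(co$genomes, co$cluster_map, co$labels,
                                    window = 0),
               class = "shieldscan_validation_error")
  # same-system defensive neighbours are not counted: a two-gene system
  # whose members are each other's only defensive neighbour gives a = 0
  nt <- strrep("ATGGCA", 20)
  genes <- data.frame(gene_id = c("d1", "d2", "ctl"), contig_id = "c1",
                      start = c(0L, 150L, 5000L),
                      end = c(0L, 150L, 5000L) + nchar(nt), strand = 1L)
  seq <- strrep("A", 6000L)
  for (i in 1:3) substr(seq, genes$start[i] + 1, genes$end[i]) <- nt
  mini <- new_genome("mini", c(c1 = seq), genes)
  labs_mini <- data.frame(gene_id = c("d1", "d2", "ctl"),
                          label = c("defense", "defense", "control"),
                          system_id = c("sysZ", "sysZ", ""),
                          dedup_group = "")
  cl <- stats::setNames(c("cd", "cd", "cc"), c("d1", "d2", "ctl"))
  gba_mini <- guilt_by_association(list(mini), cl, labs_mini, window = 10)
  expect_equal(gba_mini$a[gba_mini$cluster_id == "cd"], 0)
  # without the exclusion the pair counts each other
  gba_raw <- guilt_by_association(list(mini), cl, labs_mini, window = 10,
                                  exclusions = character(0))
  expect_equal(gba_raw$a[gba_raw$cluster_id == "cd"], 2)
})

test_that("system summaries flag completeness and count cutoff exceedances", {
  preds <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                      probability = c(0.77, 0.993, 0.73, 0.26, 0.99))
  preds$log_odds <- log_odds(preds$probability)
  inst <- data.frame(instance_id = c("i1", "i1", "i2", "i2", "i3"),
                     system_id = c("s1", "s1", "s2", "s2", "s2"),
                     gene_id = c("a", "b", "c", "d", "e"))
  res <- prospective_system_summary(preds, inst)
  i1 <- res$instances[res$instances$instance_id == "i1", ]
  expect_true(i1$complete)                       # log-odds [1.2, 5.0] both > 0
  expect_equal(i1$max_log_odds, log_odds(0.993), tolerance = 1e-9)
  i2 <- res$instances[res$instances$instance_id == "i2", ]
  expect_false(i2$complete)                      # one gene below log-odds 0
  expect_equal(res$n_above_0.5, 2L)              # both systems top out above 0.5
  expect_equal(res$n_above_0.98, 2L)             # 0.993 and 0.99
  expect_equal(res$multi_gene_complete_fraction, 0.5)
  expect_error(prospective_system_summary(preds[1:2, ], inst),
               class = "shieldscan_lookup_error")
})
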