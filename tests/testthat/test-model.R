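test_that("log-odds is a strictly increasing odd bijection with clamping", {
  p <- seq(0.05, 0.95, by = 0.05)
  lo <- log_odds(p)
  expect_true(all(diff(lo) > 0))
  expect_equal(log_odds(1 - p), -lo)
  expect_equal(log_odds(0.5), 0)
  expect_equal(log_odds(0.98), log(49), tolerance = 1e-12)
  expect_equal(round(log_odds(0.98)), 4)      # the stringent reporting cutoff
  expect_true(all(is.finite(log_odds(c(0, 1)))))
})

test_that("fold models train only on their training folds and are reproducible", {
  ds <- tiny_dataset()
  m1 <- train_fold_model(ds, held_out_fold = 1, seed = 5)
  m2 <- train_fold_model(ds, held_out_fold = 1, seed = 5)
  probe <- ds$X[1:10, , drop = FALSE]
  expect_identical(shieldscan:::member_probabilities(m1, probe),
                   shieldscan:::member_probabilities(m2, probe))
  expect_error(train_fold_model(ds, held_out_fold = 99),
               class = "shieldscan_validation_error")
  # one-class training side is refused
  ds1 <- shieldscan:::subset_dataset(ds, ds$y == 1 | ds$fold == 2)
  expect_error(train_fold_model(ds1, held_out_fold = 2),
               class = "shieldscan_validation_error")
})

test_that("a planted GC shift is linearly separable and the model finds it", {
  co <- generate_cohort(synth_config(n_genomes = 1L, genes_per_genome = 120L,
                                     defense_gc_shift = -0.15, seed = 7L),
                        cluster = FALSE)
  be <- tiny_backend()
  ds <- build_labeled_dataset(co$genomes, co$labels, be, co$edges, k = 2, seed = 7)
  m <- train_fold_model(ds, held_out_fold = 1, seed = 7)
  tr <- ds$fold != 1
  probs <- shieldscan:::member_probabilities(m, ds$X[tr, , drop = FALSE])
  expect_gte(shieldscan:::auroc(probs, ds$y[tr]), 0.99)
  # depth-1 stump oracle on the center-gene GC slot: low GC marks defense
  gc_col <- attr(ds, "layout")$index[attr(ds, "layout")$name == "gc_rel_0"]
  stump_auc <- shieldscan:::auroc(-ds$X[tr, gc_col], ds$y[tr])
  expect_gte(stump_auc, 0.95)
})

test_that("hyperparameter search is seeded and monotone in budget", {
  ds <- tiny_dataset()
  trainside <- shieldscan:::subset_dataset(ds, ds$fold != 1)
  sp <- make_validation_split(trainside, fraction = 0.3, seed = 2)
  t1 <- tune_hyperparameters(sp$train, sp$validation, budget = 1, seed = 3)
  expect_equal(nrow(t1$trials), 1L)
  t1b <- tune_hyperparameters(sp$train, sp$validation, budget = 1, seed = 3)
  expect_identical(t1$trials, t1b$trials)
  t4 <- tune_hyperparameters(sp$train, sp$validation, budget = 4, seed = 3)
  expect_gte(t4$best_ap, t1$best_ap)          # max over a superset of trials
  expect_equal(t4$trials$ap[1], t1$trials$ap[1])
  tb <- tune_hyperparameters(sp$train, sp$validation, budget = 4, seed = 3,
                             strategy = "bayes")
  expect_equal(nrow(tb$trials), 4L)
  expect_error(tune_hyperparameters(sp$train, list(X = NULL), budget = 1),
               class = "shieldscan_validation_error")
})

test_that("the ensemble has one member per fold and honours scoring modes", {
  ds <- tiny_dataset()
  em <- tiny_ensemble()
  expect_length(em$members, 5L)
  held <- vapply(em$members, `[[`, numeric(1), "held_out_fold")
  expect_setequal(held, sort(unique(ds$fold)))
  # heldout mode requires fold tags and refuses unmatched rows
  expect_error(predict_genes(em, ds$X, mode = "heldout"),
               class = "shieldscan_validation_error")
  expect_error(predict_genes(em, ds$X, mode = "heldout",
                             folds = rep(99, nrow(ds$X))),
               class = "shieldscan_validation_error")
  pr <- predict_genes(em, ds$X, mode = "heldout", folds = ds$fold)
  expect_equal(nrow(pr), nrow(ds$X))
  expect_true(all(is.finite(pr$log_odds)))
  # ensemble mode averages member probabilities
  pe <- predict_genes(em, ds$X[1:5, , drop = FALSE], mode = "ensemble")
  manual <- rowMeans(vapply(em$members, function(m) {
    shieldscan:::member_probabilities(m, ds$X[1:5, , drop = FALSE])
  }, numeric(5)))
  expect_equal(pe$probability, unname(manual))
  expect_error(predict_genes(em, ds$X[, 1:10]), class = "shieldscan_validation_error")
  # a two-fold run completes and scores (singleton components so both
  # folds carry positives)
  co <- tiny_cohort()
  no_edges <- co$edges[0, , drop = FALSE]
  ds2 <- build_labeled_dataset(co$genomes, co$labels, tiny_backend(), no_edges,
                               k = 2, seed = 9)
  em2 <- train_ensemble(ds2, k = 2, seed = 9)
  expect_length(em2$members, 2L)
  p2 <- predict_genes(em2, ds2$X, mode = "heldout", folds = ds2$fold)
  expect_equal(nrow(p2), nrow(ds2$X))
})

test_that("attribution aggregation is additive over layout blocks", {
  lay <- feature_layout(8L)
  n_feat <- nrow(lay)
  # all-ones attributions: center embedding category sums to dim per gene
  A <- matrix(1, nrow = 3, ncol = n_feat)
  agg <- aggregate_attributions(A, lay, groups = "category_position")
  center_emb <- agg$mean_attribution[agg$category == "embedding" & agg$position == "0"]
  expect_equal(center_emb, 8)
  expect_equal(sum(agg$mean_attribution), n_feat)     # additivity passthrough
  expect_true(all(aggregate_attributions(matrix(0, 2, n_feat), lay)$mean_attribution == 0))
  # random attributions: group sums reproduce row totals
  A2 <- withr::with_seed(3, matrix(rnorm(2 * n_feat), 2))
  agg2 <- aggregate_attributions(A2, lay, groups = "neighbor_gene")
  expect_equal(sum(agg2$mean_attribution), mean(rowSums(A2)))
  expect_error(aggregate_attributions(A2[, 1:5], lay),
               class = "shieldscan_validation_error")
})

test_that("tree attributions from a trained member sum to informative totals", {
  ds <- tiny_dataset()
  em <- tiny_ensemble()
  X <- ds$X[1:8, , drop = FALSE]
  A <- compute_attributions(em$members[[1]], X)
  expect_equal(dim(A), c(8L, ncol(ds$X)))
  agg <- aggregate_attributions(A, attr(ds, "layout"))
  expect_equal(sum(agg$mean_attribution), mean(rowSums(A)))
})
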