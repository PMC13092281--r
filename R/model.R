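# Gradient-boosting ensemble: one classifier per held-out fold, random
# or sequential hyperparameter search on homology-respecting validation
# splits, probability/log-odds scoring, and additive feature-attribution
# aggregation.

#' Default gradient-boosting parameters
#' @return named list of xgboost parameters plus `nrounds`.
#' @export
default_gb_params <- function() {
  list(eta = 0.1, max_depth = 5L, nrounds = 150L, subsample = 0.9,
       colsample_bytree = 0.8, lambda = 1, min_child_weight = 1L)
}

#' Hyperparameter search space
#'
#' Documented bounds used by [tune_hyperparameters()]: learning rate
#' (log-uniform 0.01-0.3), tree depth (3-8), boosting rounds (50-300),
#' row subsample (0.6-1), column subsample (0.5-1), L2 regularization
#' (log-uniform 0.01-10) and minimum child weight (1-10).
#'
#' @return list of `(low, high, type)` descriptors per parameter.
#' @export
gb_search_space <- function() {
  list(eta = list(low = 0.01, high = 0.3, type = "log"),
       max_depth = list(low = 3, high = 8, type = "int"),
       nrounds = list(low = 50, high = 300, type = "int"),
       subsample = list(low = 0.6, high = 1, type = "num"),
       colsample_bytree = list(low = 0.5, high = 1, type = "num"),
       lambda = list(low = 0.01, high = 10, type = "log"),
       min_child_weight = list(low = 1, high = 10, type = "int"))
}

sample_gb_params <- function(space = gb_search_space()) {
  out <- lapply(space, function(s) {
    switch(s$type,
           log = exp(stats::runif(1, log(s$low), log(s$high))),
           int = sample(seq.int(s$low, s$high), 1L),
           num = stats::runif(1, s$low, s$high))
  })
  out
}

# perturb one parameter of `base` within the space (sequential search)
perturb_gb_params <- function(base, space = gb_search_space()) {
  nm <- sample(names(space), 1L)
  s <- space[[nm]]
  v <- base[[nm]]
  base[[nm]] <- switch(s$type,
    log = exp(pmin(pmax(log(v) + stats::rnorm(1, 0, 0.3), log(s$low)), log(s$high))),
    int = max(s$low, min(s$high, v + sample(c(-2L, -1L, 1L, 2L), 1L))),
    num = pmin(pmax(v + stats::rnorm(1, 0, 0.1), s$low), s$high))
  base
}

#' Train one gradient-boosting member on the non-held-out folds
#'
#' Fits an xgboost binary classifier on all rows whose fold differs from
#' `held_out_fold`. Training is single-threaded and fully seeded, so a
#' refit with the same seed reproduces identical predictions.
#'
#' @param ds a `shieldscan_dataset`.
#' @param held_out_fold fold id held out as the test set.
#' @param params parameter list ([default_gb_params()] layout).
#' @param seed integer seed.
#' @return object of class `shieldscan_member` wrapping the booster.
#' @export
train_fold_model <- function(ds, held_out_fold, params = default_gb_params(),
                             seed = 1L) {
  if (!held_out_fold %in% ds$fold) stop_validation("fold label absent: ", held_out_fold)
  train_ix <- ds$fold != held_out_fold
  y <- ds$y[train_ix]
  if (length(unique(y)) < 2L) stop_validation("training side has one class only")
  booster <- fit_booster(ds$X[train_ix, , drop = FALSE], y, params, seed)
  structure(list(booster = booster, held_out_fold = held_out_fold,
                 params = params, seed = as.integer(seed),
                 n_features = ncol(ds$X)),
            class = "shieldscan_member")
}

fit_booster <- function(X, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgb_params <- list(objective = "binary:logistic", eval_metric = "logloss",
                     eta = params$eta, max_depth = as.integer(params$max_depth),
                     subsample = params$subsample,
                     colsample_bytree = params$colsample_bytree,
                     lambda = params$lambda,
                     min_child_weight = params$min_child_weight,
                     nthread = 1L, seed = as.integer(seed))
  with_seed(seed,
            xgboost::xgb.train(params = xgb_params, data = dtrain,
                               nrounds = as.integer(params$nrounds), verbose = 0))
}

member_probabilities <- function(member, X) {
  if (ncol(X) != member$n_features) stop_validation("feature length mismatch")
  as.numeric(stats::predict(member$booster, xgboost::xgb.DMatrix(X)))
}

#' Tune gradient-boosting hyperparameters on a validation split
#'
#' Maximizes average precision on the validation set over
#' [gb_search_space()]. `strategy = "random"` (the dependency-free
#' default) draws `budget` independent configurations;
#' `strategy = "bayes"` is a seeded sequential search that spends a
#' third of the budget exploring at random and the rest perturbing the
#' best configuration so far (a model-free exploit/explore loop, not a
#' Gaussian-process optimizer). Identical seeds give identical trial
#' sequences.
#'
#' @param train,validation `shieldscan_dataset`s (validation non-empty).
#' @param budget number of trials (>= 1).
#' @param seed integer seed.
#' @param strategy `"random"` or `"bayes"`.
#' @return list with `best_params`, `best_ap` and `trials` data.frame.
#' @export
tune_hyperparameters <- function(train, validation, budget = 10L, seed = 1L,
                                 strategy = c("random", "bayes")) {
  strategy <- match.arg(strategy)
  if (budget < 1L) stop_validation("budget must be >= 1")
  if (is.null(validation$X) || !nrow(validation$X)) stop_validation("empty validation set")
  space <- gb_search_space()
  trials <- vector("list", budget)
  best <- NULL; best_ap <- -Inf
  with_seed(child_seed(seed, "tuning"), {
    n_explore <- if (strategy == "bayes") max(2L, ceiling(budget / 3)) else budget
    for (t in seq_len(budget)) {
      p <- if (t <= n_explore || is.null(best)) sample_gb_params(space)
           else perturb_gb_params(best, space)
      member_seed <- child_seed(seed, paste0("trial", t))
      booster <- fit_booster(train$X, train$y, p, member_seed)
      probs <- as.numeric(stats::predict(booster, xgboost::xgb.DMatrix(validation$X)))
      ap <- average_precision(probs, validation$y)
      trials[[t]] <- data.frame(trial = t, ap = ap,
                                as.data.frame(p, stringsAsFactors = FALSE))
      if (ap > best_ap) { best_ap <- ap; best <- p }
    }
  })
  list(best_params = best, best_ap = best_ap, trials = do.call(rbind, trials))
}

#' Train the k-member cross-validated ensemble
#'
#' One gradient-boosting member per held-out fold. With `budget > 0`,
#' each member's hyperparameters are tuned on a homology-respecting
#' validation split carved out of its training folds; with `budget = 0`
#' the provided (or default) parameters are used directly.
#'
#' @param ds a `shieldscan_dataset` with `k` folds.
#' @param k number of folds/members (default 5).
#' @param budget tuning trials per member (0 = no tuning).
#' @param seed integer seed.
#' @param params parameter list used when `budget = 0`.
#' @param tune_fraction validation fraction per class for tuning splits.
#' @param strategy tuning strategy, see [tune_hyperparameters()].
#' @return object of class `shieldscan_ensemble`: `members` (one per
#'   fold), `dim`-agnostic `feature_names`, and `metadata` recording
#'   every seed and parameter set.
#' @export
train_ensemble <- function(ds, k = 5L, budget = 0L, seed = 1L,
                           params = default_gb_params(), tune_fraction = 0.1,
                           strategy = "random") {
  folds <- sort(unique(ds$fold))
  if (length(folds) != k) {
    stop_validation("dataset has ", length(folds), " folds, expected ", k)
  }
  members <- vector("list", k)
  meta_params <- vector("list", k)
  for (i in seq_along(folds)) {
    f <- folds[i]
    fold_seed <- child_seed(seed, paste0("fold", f))
    use_params <- params
    if (budget > 0L) {
      trainside <- subset_dataset(ds, ds$fold != f)
      split <- make_validation_split(trainside, fraction = tune_fraction,
                                     seed = fold_seed)
      tuned <- tune_hyperparameters(split$train, split$validation,
                                    budget = budget, seed = fold_seed,
                                    strategy = strategy)
      use_params <- tuned$best_params
    }
    members[[i]] <- train_fold_model(ds, f, params = use_params, seed = fold_seed)
    meta_params[[i]] <- use_params
  }
  structure(list(
    members = members,
    feature_names = colnames(ds$X),
    metadata = list(k = k, seed = as.integer(seed), budget = as.integer(budget),
                    folds = folds, params = meta_params,
                    trained = format(Sys.time(), "%Y-%m-%d"))
  ), class = "shieldscan_ensemble")
}

#' @export
print.shieldscan_ensemble <- function(x, ...) {
  cat(sprintf("<shieldscan_ensemble> %d members, %d features\n",
              length(x$members), length(x$feature_names)))
  invisible(x)
}

#' Score genes with the ensemble
#'
#' `mode = "heldout"` implements the evaluation protocol: each row is
#' scored by the single member whose held-out fold matches the row's
#' fold tag, so no row is ever scored by a model that saw it in
#' training (rows without a matching member raise an error).
#' `mode = "ensemble"` is new-genome inference: the probability is the
#' arithmetic mean of all members' probabilities. Log-odds are derived
#' from the (mean) probability with clamping.
#'
#' @param model a `shieldscan_ensemble`.
#' @param X feature matrix (rownames = gene ids).
#' @param mode `"heldout"` or `"ensemble"`.
#' @param folds fold tag per row (required for `"heldout"`).
#' @return data.frame `gene_id`, `probability`, `log_odds`.
#' @export
predict_genes <- function(model, X, mode = c("ensemble", "heldout"),
                          folds = NULL) {
  mode <- match.arg(mode)
  if (ncol(X) != length(model$feature_names)) {
    stop_validation("feature length mismatch: ", ncol(X), " vs ",
                    length(model$feature_names))
  }
  if (mode == "heldout") {
    if (is.null(folds) || length(folds) != nrow(X)) {
      stop_validation("heldout mode requires one fold tag per row")
    }
    held <- vapply(model$members, `[[`, numeric(1), "held_out_fold")
    if (any(!folds %in% held)) {
      stop_validation("row fold without a matching held-out member; ",
                      "refusing to score training rows")
    }
    p <- numeric(nrow(X))
    for (m in model$members) {
      ix <- folds == m$held_out_fold
      if (any(ix)) p[ix] <- member_probabilities(m, X[ix, , drop = FALSE])
    }
  } else {
    probs <- vapply(model$members, function(m) member_probabilities(m, X),
                    numeric(nrow(X)))
    p <- if (is.matrix(probs)) rowMeans(probs) else mean(probs)
  }
  data.frame(gene_id = rownames(X) %||% as.character(seq_len(nrow(X))),
             probability = p, log_odds = log_odds(p),
             stringsAsFactors = FALSE)
}

#' Per-feature attributions of one member (additive tree attribution)
#'
#' Thin wrapper over xgboost's `predcontrib` (tree SHAP) output; the
#' bias column is dropped so columns align with the feature layout.
#'
#' @param member a `shieldscan_member`.
#' @param X feature matrix.
#' @return N x F attribution matrix.
#' @export
compute_attributions <- function(member, X) {
  contrib <- stats::predict(member$booster, xgboost::xgb.DMatrix(X),
                            predcontrib = TRUE)
  # last column is the bias/intercept term, whatever its label
  contrib[, -ncol(contrib), drop = FALSE]
}

#' Aggregate attributions by feature category and window position
#'
#' For `groups = "category_position"`, attribution values are summed per
#' gene within each (feature category, window position) block of the
#' layout, then averaged over genes. For `groups = "neighbor_gene"`, all
#' blocks belonging to one window position are summed, giving the total
#' contribution of each neighbouring gene. Because the blocks partition
#' the columns, category sums per gene add up exactly to the per-gene
#' total attribution.
#'
#' @param attrib N x F attribution matrix.
#' @param layout layout registry from [feature_layout()].
#' @param groups aggregation mode.
#' @return data.frame of mean summed attributions per group.
#' @export
aggregate_attributions <- function(attrib, layout,
                                   groups = c("category_position", "neighbor_gene")) {
  groups <- match.arg(groups)
  if (ncol(attrib) != nrow(layout)) stop_validation("attribution/layout shape mismatch")
  pos_label <- ifelse(is.na(layout$position), "global", as.character(layout$position))
  key <- if (groups == "category_position") {
    paste(layout$category, pos_label, sep = "|")
  } else {
    pos_label
  }
  sums <- t(rowsum(t(attrib), group = key))  # per-gene sums within groups
  means <- colMeans(sums)
  if (groups == "category_position") {
    parts <- strsplit(names(means), "|", fixed = TRUE)
    data.frame(category = vapply(parts, `[[`, "", 1),
               position = vapply(parts, `[[`, "", 2),
               mean_attribution = as.numeric(means),
               stringsAsFactors = FALSE)
  } else {
    data.frame(position = names(means), mean_attribution = as.numeric(means),
               stringsAsFactors = FALSE)
  }
}
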