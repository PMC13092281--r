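# Discovery-mode evaluation: per-group deduplication, precision-recall
# and average precision, AUROC, top-k precision, and the three ranking
# baselines (embedding cosine nearest-neighbour, signed best-hit score,
# guilt-by-association Fisher enrichment).

#' Keep the single highest-scoring entry per dedup group
#'
#' Discovery-mode evaluation ranks one gene per defense HMM cluster and
#' per non-defense functional group. Entries with an empty/missing group
#' are treated as singletons. Score ties are broken by the
#' lexicographically smallest id (deterministic).
#'
#' @param scored data.frame with columns `id`, `score`, `label` and
#'   `dedup_group`.
#' @return deduplicated data.frame sorted by descending score (ties: id).
#' @export
dedup_top_per_group <- function(scored) {
  g <- scored$dedup_group
  g[is.na(g) | !nzchar(g)] <- scored$id[is.na(g) | !nzchar(g)]
  ord <- order(g, -scored$score, scored$id)
  s <- scored[ord, , drop = FALSE]
  keep <- !duplicated(g[ord])
  out <- s[keep, , drop = FALSE]
  out <- out[order(-out$score, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# step-wise average precision with tied scores grouped into one block
average_precision <- function(scores, labels) {
  ord <- order(-scores)
  scores <- scores[ord]; labels <- labels[ord]
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) {
    stop_validation("need at least one positive and one negative")
  }
  blocks <- cumsum(!duplicated(scores))          # tie blocks in rank order
  tp <- as.numeric(rowsum(as.numeric(labels == 1), blocks))
  n <- as.numeric(rowsum(rep(1, length(labels)), blocks))
  cum_tp <- cumsum(tp); cum_n <- cumsum(n)
  precision <- cum_tp / cum_n
  recall <- cum_tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

# rank-statistic AUROC (ties get half credit)
auroc <- function(scores, labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop_validation("need both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall curve, average precision and AUROC of a ranking
#'
#' Computes the step-wise precision/recall arrays over descending score
#' thresholds (tied scores share one block), the average precision
#' `AP = sum(dRecall x precision)`, and the rank-statistic AUROC.
#'
#' @param deduplicated data.frame with `id`, `score`, `label` (typically
#'   the output of [dedup_top_per_group()]).
#' @return list of class `shieldscan_ranking` with `entries`,
#'   `precision`, `recall`, `AP`, `AUROC`.
#' @export
pr_curve_and_ap <- function(deduplicated) {
  d <- deduplicated[order(-deduplicated$score, deduplicated$id), , drop = FALSE]
  n_pos <- sum(d$label == 1)
  if (n_pos == 0 || n_pos == nrow(d)) {
    stop_validation("need at least one positive and one negative")
  }
  blocks <- cumsum(!duplicated(d$score))
  tp <- as.numeric(rowsum(as.numeric(d$label == 1), blocks))
  n <- as.numeric(rowsum(rep(1, nrow(d)), blocks))
  cum_tp <- cumsum(tp); cum_n <- cumsum(n)
  precision <- cum_tp / cum_n
  recall <- cum_tp / n_pos
  structure(list(entries = d, precision = precision, recall = recall,
                 AP = sum(diff(c(0, recall)) * precision),
                 AUROC = auroc(d$score, d$label)),
            class = "shieldscan_ranking")
}

#' @export
print.shieldscan_ranking <- function(x, ...) {
  cat(sprintf("<shieldscan_ranking> n=%d, AP=%.4f, AUROC=%.4f\n",
              nrow(x$entries), x$AP, x$AUROC))
  invisible(x)
}

#' Precision among the k highest-scoring entries
#' @param deduplicated data.frame with `id`, `score`, `label`.
#' @param k number of top entries (>= 1); if larger than the list the
#'   full list is used with a warning.
#' @return fraction of positives among the top k.
#' @export
top_k_precision <- function(deduplicated, k) {
  if (k < 1L) stop_validation("k must be >= 1")
  d <- deduplicated[order(-deduplicated$score, deduplicated$id), , drop = FALSE]
  if (k > nrow(d)) {
    warning("k exceeds list length; using the full list", call. = FALSE)
    k <- nrow(d)
  }
  mean(d$label[seq_len(k)] == 1)
}

#' Cosine nearest-neighbour ranking baseline
#'
#' Ranks each held-out protein by the cosine similarity between its
#' embedding and that of its nearest neighbour in the reference set,
#' negated when the nearest neighbour is non-defensive. Nearest-
#' neighbour ties prefer a defense-labeled reference, then the smallest
#' id. All-zero query vectors score 0 with a warning.
#'
#' @param query_mat query embedding matrix (rownames = ids).
#' @param ref_mat reference embedding matrix (rownames = ids).
#' @param ref_labels named 0/1 vector over the reference ids (1 =
#'   defense); both classes must be present.
#' @return named numeric score vector over the queries.
#' @export
cosine_nn_baseline <- function(query_mat, ref_mat, ref_labels) {
  ref_labels <- ref_labels[rownames(ref_mat)]
  if (length(unique(ref_labels)) < 2L) stop_validation("reference needs both labels")
  qn <- sqrt(rowSums(query_mat^2)); rn <- sqrt(rowSums(ref_mat^2))
  zero_q <- qn == 0
  if (any(zero_q)) warning(sum(zero_q), " zero-vector query(ies) scored 0", call. = FALSE)
  qn[zero_q] <- 1; rn[rn == 0] <- 1
  sims <- (query_mat / qn) %*% t(ref_mat / rn)
  scores <- vapply(seq_len(nrow(sims)), function(i) {
    s <- sims[i, ]
    best <- max(s)
    cand <- which(s >= best - 1e-12)
    if (length(cand) > 1L) {
      defc <- cand[ref_labels[cand] == 1]
      cand <- if (length(defc)) defc else cand
      cand <- cand[order(rownames(ref_mat)[cand])][1]
    }
    if (ref_labels[cand[1]] == 1) best else -best
  }, numeric(1))
  scores[zero_q] <- 0
  stats::setNames(scores, rownames(query_mat))
}

#' Signed best-hit alignment-score baseline
#'
#' Score is the bit-score of a query's most significant hit, negated
#' when the best hit is non-defensive; queries without any hit score 0
#' (ranked below every scored protein). Bit-score ties prefer a
#' defense-labeled target, then the smallest target id.
#'
#' @param hits data.frame with columns `query`, `target`, `bit_score`.
#' @param labels named 0/1 vector over target ids.
#' @param query_ids ids to score (defaults to the queries in `hits`).
#' @return named numeric score vector.
#' @export
signed_best_hit_baseline <- function(hits, labels, query_ids = NULL) {
  query_ids <- query_ids %||% unique(hits$query)
  scores <- stats::setNames(numeric(length(query_ids)), query_ids)
  if (nrow(hits)) {
    hits$def <- as.integer(labels[hits$target] == 1)
    hits$def[is.na(hits$def)] <- 0L
    ord <- order(hits$query, -hits$bit_score, -hits$def, hits$target)
    h <- hits[ord, , drop = FALSE]
    best <- h[!duplicated(h$query), , drop = FALSE]
    best <- best[best$query %in% query_ids, , drop = FALSE]
    scores[best$query] <- ifelse(best$def == 1, best$bit_score, -best$bit_score)
  }
  scores
}

# one-sided (enrichment) Fisher exact p for a 2x2 table
fisher_p_greater <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                     alternative = "greater")$p.value
}

#' Guilt-by-association enrichment of clusters near known defense genes
#'
#' For every gene, determines whether at least one known defense gene
#' lies within `window` genes on the same contig, excluding defensive
#' neighbours of the query's own system and (optionally) of the query's
#' fold. Each protein cluster is then tested for enrichment of
#' near-defense genes against all other genes with a one-sided Fisher
#' exact test; clusters are ranked by ascending p.
#'
#' @param genomes list of `shieldscan_genome`.
#' @param cluster_map named character vector gene_id -> cluster id.
#' @param labels label data.frame with `gene_id`, `label`, `system_id`.
#' @param window gene-count radius (default 10).
#' @param fold_map optional named fold vector enabling the same-fold
#'   exclusion.
#' @param exclusions subset of `c("same_system", "same_fold")`.
#' @return data.frame `cluster_id`, `a`, `b`, `c`, `d`, `p_value`
#'   sorted by ascending p.
#' @export
guilt_by_association <- function(genomes, cluster_map, labels, window = 10L,
                                 fold_map = NULL,
                                 exclusions = c("same_system", "same_fold")) {
  if (window < 1L) stop_validation("window must be >= 1")
  defense_ids <- labels$gene_id[labels$label == "defense"]
  system_of <- stats::setNames(labels$system_id, labels$gene_id)
  near <- gene_near_defense(genomes, defense_ids, system_of, window,
                            fold_map, exclusions)
  ids <- names(near)
  in_cluster <- split(ids, cluster_map[ids])
  total_near <- sum(near)
  n <- length(near)
  rows <- lapply(names(in_cluster), function(cl) {
    m <- in_cluster[[cl]]
    a <- sum(near[m]); b <- length(m) - a
    c <- total_near - a; d <- n - length(m) - c
    data.frame(cluster_id = cl, a = a, b = b, c = c, d = d,
               p_value = fisher_p_greater(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-gene flag: >= 1 known defense gene within +/- window ranks, after
# exclusions; the gene itself never counts
gene_near_defense <- function(genomes, defense_ids, system_of, window,
                              fold_map, exclusions) {
  out <- logical(0)
  for (genome in genomes) {
    g <- genome$genes
    for (contig in unique(g$contig_id)) {
      gc_ <- g[g$contig_id == contig, , drop = FALSE]
      def_rows <- which(gc_$gene_id %in% defense_ids)
      flags <- vapply(seq_len(nrow(gc_)), function(i) {
        cand <- def_rows[abs(gc_$rank[def_rows] - gc_$rank[i]) <= window &
                           def_rows != i]
        if (!length(cand)) return(FALSE)
        if ("same_system" %in% exclusions) {
          qs <- system_of[gc_$gene_id[i]]
          if (!is.na(qs) && nzchar(qs)) {
            cand <- cand[is.na(system_of[gc_$gene_id[cand]]) |
                           system_of[gc_$gene_id[cand]] != qs]
          }
        }
        if ("same_fold" %in% exclusions && !is.null(fold_map)) {
          qf <- fold_map[gc_$gene_id[i]]
          if (!is.na(qf)) {
            nf <- fold_map[gc_$gene_id[cand]]
            cand <- cand[is.na(nf) | nf != qf]
          }
        }
        length(cand) > 0
      }, logical(1))
      out <- c(out, stats::setNames(flags, gc_$gene_id))
    }
  }
  out
}

#' Per-gene scores from a guilt-by-association result
#'
#' Maps each gene to `-log10(p)` of its cluster, the ranking score used
#' when comparing guilt-by-association against the classifier.
#'
#' @param gba result of [guilt_by_association()].
#' @param cluster_map named character vector gene_id -> cluster.
#' @return named numeric score vector over the genes in `cluster_map`.
#' @export
gba_gene_scores <- function(gba, cluster_map) {
  p <- stats::setNames(gba$p_value, gba$cluster_id)
  stats::setNames(-log10(p[cluster_map]), names(cluster_map))
}

#' Summarize predictions over defense-system instances
#'
#' For each system instance, flags completeness (all member genes with
#' log-odds > 0) and records the maximum member probability; for each
#' system, takes the top-scoring gene across all instances. Counts of
#' systems above probability cutoffs 0.5 and 0.98 are reported, along
#' with the fraction of multi-gene instances that are complete among
#' those with at least one predicted gene.
#'
#' @param predictions data.frame `gene_id`, `probability`, `log_odds`.
#' @param instances data.frame `instance_id`, `system_id`, `gene_id`.
#' @return list with `instances`, `systems`, `n_above_0.5`,
#'   `n_above_0.98`, `multi_gene_complete_fraction`.
#' @export
prospective_system_summary <- function(predictions, instances) {
  if (any(!instances$gene_id %in% predictions$gene_id)) {
    stop_lookup("instance gene without a prediction")
  }
  p <- stats::setNames(predictions$probability, predictions$gene_id)
  lo <- stats::setNames(predictions$log_odds, predictions$gene_id)
  inst <- do.call(rbind, lapply(split(instances, instances$instance_id), function(d) {
    data.frame(instance_id = d$instance_id[1], system_id = d$system_id[1],
               n_genes = nrow(d),
               max_probability = max(p[d$gene_id]),
               max_log_odds = max(lo[d$gene_id]),
               complete = all(lo[d$gene_id] > 0),
               stringsAsFactors = FALSE)
  }))
  rownames(inst) <- NULL
  sys <- do.call(rbind, lapply(split(inst, inst$system_id), function(d) {
    data.frame(system_id = d$system_id[1],
               max_probability = max(d$max_probability),
               stringsAsFactors = FALSE)
  }))
  rownames(sys) <- NULL
  multi <- inst[inst$n_genes > 1 & inst$max_log_odds > 0, , drop = FALSE]
  list(instances = inst, systems = sys,
       n_above_0.5 = sum(sys$max_probability > 0.5),
       n_above_0.98 = sum(sys$max_probability > 0.98),
       multi_gene_complete_fraction = if (nrow(multi)) mean(multi$complete) else NA_real_)
}
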