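# Labeled-dataset construction: redundancy reduction by sequence
# clustering, homology-aware fold assignment with zero cross-fold
# homolog leakage, and validation splits that respect homology
# components.

#' Greedy redundancy reduction by sequence clustering
#'
#' Longest-first incremental clustering: each protein joins the first
#' existing cluster whose founder it matches at `>= identity_min`
#' identity with `>= coverage_min` reciprocal coverage, where identity
#' and aligned spans come from a standard local alignment (BLOSUM62).
#' A shared-4-mer prefilter prunes candidate founders before alignment
#' (the usual seed-filter trick of fast clustering tools); pairs below
#' `kmer_min` shared distinct 4-mers are never aligned, which bounds the
#' method's sensitivity near the identity threshold but is lossless for
#' close homologs. One representative per cluster is drawn uniformly at
#' random under `seed`.
#'
#' @param proteins named character vector of amino-acid sequences
#'   (names are protein ids).
#' @param identity_min minimum fractional identity (default 0.30).
#' @param coverage_min minimum reciprocal coverage (default 0.80).
#' @param seed seed for representative choice.
#' @param kmer_min shared distinct 4-mers required to attempt alignment.
#' @return list with `cluster` (named character: id -> cluster id) and
#'   `representative` (named character: cluster id -> member id).
#' @export
reduce_redundancy <- function(proteins, identity_min = 0.30,
                              coverage_min = 0.80, seed = 1L,
                              kmer_min = 3L) {
  if (!length(proteins)) stop_validation("empty protein list")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop_validation("proteins must have unique names")
  }
  ord <- order(-nchar(proteins), names(proteins))
  ids <- names(proteins)[ord]
  seqs <- unname(proteins[ord])

  kmer_sets <- lapply(seqs, function(s) {
    if (nchar(s) < 4L) return(character(0))
    unique(substring(s, 1:(nchar(s) - 3L), 4:nchar(s)))
  })

  founders_seq <- character(0)
  founders_kmers <- list()
  cluster_of <- integer(length(ids))
  members <- list()
  mat <- "BLOSUM62"
  for (i in seq_along(ids)) {
    assigned <- 0L
    if (length(founders_seq)) {
      shared <- vapply(founders_kmers, function(ks) {
        sum(ks %in% kmer_sets[[i]])
      }, numeric(1))
      cand <- which(shared >= kmer_min)
      if (length(cand)) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::AAStringSet(founders_seq[cand]),
          subject = Biostrings::AAString(seqs[i]),
          type = "local", substitutionMatrix = mat,
          gapOpening = 11, gapExtension = 1)
        idents <- Biostrings::pid(aln, type = "PID1") / 100
        pr <- methods::slot(methods::slot(aln, "pattern"), "range")
        sr <- methods::slot(methods::slot(aln, "subject"), "range")
        cov_f <- BiocGenerics::width(pr) / nchar(founders_seq[cand])
        cov_q <- BiocGenerics::width(sr) / nchar(seqs[i])
        ok <- idents >= identity_min & cov_f >= coverage_min & cov_q >= coverage_min
        if (any(ok)) assigned <- cand[which(ok)[1]]
      }
    }
    if (assigned == 0L) {
      founders_seq <- c(founders_seq, seqs[i])
      founders_kmers[[length(founders_seq)]] <- kmer_sets[[i]]
      assigned <- length(founders_seq)
      members[[assigned]] <- character(0)
    }
    cluster_of[i] <- assigned
    members[[assigned]] <- c(members[[assigned]], ids[i])
  }

  cluster_ids <- sprintf("clu%05d", seq_along(members))
  cl_map <- stats::setNames(cluster_ids[cluster_of], ids)
  reps <- with_seed(child_seed(seed, "cluster-reps"), vapply(members, function(m) {
    if (length(m) == 1L) m else sample(m, 1L)
  }, character(1)))
  names(reps) <- cluster_ids
  list(cluster = cl_map[names(proteins)], representative = reps)
}

#' Assign homology components to folds
#'
#' Computes connected components of the homology graph and packs whole
#' components into `k` folds so that no homology edge ever crosses a
#' fold boundary. Components are sorted by (positive count desc, size
#' desc, id); components carrying positives are placed greedily into
#' the fold with the fewest positives so far (ties: fewest total
#' members, then lowest fold index), and positive-free components into
#' the fold with the fewest total members. The procedure is
#' deterministic; `seed` is accepted for interface symmetry with the
#' other builders.
#'
#' @param edges data.frame with columns `query`, `target` (undirected
#'   homolog pairs); may have zero rows.
#' @param labels named integer/logical vector (1 = defense) over all
#'   ids to assign; ids absent from `edges` are isolated nodes.
#' @param k number of folds (default 5).
#' @param seed unused (kept for interface stability).
#' @return named integer vector id -> fold in `1..k`.
#' @export
assign_folds <- function(edges, labels, k = 5L, seed = 1L) {
  if (k < 2L) stop_validation("k must be >= 2")
  ids <- names(labels)
  if (is.null(ids)) stop_validation("labels must be named")
  comp <- component_ids(edges, ids)

  comp_ids <- sort(unique(comp))
  pos <- vapply(comp_ids, function(cid) sum(labels[comp == cid] == 1), numeric(1))
  size <- vapply(comp_ids, function(cid) sum(comp == cid), numeric(1))
  ord <- order(-pos, -size, comp_ids)

  fold_pos <- numeric(k); fold_n <- numeric(k)
  comp_fold <- integer(length(comp_ids))
  for (j in ord) {
    # positive-carrying components balance the positive counts; label-free
    # components balance the totals (placing them by positive count would
    # funnel every one of them into a single fold)
    f <- if (pos[j] > 0) {
      order(fold_pos, fold_n, seq_len(k))[1]
    } else {
      order(fold_n, fold_pos, seq_len(k))[1]
    }
    comp_fold[j] <- f
    fold_pos[f] <- fold_pos[f] + pos[j]
    fold_n[f] <- fold_n[f] + size[j]
  }
  stats::setNames(comp_fold[match(comp, comp_ids)], ids)
}

#' Report homology edges that cross folds
#'
#' A valid fold assignment has zero crossing edges; this is the hard
#' leakage invariant of the evaluation protocol.
#'
#' @param fold_map named integer vector id -> fold.
#' @param edges homolog-pair data.frame (`query`, `target`).
#' @return data.frame of crossing edges (zero rows when leak-free).
#' @export
leakage_check <- function(fold_map, edges) {
  if (!nrow(edges)) return(edges[0, , drop = FALSE])
  fq <- fold_map[edges$query]
  ft <- fold_map[edges$target]
  keep <- !is.na(fq) & !is.na(ft) & fq != ft
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bundle aligned rows into a labeled dataset
#' @keywords internal
new_labeled_dataset <- function(X, y, gene_ids, dedup_group, component_id, fold) {
  n <- nrow(X)
  stopifnot(length(y) == n, length(gene_ids) == n, length(dedup_group) == n,
            length(component_id) == n, length(fold) == n)
  structure(list(X = X, y = as.integer(y), gene_ids = gene_ids,
                 dedup_group = dedup_group, component_id = component_id,
                 fold = as.integer(fold)),
            class = "shieldscan_dataset")
}

#' @export
print.shieldscan_dataset <- function(x, ...) {
  cat(sprintf("<shieldscan_dataset> %d genes x %d features; %d positives; folds: %s\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1),
              paste(sort(unique(x$fold)), collapse = ",")))
  invisible(x)
}

# row subset preserving all aligned fields
subset_dataset <- function(ds, keep) {
  new_labeled_dataset(ds$X[keep, , drop = FALSE], ds$y[keep], ds$gene_ids[keep],
                      ds$dedup_group[keep], ds$component_id[keep], ds$fold[keep])
}

#' Split a dataset into train and validation by whole components
#'
#' Moves whole homology components into the validation set until at
#' least `fraction` of the positives and of the controls are covered,
#' so no homolog of a validation protein remains in training. The
#' component order is seeded; components contributing to whichever
#' stratum is still uncovered are taken first.
#'
#' @param ds a `shieldscan_dataset` (typically the training folds).
#' @param fraction target fraction per class (default 0.1); 0 gives an
#'   empty validation set.
#' @param seed integer seed.
#' @return list with `train` and `validation` datasets.
#' @export
make_validation_split <- function(ds, fraction = 0.1, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop_validation("fraction must be in [0, 1)")
  n_pos <- sum(ds$y == 1); n_neg <- sum(ds$y == 0)
  if (fraction == 0) {
    return(list(train = ds, validation = subset_dataset(ds, logical(nrow(ds$X)))))
  }
  if (length(unique(ds$component_id)) < 2L) {
    stop_validation("need >= 2 components to split")
  }
  comp_ids <- unique(ds$component_id)
  ord <- with_seed(child_seed(seed, "valsplit"), sample(comp_ids))
  need_pos <- fraction * n_pos; need_neg <- fraction * n_neg
  got_pos <- 0; got_neg <- 0
  chosen <- character(0)
  for (cid in ord) {
    if (got_pos >= need_pos && got_neg >= need_neg) break
    rows <- ds$component_id == cid
    cp <- sum(ds$y[rows] == 1); cn <- sum(ds$y[rows] == 0)
    take <- (got_pos < need_pos && cp > 0) || (got_neg < need_neg && cn > 0)
    if (take) {
      chosen <- c(chosen, cid)
      got_pos <- got_pos + cp; got_neg <- got_neg + cn
    }
  }
  if (got_pos < need_pos || got_neg < need_neg) {
    warning("stratification target unattainable with whole components; ",
            "validation covers ", got_pos, " positives / ", got_neg, " controls",
            call. = FALSE)
  }
  val <- ds$component_id %in% chosen
  list(train = subset_dataset(ds, !val), validation = subset_dataset(ds, val))
}

#' Build a labeled dataset from genomes, labels and a homology graph
#'
#' Featurizes every genome with the backend, keeps genes labeled
#' defense or control, attaches dedup groups from the label table
#' (falling back to the gene id) and assigns homology-aware folds.
#'
#' @param genomes list of `shieldscan_genome`.
#' @param labels label data.frame ([read_label_table()] layout).
#' @param backend embedding backend.
#' @param edges homolog-pair data.frame (`query`, `target`).
#' @param k number of folds.
#' @param seed integer seed.
#' @return a `shieldscan_dataset` plus `layout` attribute.
#' @export
build_labeled_dataset <- function(genomes, labels, backend, edges,
                                  k = 5L, seed = 1L) {
  feats <- lapply(genomes, featurize_genome, backend = backend)
  X <- do.call(rbind, lapply(feats, `[[`, "X"))
  lab <- labels[labels$label %in% c("defense", "control"), , drop = FALSE]
  lab <- lab[lab$gene_id %in% rownames(X), , drop = FALSE]
  X <- X[lab$gene_id, , drop = FALSE]
  y <- as.integer(lab$label == "defense")
  names(y) <- lab$gene_id
  dedup <- ifelse(nzchar(lab$dedup_group), lab$dedup_group, lab$gene_id)
  fold <- assign_folds(edges, y, k = k, seed = seed)
  comp <- component_ids(edges, names(y))
  ds <- new_labeled_dataset(X, y, lab$gene_id, dedup, comp[lab$gene_id],
                            fold[lab$gene_id])
  attr(ds, "layout") <- feats[[1]]$layout
  ds
}

# connected-component id per node (singletons get their own component);
# edges touching nodes outside `ids` and self-loops are ignored
component_ids <- function(edges, ids) {
  if (nrow(edges)) {
    edges <- edges[edges$query %in% ids & edges$target %in% ids &
                     edges$query != edges$target, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("query", "target")] else data.frame(query = character(0), target = character(0)),
    directed = FALSE, vertices = data.frame(name = ids))
  m <- igraph::components(g)$membership
  stats::setNames(as.integer(m[ids]), ids)
}
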