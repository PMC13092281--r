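# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small 2-genome cohort without the clustering pass (fast)
tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    generate_cohort(synth_config(n_genomes = 2L, genes_per_genome = 60L, seed = 3L),
                    cluster = FALSE)
  })
}

tiny_backend <- function(dim = 16L) mock_backend(dim = dim, seed = 2L)

# labeled dataset over the tiny cohort, 5 folds
tiny_dataset <- function() {
  cached("tiny_dataset", function() {
    co <- tiny_cohort()
    build_labeled_dataset(co$genomes, co$labels, tiny_backend(), co$edges,
                          k = 5L, seed = 1L)
  })
}

tiny_ensemble <- function() {
  cached("tiny_ensemble", function() train_ensemble(tiny_dataset(), k = 5L, seed = 5L))
}

# hand-built balanced mini genome: every sequence has GC exactly 0.5 so
# coordinate-shift tests can keep genome GC fixed
balanced_genome <- function(shift = 0L) {
  unit <- "ATGC"
  gene_nt <- strrep(unit, 30)              # 120 bp, GC 0.5
  gap <- strrep(unit, 5)                   # 20 bp
  n_genes <- 5L
  pieces <- character(0)
  rows <- list()
  pos <- shift
  prefix <- strrep(unit, shift / 4L)
  for (i in seq_len(n_genes)) {
    rows[[i]] <- data.frame(gene_id = paste0("b", i), contig_id = "c1",
                            start = pos, end = pos + nchar(gene_nt),
                            strand = if (i %% 2L) 1L else -1L,
                            stringsAsFactors = FALSE)
    pieces <- c(pieces, gene_nt)
    pos <- pos + nchar(gene_nt)
    if (i < n_genes) { pieces <- c(pieces, gap); pos <- pos + nchar(gap) }
  }
  seq <- paste0(prefix, paste(pieces, collapse = ""))
  suppressWarnings(new_genome("bal", c(c1 = seq), do.call(rbind, rows)))
}

# brute-force average precision: mean of precision at each positive's
# rank (valid for distinct scores)
ap_oracle <- function(scores, labels) {
  ord <- order(-scores)
  labels <- labels[ord]
  pos_at <- which(labels == 1)
  mean(vapply(pos_at, function(k) sum(labels[1:k] == 1) / k, numeric(1)))
}

# exhaustive pair-counting AUROC (ties half credit)
auroc_oracle <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# brute-force hypergeometric tail for a 2x2 table (a,b / c,d), one-sided
# enrichment
fisher_oracle <- function(a, b, c, d) {
  n1 <- a + b; white <- a + c; black <- b + d
  xs <- a:min(n1, white)
  sum(choose(white, xs) * choose(black, n1 - xs)) / choose(white + black, n1)
}

# enumerate-runs TU oracle: maximal same-strand runs, then split at
# gaps > max_gap
tu_oracle <- function(genes, max_gap = 30L) {
  out <- list()
  for (contig in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == contig, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    runs <- split(seq_len(nrow(g)), cumsum(c(1, diff(g$strand) != 0)))
    for (r in runs) {
      cur <- r[1]
      for (i in r[-1]) {
        if (g$start[i] - g$end[i - 1] > max_gap) {
          out[[length(out) + 1L]] <- g$gene_id[cur]; cur <- integer(0)
        }
        cur <- c(cur, i)
      }
      out[[length(out) + 1L]] <- g$gene_id[cur]
    }
  }
  out
}

# random toy contig for TU oracle comparisons
random_contig_genome <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(4:12, 1)
    pos <- 0L
    rows <- list()
    nt <- strrep("ATGGCA", 10)   # 60 bp, translates cleanly
    for (i in seq_len(n)) {
      gap <- sample(c(0:40, 100), 1)
      pos <- pos + gap
      rows[[i]] <- data.frame(gene_id = sprintf("r%02d", i), contig_id = "c1",
                              start = pos, end = pos + 60L,
                              strand = sample(c(1L, -1L), 1),
                              stringsAsFactors = FALSE)
      pos <- pos + 60L
    }
    genes <- do.call(rbind, rows)
    seqlen <- pos + 50L
    seq <- strrep("A", seqlen)
    for (i in seq_len(n)) {
      substr(seq, genes$start[i] + 1L, genes$end[i]) <- nt
    }
    suppressWarnings(new_genome(paste0("rc", seed), c(c1 = seq), genes))
  })
}

# random protein set with paralog families for clustering tests
random_protein_set <- function(n = 50L, seed = 1L) {
  withr::with_seed(seed, {
    aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
    seqs <- character(0)
    while (length(seqs) < n) {
      anc <- paste(sample(aa, sample(40:90, 1), replace = TRUE), collapse = "")
      fam <- sample(1:3, 1)
      for (j in seq_len(min(fam, n - length(seqs)))) {
        v <- strsplit(anc, "")[[1]]
        hit <- which(runif(length(v)) < 0.05)
        v[hit] <- sample(aa, length(hit), replace = TRUE)
        seqs <- c(seqs, paste(v, collapse = ""))
      }
    }
    stats::setNames(seqs, sprintf("p%03d", seq_along(seqs)))
  })
}

# order-free greedy clustering oracle: same longest-first rule, but all
# pairwise matches computed up front without any prefilter
cluster_oracle <- function(proteins, identity_min = 0.30, coverage_min = 0.80) {
  ord <- order(-nchar(proteins), names(proteins))
  ids <- names(proteins)[ord]
  seqs <- unname(proteins[ord])
  match_mat <- matrix(FALSE, length(ids), length(ids))
  for (i in seq_along(ids)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(seqs),
      subject = Biostrings::AAString(seqs[i]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    idents <- Biostrings::pid(aln, type = "PID1") / 100
    covp <- BiocGenerics::width(aln@pattern@range) / nchar(seqs)
    covs <- BiocGenerics::width(aln@subject@range) / nchar(seqs[i])
    match_mat[, i] <- idents >= identity_min & covp >= coverage_min & covs >= coverage_min
  }
  founders <- integer(0)
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    hit <- founders[which(match_mat[founders, i])]
    if (length(hit)) {
      assign[i] <- hit[1]
    } else {
      founders <- c(founders, i)
      assign[i] <- i
    }
  }
  stats::setNames(ids[assign], ids)[names(proteins)]
}
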