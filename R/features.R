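# Feature construction: the 119 genomic-context features and the full
# feature vector for a center gene and its two neighbours on either side.
#
# Vector layout (dim = embedding dimension, 640 in production):
#   [1 .. 5*dim]          mean-pooled embeddings at window positions
#                         -2, -1, 0 (center), +1, +2
#   [5*dim+1 .. 5*dim+119] genomic features:
#     per window position, 22 slots: 4 mononucleotide frequencies (ACGT,
#       coding strand), 16 overlapping dinucleotide frequencies, gene GC
#       minus genome GC, gene length in bp           (5 x 22 = 110)
#     4 signed intergenic distances between consecutive window pairs
#     4 neighbour orientations relative to the center (+1 same strand)
#     1 genome-wide GC content                        (total 119)
# Missing neighbours at contig edges contribute zeros in all their slots.

NT <- c("A", "C", "G", "T")
DINUC <- as.vector(t(outer(NT, NT, paste0)))  # AA, AC, ..., TT
WINDOW_POSITIONS <- c(-2L, -1L, 0L, 1L, 2L)

pos_tag <- function(p) ifelse(p < 0, paste0("m", -p), ifelse(p > 0, paste0("p", p), "0"))

#' Feature layout registry
#'
#' One row per feature-vector slot, naming its block, feature category
#' and window position. The registry is what attribution aggregation and
#' the serialized layout sidecar are built from.
#'
#' @param dim embedding dimension per protein.
#' @return data.frame with columns `index`, `name`, `block`, `category`,
#'   `position` (window position; NA for the genome-wide GC slot).
#' @export
feature_layout <- function(dim = 640L) {
  dim <- as.integer(dim)
  rows <- list()
  for (p in WINDOW_POSITIONS) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("emb_%s_%04d", pos_tag(p), seq_len(dim)),
      block = paste0("emb_", pos_tag(p)), category = "embedding",
      position = p, stringsAsFactors = FALSE)
  }
  for (p in WINDOW_POSITIONS) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = c(paste0("freq_", NT, "_", pos_tag(p)),
               paste0("dinuc_", DINUC, "_", pos_tag(p)),
               paste0("gc_rel_", pos_tag(p)),
               paste0("len_", pos_tag(p))),
      block = paste0("genomic_", pos_tag(p)),
      category = c(rep("nucleotide_freq", 4), rep("dinucleotide_freq", 16),
                   "gc_content", "gene_length"),
      position = p, stringsAsFactors = FALSE)
  }
  dist_pos <- c(-2L, -1L, 1L, 2L)  # pair (p, p+1) attributed to the outer neighbour
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("dist_m2_m1", "dist_m1_0", "dist_0_p1", "dist_p1_p2"),
    block = "distances", category = "intergenic_distance",
    position = dist_pos, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste0("orient_", pos_tag(c(-2L, -1L, 1L, 2L))),
    block = "orientations", category = "orientation",
    position = c(-2L, -1L, 1L, 2L), stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "genome_gc", block = "genome_gc", category = "genome_gc",
    position = NA_integer_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$index <- seq_len(nrow(out))
  out[c("index", "name", "block", "category", "position")]
}

#' Mononucleotide frequencies of a coding-strand sequence
#'
#' Counts over A, C, G, T divided by the number of non-N positions; N is
#' excluded from both numerator and denominator.
#'
#' @param nt_seq non-empty nucleotide string over ACGTN.
#' @return numeric vector of length 4 (A, C, G, T order).
#' @export
nucleotide_freqs <- function(nt_seq) {
  if (!is.character(nt_seq) || !nzchar(nt_seq)) stop_validation("empty sequence")
  v <- strsplit(toupper(nt_seq), "", fixed = TRUE)[[1]]
  n_valid <- sum(v %in% NT)
  if (n_valid == 0L) return(stats::setNames(rep(0, 4), NT))
  stats::setNames(vapply(NT, function(b) sum(v == b), numeric(1)) / n_valid, NT)
}

#' Overlapping dinucleotide frequencies
#'
#' Counts of the 16 dinucleotides over all overlapping windows, divided
#' by the number of windows free of N.
#'
#' @param nt_seq nucleotide string of length >= 2.
#' @return numeric vector of length 16 (AA, AC, ..., TT order).
#' @export
dinucleotide_freqs <- function(nt_seq) {
  if (!is.character(nt_seq) || nchar(nt_seq) < 2L) {
    stop_validation("sequence must have length >= 2")
  }
  v <- strsplit(toupper(nt_seq), "", fixed = TRUE)[[1]]
  L <- length(v)
  a <- v[1:(L - 1L)]; b <- v[2:L]
  valid <- a %in% NT & b %in% NT
  out <- stats::setNames(rep(0, 16), DINUC)
  if (!any(valid)) return(out)
  tab <- table(factor(paste0(a[valid], b[valid]), levels = DINUC))
  out[] <- as.numeric(tab) / sum(valid)
  out
}

#' Gene GC content relative to the genome
#' @param nt_seq nucleotide string.
#' @param genome_gc genome-wide GC fraction in `[0, 1]`.
#' @return `gc(gene) - genome_gc`, in `[-1, 1]`.
#' @export
gc_relative <- function(nt_seq, genome_gc) {
  if (!is.character(nt_seq) || !nzchar(nt_seq)) stop_validation("empty sequence")
  if (genome_gc < 0 || genome_gc > 1) stop_validation("genome_gc outside [0,1]")
  gc_fraction(nt_seq) - genome_gc
}

#' Signed intergenic distance between two genes on one contig
#'
#' `b$start - a$end` for `a` preceding `b`: 0 means abutting, negative
#' means overlap.
#'
#' @param a,b one-row gene records (`a` must not start after `b`).
#' @return scalar distance in bp.
#' @export
intergenic_distance <- function(a, b) {
  if (!identical(a$contig_id, b$contig_id)) {
    stop_validation("genes on different contigs")
  }
  if (a$start > b$start) stop_validation("a must precede b")
  b$start - a$end
}

#' Extract the five-gene window around a center gene
#'
#' Up to two neighbours on each side by rank on the same contig; fewer
#' near contig edges. Neighbour lists are ordered nearest-first.
#'
#' @param genome a `shieldscan_genome`.
#' @param gene_id center gene.
#' @return list with `center`, `left`, `right` (lists of one-row gene
#'   data.frames) and `genome_gc`.
#' @export
build_neighborhood <- function(genome, gene_id) {
  g <- genome$genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop_lookup("unknown gene: ", gene_id)
  contig <- g$contig_id[i]
  rank0 <- g$rank[i]
  on_contig <- g[g$contig_id == contig, , drop = FALSE]
  pick <- function(r) {
    row <- on_contig[on_contig$rank == r, , drop = FALSE]
    if (nrow(row)) row else NULL
  }
  left <- Filter(Negate(is.null), lapply(c(rank0 - 1L, rank0 - 2L), pick))
  right <- Filter(Negate(is.null), lapply(c(rank0 + 1L, rank0 + 2L), pick))
  list(center = g[i, , drop = FALSE], left = left, right = right,
       genome_gc = genome$genome_gc)
}

# genes of a neighbourhood keyed by window position (-2..2); NULL if absent
window_genes <- function(nb) {
  list(`-2` = if (length(nb$left) >= 2) nb$left[[2]] else NULL,
       `-1` = if (length(nb$left) >= 1) nb$left[[1]] else NULL,
       `0` = nb$center,
       `1` = if (length(nb$right) >= 1) nb$right[[1]] else NULL,
       `2` = if (length(nb$right) >= 2) nb$right[[2]] else NULL)
}

#' Assemble the full feature vector for one center gene
#'
#' Concatenates the five pooled protein embeddings (window order -2, -1,
#' center, +1, +2) with the 119 genomic-context features. Missing
#' neighbours at contig edges contribute zeros in their embedding slots,
#' their 22 per-gene genomic slots, the adjacent intergenic distance and
#' their orientation slot, keeping the vector length fixed at
#' `5 * dim + 119`.
#'
#' @param nb neighbourhood from [build_neighborhood()].
#' @param embeddings named list or matrix (rownames = gene ids) of pooled
#'   protein embeddings covering every gene in the window.
#' @param dim embedding dimension.
#' @return list with `gene_id`, `values` (named numeric vector) and
#'   `layout` (the registry data.frame).
#' @export
assemble_features <- function(nb, embeddings, dim = 640L) {
  dim <- as.integer(dim)
  layout <- feature_layout(dim)
  wg <- window_genes(nb)
  get_emb <- function(id) {
    v <- if (is.matrix(embeddings)) {
      if (!id %in% rownames(embeddings)) NULL else embeddings[id, ]
    } else embeddings[[id]]
    if (is.null(v)) stop_lookup("missing embedding for gene ", id)
    if (length(v) != dim) stop_validation("embedding dim mismatch for ", id)
    as.numeric(v)
  }
  emb_part <- unlist(lapply(wg, function(gene) {
    if (is.null(gene)) rep(0, dim) else get_emb(gene$gene_id)
  }), use.names = FALSE)

  per_gene <- unlist(lapply(wg, function(gene) {
    if (is.null(gene)) return(rep(0, 22))
    c(nucleotide_freqs(gene$nt_seq), dinucleotide_freqs(gene$nt_seq),
      gc_relative(gene$nt_seq, nb$genome_gc), gene$end - gene$start)
  }), use.names = FALSE)

  pair_dist <- vapply(1:4, function(k) {
    a <- wg[[k]]; b <- wg[[k + 1]]
    if (is.null(a) || is.null(b)) 0 else intergenic_distance(a, b)
  }, numeric(1))

  center_strand <- nb$center$strand
  orients <- vapply(c("-2", "-1", "1", "2"), function(p) {
    gene <- wg[[p]]
    if (is.null(gene)) 0 else if (gene$strand == center_strand) 1 else -1
  }, numeric(1))

  values <- c(emb_part, per_gene, pair_dist, orients, nb$genome_gc)
  stopifnot(length(values) == 5L * dim + 119L)
  names(values) <- layout$name
  list(gene_id = nb$center$gene_id, values = values, layout = layout)
}

#' Featurize every gene of a genome
#'
#' Embeds all proteins once with the backend, then assembles the feature
#' vector of every gene.
#'
#' @param genome a `shieldscan_genome`.
#' @param backend a `shieldscan_backend`.
#' @return list with `X` (genes x features matrix, rownames = gene ids),
#'   `layout`, and `gene_ids`.
#' @export
featurize_genome <- function(genome, backend) {
  g <- genome$genes
  emb <- embed_proteins(backend, stats::setNames(g$aa_seq, g$gene_id))
  layout <- feature_layout(backend$dim)
  X <- matrix(0, nrow = nrow(g), ncol = nrow(layout),
              dimnames = list(g$gene_id, layout$name))
  for (i in seq_len(nrow(g))) {
    nb <- build_neighborhood(genome, g$gene_id[i])
    X[i, ] <- assemble_features(nb, emb, backend$dim)$values
  }
  list(X = X, layout = layout, gene_ids = g$gene_id)
}

#' Write a feature matrix with its layout sidecar
#' @param feats result of [featurize_genome()].
#' @param matrix_path TSV output for the dense matrix.
#' @param layout_path JSON output for the layout registry.
#' @return `matrix_path`, invisibly.
#' @export
write_features <- function(feats, matrix_path, layout_path) {
  utils::write.table(data.frame(gene_id = rownames(feats$X), feats$X,
                                check.names = FALSE),
                     matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(feats$layout, layout_path, digits = NA)
  invisible(matrix_path)
}
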