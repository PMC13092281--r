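# Pluggable per-protein embedding backends.
#
# A backend maps an amino-acid sequence to per-residue vectors; the
# per-residue vectors are mean-pooled into one protein-level vector of
# fixed dimension (640 by default, matching the protein language model
# the production pipeline consumes). All tests run on a deterministic
# mock backend built from hashed 3-mer identities.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Mean-pool a per-residue embedding matrix
#'
#' Element-wise arithmetic mean over residues (rows), the protein-level
#' pooling used throughout the pipeline.
#'
#' @param per_residue numeric L x dim matrix, one row per residue.
#' @return numeric vector of length `dim`.
#' @export
mean_pool <- function(per_residue) {
  if (!is.matrix(per_residue) || nrow(per_residue) < 1L) {
    stop_validation("per_residue must be a matrix with >= 1 row")
  }
  colMeans(per_residue)
}

#' Create a deterministic mock embedding backend
#'
#' A desk-scale stand-in for a protein language model: each overlapping
#' 3-mer of the sequence is hashed into one of `n_buckets` buckets, and
#' bucket identities are projected into `dim` dimensions by a fixed,
#' seeded Gaussian random matrix. The per-residue vector at position i is
#' the projection of the 3-mer starting at i, so the pooled vector is a
#' projected 3-mer composition profile: composition-sensitive (a planted
#' motif shifts the pooled vector) and exactly reproducible from
#' `(dim, seed)`.
#'
#' @param dim embedding dimension (>= 8; default 640).
#' @param seed integer seed for the projection matrix.
#' @param n_buckets number of hash buckets for 3-mers.
#' @return an object of class `shieldscan_backend` with fields `name`,
#'   `dim`, `seed` and the projection matrix.
#' @export
mock_backend <- function(dim = 640L, seed = 1L, n_buckets = 1024L) {
  if (dim < 8L) stop_validation("dim must be >= 8")
  proj <- with_seed(child_seed(seed, "mock-proj"),
                    matrix(stats::rnorm(n_buckets * dim), nrow = n_buckets, ncol = dim))
  structure(list(name = sprintf("mock-3mer-d%d-s%d", dim, seed),
                 dim = as.integer(dim), seed = as.integer(seed),
                 n_buckets = as.integer(n_buckets), proj = proj),
            class = "shieldscan_backend")
}

#' @export
print.shieldscan_backend <- function(x, ...) {
  cat(sprintf("<shieldscan_backend> %s (dim=%d)\n", x$name, x$dim))
  invisible(x)
}

# map an aa string to integer codes 0..20 (unknown characters -> X)
aa_codes <- function(aa_seq) {
  v <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  idx <- match(v, AA_ALPHABET)
  idx[is.na(idx)] <- 21L
  idx - 1L
}

# bucket index (1-based) of every overlapping 3-mer; sequences shorter
# than 3 are padded with X
kmer_buckets <- function(aa_seq, n_buckets) {
  code <- aa_codes(aa_seq)
  while (length(code) < 3L) code <- c(code, 20L)  # pad with X
  L <- length(code)
  v <- code[1:(L - 2L)] * 441L + code[2:(L - 1L)] * 21L + code[3:L]
  (v %% n_buckets) + 1L
}

# per-residue matrix for the mock backend (one row per 3-mer position)
mock_per_residue <- function(backend, aa_seq) {
  backend$proj[kmer_buckets(aa_seq, backend$n_buckets), , drop = FALSE]
}

#' Embed one protein sequence
#'
#' Runs the backend and mean-pools the per-residue vectors. Characters
#' outside the 20 amino acids are mapped to X.
#'
#' @param backend a `shieldscan_backend`.
#' @param aa_seq non-empty amino-acid string.
#' @param gene_id optional identifier attached to the result.
#' @return list with `gene_id` and `vector` (length `backend$dim`).
#' @export
embed_protein <- function(backend, aa_seq, gene_id = NA_character_) {
  if (!inherits(backend, "shieldscan_backend")) stop_validation("not a backend")
  if (!is.character(aa_seq) || length(aa_seq) != 1L || !nzchar(aa_seq)) {
    stop_validation("aa_seq must be a non-empty string")
  }
  list(gene_id = gene_id, vector = mean_pool(mock_per_residue(backend, aa_seq)))
}

#' Embed many proteins at once
#'
#' Vectorised fast path equivalent to calling [embed_protein()] per
#' sequence: the pooled vector is the projection of the mean 3-mer bucket
#' indicator, computed without materialising per-residue matrices.
#'
#' @param backend a `shieldscan_backend`.
#' @param aa_seqs named character vector of sequences.
#' @return numeric matrix, one row per sequence (rownames preserved).
#' @export
embed_proteins <- function(backend, aa_seqs) {
  if (!length(aa_seqs)) stop_validation("no sequences")
  counts <- matrix(0, nrow = length(aa_seqs), ncol = backend$n_buckets)
  for (i in seq_along(aa_seqs)) {
    b <- kmer_buckets(aa_seqs[[i]], backend$n_buckets)
    tb <- tabulate(b, nbins = backend$n_buckets)
    counts[i, ] <- tb / length(b)
  }
  out <- counts %*% backend$proj
  rownames(out) <- names(aa_seqs)
  out
}

#' Cosine similarity between two vectors
#' @param a,b numeric vectors of equal length.
#' @return scalar in `[-1, 1]`; 0 if either vector is all-zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
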