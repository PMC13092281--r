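# Genome-scale downstream analyses: transcriptional-unit calling,
# defense-island / prophage / plasmid context frequencies with genome
# bootstrap CIs, pangenome accumulation and occupancy, and the
# validation-rate-versus-log-odds curve.

#' Call transcriptional units
#'
#' A transcriptional unit (TU) is a maximal run of consecutive genes on
#' one contig, transcribed in the same direction, with each consecutive
#' pair separated by at most `max_gap` bp (30 bp by default; the bound
#' is inclusive). A TU's log-odds is the maximum log-odds of its member
#' genes when predictions are supplied.
#'
#' @param genome a `shieldscan_genome`.
#' @param predictions optional data.frame `gene_id`, `log_odds`.
#' @param max_gap maximum intergenic distance within a TU (bp).
#' @return data.frame `tu_id`, `contig_id`, `strand`, `n_genes`,
#'   `tu_log_odds` with a `genes` list-column of member gene ids in
#'   genomic order.
#' @export
call_tus <- function(genome, predictions = NULL, max_gap = 30L) {
  g <- genome$genes
  lo <- if (!is.null(predictions)) {
    stats::setNames(predictions$log_odds, predictions$gene_id)
  } else NULL
  tus <- list()
  for (contig in unique(g$contig_id)) {
    gc_ <- g[g$contig_id == contig, , drop = FALSE]
    current <- 1L
    breaks <- logical(nrow(gc_))
    if (nrow(gc_) > 1L) {
      for (i in 2:nrow(gc_)) {
        gap <- gc_$start[i] - gc_$end[i - 1]
        breaks[i] <- gc_$strand[i] != gc_$strand[i - 1] ||
          gc_$rank[i] != gc_$rank[i - 1] + 1L || gap > max_gap
      }
    }
    run <- cumsum(breaks) + 1L
    for (r in unique(run)) {
      m <- gc_[run == r, , drop = FALSE]
      tus[[length(tus) + 1L]] <- data.frame(
        tu_id = sprintf("%s_tu%04d", contig, r),
        contig_id = contig, strand = m$strand[1], n_genes = nrow(m),
        tu_log_odds = if (is.null(lo)) NA_real_ else max(lo[m$gene_id]),
        stringsAsFactors = FALSE)
      tus[[length(tus)]]$genes <- I(list(m$gene_id))
    }
  }
  out <- do.call(rbind, tus)
  rownames(out) <- NULL
  out
}

#' Flag genes by genomic context and compute category frequencies
#'
#' Flags each gene as residing in a defense island (within `window`
#' genes of a known defense gene other than itself), in a prophage, or
#' in a plasmid (interval overlap of at least 1 bp with the supplied
#' BED-like tables). Per-flag frequencies are computed for each named
#' gene set, with 95% percentile confidence intervals from seeded
#' genome-level bootstrap resampling.
#'
#' @param genomes list of `shieldscan_genome`.
#' @param defense_ids character vector of known defense gene ids.
#' @param intervals optional data.frame `genome_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `type` in
#'   `c("prophage", "plasmid")`.
#' @param window island radius in genes (default 10).
#' @param gene_sets named list of gene-id vectors (default: one set
#'   `all` covering every gene).
#' @param boot_reps bootstrap resamples of the genome collection.
#' @param seed integer seed.
#' @return list with `flags` (per-gene data.frame) and `frequencies`
#'   (`set`, `flag`, `freq`, `lo`, `hi`).
#' @export
annotate_context <- function(genomes, defense_ids, intervals = NULL,
                             window = 10L, gene_sets = NULL,
                             boot_reps = 200L, seed = 1L) {
  flag_rows <- list()
  for (genome in genomes) {
    g <- genome$genes
    if (!is.null(intervals)) {
      iv <- intervals[intervals$genome_id == genome$genome_id, , drop = FALSE]
      if (nrow(iv) && any(!iv$contig_id %in% names(genome$contigs))) {
        stop_validation("interval on unknown contig in genome ", genome$genome_id)
      }
    } else iv <- NULL
    in_island <- logical(nrow(g))
    for (contig in unique(g$contig_id)) {
      rows <- which(g$contig_id == contig)
      def_rows <- rows[g$gene_id[rows] %in% defense_ids]
      for (i in rows) {
        others <- def_rows[def_rows != i]
        in_island[i] <- length(others) > 0 &&
          any(abs(g$rank[others] - g$rank[i]) <= window)
      }
    }
    overlap_type <- function(type) {
      if (is.null(iv)) return(logical(nrow(g)))
      ivt <- iv[iv$type == type, , drop = FALSE]
      vapply(seq_len(nrow(g)), function(i) {
        any(ivt$contig_id == g$contig_id[i] &
              ivt$start < g$end[i] & ivt$end > g$start[i])
      }, logical(1))
    }
    flag_rows[[length(flag_rows) + 1L]] <- data.frame(
      genome_id = genome$genome_id, gene_id = g$gene_id,
      in_island = in_island,
      in_prophage = overlap_type("prophage"),
      in_plasmid = overlap_type("plasmid"),
      stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, flag_rows)
  rownames(flags) <- NULL

  if (is.null(gene_sets)) gene_sets <- list(all = flags$gene_id)
  genome_ids <- vapply(genomes, `[[`, "", "genome_id")
  flag_names <- c("in_island", "in_prophage", "in_plasmid")
  freq_for <- function(sampled_genomes) {
    f <- flags[flags$genome_id %in% sampled_genomes, , drop = FALSE]
    # with-replacement resampling: weight genomes by multiplicity
    mult <- table(sampled_genomes)
    w <- as.numeric(mult[f$genome_id])
    do.call(rbind, lapply(names(gene_sets), function(s) {
      sel <- f$gene_id %in% gene_sets[[s]]
      vapply(flag_names, function(fl) {
        if (!any(sel)) return(NA_real_)
        sum(w[sel] * f[[fl]][sel]) / sum(w[sel])
      }, numeric(1))
    }))
  }
  point <- freq_for(genome_ids)
  boot <- with_seed(child_seed(seed, "context-boot"), {
    replicate(boot_reps, freq_for(sample(genome_ids, replace = TRUE)))
  })
  lo <- apply(boot, c(1, 2), stats::quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(boot, c(1, 2), stats::quantile, probs = 0.975, na.rm = TRUE)
  freq <- do.call(rbind, lapply(seq_along(gene_sets), function(si) {
    data.frame(set = names(gene_sets)[si], flag = flag_names,
               freq = point[si, ], lo = lo[si, ], hi = hi[si, ],
               stringsAsFactors = FALSE)
  }))
  rownames(freq) <- NULL
  list(flags = flags, frequencies = freq)
}

#' Pangenome accumulation curves by category
#'
#' For each genome-count step, samples that many genomes without
#' replacement and counts the unique protein clusters containing at
#' least one gene of each category, averaging over `reps` resamples.
#'
#' @param gene_table data.frame `gene_id`, `genome_id`.
#' @param cluster_map named character vector gene_id -> cluster.
#' @param category_map named character vector gene_id -> category.
#' @param step genome-count step size (default 50).
#' @param reps resamples per step (default 10).
#' @param seed integer seed.
#' @return data.frame `n_genomes`, `category`, `mean_clusters`.
#' @export
accumulation_curve <- function(gene_table, cluster_map, category_map,
                               step = 50L, reps = 10L, seed = 1L) {
  if (anyNA(cluster_map[gene_table$gene_id])) {
    stop_validation("every gene must map to a cluster")
  }
  gene_table$cluster <- cluster_map[gene_table$gene_id]
  gene_table$category <- category_map[gene_table$gene_id]
  gene_table <- gene_table[!is.na(gene_table$category), , drop = FALSE]
  genome_ids <- unique(gene_table$genome_id)
  N <- length(genome_ids)
  grid <- unique(c(1L, seq.int(step, N, by = step), N))
  grid <- grid[grid >= 1L & grid <= N]
  cats <- sort(unique(gene_table$category))
  rows <- list()
  with_seed(child_seed(seed, "accumulation"), {
    for (n in grid) {
      counts <- matrix(0, nrow = reps, ncol = length(cats))
      for (r in seq_len(reps)) {
        sampled <- sample(genome_ids, n)
        sub <- gene_table[gene_table$genome_id %in% sampled, , drop = FALSE]
        counts[r, ] <- vapply(cats, function(ct) {
          length(unique(sub$cluster[sub$category == ct]))
        }, numeric(1))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        n_genomes = n, category = cats, mean_clusters = colMeans(counts),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cluster genome occupancy with accessory/core flags
#'
#' Counts the distinct genomes encoding at least one member of each
#' cluster. Clusters in five or fewer genomes are flagged accessory;
#' clusters present in every genome are flagged core.
#'
#' @param gene_table data.frame `gene_id`, `genome_id`.
#' @param cluster_map named character vector gene_id -> cluster.
#' @return data.frame `cluster_id`, `n_genomes`, `accessory`, `core`.
#' @export
occupancy_histogram <- function(gene_table, cluster_map) {
  gene_table$cluster <- cluster_map[gene_table$gene_id]
  total <- length(unique(gene_table$genome_id))
  occ <- vapply(split(gene_table$genome_id, gene_table$cluster),
                function(g) length(unique(g)), numeric(1))
  data.frame(cluster_id = names(occ), n_genomes = as.integer(occ),
             accessory = occ <= 5L, core = occ == total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Experimental validation rate as a function of TU log-odds
#'
#' For each TU, the local validation rate is the mean outcome over all
#' TUs within `half_window` log-odds (boundary inclusive; each TU's
#' window contains at least itself). Percentile 95% confidence
#' intervals come from seeded bootstrap resampling of the TUs, and the
#' Pearson correlation between log-odds and local rate is reported (NA
#' with a warning when the rate is constant).
#'
#' @param tu_log_odds numeric vector of TU log-odds.
#' @param validated logical vector of experimental outcomes.
#' @param half_window log-odds half-window (default 2).
#' @param boot_reps bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `curve` (`log_odds`, `rate`, `lo`, `hi`) and
#'   `pearson_r`.
#' @export
validation_rate_curve <- function(tu_log_odds, validated, half_window = 2,
                                  boot_reps = 1000L, seed = 1L) {
  n <- length(tu_log_odds)
  if (n < 2L) stop_validation("need >= 2 TUs")
  rate_at <- function(L, lvec, vvec) {
    vapply(L, function(x) {
      w <- abs(lvec - x) <= half_window
      if (!any(w)) NA_real_ else mean(vvec[w])
    }, numeric(1))
  }
  rate <- rate_at(tu_log_odds, tu_log_odds, validated)
  boot <- with_seed(child_seed(seed, "vrate-boot"), {
    replicate(boot_reps, {
      ix <- sample.int(n, n, replace = TRUE)
      rate_at(tu_log_odds, tu_log_odds[ix], validated[ix])
    })
  })
  lo <- apply(boot, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(boot, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
  r <- if (stats::sd(rate) == 0 || stats::sd(tu_log_odds) == 0) {
    warning("validation rate is constant; correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(tu_log_odds, rate)
  }
  list(curve = data.frame(log_odds = tu_log_odds, rate = rate, lo = lo, hi = hi),
       pearson_r = r)
}
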