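# Synthetic cohort generator: seeded genomes, labels, homology graphs
# and alignment-hit tables carrying the statistical structure the
# classifier exploits in real data — defense genes with depressed GC
# content, a detectable amino-acid motif, island co-location and
# multi-gene operonic systems — so every pipeline stage is testable
# without external downloads.

AA20 <- setdiff(AA_ALPHABET, "X")

# bacterial-code (table 11) codons per amino acid, stops excluded
codons_by_aa <- function() {
  code <- Biostrings::getGeneticCode("11")
  code <- code[code != "*"]
  split(names(code), code)
}

#' Synthetic cohort configuration
#'
#' Defaults define the study conditions of the generator: modest
#' genomes with 10% defense genes shifted 0.10 below the genome GC,
#' carrying a WWHHWW amino-acid signature and co-locating in islands
#' with probability 0.6.
#'
#' @param n_genomes number of genomes.
#' @param genes_per_genome genes per genome.
#' @param genome_gc background GC fraction.
#' @param defense_fraction fraction of genes that are defensive.
#' @param defense_gc_shift additive GC shift of defense genes.
#' @param island_probability chance a defense unit is placed adjacent
#'   to an already-placed defense unit.
#' @param motif amino-acid signature inserted into defense proteins.
#' @param seed integer master seed.
#' @return list of class `shieldscan_synth_config`.
#' @export
synth_config <- function(n_genomes = 4L, genes_per_genome = 500L,
                         genome_gc = 0.52, defense_fraction = 0.10,
                         defense_gc_shift = -0.10, island_probability = 0.6,
                         motif = "WWHHWW", seed = 1L) {
  if (defense_fraction < 0 || defense_fraction > 1 ||
      island_probability < 0 || island_probability > 1) {
    stop_validation("fractions must be in [0, 1]")
  }
  if (genome_gc + defense_gc_shift <= 0 || genome_gc + defense_gc_shift >= 1) {
    stop_validation("genome_gc + defense_gc_shift must lie in (0, 1)")
  }
  if (n_genomes < 1L || genes_per_genome < 5L) {
    stop_validation("cohort too small to be meaningful")
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 genes_per_genome = as.integer(genes_per_genome),
                 genome_gc = genome_gc, defense_fraction = defense_fraction,
                 defense_gc_shift = defense_gc_shift,
                 island_probability = island_probability,
                 motif = motif, seed = as.integer(seed)),
            class = "shieldscan_synth_config")
}

# --- sequence-level helpers ------------------------------------------------

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

# per-site substitution at `rate`, first residue (start M) kept fixed
mutate_protein <- function(aa, rate = 0.10) {
  v <- strsplit(aa, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  hit <- hit[hit > 1L]
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(x) sample(setdiff(AA20, x), 1L), "")
  }
  paste(v, collapse = "")
}

insert_motif <- function(aa, motif) {
  pos <- sample(2:max(2L, nchar(aa) - 1L), 1L)
  paste0(substr(aa, 1, pos), motif, substr(aa, pos + 1L, nchar(aa)))
}

# Reverse-translate a protein so that the coding sequence's expected GC
# equals `target_gc`: codon weights are exponentially tilted in their
# GC count, with the tilt solved per sequence by uniroot.
reverse_translate_gc <- function(aa, target_gc, codon_tab = codons_by_aa()) {
  v <- strsplit(aa, "", fixed = TRUE)[[1]]
  gc_counts <- lapply(codon_tab, function(cods) {
    vapply(strsplit(cods, ""), function(x) sum(x %in% c("G", "C")), numeric(1))
  })
  counts <- table(factor(v, levels = names(codon_tab)))
  exp_gc <- function(lambda) {
    per_aa <- vapply(names(codon_tab), function(a) {
      g <- gc_counts[[a]]
      w <- exp(lambda * g)
      sum(g * w) / sum(w)
    }, numeric(1))
    sum(per_aa * as.numeric(counts)) / (3 * length(v))
  }
  lo <- -8; hi <- 8
  lambda <- if (exp_gc(lo) >= target_gc) lo
            else if (exp_gc(hi) <= target_gc) hi
            else stats::uniroot(function(l) exp_gc(l) - target_gc, c(lo, hi),
                                tol = 1e-4)$root
  # draw all codons for each amino acid in one vectorised pass
  out <- character(length(v))
  for (a in names(counts)[counts > 0]) {
    ix <- which(v == a)
    cods <- codon_tab[[a]]
    if (length(cods) == 1L) {
      out[ix] <- cods
    } else {
      w <- exp(lambda * gc_counts[[a]])
      out[ix] <- sample(cods, length(ix), replace = TRUE, prob = w / sum(w))
    }
  }
  paste(out, collapse = "")
}

random_nt <- function(len, gc) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# --- cohort generation -----------------------------------------------------

#' Generate a synthetic cohort
#'
#' Produces seeded, deterministic genomes with planted defense signals,
#' plus the tabular artifacts the pipeline consumes: a label table, a
#' homology-pair list (paralog families simulated by copy-with-mutation
#' at 10% per-site substitution), a system/instance map, and a protein
#' cluster map from [reduce_redundancy()].
#'
#' @param config a [synth_config()].
#' @param cluster compute the cluster map (set `FALSE` to skip the
#'   clustering pass when a test does not need it).
#' @return list of class `shieldscan_cohort`: `genomes`, `labels`,
#'   `cluster_map`, `edges`, `systems`, `gene_meta`, `config`.
#' @export
generate_cohort <- function(config = synth_config(), cluster = TRUE) {
  stopifnot(inherits(config, "shieldscan_synth_config"))
  codon_tab <- codons_by_aa()
  ctl_gc <- config$genome_gc
  def_gc <- config$genome_gc + config$defense_gc_shift

  cohort <- with_seed(child_seed(config$seed, "cohort"), {
    n_total <- config$n_genomes * config$genes_per_genome
    n_def_total <- round(n_total * config$defense_fraction)

    # defense systems: 1-3 single-protein families each, with a planted motif
    n_systems <- max(2L, round(n_def_total / 5))
    sys_sizes <- sample(1:3, n_systems, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2))
    fam_anc <- list(); fam_sys <- character(0)
    for (s in seq_len(n_systems)) {
      for (j in seq_len(sys_sizes[s])) {
        fid <- sprintf("dfam_s%03d_%d", s, j)
        fam_anc[[fid]] <- insert_motif(random_protein(sample(60:160, 1L)),
                                       config$motif)
        fam_sys[fid] <- sprintf("sys%03d", s)
      }
    }
    sys_fams <- split(names(fam_sys), fam_sys)

    # control paralog families
    n_ctrl_total <- n_total - n_def_total
    n_cfam <- max(2L, round(n_ctrl_total * 0.3 / 2.5))
    cfam_anc <- stats::setNames(
      lapply(seq_len(n_cfam), function(i) random_protein(sample(60:160, 1L))),
      sprintf("cfam%04d", seq_len(n_cfam)))

    genomes <- vector("list", config$n_genomes)
    meta <- list(); labels <- list(); systems <- list()
    inst_counter <- 0L
    for (gi in seq_len(config$n_genomes)) {
      gid <- sprintf("g%02d", gi)
      def_quota <- round(config$genes_per_genome * config$defense_fraction)

      # assemble defense instances until the quota is met
      units <- list()   # each unit: list(genes = data.frame rows)
      n_def <- 0L
      while (n_def < def_quota) {
        remaining <- def_quota - n_def
        ok_sys <- which(sys_sizes <= remaining)
        s <- if (length(ok_sys)) sample(rep(ok_sys, 2L), 1L) else which.min(sys_sizes)
        inst_counter <- inst_counter + 1L
        inst_id <- sprintf("inst%05d", inst_counter)
        fams <- sys_fams[[sprintf("sys%03d", s)]]
        rows <- lapply(fams, function(fid) {
          aa <- mutate_protein(fam_anc[[fid]])
          list(aa = aa, family = fid, label = "defense",
               system_id = fam_sys[[fid]], instance_id = inst_id)
        })
        units[[length(units) + 1L]] <- rows
        n_def <- n_def + length(rows)
      }

      n_ctrl <- config$genes_per_genome - n_def
      ctrl_rows <- lapply(seq_len(n_ctrl), function(i) {
        if (stats::runif(1) < 0.3) {
          fid <- sample(names(cfam_anc), 1L)
          list(aa = mutate_protein(cfam_anc[[fid]]), family = fid,
               label = "control", system_id = "", instance_id = "")
        } else {
          list(aa = random_protein(sample(60:160, 1L)), family = NA_character_,
               label = "control", system_id = "", instance_id = "")
        }
      })

      # island placement: each element of `entries` is a consecutive unit
      entries <- lapply(ctrl_rows, list)
      is_def_entry <- rep(FALSE, length(entries))
      for (u in units) {
        def_at <- which(is_def_entry)
        if (length(def_at) && stats::runif(1) < config$island_probability) {
          at <- sample(rep(def_at, 2L), 1L)   # insert right after a defense unit
        } else {
          at <- sample.int(length(entries) + 1L, 1L) - 1L
        }
        entries <- append(entries, list(u), after = at)
        is_def_entry <- append(is_def_entry, TRUE, after = at)
      }

      # strands per unit (operonic), flipping between units with p=0.25
      strands <- integer(length(entries))
      strands[1] <- sample(c(1L, -1L), 1L)
      for (e in seq_along(entries)[-1]) {
        strands[e] <- if (stats::runif(1) < 0.25) -strands[e - 1] else strands[e - 1]
      }

      genes_flat <- list()
      for (e in seq_along(entries)) {
        for (row in entries[[e]]) {
          row$strand <- strands[e]
          genes_flat[[length(genes_flat) + 1L]] <- row
        }
      }

      # reverse-translate with class-specific GC targets
      for (i in seq_along(genes_flat)) {
        target <- if (genes_flat[[i]]$label == "defense") def_gc else ctl_gc
        genes_flat[[i]]$nt <- reverse_translate_gc(genes_flat[[i]]$aa, target,
                                                   codon_tab)
      }

      # lay out two contigs
      cut <- floor(length(genes_flat) / 2)
      contig_of <- c(rep(1L, cut), rep(2L, length(genes_flat) - cut))
      contig_seqs <- c(c1 = "", c2 = "")
      names(contig_seqs) <- paste0(gid, "_c", 1:2)
      gene_rows <- list()
      for (ci in 1:2) {
        contig_name <- names(contig_seqs)[ci]
        pos <- 100L
        seq_parts <- list(random_nt(100L, config$genome_gc))
        idx <- which(contig_of == ci)
        for (k in seq_along(idx)) {
          i <- idx[k]
          nt <- genes_flat[[i]]$nt
          fwd <- if (genes_flat[[i]]$strand == -1L) reverse_complement(nt) else nt
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = sprintf("%s_%04d", gid, i), contig_id = contig_name,
            start = pos, end = pos + nchar(nt),
            strand = genes_flat[[i]]$strand, aa_seq = genes_flat[[i]]$aa,
            stringsAsFactors = FALSE)
          seq_parts[[length(seq_parts) + 1L]] <- fwd
          pos <- pos + nchar(nt)
          gap <- if (stats::runif(1) < 0.5) sample(0:30, 1L) else sample(31:300, 1L)
          if (k < length(idx)) {
            seq_parts[[length(seq_parts) + 1L]] <- random_nt(gap, config$genome_gc)
            pos <- pos + gap
          }
        }
        seq_parts[[length(seq_parts) + 1L]] <- random_nt(100L, config$genome_gc)
        contig_seqs[contig_name] <- paste(unlist(seq_parts), collapse = "")
      }
      genes_df <- do.call(rbind, gene_rows)
      genomes[[gi]] <- new_genome(gid, contig_seqs, genes_df)

      for (i in seq_along(genes_flat)) {
        gene_id <- sprintf("%s_%04d", gid, i)
        gf <- genes_flat[[i]]
        meta[[length(meta) + 1L]] <- data.frame(
          gene_id = gene_id, genome_id = gid, label = gf$label,
          family = gf$family, system_id = gf$system_id,
          instance_id = gf$instance_id, aa_seq = gf$aa,
          stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, meta)

    # label table: family ids as dedup groups; singleton controls get a
    # synthetic functional-annotation group
    singletons <- is.na(meta$family)
    n_go <- max(2L, round(sum(singletons) / 4))
    go_groups <- sprintf("go%04d", sample.int(n_go, sum(singletons), replace = TRUE))
    dedup <- meta$family
    dedup[singletons] <- go_groups
    labels <- data.frame(gene_id = meta$gene_id, label = meta$label,
                         system_id = meta$system_id, dedup_group = dedup,
                         stringsAsFactors = FALSE)

    # homology edges within each paralog family
    fam_tab <- table(meta$family)
    fam_multi <- names(fam_tab)[fam_tab >= 2]
    edges <- do.call(rbind, lapply(fam_multi, function(f) {
      m <- sort(meta$gene_id[!is.na(meta$family) & meta$family == f])
      pairs <- utils::combn(m, 2)
      data.frame(query = pairs[1, ], target = pairs[2, ], score = 50,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(edges)) edges <- data.frame(query = character(0),
                                            target = character(0), score = numeric(0))
    rownames(edges) <- NULL

    systems <- meta[meta$label == "defense", c("instance_id", "system_id", "gene_id")]
    rownames(systems) <- NULL
    list(genomes = genomes, labels = labels, edges = edges,
         systems = systems, gene_meta = meta)
  })

  cohort$cluster_map <- if (cluster) {
    rr <- reduce_redundancy(stats::setNames(cohort$gene_meta$aa_seq,
                                            cohort$gene_meta$gene_id),
                            seed = child_seed(config$seed, "clusters"))
    rr$cluster
  } else {
    cm <- ifelse(is.na(cohort$gene_meta$family), cohort$gene_meta$gene_id,
                 cohort$gene_meta$family)
    stats::setNames(cm, cohort$gene_meta$gene_id)
  }
  cohort$config <- config
  class(cohort) <- "shieldscan_cohort"
  cohort
}

#' @export
print.shieldscan_cohort <- function(x, ...) {
  cat(sprintf("<shieldscan_cohort> %d genomes, %d genes (%d defense), %d homolog pairs\n",
              length(x$genomes), nrow(x$gene_meta),
              sum(x$gene_meta$label == "defense"), nrow(x$edges)))
  invisible(x)
}

#' Generate a synthetic alignment-hit table
#'
#' Each gene's best hit is its closest paralog-family member, with a
#' bit-score proportional to sequence identity; genes in singleton
#' families receive a weak same-label pseudo-hit so every query is
#' scored. A `noise` fraction of best hits is redirected to a random
#' gene of the opposite label.
#'
#' @param cohort a `shieldscan_cohort`.
#' @param noise fraction of corrupted best hits in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame `query`, `target`, `bit_score`.
#' @export
generate_hit_table <- function(cohort, noise = 0, seed = 1L) {
  meta <- cohort$gene_meta
  fam_members <- split(meta$gene_id, meta$family)
  aa <- stats::setNames(meta$aa_seq, meta$gene_id)
  lab <- stats::setNames(meta$label, meta$gene_id)
  ident <- function(a, b) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    L <- min(length(va), length(vb))
    sum(va[seq_len(L)] == vb[seq_len(L)]) / max(length(va), length(vb))
  }
  with_seed(child_seed(seed, "hits"), {
    rows <- lapply(seq_len(nrow(meta)), function(i) {
      q <- meta$gene_id[i]
      fam <- meta$family[i]
      sibs <- if (!is.na(fam)) setdiff(fam_members[[fam]], q) else character(0)
      if (length(sibs)) {
        idents <- vapply(sibs, function(s) ident(aa[[q]], aa[[s]]), numeric(1))
        target <- sibs[which.max(idents)]
        bit <- round(2 * nchar(aa[[q]]) * max(idents))
      } else {
        same <- setdiff(meta$gene_id[meta$label == meta$label[i]], q)
        target <- sample(same, 1L)
        bit <- 25
      }
      if (noise > 0 && stats::runif(1) < noise) {
        opp <- meta$gene_id[meta$label != meta$label[i]]
        target <- sample(opp, 1L)
      }
      data.frame(query = q, target = target, bit_score = bit,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
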