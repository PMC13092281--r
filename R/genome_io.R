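# Genome parsing and tabular artifacts.
#
# Internal coordinate convention: 0-based half-open [start, end) on the
# forward strand of the contig; strand is +1/-1; nt_seq is always the
# coding strand. GenBank and GFF3 sources (1-based inclusive) are
# converted on read.

#' Construct a genome object
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Genes are sorted by (contig, start), assigned a 0-based `rank` within
#' each contig, and validated against the contig sequences.
#'
#' @param genome_id character scalar.
#' @param contig_seqs named character vector of contig nucleotide
#'   sequences.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (+1/-1), and optionally `aa_seq`
#'   (provided translations) and `nt_seq`.
#' @return an object of class `shieldscan_genome` with fields
#'   `genome_id`, `contigs` (named lengths), `contig_seqs`, `genes`
#'   (ordered data.frame incl. `nt_seq`, `aa_seq`, `rank`,
#'   `provided_translation`) and `genome_gc`.
#' @export
new_genome <- function(genome_id, contig_seqs, genes) {
  if (is.null(names(contig_seqs)) || any(!nzchar(names(contig_seqs)))) {
    stop_validation("contig_seqs must be named")
  }
  required <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(required %in% names(genes))) {
    stop_validation("genes must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop_validation("duplicate gene_id in genome '", genome_id, "'")
  }
  if (any(!genes$contig_id %in% names(contig_seqs))) {
    stop_validation("gene on unknown contig")
  }
  if (any(genes$end <= genes$start)) stop_validation("gene with end <= start")
  if (any(!genes$strand %in% c(1L, -1L))) stop_validation("strand must be +1 or -1")

  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  # rows are contig-sorted, so split() groups are contiguous and in order
  genes$rank <- unlist(lapply(split(genes$contig_id, genes$contig_id), seq_along),
                       use.names = FALSE) - 1L

  if (is.null(genes$nt_seq)) {
    genes$nt_seq <- vapply(seq_len(nrow(genes)), function(i) {
      s <- substr(contig_seqs[[genes$contig_id[i]]], genes$start[i] + 1L, genes$end[i])
      if (genes$strand[i] == -1L) reverse_complement(s) else s
    }, character(1))
  }
  if (any(nchar(genes$nt_seq) != genes$end - genes$start)) {
    stop_validation("nt_seq length disagrees with coordinates")
  }
  if (is.null(genes$provided_translation)) {
    genes$provided_translation <- !is.null(genes$aa_seq) && !anyNA(genes$aa_seq)
  }
  if (is.null(genes$aa_seq)) {
    genes$aa_seq <- vapply(genes$nt_seq, translate_cds, character(1), USE.NAMES = FALSE)
    genes$provided_translation <- FALSE
  }
  bad <- is.na(genes$aa_seq) | !nzchar(genes$aa_seq)
  if (any(bad)) {
    warning(sum(bad), " CDS(s) without a clean protein product skipped ",
            "(internal stop or too short)", call. = FALSE)
    genes <- genes[!bad, , drop = FALSE]
    genes$rank <- unlist(lapply(split(genes$contig_id, genes$contig_id), seq_along),
                         use.names = FALSE) - 1L
  }
  rownames(genes) <- NULL

  gc <- gc_fraction(paste(contig_seqs, collapse = ""))
  structure(list(
    genome_id = genome_id,
    contigs = vapply(contig_seqs, nchar, integer(1)),
    contig_seqs = contig_seqs,
    genes = genes,
    genome_gc = gc
  ), class = "shieldscan_genome")
}

#' @export
print.shieldscan_genome <- function(x, ...) {
  cat(sprintf("<shieldscan_genome> %s: %d contig(s), %d genes, GC %.3f\n",
              x$genome_id, length(x$contigs), nrow(x$genes), x$genome_gc))
  invisible(x)
}

#' Read a genome annotation into a genome object
#'
#' Parses either a GenBank flat file or a GFF3 annotation plus nucleotide
#' FASTA into an ordered set of CDS gene records. Source coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention; minus-strand `nt_seq` is the reverse complement of the
#' genomic slice. CDSs whose translation contains an internal stop and
#' compound (join) locations are skipped with a warning. GenBank
#' `/translation` qualifiers take precedence over re-translation.
#'
#' @param path GenBank file, or GFF3 file when `format = "gff_fasta"`.
#' @param format `"genbank"` or `"gff_fasta"`.
#' @param fasta nucleotide FASTA path (required for `"gff_fasta"`).
#' @param genome_id identifier; defaults to the file base name.
#' @return a `shieldscan_genome`.
#' @export
read_genome <- function(path, format = c("genbank", "gff_fasta"),
                        fasta = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("no such file: ", path)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "genbank") {
    parsed <- parse_genbank(path)
  } else {
    if (is.null(fasta)) stop_validation("gff_fasta format requires a fasta= path")
    parsed <- parse_gff_fasta(path, fasta)
  }
  new_genome(genome_id, parsed$contig_seqs, parsed$genes)
}

# --- GenBank flat file -----------------------------------------------------
# Minimal parser for LOCUS/FEATURES/ORIGIN records: simple and
# complement() CDS locations, /locus_tag, /protein_id, /translation.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    stop_format("not a GenBank flat file: ", path)
  }
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- grep("^//\\s*$", lines)
  if (length(rec_ends) < length(rec_starts)) rec_ends <- c(rec_ends, length(lines))

  contig_seqs <- character(0)
  gene_rows <- list()
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(trimws(sub("^LOCUS\\s+", "", rec[1])), "\\s+")[[1]][1]
    ori <- grep("^ORIGIN", rec)
    if (!length(ori)) stop_format("GenBank record without ORIGIN: ", locus)
    seq_lines <- rec[(ori + 1):(length(rec) - 1)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contig_seqs[locus] <- seq

    fstart <- grep("^FEATURES", rec)
    if (!length(fstart)) next
    feat <- rec[(fstart + 1):(ori - 1)]
    # feature lines start at col 6, qualifier/continuation lines at col 22
    is_key <- grepl("^ {5}\\S", feat)
    key_ix <- which(is_key)
    for (j in seq_along(key_ix)) {
      first <- feat[key_ix[j]]
      key <- sub("^\\s+", "", substr(first, 1, 20))
      key <- strsplit(key, "\\s+")[[1]][1]
      if (!identical(key, "CDS")) next
      last <- if (j < length(key_ix)) key_ix[j + 1] - 1L else length(feat)
      block <- feat[key_ix[j]:last]
      loc <- trimws(sub("^\\s+CDS\\s+", "", block[1]))
      # location may wrap onto following lines until the first qualifier
      qstart <- grep("^\\s+/", block)
      loc_end <- if (length(qstart)) qstart[1] - 1L else length(block)
      if (loc_end > 1L) loc <- paste0(loc, paste(trimws(block[2:loc_end]), collapse = ""))
      if (grepl("join|order", loc)) {
        warning("compound CDS location skipped in ", locus, call. = FALSE)
        next
      }
      strand <- if (grepl("^complement", loc)) -1L else 1L
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2) {
        warning("unparsable CDS location '", loc, "' skipped", call. = FALSE)
        next
      }
      start1 <- as.integer(nums[1]); end1 <- as.integer(nums[2])
      quals <- parse_genbank_qualifiers(block[seq.int(loc_end + 1L, length.out = max(0L, length(block) - loc_end))])
      gid <- quals[["locus_tag"]] %||% quals[["gene"]] %||% quals[["protein_id"]] %||%
        paste0(locus, "_", start1)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, contig_id = locus,
        start = start1 - 1L, end = end1, strand = strand,
        aa_seq = quals[["translation"]] %||% NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  genes <- do.call(rbind, gene_rows)
  if (is.null(genes)) genes <- data.frame(gene_id = character(0), contig_id = character(0),
                                          start = integer(0), end = integer(0),
                                          strand = integer(0), aa_seq = character(0))
  # provided translations only where present; re-translate the rest
  genes$provided_translation <- !is.na(genes$aa_seq)
  if (any(!genes$provided_translation)) {
    need <- which(!genes$provided_translation)
    for (i in need) {
      s <- substr(contig_seqs[[genes$contig_id[i]]], genes$start[i] + 1L, genes$end[i])
      if (genes$strand[i] == -1L) s <- reverse_complement(s)
      genes$aa_seq[i] <- translate_cds(s)
    }
  }
  list(contig_seqs = contig_seqs, genes = genes)
}

parse_genbank_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- paste(trimws(lines), collapse = "\n")
  # qualifiers start with /name= ; values may be quoted and span lines
  pieces <- strsplit(txt, "\n/", fixed = TRUE)[[1]]
  pieces[1] <- sub("^/", "", pieces[1])
  out <- list()
  for (p in pieces) {
    p <- gsub("\n", "", p)
    if (!grepl("=", p, fixed = TRUE)) { out[[p]] <- TRUE; next }
    name <- sub("=.*$", "", p)
    val <- sub("^[^=]*=", "", p)
    val <- gsub("^\"|\"$", "", val)
    if (name == "translation") val <- gsub("\\s", "", val)
    out[[name]] <- val
  }
  out
}

# --- GFF3 + FASTA ----------------------------------------------------------
parse_gff_fasta <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  contig_seqs <- stats::setNames(as.character(seqs), names(seqs))

  lines <- readLines(gff_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop_format("empty GFF3: ", gff_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) stop_format("malformed GFF3 line in ", gff_path)
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "CDS"
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) stop_format("no CDS features in ", gff_path)
  attr_field <- m[, 9]
  ids <- vapply(attr_field, function(a) {
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    found <- vapply(kv, function(x) if (x[1] %in% c("ID", "locus_tag")) x[2] else NA_character_, character(1))
    found <- found[!is.na(found)]
    if (length(found)) found[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(ids)) stop_format("GFF3 CDS without ID or locus_tag attribute")
  genes <- data.frame(
    gene_id = ids,
    contig_id = m[, 1],
    start = as.integer(m[, 4]) - 1L,   # 1-based inclusive -> 0-based half-open
    end = as.integer(m[, 5]),
    strand = ifelse(m[, 7] == "-", -1L, 1L),
    stringsAsFactors = FALSE
  )
  list(contig_seqs = contig_seqs, genes = genes)
}

# --- writers ---------------------------------------------------------------

#' Write a genome as a GenBank flat file
#' @param genome a `shieldscan_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (contig in names(genome$contig_seqs)) {
    seq <- genome$contig_seqs[[contig]]
    writeLines(sprintf("LOCUS       %-17s %d bp    DNA     linear   BCT 01-JAN-2026",
                       contig, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s synthetic contig.", genome$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    g <- genome$genes[genome$genes$contig_id == contig, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == -1L) loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id[i]), con)
      tr <- g$aa_seq[i]
      chunks <- substring(tr, seq(1, nchar(tr), 44), pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
      writeLines(paste0("                     /translation=\"", chunks[1],
                        if (length(chunks) == 1) "\"" else ""), con)
      if (length(chunks) > 1) {
        for (k in 2:length(chunks)) {
          writeLines(paste0("                     ", chunks[k],
                            if (k == length(chunks)) "\"" else ""), con)
        }
      }
    }
    writeLines("ORIGIN", con)
    lower <- tolower(seq)
    starts <- seq(1, nchar(lower), 60)
    for (s in starts) {
      chunk <- substr(lower, s, min(s + 59, nchar(lower)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
      writeLines(sprintf("%9d %s", s, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a genome as GFF3 + FASTA
#' @param genome a `shieldscan_genome`.
#' @param gff_path,fasta_path output files.
#' @return `gff_path`, invisibly.
#' @export
write_gff_fasta <- function(genome, gff_path, fasta_path) {
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tshieldscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     g$contig_id, g$start + 1L, g$end,
                     ifelse(g$strand == -1L, "-", "+"), g$gene_id))
  writeLines(lines, gff_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome$contig_seqs)), fasta_path)
  invisible(gff_path)
}

# --- label tables ----------------------------------------------------------

#' Read a gene label table
#'
#' TSV with required columns `gene_id` and `label`
#' (defense/control/unlabeled) and optional `system_id` and
#' `dedup_group`. Labels typically come from an external
#' defense-system annotation run consumed as a table.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene_id`, `label`, `system_id`,
#'   `dedup_group` (missing optional values are `""`).
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "label") %in% names(df))) {
    stop_validation("label table needs columns gene_id, label")
  }
  ok <- c("defense", "control", "unlabeled")
  if (nrow(df) && any(!df$label %in% ok)) {
    stop_validation("label outside {defense, control, unlabeled}: ",
                    paste(unique(setdiff(df$label, ok)), collapse = ", "))
  }
  df$system_id <- if (is.null(df$system_id)) rep("", nrow(df)) else ifelse(is.na(df$system_id), "", df$system_id)
  df$dedup_group <- if (is.null(df$dedup_group)) rep("", nrow(df)) else ifelse(is.na(df$dedup_group), "", df$dedup_group)
  df[c("gene_id", "label", "system_id", "dedup_group")]
}

#' Write a gene label table
#' @param labels data.frame as returned by [read_label_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- prediction tables -----------------------------------------------------

#' Write per-gene predictions as TSV
#'
#' Columns: genome_id, gene_id, contig_id, start, end, strand,
#' probability, log_odds; rows in genomic order; probability printed with
#' enough digits to round-trip.
#'
#' @param records data.frame with at least `gene_id` and `probability`;
#'   positional columns are filled from `genome` when given.
#' @param path output TSV.
#' @param genome optional `shieldscan_genome` supplying coordinates.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path, genome = NULL) {
  cols <- c("genome_id", "gene_id", "contig_id", "start", "end", "strand",
            "probability", "log_odds")
  if (!is.null(genome)) {
    g <- genome$genes
    m <- match(records$gene_id, g$gene_id)
    records$genome_id <- genome$genome_id
    records$contig_id <- g$contig_id[m]
    records$start <- g$start[m]
    records$end <- g$end[m]
    records$strand <- g$strand[m]
    records <- records[order(records$contig_id, records$start), , drop = FALSE]
  }
  for (nm in cols) if (is.null(records[[nm]])) records[[nm]] <- rep(NA, nrow(records))
  records$log_odds <- log_odds(records$probability)
  out <- records[cols]
  out$probability <- formatC(out$probability, digits = 9, format = "g")
  out$log_odds <- formatC(out$log_odds, digits = 9, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#' @param path TSV file.
#' @return data.frame with numeric `probability` and `log_odds`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$probability <- as.numeric(df$probability)
  df$log_odds <- as.numeric(df$log_odds)
  df
}
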