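# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a reproducible child seed from a parent seed and a stream label;
# kept below 2^31 so it is a valid R integer
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("shieldscan_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("shieldscan_format_error", "error")))
}

stop_lookup <- function(...) {
  stop(errorCondition(paste0(...), class = c("shieldscan_lookup_error", "error")))
}

#' Log-odds transform of a probability
#'
#' `log_odds(p) = ln(p / (1 - p))`, with `p` clamped to
#' `[1e-9, 1 - 1e-9]` beforehand so saturated tree probabilities stay
#' finite. A probability of 0.98 gives `ln(49) ~= 3.89`, the stringent
#' "log-odds 4" reporting cutoff.
#'
#' @param p numeric vector of probabilities in `(0, 1)`.
#' @return numeric vector of log-odds, always finite.
#' @examples
#' log_odds(0.5)   # 0
#' log_odds(0.98)  # ~3.89
#' @export
log_odds <- function(p) {
  if (!is.numeric(p)) stop_validation("p must be numeric")
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  log(p / (1 - p))
}

# translate a coding-strand CDS with the bacterial code (table 11),
# dropping a trailing stop. Returns NA_character_ if the CDS contains an
# internal stop (pseudogene policy: skip).
translate_cds <- function(nt_seq) {
  if (nchar(nt_seq) < 3L) return(NA_character_)
  usable <- nchar(nt_seq) - (nchar(nt_seq) %% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt_seq, 1L, usable)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"
  ))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE) || !nzchar(aa)) return(NA_character_)
  aa
}

reverse_complement <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# GC fraction of a nucleotide string, Ns excluded from both numerator and
# denominator
gc_fraction <- function(nt) {
  v <- strsplit(toupper(nt), "", fixed = TRUE)[[1]]
  acgt <- v %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  sum(v %in% c("G", "C")) / sum(acgt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
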