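# Karlin-Altschul significance: bit scores and E-values as in BLAST.

#' Bit score from a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param raw raw score in substitution-matrix units.
#' @param params a [karlin_params()].
#' @return bit score.
#' @examples
#' bit_score(100, karlin_params("gapped"))
#' @export
bit_score <- function(raw, params = karlin_params("gapped")) {
  stopifnot(is.finite(raw))
  (params$lambda * raw - log(params$K)) / log(2)
}

# expected HSP length correction: l = ln(K m n) / H, the standard
# edge-effect adjustment; effective lengths never drop below 1
effective_lengths <- function(query_len, db_len, n_seqs, params) {
  l <- log(params$K * query_len * db_len) / params$H
  m_eff <- max(query_len - l, 1)
  n_eff <- max(db_len - n_seqs * l, 1)
  c(m = m_eff, n = n_eff)
}

#' E-value of a hit
#'
#' `E = m' * n' * 2^(-S')` with effective lengths `m'`, `n'` after the
#' standard expected-HSP-length edge correction (`correction = FALSE`
#' uses the plain search-space product `m * n`).
#'
#' @param bits bit score.
#' @param query_len query length (residues of the searched peptide frame).
#' @param db_len total residue count of the database (20-aa space).
#' @param n_seqs number of database sequences (used by the correction).
#' @param params a [karlin_params()].
#' @param correction apply the edge-effect length correction?
#' @return expected number of chance hits at this score.
#' @examples
#' evalue(30, 1000, 1000, correction = FALSE)  # 1e6 * 2^-30
#' @export
evalue <- function(bits, query_len, db_len, n_seqs = 1L,
                   params = karlin_params("gapped"), correction = TRUE) {
  stopifnot(query_len >= 1, db_len >= 1)
  if (correction) {
    eff <- effective_lengths(query_len, db_len, n_seqs, params)
    eff[["m"]] * eff[["n"]] * 2^(-bits)
  } else {
    query_len * db_len * 2^(-bits)
  }
}

#' Filter and rank hits
#'
#' Keeps hits at or below the E-value cutoff, sorts by ascending E-value,
#' then descending bit score, then subject id (a total order, so output is
#' deterministic), and truncates to `max_hits`.
#'
#' @param hits data.frame with at least `evalue`, `bitscore`, `sseqid`.
#' @param evalue_cutoff maximum E-value (default 10).
#' @param max_hits maximum hits retained (default 100).
#' @return the filtered, ordered data.frame.
#' @export
filter_hits <- function(hits, evalue_cutoff = 10, max_hits = 100) {
  stopifnot(max_hits >= 1, evalue_cutoff > 0)
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$evalue, -hits$bitscore, hits$sseqid)
  head(hits[ord, , drop = FALSE], max_hits)
}
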