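# Seed detection: flexible-length maximal exact matches in reduced space
# (minimum length 6-9 chosen per query position from database 6-mer
# frequencies), plus long single-mismatch seeds.

#' Adaptive minimum seed length at a query position
#'
#' The minimum seed length starting at a query position is chosen from the
#' database frequency of the reduced 6-mer at that position: rare 6-mers
#' seed at length 6; frequent 6-mers are lengthened one symbol at a time —
#' multiplying the running expected frequency by the database composition
#' of each successive query symbol — until the expected frequency falls to
#' the database median, capped at length 9. Lengthening also stops at the
#' query end. This keeps the seed pool from being dominated by matches
#' between a few extremely frequent words.
#'
#' @param index a `seed_index`.
#' @param reduced_query reduced-alphabet query string (see
#'   [reduce_sequence()]).
#' @param pos 1-based query position; `pos + 5` must not exceed the query
#'   length.
#' @return integer minimum seed length in 6..9.
#' @export
min_seed_length <- function(index, reduced_query, pos) {
  qlen <- nchar(reduced_query)
  stopifnot(pos >= 1, pos + 5 <= qlen)
  word <- substr(reduced_query, pos, pos + 5L)
  f <- index$hexamer_counts[word]
  f <- if (is.na(f)) 0 else as.numeric(f)
  nxt <- if (pos + 6L <= qlen)
    index$composition[strsplit(substr(reduced_query, pos + 6L, qlen),
                               "")[[1]]] else numeric(0)
  nxt[is.na(nxt)] <- 0  # symbols absent from the database
  min_seed_length_core(f, index$median_hexamer_freq, nxt)
}

#' Minimum-seed-length rule on explicit frequencies
#'
#' The decision rule of [min_seed_length()] exposed directly on a 6-mer
#' frequency, a median frequency, and the compositions of the candidate
#' lengthening symbols, for sweeps and property checks.
#'
#' @param hexamer_freq database count of the query position's 6-mer.
#' @param median_freq median database count over distinct observed 6-mers.
#' @param comps numeric vector of composition values (frequencies in
#'   \[0, 1\]) of the query symbols following the 6-mer, in order; may be
#'   shorter than 3 when the query ends.
#' @return integer in 6..9.
#' @export
min_seed_length_core <- function(hexamer_freq, median_freq, comps) {
  minseed <- 6L
  expectF <- as.numeric(hexamer_freq)
  if (expectF > median_freq) {
    addlen <- 0L
    while (expectF > median_freq && addlen < 3L &&
           addlen < length(comps)) {
      addlen <- addlen + 1L
      expectF <- expectF * comps[addlen]
    }
    minseed <- minseed + addlen
  }
  minseed
}

min_seed_lengths <- function(index, reduced_query) {
  qlen <- nchar(reduced_query)
  if (qlen < 6L) return(integer(0))
  vapply(seq_len(qlen - 5L), function(p)
    min_seed_length(index, reduced_query, p), integer(1))
}

#' Find maximal exact match seeds for a query
#'
#' For every query position, every database position whose suffix shares a
#' common prefix of at least the position's minimum seed length (6-9; see
#' [min_seed_length()]) with the query suffix is reported at the full
#' (maximal) match length, by binary search over the suffix array of the
#' reduced database text. Matches wholly contained in a longer reported
#' match on the same diagonal are suppressed. Wildcard symbols never match.
#'
#' @param index a `seed_index`.
#' @param reduced_query reduced-alphabet query string of length >= 6.
#' @return A data.frame of seeds: `query_pos`, `record` (database record
#'   index), `subject_pos` (1-based within the record), `length`,
#'   `mismatch_pos` (NA for exact seeds).
#' @export
find_mems <- function(index, reduced_query) {
  stopifnot(inherits(index, "seed_index"), nchar(reduced_query) >= 6)
  q <- encode_reduced_query(index$alphabet, reduced_query)
  ml <- min_seed_lengths(index, reduced_query)
  res <- sa_mems_cpp(index$text_codes, index$suffix_array, q, ml)
  seeds_to_records(index, res, mismatch = FALSE)
}

#' Find long single-mismatch seeds
#'
#' Length-10 seeds allowing exactly one mismatch at the 4th-7th seed
#' column: the query symbol at each such column is replaced by every other
#' reduced symbol in turn and the modified word is searched exactly in the
#' suffix array, so the database symbol at the substituted column always
#' differs from the query's (exact matches are never re-reported as
#' mismatch seeds). Matches are extended forward maximally past the
#' 10-symbol window. Windows containing wildcards are skipped.
#'
#' @inheritParams find_mems
#' @return A data.frame as in [find_mems()], with `mismatch_pos` the
#'   1-based column of the mismatch within the seed (4..7).
#' @export
find_mismatch_seeds <- function(index, reduced_query) {
  stopifnot(inherits(index, "seed_index"), nchar(reduced_query) >= 10)
  q <- encode_reduced_query(index$alphabet, reduced_query)
  res <- sa_mismatch_seeds_cpp(index$text_codes, index$suffix_array, q,
                               index$alphabet$n_symbols)
  seeds_to_records(index, res, mismatch = TRUE)
}

encode_reduced_query <- function(alphabet, reduced_query) {
  ch <- strsplit(reduced_query, "")[[1]]
  v <- match(ch, alphabet$symbols)
  v[is.na(v)] <- 0L  # wildcards: match nothing
  as.numeric(v)
}

seeds_to_records <- function(index, res, mismatch) {
  data.frame(
    query_pos = res$qpos,
    record = index$rec_of[res$tpos],
    subject_pos = index$loc_of[res$tpos],
    length = res$len,
    mismatch_pos = if (mismatch) res$mismatch_pos
                   else rep(NA_integer_, nrow(res)))
}
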