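# Seed extension in the original 20-letter alphabet: X-drop ungapped
# extension of a seed, then affine-gap X-drop extension from an anchor,
# following the seed-extension strategy of BLAST.

#' Ungapped X-drop extension of a seed
#'
#' Extends the seed left and right on its diagonal without gaps; each
#' direction stops once the running score drops more than `xdrop` below
#' the running maximum. The seed itself is always retained, so the result
#' is the maximal-scoring ungapped segment containing the seed (exactly
#' so when `xdrop = Inf`).
#'
#' @param query20,subject20 amino-acid strings (may contain X and `*`).
#' @param seed a list or one-row data.frame with `query_pos`,
#'   `subject_pos`, `length` (1-based, as returned by [find_mems()] after
#'   record lookup).
#' @param scheme a [scoring_scheme()].
#' @param xdrop X-drop margin in raw score units (default: the scheme's
#'   ungapped margin); `Inf` disables the heuristic.
#' @return A list with `qstart`, `qend`, `sstart`, `send` (1-based
#'   inclusive), `score`, and `anchor` (query, subject position of the
#'   highest-scoring column, used to anchor gapped extension).
#' @export
ungapped_extend <- function(query20, subject20, seed, scheme,
                            xdrop = scheme$xdrop_ungapped) {
  ungapped_extend_codes(encode_aa(query20), encode_aa(subject20), seed,
                        scheme, xdrop)
}

ungapped_extend_codes <- function(q, s, seed, scheme,
                                  xdrop = scheme$xdrop_ungapped) {
  stopifnot(seed$query_pos >= 1, seed$subject_pos >= 1,
            seed$query_pos + seed$length - 1 <= length(q),
            seed$subject_pos + seed$length - 1 <= length(s))
  v <- ungapped_extend_cpp(q, s, seed$query_pos, seed$subject_pos,
                           seed$length, scheme$matrix, xdrop)
  list(qstart = v[1], qend = v[2], sstart = v[3], send = v[4],
       score = v[5], anchor = c(query = v[6],
                                subject = seed$subject_pos +
                                  (v[6] - seed$query_pos)))
}

#' Gapped X-drop extension from an anchor
#'
#' Affine-gap dynamic programming outward from an anchor column in both
#' directions, abandoning cells whose score falls more than `xdrop` below
#' the best seen; the two half-alignments are stitched through the anchor.
#' With `xdrop = Inf` and an anchor lying on an optimal local alignment
#' path the result attains the Smith-Waterman local score.
#'
#' @param anchor length-2 vector `(query_pos, subject_pos)`, 1-based; the
#'   anchor column is always aligned.
#' @inheritParams ungapped_extend
#' @param xdrop raw-unit margin (default: the scheme's gapped margin).
#' @return An `alignment` list: coordinates (1-based inclusive),
#'   `raw_score`, gapped `aligned_query` / `aligned_subject` strings,
#'   `identities`, `mismatches`, `gap_openings`, `length` (columns).
#' @export
gapped_extend <- function(query20, subject20, anchor, scheme,
                          xdrop = scheme$xdrop_gapped) {
  gapped_extend_codes(encode_aa(query20), encode_aa(subject20), anchor,
                      scheme, xdrop)
}

gapped_extend_codes <- function(q, s, anchor, scheme,
                                xdrop = scheme$xdrop_gapped) {
  stopifnot(length(anchor) >= 2, anchor[1] >= 1, anchor[1] <= length(q),
            anchor[2] >= 1, anchor[2] <= length(s))
  r <- gapped_extend_cpp(q, s, as.integer(anchor[1]), as.integer(anchor[2]),
                         scheme$matrix, scheme$gap_open, scheme$gap_extend,
                         xdrop)
  alignment_from_codes(r$qaln, r$saln, r$qstart, r$qend, r$sstart, r$send,
                       r$score)
}

alignment_from_codes <- function(qaln, saln, qstart, qend, sstart, send,
                                 score) {
  qgap <- qaln == 0L
  sgap <- saln == 0L
  aligned <- !qgap & !sgap
  ident <- sum(aligned & qaln == saln)
  gap_open <- count_gap_openings(qgap) + count_gap_openings(sgap)
  structure(list(
    qstart = qstart, qend = qend, sstart = sstart, send = send,
    raw_score = score,
    aligned_query = decode_aa(qaln),
    aligned_subject = decode_aa(saln),
    identities = ident,
    mismatches = sum(aligned) - ident,
    gap_openings = gap_open,
    length = length(qaln)
  ), class = "alignment")
}

count_gap_openings <- function(gap) {
  if (!length(gap)) return(0L)
  sum(gap & !c(FALSE, gap[-length(gap)]))
}

#' Recompute an alignment's raw score from its aligned strings
#'
#' Sums substitution scores over aligned columns and affine penalties over
#' gap runs; every emitted alignment's `raw_score` must re-derive exactly
#' this way.
#'
#' @param alignment an `alignment`.
#' @param scheme a [scoring_scheme()].
#' @return numeric raw score.
#' @export
rescore_alignment <- function(alignment, scheme) {
  qa <- strsplit(alignment$aligned_query, "")[[1]]
  sa <- strsplit(alignment$aligned_subject, "")[[1]]
  stopifnot(length(qa) == length(sa))
  qgap <- qa == "-"
  sgap <- sa == "-"
  score <- 0
  for (i in seq_along(qa)) {
    if (!qgap[i] && !sgap[i])
      score <- score + scheme$matrix[qa[i], sa[i]]
  }
  for (gp in list(qgap, sgap)) {
    r <- rle(gp)
    glens <- r$lengths[r$values]
    score <- score - sum(scheme$gap_open + glens * scheme$gap_extend)
  }
  score
}

# ungapped alignment object for segments that never trigger gapped
# extension
ungapped_alignment <- function(q, s, ext) {
  alignment_from_codes(q[ext$qstart:ext$qend], s[ext$sstart:ext$send],
                       ext$qstart, ext$qend, ext$sstart, ext$send,
                       ext$score)
}

#' Extend all seeds of one query against one subject record
#'
#' Runs the two-stage extension used by the search pipeline: ungapped
#' X-drop extension of every seed (longest seeds first), gapped extension
#' from the best ungapped column when the ungapped score reaches the
#' trigger. A seed falling inside the query and subject span of an
#' alignment already produced for this record is not re-extended, and
#' duplicate alignments (identical coordinates) are dropped.
#'
#' @param query20 query peptide (possibly masked).
#' @param subject20 subject record sequence.
#' @param seeds data.frame with `query_pos`, `subject_pos`, `length` rows
#'   for this record.
#' @param scheme a [scoring_scheme()].
#' @return list of `alignment` objects.
#' @export
extend_seeds <- function(query20, subject20, seeds, scheme) {
  if (nrow(seeds) == 0L) return(list())
  qc <- if (is.character(query20)) encode_aa(query20) else query20
  sc <- if (is.character(subject20)) encode_aa(subject20) else subject20
  ord <- order(-seeds$length)
  qp <- seeds$query_pos[ord]
  sp <- seeds$subject_pos[ord]
  ln <- seeds$length[ord]
  alns <- list()
  for (i in seq_along(qp)) {
    sd <- list(query_pos = qp[i], subject_pos = sp[i], length = ln[i])
    covered <- any(vapply(alns, function(a)
      sd$query_pos >= a$qstart &&
        sd$query_pos + sd$length - 1 <= a$qend &&
        sd$subject_pos >= a$sstart &&
        sd$subject_pos + sd$length - 1 <= a$send, logical(1)))
    if (covered) next
    ext <- ungapped_extend_codes(qc, sc, sd, scheme)
    aln <- if (ext$score >= scheme$ungapped_trigger)
      gapped_extend_codes(qc, sc, ext$anchor, scheme)
    else
      ungapped_alignment(qc, sc, ext)
    dup <- any(vapply(alns, function(a)
      a$qstart == aln$qstart && a$qend == aln$qend &&
        a$sstart == aln$sstart && a$send == aln$send, logical(1)))
    if (!dup) alns[[length(alns) + 1L]] <- aln
  }
  alns
}
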