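# Query preparation: six-frame translation of nucleotide reads (with a
# coordinate map back to the read) and SEG-style low-complexity masking.

#' Translate a nucleotide read in all six frames
#'
#' Standard genetic code (translation table 1); stop codons translate to
#' `*` (kept in the frame — extension is blocked by their strongly
#' negative scores), codons containing an ambiguous base translate to `X`.
#' Frames -1..-3 translate the reverse complement. Each frame carries a
#' coordinate map back to the read (see [frame_to_read_coords()]).
#'
#' @param read DNA string over A/C/G/T/N (other IUPAC codes are treated
#'   as N); length >= 3 for any usable frame.
#' @param read_id identifier carried through to hits.
#' @return A list of `query_frame` objects (fields `read_id`, `frame`,
#'   `peptide`, `read_len`); empty (with a warning) for reads shorter
#'   than 3 nt.
#' @export
translate_six_frames <- function(read, read_id = "read") {
  read <- toupper(read)
  read <- gsub("[^ACGT]", "N", read)
  n <- nchar(read)
  if (n < 3) {
    warning("read '", read_id, "' shorter than 3 nt; no usable frame")
    return(list())
  }
  fwd <- Biostrings::DNAString(read)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (f in 1:3) {
    for (strand in c(1L, -1L)) {
      src <- if (strand == 1L) fwd else rev
      plen <- (n - f + 1L) %/% 3L
      if (plen < 1L) next
      sub <- Biostrings::subseq(src, f, f + 3L * plen - 1L)
      pep <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                                no.init.codon = TRUE))
      out[[length(out) + 1L]] <- structure(
        list(read_id = read_id, frame = strand * f, peptide = pep,
             read_len = n),
        class = "query_frame")
    }
  }
  out
}

#' Map peptide coordinates on a frame back to read coordinates
#'
#' For plus frames the returned nucleotide range runs forward; for minus
#' frames it runs backward (`start > end`), the translated-search output
#' convention.
#'
#' @param frame a `query_frame`.
#' @param pep_start,pep_end 1-based peptide positions.
#' @return integer vector `(start, end)` of 1-based read coordinates.
#' @export
frame_to_read_coords <- function(frame, pep_start, pep_end) {
  f <- abs(frame$frame)
  n <- frame$read_len
  nt_start <- f + 3L * (pep_start - 1L)
  nt_end <- f + 3L * pep_end - 1L
  if (frame$frame > 0) c(start = nt_start, end = nt_end)
  else c(start = n - nt_start + 1L, end = n - nt_end + 1L)
}

# Shannon entropy (bits) of the residue composition of a window.
# Wildcards (X, *) each count as a distinct unique symbol: splitting mass
# into singletons can only raise entropy (Schur concavity), which makes
# masking idempotent — residues masked to X can never pull a neighbouring
# window below the cutoffs on a second pass.
window_entropy <- function(ch) {
  wild <- ch %in% c("X", "*")
  cnt <- c(as.numeric(table(ch[!wild])), rep(1, sum(wild)))
  p <- cnt / length(ch)
  -sum(p * log2(p))
}

#' SEG-style low-complexity masking
#'
#' Single-pass Wootton-Federhen-style masking: the compositional entropy
#' (bits) of every sliding window is computed; runs of windows below the
#' trigger entropy, extended over adjacent windows below the higher
#' extension entropy, are masked (every residue covered by such a window
#' becomes `X`). Masked residues can never seed and score at most 0, so
#' compositionally biased runs cannot produce spurious hits. Masking is
#' idempotent; the caller keeps the original peptide for display.
#'
#' @param peptide amino-acid string (may contain `*`/X).
#' @param window window width in residues (>= 2).
#' @param low_cut trigger entropy in bits.
#' @param high_cut extension entropy in bits.
#' @return the peptide with masked residues replaced by `X`.
#' @examples
#' mask_low_complexity(strrep("A", 20))
#' @export
mask_low_complexity <- function(peptide, window = 12, low_cut = 2.2,
                                high_cut = 2.5) {
  stopifnot(window >= 2)
  n <- nchar(peptide)
  if (n == 0L) return(peptide)
  ch <- strsplit(peptide, "")[[1]]
  w <- min(window, n)
  starts <- seq_len(n - w + 1L)
  ent <- vapply(starts, function(i) window_entropy(ch[i:(i + w - 1L)]),
                numeric(1))
  low <- ent < low_cut
  high <- ent < high_cut
  if (!any(low)) return(peptide)
  # maximal runs of consecutive high-flagged windows containing >= 1
  # low-flagged window
  mask <- logical(n)
  r <- rle(high)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    ws <- idx_start[k]:idx_end[k]
    if (!any(low[ws])) next
    mask[ws[1]:(ws[length(ws)] + w - 1L)] <- TRUE
  }
  ch[mask & ch != "*"] <- "X"
  paste(ch, collapse = "")
}

#' Read query sequences (FASTA or FASTQ)
#'
#' Qualities of FASTQ input are ignored. Sequence type can be forced or
#' auto-detected (sequences composed at least 90% of A/C/G/T/N are taken
#' as nucleotide).
#'
#' @param path input file.
#' @param type `"auto"`, `"aa"` or `"nt"`.
#' @return data.frame with columns `id`, `seq`, `type`.
#' @export
read_queries <- function(path, type = c("auto", "aa", "nt")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  bset <- Biostrings::readBStringSet(path, format = fmt)
  if (length(bset) == 0L) stop("no query records in ", path)
  seqs <- toupper(as.character(bset))
  id <- sub("\\s.*$", "", names(bset))
  if (type == "auto") {
    acgtn <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      mean(ch %in% c("A", "C", "G", "T", "N", "U"))
    }, numeric(1))
    type <- ifelse(acgtn >= 0.9, "nt", "aa")
  } else {
    type <- rep(type, length(seqs))
  }
  data.frame(id = id, seq = unname(seqs), type = type,
             stringsAsFactors = FALSE)
}
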