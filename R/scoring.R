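# Substitution scoring and Karlin-Altschul parameters.
#
# Internally sequences are encoded as integers over the 22-letter scoring
# alphabet AA20 + X + '*' (ambiguity codes are resolved at load time), and
# the substitution matrix is indexed by those codes.

SCORE_ALPHA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Read a substitution matrix in NCBI format
#'
#' Parses the standard whitespace-separated matrix layout (comment lines
#' starting with `#`, a header row of residue letters, one labelled row per
#' residue) as shipped with BLAST.
#'
#' @param path path to the matrix file.
#' @return A symmetric numeric matrix with residue letters as dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  header <- toks[[1]]
  rows <- toks[-1]
  mat <- matrix(NA_real_, length(rows), length(header),
                dimnames = list(vapply(rows, `[`, character(1), 1), header))
  for (r in rows) mat[r[1], ] <- as.numeric(r[-1])
  if (any(is.na(mat))) stop("malformed score matrix: ", path)
  if (!isTRUE(all.equal(mat, t(mat)))) stop("score matrix is not symmetric")
  mat
}

#' The BLOSUM62 substitution matrix
#'
#' Parsed from the NCBI-format copy shipped under `extdata/BLOSUM62.txt`
#' (half-bit units).
#'
#' @return numeric matrix including rows/columns for B, Z, X and `*`.
#' @export
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
                                              package = "redseek"))
    cache
  }
})

#' Karlin-Altschul parameters
#'
#' The published BLAST parameters for BLOSUM62: for gapped alignments with
#' gap open 11 / extend 1, lambda = 0.267, K = 0.041, H = 0.14; for
#' ungapped alignments lambda = 0.3176, K = 0.134, H = 0.4012. `lambda` is
#' in nats per raw-score unit, `K` dimensionless, `H` the relative entropy
#' (nats per aligned pair) used in the edge-effect length correction.
#'
#' @param source `"gapped"` or `"ungapped"`.
#' @return A `karlin_params` list with `lambda`, `K`, `H`, `source`.
#' @export
karlin_params <- function(source = c("gapped", "ungapped")) {
  source <- match.arg(source)
  p <- switch(source,
              gapped = list(lambda = 0.267, K = 0.041, H = 0.14),
              ungapped = list(lambda = 0.3176, K = 0.134, H = 0.4012))
  structure(c(p, list(source = source)), class = "karlin_params")
}

#' Build a scoring scheme for seed extension
#'
#' X-drop thresholds and the gapped-extension trigger are specified in
#' bits and converted to raw matrix units through the appropriate lambda
#' (ungapped lambda for the ungapped stage and trigger, gapped lambda for
#' the gapped stage), mirroring how BLAST parameterizes its extension
#' heuristics.
#'
#' @param matrix substitution matrix (defaults to [blosum62()]).
#' @param gap_open,gap_extend positive affine gap penalties; a gap of
#'   length g costs `gap_open + g * gap_extend`.
#' @param xdrop_ungapped_bits,xdrop_gapped_bits X-drop margins in bits.
#' @param trigger_bits ungapped score (bits) required to attempt gapped
#'   extension.
#' @return A `scoring_scheme` list; raw-unit fields `xdrop_ungapped`,
#'   `xdrop_gapped`, `ungapped_trigger` are precomputed.
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = 11,
                           gap_extend = 1, xdrop_ungapped_bits = 7,
                           xdrop_gapped_bits = 15, trigger_bits = 22) {
  stopifnot(gap_open > 0, gap_extend > 0)
  kg <- karlin_params("gapped")
  ku <- karlin_params("ungapped")
  m <- matrix[SCORE_ALPHA, SCORE_ALPHA]
  structure(list(
    matrix = m,
    gap_open = gap_open, gap_extend = gap_extend,
    xdrop_ungapped = xdrop_ungapped_bits * log(2) / ku$lambda,
    xdrop_gapped = xdrop_gapped_bits * log(2) / kg$lambda,
    ungapped_trigger = trigger_bits * log(2) / ku$lambda,
    params_gapped = kg, params_ungapped = ku
  ), class = "scoring_scheme")
}

# encode a 20-aa (+X/*) string as 1-based codes into SCORE_ALPHA;
# ambiguity codes are resolved like in reduce_sequence
encode_aa <- function(seq) {
  lut <- setNames(seq_along(SCORE_ALPHA), SCORE_ALPHA)
  lut <- c(lut, setNames(lut[ifelse(AA_AMBIG == "X", "X", AA_AMBIG)],
                         names(AA_AMBIG)))
  ch <- strsplit(toupper(seq), "")[[1]]
  codes <- lut[ch]
  if (anyNA(codes))
    stop("cannot encode residue(s): ",
         paste(unique(ch[is.na(codes)]), collapse = ", "))
  unname(codes)
}

decode_aa <- function(codes) {
  # 0 marks a gap column in alignments
  ch <- rep("-", length(codes))
  nz <- codes != 0L
  ch[nz] <- SCORE_ALPHA[codes[nz]]
  paste(ch, collapse = "")
}
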