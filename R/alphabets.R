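#' @useDynLib redseek, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rbinom rgeom runif setNames
#' @importFrom utils head read.delim
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# ambiguity codes resolved to a canonical residue (NCBI practice);
# X stays a never-matching wildcard, J (I/L) is unresolvable -> X
AA_AMBIG <- c(B = "D", Z = "E", U = "C", O = "K", J = "X")

#' Parse a reduced amino-acid alphabet from a grouping string
#'
#' A reduced (compressed) amino-acid alphabet partitions the 20 standard
#' residues into groups of chemically similar residues; homologous proteins
#' rewritten over group symbols show higher sequence identity, which is what
#' makes longer exact seed matches possible. A grouping string lists the
#' groups in order, each group either a single residue letter or a bracketed
#' run such as `"[KR]"`, e.g. the 10-letter BLOSUM-derived alphabet
#' `"A [KR] [EDNQ] C G H [ILVM] [FYW] P [ST]"`.
#'
#' @param spec grouping string (whitespace-separated tokens).
#' @param name label for the alphabet.
#' @return An object of class `reduced_alphabet` with elements `name`,
#'   `groups` (list of character vectors), `symbol_of` (named integer map
#'   residue -> group index) and `n_symbols`.
#' @examples
#' ab <- parse_alphabet("A [KR] [EDNQ] C G H [ILVM] [FYW] P [ST]", "murphy.10")
#' ab$n_symbols
#' @export
parse_alphabet <- function(spec, name = "custom") {
  stopifnot(is.character(spec), length(spec) == 1L)
  tokens <- strsplit(trimws(spec), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty alphabet specification")
  groups <- lapply(tokens, function(tok) {
    if (grepl("^\\[[A-Z]+\\]$", tok)) {
      strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]]
    } else if (grepl("^[A-Z]$", tok)) {
      tok
    } else {
      stop("malformed alphabet token: ", tok)
    }
  })
  res <- unlist(groups)
  if (anyDuplicated(res))
    stop("residue assigned to more than one group: ",
         paste(unique(res[duplicated(res)]), collapse = ", "))
  missing <- setdiff(AA20, res)
  extra <- setdiff(res, AA20)
  if (length(extra))
    stop("non-standard residues in alphabet: ", paste(extra, collapse = ", "))
  if (length(missing))
    stop("alphabet does not cover all 20 residues; missing: ",
         paste(missing, collapse = ", "))
  symbol_of <- integer(20)
  names(symbol_of) <- AA20
  for (g in seq_along(groups)) symbol_of[groups[[g]]] <- g
  # each group is written as its first residue, so a reduced string is
  # itself a valid protein string and re-reduction is the identity
  symbols <- vapply(groups, `[`, character(1), 1)
  structure(list(name = name, groups = groups, symbol_of = symbol_of,
                 symbols = symbols, n_symbols = length(groups)),
            class = "reduced_alphabet")
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  grp <- vapply(x$groups, function(g)
    if (length(g) == 1L) g else paste0("[", paste(g, collapse = ""), "]"),
    character(1))
  cat("Reduced amino-acid alphabet '", x$name, "' (", x$n_symbols,
      " symbols)\n  ", paste(grp, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Built-in reduced alphabets
#'
#' Returns the registry of reduced amino-acid alphabets shipped with the
#' package (a tab-separated table under `extdata/alphabets.tsv`), covering
#' the standard published alphabets from hydrophobic-polar-style 4/5-letter
#' schemes to the 10-letter `murphy.10` default used for seeding.
#'
#' @return A data.frame with columns `name`, `size`, `groups`.
#' @export
builtin_alphabets <- function() {
  path <- system.file("extdata", "alphabets.tsv", package = "redseek")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Look up a built-in alphabet by name
#'
#' @param name alphabet name, e.g. `"murphy.10"` (the default search
#'   alphabet) or `"all.20"` (the identity alphabet).
#' @return A `reduced_alphabet`.
#' @export
get_alphabet <- function(name) {
  reg <- builtin_alphabets()
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown alphabet '", name, "'; see builtin_alphabets()")
  ab <- parse_alphabet(reg$groups[i], name)
  stopifnot(ab$n_symbols == reg$size[i])
  ab
}

#' Rewrite a protein sequence in a reduced alphabet
#'
#' Each residue is replaced by the letter of its group (a group is written
#' as its first residue, so re-reducing a reduced string changes
#' nothing). The wildcard `X` and the stop `*` map to the dedicated
#' never-matching symbols `"X"` and `"*"`: they can never participate in a
#' seed match. Ambiguity codes are resolved first (B->D, Z->E, U->C, O->K).
#'
#' @param seq character vector of amino-acid strings.
#' @param alphabet a `reduced_alphabet`.
#' @return character vector of reduced strings, same lengths as the input.
#' @examples
#' reduce_sequence("ILVM", get_alphabet("murphy.10"))
#' @export
reduce_sequence <- function(seq, alphabet) {
  stopifnot(inherits(alphabet, "reduced_alphabet"))
  lut <- c(setNames(alphabet$symbols[alphabet$symbol_of], AA20),
           X = "X", "*" = "*")
  lut <- c(lut, setNames(ifelse(AA_AMBIG == "X", "X",
                                lut[AA_AMBIG]), names(AA_AMBIG)))
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- !(ch %in% names(lut))
    if (any(bad))
      stop("unknown residue character(s): ",
           paste(unique(ch[bad]), collapse = ", "))
    paste(lut[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# k-mer set of one reduced string, excluding any window containing a
# never-matching symbol
reduced_kmers <- function(rseq, k) {
  n <- nchar(rseq)
  if (n < k) return(character(0))
  km <- substring(rseq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  km[!grepl("[X*]", km, fixed = FALSE)]
}

pair_has_seed <- function(a, b, alphabet, seed_len) {
  ka <- reduced_kmers(reduce_sequence(a, alphabet), seed_len)
  if (!length(ka)) return(FALSE)
  kb <- reduced_kmers(reduce_sequence(b, alphabet), seed_len)
  any(ka %in% kb)
}

#' Seed coverage of an alphabet on homolog pairs
#'
#' Coverage is the fraction of sequence pairs whose reduced-alphabet
#' representations share at least one exact common substring (seed) of the
#' given length. High coverage on distant homologs is the sensitivity side
#' of a seed design.
#'
#' @param pairs a homolog pair set from [make_pair_set()] (a data.frame
#'   with columns `a` and `b`).
#' @param alphabet a `reduced_alphabet`.
#' @param seed_len seed length in residues (>= 1).
#' @return fraction in \[0, 1\].
#' @export
seed_coverage <- function(pairs, alphabet, seed_len) {
  stopifnot(seed_len >= 1, is.data.frame(pairs))
  if (nrow(pairs) == 0L) stop("empty pair set")
  hits <- mapply(pair_has_seed, pairs$a, pairs$b,
                 MoreArgs = list(alphabet = alphabet, seed_len = seed_len))
  mean(hits)
}

#' Seed efficiency of an alphabet
#'
#' Efficiency is the log10 ratio of the number of homologous pairs to the
#' number of non-homologous pairs containing at least one seed match. It is
#' the specificity side of a seed design: alphabets that are too compressed
#' seed unrelated sequences as readily as homologs. A +1 pseudocount is
#' applied to the denominator when no non-homologous pair has a seed, to
#' keep the statistic finite on small sets.
#'
#' @param hom,nonhom pair sets (see [make_pair_set()]).
#' @inheritParams seed_coverage
#' @return log10 ratio (can be `-Inf` when no homolog pair has a seed).
#' @export
seed_efficiency <- function(hom, nonhom, alphabet, seed_len) {
  stopifnot(nrow(hom) > 0L, nrow(nonhom) > 0L)
  nh <- sum(mapply(pair_has_seed, hom$a, hom$b,
                   MoreArgs = list(alphabet = alphabet, seed_len = seed_len)))
  nn <- sum(mapply(pair_has_seed, nonhom$a, nonhom$b,
                   MoreArgs = list(alphabet = alphabet, seed_len = seed_len)))
  if (nn == 0L) nn <- 1L
  log10(nh / nn)
}

#' Evaluate alphabets over a grid of seed lengths
#'
#' Runs the coverage/efficiency experiment used to choose a seeding
#' alphabet: for each alphabet and seed length, the fraction of homolog
#' pairs with at least one seed and the log ratio against non-homolog pairs.
#'
#' @param hom,nonhom pair sets.
#' @param alphabets character vector of built-in alphabet names, or a list
#'   of `reduced_alphabet` objects.
#' @param seed_lens integer vector of seed lengths.
#' @return A data.frame with columns `alphabet`, `seed_len`, `coverage`,
#'   `efficiency`, suitable for `write.table()`.
#' @export
evaluate_alphabets <- function(hom, nonhom, alphabets, seed_lens = 3:15) {
  if (is.character(alphabets)) alphabets <- lapply(alphabets, get_alphabet)
  res <- do.call(rbind, lapply(alphabets, function(ab) {
    do.call(rbind, lapply(seed_lens, function(L) {
      data.frame(alphabet = ab$name, seed_len = L,
                 coverage = seed_coverage(hom, ab, L),
                 efficiency = seed_efficiency(hom, nonhom, ab, L),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL
  res
}

#' Random seed-space ratio between two seed designs
#'
#' The expected number of random seed matches scales as the inverse of the
#' seed-space size `k^L` for an alphabet of `k` symbols and seed length
#' `L`. The ratio `(k1^L1) / (k2^L2)` compares how many random seeds one
#' design admits relative to another; e.g. length-6 seeds over 10 symbols
#' versus BLAST's length-3 seeds over 20 symbols give 10^6 / 20^3 = 125.
#'
#' @param k1,l1 alphabet size and seed length of the first design.
#' @param k2,l2 alphabet size and seed length of the second design.
#' @return the ratio `k1^l1 / k2^l2`.
#' @export
seed_space_ratio <- function(k1, l1, k2, l2) (k1^l1) / (k2^l2)
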