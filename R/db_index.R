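# Build and persist the searchable database: reduced-alphabet text with
# per-sequence sentinels, suffix array + LCP array over it, hexamer
# frequency table and median, and residue composition.

INDEX_FORMAT <- "redseek_index/1"

sanitize_residues <- function(seqs) {
  seqs <- toupper(seqs)
  seqs <- gsub("[*.\\-]", "", seqs)
  ok <- c(AA20, names(AA_AMBIG), "X")
  bad_pat <- paste0("[^", paste(ok, collapse = ""), "]")
  n_bad <- sum(vapply(gregexpr(bad_pat, seqs),
                      function(m) sum(m > 0), integer(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-residue character(s) replaced by X")
    seqs <- gsub(bad_pat, "X", seqs)
  }
  seqs
}

#' Read protein records from a FASTA file
#'
#' Sequences are uppercased; stops (`*`) and gap characters are stripped;
#' characters that are not standard residues or recognized ambiguity codes
#' are replaced by `X` with a warning; records left empty are dropped with
#' a warning.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return A data.frame of protein records (`id`, `desc`, `seq`).
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aset <- Biostrings::readAAStringSet(path)
  if (length(aset) == 0L) stop("no FASTA records in ", path)
  hdr <- names(aset)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- sanitize_residues(as.character(aset))
  keep <- nzchar(seqs)
  if (!all(keep))
    warning(sum(!keep), " record(s) empty after sanitization; dropped")
  if (!any(keep)) return(data.frame(id = character(0), desc = character(0),
                                    seq = character(0),
                                    stringsAsFactors = FALSE))
  data.frame(id = id[keep], desc = desc[keep], seq = unname(seqs[keep]),
             stringsAsFactors = FALSE)
}

#' Build a searchable index over a protein database
#'
#' The database sequences are rewritten in the reduced alphabet and
#' concatenated with one distinct sentinel symbol after each sequence
#' (sentinels sort below every group symbol and can never match, so no
#' seed crosses a sequence boundary); a suffix array and LCP array are
#' built over the concatenation. Database wildcard positions (`X`) also
#' receive distinct never-matching codes. The 6-mer frequency table of the
#' reduced text, its median (over distinct observed 6-mers), and the
#' reduced-symbol composition are precomputed for the adaptive minimum
#' seed length rule.
#'
#' @param records protein records from [load_fasta()] or
#'   [generate_protein_db()].
#' @param alphabet a `reduced_alphabet` (default `murphy.10`).
#' @return An object of class `seed_index`.
#' @export
build_index <- function(records, alphabet = get_alphabet("murphy.10")) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            inherits(alphabet, "reduced_alphabet"))
  reduced <- reduce_sequence(records$seq, alphabet)
  nrec <- length(reduced)
  lens <- nchar(reduced)
  total <- sum(lens) + nrec  # one sentinel per record
  codes <- numeric(total)
  rec_of <- integer(total)
  loc_of <- integer(total)
  kind_sent <- logical(total)
  neg <- 0
  pos <- 1L
  for (r in seq_len(nrec)) {
    ch <- strsplit(reduced[r], "")[[1]]
    v <- match(ch, alphabet$symbols)
    for (j in seq_along(ch)) {
      if (is.na(v[j])) { neg <- neg - 1; codes[pos] <- neg }  # X wildcard
      else codes[pos] <- v[j]
      rec_of[pos] <- r; loc_of[pos] <- j
      pos <- pos + 1L
    }
    neg <- neg - 1
    codes[pos] <- neg           # sentinel
    rec_of[pos] <- NA_integer_; loc_of[pos] <- NA_integer_
    kind_sent[pos] <- TRUE
    pos <- pos + 1L
  }
  sx <- build_suffix_index_cpp(codes, !kind_sent)
  # hexamer counts within records (sentinels never inside a window)
  hex <- unlist(lapply(reduced, function(s) {
    n <- nchar(s)
    if (n < 6) character(0)
    else substring(s, seq_len(n - 5L), seq_len(n - 5L) + 5L)
  }))
  hexamer_counts <- if (length(hex)) {
    tb <- table(hex)
    setNames(as.integer(tb), names(tb))
  } else integer(0)
  median_hex <- if (length(hexamer_counts))
    as.integer(floor(median(as.numeric(hexamer_counts)))) else 0L
  symbols <- unlist(strsplit(reduced, ""))
  comp_tb <- table(symbols)
  composition <- setNames(as.numeric(comp_tb) / length(symbols),
                          names(comp_tb))
  structure(list(
    format = INDEX_FORMAT,
    records = records,
    alphabet = alphabet,
    reduced = reduced,
    text_codes = codes,
    sentinel = kind_sent,
    rec_of = rec_of,
    loc_of = loc_of,
    suffix_array = sx$sa,
    lcp_array = sx$lcp,
    hexamer_counts = hexamer_counts,
    median_hexamer_freq = median_hex,
    composition = composition,
    aa_encoded = lapply(records$seq, encode_aa),
    db_residues = sum(nchar(records$seq)),
    n_records = nrec
  ), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: ", x$n_records, " sequences, ", x$db_residues,
      " residues\n  alphabet: ", x$alphabet$name,
      "; median 6-mer frequency: ", x$median_hexamer_freq, "\n", sep = "")
  invisible(x)
}

#' Persist / restore an index
#'
#' The index is written as a single serialized file carrying a format
#' version tag; loading verifies the tag and fails on truncated or foreign
#' files. A round trip reproduces every field exactly.
#'
#' @param index a `seed_index`.
#' @param path file path.
#' @return `load_index` returns the `seed_index`; `save_index` its path,
#'   invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "seed_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable index file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, INDEX_FORMAT))
    stop("not a compatible index file (expected format ", INDEX_FORMAT, ")")
  obj
}
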