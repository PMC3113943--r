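# End-to-end search: mask -> seed (exact + mismatch) -> extend -> score ->
# filter, with BLAST-style 12-column tabular output, plus the two
# tool entry points (index building and searching).

#' Search configuration
#'
#' @param evalue_cutoff report hits with E-value at or below this (default
#'   10).
#' @param max_hits at most this many hits per query (default 100).
#' @param query_type `"auto"`, `"aa"` (protein) or `"nt"` (nucleotide,
#'   translated in six frames).
#' @param alphabet reduced alphabet name used at index time (checked
#'   against the index).
#' @param mask apply SEG-style low-complexity masking to query peptides?
#' @param mismatch_seeds also use long single-mismatch seeds?
#' @param scheme a [scoring_scheme()]; override to change matrix, gap
#'   penalties or X-drop/trigger thresholds.
#' @param correction apply the E-value edge-effect length correction?
#' @param verbose print per-query progress messages?
#' @param rng_seed seed for any randomized behaviour (none in the default
#'   pipeline; kept for reproducible extensions).
#' @return A `search_config` list.
#' @export
search_config <- function(evalue_cutoff = 10, max_hits = 100,
                          query_type = c("auto", "aa", "nt"),
                          alphabet = "murphy.10", mask = TRUE,
                          mismatch_seeds = TRUE, scheme = scoring_scheme(),
                          correction = TRUE, verbose = FALSE,
                          rng_seed = NULL) {
  stopifnot(evalue_cutoff > 0, max_hits >= 1)
  structure(list(evalue_cutoff = evalue_cutoff, max_hits = max_hits,
                 query_type = match.arg(query_type), alphabet = alphabet,
                 mask = mask, mismatch_seeds = mismatch_seeds,
                 scheme = scheme, correction = correction,
                 verbose = verbose, rng_seed = rng_seed),
            class = "search_config")
}

#' Override a search configuration from a key=value file
#'
#' Recognized keys are the fields of [search_config()] that have scalar
#' values (`evalue_cutoff`, `max_hits`, `query_type`, `alphabet`, `mask`,
#' `mismatch_seeds`, `correction`, `verbose`, `rng_seed`). Values given as
#' function arguments (e.g. command-line flags) should be applied after
#' this and win over the file.
#'
#' @param config a `search_config`.
#' @param path key=value text file; lines starting with `#` are ignored.
#' @return the updated `search_config`.
#' @export
config_from_file <- function(config, path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% c("evalue_cutoff", "max_hits", "query_type", "alphabet",
                    "mask", "mismatch_seeds", "correction", "verbose",
                    "rng_seed"))
      stop("unknown config key: ", key)
    cur <- config[[key]]
    config[[key]] <- if (is.logical(cur)) as.logical(val)
    else if (is.numeric(cur) || key %in% c("rng_seed")) as.numeric(val)
    else val
  }
  stopifnot(config$evalue_cutoff > 0, config$max_hits >= 1)
  config
}

# search one peptide (already a protein / translated frame) against the
# index; returns raw hit rows (unformatted)
search_peptide <- function(index, peptide, config, query_id = "query",
                           frame = NULL) {
  scheme <- config$scheme
  masked <- if (config$mask) mask_low_complexity(peptide) else peptide
  reduced <- reduce_sequence(masked, index$alphabet)
  if (nchar(reduced) < 6) return(empty_hits())
  seeds <- find_mems(index, reduced)
  if (config$mismatch_seeds && nchar(reduced) >= 10) {
    mm <- find_mismatch_seeds(index, reduced)
    seeds <- rbind(seeds, mm)
  }
  if (nrow(seeds) == 0L) return(empty_hits())
  qcodes <- encode_aa(masked)
  rows <- list()
  for (rec in unique(seeds$record)) {
    srec <- seeds[seeds$record == rec, , drop = FALSE]
    alns <- extend_seeds(qcodes, index$aa_encoded[[rec]], srec, scheme)
    for (aln in alns) {
      bits <- bit_score(aln$raw_score, scheme$params_gapped)
      ev <- evalue(bits, nchar(peptide), index$db_residues,
                   index$n_records, scheme$params_gapped,
                   correction = config$correction)
      # display identities from the unmasked query residues
      disp <- display_counts(aln, peptide)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = query_id, sseqid = index$records$id[rec],
        pident = 100 * disp$identities / aln$length,
        length = aln$length, mismatch = disp$mismatches,
        gapopen = aln$gap_openings,
        qstart = aln$qstart, qend = aln$qend,
        sstart = aln$sstart, send = aln$send,
        evalue = ev, bitscore = bits,
        frame = if (is.null(frame)) 0L else frame,
        raw_score = aln$raw_score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  do.call(rbind, rows)
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), evalue = numeric(0), bitscore = numeric(0),
             frame = integer(0), raw_score = numeric(0),
             stringsAsFactors = FALSE)
}

# recount identities/mismatches substituting original (unmasked) query
# residues into the aligned query string
display_counts <- function(aln, peptide) {
  qa <- strsplit(aln$aligned_query, "")[[1]]
  sa <- strsplit(aln$aligned_subject, "")[[1]]
  orig <- strsplit(peptide, "")[[1]]
  qpos <- aln$qstart - 1L
  for (i in seq_along(qa)) {
    if (qa[i] != "-") {
      qpos <- qpos + 1L
      qa[i] <- orig[qpos]
    }
  }
  aligned <- qa != "-" & sa != "-"
  ident <- sum(aligned & qa == sa)
  list(identities = ident, mismatches = sum(aligned) - ident)
}

#' Search queries against an indexed database
#'
#' For each query — each of the six translated frames when the query is
#' nucleotide — the pipeline is: mask low-complexity regions, seed (exact
#' flexible-length MEMs plus single-mismatch seeds), extend (ungapped then
#' gapped X-drop), score (bit score, E-value) and filter/rank. Nucleotide
#' query coordinates are reported on the read, with `qstart > qend` on the
#' minus strand.
#'
#' @param queries data.frame from [read_queries()], or a named character
#'   vector of sequences.
#' @param index a `seed_index` (or path to one).
#' @param config a [search_config()].
#' @return A data.frame of hits in 12-column BLAST tabular (`m8`) order:
#'   `qseqid`, `sseqid`, `pident`, `length`, `mismatch`, `gapopen`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
search_queries <- function(queries, index, config = search_config()) {
  if (is.character(index)) index <- load_index(index)
  stopifnot(inherits(index, "seed_index"))
  if (!identical(index$alphabet$name, config$alphabet))
    stop("index was built with alphabet '", index$alphabet$name,
         "' but config requests '", config$alphabet, "'")
  if (is.character(queries))
    queries <- data.frame(id = if (is.null(names(queries)))
      sprintf("query%04d", seq_along(queries)) else names(queries),
      seq = unname(queries), type = "auto", stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(queries))) {
    qid <- queries$id[i]
    qseq <- queries$seq[i]
    qtype <- if (config$query_type != "auto") config$query_type
    else if (!identical(queries$type[i], "auto")) queries$type[i]
    else detect_seq_type(qseq)
    if (config$verbose) message("query ", qid, " (", qtype, ")")
    hits <- if (qtype == "nt") {
      frames <- translate_six_frames(qseq, qid)
      fh <- lapply(frames, function(fr) {
        h <- search_peptide(index, fr$peptide, config, qid, fr$frame)
        if (nrow(h)) {
          for (r in seq_len(nrow(h))) {
            cc <- frame_to_read_coords(fr, h$qstart[r], h$qend[r])
            h$qstart[r] <- cc[["start"]]
            h$qend[r] <- cc[["end"]]
          }
        }
        h
      })
      do.call(rbind, c(fh, list(empty_hits())))
    } else {
      search_peptide(index, qseq, config, qid)
    }
    out[[i]] <- filter_hits(hits, config$evalue_cutoff, config$max_hits)
  }
  res <- do.call(rbind, c(out, list(empty_hits())))
  rownames(res) <- NULL
  res[, setdiff(names(res), c("frame", "raw_score")), drop = FALSE]
}

detect_seq_type <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  if (mean(ch %in% c("A", "C", "G", "T", "N", "U")) >= 0.9) "nt" else "aa"
}

format_m8 <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
          hits$qseqid, hits$sseqid, hits$pident, hits$length,
          hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
          hits$sstart, hits$send, hits$evalue, hits$bitscore)
}

#' Build and persist a database index (tool entry point)
#'
#' @param db_fasta protein database FASTA.
#' @param out_path output index path.
#' @param alphabet reduced alphabet name.
#' @param quiet suppress the summary message?
#' @return the `seed_index`, invisibly.
#' @export
cmd_index <- function(db_fasta, out_path, alphabet = "murphy.10",
                      quiet = FALSE) {
  records <- load_fasta(db_fasta)
  if (nrow(records) == 0L) stop("no usable records in ", db_fasta)
  index <- build_index(records, get_alphabet(alphabet))
  save_index(index, out_path)
  if (!quiet)
    message("indexed ", index$n_records, " sequences (",
            index$db_residues, " residues); median 6-mer frequency ",
            index$median_hexamer_freq, "; wrote ", out_path)
  invisible(index)
}

#' Search a query file against an index (tool entry point)
#'
#' Writes 12-column BLAST tabular (`m8`) output: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore. Output is deterministic: identical inputs and configuration
#' give a byte-identical file.
#'
#' @param query_fasta FASTA (or FASTQ) of protein or nucleotide queries.
#' @param index_path index file from [cmd_index()] (or a `seed_index`).
#' @param out_path output path (`NULL` for none).
#' @param config a [search_config()].
#' @return the hit data.frame, invisibly.
#' @export
cmd_search <- function(query_fasta, index_path, out_path = NULL,
                       config = search_config()) {
  index <- if (inherits(index_path, "seed_index")) index_path
  else load_index(index_path)
  queries <- read_queries(query_fasta, config$query_type)
  hits <- search_queries(queries, index, config)
  if (!is.null(out_path))
    writeLines(format_m8(hits), out_path)
  invisible(hits)
}
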