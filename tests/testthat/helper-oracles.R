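# Brute-force / independent oracles. These deliberately avoid the
# package's suffix-array and X-drop code paths: suffix order by string
# sort, matches by direct scanning, optimal local alignment scores via
# Biostrings' Smith-Waterman implementation.

# lexicographic suffix order of an integer-coded text (string-sort based)
oracle_suffix_order <- function(codes, keep = rep(TRUE, length(codes))) {
  n <- length(codes)
  rank <- match(codes, sort(unique(codes)))
  key <- sprintf("%05d", rank)
  suf <- vapply(seq_len(n), function(i)
    paste(key[i:n], collapse = ""), character(1))
  ord <- order(suf, method = "radix")
  ord[keep[ord]]
}

# character-by-character LCP of lexicographically adjacent suffixes
oracle_lcp <- function(codes, sa) {
  n <- length(codes)
  vapply(seq_along(sa), function(i) {
    if (i == 1L) return(0L)
    a <- sa[i - 1L]; b <- sa[i]; l <- 0L
    while (a + l <= n && b + l <= n && codes[a + l] == codes[b + l])
      l <- l + 1L
    l
  }, integer(1))
}

# containment suppression on a (p, t, len) matrix, per diagonal
oracle_suppress <- function(mat) {
  if (is.null(mat) || nrow(mat) == 0L) return(mat)
  d <- mat[, 2] - mat[, 1]
  o <- order(d, mat[, 1], -mat[, 3])
  mat <- mat[o, , drop = FALSE]
  d <- d[o]
  keep <- logical(nrow(mat))
  max_end <- -1; cur <- NA
  for (i in seq_len(nrow(mat))) {
    if (is.na(cur) || d[i] != cur) { cur <- d[i]; max_end <- -1 }
    e <- mat[i, 1] + mat[i, 3]
    if (e > max_end) { keep[i] <- TRUE; max_end <- e }
  }
  mat[keep, , drop = FALSE]
}

# all maximal forward matches of length >= per-position minimum, by
# diagonal-wise run-length scanning of the full equality structure
oracle_mems <- function(text, query, minlens) {
  n <- length(text); m <- length(query)
  rows <- list()
  for (d in (1 - m):(n - 1)) {
    ps <- max(1L, 1L - d):min(m, n - d)
    if (!length(ps)) next
    eq <- text[ps + d] == query[ps]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      pend <- ps[ends[k]]
      for (p in ps[starts[k]]:pend) {
        len <- pend - p + 1L
        if (p > length(minlens)) next
        L <- minlens[p]
        if (!is.na(L) && len >= L)
          rows[[length(rows) + 1L]] <- c(p, p + d, len)
      }
    }
  }
  oracle_suppress(do.call(rbind, rows))
}

# length-10 windows at Hamming distance exactly 1, mismatch at seed
# columns 4..7, query window wildcard-free, database mismatch symbol a
# real group symbol; extended forward maximally
oracle_mismatch_seeds <- function(text, query) {
  n <- length(text); m <- length(query)
  rows <- list()
  if (m < 10L) return(NULL)
  for (p in seq_len(m - 9L)) {
    w <- query[p:(p + 9L)]
    if (any(w <= 0)) next
    for (t in seq_len(n - 9L)) {
      tw <- text[t:(t + 9L)]
      mis <- which(tw != w)
      if (length(mis) == 1L && mis >= 4L && mis <= 7L && tw[mis] >= 1) {
        l <- 10L
        while (p + l <= m && t + l <= n && text[t + l] == query[p + l])
          l <- l + 1L
        rows[[length(rows) + 1L]] <- c(p, t, mis, l)
      }
    }
  }
  do.call(rbind, rows)
}

# exhaustive best ungapped segment containing a seed (prefix sums over
# the diagonal; all (a, b) with a <= seed start, b >= seed end)
oracle_ungapped_score <- function(qc, sc, qbeg, sbeg, len, mat) {
  off <- sbeg - qbeg
  ps <- max(1L, 1L - off):min(length(qc), length(sc) - off)
  cols <- mat[cbind(qc[ps], sc[ps + off])]
  cs <- cumsum(cols)
  i0 <- match(qbeg, ps); i1 <- match(qbeg + len - 1L, ps)
  # segment [a..b]: cs[b] - (a > 1 ? cs[a-1] : 0); maximize over a <= seed
  # start, b >= seed end
  amin <- min(c(0, if (i0 > 1L) cs[seq_len(i0 - 1L)]))
  bmax <- max(cs[i1:length(cs)])
  bmax - amin
}

.b62_env <- new.env()

biostrings_b62 <- function() {
  if (is.null(.b62_env$m)) {
    data("BLOSUM62", package = "Biostrings", envir = .b62_env)
    .b62_env$m <- .b62_env$BLOSUM62
  }
  .b62_env$m
}

# Smith-Waterman local score (independent implementation via Biostrings),
# same scoring model: BLOSUM62, gap of length g costs 11 + g
sw_score <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = biostrings_b62(), gapOpening = 11,
    gapExtension = 1, scoreOnly = TRUE)
}

sw_scores_vs_db <- function(query, subjects) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    type = "local", substitutionMatrix = biostrings_b62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

# optimal local score plus one aligned column (query, subject position)
# lying on the optimal path
sw_score_and_anchor <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = biostrings_b62(), gapOpening = 11,
    gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(al)) - 1L
  spos <- Biostrings::start(Biostrings::subject(al)) - 1L
  anchor <- NULL
  for (i in seq_along(pa)) {
    qg <- pa[i] == "-"; sg <- sa[i] == "-"
    if (!qg) qpos <- qpos + 1L
    if (!sg) spos <- spos + 1L
    if (!qg && !sg && is.null(anchor)) anchor <- c(qpos, spos)
    if (!qg && !sg && pa[i] == sa[i]) {  # prefer an identical column
      anchor <- c(qpos, spos)
      break
    }
  }
  list(score = Biostrings::score(al), anchor = anchor)
}
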