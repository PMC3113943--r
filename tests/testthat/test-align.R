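scheme <- scoring_scheme()

test_that("ungapped extension recovers a perfect full-length match", {
  s <- random_aa(60, seed = 40)
  seed <- list(query_pos = 20, subject_pos = 20, length = 8)
  ext <- ungapped_extend(s, s, seed, scheme)
  expect_equal(ext$qstart, 1)
  expect_equal(ext$qend, 60)
  ch <- strsplit(s, "")[[1]]
  expect_equal(ext$score, sum(scheme$matrix[cbind(ch, ch)]))
  # seed at position 1: left extension is a no-op
  e2 <- ungapped_extend(s, s, list(query_pos = 1, subject_pos = 1,
                                   length = 6), scheme)
  expect_equal(e2$qstart, 1)
})

test_that("ungapped extension with infinite X-drop is exhaustive-optimal", {
  set.seed(41)
  for (trial in 1:20) {
    q <- random_aa(sample(40:100, 1))
    s <- random_aa(sample(40:100, 1))
    # plant an exact copy of a query fragment inside the subject
    L <- sample(4:8, 1)
    qs <- sample(seq_len(nchar(q) - L + 1), 1)
    ss <- sample(seq_len(nchar(s) - L + 1), 1)
    substr(s, ss, ss + L - 1) <- substr(q, qs, qs + L - 1)
    seed <- list(query_pos = qs, subject_pos = ss, length = L)
    ext <- ungapped_extend(q, s, seed, scheme, xdrop = Inf)
    want <- oracle_ungapped_score(redseek:::encode_aa(q),
                                  redseek:::encode_aa(s),
                                  qs, ss, L, scheme$matrix)
    expect_equal(ext$score, want)
    # finite X-drop can never beat the exhaustive optimum
    efin <- ungapped_extend(q, s, seed, scheme)
    expect_lte(efin$score, want)
  }
})

test_that("gapped extension recovers a planted clean insertion", {
  set.seed(42)
  a <- random_aa(80)
  ins_at <- 40
  b <- paste0(substr(a, 1, ins_at), "WC",
              substr(a, ins_at + 1, nchar(a)))
  anchor <- c(10, 10)  # left of the insertion, on the main diagonal
  aln <- gapped_extend(a, b, anchor, scheme, xdrop = Inf)
  ch <- strsplit(a, "")[[1]]
  diag_sum <- sum(scheme$matrix[cbind(ch, ch)])
  expect_equal(aln$raw_score,
               diag_sum - scheme$gap_open - 2 * scheme$gap_extend)
  expect_equal(aln$gap_openings, 1)
  expect_equal(sw_score(a, b), aln$raw_score)
})

test_that("gapped extension on identical sequences equals ungapped", {
  s <- random_aa(70, seed = 43)
  aln <- gapped_extend(s, s, c(35, 35), scheme, xdrop = Inf)
  ext <- ungapped_extend(s, s, list(query_pos = 35, subject_pos = 35,
                                    length = 1), scheme, xdrop = Inf)
  expect_equal(aln$raw_score, ext$score)
  expect_equal(aln$gap_openings, 0)
  expect_equal(aln$identities, 70)
})

test_that("anchored extension attains the Smith-Waterman optimum", {
  set.seed(44)
  for (trial in 1:15) {
    p <- random_aa(sample(60:140, 1))
    h <- mutate_homolog(p, mutation_model(0.6, indel_rate = 0.03))
    sw <- sw_score_and_anchor(p, h$seq)
    aln <- gapped_extend(p, h$seq, sw$anchor, scheme, xdrop = Inf)
    expect_equal(aln$raw_score, sw$score)
    # and with a finite X-drop the score never exceeds the optimum
    fin <- gapped_extend(p, h$seq, sw$anchor, scheme)
    expect_lte(fin$raw_score, sw$score)
  }
})

test_that("alignment scores re-derive from their aligned strings", {
  set.seed(45)
  for (trial in 1:10) {
    p <- random_aa(100)
    h <- mutate_homolog(p, mutation_model(0.55, indel_rate = 0.04))
    sw <- sw_score_and_anchor(p, h$seq)
    for (xd in c(Inf, scheme$xdrop_gapped)) {
      aln <- gapped_extend(p, h$seq, sw$anchor, scheme, xdrop = xd)
      expect_equal(rescore_alignment(aln, scheme), aln$raw_score)
      # coordinates consistent with the gapped strings
      qa <- strsplit(aln$aligned_query, "")[[1]]
      sa <- strsplit(aln$aligned_subject, "")[[1]]
      expect_equal(sum(qa != "-"), aln$qend - aln$qstart + 1)
      expect_equal(sum(sa != "-"), aln$send - aln$sstart + 1)
      expect_equal(aln$identities + aln$mismatches,
                   sum(qa != "-" & sa != "-"))
    }
  }
})

test_that("a stop-codon run blocks ungapped extension", {
  left <- random_aa(30, seed = 46)
  right <- random_aa(30, seed = 47)
  q <- paste0(left, "****", right)   # translated frame with stop run
  s <- paste0(left, "AAAA", right)   # stop-free subject
  seed <- list(query_pos = 5, subject_pos = 5, length = 6)
  # '*' vs residue scores -4; four stops cost more than the X-drop margin
  ext <- ungapped_extend(q, s, seed, scheme)
  expect_lte(ext$qend, 33)
  # with the default margin the segment stays within the left block
  expect_equal(substr(q, ext$qstart, ext$qend),
               substr(s, ext$sstart, ext$send))
})

test_that("seed-level deduplication keeps one alignment per region", {
  db <- generate_protein_db(3, c(80, 120), rng_seed = 48)
  idx <- build_index(db, get_alphabet("murphy.10"))
  q <- db$seq[2]
  rq <- reduce_sequence(q, idx$alphabet)
  seeds <- find_mems(idx, rq)
  s2 <- seeds[seeds$record == 2, , drop = FALSE]
  alns <- extend_seeds(q, db$seq[2], s2, scheme)
  spans <- vapply(alns, function(a)
    paste(a$qstart, a$qend, a$sstart, a$send), character(1))
  expect_false(anyDuplicated(spans) > 0)
  expect_true(any(vapply(alns, function(a)
    a$qstart == 1 && a$qend == nchar(q), logical(1))))
})
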