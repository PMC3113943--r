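test_that("minimum seed length follows the frequency rule", {
  # at or below the median frequency: always 6
  expect_equal(min_seed_length_core(0, 176, c(0.1, 0.1, 0.1)), 6L)
  expect_equal(min_seed_length_core(176, 176, c(0.1, 0.1, 0.1)), 6L)
  # one lengthening step drops 1000 -> 100 below the median of 176
  expect_equal(min_seed_length_core(1000, 176, c(0.1, 0.1, 0.1)), 7L)
  # frequency so high that the cap at 9 kicks in
  expect_equal(min_seed_length_core(1e6, 176, rep(0.99, 10)), 9L)
  # lengthening stops at the query end
  expect_equal(min_seed_length_core(1e6, 176, numeric(0)), 6L)
  expect_equal(min_seed_length_core(1e6, 176, 0.99), 7L)
})

test_that("minimum seed length is monotone in frequency and within 6..9", {
  freqs <- c(0, 1, 10, 176, 177, 500, 1e3, 1e4, 1e5, 1e6, 1e7)
  for (comp in c(0.01, 0.05, 0.2, 0.5, 0.99)) {
    ls <- vapply(freqs, min_seed_length_core, integer(1),
                 median_freq = 176, comps = rep(comp, 3))
    expect_true(all(ls >= 6L & ls <= 9L))
    expect_true(all(diff(ls) >= 0L))
  }
})

test_that("min_seed_length on a real index agrees with the core rule", {
  idx <- tiny_index(10, c(40, 80), seed = 30)
  q <- reduce_sequence(idx$records$seq[3], idx$alphabet)
  for (pos in c(1, 5, nchar(q) - 5)) {
    word <- substr(q, pos, pos + 5)
    f <- idx$hexamer_counts[word]
    f <- if (is.na(f)) 0 else f
    comps <- idx$composition[strsplit(substr(q, pos + 6, nchar(q)),
                                      "")[[1]]]
    comps[is.na(comps)] <- 0
    expect_equal(min_seed_length(idx, q, pos),
                 min_seed_length_core(f, idx$median_hexamer_freq, comps))
  }
})

test_that("a query identical to a database record yields a full-length seed", {
  idx <- tiny_index(12, c(40, 100), seed = 31)
  q <- reduce_sequence(idx$records$seq[7], idx$alphabet)
  mems <- find_mems(idx, q)
  full <- mems[mems$record == 7 & mems$query_pos == 1 &
                 mems$subject_pos == 1, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$length, nchar(q))
})

test_that("queries sharing no 6-mer with the database yield no seeds", {
  db <- data.frame(id = "r1", desc = "",
                   seq = strrep("A", 60), stringsAsFactors = FALSE)
  idx <- build_index(db, get_alphabet("murphy.10"))
  q <- reduce_sequence(strrep("K", 30), idx$alphabet)
  expect_equal(nrow(find_mems(idx, q)), 0)
})

test_that("MEM enumeration matches the brute-force oracle", {
  set.seed(32)
  for (trial in 1:10) {
    idx <- tiny_index(sample(3:10, 1), c(20, 80), seed = 320 + trial)
    # half the trials query a mutated homolog (seed-rich), half random
    qaa <- if (trial %% 2 == 0)
      mutate_homolog(idx$records$seq[1], mutation_model(0.5))$seq
    else random_aa(sample(30:120, 1))
    rq <- reduce_sequence(qaa, idx$alphabet)
    qcodes <- redseek:::encode_reduced_query(idx$alphabet, rq)
    minlens <- redseek:::min_seed_lengths(idx, rq)
    got <- find_mems(idx, rq)
    want <- oracle_mems(idx$text_codes, qcodes, minlens)
    if (is.null(want) || nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      wdf <- data.frame(query_pos = want[, 1],
                        record = idx$rec_of[want[, 2]],
                        subject_pos = idx$loc_of[want[, 2]],
                        length = want[, 3])
      o1 <- order(got$query_pos, got$record, got$subject_pos)
      o2 <- order(wdf$query_pos, wdf$record, wdf$subject_pos)
      expect_equal(got[o1, c("query_pos", "record", "subject_pos",
                             "length")],
                   wdf[o2, ], ignore_attr = TRUE)
    }
    # every reported seed re-checks symbol by symbol
    rch <- strsplit(rq, "")[[1]]
    for (r in seq_len(min(nrow(got), 25))) {
      sub <- strsplit(idx$reduced[got$record[r]], "")[[1]]
      qs <- got$query_pos[r]; ss <- got$subject_pos[r]; L <- got$length[r]
      expect_identical(rch[qs:(qs + L - 1)], sub[ss:(ss + L - 1)])
    }
  }
})

test_that("single-mismatch seeds match the Hamming-window oracle", {
  set.seed(33)
  for (trial in 1:8) {
    idx <- tiny_index(sample(2:5, 1), c(20, 60), seed = 330 + trial)
    qaa <- if (trial %% 2 == 0)
      mutate_homolog(idx$records$seq[1], mutation_model(0.75,
                                                        indel_rate = 0))$seq
    else random_aa(sample(20:60, 1))
    rq <- reduce_sequence(qaa, idx$alphabet)
    qcodes <- redseek:::encode_reduced_query(idx$alphabet, rq)
    got <- find_mismatch_seeds(idx, rq)
    want <- oracle_mismatch_seeds(idx$text_codes, qcodes)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      wdf <- data.frame(query_pos = want[, 1],
                        record = idx$rec_of[want[, 2]],
                        subject_pos = idx$loc_of[want[, 2]],
                        length = want[, 4],
                        mismatch_pos = want[, 3])
      cols <- c("query_pos", "record", "subject_pos", "length",
                "mismatch_pos")
      o1 <- do.call(order, got[cols])
      o2 <- do.call(order, wdf[cols])
      expect_equal(got[o1, cols], wdf[o2, cols], ignore_attr = TRUE)
    }
  }
})

test_that("mismatch seeds carry one real mismatch at an allowed column", {
  db <- generate_protein_db(1, c(40, 40), rng_seed = 34)
  idx <- build_index(db, get_alphabet("murphy.10"))
  red <- idx$reduced[1]
  # plant one changed symbol at seed column 5 of a length-10 window
  win_start <- 8L
  q <- red
  pos <- win_start + 4L
  old <- substr(q, pos, pos)
  repl <- setdiff(idx$alphabet$symbols, old)[1]
  substr(q, pos, pos) <- repl
  mm <- find_mismatch_seeds(idx, q)
  hit <- mm[mm$query_pos == win_start & mm$subject_pos == win_start, ]
  expect_true(nrow(hit) >= 1)
  expect_true(5 %in% hit$mismatch_pos)
  expect_true(all(mm$length >= 10))
  expect_true(all(mm$mismatch_pos %in% 4:7))
  # identical query: every window matches exactly, so no mismatch seeds
  expect_equal(nrow(find_mismatch_seeds(idx, red)), 0)
})

test_that("reduced-alphabet seeding dominates identity-alphabet seeding", {
  pairs <- make_pair_set(40, "homologous", mutation_model(0.35),
                         length_range = c(60, 120), rng_seed = 35)
  mu <- get_alphabet("murphy.10")
  id20 <- get_alphabet("all.20")
  for (L in c(5, 6, 8)) {
    expect_gte(seed_coverage(pairs, mu, L), seed_coverage(pairs, id20, L))
  }
})
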