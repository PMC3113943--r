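test_that("grouping strings parse into valid alphabets", {
  ab <- parse_alphabet("A [KR] [EDNQ] C G H [ILVM] [FYW] P [ST]",
                       "murphy.10")
  expect_s3_class(ab, "reduced_alphabet")
  expect_equal(ab$n_symbols, 10)
  expect_equal(ab$symbol_of[["K"]], ab$symbol_of[["R"]])
  expect_equal(sort(unname(unlist(ab$groups))),
               sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))

  id20 <- parse_alphabet("P G E K R Q D S N T H C I V W Y F A L M",
                         "all.20")
  expect_equal(id20$n_symbols, 20)
  expect_true(all(lengths(id20$groups) == 1))

  expect_error(parse_alphabet("A [KR]"), "missing")
  expect_error(parse_alphabet("A A [KR] [EDNQ] C G H [ILVM] [FYW] P [ST]"),
               "more than one group")
  expect_error(parse_alphabet(""), "empty")
  expect_error(parse_alphabet("A [KR] [EDNQ] C G H [ILVM] [FYW] P [STB]"),
               "non-standard")
})

test_that("every shipped alphabet row parses at its printed size", {
  reg <- builtin_alphabets()
  expect_gte(nrow(reg), 11)
  for (i in seq_len(nrow(reg))) {
    ab <- parse_alphabet(reg$groups[i], reg$name[i])
    expect_equal(ab$n_symbols, reg$size[i], info = reg$name[i])
  }
})

test_that("sequence reduction collapses groups and handles wildcards", {
  mu <- get_alphabet("murphy.10")
  r <- reduce_sequence("ILVM", mu)
  expect_equal(nchar(r), 4)
  expect_length(unique(strsplit(r, "")[[1]]), 1)
  expect_equal(reduce_sequence("", mu), "")
  # identity alphabet: unchanged up to symbol renaming (here: literally)
  all20 <- get_alphabet("all.20")
  s <- random_aa(50, seed = 3)
  expect_equal(reduce_sequence(s, all20), s)
  # X and * stay as never-matching symbols; ambiguity codes resolve
  expect_equal(reduce_sequence("KXR*", mu),
               paste0(reduce_sequence("K", mu), "X",
                      reduce_sequence("R", mu), "*"))
  expect_equal(reduce_sequence("B", mu), reduce_sequence("D", mu))
  expect_equal(reduce_sequence("Z", mu), reduce_sequence("E", mu))
  expect_error(reduce_sequence("AC1", mu), "unknown residue")
  # idempotent once in reduced space
  r2 <- reduce_sequence(random_aa(80, seed = 4), mu)
  expect_equal(reduce_sequence(r2, mu), r2)
})

test_that("reduction can only raise percent identity", {
  mu <- get_alphabet("murphy.10")
  set.seed(11)
  for (i in 1:25) {
    a <- random_aa(60)
    b <- random_aa(60)
    ch_a <- strsplit(a, "")[[1]]; ch_b <- strsplit(b, "")[[1]]
    ra <- strsplit(reduce_sequence(a, mu), "")[[1]]
    rb <- strsplit(reduce_sequence(b, mu), "")[[1]]
    expect_gte(mean(ra == rb), mean(ch_a == ch_b))
  }
})

test_that("seed coverage behaves on forced pair sets", {
  mu <- get_alphabet("murphy.10")
  s <- vapply(1:10, function(i) random_aa(40, seed = 100 + i), character(1))
  ident <- data.frame(a = s, b = s, stringsAsFactors = FALSE)
  expect_equal(seed_coverage(ident, mu, 6), 1.0)
  # group-1-only vs group-2-only sequences can never share a symbol
  g1 <- strrep("A", 30)   # A group
  g2 <- strrep("K", 30)   # KR group
  disj <- data.frame(a = rep(g1, 5), b = rep(g2, 5),
                     stringsAsFactors = FALSE)
  expect_equal(seed_coverage(disj, mu, 3), 0.0)
  expect_error(seed_coverage(ident[0, ], mu, 6), "empty")
})

test_that("coverage is non-increasing in seed length (vs brute force)", {
  mu <- get_alphabet("murphy.10")
  pairs <- make_pair_set(60, "homologous", mutation_model(0.3),
                         length_range = c(60, 120), rng_seed = 5)
  cov <- vapply(3:15, function(L) seed_coverage(pairs, mu, L), numeric(1))
  expect_true(all(diff(cov) <= 1e-12))
  # spot-check one length against direct substring comparison
  L <- 7
  direct <- mean(mapply(function(a, b) {
    ra <- reduce_sequence(a, mu); rb <- reduce_sequence(b, mu)
    ka <- unique(substring(ra, 1:(nchar(ra) - L + 1), L:nchar(ra)))
    any(vapply(ka, function(k) grepl(k, rb, fixed = TRUE), logical(1)))
  }, pairs$a, pairs$b))
  expect_equal(seed_coverage(pairs, mu, L), direct)
})

test_that("seed efficiency matches forced counts and is 0 on identical sets", {
  mu <- get_alphabet("murphy.10")
  pairs <- make_pair_set(20, "homologous", mutation_model(0.35),
                         length_range = c(60, 100), rng_seed = 6)
  expect_equal(seed_efficiency(pairs, pairs, mu, 6), 0.0)
  s <- vapply(1:8, function(i) random_aa(40, seed = 200 + i), character(1))
  hom <- data.frame(a = s, b = s, stringsAsFactors = FALSE)
  non <- data.frame(a = rep(strrep("A", 30), 8),
                    b = rep(strrep("K", 30), 8), stringsAsFactors = FALSE)
  # denominator 0 -> +1 pseudocount
  expect_equal(seed_efficiency(hom, non, mu, 5), log10(8))
})

test_that("alphabet evaluation grid returns a tidy table", {
  mu_hom <- make_pair_set(15, "homologous", mutation_model(0.3),
                          length_range = c(60, 100), rng_seed = 7)
  mu_non <- make_pair_set(15, "non-homologous",
                          length_range = c(60, 100), rng_seed = 8)
  tab <- evaluate_alphabets(mu_hom, mu_non, c("murphy.10", "all.20"),
                            seed_lens = c(4, 6, 8))
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("alphabet", "seed_len", "coverage", "efficiency"))
  expect_true(all(tab$coverage >= 0 & tab$coverage <= 1))
  # merging residues can only add seed matches: any reduced alphabet
  # covers at least what the identity alphabet covers
  for (L in c(4, 6, 8))
    expect_gte(tab$coverage[tab$alphabet == "murphy.10" & tab$seed_len == L],
               tab$coverage[tab$alphabet == "all.20" & tab$seed_len == L])
})
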