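# shared fixture builders (everything generated in code, fixed seeds)

tiny_index <- function(n = 20, len = c(40, 120), seed = 1,
                       alphabet = "murphy.10") {
  db <- generate_protein_db(n, len, rng_seed = seed)
  build_index(db, get_alphabet(alphabet))
}

write_temp_fasta <- function(seqs, ids = names(seqs), width = 60) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  path
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
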