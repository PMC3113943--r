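# Synthetic-data generators: random protein databases, homolog pairs of
# controlled identity, and simulated short reads. Everything is
# reproducible under a fixed rng_seed so oracle tests can replay inputs.

# Robinson & Robinson (1991) background amino-acid frequencies, the
# standard composition used for BLAST statistics; order follows AA20.
ROBINSON_FREQ <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Generate a synthetic protein database
#'
#' Sequences are drawn i.i.d. from a residue composition (by default the
#' Robinson-Robinson background frequencies) with lengths uniform over
#' `length_range`.
#'
#' @param n number of sequences.
#' @param length_range integer vector of length 2, inclusive bounds.
#' @param composition named numeric vector of residue frequencies over the
#'   20 standard residues (normalized internally).
#' @param rng_seed integer seed; identical seeds give identical output.
#' @param prefix id prefix.
#' @return A data.frame of protein records with columns `id`, `desc`, `seq`.
#' @examples
#' db <- generate_protein_db(5, c(60, 80), rng_seed = 1)
#' nchar(db$seq)
#' @export
generate_protein_db <- function(n, length_range = c(80, 300),
                                composition = ROBINSON_FREQ,
                                rng_seed = NULL, prefix = "prot") {
  stopifnot(n >= 1, length(length_range) == 2)
  comp <- composition[AA20]
  if (anyNA(comp)) stop("composition must name all 20 standard residues")
  comp <- comp / sum(comp)
  with_seed(rng_seed, {
    lens <- if (length_range[1] == length_range[2])
      rep(length_range[1], n)
    else sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE, prob = comp), collapse = ""),
      character(1))
    data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
               desc = rep("synthetic protein", n),
               seq = seqs, stringsAsFactors = FALSE)
  })
}

#' Mutation model for synthetic homologs
#'
#' @param target_identity desired fraction of identical aligned columns.
#' @param indel_rate per-residue probability of starting an indel.
#' @param indel_length geometric mean-ish parameter: indel lengths are
#'   `1 + rgeom(prob = 1/indel_length)`.
#' @param substitution `"blosum"` (substitutions sampled proportional to
#'   `exp(BLOSUM62 score)` off the diagonal, so divergence resembles real
#'   substitution patterns) or `"uniform"`.
#' @param rng_seed integer seed or NULL.
#' @return A `mutation_model` list.
#' @export
mutation_model <- function(target_identity = 0.3, indel_rate = 0.01,
                           indel_length = 2, substitution = c("blosum",
                                                              "uniform"),
                           rng_seed = NULL) {
  stopifnot(target_identity > 0, target_identity <= 1,
            indel_rate >= 0, indel_rate <= 1)
  structure(list(target_identity = target_identity, indel_rate = indel_rate,
                 indel_length = indel_length,
                 substitution = match.arg(substitution),
                 rng_seed = rng_seed),
            class = "mutation_model")
}

# substitution sampling table: for each residue, probabilities over the
# other 19 proportional to exp(score)
subst_tables <- function(mode) {
  mat <- blosum62()[AA20, AA20]
  lapply(setNames(AA20, AA20), function(a) {
    others <- setdiff(AA20, a)
    if (mode == "uniform") {
      setNames(rep(1 / 19, 19), others)
    } else {
      w <- exp(mat[a, others])
      w / sum(w)
    }
  })
}

#' Mutate a protein into a synthetic homolog of controlled identity
#'
#' Applies per-position substitutions (at rate `1 - target_identity`) and
#' geometric-length indels, then measures the realized identity on the
#' recorded true alignment (identical aligned residue pairs over aligned
#' columns, gaps excluded); resamples until the realized identity is within
#' 5 percentage points of the target.
#'
#' @param protein amino-acid string of length >= 20.
#' @param model a [mutation_model()].
#' @param max_tries resampling bound before giving up.
#' @return A list with `seq` (the homolog), `identity` (realized), and
#'   `alignment` (the true alignment as two gapped strings `a`, `b`).
#' @export
mutate_homolog <- function(protein, model, max_tries = 60) {
  stopifnot(inherits(model, "mutation_model"), nchar(protein) >= 20)
  tabs <- subst_tables(model$substitution)
  res <- with_seed(model$rng_seed, {
    out <- NULL
    for (try in seq_len(max_tries)) {
      h <- mutate_once(protein, model, tabs)
      if (abs(h$identity - model$target_identity) <= 0.05) {
        out <- h
        break
      }
    }
    out
  })
  if (is.null(res))
    stop("could not reach target identity ", model$target_identity,
         " within ", max_tries, " tries")
  res
}

mutate_once <- function(protein, model, tabs) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  p_sub <- 1 - model$target_identity
  out_a <- character(0)  # original, gapped
  out_b <- character(0)  # homolog, gapped
  i <- 1L
  while (i <= n) {
    if (model$indel_rate > 0 && runif(1) < model$indel_rate) {
      len <- 1L + rgeom(1, prob = min(1, 1 / model$indel_length))
      if (runif(1) < 0.5) {  # deletion in homolog
        take <- min(len, n - i + 1L)
        out_a <- c(out_a, ch[i:(i + take - 1L)])
        out_b <- c(out_b, rep("-", take))
        i <- i + take
      } else {               # insertion in homolog
        ins <- sample(AA20, len, replace = TRUE)
        out_a <- c(out_a, rep("-", len))
        out_b <- c(out_b, ins)
      }
      next
    }
    a <- ch[i]
    b <- if (runif(1) < p_sub) sample(names(tabs[[a]]), 1,
                                      prob = tabs[[a]]) else a
    out_a <- c(out_a, a)
    out_b <- c(out_b, b)
    i <- i + 1L
  }
  aligned <- out_a != "-" & out_b != "-"
  ident <- sum(out_a == out_b & aligned) / max(1L, sum(aligned))
  list(seq = paste(out_b[out_b != "-"], collapse = ""),
       identity = ident,
       alignment = list(a = paste(out_a, collapse = ""),
                        b = paste(out_b, collapse = "")))
}

#' Build a labelled pair set for alphabet evaluation
#'
#' Homologous pairs are (protein, mutated homolog) at the model's target
#' identity; non-homologous pairs are independent random proteins of
#' matched composition. These stand in for curated distant-homolog
#' alignment pairs in the coverage/efficiency experiment.
#'
#' @param n number of pairs.
#' @param label `"homologous"` or `"non-homologous"`.
#' @param model a [mutation_model()] (used for homologous pairs).
#' @param length_range protein length bounds.
#' @param rng_seed integer seed.
#' @return data.frame with columns `a`, `b`, `label` and (for homologous
#'   pairs) `identity`.
#' @export
make_pair_set <- function(n, label = c("homologous", "non-homologous"),
                          model = mutation_model(0.3),
                          length_range = c(100, 200), rng_seed = 1) {
  label <- match.arg(label)
  with_seed(rng_seed, {
    base <- generate_protein_db(n, length_range)
    if (label == "homologous") {
      m2 <- model; m2$rng_seed <- NULL  # draw from the outer stream
      hom <- lapply(base$seq, mutate_homolog, model = m2)
      data.frame(a = base$seq,
                 b = vapply(hom, `[[`, character(1), "seq"),
                 identity = vapply(hom, `[[`, numeric(1), "identity"),
                 label = label, stringsAsFactors = FALSE)
    } else {
      other <- generate_protein_db(n, length_range, prefix = "alt")
      data.frame(a = base$seq, b = other$seq, label = label,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Back-translate proteins to coding sequences
#'
#' Codons are sampled uniformly among the synonymous codons of each
#' residue (standard genetic code); used to make nucleotide fixtures whose
#' translations are known.
#'
#' @param proteins character vector of amino-acid strings.
#' @param rng_seed integer seed.
#' @return character vector of DNA strings, 3x the protein lengths.
#' @export
proteins_to_cds <- function(proteins, rng_seed = NULL) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  with_seed(rng_seed, {
    vapply(proteins, function(p) {
      ch <- strsplit(p, "")[[1]]
      paste(vapply(ch, function(a) {
        cods <- by_aa[[a]]
        if (is.null(cods)) stop("cannot back-translate residue ", a)
        if (length(cods) == 1L) cods else sample(cods, 1)
      }, character(1)), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Simulate short reads from coding sequences
#'
#' Reads are sampled uniformly over sequences, offsets and strands, with
#' the true origin recorded so recall can be scored against it.
#'
#' @param cds_set named character vector (or data.frame with `id`, `seq`)
#'   of DNA sequences, each at least `read_length` long.
#' @param read_length read length in nucleotides.
#' @param n_reads number of reads.
#' @param rng_seed integer seed.
#' @return A data.frame with columns `read_id`, `seq`, `source_id`,
#'   `offset` (1-based on the forward strand), `strand` (`"+"`/`"-"`).
#' @export
simulate_reads <- function(cds_set, read_length = 72, n_reads = 100,
                           rng_seed = NULL) {
  if (is.data.frame(cds_set)) cds_set <- setNames(cds_set$seq, cds_set$id)
  if (is.null(names(cds_set))) names(cds_set) <- sprintf("cds%04d",
                                                         seq_along(cds_set))
  lens <- nchar(cds_set)
  if (any(lens < read_length))
    stop("all sequences must be at least read_length long")
  with_seed(rng_seed, {
    src <- sample(seq_along(cds_set), n_reads, replace = TRUE)
    off <- vapply(src, function(i)
      sample.int(lens[i] - read_length + 1L, 1L), integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(cds_set[src], off, off + read_length - 1L)
    flip <- strand == "-"
    if (any(flip))
      seqs[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
    data.frame(read_id = sprintf("read%05d", seq_len(n_reads)),
               seq = unname(seqs), source_id = names(cds_set)[src],
               offset = off, strand = strand, stringsAsFactors = FALSE)
  })
}
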