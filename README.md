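# redseek

Fast protein similarity search with reduced amino-acid alphabet seeds — an
R implementation of the seed-and-extend search strategy used for
annotating short translated reads against protein databases, aimed at
metagenomics-scale workloads where BLASTX-style search is the bottleneck.

## The idea

Homologous proteins often share only short exact matches in the 20-letter
alphabet, so protein search tools must chase huge numbers of short seeds.
In a **reduced (compressed) amino-acid alphabet** — a partition of the 20
residues into groups of chemically similar residues, e.g. the 10-letter
BLOSUM-derived grouping `A [KR] [EDNQ] C G H [ILVM] [FYW] P [ST]`
(`murphy.10`) — homologs share much longer exact matches, while a
length-*L* seed over *k* symbols still admits only ~*k*<sup>−*L*</sup>
chance matches. Length-6 seeds over 10 symbols are 10<sup>6</sup>/20<sup>3</sup> = 125×
more selective than length-3 seeds over 20 symbols, which is where the
speedup comes from.

The search pipeline:

1. **Index**: the database is rewritten in the reduced alphabet and
   concatenated with per-sequence sentinels; a suffix array + LCP array
   index the text. A 6-mer frequency table (with its median) and the
   residue composition are precomputed.
2. **Seed**: for every query position the minimum seed length is chosen
   adaptively in 6–9 — rare 6-mers seed at 6; frequent 6-mers are
   lengthened while their expected frequency (6-mer count times the
   composition of each following query symbol) stays above the database
   median. All maximal exact matches of at least that length are
   enumerated from the suffix array, plus long (≥ 10) seeds carrying one
   mismatch at seed columns 4–7.
3. **Extend**: seeds are extended in the original 20-letter alphabet with
   BLOSUM62 — X-drop ungapped extension, then affine-gap X-drop dynamic
   programming (gap open 11, extend 1) from the best ungapped column.
4. **Score**: Karlin–Altschul statistics, as in BLAST:
   bit score S′ = (λS − ln K)/ln 2 with λ = 0.267, K = 0.041 for gapped
   BLOSUM62 11/1, and E = m′·n′·2<sup>−S′</sup> with edge-corrected
   effective lengths.

Nucleotide queries are translated in all six frames; query peptides are
SEG-style masked for low-complexity regions before seeding. Output is
12-column BLAST tabular (`m8`). The package also ships the evaluation
framework used to choose a seeding alphabet (seed *coverage* on homolog
pairs and *efficiency*, the log10 ratio of homolog to non-homolog pairs
with at least one seed) and synthetic-data generators (databases, homolog
pairs of controlled identity, simulated short reads) so everything is
testable without downloads.

## Worked example

```r
library(redseek)
# 1. synthetic database and index
db  <- generate_protein_db(50, c(80, 200), rng_seed = 101)
idx <- build_index(db, get_alphabet("murphy.10"))
print(idx)
#> seed_index: 50 sequences, 7441 residues
#>   alphabet: murphy.10; median 6-mer frequency: 1

# 2. a homolog of database protein 12 at ~40% identity
hom <- mutate_homolog(db$seq[12], mutation_model(0.4, rng_seed = 7))
round(hom$identity, 3)
#> 0.415

# 3. search
search_queries(c(query1 = hom$seq), idx, search_config(evalue_cutoff = 1e-3))
#>   qseqid   sseqid   pident length mismatch gapopen qstart qend sstart send
#> 1 query1 prot0012 41.53846    195      112       1      4  196      3  197
#>         evalue bitscore
#> 1 6.529125e-57 205.2972
```

The one reported hit is the true source protein: a 195-column alignment at
41.5% identity with one gap opening, bit score 205.3, E ≈ 6.5e−57 against
this 7,441-residue database — i.e. far below any plausible chance score.

From the shell, the same two steps are exposed as a thin command-line
wrapper:

```sh
Rscript inst/cli/redseek.R index -d db.fasta -o db.idx --alphabet murphy.10
Rscript inst/cli/redseek.R search -q reads.fasta -d db.idx -o hits.m8 -e 1e-3
```

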