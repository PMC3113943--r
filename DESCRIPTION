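Package: redseek
Title: Protein Similarity Search with Reduced Amino-Acid Alphabet Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seed-and-extend protein similarity search engine for short
    translated reads and protein queries. Sequences are rewritten in a
    reduced (compressed) amino-acid alphabet, in which homologous proteins
    share longer exact matches; seeds are flexible-length maximal exact
    matches (6-9 residues, chosen per query position from database 6-mer
    frequencies) found with a suffix array and LCP array over the reduced
    database text, optionally augmented with long single-mismatch seeds.
    Seeds are extended in the original 20-letter alphabet with BLOSUM62
    by X-drop ungapped and affine-gap extension, and scored with
    Karlin-Altschul bit scores and E-values. Includes six-frame
    translation of nucleotide queries, SEG-style low-complexity masking,
    an alphabet-evaluation framework (seed coverage and efficiency on
    homolog pair sets), and synthetic-data generators for databases,
    homolog pairs of controlled identity, and simulated short reads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
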