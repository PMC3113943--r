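---
title: "Methods: reduced-alphabet seeding, X-drop extension, and search statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-alphabet seeding, X-drop extension, and search statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where genuinely open design points were settled.

## The model

`redseek` is a seed-and-extend local alignment search engine for protein
(or six-frame translated nucleotide) queries against a protein database.
Its distinguishing component is the seeding stage, which operates in a
*reduced amino-acid alphabet*: a partition of the 20 residues into groups
of chemically interchangeable residues. Because homologs exhibit higher
sequence identity over group symbols than over residues, exact matches in
reduced space are much longer than in 20-letter space, and a longer
minimum seed length can be used without losing sensitivity. A seed of
length $L$ over $k$ symbols has chance frequency $\sim k^{-L}$ per
position pair, so length-6 seeds over the default 10-letter alphabet are
$10^6/20^3 = 125\times$ more selective than the length-3 seeds a
hash-table protein search would use.

The stages are:

1. **Reduction and indexing.** Database sequences are rewritten over
   group symbols (each group is written as its first residue, which makes
   re-reduction the identity) and concatenated. A suffix array and LCP
   array over the concatenation support all seed queries.
2. **Adaptive minimum seed length.** For a query position $i$, let $f$ be
   the database count of the reduced 6-mer starting at $i$ and $\tilde f$
   the median count over distinct observed 6-mers. If $f \le \tilde f$
   the minimum seed length is 6. Otherwise the expected frequency is
   multiplied by the database composition of each successive query symbol
   and the seed lengthened until that product falls to $\tilde f$, capped
   at 9. Frequent words therefore need longer (more specific) seeds,
   keeping the seed pool balanced under compositional bias.
3. **Seeds.** All maximal exact matches of at least the per-position
   minimum length, by binary search over the suffix array; plus seeds of
   length $\ge 10$ carrying exactly one mismatch at seed columns 4–7
   (found by substituting every other group symbol at those columns and
   searching exactly). Matches wholly contained in a longer match on the
   same diagonal are suppressed. Every single seed is extended — there is
   no two-hit requirement.
4. **Extension.** In the original 20-letter alphabet with BLOSUM62:
   ungapped X-drop extension of the seed; if the segment score reaches a
   trigger, affine-gap X-drop dynamic programming outward from the
   segment's best-scoring column.
5. **Statistics.** Karlin–Altschul: $S' = (\lambda S - \ln K)/\ln 2$ and
   $E = m'n'\,2^{-S'}$, with the standard expected-HSP-length edge
   correction applied to the query and database lengths (toggleable, for
   exact testability). Hits are filtered at the E-value cutoff, ranked by
   E-value, bit score and subject id (a total order, so output is
   deterministic), and truncated to the per-query maximum.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| alphabet | `murphy.10` | — | 10-letter BLOSUM-derived grouping; the best efficiency/coverage compromise among the shipped alphabets |
| minimum seed length | 6–9, adaptive | residues | see above; the cap of +3 keeps seeds inside the 6–9 band |
| mismatch-seed length | ≥ 10, mismatch at columns 4–7 | residues | long seeds tolerate one post-reduction mismatch without losing specificity |
| matrix / gaps | BLOSUM62, open 11, extend 1 | half-bits | the parameterization the gapped λ, K assume |
| λ, K (gapped) | 0.267, 0.041 | nats, — | published values for BLOSUM62 11/1 |
| λ, K (ungapped) | 0.3176, 0.134 | nats, — | published ungapped BLOSUM62 values |
| X-drop (ungapped, gapped) | 7, 15 | bits | converted to raw units via the matching λ; standard extension margins |
| gapped trigger | 22 | bits | ungapped score needed before gapped extension is attempted |
| masking window / cutoffs | 12 / 2.2 / 2.5 | residues, bits | SEG-like defaults: trigger and extension entropies of a sliding window |
| E-value cutoff / max hits | 10 / 100 | — | tabular-output conventions |

The X-drop margins and the trigger are implementation choices (no
reference values exist for this design); they are stored in the
`scoring_scheme` and overridable.

## Numerical and representational choices

- **Sentinels.** One distinct terminator symbol per concatenated
  sequence, lexicographically below every group symbol and excluded from
  the suffix array, so no match can cross a sequence boundary. Database
  wildcard (`X`) positions get their own distinct never-matching codes;
  query wildcards match nothing, so masked or ambiguous residues can
  never seed.
- **Hexamer median.** The median is taken over the counts of *distinct
  observed* 6-mers (not over all $10^6$ possible words, and not over
  positions), floored to an integer — for integer counts the seed-length
  decision $f \le \tilde f$ is unchanged by flooring.
- **Composition.** Residue composition is measured on the reduced
  database text, and the lengthening step uses the database composition
  of the query's symbol at each successive position.
- **Seed-length pseudocode fix.** Read literally, "extend while the
  expected frequency is *below* the median" never terminates (the product
  only shrinks once lengthening begins); the implemented rule extends
  while the expected frequency remains *above* the median, the only
  reading consistent with longer seeds for frequent words and a 6–9
  range.
- **Efficiency statistic.** Defined as log10 of the ratio of homolog to
  non-homolog pairs with at least one seed; a +1 pseudocount is applied
  to a zero denominator so the statistic stays finite on small synthetic
  sets. Coverage counts *pairs* (not individual proteins).
- **Anchor choice.** Gapped extension starts from the highest-scoring
  single column of the ungapped segment. With an infinite X-drop and an
  anchor lying on an optimal local path, the two anchored half-extensions
  provably attain the Smith–Waterman optimum (the anchor is a diagonal
  column, so no affine gap state crosses it); with a finite X-drop the
  score can only be lower. Both facts are tested.
- **Deduplication.** A seed falling entirely inside the query and subject
  span of an alignment already produced for the same record is not
  re-extended; identical alignments are dropped.
- **Stops and frames.** Six-frame translation keeps stop codons as `*`
  in the frame (no ORF splitting); the strongly negative `*`-vs-residue
  scores block extension across real stops. Translation uses the standard
  code with initiator-codon logic disabled (a mid-read TTG is leucine,
  not methionine); codons containing ambiguous bases become `X`.
- **Masking.** A single-pass Wootton–Federhen-style scheme: windows below
  the trigger entropy, extended over adjacent windows below the extension
  entropy, are masked to `X`. Window entropy counts each wildcard as a
  distinct singleton symbol, which makes masking provably idempotent
  (splitting mass can only raise entropy, so masked runs never drag
  neighbouring windows under the cutoffs). Masking affects seeding and
  scoring; reported alignments display (and count identities over) the
  original residues, so a reported percent identity refers to the
  unmasked sequence while the score and E-value are computed
  conservatively on the masked one. Full recursive SEG refinement is out
  of scope; the contract — low-entropy runs cannot seed or score — is
  what the pipeline needs. Masking is applied to queries only by default
  (database masking was left off; the statistic-relevant masking is on
  the translated reads).
- **Coordinates.** R-facing interfaces are 1-based inclusive; tabular
  output follows the translated-search convention with `qstart > qend`
  on the minus strand. Mismatch positions within seeds are reported
  1-based (columns 4–7).
- **Index persistence.** A single serialized file with an embedded format
  version tag, checked on load; a round trip reproduces every field
  exactly, and index construction is fully deterministic (byte-identical
  rebuilds).

## Synthetic data: what it emulates and what it does not

The generators stand in for curated benchmark data so that every stage is
testable offline:

- `generate_protein_db()` draws i.i.d. residues from the
  Robinson–Robinson background composition — realistic marginal
  frequencies, but no domain structure, repeats, or true homology.
- `mutate_homolog()` produces pairs of controlled identity (substitutions
  sampled $\propto e^{\mathrm{BLOSUM62}}$ off the diagonal, geometric
  indels, resampling until the realized identity is within ±5 points of
  target, with the true alignment recorded for oracle scoring). The
  alphabet-evaluation experiments use 20–40% identity pairs, the range
  where reduced-alphabet seeding matters most.
- `simulate_reads()` samples uniform fragments from either strand of
  back-translated coding sequences (default 72 nt, a typical short-read
  length), recording the true origin for recall scoring. There is no
  platform error model.

Passing tests on these inputs therefore demonstrates algorithmic
correctness (oracle equivalence, statistics self-consistency, recall
against a Smith–Waterman oracle under the stated conditions), not
performance on real metagenomes: real databases have skewed redundancy,
real reads have sequencing errors, and real homology is not an i.i.d.
substitution process.

## Problem sizes in the test suite

Oracle-equivalence checks run on randomized instances up to ~2,000 text
symbols and 200-residue queries (100 trials per stage); the end-to-end
sensitivity experiment uses a 200-protein database with 50 queries at
~60% and 50 at ~25% identity, scored against a Smith–Waterman oracle at
E ≤ 1e−3. These sizes exercise every code path while keeping the default
suite fast; all generators accept seeds, so the instances are exactly
reproducible.

## Known limitations

- Single-threaded; no memory-mapped or compressed index.
- No spaced seeds, multi-mismatch seeds, seed chaining, or two-hit rule.
- No composition-based score adjustment or multi-HSP sum statistics;
  λ and K are the published constants, not re-solved from the matrix.
- Database non-redundancy filtering (e.g. clustering at 98%) is assumed
  to have happened upstream.
- The coverage/efficiency experiment runs on synthetic pairs; absolute
  coverage values are not comparable to curated-alignment benchmarks,
  though the orderings the tests assert (coverage monotone in seed
  length, reduced dominating identity alphabets) are scale-free.
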