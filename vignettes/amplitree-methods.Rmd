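---
title: "Methods: in-silico primer evaluation and eDNA read processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico primer evaluation and eDNA read processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplitree)
```

## Scope and model

`amplitree` supports two connected tasks in broad-taxon environmental-DNA
(eDNA) surveys:

1. **Primer evaluation.** Before sequencing, a "universal" primer pair
   (one intended to amplify a whole taxon, e.g. all mammals) is screened
   against a local taxonomy-annotated reference database: which taxa would it
   amplify, and does the amplified fragment carry enough variation to tell
   species apart? The result is a taxonomically annotated Neighbor-Joining
   tree of predicted amplicons plus per-rank resolution metrics.
2. **Read processing.** After sequencing a multiplexed run (many samples,
   several taxon-targeted assays pooled per sample, 6-nt sample indices),
   reads are demultiplexed, primer-trimmed, filtered, merged into consensus
   sequences, dereplicated, and assigned to species by best-hit identity,
   yielding a per-sample species presence/absence matrix and exact
   association tests against sample groupings.

Everything operates on a *local* reference database (FASTA plus a
tab-separated lineage table over the fixed rank ladder superkingdom →
species). Remote database services are deliberately out of scope: a local
database makes results reproducible and lets the user restrict the search to
one taxon (`subset_by_taxon()`), e.g. to ask whether a primer pair is
informative *within* a single family.

## In-silico PCR

A primer may contain IUPAC ambiguity codes; each degenerate position
multiplies the number of concrete primer sequences by up to four.
`expand_degenerate()` enumerates all concrete permutations when there are no
more than `permutation_cap` (default 25) and otherwise samples that many
distinct permutations uniformly without replacement. `match_primer()` itself
is degeneracy-aware, so prediction does not depend on expansion; the
expansion exists for workflows that need concrete oligos.

Primer-binding semantics are deliberately simple and fully declared, since
heuristic search engines do not publish a precise contract:

* a site is a hit when it has at most `max_mismatch_per_primer` (default 2)
  mismatches **and** its final `three_prime_exact` (default 2) 3' bases match
  exactly — mismatches at the 3' terminus abolish polymerase extension;
* a degenerate primer position matches any base of its set at zero cost;
* an `N` (or any ambiguity code) in the *reference* never satisfies a primer
  position — the conservative reading;
* both strands are scanned, and every inward-facing forward/reverse hit
  combination whose product (primers included) lies within the pair's
  `[min_product, max_product]` (defaults 50–3000 bp) yields one amplicon.
  No "shortest product wins" rule is applied; the amplicon cap handles
  pathological references.

When more than `amplicon_cap` (default 500) amplicons are predicted, that
many are sampled uniformly without replacement with a caller-supplied seed;
below the cap the result is deterministic and seed-independent. The insert
(the sequence strictly between the primer sites, reported 5'→3' from the
forward primer) is what downstream alignment and identity work on, and all
coordinates are 0-based half-open on the reference plus strand, so every
insert is re-extractable from its reference.

## Alignment, trees and resolution metrics

Amplicons from one assay are short homologous fragments of similar length,
so a center-star multiple alignment is adequate for counting nucleotide
differences and is exactly reproducible: the center is the sequence with the
smallest total pairwise Levenshtein distance (ties: lowest input index);
every other sequence is globally aligned to the center under unit costs and
gaps are merged by "once a gap, always a gap". Pairwise distances are plain
difference counts — base-vs-gap counts as a difference, gap-vs-gap is
skipped, and any column containing `N` in either row is skipped.

`nj_tree()` implements Saitou–Nei Neighbor-Joining with the standard Q
criterion. Ties in the minimum of Q are broken toward the lexicographically
smallest pair of positions in the current matrix (which follows the input id
order, with joined nodes appended at the end), and negative estimated branch
lengths are clamped to zero. On additive matrices the algorithm recovers the
generating tree exactly; the test suite verifies this on random trees of up
to 8 tips with integer branch lengths at tolerance 1e-9, and cross-checks
topologies against an independent NJ implementation. Because amplicons are
short, these trees are a primer-assessment device, not an estimate of the
true species phylogeny; branch lengths (in nucleotide differences) indicate
how distinguishable the amplified taxa are.

`resolution_summary()` reports, per rank: the number of distinct taxa
amplified, the mean pairwise difference between amplicons of the same taxon,
and the mean number of distinct taxa sharing each unique insert sequence. At
the species rank the last metric is the familiar "species per unique
sequence": 1.0 means every amplicon identifies one species; large values
flag a marker that cannot separate species at all.

## Read processing

The pipeline stages mirror the laboratory design — per-sample PCR with 12
pooled taxon assays, 6-nt indices distinct at Hamming distance ≥ 2, 250 bp
paired-end reads — and keep an explicit per-stage rejection log so that
reads are conserved: `unassigned + rejections + merged = input`.

* **Demultiplexing** is exact-match only by default. With indices designed
  at pairwise distance 2, a single sequencing error can sit at distance 1
  from *two* different indices, so single-error correction could mis-assign
  reads; discarding them is the safe choice. `design_index_set()` constructs
  index sets greedily from a seeded stream and an error states the count
  reached if the request is infeasible.
* **Primer identification** searches each assay's forward primer at the 5'
  end of read 1 (offsets 0–5) and the reverse primer at the 5' end of read
  2, degeneracy-aware, at most 2 mismatches each. The assay minimizing total
  mismatches wins; an exact tie across assays is rejected as `ambiguous`
  rather than guessed. Primers and any preceding bases are trimmed. Because
  some assays amplify fragments far shorter than the read (down to ~17 bp
  plant inserts), the read continues through the opposite primer into
  adapter; the reverse complement of the opposite primer is therefore
  searched inside each insert and everything from it onward is trimmed.
* **Length filters** then discard pairs whose insert is shorter than the
  assay minimum (50 bp default; short-amplicon assays override it in the
  panel, e.g. 17 bp for plant trnL) and pairs whose two inserts differ by
  more than 5 bp — the signature of a primer found in only one mate. The
  minimum-length rule is applied per trimmed mate *before* merging,
  matching the stated order trim → length filter → merge.
* **Merging** reverse-complements read 2 and slides it along read 1; among
  offsets with overlap ≥ 10 bp and overlap identity ≥ 0.8 the offset
  maximizing (+1 match / −1 mismatch) wins, smaller offsets breaking ties.
  Agreements are kept; disagreements resolve to the base with the higher
  Phred score, quality ties keeping the read-1 base. This replaces a
  probabilistic merger with a deterministic, testable rule: error-free pairs
  reconstruct their fragment exactly (a property the suite checks on 500
  random fragments of 60–400 bp).
* **Dereplication** collapses identical (assay, sequence) strings and counts
  reads per sample; it is order-invariant and count-conserving.

## Taxonomic assignment and presence calls

Unique sequences observed in fewer than 10 reads *total across all samples*
are removed first; at realistic depths genuine templates are represented by
hundreds of reads (a species at 1% of a sample averaging 14,211 reads is
expected in ~142), so singletons and doubletons are overwhelmingly PCR or
sequencing errors. The simulation reproduces this signature: at a 0.005
per-base error rate the filter removes most *unique sequences* while
removing well under 5% of *reads*.

Each surviving sequence is compared against every reference with a glocal
(semi-global) alignment: the query aligns end-to-end, end gaps on the
reference are free, and edits cost one unit. Among minimum-edit alignments
those with fewer internal gaps are preferred — a terminal mismatch is scored
as a substitution rather than dodged by gapping the reference, which would
otherwise let two markers differing only at their last base tie at identity
1.0 — and among those the one with the most matches is scored. Identity is
matches divided by
query length; `N` matches nothing, so an all-`N` query has identity 0. A
sequence is assigned only when its best identity **strictly** exceeds 0.90
("greater than 90%" read literally — 0.90 exactly is unassigned), and the
species set keeps *all* references tied at the maximum, because short
markers often cannot separate close species. Exhaustive comparison against
a small local database is exact and removes the database-version
nondeterminism that heuristic remote searches suffer from.

Per sample, read counts are summed over all unique sequences whose species
set contains a given species (a tied sequence counts toward every tied
species — a deliberate, documented over-count) and a species is called
present at ≥ 10 reads in that sample. Whether the per-sample rule should
apply per unique sequence or per species sum is genuinely open; the species
sum is the default here (and configurable) because presence is a
species-level claim. Species seen in blank extraction controls are visible
in the matrix rather than auto-subtracted, so contamination is flagged, not
silently removed. `fisher_association()` tests presence against a 2–3-level
sample grouping (region, collection time) with Fisher's exact test on the
per-sample presence table, returning p = 1 with a warning when a margin is
zero; p-values are reported raw, without multiplicity correction.

## The simulator: what it emulates and what it does not

`simulate_study()` generates the complete input of a run: a reference
database, an index set, per-sample species compositions, indexed paired
FASTQ reads and blank controls, with full ground truth. Its defaults *are*
the study conditions of the test suite and acceptance runs:

* three assays with contrasting insert lengths (~100 bp mammal-type, ~160 bp
  fish-type, ~48 bp plant-type with a 17 bp minimum), one degenerate primer
  position among them;
* per clade, 2 families × 2 genera × 2 species evolved by i.i.d.
  substitution down a star-shaped taxonomy at 0.12/0.05/0.02 substitutions
  per site per level, so within-genus < within-family distances in
  expectation; species inserts are forced distinct within an assay;
* 12 samples plus 2 blank controls; 5,000 read pairs per sample; 3–6
  species per sample with fractions drawn as `runif(1, 10)` normalized, so
  every fraction stays near or above 2% — comfortably detectable at this
  depth; regions (upper/middle/lower) and two collection timepoints are
  assigned on the sheet;
* 250 bp reads; a 0.005 per-base substitution error rate; constant Phred 37
  with error-linked dips to Phred 15; errors also hit the index read, which
  exercises the exact-demultiplexing policy.

Deliberately **not** modeled: amplification-efficiency competition between
templates, PCR chimeras, indels, quality decay along the read, and
cross-contamination. Passing the end-to-end tests therefore demonstrates
the pipeline's correctness under its stated assumptions — lossless
reconstruction, exact threshold behavior, correct bookkeeping — not
robustness to every artifact of real sequencing runs. The quality model is
the minimum needed to test quality-resolved conflict handling in the
merger; because opposite-strand errors rarely coincide, most simulated
errors are corrected during merging and the survivors are exactly the
low-count unique sequences the 10-read filter is designed to remove.

## Numerical choices and degenerate inputs

* Sequences are uppercased and RNA `U` normalized to `T` on input; duplicate
  ids, missing taxonomy columns and non-IUPAC characters are hard errors
  naming the offender.
* All sampling (permutations, amplicon cap, index design, simulation) uses
  a single seeded generator per invocation and restores the caller's RNG
  state; identical seeds give byte-identical runs.
* Branch lengths are clamped at zero after estimation; distance matrices
  must be symmetric; trees need ≥ 3 ids, alignments ≥ 1 sequence.
* Empty subsets, zero amplicons, empty assignments and blank samples are
  valid results (logged), not errors.
* Problem sizes in the test and acceptance runs — 200 random trees of ≤ 8
  tips, 100 random 1 kb primer-matching instances, 500 merge round-trips,
  two 60,000-pair studies — were chosen as the smallest sizes that exercise
  every code path while completing in about a minute each on one CPU.

## Known limitations

Center-star alignment can differ from a profile aligner on gappy inputs;
since the package counts differences on short, nearly equal-length inserts,
this affects tree topology far less than it would a real phylogenetic
analysis — and these trees are explicitly a screening device. The presence
over-count for tied species means a sequence shared by *k* species
contributes to all *k*; resolution metrics make this visible. Identity
against a small local database is only as good as the database: a missing
species is attracted to its closest sequenced relative, which is why
low-identity best hits deserve caution and why the threshold is strict.
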