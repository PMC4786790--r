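# amplitree

Tools for two connected tasks in broad-taxon environmental-DNA (eDNA)
surveys, where water or soil samples are amplified with "universal"
(taxon-wide) primer pairs and sequenced to identify the species that shed
the DNA:

1. **In-silico primer evaluation.** Given a local, taxonomy-annotated
   reference database, predict which sequences a (possibly degenerate)
   primer pair would amplify, align the predicted amplicons, build a
   taxonomically annotated Neighbor-Joining tree, and compute per-rank
   resolution metrics. Long branches mean the marker can distinguish
   species; a high "species per unique sequence" means it cannot.
2. **Metabarcoding read processing.** Turn a multiplexed sequencing run
   (indexed paired 250 bp reads pooled over many samples and several
   taxon-targeted assays) into a per-sample species presence/absence
   matrix: exact demultiplexing on 6-nt indices, degeneracy-aware primer
   identification and trimming (including 3' read-through across short
   amplicons), length filters (50 bp minimum, 5 bp pair-difference rule),
   quality-resolved pair merging, dereplication, a 10-reads-total abundance
   filter, best-hit species assignment at strictly >90% glocal identity
   with multi-species ties retained, a 10-reads-per-sample presence rule,
   and Fisher's exact association tests against sample groupings.

A simulation module generates complete synthetic runs — taxonomy-structured
reference databases, per-sample compositions, indexed FASTQ reads with a
configurable error model, and blank controls — with full ground truth, so
every stage is testable without downloading anything.

## The core quantities

For a primer pair *P* against database *D*, in-silico PCR reports every
inward-facing pair of binding sites with ≤ 2 mismatches per primer, an
exact 2-base 3' terminus, and product length within bounds; degenerate
positions match their IUPAC set freely and reference `N` matches nothing.
Amplicon distances are plain nucleotide differences from a center-star
alignment, and the tree is Saitou–Nei Neighbor-Joining (ties broken
deterministically, negative branch lengths clamped to zero). For a query
read *q* and reference *r*, assignment identity is

```
identity(q, r) = matches(q, r) / |q|
```

from a glocal alignment (query end-to-end, free end gaps on the reference,
unit edit costs, maximum matches among minimum-edit alignments). A species
is called present in a sample when its reads — summed over all unique
sequences assigned to it — reach 10 in that sample.

## Worked example

```r
library(amplitree)

## 1. primer evaluation against a simulated reference database
ref <- simulate_reference_db(sim_config(seed = 42))
pt  <- primer_tree(ref$db, ref$panel[1, ], rank = "genus")
pt
#> primer_tree analysis
#> in-silico PCR summary: 8 amplicon(s)
#>   insert length: min 100 / mean 100.0 / max 100 bp
#>   distinct taxa amplified:
#>     superkingdom  1
#>     phylum        1
#>     class         1
#>     order         2
#>     family        2
#>     genus         4
#>     species       8
#>   tree: 8 tips, 4 taxa at annotation rank
```

The mammal-type assay amplifies all 8 simulated mammal species and no
off-target clade. Resolution metrics show the marker separates even genera:
the mean pairwise difference *within* a genus (4.25 nt) is far below the
within-class value (23 nt), and every unique amplicon maps to exactly one
species:

```r
resolution_summary(pt$amplicons)
#>           rank distinct_taxa mean_within_taxon_pairwise_diff mean_species_per_unique_sequence
#> 1 superkingdom             1                           23.00                                1
#> 4        order             2                           13.25                                1
#> 6        genus             4                            4.25                                1
#> 7      species             8                              NA                                1
```

```r
## 2. full read pipeline on a simulated 12-sample run (5,000 pairs/sample,
##    0.005/base error rate, 2 blank controls)
study <- simulate_study(sim_config(seed = 42))
res   <- run_read_pipeline(study$pairs, study$sheet, study$panel)
res$log
#>           stage          reason     n
#> 1   demultiplex      unassigned  1736
#> 2          trim       no_primer    22
#> 3 length_filter length_mismatch    15
#> 4         merge          merged 58227

fl <- filter_low_count(res$derep, min_total = 10)
#> removed 160 of 181 unique sequences (0.28% of reads)
asn <- assign_best_hit(fl$kept, study$db)
pm  <- presence_matrix(asn, fl$kept, study$sheet)
pm
#> presence_matrix: 14 sample(s) x 21 species, threshold 10 reads
#>   44 presence call(s)
```

Reads are conserved through every stage (1,736 + 22 + 15 + 58,227 =
60,000). The 10-reads-total filter removes 88% of *unique sequences* —
the error-derived ones — while discarding only 0.28% of *reads*, and the 44
presence calls reproduce the simulated ground truth exactly (both blank
controls stay empty). The read-count arithmetic behind that filter:

```r
expected_read_count(0.01, 14211)   # a 1% template at mean mammal depth
#> [1] 142
```

A thin command-line wrapper over these functions is installed at
`inst/cli/amplitree.R` (subcommands `db`, `pcr`, `tree`, `simulate`,
`pipeline`).

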