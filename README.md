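# synsieve

Collection and dereplication of genomic neighbourhoods for
neighbourhood-scale synteny plots.

## The problem

Comparative analyses of clustered genes — most prominently biosynthetic
gene clusters (BGCs) — are usually presented as synteny plots: one track
per genomic neighbourhood, genes drawn as arrows, homologous genes linked
across tracks. Homology searches over public databases routinely return
dozens to hundreds of candidate neighbourhoods, most of them
near-duplicates (same strain deposited many times, closely related
isolates). Redundant tracks make a synteny plot unreadable and can exceed
what plotting tools accept at all. `synsieve` prepares a *diverse*,
*named*, *fixed-length* set of neighbourhoods:

* **collect** — parses a [cblaster](https://github.com/gamcil/cblaster)
  "binary" hit table, cuts a fixed-length span centred on each clustered-hit
  interval out of the source record, filters hits that are too dispersed
  (their own span exceeds the requested neighbourhood length) or sit on
  contigs too short to supply the span, and writes each survivor as a
  GenBank file named after its accession or organism — so downstream
  plotting tools label tracks automatically.
* **sieve** — dereplicates any folder of GenBank neighbourhoods. All
  protein products are compared all-vs-all; for each pair of
  neighbourhoods *A*, *B* the similarity is

  ```
  s(A, B) = |RBH(A, B)| / min(|genes(A)|, |genes(B)|)
  ```

  the proportion of genes in the smaller neighbourhood that have a
  reciprocal best hit (RBH) in the larger one. Pairs whose similarity
  *exceeds* a user threshold (default **0.7**) become edges of a
  similarity graph, which is pruned by deterministic greedy
  maximum-degree vertex deletion until no edge remains: every surviving
  pair of neighbourhoods is at most `threshold`-similar. Similarity is
  deliberately treated as a graph property, not a clustering, because it
  is non-transitive: *A* and *B* can each resemble *C* without resembling
  each other.

Every sieve run also writes diagnostics for threshold tuning: a
self-contained interactive HTML view of the similarity graph
(kept/removed status and organism per node, similarity per edge) and a
histogram of *all* non-zero pairwise scores with the active threshold
marked.

Alignments run through a pluggable engine: a built-in deterministic
Smith–Waterman (BLOSUM62, gap open 11 / extend 1, Karlin–Altschul
bitscores — no external binaries needed), or `blastp` / DIAMOND when
installed.

## Worked example

The package ships a synthetic-neighbourhood generator whose construction
fixes the right answer in advance: genes are mutated copies of shared
"family" proteins, so the expected similarity between two neighbourhoods
is `shared families / min(gene count)`. Three near-identical copies of a
five-gene neighbourhood plus one unrelated three-gene neighbourhood:

```r
library(synsieve)

spec <- family_spec(
  n_families = 8,
  plans = list(copy1 = 1:5, copy2 = 1:5, copy3 = 1:5, outsider = 6:8),
  substitution_rate = 0.02, seed = 101
)
dir <- file.path(tempdir(), "neighbourhoods")
build_neighbourhood_set(spec, dir)

report <- sieve(dir, threshold = 0.7, out_dir = file.path(tempdir(), "sieved"))
#> INFO  sieve  kept 2 of 4 neighbourhoods (threshold 0.70)

report$scores
#>   label_i  label_j score n_rbh
#> 1   copy1    copy2     1     5
#> 2   copy1    copy3     1     5
#> 3   copy1 outsider     0     0
#> 4   copy2    copy3     1     5
#> 5   copy2 outsider     0     0
#> 6   copy3 outsider     0     0

report$removed
#>   label trigger_neighbour degree_at_removal
#> 1 copy3             copy1                 2
#> 2 copy2             copy1                 1

report$kept
#> [1] "copy1"    "outsider"
```

The three copies score 1.0 pairwise (all five genes of the smaller
neighbourhood have an RBH) and form a triangle above the 0.7 threshold;
greedy pruning deletes two of them and keeps one representative plus the
unrelated neighbourhood, whose scores are 0.0. The kept files in
`sieved/kept/` are byte-identical copies of their inputs, ready for a
synteny plotting tool such as clinker.

The same run from a shell, via the bundled launcher:

```sh
Rscript inst/scripts/synsieve sieve -gf neighbourhoods/ -sf 0.7 -o sieved/
Rscript inst/scripts/synsieve collect -bp binary.csv -ns 60000 \
    -fn organism -em you@example.org -o collected/
```

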