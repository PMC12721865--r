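---
title: "Neighbourhood collection and dereplication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbourhood collection and dereplication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`synsieve` prepares genomic neighbourhoods for neighbourhood-scale
synteny plots in two stages: **collect** (extraction of fixed-length,
centred, quality-filtered neighbourhoods from the records named in a
cblaster hit table) and **sieve** (removal of redundant neighbourhoods by
reciprocal-best-hit similarity and graph pruning). This vignette explains
the model behind each stage, the parameters that matter, the numerical
conventions, and the design choices that were genuinely open.

## Coordinates and gene model

GenBank files are 1-based and inclusive on disk; internally every
coordinate is 0-based and half-open, converted only at the I/O boundary.
A *neighbourhood* is a nucleotide interval plus an ordered table of
protein-coding genes: only CDS features participate, because the
similarity metric is protein-based — tRNA/rRNA/pseudo features are
ignored for scoring. A CDS without a `/translation` qualifier is
translated from its span with translation table 11 (bacteria/archaea)
when the span is a codon multiple, otherwise skipped with a logged
warning; trailing stop symbols are stripped to normalize GenBank
dialects. Compound (`join`) locations keep their outermost span for plot
geometry but are translated from the joined exons. Gene identifiers come
from `protein_id`, then `locus_tag`, then a positional `cds_<n>`
fallback, and are de-duplicated within one record.

## Collect

Each row of the cblaster binary table carries an organism, a scaffold
accession and a hit interval. For a requested neighbourhood length
$L$ (bp) the span is centred on the hit midpoint using integer
arithmetic: $m = \lfloor (s+e)/2 \rfloor$, span
$[m - \lfloor L/2 \rfloor,\; m - \lfloor L/2 \rfloor + L)$. Two quality
filters apply:

* **dispersed** — the hit interval itself is longer than $L$: the
  clustered hits do not fit the requested span, so a fixed-length
  neighbourhood centred on them would truncate them arbitrarily;
* **small** — the span overhangs its contig. In strict mode the row is
  rejected (typically a fragmented contig); in permissive mode the span
  is clamped to the contig, provided the clamped span still covers the
  whole hit interval.

Both behaviours are exposed (`strict`) because truncation versus
rejection is a genuine analysis decision; strict is the conservative
default in the examples. Genes straddling a span boundary are dropped
(and logged) rather than truncated: a partial gene would align as a
spurious fragment. Records are obtained through an injected fetcher
contract — an NCBI Entrez `efetch` client with retry/backoff for
production, a local-fixture resolver for tests and offline work — so no
code path in the test suite touches the network. Per-row failures
(missing accession, malformed record) are recorded, never fatal: the
report partitions every input row into written / dispersed / small /
fetch-failure, and that partition is asserted on every run.

Multiple rows on the same scaffold are treated as independent
neighbourhoods and disambiguated by file-name suffixes; losing hits
silently would be worse than writing near-duplicate files that sieve can
remove later.

## Sieve

### Similarity score

All protein products are compared all-vs-all. Hits are kept when
`evalue <= 1e-5` and `percent identity >= 50` — conventional
homology-screen defaults, exposed as parameters (`max_evalue`,
`min_identity`) rather than hidden. Per neighbourhood pair, best hits in
each direction (maximal bitscore; ties by identity, then lexicographic
subject id) are intersected into reciprocal best hits, which form a
partial matching by construction. The pair score is

$$ s(A,B) = \frac{|\mathrm{RBH}(A,B)|}{\min(|A|, |B|)} \in [0,1], $$

with $|A|$ the gene count: the proportion of genes in the smaller
neighbourhood with a reciprocal best hit in the larger one. The
denominator makes a small cluster embedded in a larger region score
high — intended, since such pairs are redundant *as synteny-plot
tracks*.

### Alignment engines

The engine is pluggable behind one contract (qualified ids
`label::gene`, tabular `query, subject, pident, evalue, bitscore`):

* **builtin** (default): Smith–Waterman local alignment via Biostrings,
  BLOSUM62, gap open 11 / extend 1; bitscores from the standard gapped
  Karlin–Altschul constants for that matrix ($\lambda = 0.267$,
  $K = 0.041$); e-values against the concatenated subject-set size.
  Deterministic and dependency-free, suitable for the tens-of-proteins
  scale of neighbourhood sets.
* **blast** / **diamond**: shell out to `blastp` or `diamond blastp`
  (DIAMOND at `--very-sensitive`, one HSP per pair). The FASTA and raw
  tabular output stay in the run folder for audit.

Raw scores differ between engines, but the *matching* must not: the test
suite asserts identical RBH sets between the builtin path and `blastp`
on fixture sets, and against DIAMOND when a binary is present.

### Graph pruning

Scores strictly greater than the threshold (default **0.7**; "exceeds"
is read as strict inequality) define edges on the neighbourhood labels.
The graph is pruned by greedy maximum-degree deletion:

> while edges remain: delete the node of maximal degree — ties broken by
> maximal sum of incident edge weights, then by lexicographically
> largest label — together with its edges.

This guarantees the postcondition that no surviving pair exceeds the
threshold (asserted on every run), removes the most redundant hubs
first — retaining as much diversity as possible for a greedy
minimum-vertex-cover-style heuristic — and is fully deterministic: the
kept set does not depend on file enumeration order, and re-sieving a
sieve output removes nothing. Whether greedy-by-degree is the *optimal*
deletion order is deliberately out of scope; determinism and the safety
postcondition are the contract. Each removal records a *trigger
neighbour* — the neighbour on the heaviest incident edge
(lexicographically smallest on ties) — as a human-readable hint for why
the node went.

Kept neighbourhoods are copied **byte-identically**: a filter must not
mutate data it merely selects.

### Choosing the threshold

Two diagnostics support tuning. The interactive HTML view draws the
supra-threshold (pruning) graph — the structure pruning acts on — with
kept/removed styling and organism tooltips, so neighbourhood redundancy
can be compared with host diversity within a sub-network. The histogram
bins **all** non-zero pairwise scores (not only supra-threshold edges)
into 20 fixed-width bins over $(0,1]$ with the active threshold marked:
pre-threshold scores are what one needs to predict how moving the filter
would change the topology. If most mass sits near 1.0, raising the
filter changes little and collecting longer neighbourhoods that extend
beyond the conserved core is the better lever; large neighbourhoods
stretching far beyond the core may conversely need a lower filter.

## Synthetic neighbourhood generator

The generator builds neighbourhoods from ancestral protein families:
uniform-random proteins (≥ 30 residues; default 100) copied into
neighbourhood plans and mutated at a per-residue substitution rate
(default 0.02, i.e. ~98% identity between copies). Back-translation uses
a fixed codon per residue (lexicographically first table-11 codon) and
genes are laid head-to-tail with 50 nt spacers, so regenerated sets are
byte-identical under a fixed seed. By construction the expected RBH
count between two neighbourhoods is the number of shared families and
the expected score is `shared / min(gene count)`; the recorded manifest
therefore provides exact expectations, which the pipeline must
reproduce *exactly* at low substitution rates (≤ 0.05), where best hits
are unambiguous.

What the generator deliberately does **not** emulate: realistic codon
usage, indels and rearrangements, paralogous gene families *within* one
neighbourhood, partial genes at contig edges, and annotation noise. A
green test suite therefore demonstrates correctness of the scoring and
pruning machinery under controlled homology, not robustness to
real-world annotation pathology; high internal homology (many paralogs)
in real data can still make best hits ambiguous and depress RBH counts.

## Numerical and testing conventions

* Even-length spans use `floor()` for midpoint and half-length;
  documented, deterministic.
* Best-hit and pruning tie-breaks are total orders, so every result is
  reproducible bit-for-bit.
* Property tests draw edge weights from the dyadic grid $k/64$: sums of
  such weights are exact in floating point, so weight-sum tie-breaks
  cannot depend on summation order.
* Pruning is validated against an independent, matrix-based
  transcription of the greedy rules on exhaustively re-seeded small
  graphs (n ≤ 7), plus safety/idempotence checks on random matrices up
  to n = 15. Problem sizes throughout the suite (families of ~100
  residues, neighbourhoods of 1–7 genes, sets of 2–5 neighbourhoods)
  were chosen as the smallest scales at which alignment behaviour is
  stable and every contract is exercised.

## Known limitations

* **Threshold monotonicity does not hold.** Raising the threshold
  *usually* increases the kept count, but greedy vertex deletion admits
  counterexamples: a denser low-threshold graph can contain a hub whose
  early removal saves more nodes than the sparser high-threshold graph,
  where deletions cascade one edge at a time. Treat kept counts at
  different thresholds as independent runs, not a nested family.
* The score is gene-content-based and order-blind: two neighbourhoods
  with identical gene sets but rearranged order score 1.0. Synteny-aware
  (order-conserving) matching is out of scope.
* Single-record GenBank files only; EMBL/GFF input and nucleotide-level
  similarity are out of scope.
* The greedy deletion order is one principled, deterministic choice
  among several defensible pruning strategies (e.g. component
  representative selection); alternatives would keep the same safety
  postcondition but may retain different representatives.
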