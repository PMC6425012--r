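---
title: "Variant-to-gene mapping with promoter Capture C and ATAC-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-to-gene mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capv2g)
```

## The problem and the model

Most GWAS signals are non-coding, and the gene a risk variant regulates need
not be the gene it sits in or the nearest one. This package implements a
physical mapping from variants to candidate effector genes in a single
assayed cell type. It takes three inputs measured (or computed) in that cell
type — LD proxy sets around GWAS sentinels, ATAC-seq open-chromatin peaks,
and significant promoter-focused Capture C interaction calls — and emits, per
locus, the proxies in open chromatin that physically contact an open gene
promoter.

A proxy variant $v$ is linked to gene $g$ iff all four predicates hold:

1. **open(v)**: the 1-bp interval of $v$ overlaps an ATAC-seq peak;
2. **non-bait(v)**: the restriction fragment containing $v$ is not itself a
   baited promoter fragment — a variant inside a promoter needs no loop to
   implicate that promoter, and such contacts would be trivially confounded
   by the capture design;
3. **loop(v, g)**: a retained interaction call joins $v$'s fragment (or a
   4-fragment bin containing it) to a bait fragment of $g$;
4. **open-promoter(g)**: at least one baited fragment of $g$ overlaps a peak.

The conjunction is deliberately conservative: each predicate removes a
distinct failure mode (closed decoy variants, promoter-resident variants,
sub-threshold contacts, contacts to inactive promoters).

## Coordinates and interval arithmetic

All internal coordinates are 0-based half-open (BED convention); 1-based
variant positions are converted on ingest to the point interval
$[pos-1, pos)$. *Open* means a shared ≥ 1 bp: two intervals overlap iff
$\max(\text{starts}) < \min(\text{ends})$, so touching intervals do not
overlap. rmap/baitmap exports use the 1-based start convention of the
interaction-calling ecosystem; the conversion is applied on write and
inverted on read. Interval overlap itself is delegated to
GenomicRanges/IRanges; the test suite checks it against brute-force double
loops rather than trusting either implementation alone.

## Restriction map, bins, and baits

`digest_genome()` places a cut at the 0-based start of every occurrence of
the recognition site (default `GATC`, the DpnII site; matching is
case-insensitive; a cut at index 0 is a no-op). Any consistent cut-offset
convention yields identical fragment counts; cutting at the site start is
simplest and makes rmap files reproducible. Fragments tile each chromosome
exactly and carry globally ascending integer ids.

`bin_fragments(fm, k = 4)` groups consecutive runs of `k` fragments per
chromosome (final bin possibly smaller; bins never span chromosomes, since
cross-chromosome bins would make cis distances meaningless). The binned map
exists because single short fragments rarely have the read depth to support
longer-range interaction calls; calls are made at both resolutions and merged.

`design_baits()` baits every fragment overlapping $[tss - w, tss + w]$
(default $w = 0$: point containment). The unit of capture is the whole
fragment — probe placement at fragment ends is an experimental detail below
the resolution of this analysis. One fragment may serve several genes and a
gene with alternative promoters several fragments; promoter openness is
*any-bait-open*.

## Merging two call resolutions

`merge_resolutions()` keeps the union of both call sets at native
resolution. By default a 4-fragment call is removed when a 1-fragment call
exists whose bait and other-end fragments are contained in the corresponding
bins — the high-resolution call carries strictly more information. The
published analysis says only that the two call sets were "merged"; the
containment rule is this package's design choice, and the plain union is
available with `dedup = FALSE`. Output order is sorted and therefore
independent of input order.

Cis distance is measured midpoint-to-midpoint between anchors: symmetric and
well-defined at both resolutions (the distance convention of the original
analysis is not stated). A call is bait-to-bait when its other end is — or,
for binned calls, contains — a baited fragment.

## LD proxies

`compute_r2()` implements the standard haplotype-frequency formula
$r^2 = (p_{AB} - p_A p_B)^2 / (p_A(1-p_A)p_B(1-p_B))$; it is symmetric and
invariant to allele relabelling, and tests cross-check it against both
exhaustive contingency counting and squared Pearson correlation.
`find_proxies()` returns all panel variants within a window (default 500 kb,
a conventional LD search radius) with $r^2$ at or above the threshold.

Two conventions deserve note. The threshold comparison is **inclusive**
($\geq 0.8$): the packaged results table itself lists proxies printed at
exactly 0.8, which settles an inconsistency in how the original text states
the cutoff. And the sentinel is always its own proxy with $r^2 = 1$, matching
rows where the sentinel is the only listed proxy. Pre-computed proxy tables
(CSV) are accepted interchangeably with panel-derived ones; both produce the
same record shape.

## Locus classification and summaries

`classify_locus()` compares the implicated gene set with the sentinel's
nearest gene — nearest by TSS distance over all annotated genes, coding and
non-coding, because loci are conventionally named after the nearest gene.
Nearest-TSS (rather than nearest gene body) is a design choice; ties are
broken by smaller `gene_id` and logged. Classification is locus-level (the
worked examples in the source study are locus-level figures); a per-link
variant would only re-weight loci by their link counts.

`annotate_expression()` uses mean-rank percentiles,
$100 \cdot \mathrm{rank}(\mathrm{fpkm}, \text{ties = average}) / n$, with
*highly expressed* meaning percentile strictly above 50. Under this
convention four distinct values score 25/50/75/100; fully tied values share
the mean rank (e.g. 62.5 for four equal values) — ties inflate percentiles
above the midpoint, which is the standard mean-rank behaviour and is the
single convention applied everywhere.

DEXA- and heel-derived loci whose sentinels coincide are labelled "Both"; the
packaged table carries these labels verbatim.

## Enrichment and association tests

`feature_enrichment()` tests whether PIRs overlap a feature set more than
expected. Interaction distance strongly structures both contact frequency
and chromatin state, so the permutation null is **distance-matched**: each
draw samples `|PIR|` regions from the non-significant other-end pool so as to
match the PIRs' decile distribution of distance-to-nearest-bait (sampling
with replacement within a stratum; an unfillable stratum is an error naming
the decile). The empirical p-value uses the add-one rule
$p = (1 + \#\{\text{null} \geq \text{obs}\})/(n_{\text{draws}} + 1)$ and so
is never 0; `n_draws` defaults to 100 and seeded runs are bit-identical.

`welch_test()` is the unequal-variance two-sample t-test written from its
closed form (Welch–Satterthwaite df), used for the open-vs-inaccessible
promoter contact comparison; tests verify it against `stats::t.test` to ten
decimals and calibrate its type-I rate by simulation. The expression–contact
association uses Spearman rank correlation per promoter-openness stratum —
the original report shows the pattern graphically without naming a
statistic, and a rank correlation is assumption-free on the heavy-tailed
contact counts.

## The synthetic-study generator

`generate_study()` builds a complete, self-consistent study whose correct
output is known exactly. Defaults define the validation conditions: 3
chromosomes × 1 Mb, GATC density 2.31/kb (expected mean fragment ≈ 433 bp,
the DpnII regime of the human genome), 80 genes (10% with an alternative
promoter), 20 planted loci (1–2 proxies each, ~30% with a second target
gene, ~30% detectable only at 4-fragment resolution), interaction score
threshold 5, background noise with ~14% bait-to-bait and ~1% trans calls,
plus sub-threshold rows. These sizes keep full generation under a few
seconds while leaving every code path exercised.

Background sequence is uniform over A/C/G/T with accidental `GATC`
occurrences scrubbed before planting sites as a Poisson process — fragment
statistics are thereby controlled by one parameter instead of base
composition. Every placement (target baits, causal fragments, decoys, noise
anchors) claims a distinct 4-fragment bin, so bin-resolution anchors can
never accidentally bridge two planted elements; target genes additionally sit
alone on their bait fragment so a planted loop implicates exactly one
promoter. Four decoy classes each violate exactly one linkage predicate,
which lets test failures be attributed to a specific rule. All randomness
derives from one integer seed through named sub-streams; the emitted fixture
is byte-reproducible.

What the generator does *not* emulate: read-level noise and caller score
distributions (scores are only above/below threshold), realistic LD decay
along a region, GC/mappability structure, multi-donor peak variability
(peaks are consumed as one pre-merged conservative set), or genome-scale
interactome size. Passing the planted-truth test therefore demonstrates the
correctness of the *logic* — the four predicates, the merging, the
bookkeeping — not calibration of the upstream callers on real data, and the
published genome-scale magnitudes (hundreds of thousands of calls, 50.5 kb
median cis distance) are not reproducible at this scale by construction.

## Numerical and degenerate-input choices

* Score and r² thresholds are inclusive everywhere.
* Empty chromosomes digest to zero fragments with a warning; an empty
  interactome is an error ("no calls"); an all-trans interactome reports a
  missing median cis distance.
* `welch_test` errors only in the fully degenerate case (both variances zero
  and equal means); identical samples give $t = 0, p = 1$.
* Enrichment $z$ is defined as 0 when the null is degenerate
  (e.g. features covering everything).
* Genes without baits are marked not-assessable (`NA`) rather than closed.
* Fragment lookup is `findInterval`-based (logarithmic) and exact at
  half-open boundaries: a position equal to a fragment end belongs to the
  next fragment.

## Known limitations

* The designability of real capture probes (repeats, GC, duplicated
  promoters) is out of scope; every promoter fragment is considered baited.
* The interaction caller's statistical model is upstream: its calls are an
  input, and the score-5 default is the caller's conventional cutoff, not a
  fitted quantity.
* The DEXA/heel locus merge rule (identical sentinels, or within 1 Mb in LD
  when a panel is available) is a reconstruction; the original merge is not
  fully specified.
* Classification depends on the completeness of the gene annotation given:
  with a sparse annotation, "nearest gene" can differ from the conventional
  locus name.

## A worked run

```{r example, eval = FALSE}
st <- generate_study(seed = 1)
c1 <- load_calls(st$calls_frag1, st$fragment_map, 5, "frag1")
c4 <- load_calls(st$calls_frag4, st$bins, 5, "frag4")
ix <- merge_resolutions(c1, c4, baits = st$baits)
links <- map_variants_to_genes(st$proxies, st$peaks, st$fragment_map,
                               st$baits, ix)
summarize_loci(links, genes = st$genes, sentinels = st$sentinels)
```

The same computation driven from files is `run_pipeline(pipeline_config(...))`;
the packaged mini-study under `synthetic_study_path()` is a ready-made input.
The three locus geometries of the classification rule (nearest-only,
nearest-plus-distant, distant-only) are exercised as worked examples in
`tests/testthat/test-acceptance.R` on a hand-built mini-annotation.
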