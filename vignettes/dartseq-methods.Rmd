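---
title: "Methods: deamination-based m6A site calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deamination-based m6A site calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model and of the design
choices that were genuinely open: what the caller assumes about DART-seq
data, what each tunable parameter means, what the synthetic generator does
and does not emulate, and the numerical conventions that make results
deterministic.

## The measurement model

DART-seq converts m⁶A into a sequence change. An APOBEC1–YTH fusion binds
methylated adenosines (which live in the RAC consensus, R = A/G) and
deaminates the cytidine immediately 3′ of the methylated A, so a C2U site
records the m⁶A at single-nucleotide offset −1. An ADARcd–YTH fusion
instead edits adenosines in the vicinity of m⁶A; because the edited A is
not at a fixed offset, A2I mode carries no motif constraint. Editing is
read out from ordinary RNA-seq as C→T (plus-strand genes) / G→A
(minus-strand genes) mismatches, or A→G / T→C for A2I.

Three conditions feed the caller:

* **DART**: the active fusion; truth sites edited at a per-site rate.
* **control**: a binding-impaired mutant fusion (YTHᵐᵘᵗ) or a YTH
  pre-blocking condition. Crucially, the mutant retains *low-level* m⁶A
  binding, so truth sites show residual editing in the control — this is
  why the caller uses a fold-enrichment test rather than requiring zero
  control editing. Both control kinds are the same computation; the
  `control_kind` field is metadata only.
* **deaminase alone**: the deaminase without a YTH domain; positions it
  edits are methylation-independent artifacts and are blacklisted.

## The caller and its parameters

For each position the informative reads are those carrying the
strand-corrected reference or edited base; the edit ratio is
`n_alt / (n_ref + n_alt)`. Defaults in `caller_params()`:

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 10 reads | minimum informative coverage in the DART sample |
| `min_alt_reads` | 2 reads | minimum edited reads |
| `ratio_low`, `ratio_high` | 0.05, 0.95 | inclusive edit-ratio window; the upper bound removes homozygous-variant-like positions |
| `min_fold` | 1.2 | minimum edit-ratio enrichment over the control |
| `min_control_coverage` | 10 reads | control coverage below which enrichment cannot be assessed |
| `min_replicates` | 2 | replicate-concordance threshold |

Decisions the thresholds alone do not fix, and how this package resolves
them:

* **Edit-ratio denominator.** `n_ref + n_alt`, not total coverage:
  unrelated mismatches and sequencing error at the position then cannot
  dilute the ratio. (Total coverage is still reported per site.)
* **Control pooling.** Control replicates are pooled (counts summed)
  before the ratio is formed, maximising control coverage where the fold
  test is most fragile. Per-replicate control calling is possible by
  passing a single replicate as the control.
* **Zero control editing** passes the fold test by convention — it is
  maximal enrichment. Conversely, positions with control coverage below
  `min_control_coverage` are not callable at all rather than trivially
  enriched.
* **Unannotated positions are not callable**: without a gene strand the
  ref/alt pair is ambiguous. Intronic positions of annotated genes carry
  the gene strand and are callable; they are excluded from metagene
  profiles, which live in exon space.
* **Replicate merging** keeps sites present in `min_replicates` of the
  per-replicate sets; the merged edit ratio is the arithmetic mean of the
  per-replicate ratios (counts are also summed for reference).

The RAC filter applies only to C2U sites: the transcript-strand
trinucleotide ending at the edited C must match R-A-C, with minus-strand
genes evaluated on the reverse complement. Ambiguous bases (N) fail
conservatively. A2I site sets refuse the filter outright. Blacklist
subtraction is by exact `(contig, pos, strand, edit_type)` key, union over
blacklist replicates ("seen in any replicate" rule). Concordance, motif
and blacklist filters are all subset filters on keys/sequence only, so
their order cannot change the result; the pipeline fixes the order
concordance → motif → blacklist and writes each intermediate table.

## Coordinates and containers

Everything user-facing is a tibble. Genomic coordinates are 1-based and
closed throughout the package — the native convention of the Bioconductor
stack (GRanges, Rsamtools, rtracklayer) this package stands on — and of
the serialized pileup and site TSVs; BED output is 0-based half-open, and
every writer's header states its convention. Pileup counts live in
reference-plus-strand space; strand resolution happens at calling time via
the annotation, which matches how the downstream filters are defined.

The canonical transcript of a gene is the one with the longest CDS (ties:
longest exonic length, then smallest transcript id) — a stable,
annotation-version-independent proxy for the representative transcript.
Metagene coordinates rescale 5′UTR, CDS and 3′UTR each to a unit interval
(`[0,1)`, `[1,2)`, `[2,3)`), measured 5′→3′ on the transcript strand, with
half-open region boundaries: the first CDS base maps to exactly 1.0 and
belongs to the CDS. Regions are equal-width in the profile; rescaling by
median region lengths (as some metagene tools do) is deliberately not
applied — with equal widths a bin is interpretable as a fixed fraction of
its region, and comparisons between site sets do not depend on a
annotation-wide length summary.

## Site-set statistics

* **Distance to reference.** Signed offset to the nearest reference site
  on the same contig and strand within ±`window` (default 1000 nt; the
  histogram is reported over the full window and sites without a
  reference site in range are counted, not silently dropped). Offsets are
  transcript-strand aware: +1 means the edit site is 1 nt 3′ of the
  reference site, which is exactly where C2U edits sit relative to m⁶A.
  Distances are genomic, not spliced: for the ±1 kb windows of interest
  the two agree except across junctions, and genomic distance keeps the
  null model (below) exact.
* **Shuffle null.** For each transcript carrying sites, the same number
  of sites is re-placed uniformly without replacement over that
  transcript's exonic positions. This conserves per-transcript site
  counts and expression structure while destroying positional signal, and
  is deterministic under a seed.
* **Rank-sum comparison.** `compare_ratio_distributions()` wraps the
  Mann–Whitney U test: exact p when `min(n, m) ≤ 8` with no ties, normal
  approximation with tie and continuity corrections otherwise, plus ECDF
  tables for cumulative-distribution plots.
* **Gene-set overlap.** Consensus membership in ≥ `min_support` sets
  after case normalisation — e.g. transcripts with peaks in at least two
  of three antibody-based studies.

## The synthetic study

`sim_config()` defines the generative model the tests and the acceptance
script use. Defaults: 60 single-transcript genes (1–4 exons, both
strands, 5′UTR 100–300 nt, CDS 300–900 nt, 3′UTR 300–900 nt) across two
contigs; 200 truth m⁶A sites planted in RAC transcript-strand contexts
with 60% in the 3′UTR (remainder 3:1 CDS:5′UTR), emulating the known
3′UTR/stop-codon enrichment of m⁶A; per-site DART editing rates
Beta(3, 7) (mean 0.3); control residual editing at 0.1× the site rate;
background off-target editing at 0.005 at every eligible base; coverage
negative binomial with mean 50 and size 20; 3 replicates per condition;
and 20 deaminase-alone artifact positions edited at rate 0.3.

Two generator choices deserve justification:

* **Artifact positions sit in RAC contexts.** Were they in random
  contexts the motif filter would remove most of them and blacklist
  subtraction would be untestable; planting them in the same context
  class as truth sites makes the blacklist the only stage that can remove
  them.
* **Artifacts are edited in the DART and deaminase-alone conditions but
  only at background in the control.** Deaminase-intrinsic editing that
  also appeared in the control would fail the fold test and never reach
  the blacklist stage; this configuration makes artifacts realistic
  confounders that the blacklist demonstrably removes.

Rates combine additively and are capped at 1. The simulator deliberately
omits sequencing error, base-quality variation, splice-junction reads
(simulated reads tile within single exons), multi-isoform genes and
overdispersion beyond the negative binomial. Passing the recovery test
therefore shows the pipeline's logic is correct under its own model
assumptions — not that real libraries, with alignment artifacts and SNPs,
would behave as cleanly; the blacklist and control conditions carry that
burden on real data.

With these defaults the end-to-end recovery test asserts sensitivity
≥ 0.90 and FDR ≤ 0.10 for the full pipeline, bounds fixed from a pilot
simulation before the suite was frozen; typical runs recover 96–99% of
truth sites with zero to a handful of false positives.

## Numerical conventions

* The fold comparison `edit_ratio ≥ min_fold × control_ratio` subtracts
  1e-9 before comparing, so exact-boundary cases (e.g. ratio 0.24 vs
  1.2 × 0.2) do not depend on floating-point rounding direction.
* Metagene bin assignment adds 1e-9 before `floor()` for the same reason;
  region boundaries would otherwise bin one slot low for some region
  lengths.
* Nearest-reference ties (a site equidistant from two reference sites)
  resolve to the genomic-left site, deterministically.
* Ambiguous genome bases fail the motif filter; `filter_motif` never
  passes a context it cannot fully read.
* All simulation randomness flows from explicit integer seeds;
  `shuffle_sites()` takes its own seed so the null is reproducible
  independently of session state.

## Problem sizes

The test suite and the acceptance script run the synthetic study at its
default size (≈85,000 exonic positions, 200 truth sites, 9 pileup
replicates), oracle comparisons on ~10 kb matrices, and resampling checks
at 10,000 draws — sizes chosen so every distributional assertion has
comfortable statistical margin while the whole suite stays quick on a
laptop.

## Known limitations

* Single-isoform reasoning: sites are interpreted on one canonical
  transcript per gene; isoform-specific methylation is out of scope.
* No per-site statistical test: the caller reproduces the hard-threshold
  scheme; posterior/FDR-controlled calling would need a different design.
* Window-based blacklist matching is not offered; subtraction is
  position-exact.
* Metagene profiles ignore noncoding genes entirely.
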