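---
title: "Two-stage clustering of amplicon tags into OTUs: methods and design notes"
author: "tscotu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage clustering of amplicon tags into OTUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscotu)
```

## The problem and the strategy

Clustering 16S/18S rRNA amplicon reads into operational taxonomic units
(OTUs) at a fixed pairwise-distance threshold (conventionally 0.03) is the
rate-limiting step of most microbial-diversity pipelines: the number of
pairwise Needleman–Wunsch (NW) alignments grows quadratically with the
number of unique sequences, and average-linkage clustering needs the
distance matrix in memory.

Amplicon libraries, however, have a very particular shape: a small set of
abundant unique tags carries most of the reads, while the large majority
of unique tags are singletons and doubletons, a substantial share of which
are PCR or sequencing noise derived from an abundant parent.  `tscotu`
exploits that shape by clustering in two stages:

1. **Stage 1 (abundant tags, hierarchical).**  Tags at or above an
   abundance cutoff (default 3) are compared all-vs-all.  A k-mer distance
   prescreen skips pairs that cannot be close; surviving pairs are aligned
   and their NW distances kept in a sparse set up to a storage cap.  One
   sequential single-linkage *precluster* pass at distance 0.02 then
   absorbs lower-frequency tags into more abundant near-identical parents
   (the classic noise signature), and the surviving seeds are clustered
   agglomeratively — complete (CL), average (AL) or single (SL) linkage —
   cut at the OTU threshold.  The result are the high-abundance OTUs
   (HAOTUs).
2. **Stage 2 (rare tags, greedy).**  Rare tags are processed in abundance
   order.  An alignment-free shortcut compares the tag base-by-base
   against current OTU representatives and places it immediately when that
   direct distance is already below the threshold (the direct distance
   upper-bounds the NW distance, so the placement is sound).  Otherwise
   the placed tags are ranked by k-mer distance and aligned in batches of
   10 until a batch produces no hit.  The accumulated hit set decides one
   of five cases: no hit founds a new low-abundance OTU (LAOTU); hits in a
   single OTU join it; hits in several HAOTUs join the HAOTU of the most
   abundant hit tag *without* merging HAOTUs; hits in several LAOTUs merge
   them; mixed hits fold all hit LAOTUs into the HAOTU of the most
   abundant hit tag.  Rare tags may therefore consolidate rare OTUs but
   can never collapse the abundant backbone.

Every tag ends up in exactly one OTU and every placement is justified by a
pairwise NW distance (or a provable upper bound on one), which is what
distinguishes this design from purely greedy centroid clusterers.

## Distances

**Alignment scoring.**  Global affine-gap alignment with match +1,
mismatch −1, gap opening −10, gap extension −1 (changeable).  A gap run of
length $L$ costs $g + (L-1)\,\mathrm{ext}$, *terminal runs included*; the
platform sets the extension value: −1 per column for Illumina-type data,
0 for 454-type data, so a 454 gap run costs the opening penalty once — a
single indel however long, matching the homopolymer error mode of
pyrosequencing.  Ambiguity codes (kept only with `allow_ambiguous`) never
match, not even against themselves.  Traceback ties are resolved
deterministically: substitution column, then gap in the second sequence,
then gap in the first.

We considered an alternative end-gap model in which terminal runs carry no
opening penalty.  It is superficially closer to a literal reading of the
flag descriptions of comparable tools, but it is unusable for this
pipeline: without an opening cost, a deletion near the end of a read
aligns as a shifted overlap with a couple of substitutions instead of as
one internal indel, inflating its distance from ~0.012 to ~0.025 on an
80-mer.  Such noise tags then escape the 0.02 precluster and split
complete/average-linkage clusters.  The fully affine model (also the
convention of the ESPRIT family of tools) keeps indel noise where it
belongs.

**Distance.**  With `free_end_gaps` (the default, the `-x` convention),
terminal gap columns are trimmed before counting.  Illumina mode counts
(substitutions + gap columns) / alignment length; 454 mode counts each gap
run once: (substitutions + gap runs) / alignment length, so
454-distance ≤ Illumina-distance on any alignment.  A degenerate
alignment whose trimmed length is zero (one sequence entirely overhanging
the other) is assigned distance 1.  For gap-free equal-length pairs the
distance reduces to normalized Hamming distance, which is exactly why the
stage-2 shortcut is a sound upper bound.

**k-mer prescreen.**  $d_k = 1 - \sum_w \min(c_1(w), c_2(w)) /
(\min(|s_1|,|s_2|) - k + 1)$ over overlapping forward-strand words
(default $k = 6$); words containing ambiguity codes are skipped, which can
only increase the distance and is therefore conservative.  Pairs with
$d_k > f_{\max}$ (default 0.5) are never aligned and are treated as
farther than any usable threshold.  No reverse-complement handling:
amplicons are orientation-normalized upstream.

## Clustering details and numerical choices

* **Sparse matrix.**  Distances at or below the cap (default 0.10, enough
  for thresholds up to 0.10) are stored as `i j d` triples; everything
  else is "absent = far".  For CL/AL the absent pairs are valued at
  cap + 0.01 — definitely above any usable threshold, the sparse-matrix
  convention of hcluster-style tools.
* **Agglomeration.**  CL/AL use size-weighted Lance–Williams updates
  (mathematically identical to max/mean over all between-cluster pairs)
  and stop when the smallest criterion exceeds the threshold; equal merge
  criteria take the pair with the smaller rank indices, making runs
  reproducible.  SL is computed directly as union-find connected
  components over stored edges at or below the threshold.
* **Precluster bookkeeping.**  The sequential precluster is sometimes
  described as incrementing the parent's frequency *by one* per absorbed
  tag; that discards the absorbed multiplicity, so the default here adds
  the absorbed tag's full abundance (read counts are then conserved, as
  in the single-linkage-precluster precedent).  `precluster = "literal"`
  reproduces the increment-by-one behavior.  Both modes give identical
  memberships; only seed weights differ.
* **Stage-2 conventions.**  The shortcut uses strict `< d` (it is an
  upper bound, so borderline cases fall through to the exact search); NW
  hits use `<= d`.  The shortcut compares against OTU *representatives*
  (most abundant member, ties to the lexicographically smaller sequence)
  in OTU-creation order — linear in the number of OTUs and biased toward
  abundant parents, which is the point of a denoising shortcut.  The
  k-mer ranking runs against *all* placed tags, so freshly placed rare
  tags are immediately searchable (the LAOTU-merging cases require it).
  Unequal-length direct comparison counts the length difference as
  mismatches with the longer length as denominator, preserving the
  upper-bound property.  "Most abundant hit tag" ties break toward the
  earlier OTU id.
* **Determinism.**  All merge decisions are made in a fixed serial order;
  the CLI accepts a thread-count flag for interface compatibility, but
  results are identical at any setting.

## The mock-community generator

The generator emulates a clone-library mock experiment, the standard
instrument for measuring clustering accuracy: `K` template sequences
(default 43, length 80, all pairwise NW distances at least 0.10) are
amplified into reads (default 50,000) with power-law template weights
(exponent 1.5; every template receives at least one read) and per-base
errors; any read farther than `max_noise_dist` (default 0.03) from its
parent is resampled, emulating the distance screens applied to published
mock libraries.  Because `min_template_dist` exceeds twice the screen,
every read is identifiable: it cannot be within the screen of a
non-parent template, and no chain of reads can bridge two templates, so
the true partition is recoverable by construction.

Default error rates are substitution-dominated (substitution 0.001,
insertion and deletion 2 × 10⁻⁴ per base), chosen on two grounds.  First,
the singleton+doubleton share of unique tags lands at ~80%, the upper end
of the 70–80% regime reported for real amplicon libraries; the share is
almost flat in the substitution rate (the singleton tail dominates it),
so pushing it lower is not possible with that knob.  Second, exact
recovery at cutoff 2 under complete/average linkage requires that no
template acquires two *multi-copy* two-substitution variants (two such
seeds sit ~0.05 apart and would split a CL cluster); at 50,000 reads with
power-law weights the expected number of such collisions on the most
abundant template is ≈ 0.07 at rate 0.001 but ≈ 1 at 0.002.  For
454-style fixtures, raise the indel rates and cluster with
`alignment_params(platform = "454")`.

What the generator does **not** emulate: chimeras, quality scores,
homopolymer-length-dependent indel hotspots, primer/barcode artifacts, or
a true rare biosphere (every rare tag is noise by construction).  Passing
the recovery experiments therefore demonstrates correctness of the
clustering machinery under the stated noise model, not denoising power on
real data — the tool assumes noise screening (e.g. AmpliconNoise, UChime)
upstream, as distance-based OTU pipelines generally do.

## Experiment sizes

The recovery experiment runs the full published design point — 43
templates, 50,000 reads, cutoffs 2 and 3, all three linkages — in about a
minute on one core.  The linkage-convergence experiment uses 15 templates,
4,000 reads and a 10× substitution rate, which is enough to reproduce the
qualitative signature (CL/AL explode into hundreds of OTUs at cutoff 1
while SL stays near the template count; all three coincide by cutoff 3).
Linkage implementations are verified against dense agglomerative
references on 200 random instances of up to 50 items, and the aligner
against exhaustive alignment enumeration on every sequence pair up to
length 6 over a two-letter alphabet under all four platform/end-gap
settings.

```{r example, eval = FALSE}
cfg <- mock_config(n_templates = 8, n_reads = 2000, seed = 11)
gen <- generate_reads(generate_templates(cfg), cfg)
fit <- tsc(gen$reads, cutoff = 2, linkage = "al")
fit
plot(fit)
```

## Known limitations

* Stage-2 batch search is a heuristic: if the k-mer ranking is a poor
  proxy for NW distance (adversarially constructed inputs), a qualifying
  placed tag beyond the first hit-free batch is missed and a spurious
  LAOTU can form.  On realistic noise this does not occur (the batched
  and exhaustive searches agree in the test suite), but it is a property
  of the published search rule, not an accident.
* The abundance cutoff interacts with preclustering: absorption happens
  after the split, so a rare tag can never be promoted into the abundant
  group by merges.  Cutoff 1 disables stage 2 entirely and is intended
  for algorithm study only.
* AL on the sparse matrix values missing pairs at cap + 0.01; with very
  sparse matrices and thresholds near the cap this makes AL conservative
  about merging, which is the safe direction but is still a convention.
* Memory is dominated by the dense seed matrix in CL/AL (fine up to a few
  thousand seeds) and by the k-mer profiles of placed tags in stage 2.
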