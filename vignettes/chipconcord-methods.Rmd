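---
title: "Methods: replicate concordance assessment for ChIP-seq peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate concordance assessment for ChIP-seq peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipconcord)
```

# The problem

A replicated ChIP-seq *condition* is a set of 2–5 independent experiments
for the same factor, cell line and treatment, each delivering its own
peak list. Public resources frequently ship such replicates unmerged and
undocumented, leaving the user to decide which list to trust.
`chipconcord` audits each condition from peak overlap, fragment
enrichment, TSS proximity, between-replicate differential binding and
cross-experiment clustering, and recommends a merge strategy.

# Coordinate model

All coordinates are 0-based half-open `[start, end)`, the
BED/narrowPeak convention. Two intervals overlap when they share at
least one base: `max(starts) < min(ends)` on the same chromosome, so
`[100,200)` and `[200,300)` do not overlap. Chromosome names are
compared as literal strings. Strand is ignored in all overlap
computations (ChIP peaks are unstranded), and peaks within one list are
*not* pre-merged: input rows are counted as provided, mirroring raw
peak-caller output. Interval algebra is delegated to
GenomicRanges/IRanges internally; the test suite checks every operator
against per-base and nested-loop brute-force oracles.

Two related notions of "common" coexist and are deliberately kept
distinct:

* the **common peak list** of a condition
  (`common_regions()`): maximal genomic segments covered by at least one
  peak in *every* replicate. Because intersection boundaries contributed
  by different lists can abut, adjacent covered-by-all segments are
  merged — the result equals the per-base definition "mark every base
  covered by all lists, merge runs".
* an experiment's **common peaks** (`partition_condition()`): its own
  native peaks that overlap at least one peak of every other replicate.
  These keep native widths and summits and are what coverage and FPKM
  summaries are computed on.

`merge_regions()` (the peak *union*) merges only intervals that overlap
by ≥ 1 bp; half-open abutting intervals stay separate. Its per-base
coverage still equals the brute-force union, which is what the tests
assert.

# Classification

With $f_e$ the fraction of experiment $e$'s peaks overlapping the common
peak list, a condition is

* **similar** iff $f_e \ge 0.5$ for every replicate;
* else **sensitive** iff $\max_e n_e \ge 2 \cdot \min_e n_e$ and the
  smallest list satisfies $f > 0.7$;
* else **dissimilar**.

Boundary semantics follow the rule wording literally: the 50 % and 2×
comparisons are inclusive, the 70 % comparison is strict. All three
thresholds are exposed in `class_thresholds()`. Fractions are over peak
*counts*, not base pairs. For conditions with more than two replicates
the size-ratio rule compares the largest against the smallest list and
tests the smallest list's fraction — the most conservative single
reading of a rule stated for a pair; this choice is configurable in
spirit by calling `classify_condition()` on any hand-built summary.

Recommended merged lists: union of all replicate peaks for similar and
sensitive conditions; for dissimilar conditions a preferred replicate
when external evidence (clustering neighbors, TSS profiles, motifs)
names one, otherwise the conservative intersection with a warning flag.

# Fragment model and enrichment metrics

A fragment is reduced to a single shifted 5′ point: `pos + shift` on +,
`pos - shift` on −, with `shift = 150` bp by default — the only stated
value in the upstream protocol this mirrors, applied consistently across
coverage and MA modules. No read extension is performed. Library size is
the number of fragments provided, assumed uniquely aligned and
deduplicated; no duplicate marking, mappability correction or
input-control subtraction is attempted.

Peak FPKM is `count / ((len/1000) * (library/1e6))`. FRiP merges peaks
first so overlapping peaks cannot double-count a fragment. Coverage
profiles center windows of ±2000 bp on peak *midpoints* in 10 bp bins
(window and bin are free choices — the source protocol does not state
them — and are configurable); undetected regions have no native summit,
which is why midpoint anchoring is used uniformly. Per-bin counts are
converted to FPKM with the bin as the length term and averaged over
peaks; empty peak sets yield `NA` curves rather than zeros so "no data"
is distinguishable from "no signal".

# TSS annotation

The TSS of a transcript is its start on + and its last base (`end - 1`)
on −; GTF input is converted from 1-based closed coordinates on read,
and transcripts sharing a (chromosome, position, strand) collapse into
one index entry. The nearest TSS minimizes absolute distance from the
peak midpoint; the sign is positive when the midpoint lies downstream of
that TSS in gene orientation, ties resolving toward the downstream TSS.
This convention is a package decision (the underlying recommendation
"prefer the replicate with more peaks downstream of TSSs" needs *some*
sign convention); it is recorded, not inferred.

One symmetry subtlety: reflecting all coordinates *and* flipping all
strands preserves signed distances rather than negating them, because a
peak downstream of a gene stays downstream of the mirrored gene. The
negating operation is flipping gene orientation at fixed TSS positions;
the test suite encodes both properties.

# MA normalization and differential binding

For region counts $x_1, x_2$ with pseudocount $c = 0.5$:
$M = \log_2\frac{x_1+c}{x_2+c}$, $A = \tfrac12\log_2((x_1+c)(x_2+c))$.
Regions are the merged union of both replicates' peaks; the
normalization line $M = a + bA$ is fitted only on regions detected in
both replicates (at least 10 required — fewer means the condition is too
discordant to normalize), by iteratively reweighted least squares with
Huber weights ($k = 1.345$, scale from the MAD, at most 50 iterations,
coefficient tolerance $10^{-8}$). The cited normalization method
specifies robust regression without naming the weight function; Huber is
the standard choice and `MASS::rlm` serves as an independent
cross-check in the tests, never as the implementation.

Normalized counts are reconstructed on the pseudocounted scale —
preserving $A$ and setting the log-ratio to $M_{norm}$ — and the
pseudocount is then removed before rounding, so an identity fit returns
the raw counts exactly. Each region is tested with a two-sided exact
binomial test of $x_1'$ in $x_1'+x_2'$ trials at $p = \tfrac12$
(empty regions get $p = 1$), significant at $p < 0.01$ with no
multiple-testing correction by default (Benjamini–Hochberg behind a
flag); the upstream analysis reports raw "statistically significant"
fractions and states no threshold, so 0.01 follows the normalization
method's own convention and is configurable. Condition summaries band
the significant fraction at > 50 % ("majority-differential") and < 25 %
("concordant").

Null calibration (both replicates drawn from the same rates) keeps the
significant fraction at or below 0.02, comfortably close to the nominal
0.01 — the binomial's discreteness makes the test slightly conservative.
In calibration and scaling tests, region rates are drawn log-normally
(median ≈ 40–100 fragments, log-sd 0.6–1): ChIP region counts span
orders of magnitude, and a realistic spread in $A$ is also what
identifies the intercept of the normalization line without
extrapolation artifacts.

# Occupancy clustering

The occupancy matrix is binary over the merged universe of the analyzed
experiments' peaks (the construction generalizes to any peak
compendium). Pearson correlation between binary columns is the phi
coefficient of the 2×2 overlap table; constant columns yield `NA` with a
warning. Clustering is agglomerative on $d = 1 - r$ with complete
linkage by default (average and single available): the upstream analysis
names only "hierarchical clustering", and complete linkage is the
default of the environment it was performed in. Experiments are ordered
lexicographically before clustering so ties resolve deterministically.
Nearest-neighbor queries over the correlation matrix support replicate
arbitration: the dissimilar replicate whose occupancy clusters with
biologically related experiments is the better candidate.

# The synthetic generator: its stated world

`generate_condition()` emulates the mechanisms the three classes are
attributed to:

* **True sites** are placed uniformly without overlap (a gap-sampling
  construction that cannot collide), widths uniform on 150–400 bp,
  defaults of 1000 sites on a 20 Mb two-chromosome genome — narrowPeak-
  scale peaks at realistic density.
* **Site strength** is Gamma(shape 2, mean 1): a right-skewed strength
  spectrum with many weak and few strong sites.
* **Detection** is strength-dependent: each replicate detects a site
  with probability `plogis(a + 2 log s)`, the intercept calibrated so
  the mean detection rate equals the replicate's `sensitivity`. This is
  the feature that reproduces the observed coverage ordering — missed
  ("undetected") sites are preferentially weak, so their mean coverage
  sits between background and common peaks instead of equalling the
  common peaks'.
* **Class presets**: similar = sensitivity 0.92 for all replicates;
  sensitive = (0.95, 0.30); dissimilar = sensitivity 0.90 with only 20 %
  of sites detectable by all replicates (the rest split into
  replicate-exclusive subsets). False peaks arrive as a Poisson process
  (2 per Mb) with the same width distribution; peak boundaries are
  jittered ±20 bp.
* **Fragments** are uniform background plus enrichment mass proportional
  to site strength at *true* sites (enrichment fold 5 at the mean,
  positions normal around the site midpoint with sd = width/4), so
  undetected peaks still carry signal. The background rate is derived
  from the target library size (default 10⁶), or fixed directly for
  experiments that vary enrichment at constant background. Fragment 5′
  positions are emitted pre-shifted so that the configured read shift
  recovers the intended target positions.

Everything is seeded: identical seeds give byte-identical peak, fragment
and annotation files. The frozen 60-condition recovery table
(`inst/extdata/recovery_specs.tsv`) instantiates 20 conditions per class
with these presets, varying site counts (800–1200) and including
three-replicate conditions; its per-condition seeds are offset by the
caller's base seed so the whole dataset moves with one number.

What the generator does *not* emulate: read-level sequences (no FASTQ or
alignment), mappability and blacklist structure, duplicate reads,
input-control biases, copy-number variation, or correlated false peaks
between replicates sharing a lab. A green classification-recovery test
therefore establishes that the decision rules and interval algebra are
implemented correctly on data satisfying the model's assumptions — not
that real discordant ENCODE conditions are detected with any particular
sensitivity; that reproduction requires the original peak files.

# Numerical and degenerate-input choices

* Interval validation rejects `end <= start` and negative starts at
  parse time, naming the offending line.
* narrowPeak sentinels: absent signal/p/q are `NA` internally and `-1`
  on write; summit offset `-1` means "no summit".
* The IRLS scale guard: when the residual MAD is (near) zero the current
  fit is already (near-)perfect and iteration stops — this covers the
  `M ≡ 0` case exactly.
* Binomial p-values use the symmetric closed form
  `2 * pbinom(min(x, n - x), n, 1/2)`, exact at $p = \tfrac12$ and free
  of the floating-point asymmetry a density-comparison rule suffers.
* Coverage windows extending past position 0 are counted as-is (no
  fragments exist there) and tallied in `n_clipped`.
* Conditions are processed lexicographically and experiments ordered by
  id within a condition, so reports are invariant to manifest row order.

# Known limitations

* The sensitive rule for > 2 replicates (largest vs smallest) is one of
  several defensible readings of a pairwise rule.
* The MA test inherits the usual caveat: false-positive peaks with few
  reads in both replicates are unlikely to be flagged as differential,
  so a low differential fraction alone does not certify both replicates.
* No motif-based arbitration is provided; clustering and TSS evidence
  only.
* The pipeline consumes already-aligned, already-deduplicated fragment
  positions; peak calling, BAM manipulation and coordinate liftover are
  out of scope.
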