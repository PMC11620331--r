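---
title: "Quantifying nick-induced replication fork collapse from strand-specific break-end coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nick-induced replication fork collapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forkcollapse)
```

## The biological model

A single-strand nick becomes a double-strand break (DSB) when a replication
fork runs through it, and the structure of that break depends on which
template strand carries the nick relative to the incoming fork:

* **Leading-strand nick**: the replisome runs off the broken template and a
  *single-ended* DSB (seDSB) is formed, with one DNA end on the side the
  fork came from. That end is resected 5'→3', so break-end reads spread
  over the per-cell resection extents on one side of the nick only.
* **Lagging-strand nick**: the helicase bypasses the nick-bound protein and
  synthesis terminates at or near the nick on the other strand, generating
  a *double-ended* DSB (deDSB) with resected ends on both sides.
* **Converging fork**: an unrepaired single end can gain a second end when
  a fork arrives from the other direction, converting an seDSB to a deDSB
  at the converging-fork distance.

Because a genomic locus is replicated by rightward and leftward forks in
proportions given by the local replication fork directionality (RFD), a
nick on a given strand produces a *mixture* of the two collision classes,
weighted by the fraction `f` of rightward forks (`f = (1 + RFD) / 2`).
Everything this package measures — peak asymmetry, resection length,
leading/lagging designation, deletion junctions — derives from this model.

## The asymmetry statistic

For a nick at position `p`, reads (both strand channels) are counted in
`[p - w, p)` (left, `L`) and `[p, p + w)` (right, `R`) with `w = 3000` bp
by default, and

$$\mathrm{asymmetry} = 0.5 - \frac{R}{L + R} \in [-0.5,\, 0.5].$$

The value is 0.5 when every read lies left of the nick (fully single-ended),
0 for balanced reads (double-ended), and negative when the right side
dominates. We keep the *sign* (the published statistic is effectively a
magnitude, since display sites are oriented by fork direction): the signed
form makes the mirror-reflection property testable — reflecting the track
about the nick negates the asymmetry exactly — and handles leftward-fork
sites without re-orientation. Classification uses the magnitude, with
defaults chosen from the observed ranges: `|a| >= 0.25` is called seDSB
(observed seDSB values cluster at 0.3–0.4), `|a| <= 0.10` deDSB (observed
0–0.1), anything between is ambiguous. Both thresholds are arguments.

A convention worth stating: the nick base itself belongs to the right
window (half-open intervals everywhere, 0-based internally, BED dialect at
the file boundary). With `L + R = 0` the statistic is undefined; such sites
are flagged `NA` and dropped from correlations.

## Normalization

Reads-per-million uses the library size carried as track metadata
(`total_reads`), not the sum of in-track counts, because reads mapped
outside any displayed region still dilute the library. Spike-in scaling
divides RPM values by `spike-in locus reads / total main-genome reads`.
The orientation matters and is deliberate: *more* spike-in signal means a
*smaller* normalized value. Since the spike-in cells (carrying one
always-cut locus) are mixed at a fixed 20% cell fraction, the locus read
count is proportional to per-cell sequencing depth, and dividing by it
places samples on a common per-cell scale. Both operations are linear, so
uniformly rescaling all raw counts and totals leaves the spike-in
normalized track unchanged — asserted numerically in the tests. The state
machine `raw → RPM → spike_normalized` is enforced; out-of-order
applications raise immediately rather than silently double-normalizing.

## Peak calling and qualification

The peak caller is a deliberately simple, fully documented stand-in for a
broad-peak caller: maximal runs of combined-strand signal above
`min_signal` (default 3, the filter value applied downstream of the
external caller in this assay), merged across gaps of at most `merge_gap`
bp, each annotated with its summit (leftmost argmax on ties) and a Poisson
upper-tail probability of the summit height under a uniform background
rate as the significance surrogate (filtered at `q < 0.001`). What carries
the downstream analysis is not the caller internals but the qualification
rules, which are implemented exactly: a peak must contain exactly one
target site, and that site must be more than 8 kb from every other target
site. We read the separation rule as a *site-to-site* distance (its
subject is "other target sites"); peak-edge-to-site is the plausible
alternative and would only be stricter.

## Resection length estimation

Two estimators are provided, matching the two experimental designs.

**Boundary method** (unique, isolated nick sites): the peak edge is the
farthest position from the nick with signal at or above a threshold
`tau = mean + k * sd` (default `k = 3`) of a flank background region
(default 20–30 kb from the nick, consistent with the ±30 kb intensity
window), tolerating sub-threshold dips up to `max_gap = 200` bp inside the
peak. The published workflow set this threshold by visual inspection per
locus; an automated flank-statistics threshold is this package's own
choice, made so results are reproducible and testable. When the flank is
exactly flat zero the threshold falls back to a floor (logged), since
`mean + k·sd = 0` would accept arbitrary noise.

**Sliding-window method** (degenerate, many-site guides): the scanned side
is cut into 50-bp bins outward from the nick; the background `B` is the
mean bin signal over bins fully within 7–9 kb of the nick; a 12-bin window
slides outward, and at the first window in which strictly more than 8 bins
fall strictly below `B`, the endpoint is the outer edge of the farthest
above-`B` bin in that window. Boundary conventions we fixed (all
configurable): "more than eight" is `> 8`, i.e. at least 9 of 12; ties
with `B` count as neither below nor above; the endpoint is reported at the
bin's *outer* edge (the inner edge would differ by at most one bin, 50
bp); if no window triggers within `search_limit` (default 50 kb), the
limit is returned with an `at_limit` flag; if the triggering window
contains no above-background bin, the last above-background bin before the
window is used (0 if none). The estimate is therefore always a multiple of
the bin size. An exact brute-force re-implementation (nested loops over
every window) is kept in the test suite and must agree on thousands of
randomized profiles.

Two numerical points deserve emphasis. First, if the background bins are
all zero (possible only with near-zero simulated background), strict
comparisons could never trigger; a tiny positive floor (`bg_floor`,
default 1e-9) substitutes for `B` so that empty bins count as below
background. Real data always has nonzero background, so the floor is inert
there. Second, the 7–9 kb background window presumes the resection tract
has ended by 7 kb. In hyper-resection regimes (e.g. loss of the
recombinase that normally limits resection, with tracts beyond 40 kb) that
region lies *inside* the signal and the estimator, applied naively,
saturates where signal meets its own tail. The hyper-resection fixtures
therefore carry a background window placed beyond the simulated tract
(47–50 kb), and users analyzing hyper-resected samples should move
`bg_range` outward likewise. This is a property of the estimator's design,
not of the implementation.

## RFD and leading/lagging designation

RFD per bin is `(C − W) / (C + W)` from Crick/Watson stranded fragment
counts, in [−1, 1], positive for predominantly rightward forks; empty bins
are undefined (`NA`). The polarity convention is fixed at this API —
stranded inputs whose chemistry labels strands the other way must be
sign-flipped by the caller. A nick is designated by the rule: Crick-strand
nick with RFD > 0 → lagging; RFD < 0 → leading; Watson-strand nicks
mirror it; RFD exactly 0 or undefined → unclassified. The RFD at a nick is
the value of the bin containing it (default 1 kb bins, configurable; no
interpolation — the designation only uses the sign, which interpolation
cannot change inside a bin). The asymmetry–RFD correlation is Spearman
(average ranks) on the magnitudes |asymmetry| vs |RFD| within one
designated class, since both signs flip together with fork direction.

## Deletion and microhomology calling

Amplicon reads are explained under a single-deletion model: longest
matching prefix plus longest matching suffix; reads they cannot jointly
cover, or that match the reference length without matching its sequence,
are counted `unclassified` rather than force-fitted — matching is exact,
and richer grammars (insertions, substitutions near junctions) belong to
dedicated editing-outcome tools. Where a deletion
junction is ambiguous (flanking repeats), the call is canonicalized by
left-alignment, the VCF convention, which makes coordinates stable and
microhomology well defined. Microhomology is the largest `m` with
`ref[s, s+m) == ref[e, e+m)` for a deletion `[s, e)` — the identical
sequence shared by the two junction flanks. Calls are aggregated by exact
`(start, end)` identity.

## The synthetic-data generator

The generator emulates exactly the statistical structure the estimators
assume: per cell, a fork direction drawn `Bernoulli(f)`; the collision
class resolved from fork direction and nick strand (the orientation rule
above, used as generative ground truth); one break end at `nick − r`
(leading, rightward fork) or two ends at `nick − r1`, `nick + r2`
(lagging) with independent resection draws; optional converging-fork
conversion placing the second end at a fixed distance; uniform Poisson
background. A read is a single base position (the blunted end) — fragment
length is not modelled, since every statistic here consumes end positions.
Left-side ends are recorded on the plus channel and right-side ends on the
minus channel; this is a package convention (the asymmetry statistic is
positional, so channel labels do not affect it, but the RPA polarity
simulations rely on it being fixed).

The resection-length family defaults to uniform on `(0, L_max]`: the
reported experimental quantity is the *maximum* tract length, which is
insensitive to the family; a truncated exponential is available. Default
study conditions mirror the analysis settings: fork directionality 0.85 at
displayed unidirectional sites, 1,000 events per nick, `L_max` 5 kb,
background contributing 5% of signal reads
(`background_rate_for_fraction()` converts that fraction to a per-bp
rate), spike-in cell fraction 0.20. Background is uniform — no chromatin
covariates, no sequence-context nicking model, no replisome kinetics
(cut efficiency is a single scalar). Passing tests on this generator
therefore validates the estimators' logic and conventions, not their
robustness to mappability artifacts, copy-number variation, or non-uniform
background in real sequencing data.

Amplicon reads carry a deletion spanning the nick with probability
`p_del`; junction endpoints are drawn uniformly within a flank, or, with
microhomology bias on, sampled with probability proportional to
`bias_weight^m` where `m` is the junctional microhomology — a simple
annealing-preference model that concentrates junctions on planted flanking
repeats. Deletion endpoints may coincide with the nick so that one full
copy of a repeat abutting the nick can be deleted cleanly.

All generators are byte-identical under a fixed seed, and the collision
generator's bookkeeping (signal ends, background reads, per-class event
counts, true end positions) is attached to the track so tests can assert
exact read accounting and parameter recovery against ground truth.

## Problem sizes and reproducibility

The shipped test-suite and acceptance-script runs use single-chromosome
genomes of 0.2–2 Mb, 50–3,000 events per nick, 200 nicks for the
classification-recovery study, and 1,000-case randomized oracle
comparisons for the sliding-window and microhomology algorithms — sizes
chosen so the full suite completes in about two minutes on one CPU while
keeping binomial sampling error well inside every asserted margin. The
pipeline driver (`run_pipeline()`) expands one global seed into fixed
per-stage substreams, so any stage can be re-run in isolation with
identical results, and writes a JSON manifest (version, seed, parameters,
read bookkeeping) from which every artifact is re-derivable.

## Known limitations

* The peak caller is a thresholding caller; it does not model local
  background variation and is not a general-purpose replacement for
  broad-peak callers on real data.
* The sliding-window estimator requires per-bin coverage comfortably above
  zero across the tract; at very low coverage (roughly under 2 reads per
  50-bp bin) empty bins trigger the stop rule early and the tract is
  underestimated. Recovery tests scale depth with tract length
  accordingly.
* Initiation/termination-zone segmentation of RFD profiles (HMM-based in
  dedicated packages) is out of scope; only binned RFD values and the
  sign-based designation rule are provided.
* The deletion caller's single-event grammar ignores insertions and
  substitutions; in data with appreciable sequencing error the
  `unclassified` fraction should be monitored.
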