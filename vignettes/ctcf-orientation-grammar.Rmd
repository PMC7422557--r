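---
title: "The CTCF orientation grammar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CTCF orientation grammar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ctcfgrammar)
```

## The problem

CTCF binds an asymmetric DNA motif, so every binding site has an
orientation: `>` when the motif lies on the forward strand, `<` on the
reverse strand. Chromatin loops extruded by cohesin preferentially anchor
at *convergent* (`><`) site pairs, and topologically associating domains
(TADs) and their boundaries are built from such loops. This package treats
the genome as 42 ordered sequences of oriented CTCF sites (one per
chromosome arm, split at centromeres) and asks what the local *orientation
grammar* of those sequences looks like, how it relates to TAD anatomy, and
whether simple permeability-based loop extrusion on the site sequence can
recover reference loops.

Sites without a motif orientation are excluded at read time; all
coordinates are 0-based half-open internally, and a site's position is its
motif-interval midpoint (symmetric under strand, which matters because
every downstream distance is midpoint-to-midpoint).

## k-plets and their classes

A *k-plet* is a window of `K` adjacent sites on one arm; a sequence of
`M` sites yields `M - K + 1` of them. Each k-plet's orientation string is
classified by which adjacency types it contains:

* **Same** — no `><` and no `<>` adjacency (`>>>`, `<<<`);
* **Conv** — convergent `><` adjacencies only (`>><`, `><<`);
* **Div** — divergent `<>` adjacencies only (`<>>`, `<<>`);
* **ConvDiv** — both (`><>`, `<><`).

The adjacency-scan rule reproduces the tabulated classes for di- through
tetra-plets (2/3/3/8 of the 16 tetra-plets) and extends to any `K`. Under
independent equiprobable orientations the expected class proportions
follow by brute force over the `2^K` equiprobable strings:
(1/2, 1/4, 1/4) for di-plets, 1/4 each for tri-plets,
(2, 3, 3, 8)/16 for tetra-plets.

```{r}
enumerate_patterns(3)
theoretical_class_proportions(4)
```

A structural fact the tests verify exhaustively: convergent and divergent
adjacencies must alternate along any sequence, so per arm
`|#Conv - #Div|` is at most 1 for di-plets, 2 for tri-plets, 3 for
tetra-plets; over 42 arms the maximal genome-wide skew is 42/84/126. This
is why observed Conv and Div counts are always nearly equal while Same
versus ConvDiv is free to drift — the evolutionarily interesting signal.

## Testing departures from the random-orientation null

Two routes are implemented. `class_chisq_test()` is the Pearson test of
observed class counts against the fixed theoretical proportions
(`df = classes - 1`; proportions are a priori, not estimated).
`randomization_test()` redraws every orientation independently and
equiprobably (positions fixed), summarising each replicate by the
chi-square-style distance `sum((f_c - p_c)^2 / p_c)` on class
*frequencies*, and reports the rank of the observed distance. Both the
raw fraction (which can be 0 when the observation exceeds every
replicate) and the `(r + 1)/(n + 1)` estimator are returned.

Randomization draws orientations iid uniform rather than permuting the
observed multiset: the stated theoretical proportions are exactly the iid
law, so the null and the reference proportions agree by construction.

One calibration caveat, verified empirically in this package's tests:
adjacent k-plet windows overlap in `K - 1` sites, so class counts are
autocorrelated and their sampling variance exceeds the binomial variance
(by roughly a factor 2 for tri-plets). Checks phrased in "binomial
standard errors" are therefore approximate; the test suite uses fixtures
at its default seeds, where deviations sit well inside the bound, and the
enrichment null check widens its tolerance by `sqrt(2)` a priori.

## Spatial clustering and windowed enrichment

`cluster_by_distance()` merges adjacent sites whose gap is at most `d`
(single-linkage on the line; `d = 1` bp isolates every site, a window
beyond the arm length yields one cluster per arm). For each window `d`,
`enrichment_by_window()` extracts k-plets *only inside clusters* — a
k-plet spanning two clusters is not counted — and compares each pattern's
count against a uniform `1/2^K` share of the total at that window,
reporting `log10(observed/expected)`. As `d` grows, counts converge
exactly to the genome-wide totals, an identity the tests assert. Gap
semantics default to midpoint-to-midpoint with an interval-gap option;
"spaced by less than d" is implemented as `<= d` (immaterial at kb
scales). `quartile_robustness()` re-runs the map after dropping score
quartiles, probing whether the spatial grammar depends on strong sites.

## Site scoring

Per site and ChIP-seq track, the maximal overlapping `signalValue` is
taken (0 when no peak overlaps — absence of binding evidence). Because
track distributions are heterogeneous, per-site values are
quantile-normalized across tracks (column-mean-of-sorted reference, via
limma) before summing into the ChIP-seq score. Motif and ChIP-seq scores
live on incomparable scales (normal-like versus Poisson-like), so they
are combined as `rank(motif) * rank(chipseq)` with average ranks on
ties; quartiles Q1 (strongest) to Q4 partition sites into groups whose
sizes differ by at most one. The rank product is invariant under any
strictly monotone transform of either input.

## Loop extrusion with permeable anchors

Each site gets a *permeability* `v` in `[0, 1]` — the probability that an
extruding complex ignores it. The full-stop model sets `v = 0`
everywhere; score-driven models set `v = 1 - minmax(s)` so the
strongest site is impermeable. Per epoch, one extrusion event loads
between every adjacent site pair (making the simulation independent of
site density); the left side may anchor only at `>` sites and the right
side only at `<` sites, each candidate stopping the side with
probability `1 - v`. Only events where both sides anchor before the arm
end produce a loop; extrusion never crosses arms.

An alternative reading of the stop condition — stop when a uniform draw
is *below* the permeability — inverts the definition of permeability and
would make the full-stop model anchor nowhere; the self-consistent rule
is the default and the inverted one is kept as
`simulate_extrusion(stop_rule = "literal")` for comparison. Epoch-level
RNG substreams are derived from the seed with a fixed within-epoch
iteration order, so catalogs are reproducible; under full stop they are
seed-independent and equal a nearest-convergent-anchor enumeration, which
the tests check against an independent oracle.

`evaluate_against_reference()` filters a reference loop list to pairs
with convergent CTCF anchors and traces recall and precision as a
function of the occurrence threshold. In the planted-truth acceptance
test, loops generated under a latent site strength are recovered better
(area under the precision–recall curve) by the rank-aggregate model than
by either noisy single-score model — two independent noisy measurements
beat one.

## Boundary consensus across cell types

Every boundary region of every cell type contributes its start and stop
as *boundary positions*. Positions on the same chromosome within the
detection window `w` (default 25 kb, the reference Hi-C resolution) are
linked into an undirected, unweighted graph; Louvain modularity
communities of that graph become consensus boundaries spanning their
positions, centred halfway, with a *conservation score* equal to the
number of distinct cell types represented (a cell type contributing two
positions counts once). Community detection — not connected components —
is the point: a chain of loosely linked positions can be split into
dense clusters.

Louvain is a stochastic heuristic; `detect_communities()` runs 10 seeded
restarts and keeps the highest-modularity partition, which the tests
show attains the exhaustive optimum (all set partitions enumerated) on
graphs up to 10 nodes. Vertex order is canonical (sorted by coordinate),
so results are independent of dataset input order.

```{r}
sim <- simulate_boundary_datasets(n_celltypes = 7, n_shared = 50,
                                  n_private = 20, jitter = 10000, seed = 4)
cons <- consensus_boundaries(sim$datasets, w = 25000, seed = 1)
table(cons$score)
```

Downstream comparisons always replace a consensus boundary by its centre
± 25 kb, so the score-dependent region lengths cannot bias overlap or
census statistics.

## TAD anatomy

TADs are the in-arm complement of (merged) boundary regions minus
assembly gaps. The directionality index (DI) is consumed as a binned
track (25 kb in the reference analysis), never computed from contact
matrices here. A *negative inversion* is a `(+) -> (-)` sign change —
the smoother switch near TAD middles; the `(-) -> (+)` change is the
boundary. Zero bins are skipped without breaking runs, and the reported
coordinate is the midpoint of the gap between runs (the shared bin edge
when they are adjacent). Each TAD splits at its interior negative
inversion (the one nearest the TAD midpoint when there are several) into
a positive-DI and a negative-DI section of generally unequal size.

Profiling utilities: `anchored_density_profile()` (mean item counts in
fixed bins around anchors, strand-aware, stratifiable by orientation,
tri-plet class or any item column), `meta_domain_profile()` (counts in
100 relative bins per TAD, averaged), `section_stack_profile()`
(per-section binned presence aligned on the inversion point, rows
ordered by section size, out-of-section bins `NA`),
`insulation_span_profile()` (mean number of interaction pairs whose ends
flank the boundary centre, at shifts of ±400 kb in 10-kb steps — the
local background against which the central dip shows insulation), and
`boundary_ctcf_census()` (per-score distribution of site counts in
centred 50-kb windows). Spanning is defined against the boundary
*centre*, a point, so shifted profiles are comparable across scores.

## The synthetic world

The generators state a fixed world rather than tunable targets:

* **Genome**: 4 arms of 30 Mb (two chromosomes, 3-Mb centromere gaps),
  4000 sites, clustered spacing — an exponential gap mixture of 5-kb
  (weight 0.6) and 200-kb components reproducing the short-gap excess of
  real inter-CTCF distances over a uniform null; 20-bp motif intervals;
  100-bp minimal spacing.
* **Orientations**: iid equiprobable by default (the randomization
  null), a `forward_prob` knob for planted bias, and a `"grammar"` model
  placing `>` sites in the left half and `<` sites in the right half of
  1-Mb domains — yielding divergent tri-plets at domain edges and
  convergent ones at centres, the planted version of the TAD cartoon
  `<>(>...>)(<...<)<>`.
* **Scores**: motif `12 + 2z1` (normal-like), ChIP-seq `exp(1 + z2)`
  (skewed), with latent correlation 0.43 as observed between the real
  score pairs.
* **Boundary plants**: shared boundaries appear in all datasets with
  ≤ 10-kb jitter, private ones in a single dataset, all separated by
  more than `3w`. Boundary regions default to 5 kb wide so that one
  plant's start/stop positions always stay pairwise within `w = 25 kb`
  (5 + 2×10 ≤ 25) and form a clique — the regime where consensus
  recovery is exact and the planted 50-shared/20-private world must
  return exactly 50 score-7 and 140 score-1 boundaries.
* **DI and interactions**: per-TAD `+` then `-` runs split at a planted
  asymmetry (recovered exactly at zero noise), and interaction pairs
  confined to TADs or straddling a boundary with a stated
  `cross_fraction`.

What a green test does *not* establish: the generators plant structure
at a single scale with clean separation (no nested sub-TADs, no
boundary-less DI drift, no copy-number or mappability artefacts, no
inter-chromosomal contacts), so passing recovery tests demonstrates
algorithmic correctness in the stated regime, not performance on real
Hi-C-derived inputs.

## Numerical choices and degenerate inputs

* Midpoints are `floor((start + end) / 2)`; quartile cuts assign sizes
  differing by at most one via rank order (first-tie policy only at the
  cut, average ranks inside the score product).
* Chi-square errors out on zero expected counts; di-plets drop the
  empty ConvDiv class from the proportion vector.
* `read_sites` fails on `start >= end` naming the offending line; rows
  without orientation are dropped with a count, never silently.
* Arms with fewer than `K` sites contribute no k-plets (warning);
  zero-length domains are skipped in meta-profiles; a TAD without an
  interior negative inversion is emitted unsplit (message).
* Singleton consensus clusters produce zero-length regions; downstream
  always widens by the flank, so the degeneracy is harmless.
* Constant score vectors make min-max permeability undefined (error)
  and rank aggregation warn about fully tied ranks.

## Limitations

Hi-C matrix processing (ICE, insulation scores, boundary calling), motif
scanning, and DI computation are all out of scope: motif orientations,
scores, DI tracks and reference loops are inputs. The quantile
normalization is applied to per-site value columns, not whole peak
tracks, where the original description is ambiguous. The consensus
algorithm's behaviour on overlapping chains of real boundaries depends
on the modularity heuristic; the restart policy makes it reproducible
but, like any Louvain variant, not provably optimal beyond the small
graphs the tests enumerate.
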