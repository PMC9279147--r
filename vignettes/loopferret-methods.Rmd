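---
title: "Models and methods behind loopferret"
author: "loopferret authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loopferret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopferret)
```

# The biological question

TAD boundaries are usually clusters of oriented CTCF binding sites (CBSs).
Under the loop-extrusion model, cohesin extrudes chromatin until a leg meets
a CBS whose motif points *toward* the approaching complex; loops therefore
form preferentially between convergent CBS pairs. Two quantitative puzzles
motivate this package: how boundary insulation scales with the number and
orientation of clustered CBSs, and why a sizable minority of loop anchors
sustain loops in a direction for which they have no correctly oriented
motif. The steric *loop-interference* hypothesis holds that a cohesin
complex stalled at a CBS blocks later complexes from sliding through,
stabilizing them just behind the anchor and creating a paired loop in the
nonconvergent direction. `loopferret` implements the full analysis chain on
contact matrices and a generative simulator in which both signatures can be
planted and recovered.

# The extrusion simulator

`simulate_extrusion()` runs a 1D lattice model. Each extruder has a left and
a right leg; per step a non-stalled left leg moves one bin toward lower
coordinates and a right leg toward higher coordinates. On *entering* a bin
holding a forward-oriented CBS, a left-moving leg stalls with that site's
capture probability (forward CBSs are the left anchors of rightward loops);
right-moving legs stall likewise at reverse CBSs. One-sided stalling is
deliberate: it is the minimal rule that reproduces the convergent bias.
Stalled legs are released only when the whole extruder unloads (probability
`unload_prob` per step), after which it reloads with both legs co-located at
a uniformly random bin.

With `interference_enabled`, a moving leg may never enter a bin occupied by
another extruder's stalled leg: it parks in the adjacent bin and remains
blocked for as long as the blocker persists, resuming when it disappears.
This is a concrete, testable discretization of a steric impediment; how long
a blocked complex persists in vivo is unknown, so blocked legs here simply
track their blocker rather than acquiring kinetics of their own.

`render_contact_map()` converts snapshots into a Hi-C-like observable: a
deterministic distance-decay background
`background_weight * (d + 1)^(-background_exponent)`, one count per extruder
per snapshot at its (left, right) pixel, and `intra_loop_samples` uniform
bin pairs inside each extruded interval (the within-loop contact cloud).
Masked bins are zeroed, emulating unmappable regions.

## Default study conditions

The default configuration is `n_bins = 400` bins of 10 kb, `n_extruders =
40`, `unload_prob = 0.002`, `capture_prob_default = 0.9`, `n_snapshots =
2000` (five steps apart after a 500-step burn-in), `intra_loop_samples = 3`,
and a background with exponent 1 and weight 0.5. These give minutes-scale
runs with clearly resolvable loop pixels and extruder lifetimes (~500 steps)
long compared with the time to traverse a TAD, so anchors are strongly
occupied. Snapshot spacing and burn-in were chosen once so the ensemble
decorrelates from its uniform initial condition; the background weight keeps
short-range marginals realistic without drowning the extrusion signal.

Scenario layouts plant CBSs on this lattice. `two_tads` places a divergent
reverse/forward pair at bins 199/201, so the junction (bin 200) is the
single depleted bin between two edge-to-edge domains; `ep_boundary_like`
plants the six-site R,R,F,R,F,R cluster with heterogeneous occupancy
(0.9/0.5/0.9/0.7/0.9/0.5) that typifies a clustered developmental boundary;
`forward_only_boundary` places a forward-only cluster between distal
anchors, the configuration in which interference manufactures nonconvergent
loops; `divergent_vs_nondivergent_panel` pairs a divergent and a
reverse-only boundary at matched CBS count.

## Where steric blocking is switched off, and why

At these extruder densities, steric blocking produces realistic but
dominating traffic jams: stalled legs queue for many bins behind every
anchor, the insulation dip tracks the fluctuating queue tail rather than the
planted junction, and each additional CBS at a cluster adds almost nothing
because the first stalled leg already blocks the lane. The package therefore
separates the two questions. The *insulation-response* experiments
(`two_tads` recovery, `run_boundary_panel()`, `run_boundary_weakening()`)
disable interference so that crossing probabilities multiply across planted
sites and the measured boundary score responds gradedly to CBS number and
occupancy. The *interference* experiment (`run_interference_experiment()`)
runs the forward-only scenario with blocking on and off and reads out the
signatures blocking creates. This is a design choice of the synthetic study,
not a claim about which regime chromatin occupies.

# Contact-matrix methods

Balancing uses symmetric Sinkhorn–Knopp iteration, which converges to the
same doubly-stochastic-up-to-scale fixed point targeted by the Knight–Ruiz
algorithm; the result, not the algorithm, is what downstream analyses
consume. Bins with zero marginals are masked before balancing and the target
row sum is the mean unmasked marginal, keeping weights O(1). Convergence is
declared at relative row-sum deviation `tol = 1e-8` (at most `max_iter =
1000` iterations); non-convergence is an error, never a silent partial
result. The expected profile `e(d)` is the mean balanced value over unmasked
pairs at each separation, and obs/exp pixels divide by it; coverage
equalization divides each matrix by its own total so that subtraction
operates on comparable scales.

# Insulation, boundaries, mappability

The insulation score of bin *i* is the mean balanced signal in the square
window `[i−w, i−1] × [i+1, i+w]`, log2-transformed relative to the
arithmetic mean of the raw scores over valid bins (arithmetic rather than
geometric, which tolerates zeros and only shifts the track's offset). Bins
within `w` of the edge, or with more than half of their window masked, are
invalid. The default window is 250 kb, the scale used for boundary analysis
on real Hi-C maps.

Boundaries are strict local minima of the valid track (plateaus resolve to
their leftmost bin). The boundary score is the depth to the *lower* of the
two nearest flanking maxima — a conservative, symmetric choice; segment ends
count as maxima. Because a single noisy bin inside a wide basin would
otherwise truncate the depth, `call_boundaries()` optionally smooths the
track with a short moving average before minima detection; the pipelines use
a 2-bin half-width, while the default (no smoothing) keeps the raw formula
exact. The boundary-score formula and smoothing of the upstream toolchains
are not published; these choices are explicit substitutes.

Low-mappability bins are flagged by a two-component Gaussian mixture fitted
to `log1p` marginal counts (EM via `mclust`), taking bins with posterior
above 0.5 for the lower-mean component. Three guards define "no separable
low-mappability class": the component means must differ by at least one
pooled standard deviation; the low component must be a minority; and it must
hold at least 1% of bins (and two bins) — a lone depleted bin, such as the
insulated junction bin itself, is not a mappability class. Zero-marginal
bins are always flagged. Boundaries within ±125 kb of a flagged bin are
marked `filtered` and excluded from summaries.

# Motifs and boundary composition

`scan_peak()` scores every offset of a peak sequence on both strands with
log2-odds against an order-0 background (uniform by default), positions with
N scoring −∞, and keeps the single best hit (ties: leftmost offset, then +
strand), discarded below a log-odds threshold of 0. PWMs parse from JASPAR
raw counts with a +0.25 pseudocount per cell. `compose_boundaries()`
collects CBSs overlapping each boundary ±100 kb and counts *divergent
pairs*: any reverse-oriented CBS strictly upstream of any forward-oriented
one — adjacency is deliberately not required, since the divergent signature
concerns the cluster as a whole. Quantiles in `composition_summary()` use
linear interpolation and whiskers extend to the last observation within 1.5
IQR.

# Loop anchors, categories and statistics

Anchor intervals merge when they overlap after ±1 bin padding
(multi-resolution loop calls produce overlapping anchors). An anchor "has a
directional CBS" for rightward loops iff it contains at least one forward
CBS — existence, not exclusivity, following the convergent-rule wording.
Categories: `no_ctcf` (no CBS), `nonconvergent` (anchors a loop in a
direction lacking a directional CBS), else `convergent_only`. A loop is
convergent iff its lower anchor has a forward and its upper anchor a reverse
CBS; convergent loops subdivide by their anchors' opposite-direction
engagements with precedence `convergent_associated` >
`double_sided_convergent` > `single_sided_convergent`, so the
interference-paired class is never absorbed by the broader one.

Bidirectionality uses a chi-squared omnibus on the category-by-bidirectional
table (no continuity correction) with pairwise post-hoc chi-squared tests,
BH-corrected over exactly the tests performed. Distance and strength
comparisons use Kruskal–Wallis followed, when significant at 0.05, by
pairwise Mann–Whitney tests with BH correction.

Loop strength is `log2` of the center square (side 3) over the two corner
squares of the ±10-bin window displaced along the diagonal — the corners at
the same genomic distance as the pixel, so the distance decay cancels. The
upstream geometry is unpublished; this window is the package's stated
default. `aggregate_loops()` averages obs/exp windows elementwise.

`call_loops_simple()` is a deliberately minimal local-enrichment caller that
exists to close the synthetic pipeline: obs/exp local maxima above a
threshold, non-maximum-suppressed within a Chebyshev radius, at least three
bins off-diagonal. Two optional guards make it usable on sparse synthetic
maps: an absolute raw-count support (`min_count`) against obs/exp spikes at
sparsely sampled distances, and a minimum anchor separation, used by the
interference experiment to restrict calling to the long-range window where
the scenario's loops live. It is not an FDR-controlled HiCCUPS replacement,
and real loop calls should be supplied as BEDPE-style tables instead.

# Comparison views

Subtraction maps equalize coverage, subtract elementwise and convert each
value to a z-score against the other values of its sub-diagonal (population
standard deviation). Diagonals with fewer than three defined pixels or zero
spread are reported as zero and flagged — without this, the farthest
diagonals produce spurious extremes. Virtual 4C averages the balanced rows
of a viewpoint, blanks the viewpoint ±2 bins, normalizes the defined bins to
unit mass and reports the share inside a quantification window. Multi-bin
viewpoints (a promoter-region viewpoint) average out single-row sampling
noise and are used by the weakening experiment (viewpoint bins 250–270,
window 80–160). The upstream virtual-4C normalization is unpublished;
sum-to-one over defined bins is this package's convention.

# The synthetic experiments

`run_boundary_panel()` plants 0–10 CBSs of capture probability 0.4 at the
lattice midpoint (divergent arrangement: reverse sites upstream, forward
downstream, adjacent spacing) and records the strongest unfiltered boundary
score within ±10 bins of the junction. Per-site occupancy of 0.4 keeps the
response graded across the whole 0–10 range instead of saturating after the
first site or two. The recovered medians rise monotonically with CBS count,
and divergent clusters insulate at least as well as reverse-only clusters of
the same size — both directions of crossing are partially blocked instead of
one.

`run_interference_experiment()` simulates the forward-only boundary with
blocking on and off over matched seeds. With blocking on, extruders arriving
from the centromeric side park adjacent to the stalled cluster, producing a
leftward loop anchored at the forward-only cluster — a nonconvergent,
bidirectional anchor paired with the convergent loop on the other side. The
pooled contrasts are the bidirectional fraction of nonconvergent versus
convergent-only anchors (post-hoc chi-squared) and the strengths of
convergent-associated versus nonconvergent-associated loops (one-sided
Mann–Whitney). With blocking off, nonconvergent anchors simply do not form.

`run_boundary_weakening()` removes the six CBSs of the clustered boundary
one at a time (left to right), re-simulating each level of a series from
the same seed, and quantifies the cross-boundary share of a virtual-4C
profile. Each removal lifts one factor of the crossing probability, so the
share is non-decreasing along a series up to sampling noise.

# What the simulations do and do not show

The generator emulates distance decay, TADs bounded by oriented CBS clusters
with heterogeneous occupancy, convergent loop pixels, interference-induced
nonconvergent loops and unmappable bins — enough for every pipeline stage to
be checked against planted truth. It does not emulate 3D polymer mechanics,
CTCF/cohesin residence-time kinetics, replication or cell-cycle structure,
trans contacts, or the read-level noise of real Hi-C libraries; lattice
edges act as absorbing anchors that real chromosomes do not have. Passing
recovery tests therefore demonstrates the correctness and sensitivity of the
analysis chain under a faithful cartoon of the mechanism, not the
mechanism's sufficiency in vivo. Genome-scale figures from published Hi-C
data (anchor-category percentages, boundary-score distributions) depend on
deep sequencing and FDR-controlled loop calling and are outside what these
desk-scale simulations can reproduce.

# Numerical notes

Problem sizes used by the shipped experiments: 400-bin lattices, 100 seeds
for boundary recovery, 8 seeds per CBS-count level for the panel, 20 seeds
per interference arm, 20 weakening series of 7 levels. Balancing tolerance
is 1e-8 relative; virtual-4C normalization and z-map diagonals are exact to
floating-point round-off. All randomness flows from one root seed via
derived per-run seeds; file outputs are byte-identical across reruns with
the same seed. Degenerate inputs fail loudly: matrices with fewer than two
unmasked bins, non-converged balancing, fully masked viewpoints and
zero-signal profiles are errors, not warnings.
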