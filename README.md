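# loopferret

Dissection of clustered-CTCF TAD boundaries in chromatin contact maps.

Topologically associating domains (TADs) are separated by boundary regions
that are typically built from clusters of CTCF binding sites (CBSs) with
mixed motif orientations. Cohesin extrudes chromatin loops and is stalled by
CTCF in an orientation-dependent way, which explains why chromatin loops
preferentially connect convergently oriented CBS pairs — yet a measurable
fraction of loop anchors sustain loops in a direction for which they carry
no correctly oriented motif. A steric *loop-interference* mechanism can
produce these nonconvergent loops: a cohesin complex stalled at a CBS
physically blocks further complexes from sliding through, stabilizing them
on the opposite side of the anchor and creating a paired loop in the
nonconvergent direction.

`loopferret` packages the computational machinery needed to dissect this
biology quantitatively, and a synthetic-data generator that makes every
stage verifiable at desk scale:

* **Simulator** (`sim_config()`, `simulate_extrusion()`,
  `render_contact_map()`, `generate_dataset()`): a 1D lattice cohesin
  model with orientation-dependent stalling (a forward CBS captures
  left-moving legs, a reverse CBS right-moving legs) and an explicit steric
  blocking rule, rendered into Hi-C-like contact maps with ground-truth CBS,
  loop and boundary annotations.
* **Contact matrices** (`contact_matrix()`, `read_contact_matrix()`,
  `kr_balance()`, `expected_by_distance()`, `oe_transform()`,
  `equalize_coverage()`): sparse-triplet I/O, Sinkhorn–Knopp (KR-type)
  balancing to uniform row sums, distance-decay expectation and
  observed/expected pixels.
* **Insulation and boundaries** (`insulation_score()`, `call_boundaries()`,
  `fit_mappability_mask()`): sliding square-window insulation,
  `IS(i) = log2(raw(i) / mean(raw))`; boundaries at strict local minima with
  boundary score `BS = min(IS_leftmax, IS_rightmax) − IS(min)`; a
  two-component Gaussian-mixture mask flags low-mappability bins and
  boundaries within ±125 kb of them are filtered.
* **Motifs and composition** (`read_jaspar_pwm()`, `scan_peak()`,
  `compose_boundaries()`, `composition_summary()`): FIMO-style best-hit PWM
  scanning (log2-odds, both strands, one motif per peak) and per-boundary
  CBS counts and divergent-pair statistics within a 100-kb flank.
* **Loop classification and statistics** (`classify_anchors()`,
  `classify_loops()`, `bidirectional_stats()`, `loop_strength()`,
  `aggregate_loops()`, `corner_association()`, `call_loops_simple()`):
  anchors as convergent-only / nonconvergent / no-CTCF, loops into the
  five-way convergence scheme, chi-squared and Kruskal–Wallis/Mann–Whitney
  testing with Benjamini–Hochberg correction, APA-style aggregate windows
  and log2 center-over-corner loop strengths.
* **Comparison views** (`subtraction_map()`, `virtual_4c()`):
  coverage-equalized subtraction maps z-scored per sub-diagonal, and
  normalized virtual-4C profiles with window quantification.
* **Experiments** (`run_boundary_panel()`, `run_interference_experiment()`,
  `run_boundary_weakening()`): end-to-end syntheses that recover the
  boundary-composition and loop-interference signatures from simulated maps.

## Worked example

Simulate a two-TAD map, balance it, and call boundaries:

```r
library(loopferret)
sim <- simulate_scenario("two_tads", seed = 101)
sim$matrix
#> <contact_matrix> chrS: 400 bins x 10000 bp (6.35e+05 total counts, 2 masked)

bp <- boundary_pipeline(sim$matrix)
b  <- bp$boundaries[!bp$boundaries$filtered, ]
head(b[order(-b$boundary_score), ], 3)
#>    bin  insulation boundary_score filtered
#> 14 200 -2.98672800     3.13014641    FALSE
#> 2   48  0.11932807     0.01882729    FALSE
#> 5   84  0.06309377     0.01467480    FALSE
```

The strongest boundary sits at bin 200 — the planted junction between the
two domains — with a boundary score two orders of magnitude above the noise
floor, and the mappability mask recovered exactly the two masked bins.

The loop-interference experiment contrasts simulations with steric blocking
on and off:

```r
ex <- run_interference_experiment(n_seeds = 5, seed = 11)
ex$on$stats$fractions
#>          category  n n_bidirectional   fraction
#> 1 convergent_only 10               0 0.00000000
#> 2   nonconvergent  5               5 1.00000000
#> 3         no_ctcf 27               2 0.07407407
round(ex$contrast$strength_p_one_sided, 4)
#> [1] 0.0017
```

With interference enabled, every nonconvergent anchor is bidirectional (it
anchors a convergent loop in the opposite direction) while convergent-only
anchors are not, and the convergent partners are significantly stronger than
their nonconvergent counterparts — the qualitative fingerprints of loop
interference. With interference disabled, nonconvergent anchors do not form.

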