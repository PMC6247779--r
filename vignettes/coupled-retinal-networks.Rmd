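---
title: "Mining heterocellular coupling in retinal connectome graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining heterocellular coupling in retinal connectome graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retcouple)
```

## The problem

Ganglion cells (GCs) in the vertebrate retina often carry an intermediate
GABA immunosignal — well above background but an order of magnitude below
true GABAergic amacrine cells (ACs). Because no GABA transporter or
synthesis machinery is established in adult GCs, the parsimonious
explanation is *heterocellular coupling*: small molecules diffusing into
the GC through gap junctions shared with GABAergic amacrine cells. Testing
that explanation requires two kinds of evidence, and this package
implements the computational side of both:

1. **Connectomics** — given a densely annotated volume expressed as a typed
   graph (neurons; directed ribbon and conventional synapses; undirected
   gap junctions), mine the coupling motifs, tabulate each cell's
   excitatory, inhibitory and coupling drive, and extrapolate from the
   fraction of the arbor inside the volume to the whole cell.
2. **Computational molecular phenotyping (CMP)** — given registered
   multichannel small-molecule images (GABA, glutamate, ...), calibrate
   pixel values to concentrations, cluster pixel signatures into theme
   maps, and segment the GC layer into GABA-content classes.

## The graph model and the query engine

A `connectome()` is two tibbles: `neurons` (class label, superclass,
polarity, transmitter, arbor fraction, optional morphometrics) and
`contacts` (kind, endpoints, PSD or junction area in µm², optional
diameter in nm). Three conventions matter:

* **Gap junctions are undirected.** They are stored with a canonical
  endpoint order, so every census and query result is invariant to the
  order in which an annotator happened to record the two cells.
* **The disc model links diameter and area.** Junctions are near-circular
  en face, so `area = π(d/2)²`; when only one measurement is present the
  other is derived, and `validate_connectome()` flags pairs that disagree
  by more than 1%.
* **`bc_conventional` is matched as `conventional`.** Bipolar-cell
  conventional synapses differ from amacrine conventional synapses only by
  the presynaptic superclass, which the query's node patterns already
  express.

Path queries are comma-separated alternating tokens: anchored regular
expressions over class labels at odd positions, edge kinds
(`ribbon`, `conventional`, `gap junction`, `any`) at even positions.

```{r query}
g <- rc1_summary_fixture()
m <- find_paths(g, "CB.*, ribbon, GC tON DS")
nrow(m)
count_matches(m, "first_class")
```

Semantics are *simple paths* (no repeated neuron): the motifs of interest
— e.g. a GC coupled to an AC that inhibits a GC of a different class,
`GC1 :: AC > GC2` with `disjoint_filter()` enforcing class 1 ≠ class 2 —
are acyclic, and the restriction bounds the search. Named synapse kinds
traverse pre→post only; `gap junction` and the `any` wildcard traverse
either direction. Matches are returned in a deterministic lexicographic
order. Correctness is checked against an independent brute-force
enumerator on hundreds of small random graphs rather than against
hand-picked cases.

## Drive tables and extrapolation

`drive_table()` tallies contacts incident to one cell by kind and
extrapolates with the cell's *arbor fraction* — the fraction of its
dendritic length inside the volume: `extrapolated_n = round(n / f)`.
The rounding policy reports values ≥ 1000 to the nearest ten and smaller
values to the nearest integer, which is the precision at which whole-cell
estimates are conventionally quoted; `rounding = "none"` disables it.
Totals are exact sums of per-contact areas; means and SDs are reported
alongside.

`network_ff_fb_totals()` counts amacrine conventional output by target
superclass (feedback → bipolar; feedforward → ganglion or amacrine). It
accepts an optional presynaptic *cohort* because published network-level
tallies are normally scoped to one bipolar-cell network rather than to the
whole volume; the packaged fixture carries its ON-network amacrine cohort
explicitly (`rc1_cohorts()$on_network_acs`), which also keeps the
single-cell tallies (e.g. 783 inhibitory inputs on the GC606 analog) and
the network totals simultaneously representable in one graph.

## The summary fixture

`rc1_summary_fixture()` deterministically rebuilds a graph whose tallies
equal a published contact census (259/783/228 contacts at 9.8/53.6/6.4
µm² on the coupled ON DS GC analog, the 2359/336/564 network totals, the
feedback-only AI cohort, the feedforward-biased IAC, and the OFF-alpha
dendrite at 9142 nm²/µm of coupling). Per-contact areas are not published,
so each area list is a symmetric deterministic ramp around the target
mean: counts and totals are exact, construction involves no randomness,
and serialization is byte-identical across runs. The ramp's spread (±80%
of the mean) is a display choice, not an estimate of the real SD, which is
why tests assert counts and totals but never the fixture's dispersion.

## Statistics

`compare_gap_junction_sizes()` runs the standard two-sample battery
(Student and Welch t, F variance ratio, two-sample KS) plus pooled-SD
Cohen's *d* and post-hoc power. Power uses the noncentral-*t*
distribution with noncentrality `d·√(n₁n₂/(n₁+n₂))` on `n₁+n₂−2` df —
the textbook two-sample calculation — and is verified against a
10,000-replicate Monte-Carlo rejection-rate oracle to within 0.02
absolute. In very unbalanced designs the smaller sample caps attainable
power, which is the practical caveat when a 13-junction dendrite is
compared with a 228-junction arbor: with the printed moments the
calculation yields power ≈ 0.4 at α = 0.05, and we report exactly what
the documented method produces.

## The synthetic connectome generator

`generator_config()` defines the study conditions; the generator is not a
tuning knob. Defaults encode the structure the analysis assumes:

* **Wiring.** Per ordered cell pair, synapse counts are Poisson with the
  rule's mean; the ribbon drive onto the ON DS GC class is biased so
  ~54% arrives from CBb4w and under 1% from CBb5. Contact areas are
  lognormal (positive, right-skewed) with means 0.038 µm² (ribbon) and
  0.068 µm² (conventional).
* **Coupling.** Per unordered pair, junction counts are Poisson
  (expected 228 junctions onto the ON DS GC); diameters are
  Normal(181, 56) truncated to [72, 357] nm. Truncating a normal shifts
  its mean (to ≈184 nm here), so the sampler calibrates the parent
  location such that the *truncated* distribution has the configured
  mean — the moment-recovery property ("sample mean within 3 SE of
  181 nm at n ≈ 228") then holds exactly as stated.
* **Motif switches.** Homocellular GC::GC coupling is off by default
  (no proven instances exist); coupled amacrine cells feed forward onto
  ganglion classes disjoint from their coupled class, with the target
  class drawn uniformly because only disjointness, not a distribution,
  is established.

Stratification depth is represented only through class identity: the
analysis consumes topology and contact sizes, not 3D geometry, so
generated graphs make no claim about spatial realism. Passing tests on
generated graphs therefore validate the *census and query machinery*, not
the anatomical fidelity of any particular wiring diagram.

## The image pipeline and its phantoms

The calibration model is log-linear: `PV = 96 + 64·log₁₀(c/0.1 mM)`,
clamped to [0, 255], spanning ≈0.003–30 mM. The true constants of any
given imaging run live in its densitometry calibration and are fully
user-configurable; the defaults were chosen once to span the 0.1–10 mM
decision range with headroom, and GABA segmentation thresholds
(0.1 / 1 / 10 mM) are applied in pixel-value space with half-open
`[low, high)` boundaries (a pixel exactly at a threshold joins the upper
class; content above 10 mM remains in the amacrine class).

Theme maps use `stats::kmeans` (Hartigan–Wong) on the pixel-by-channel
matrix, best of 10 restarts by within-cluster sum of squares under a
fixed seed, with cluster labels renumbered lexicographically by mean
signature so label identity is stable run-to-run. Registration is an
exhaustive integer-shift search maximizing overlap correlation; subpixel
refinement is deliberately out of scope, matching the 200 nm section
registration problem where integer shifts suffice.

Phantoms (`generate_cmp_phantom()`) place non-overlapping soma discs with
class signatures: SAC GABA 5–10 mM; coupled GC 0.3–0.6 mM (ten-fold lower,
the published center of the intermediate population); uncoupled GC at
background. Glutamate is identical for the two GC classes — a coupled GC
keeps the classic high-glutamate signature — so the phantom reproduces the
key identifiability fact: the classes separate in the GABA channel and are
indistinguishable in glutamate (`separability()` overlap > 0.9). Noise is
additive Gaussian on pixel value, clipped to [0, 255]; at zero noise,
segmentation and object counts recover ground truth exactly, which is the
oracle the tests use. What phantoms do **not** model: real soma shapes,
silver-grain densitometry physics, antibody cross-reactivity, or
section-to-section registration error beyond pure translation — so a
passing phantom suite shows the pipeline's arithmetic is right, not that
real imagery will classify this cleanly.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`withr::with_seed`),
so every generator output, theme map and simulated comparison is
bit-reproducible. The test suite works at deliberately small scales — toy
graphs of ≤ 8 neurons for oracle comparisons (200 random cases), one
generated connectome of ~60 cells, 160-pixel phantoms, and a
10,000-replicate Monte-Carlo power check — sizes at which the independent
oracles (exhaustive enumeration, hand arithmetic, ground-truth recovery)
are exact and fast.

## Known limitations

* The fixture encodes published *summaries*; per-contact dispersion,
  spatial positions and per-partner junction splits are constructions,
  and analyses of those aspects on the fixture would be circular.
* The reference-area column sometimes printed alongside published drive
  tables has no stated denominator; the package reports area densities
  only when the user supplies the reference explicitly
  (e.g. `gj_density_per_length()` requires a dendrite length).
* Class-label vocabularies differ between annotation databases; the
  bundled roster defines this package's vocabulary, and unknown labels are
  allowed but flagged rather than coerced.
* Power analysis follows the documented noncentral-*t* convention; other
  software may use different post-hoc definitions and give values as low
  as ≈0.3 for the unbalanced 13-vs-228 design, and no attempt is made to
  match any particular implementation.
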