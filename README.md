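# retcouple

Tools for mining **heterocellular coupling** — gap junctions between
ganglion cells (GCs) and GABAergic amacrine cells (ACs) — in densely
annotated retinal connectome volumes, together with the **computational
molecular phenotyping (CMP)** image pipeline that identifies provisionally
coupled cells by their intermediate GABA signatures.

Many GC classes carry a GABA immunosignal far above background but an
order of magnitude below true GABAergic amacrine cells. Since adult GCs
have no established GABA transport or synthesis, the working explanation
is diffusion through GC::AC gap junctions. Testing it computationally
needs: a typed graph model of neurons and contacts, a path-query engine
for coupling motifs, quantitative drive tables with whole-cell
extrapolation, gap-junction statistics with post-hoc power, and an image
pipeline that turns calibrated multichannel immunosignals into cell-class
maps. `retcouple` implements all of these with tidyverse-style interfaces
(tibbles in, tibbles out; `autoplot()`, `tidy()`, `glance()` methods).

## The core quantities

For a cell with `n` contacts of a kind inside the volume and arbor
fraction `f` (the fraction of its dendritic length the volume contains),
the whole-cell estimate is `n / f`, reported to the nearest ten above
1000. Gap junctions are undirected, stored canonically, and obey the disc
model `area = π(d/2)²` linking junction diameter (nm) and area (µm²).
Path queries are comma-separated alternating tokens — anchored class-label
regexes and edge kinds — e.g. `"CB.*, ribbon, GC ON"` for all cone
bipolar ribbon inputs onto ON GCs, and the coupled feedforward motif
`GC1 :: AC > GC2` (class 1 ≠ class 2) is `"GC.*, gap junction, .*AC.*,
conventional, GC.*"` followed by `disjoint_filter()`. Two-sample
gap-junction size comparisons report Student/Welch t, F and KS tests plus
noncentral-*t* post-hoc power at pooled-SD Cohen's *d*.

## Worked example

The package ships a deterministic summary fixture encoding the published
contact census of a heavily coupled transient ON DS ganglion cell:

```r
library(retcouple)

g <- rc1_summary_fixture()
g
#> <connectome> 132 neurons, 4566 contacts
#>   ribbon: 280, conventional: 4042, bc_conventional: 0, gap_junction: 244

drive_table(g, "GC606", arbor_fraction = 0.18)
#> # A tibble: 3 × 9
#>   kind      n mean_area_um2 sd_area_um2 min_area_um2 max_area_um2 total_area_um2
#> * <chr> <int>         <dbl>       <dbl>        <dbl>        <dbl>          <dbl>
#> 1 ribb…   259        0.0378      0.0176      0.00757       0.0681            9.8
#> 2 conv…   783        0.0685      0.0317      0.0137        0.123            53.6
#> 3 gap_…   228        0.0281      0.0131      0.00561       0.0505            6.4
```

Reading the rows: the cell's in-volume arbor receives **259** excitatory
ribbon synapses (9.8 µm² of PSD), **783** inhibitory conventional
synapses (53.6 µm² — about 3 inhibitory synapses and 5.5 µm² of
inhibitory PSD per unit of excitation), and makes **228** gap junctions
(6.4 µm² of coupling area). The `extrapolated_n` column scales these by
the 18% arbor fraction to a whole-cell estimate of ≈1440 ribbons, ≈4350
conventional synapses and ≈1270 gap junctions. Every junction partner is
a GABAergic amacrine class:

```r
coupled_partners(g, "GC606")
#> # A tibble: 28 × 5
#>   partner_id class_label transmitter n_junctions total_area_um2
#>   <chr>      <chr>       <chr>             <int>          <dbl>
#> 1 IAC9769    IAC         GABA                 25          0.200
#> 2 gAC_01     gAC         GABA                  9          0.166
#> ...
```

Seeded generators provide synthetic connectomes
(`generate_connectome()`) and multichannel image phantoms with ground
truth (`generate_cmp_phantom()`); `cluster_theme_map()`,
`segment_gaba_classes()` and `masked_histogram()` implement the CMP side.
A thin command-line interface over the same functions lives at
`inst/scripts/retcouple.R` (subcommands `make-fixture`, `drive-table`,
`query`, `census`, `compare-gj`, ...; exit codes 0/1/2 for
success/data error/usage error).

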