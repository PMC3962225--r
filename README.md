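# csmtools

Compound promiscuity — the specific activity of one small molecule against
multiple biological targets — is the molecular basis of polypharmacology.
`csmtools` is an R toolkit for mining multi-target activity spaces: it curates
compound activity data, quantifies promiscuity, relates structure to
promiscuity through matched molecular pairs (MMPs), and organizes analog
series into **Compound Series Matrices (CSMs)** whose empty cells are virtual
compounds, i.e. enumerable design candidates.

It is aimed at cheminformaticians and medicinal chemists who work with
ChEMBL-style potency tables (K_i / IC50) or binary profiling matrices and want
reproducible, scriptable promiscuity analyses without a database server.

## What it computes

**Curation.** Activity records are filtered to a single measurement type,
records with approximate potency annotations (`>`, `<`, `~`) are excluded, and
a potency cutoff (default 10 µM) defines activity. Structures are
salt-stripped and canonicalized (via OpenBabel through ChemmineR/ChemmineOB);
compounds with identical canonical structures are merged and replicate
potencies aggregated by geometric mean.

**Promiscuity statistics.** For per-compound target counts *T*, the
promiscuity rate is the mean of *T* over multi-target compounds only
(*T* ≥ 2); the probabilities P(*T* ≥ 2) and P(*T* > 5) use all compounds in
the denominator. Summaries can be stratified by target family (restricting
each compound's target set to the family) and by molecular-weight bin
(default bins (0,200], (200,300], …, (700,∞) Da).

**MMPs and promiscuity cliffs.** A matched molecular pair is two compounds
that differ only by the exchange of two substructures at a single site. The
implementation enumerates single-cut fragmentations over acyclic bonds,
indexes them by canonical core, and applies transformation size restrictions
(substituent ≤ 13 heavy atoms, core ≥ 2× substituent, exchange delta ≤ 8).
MMPs whose compounds differ by ≥ 50 target annotations are *promiscuity
cliffs*; cliffs form a compound network whose multi-cliff nodes are
promiscuity hubs.

**Target networks.** Targets sharing at least five compounds (configurable)
are linked into a co-activity network with intra-/inter-family pair counts; a
compound–target bipartite network carries the compound degree distribution.

**CSMs.** A two-step scheme: MMPs over compounds define analog series (one
per core); MMPs computed over the core fragments themselves — with the
attachment point kept as an inert marker that is never cut — relate series
whose cores differ at a single site. Each connected component of the
core-level MMP graph becomes one matrix: rows are related cores, columns are
substituents, real cells hold compounds colored by target count, and empty
cells are virtual compounds that `design_candidates()` reassembles into full
structures.

A seeded synthetic-fixture module (`generate_analog_grid()`,
`generate_binary_matrix()`) plants analog grids and cliff pairs with exact
ground truth, so the whole pipeline is testable without external data.

## Worked example

```r
library(csmtools)

fix <- generate_analog_grid(fixture_spec(seed = 42))
fix$dataset
#> Curated Ki dataset: 15 compounds, 22 compound-target activities, 15 targets (potency <= 10000 nM)

summarize_promiscuity(fix$profiles)
#> Promiscuity summary over 15 compounds
#>   multi-target compounds: 4
#>   promiscuity rate (mean T | T >= 2): 2.75
#>   P(T >= 2): 0.267
#>   P(T > 5):  0

mmps <- generate_mmps(fix$dataset)
head(mmps[, c("compound_a", "compound_b", "core", "transformation")], 3)
#> # A tibble: 3 × 4
#>   compound_a compound_b core         transformation
#> 1 CMP-1-N    CMP-1-O    *c1ccccc1    *N>>*O
#> 2 CMP-2-C    CMP-2-Cl   *c1ccc(cc1)F *C>>*Cl
#> 3 CMP-2-C    CMP-2-N    *c1ccc(cc1)F *C>>*N

csms <- build_csms(build_series(fix$dataset), fix$profiles)
csms[[1]]
#> Compound Series Matrix: 4 cores x 5 substituents; 15 real, 5 virtual cells
```

The summary says that 4 of the 15 curated compounds are active against two or
more targets and that those multi-target compounds hit 2.75 targets on
average. The 23 MMPs group the compounds into four analog series whose cores
(a fluorine-decoration ladder on a benzene scaffold) are related by
core-level MMPs, so they merge into a single 4 × 5 CSM; its 5 empty cells are
the core–substituent combinations absent from the dataset. Reassembling the
virtual cells of one column proposes concrete analogs:

```r
design_candidates(csms[[1]], "*Br")
#> # A tibble: 2 × 3
#>   core         substituent smiles
#> 1 *c1ccccc1    *Br         Brc1ccccc1
#> 2 *c1ccc(cc1)F *Br         Fc1ccc(cc1)Br
```

`autoplot()` methods draw the target-count distribution, the CSM tile view
and the networks; `tidy()`/`glance()` return tabular views of every result
object. A thin command-line wrapper is installed at
`system.file("cli", "csmtool.R", package = "csmtools")` with subcommands
`curate`, `mmp`, `rates`, `cliffs`, `network`, `csm` and `simulate`.

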