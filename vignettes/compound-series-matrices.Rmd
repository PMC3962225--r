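---
title: "Methods: promiscuity analysis and Compound Series Matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promiscuity analysis and Compound Series Matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods implemented in `csmtools`: the data
model, the statistics, the fragmentation and matrix machinery, the design
choices that were genuinely open, and what the synthetic fixtures do and do
not establish about real data.

## Data model and curation

The unit of input is one activity record: a compound (identifier + SMILES),
a target (identifier + family label), a measurement type (`Ki`, `IC50` or
`binary`), a relation symbol and a potency in nM. Equilibrium constants and
assay-dependent IC50 values answer different questions, so a curated dataset
holds exactly one measurement type; mixed tables are legal at read time and
type selection happens only in `curate_activities()`.

Curation applies three rules:

1. **Approximate annotations are excluded.** Records with relations `>`,
   `<` or `~` carry censored or imprecise potencies; only `=` records
   survive. Keeping censored values would bias both activity calls and
   potency aggregation.
2. **A potency cutoff defines activity.** The default is 10 µM
   (`potency_threshold_nm = 10000`): a compound–target pair with a weaker
   measured potency is not counted as an activity. The cutoff is an argument
   because profiling contexts differ.
3. **Structure-level deduplication.** Database exports routinely list the
   same molecule under several identifiers (salt forms, re-registrations).
   Structures are salt-stripped (largest covalent component) and
   canonicalized; identical canonical structures are merged, with the
   lexicographically smallest identifier kept as representative and the
   union of activities attached.

Replicate potencies for one compound–target pair are aggregated by the
**geometric mean**, the standard choice for log-scaled potency data. Target
*counting* is unaffected by the aggregate: one qualifying measurement makes
the pair active.

A target profile is a compound's set of distinct active targets; its size
*T* is the promiscuity measure everything downstream consumes.

## Promiscuity statistics

The promiscuity **rate** is the mean of *T* over compounds with *T* ≥ 2.
Single-target compounds are excluded from the mean — including them would
deflate the rate toward 1 in the typical heavily single-target-skewed
dataset — but they stay in the denominators of the threshold probabilities
P(*T* ≥ 2) and P(*T* > 5), which are fractions of *all* compounds. For
binary profiling matrices, inactive compounds (*T* = 0) additionally remain
in distributions and probability denominators, but never enter a rate. When
no multi-target compound exists the rate is reported as `NA`, not 0.

Two stratifications:

* **By target family** (`summarize_by_family()`): each compound's target set
  is restricted to the family before summarizing, and the multi-target
  condition applies *within* the family. A compound with one kinase and four
  GPCR activities is a single-target compound from the kinase family's
  point of view: it counts toward the family's denominator but not its rate.
* **By molecular weight** (`summarize_by_mw()`): weights are computed from
  the desalted structure including implicit hydrogens. Default bins follow a
  100-Da progression — (0,200], (200,300], …, (700,∞) Da. Only the 200- and
  300-Da boundaries are canonical in the field; the rest of the progression
  is the evident continuation and is configurable via `mw_bins()`. Bins are
  left-open/right-closed, so a compound exactly at an edge falls in the
  lower bin; weights beyond the last edge go to the open last bin rather
  than being dropped.

## Fragmentation and matched molecular pairs

`enumerate_fragmentations()` cuts every **acyclic single bond between two
heavy atoms** — ring bonds and bonds to hydrogen are never cut — and emits
both orientations of each cut as (core, substituent) pairs, each fragment a
canonical SMILES with one wildcard (`*`) attachment point. Single-cut
fragmentation only: the matrix machinery needs exactly one core and one
R-group per compound (one substituent axis per matrix), so multi-cut
variants of the general fragment-and-index approach are deliberately
omitted.

MMP generation indexes size-restricted fragmentations by canonical core and
pairs compounds sharing a core with distinct substituents. The
**transformation size restrictions** default to: substituent ≤ 13 heavy
atoms, core ≥ 2 × substituent heavy atoms, and exchanged substituents
differing by ≤ 8 heavy atoms. No canonical numeric values exist for these
limits in the literature line this follows; the defaults are the
conventional choices of that methodology family and are fully configurable
through `size_limits()`. Two further conventions make output deterministic:

* When a compound pair shares several cores, only the MMP with the
  **largest core** is kept (the most conservative transformation); ties
  break lexicographically. An ethyl/propyl analog pair, for example, is
  reported under the benzyl-type core rather than the smaller phenyl core.
* The stored transformation is oriented so `substituent_a` sorts before
  `substituent_b` in C-locale byte order, making pair objects unique and
  exports diff-stable. All ordering in the package uses locale-independent
  radix sorting.

Chemistry handling (SMILES parsing, canonical SMILES, molecular weights)
runs through OpenBabel via ChemmineOB/ChemmineR; the fragmentation,
indexing, pairing and matrix logic operate on plain molecular graphs
extracted from those parsers.

## Promiscuity cliffs

A promiscuity cliff is an MMP whose compounds differ in target count by at
least `delta_threshold`, **inclusively** (default ≥ 50): a minimal chemical
change coupled to a large promiscuity change. Cliffs form a network whose
nodes are compounds (annotated with *T* for color mapping) and whose
hubs are nodes of degree ≥ 2. For transformation-frequency accounting the
exchange is oriented from the less to the more promiscuous compound; ties
cannot occur in a cliff at any positive threshold.

## Target networks

`build_target_network()` counts, for every unordered target pair, the
compounds active against both, and draws an edge at ≥ `min_shared` shared
compounds (default 5). Nodes are restricted to targets incident to at least
one edge: the network describes target *pairs*, and isolated targets carry
no pair information. Edges are classified intra-/inter-family by label
equality; targets missing a family label are classified `"other"` with a
warning. Edge weights (shared counts) are retained in exports so networks
can be re-thresholded without recomputation. Graph layout is a rendering
concern and deliberately out of scope; `autoplot()` uses a seeded
force-directed layout for inspection only.

## Compound Series Matrices

The construction is strictly two-step:

1. **Compound-level MMPs** group compounds into analog series — one series
   per core that occurs in at least one MMP, containing every compound that
   fragments to that core under the size restrictions.
2. **Core-level MMPs**: the core fragments are treated as molecules, with
   the attachment point preserved as an inert marker atom (astatine — an
   element absent from drug-like chemistry) that is never cut. Single-cut
   MMP generation over these marker molecules relates cores differing by a
   structural change at a single site. At this level,
   **hydrogen-replacement fragmentations** are included (core = molecule
   with an attachment at a hydrogen position, substituent = `[*H]`):
   without them, an unsubstituted core (phenyl) could never be related to
   its monosubstituted analog (4-methylphenyl), a relationship the matrix
   scheme requires. Cuts on the marker side of a core are legitimate too:
   they relate cores differing at the attachment linker (benzyl vs.
   phenethyl), which is still a single-site change. No third fragmentation
   round exists, structurally: core-level cores are never re-fragmented.

Each connected **component** of the core-level MMP graph with ≥ 2 cores
becomes one CSM. Components are the minimal faithful grouping rule: any
chain of single-site core changes ends up in one matrix, and no unrelated
cores are forced together. Rows (cores) and columns (substituents) are
sorted by heavy-atom count, then lexicographically — deterministic,
diff-stable exports. A cell is real when its core–substituent combination
exists (exactly one compound; two distinct compounds in one cell indicate
an upstream deduplication failure and raise an error), otherwise virtual. A
compound fragmenting into several cells of one CSM is placed once, at the
cell with the largest core. Per-cell target counts are the raw *T* values;
mapping them to a color spectrum happens only in `autoplot()`.

`extract_promiscuous_submatrix()` keeps real cells at or above a target
count, drops rows/columns without surviving real cells, and recomputes
virtual cells on the reduced grid. `design_candidates()` reassembles the
virtual cells of a column into full canonical structures — design
hypotheses, not activity predictions.

## Synthetic fixtures: what they emulate and what they do not

`generate_analog_grid()` plants a full cores × substituents grid with seeded
random deletions. Cores are a fluorine-decoration ladder on a benzene
scaffold (0, 1, 2, … fluorines added at fixed positions), so consecutive
cores are related by a single H→F change **by construction**; substituents
are single heavy atoms disjoint from fluorine. This choice is deliberate:
with single-atom substituents and decoration atoms disjoint from the
substituent set, the planted within-row pairs are *provably* the complete
MMP set under the default size restrictions — no accidental alternative
shared cores exist — so the generator's ground truth (MMPs, series, matrix
layout, virtual-cell coordinates) is exact, and recovery tests can demand
identity rather than approximation. Target counts are sampled from a
zero-truncated geometric distribution (default success probability 0.6,
mean ≈ 1.7), reproducing the heavy single-target skew of curated potency
datasets; targets are drawn from a family-structured panel (default 20
targets in 5 families). Potencies are log-uniform over 1 nM–10 µM.

`generate_binary_matrix()` emulates a profiling microarray readout: a
binary compound × target matrix (default 100 targets) with background
activity at a per-cell rate (default 0.03) over unsubstituted cycloalkanes
of distinct ring sizes — molecules with no acyclic bond, hence provably no
fragmentations and no MMPs — plus planted cliff pairs built as true MMP
partners (methyl vs. chloro on the same ring) whose target counts differ by
an exact delta (default 55).

What passing tests on these fixtures establish: the fragmentation, pairing,
grouping, layout and recovery logic are exact on inputs whose answer is
known. What they do not establish: behavior on real medicinal chemistry —
large flexible molecules, charged and stereo-annotated structures, tautomer
ambiguity, pathological symmetry — nor any statistical property of real
promiscuity data beyond the planted distributions.

## Numerical and degenerate-input conventions

* Canonicalization is delegated to OpenBabel's canonical SMILES; equality
  of structures always means equality of canonical strings.
* Supported chemistry is neutral organic molecules without stereo
  annotations; fragment round-trips through SDF do not preserve charges or
  stereo at cut sites. Salt stripping keeps the largest covalent component
  (ties: lexicographically smallest canonical component).
* Unparseable structures raise errors carrying the offending compound
  identifier; they are never silently dropped.
* An empty curation result, an empty promiscuous submatrix, and a cliff-free
  input are explicit signals (typed conditions or empty typed tibbles), not
  silent empty containers.
* All randomness is confined to the fixture generators and flows from a
  single integer seed; everything else is deterministic, and repeated runs
  are byte-identical.

## Problem sizes

The test suite exercises: 50 random compound sets of 10–30 molecules
(drawn from a 100-molecule template library) for MMP oracle equivalence;
100 molecules × 10 alternative SMILES encodings for canonicalization
invariance; 20 seeded analog grids for planted-layout recovery; a
210-compound binary matrix (> 1700 structurally MMP-free background pairs)
for cliff recovery; and 50 random profile sets for network oracle
equivalence. These sizes give exhaustive coverage of the combinatorial
logic while keeping a full run in the low minutes on one CPU; the
acceptance script uses a 5 × 7 analog grid (35 planted compounds) and a
200-compound binary matrix.

## Known limitations

* Hydrogen-replacement fragmentations are core-level only; compound-level
  MMPs require both exchanged substituents to contain at least one heavy
  atom. An H→F compound pair (benzene/fluorobenzene) is therefore not a
  compound-level MMP, which matches the strict single-cut definition.
* Aromaticity perception follows OpenBabel; exotic ring systems may
  canonicalize differently than in other toolkits, changing fragment
  strings (not the topology of results).
* The cliff threshold semantics assume profiling-scale target panels;
  with small panels the inclusive ≥ 50 default is unreachable and should be
  lowered explicitly.
* CSM component semantics mean one very promiscuous core chain can merge
  many series into a single sparse matrix; `extract_promiscuous_submatrix()`
  is the intended remedy.
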