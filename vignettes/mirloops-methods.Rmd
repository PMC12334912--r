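---
title: "Models and methods behind mirloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirloops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirloops)
```

`mirloops` couples a signed TF–miRNA network data model and motif search
with Hill-kinetics ODE analyses of the circuits those motifs form around
SOX10 and MITF. This vignette records the modelling choices, their
rationale, and what the package's tests do and do not establish.

## Network data model

A `reg_network` is a node tibble (`symbol`, `node_class` ∈ {TF, MIRNA,
PCG}, `origins`) plus an edge tibble (`source`, `target`, `sign` ∈ {+1,
−1}, `mechanism` ∈ {transcriptional, post_transcriptional},
`provenance`, `evidence`). Invariants enforced at construction: unique
symbols after normalization, endpoints present, no duplicate
`(source, target, mechanism)` triples, no self-loops by default, and
miRNA-source edges always post-transcriptional.

Choices worth flagging:

* **Symbol normalization.** Gene symbols are uppercased; miRNA names in
  any common style (`miR-155-5p`, `hsa-miR-155`, `MIR155`) collapse to a
  canonical `MIR155`. Mixed-style inputs therefore cannot split one
  regulator across two nodes. The arm suffix (`-5p`/`-3p`) is dropped;
  analyses at arm resolution would need a finer key.
* **miRNA edge signs.** Integrated miRNA-target records default to sign
  −1 (canonical seed-mediated repression). A per-record override is
  accepted with a warning, since non-canonical binding can activate.
* **Merging.** `merge_networks()` unions nodes and edges; a node's
  `origins` becomes the union of its existing origins and the labels of
  the networks containing it, which is what the origin-ring/hub
  summaries count. Class conflicts resolve by priority TF > MIRNA > PCG
  (logged), the least destructive rule for downstream motif filters.
* **Ego extraction is an induced subgraph.** The focal subnetwork keeps
  *all* edges among retained nodes, not only those touching the focal
  gene, because motif search needs the edges between the focal gene's
  neighbours (e.g. the miRNA→target arm of an FFL whose intermediate is
  the focal TF).
* **Dialects.** TSV is the native format. SIF bodies are the standard
  three columns (`source relation target`); node classes, origins and
  edge metadata travel in `#%`-prefixed comment lines that other SIF
  readers ignore, so a write→read cycle is lossless in every dialect.
  GraphML carries all attributes natively.

## Motif enumeration and classification

FFLs are ordered triples (regulator, intermediate, target) with all
three edges present; FBLs are directed simple cycles of length 2 or 3,
reported once in canonical rotation (lexicographically smallest member
first). If a pair is connected by parallel transcriptional and
post-transcriptional edges, each mechanism combination is a distinct
instance — the arms can differ in sign and certainly differ in dynamics.

Coherence follows the sign-product rule (direct sign equals the product
of the indirect signs); FBL polarity is the cycle sign product. Subtypes
1–4 use the standard coherent/incoherent type numbering keyed on
(sign(reg→int), sign(int→tgt)); only the coherent/incoherent and
positive/negative distinctions matter downstream, the subtype is
informational. Enumeration is validated two independent ways: an
exhaustive triple/pair loop oracle in the test suite, and a separate
adjacency-matrix census used internally by the planted-motif generator.
No enrichment null model (degree-preserving rewiring) is provided — the
package identifies motifs, it does not score over-representation.

## Circuit models

No equation set is canonical for these circuits, so all models are
standard production–degradation ODEs with Hill regulation,
`H⁺(x) = xⁿ/(kⁿ+xⁿ)`, `H⁻(x) = kⁿ/(kⁿ+xⁿ)`; concentrations and times
are in arbitrary units and all default rates are order one.

### Feedforward circuit (miR-155 → SOX10 → MITF)

Species: signal-driven `MIR155`, `SOX10` (repressed by miR-155),
`MITF_mRNA`, `MITF_protein`. Two logic modes:

* **threshold** — the promoter follows a literal truth table: AND
  transcribes iff `SOX10 > θ_S` and `MIR155 < θ_M`; OR iff either
  condition holds. This mode is the surface for the phase-pattern
  analyses (sign-sensitive delay, pulse rejection) because the claims
  are stated in threshold language. In this mode the miRNA's direct arm
  is carried by the gate; adding the continuous translational arm on
  top would shut MITF protein down instantly whenever the miRNA rises
  and erase the OR gate's onset delay.
* **continuous** — smooth composition (product for AND,
  probabilistic sum for OR), with `mirna_action` selecting translational
  repression (Hill factor on protein synthesis), enhanced mRNA
  degradation (`δ_R + λ·[miR]`), or both (default).

Default parameters make the miRNA arm fast (`δ_m = 3`) relative to SOX10
(`δ_S = 0.8`): the indirect arm is then the slow one, which is the
regime in which the AND gate acts as a persistence detector. Thresholds
(`θ_S = 0.8`, `θ_M = 0.5`) sit at roughly 60% and 50% of the respective
dynamic ranges.

**Delay metric.** The response delay of a species is the time from the
signal step until it crosses the midpoint between its pre- and
post-transition steady levels. Steady levels come from plateau windows
(final 10% of each signal interval) required to have a coefficient of
variation below 1%; near-zero plateaus are judged against 1% of the
species' dynamic range instead of the vanishing mean. The midpoint
convention is one of several defensible choices; differences (e.g.
10–90% rise time) shift absolute delays but not the AND/OFF vs OR/ON
asymmetry the analyses assert.

**Pulse rejection.** A pulse "elicits a response" when the MITF protein
excursion exceeds ε = 5% of the circuit's full dynamic range (steady
MITF under sustained baseline vs sustained pulse-level signal). ε is
arbitrary but fixed and configurable.

**Leak clearance.** The hypoxia analysis shuts transcription off and
induces the miRNA at the same instant, then compares mRNA decay with the
enhanced-degradation arm (`δ_R + λ·[miR]`) against the λ = 0 control;
with the miRNA held constant the decay is exactly exponential, giving
the closed-form half-life checks used in the tests.

### Feedback circuit (SOX10 → miR-204 ⊣ ATF2 ⊣ SOX10)

ATF2 is by default a *scanned input*: its effective activity is
`max(u + basal, 0) · H⁻([miR-204])`, SOX10 is repressed by that
activity, miR-204 is SOX10-activated, and MITF is a SOX10-driven
reporter outside the loop (the loop's sign product is
(+)(−)(−) = +1). A dynamic-ATF2 variant (first-order relaxation toward
the modulated input) exists for time-course replays. Bistability
requires cooperativity; both repressive arms default to Hill n = 2, and
the constructor warns when no arm has n ≥ 2.

The default parameterization (β_S = β_m = 2, all δ = 1, k_AS = k_Sm = 1,
k_mA = 0.5) was chosen once, by a coarse scan, to put a clearly bistable
window at positive ATF2 activity (folds near 2.6 and 5.4). `atf2_basal`
adds constant ATF2 activity and slides the window left; at basal = 3 the
left fold sits below zero activity, the configuration used for the
irreversible-switch analyses.

### Numerics

* Integration: `deSolve::lsoda`, rtol 1e−8 / atol 1e−10, restarted at
  every signal breakpoint so piecewise-constant inputs are handled
  exactly. Threshold-mode right-hand sides are discontinuous in state;
  lsoda's step control handles the crossings at these tolerances, and
  the solver-contract test (halving tolerances moves steady levels by
  < 1e−6 relative) is run in continuous mode where the contract is
  meaningful.
* Steady states: multi-start root finding (`pracma::fsolve`) over the
  plausible state box, seeded additionally by the roots of the model's
  one-dimensional steady-state reduction where one exists (the FBL) and
  by neighbouring grid points during scans (continuation); duplicates
  merge at 1e−6 relative; stability is the sign of the largest real
  eigenvalue part of a central-difference Jacobian. Univariate models
  use an exhaustive sign-change scan instead.
* Folds: bisection on the fixed-point count to 1e−4 of the grid span.
  The scan refines locally when a neighbour pair hides more than one
  transition and errors if refinement does not resolve it.
  Reversibility is *irreversible* iff the left fold lies outside the
  admissible input range (including the case where bistability persists
  to the scan's lower boundary at the edge of that range).
* Hysteresis: quasi-static stepping with the state carried over;
  dwell 40 time units per step (relaxation times are ~1), extended up
  to 4× when the plateau check fails. Up/down thresholds are midpoint
  crossings between the ON and OFF branch levels.

## Phenotype maps

MITF level maps onto ordered phenotype zones with gray transition bands
(half-width `gray_width`) around each boundary. Two stock maps: the
four-zone rheostat reading (senescence, invasion, proliferation,
differentiation; default boundaries 0.25/0.5/0.75 on a 0–1 MITF scale)
and a three-state map (mesenchymal, intermediate, melanocytic) scaled to
a circuit's MITF range for toggle-switch readouts. All boundary values
are user configuration — no quantitative boundary is established
anywhere — so zone calls are qualitative labels, not measurements.

## Synthetic data: what it emulates, what it does not

The generators emulate the *structural* features the pipeline needs:
typed nodes with multi-origin provenance, repressive post-transcriptional
miRNA edges, regulator/target asymmetry (PCGs are sinks), miRTarBase-like
target tables with a small evidence vocabulary, and plantable motifs
with exact ground truth (collision-freedom verified by the independent
brute-force census, with rejection sampling capped at 1000 redraws).
They do not emulate realistic degree distributions (no scale-free
fitting), expression data, or noisy/incomplete annotation. Passing
recovery tests therefore demonstrates correctness of the algorithms on
networks whose ground truth is known — not robustness to the biases of
real interaction databases.

## Problem sizes and determinism

The shipped tests run the motif oracle on 50 random networks of up to 50
nodes, the delay/pulse sweep on 20 parameter draws (rates jittered ±20%
around defaults), bifurcation scans on 61-point grids with hysteresis
sweeps at 0.25 steps, and round trips on 20 randomized networks — sizes
at which every check is exact or tightly toleranced while the whole
suite stays fast. Every stochastic step takes an explicit seed, and
workflow runs echo their configuration and seed into a manifest, so all
outputs are bit-for-bit reproducible.

## Known limitations

* No stochastic (Gillespie-type) simulation; all claims are about the
  deterministic mean field.
* No parameter fitting to experimental data; parameters are qualitative
  and order-one by design.
* Coupled FFL+FBL systems (which can produce tristability) are out of
  scope; the two circuits are analysed separately.
* Motif search stops at 3 nodes and does not test enrichment.
* The AND/OR threshold gates are idealizations; real promoters
  interpolate between them.
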