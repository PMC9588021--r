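---
title: "Sequence-controlled generation of lignin structures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-controlled generation of lignin structures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligninsmith)
```

## The modeling problem

Lignin has no template-encoded primary structure: monolignols
(p-coumaryl = H, coniferyl = G, sinapyl = S alcohol) couple radically and
near-combinatorially during lignification, so any experimental
characterization (NMR linkage frequencies, wet-chemistry functional-group
counts, Mw) describes a *population* of molecules, not one structure.
`ligninsmith` inverts that description: given an S/G ratio, target inter-unit
bond frequencies and a degree of polymerization (DP), it samples explicit,
chemically valid 2D macromolecular structures whose population statistics
match the experimental ranges for milled wood lignin (MWL).

The generative model makes three structural assumptions:

1. **Random sequence.** Monomer order carries no information beyond the
   composition; all unique orderings of the composition multiset are
   equally likely. The composition is the integer split of the DP closest to
   the requested S/G ratio (ties toward S, since hardwoods have S >= G).
2. **Endwise growth under coupling rules.** Linear chains grow one unit at a
   time. The first junction of a fragment is a monomer-monomer coupling
   (beta-O-4, beta-beta or beta-5); later junctions are oligomer-monomer
   couplings, where resinol is no longer possible (both beta positions are
   needed, and the chain end has only one). Couplings onto an S acceptor
   exclude every 5-position linkage - the 5-methoxy blocks the site. After a
   resinol junction the chain end's beta carbon is consumed, so growth
   continues with reversed polarity (each new unit donates its beta into the
   free 4-O or C5 of the previous one). This reversal is the only chemically
   consistent continuation and is applied deterministically.
3. **Oligomer coupling for condensed linkages.** 5-5 (biphenyl), 4-O-5
   (diaryl ether) and dibenzodioxocin (DBDO) couplings join fragments of the
   chain through ring sites. A coupling onto a fragment *end* preserves a
   path (the macromolecule stays linear); a coupling onto an *interior*
   unit creates a degree-3 branch point. We classify a structure as branched
   iff it has a degree-3 unit. This is a deliberate reading: experimental
   reports count a median of 1-2 diaryl ethers per hardwood DP-18 structure
   while putting hardwood branching at only 15-30%, which is only consistent
   if end-to-end condensed couplings do not count as branching.

DBDO deserves a note: it is represented as a motif annotation on the monomer
tree - a 5-5 edge between the biphenyl pair plus the existing beta-O-4 edge
of the bridging unit - and the alpha-O-4 ring closure is applied only at
molecule build time. The monomer graph therefore always remains a tree with
exactly DP - 1 edges, which keeps the adjacency/connectivity matrix encoding
well-formed, while the built molecule still contains the 8-membered dioxocin
ring.

## From target frequencies to junction weights

Per-junction linkage types are sampled proportionally to weights restricted
to the allowed couplings of the junction (`assign_linkages()`). Raw target
frequencies cannot be used directly as weights: resinol only competes at
fragment-start junctions and S acceptors force beta-O-4, so raw weights
systematically overproduce beta-O-4. `calibrate_weights()` therefore solves -
by a damped, deterministic fixed-point iteration on an expected-count model
of the junction process - for the sampling weights whose *expected realized*
linkage fractions equal the configured targets at each DP and composition.
Configurations express intent (target fractions); calibration is mechanism.

Target bond frequencies are DP-dependent: the beta-O-4 share of all linkages
rises with chain length (short oligomers are relatively rich in the
condensed dimeric linkages), so each preset interpolates linearly between a
DP-3 anchor and a reference-DP anchor:

| preset | anchor | beta-O-4 | beta-beta | beta-5 | 4-O-5 | 5-5 | DBDO |
|--------|--------|----------|-----------|--------|-------|-----|------|
| spruce (G-type) | DP 3 | 0.50 | 0.20 | 0.25 | 0.03 | 0.01 | 0.01 |
| spruce (G-type) | DP 20 | 0.66 | 0.09 | 0.15 | 0.05 | 0.025 | 0.025 |
| birch (SG-type, S/G 1.8) | DP 3 | 0.50 | 0.28 | 0.12 | 0.08 | 0.01 | 0.01 |
| birch (SG-type, S/G 1.8) | DP 18 | 0.65 | 0.14 | 0.10 | 0.09 | 0.012 | 0.008 |

The reference-DP anchors were fixed once, analytically, from the published
experimental per-structure composition tables for spruce (DP 20) and birch
(DP 18) MWL (shipped in `inst/extdata/reference_compositions.csv`); the DP-3
anchors are the package's own choice of a realistic short-oligomer
composition. The number of oligomer cross-couplings per structure is a
stochastic rounding of the summed condensed-linkage targets times DP - 1.

Branching probability follows a monotone piecewise-logistic schedule in DP
(`branch_probability()`): zero through DP 4 (linear chains dominate short
oligomers), then a logistic rise (midpoint DP 7, unit scale) to a plateau of
0.80 for G-type and 0.22 for SG-type lignin. The plateaus encode the
experimental picture - every guaiacyl ring offers a free C5, so softwood
branching rises steeply past DP ~10 toward ~85%, while the syringyl
5-methoxy caps hardwood branching in the 15-30% band. Realized branching
runs slightly below the schedule when no feasible interior coupling site
exists and the event falls back to an end coupling.

## Atom-level chemistry and mass balance

`build_molecule()` expands the monomer tree into an explicit atom/bond table
(Kekulé aromatic rings, implicit hydrogens by valence completion). Side
chains follow the unit state: cinnamyl ends keep the unsaturated propenol
chain; ordinary beta-O-4 donors hydrate at the alpha carbon (arylglycerol,
secondary alpha-OH); resinol pairs close the pinoresinol furofuran
(consuming both gamma oxygens); beta-5 donors close the phenylcoumaran
alpha-O-4 ring; the DBDO bridge closes beta-O-4 and alpha-O-4 onto the
biphenyl pair without water. Stereochemistry is not assigned - the modeled
2D constitution carries no stereo descriptors.

The elemental formula and average molecular mass (C 12.011, H 1.008,
O 15.999 g/mol - average, not monoisotopic, masses, matching
polymer-chemistry Mw) are computed from the atom table. An independent route,
`linkage_mass_balance()`, predicts the mass from counting alone: every
radical coupling costs two hydrogens, and every hydrated beta-O-4
additionally gains a water (net +O). The two routes must agree within
0.1 g/mol on every structure; the test suite enforces this.

SMILES strings are emitted by the package's own depth-first Kekulé writer
and canonicalized with OpenBabel (via ChemmineOB), which also provides MOL
V2000 output with seeded distance-geometry 3D embedding (2D fallback with a
warning). Structure uniqueness during generation uses `structure_key()`, a
canonical encoding of the labeled monomer tree (rooted-code minimization
over all roots; the symmetric 5-5 and beta-beta linkages are treated as
undirected, the DBDO-internal beta-O-4 is coded distinctly). The key is
equivalent to canonical-SMILES equality but orders of magnitude faster; the
test suite verifies the equivalence empirically against both OpenBabel
canonical SMILES and VF2 atom-graph isomorphism on DP-6 batches, and large
statistical runs set `canonicalize = FALSE` to use it.

## Numerical and degenerate-input choices

* Sequence enumeration is exhaustive (lexicographic, G < H < S, by
  next-permutation over the multiset) when the multinomial count fits the
  cap, otherwise a seeded rejection sample of distinct sequences; a balanced
  DP-25 composition has ~1e10 unique orderings, so permute-then-filter is
  not an option at scale.
* A junction whose allowed coupling set has no positively weighted linkage
  raises an infeasible-sequence error (only possible for degenerate weight
  configurations, since beta-O-4 is always allowed).
* Infeasible cross-coupling draws (e.g. all-S partners) retry with new split
  points and reshuffled sequences (default 25 attempts), then fall back to a
  single linear chain; the fallback is tallied in the run summary.
* One RNG stream per DP level is derived from the master seed, so per-DP
  output is independent of the order of `dp_values`; catalogs contain no
  timestamps and are byte-identical across reruns of one seed.
* Integer cross-link counts use stochastic rounding so that non-integer
  expected counts are honored in distribution.

## What the generator does and does not emulate

The generator reproduces population-level structural composition: linkage
fractions and their DP trend, branching fractions by wood type,
functional-group counts, Mw as a deterministic function of composition. It
does **not** model reaction kinetics or time (no rate constants - couplings
are drawn from calibrated static distributions), lignin-carbohydrate
cross-links, the spirodienone (beta-1) linkage, acylated or noncanonical
monomers, stereochemistry, or conformational (3D) quality beyond a
best-effort embedding for visualization. Passing tests therefore show
consistency with experimental *composition ranges*, not that any generated
molecule exists in a real cell wall.

Two reference features are known to sit outside the experimental intervals
under this model's bookkeeping and are reported honestly by
`compare_to_reference()`: secondary aliphatic OH (experimental tables report
more alpha-OH than the count of beta-O-4 donors, suggesting a different
accounting of side-chain states) and, for softwood, cinnamyl ends (each
chain fragment keeps one unreacted growth end, so multi-fragment structures
carry more cinnamyl ends than the experimental 0-1). The overall match
fraction over the 11 tabulated features is the package's operational
definition of agreement with the experimental record; no single metric for
"accuracy" is imposed.

## Problem sizes

The shipped test suite and the reproduction script use 500 structures per
statistical condition (22 per DP for pooled DP 3-25 batches, 500 at a single
reference DP), 10,000 structures for the rule-compliance sweep, and 120
structures for the DP-6 isomorphism cross-check; these sizes put the Monte
Carlo error of each checked statistic well inside the checked interval while
keeping a full run in the minutes range on one CPU. Pure-G runs at DP <= 5
cannot fill a 22-structure quota (the number of distinct molecules is
smaller); the shortfall is expected and logged.
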