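# ligninsmith

Sequence-controlled generation of lignin macromolecule structures in R.

Lignin — the second most abundant biopolymer after cellulose — has no
template-defined primary structure: its monolignols (p-coumaryl **H**,
coniferyl **G**, sinapyl **S** alcohol) couple radically and
near-combinatorially during lignification. Experiments (NMR, thioacidolysis)
yield only population statistics: linkage frequencies, functional-group
counts, Mw. Researchers who need *explicit* molecules — for force-field
simulation, depolymerization modeling, or machine learning on lignin
chemical space — therefore need a generator that turns those statistics into
chemically valid structures.

`ligninsmith` is that generator. From an S/G ratio, target bond frequencies
over the six major inter-unit linkages (β-O-4 aryl ether, β-β resinol, β-5
phenylcoumaran, 5-5 biphenyl, 4-O-5 diaryl ether, and the 8-membered
dibenzodioxocin ring, DBDO), and a degree of polymerization DP ∈ [3, 25], it:

1. splits DP into monomer counts closest to the S/G ratio and enumerates (or
   samples) the `dp!/∏(countₗ!)` unique monomer orderings;
2. assigns one linkage per junction, sampled ∝ calibrated weights restricted
   to literature coupling rules (e.g. an S unit's methoxylated 5-position
   never bonds; resinol requires two free β positions and so occurs only
   between a monomer pair); condensed 5-5/4-O-5/DBDO couplings join chain
   fragments, on interior units creating true branch points;
3. encodes each structure as a directed monomer tree and paired
   adjacency/connectivity matrices (CSV);
4. expands it to an atom-level molecule — arylglycerol β-O-4 units with
   α-OH, pinoresinol, phenylcoumaran and dioxocin ring closures — and emits
   canonical SMILES (OpenBabel) and MOL V2000 files with 3D coordinates;
5. accepts only structures with valid, unique SMILES and the requested node
   count, and reports per-structure linkage/functional-group compositions
   against experimental spruce (DP 20) and birch (DP 18) milled-wood-lignin
   ranges.

Every structure obeys the mass balance
`Mw = Σ monomer masses + 15.999·(hydrated β-O-4) − 2.016·(other couplings)`,
checked against an independent atom-count formula on every build.

## Worked example

```r
library(ligninsmith)

composition_from_ratio(1.8, 5)
#> <monomer composition> DP 5: {G:2, S:3}; 10 unique sequences

sapply(enumerate_unique_sequences(composition_from_ratio(1.8, 5)), paste, collapse = "")
#> "GGSSS" "GSGSS" "GSSGS" "GSSSG" "SGGSS" "SGSGS" "SGSSG" "SSGGS" "SSGSG" "SSSGG"

cfg <- preset_config("birch", dp_values = 6L, structures_per_dp = 3L,
                     seed = 42L, formats = character(0), verbose = FALSE)
ds <- generate_dataset(cfg)
ds
#> <lignin dataset> SG-type, 3 structure(s) over 1 DP level(s)
#>  dp requested accepted duplicate dp_mismatch invalid fallback_linear proposals
#>   6         3        3         0           0       0               0         3

ds$catalog[["6"]][[1]][c("sequence", "formula", "mw")]
#> $sequence  "SSGGSS"
#> $formula   "C64H74O24"
#> $mw        1227.27

ds$reports[, c("dp", "mw", "bond_beta_O_4", "bond_beta_beta", "bond_beta_5",
               "oh_phenolic_free", "branched")]
#>   dp       mw bond_beta_O_4 bond_beta_beta bond_beta_5 oh_phenolic_free branched
#> 1  6 1227.272             2              1           2                2    FALSE
#> 2  6 1245.287             3              1           1                2    FALSE
#> 3  6 1227.272             2              1           1                2    FALSE
```

The first DP-6 birch structure is the hexamer SSGGSS (S/G = 2, the closest
integer split to 1.8), C₆₄H₇₄O₂₄, Mw 1227.3 g/mol, with two β-aryl ethers,
one resinol and two phenylcoumarans among its five linkages and two free
phenolic hydroxyls. The 18 g/mol spread between rows is one water: structure
2 has one more hydrated β-O-4.

Presets: `preset_config("spruce")` (softwood, pure G) and
`preset_config("birch")` (hardwood, S/G = 1.8), both with DP-dependent
bond-frequency targets anchored to experimental composition tables; any
field is overridable in code or via a YAML file (`load_config()`), and
`inst/cli/ligninsmith.R` exposes `generate` / `analyze` / `validate` verbs
for shell use. See the vignette
(`vignettes/lignin-structure-generation.Rmd`) for the model, its
calibration, and its limitations.

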