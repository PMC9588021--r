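# known canonical reference: coniferyl alcohol drawn independently
CONIFERYL_REF <- "COc1cc(/C=C/CO)ccc1O"

test_that("a single G node builds into coniferyl alcohol", {
  g <- lignin_graph("G", data.frame(donor = integer(0), acceptor = integer(0),
                                    type = character(0)))
  mol <- build_molecule(g)
  expect_equal(mol$formula_string, "C10H12O3")
  expect_equal(mol$mw, oracle_formula_mass(10, 12, 3), tolerance = 1e-6)
  # canonical form agrees with an independently written coniferyl SMILES
  # (stereo is not modeled, so canonicalize the reference without it)
  ref <- canonical_smiles(gsub("/", "", CONIFERYL_REF, fixed = TRUE))
  expect_identical(mol$smiles, ref)
})

test_that("dimer formulas and masses follow the coupling mass balance", {
  w1 <- c("beta-O-4" = 1)
  bo4 <- build_molecule(grow_linear(c("G", "G"), assign_linkages(c("G", "G"), w1)),
                        canonicalize = FALSE)
  expect_equal(bo4$formula_string, "C20H24O7")
  expect_lt(abs(bo4$mw - 376.4), 0.1)      # guaiacylglycerol-beta-coniferyl ether
  set.seed(2)
  bb <- build_molecule(grow_linear(c("G", "G"),
                                   assign_linkages(c("G", "G"), c("beta-beta" = 1))),
                       canonicalize = FALSE)
  expect_equal(bb$formula_string, "C20H22O6")
  expect_lt(abs(bb$mw - 358.4), 0.1)       # pinoresinol
  b5 <- build_molecule(grow_linear(c("G", "G"),
                                   assign_linkages(c("G", "G"), c("beta-5" = 1))),
                       canonicalize = FALSE)
  expect_equal(b5$formula_string, "C20H22O6")  # dehydrodiconiferyl skeleton
})

test_that("canonicalization is invariant to node relabeling and separates isomers", {
  w <- c("beta-O-4" = 1)
  # same constitution entered with reversed indices
  gA <- lignin_graph(c("G", "S"), data.frame(donor = 1L, acceptor = 2L, type = "beta-O-4"))
  gB <- lignin_graph(c("S", "G"), data.frame(donor = 2L, acceptor = 1L, type = "beta-O-4"))
  expect_identical(canonical_smiles(build_molecule(gA, canonicalize = FALSE)),
                   canonical_smiles(build_molecule(gB, canonicalize = FALSE)))
  expect_identical(structure_key(gA), structure_key(gB))
  # different constitution -> different strings and keys
  set.seed(3)
  bb <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), c("beta-beta" = 1)))
  bo4 <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), w))
  expect_false(identical(canonical_smiles(build_molecule(bb, canonicalize = FALSE)),
                         canonical_smiles(build_molecule(bo4, canonicalize = FALSE))))
  expect_false(identical(structure_key(bb), structure_key(bo4)))
  # 5-5 and beta-beta are symmetric: direction does not change the key
  g55a <- lignin_graph(c("G", "G", "G", "G"),
    data.frame(donor = c(1, 3, 2), acceptor = c(2, 4, 3),
               type = c("beta-O-4", "beta-O-4", "5-5")))
  g55b <- lignin_graph(c("G", "G", "G", "G"),
    data.frame(donor = c(1, 3, 3), acceptor = c(2, 4, 2),
               type = c("beta-O-4", "beta-O-4", "5-5")))
  expect_identical(structure_key(g55a), structure_key(g55b))
})

test_that("validate_structure applies uniqueness and DP-match acceptance criteria", {
  g <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), c("beta-O-4" = 1)))
  mol <- build_molecule(g)
  seen <- seen_smiles()
  v1 <- validate_structure(mol, 2, seen)
  expect_true(v1$accepted)
  v2 <- validate_structure(mol, 2, seen)
  expect_false(v2$accepted); expect_equal(v2$reason, "duplicate")
  v3 <- validate_structure(mol, 3, seen_smiles())
  expect_false(v3$accepted); expect_equal(v3$reason, "dp-mismatch")
  bad <- mol; bad$smiles <- NA_character_
  expect_equal(validate_structure(bad, 2, seen_smiles())$reason, "invalid-smiles")
})

test_that("MOL output is self-consistent and round-trips through OpenBabel", {
  g <- lignin_graph("G", data.frame(donor = integer(0), acceptor = integer(0),
                                    type = character(0)))
  mol <- build_molecule(g)
  mol$lg_id <- "mono01"
  f <- withr::local_tempfile(fileext = ".mol")
  write_mol(mol, f, dims = 3)
  lines <- readLines(f)
  expect_equal(lines[1], "mono01")
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  expect_equal(sum(elements != "H"), 13)  # heavy atoms of C10H12O3
  # atom block size matches the counts line
  expect_equal(sum(grepl("^\\s*-?\\d+\\.\\d{4}", lines)), n_atoms)
  expect_identical(read_mol_smiles(f), mol$smiles)
  # 3D coordinates present (some nonzero z)
  z <- as.numeric(substr(lines[5:(4 + n_atoms)], 21, 30))
  expect_true(any(abs(z) > 1e-6))
})

test_that("mass balance identity holds on every generated structure", {
  set.seed(31)
  for (i in 1:60) {
    dp <- sample(3:20, 1)
    g <- random_graph(dp, if (i %% 2) "spruce" else "birch")
    mol <- build_molecule(g, canonicalize = FALSE)
    expect_lt(abs(mol$mw - linkage_mass_balance(g)), 0.1)
    # benzene ring count equals DP (cycle rank accounting)
    cycle_rank <- nrow(mol$bonds) - length(mol$atoms) + 1
    expect_equal(cycle_rank, expected_ring_count(g))
    expect_gte(expected_ring_count(g), dp)
  }
})
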