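test_that("linkage metadata distinguishes linear and branching motifs", {
  lt <- linkage_types()
  expect_setequal(lt$name[lt$motif == "linear"], c("beta-O-4", "beta-beta", "beta-5"))
  expect_setequal(lt$name[lt$motif == "branched"], c("4-O-5", "5-5", "dbdo"))
  expect_equal(lt$category[lt$name == "beta-O-4"], "C-O")
  expect_equal(lt$category[lt$name == "4-O-5"], "C-O")
  expect_equal(lt$category[lt$name == "5-5"], "C-C")
  expect_true(all(lt$category[lt$name %in% c("beta-beta", "beta-5", "dbdo")] == "mixed"))
})

test_that("all twelve coupling-rule rows are transcribed verbatim", {
  # dimer rows
  expect_setequal(allowed_couplings("dimer", "G", "G"), c("beta-O-4", "beta-beta", "beta-5"))
  expect_setequal(allowed_couplings("dimer", "S", "S"), c("beta-O-4", "beta-beta"))
  expect_setequal(allowed_couplings("dimer", "S", "G"), c("beta-O-4", "beta-beta", "beta-5"))
  expect_setequal(allowed_couplings("dimer", "G", "S"), c("beta-O-4", "beta-beta"))
  # oligomer-monomer rows (no resinol available)
  expect_setequal(allowed_couplings("oligomer-monomer", "G", "G"), c("beta-O-4", "beta-5"))
  expect_setequal(allowed_couplings("oligomer-monomer", "S", "S"), "beta-O-4")
  expect_setequal(allowed_couplings("oligomer-monomer", "S", "G"), c("beta-O-4", "beta-5"))
  expect_setequal(allowed_couplings("oligomer-monomer", "G", "S"), "beta-O-4")
  # oligomer cross-coupling rows (DBDO rides with 5-5)
  expect_setequal(allowed_couplings("oligomer-oligomer", "G", "G"), c("4-O-5", "5-5", "dbdo"))
  expect_length(allowed_couplings("oligomer-oligomer", "S", "S"), 0)
  expect_length(allowed_couplings("oligomer-oligomer", "G", "S"), 0)
  expect_setequal(allowed_couplings("oligomer-oligomer", "S", "G"), "4-O-5")
  # and the exported table matches
  tab <- coupling_rule_table()
  expect_equal(sum(tab$context == "dimer" & tab$allowed), 10)  # 4x beta-O-4/beta-beta + 2x beta-5
  expect_false(tab$allowed[tab$context == "dimer" & tab$donor == "S" &
                             tab$acceptor == "S" & tab$linkage == "beta-5"])
})

test_that("junction assignment respects allowed couplings and weights", {
  set.seed(101)
  # S -> S junction never receives beta-5, at any weights
  w <- c("beta-O-4" = 0.1, "beta-beta" = 0.1, "beta-5" = 10)
  for (i in 1:200) {
    a <- assign_linkages(c("S", "S", "S"), w)
    expect_false(any(a$type == "beta-5"))
  }
  # degenerate weights give all beta-O-4
  a <- assign_linkages(rep("G", 6), c("beta-O-4" = 1))
  expect_true(all(a$type == "beta-O-4"))
  expect_equal(nrow(a), 5)
  # infeasible junction errors (beta-5 cannot land on the S acceptor and no
  # other linkage has weight)
  expect_error(assign_linkages(c("G", "S"), c("beta-5" = 1)), "infeasible")
})

test_that("empirical dimer-junction fractions follow the weights (law of large numbers)", {
  set.seed(202)
  w <- c("beta-O-4" = 0.75, "beta-beta" = 0.10, "beta-5" = 0.15)
  draws <- vapply(1:10000, function(i)
    assign_linkages(c("G", "G"), w)$type, character(1))
  frac <- table(factor(draws, levels = names(w))) / 10000
  expect_true(all(abs(as.numeric(frac) - w) < 0.02))
})

test_that("growth direction reverses after a resinol junction", {
  set.seed(7)
  w <- c("beta-beta" = 1e9, "beta-O-4" = 1)  # junction 1 is beta-beta a.s.
  a <- assign_linkages(c("G", "G", "G", "G"), w)
  expect_equal(a$type[1], "beta-beta")
  # subsequent junctions flip: the new unit donates into the previous one
  expect_equal(a$donor[2], 3); expect_equal(a$acceptor[2], 2)
  expect_equal(a$donor[3], 4); expect_equal(a$acceptor[3], 3)
  expect_false(any(a$type[-1] == "beta-beta"))
})

test_that("calibrated weights reproduce target linkage fractions in expectation", {
  cfg <- preset_config("spruce")
  targets <- bond_freqs_at(cfg, 20)
  comp <- composition_from_ratio(0, 20)
  w <- calibrate_weights(targets, 20, comp)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # simulate junction draws through the real assignment path and compare
  set.seed(33)
  reps <- lapply(1:400, function(i) {
    ds <- generate_graph(rep("G", 20), w, targets, branched = FALSE)
    analyze(ds)
  })
  r <- do.call(rbind, reps)
  realized <- mean(r$bond_beta_O_4) / 19
  expect_lt(abs(realized - targets[["beta-O-4"]]), 0.04)
})
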