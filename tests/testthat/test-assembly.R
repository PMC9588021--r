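test_that("linear growth sets side-chain and phenolic states per linkage chemistry", {
  # beta-O-4 dimer: donor keeps the free phenol, acceptor is etherified
  g <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), c("beta-O-4" = 1)))
  st <- graph_sites(g)
  expect_equal(nrow(g$edges), 1)
  expect_equal(st$phenolic_free, c(TRUE, FALSE))
  expect_equal(st$side_state, c("arylglycerol", "cinnamyl"))
  # beta-beta dimer: both resinol, both phenols free
  set.seed(1)
  g2 <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), c("beta-beta" = 1)))
  st2 <- graph_sites(g2)
  expect_equal(st2$side_state, c("resinol", "resinol"))
  expect_true(all(st2$phenolic_free))
  # S-S-S all beta-O-4: exactly one free phenolic OH, at the acceptor-free end
  g3 <- grow_linear(c("S", "S", "S"), assign_linkages(c("S", "S", "S"), c("beta-O-4" = 1)))
  st3 <- graph_sites(g3)
  expect_equal(sum(st3$phenolic_free), 1)
  expect_equal(sum(st3$side_state == "cinnamyl"), 1)
})

test_that("state bookkeeping rejects double site use", {
  expect_error(lignin_graph(c("G", "G", "G"),
    data.frame(donor = c(1, 1), acceptor = c(2, 3),
               type = c("beta-O-4", "beta-O-4"))),
    "beta position donates more than one")
  expect_error(lignin_graph(c("G", "G", "G"),
    data.frame(donor = c(1, 3), acceptor = c(2, 2),
               type = c("beta-O-4", "beta-O-4"))),
    "accepts more than one")
})

test_that("oligomer coupling: all-S fragments are infeasible, G fragments couple", {
  w <- c("beta-O-4" = 1)
  s1 <- grow_linear(c("S", "S"), assign_linkages(c("S", "S"), w))
  s2 <- grow_linear(c("S", "S"), assign_linkages(c("S", "S"), w))
  for (ty in c("5-5", "4-O-5", "dbdo"))
    expect_error(branch_couple(s1, s2, ty), "branch-infeasible")
  g1 <- grow_linear(c("G", "G", "G"), assign_linkages(c("G", "G", "G"), w))
  g2 <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), w))
  set.seed(5)
  m <- branch_couple(g1, g2, "5-5")
  expect_length(m$labels, 5)
  expect_equal(nrow(m$edges), 4)           # additive + 1, still a tree
  expect_equal(sum(m$edges$type == "5-5"), 1)
})

test_that("DBDO coupling registers a three-unit motif that builds one extra ring", {
  w <- c("beta-O-4" = 1)
  g1 <- grow_linear(c("G", "G", "G"), assign_linkages(c("G", "G", "G"), w))
  g2 <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), w))
  set.seed(6)
  m <- branch_couple(g1, g2, "dbdo")
  expect_length(m$dbdo, 1)
  motif <- m$dbdo[[1]]
  expect_length(unique(c(motif$x, motif$a, motif$b)), 3)
  # the bridging beta-O-4 exists and the biphenyl pair is the dbdo edge
  expect_true(any(m$edges$donor == motif$x & m$edges$acceptor == motif$a &
                    m$edges$type == "beta-O-4"))
  expect_equal(sum(m$edges$type == "dbdo"), 1)
  # the molecule gains exactly one ring beyond the benzene rings + none else
  mol <- build_molecule(m, canonicalize = FALSE)
  cycle_rank <- nrow(mol$bonds) - length(mol$atoms) + 1
  expect_equal(cycle_rank, expected_ring_count(m))
  expect_equal(expected_ring_count(m), 5 + 1)
  # both biphenyl phenols are etherified into the dioxocin ring
  st <- graph_sites(m)
  expect_false(st$phenolic_free[motif$a])
  expect_false(st$phenolic_free[motif$b])
})

test_that("topology plans are linear up to DP 4 and follow the wood-type schedule", {
  set.seed(9)
  expect_false(any(vapply(1:100, function(i) plan_topology(3, "G-type")$branched, logical(1))))
  expect_false(any(vapply(1:100, function(i) plan_topology(4, "SG-type")$branched, logical(1))))
  expect_equal(plan_topology(3, "G-type")$p_branch, 0)
  # schedule is monotone and respects the plateaus
  p_g <- branch_probability(3:25, "G-type")
  p_sg <- branch_probability(3:25, "SG-type")
  expect_true(all(diff(p_g) >= 0))
  expect_lte(max(p_g), 0.80 + 1e-9)
  expect_true(all(p_sg[(11:25) - 2] <= 0.30 & p_sg[(11:25) - 2] >= 0.15))
})

test_that("generated graphs are trees with single-use sites and no S-unit C5 bonds", {
  set.seed(12)
  for (i in 1:150) {
    dp <- sample(3:25, 1)
    preset <- if (i %% 2) "spruce" else "birch"
    g <- random_graph(dp, preset)  # validate_graph runs inside construction
    expect_length(g$labels, dp)
    expect_equal(nrow(g$edges), dp - 1)
    st <- graph_sites(g)
    s_units <- g$labels == "S"
    expect_true(all(st$c5_used[s_units] == 0))
    expect_true(all(st$beta_used <= 1), all(st$o4_used <= 1), all(st$c5_used <= 1))
  }
})
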