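# Independent oracles used across the suite. These deliberately do not share
# code paths with the package implementation.

# standard average atomic masses, written down independently of the package
ORACLE_MASS <- c(C = 12.011, H = 1.008, O = 15.999)

oracle_formula_mass <- function(c_n, h_n, o_n) {
  c_n * ORACLE_MASS[["C"]] + h_n * ORACLE_MASS[["H"]] + o_n * ORACLE_MASS[["O"]]
}

# exhaustive unique-sequence oracle: every string over {G,H,S} of length dp
# whose letter counts match the composition. This is brute-force enumeration
# with built-in deduplication.
oracle_unique_sequences <- function(counts, dp) {
  grid <- do.call(expand.grid, c(rep(list(c("G", "H", "S")), dp),
                                 stringsAsFactors = FALSE))
  strings <- do.call(paste0, grid)
  keep <- vapply(strings, function(s) {
    v <- strsplit(s, "")[[1]]
    sum(v == "G") == counts[["G"]] && sum(v == "H") == counts[["H"]] &&
      sum(v == "S") == counts[["S"]]
  }, logical(1))
  sort(strings[keep])
}

# recursive generation of all permutations (index level), then dedup -
# the permute-then-filter route, independent of the package's
# next-permutation enumeration
oracle_permute_dedup <- function(labels) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  sort(unique(vapply(perms(labels), paste, character(1), collapse = "")))
}

# shared small-batch generator for statistical and property tests
gen_batch <- function(preset, dp_values, n_per_dp, seed,
                      keep_structures = FALSE, canonicalize = FALSE, ...) {
  cfg <- preset_config(preset, dp_values = dp_values,
                       structures_per_dp = n_per_dp, seed = seed,
                       formats = character(0), verbose = FALSE,
                       keep_structures = keep_structures,
                       canonicalize = canonicalize, ...)
  generate_dataset(cfg)
}

# a random structure graph drawn from a preset's generative model
random_graph <- function(dp, preset = "spruce") {
  cfg <- preset_config(preset)
  comp <- composition_from_ratio(if (preset == "spruce") 0 else cfg$sg_ratio, dp)
  sq <- sample(rep(names(comp$counts), comp$counts))
  targets <- bond_freqs_at(cfg, dp)
  w <- calibrate_weights(targets, dp, comp)
  wood <- if (preset == "spruce") "G-type" else "SG-type"
  branched <- plan_topology(dp, wood, cfg$branch_schedule)$branched
  generate_graph(sq, w, targets, branched)
}

# igraph oracle: atom-level molecular graph isomorphism (VF2 with element
# vertex colors and bond-order edge colors)
mol_isomorphic <- function(m1, m2) {
  to_ig <- function(m) {
    igraph::graph_from_edgelist(m$bonds[, c("a", "b"), drop = FALSE],
                                directed = FALSE)
  }
  el_code <- function(m) match(m$atoms, c("C", "O"))
  if (length(m1$atoms) != length(m2$atoms)) return(FALSE)
  igraph::isomorphic(to_ig(m1), to_ig(m2), method = "vf2",
                     vertex.color1 = el_code(m1), vertex.color2 = el_code(m2),
                     edge.color1 = m1$bonds[, "order"],
                     edge.color2 = m2$bonds[, "order"])
}
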