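#' @title Dataset generation pipeline
#' @name dataset
#' @description
#' End-to-end orchestration: a generation configuration (wood-type preset or
#' custom YAML) fixes the monomer ratio, DP-dependent bond-frequency targets,
#' branching schedule, DP levels, per-DP structure quota and master seed.
#' For each DP the pipeline enumerates/samples monomer sequences, calibrates
#' junction weights, assembles graphs, builds molecules, applies the
#' acceptance criteria (valid + unique canonical SMILES, node count equal to
#' the requested DP) and writes the accepted structures as MOL files, matrix
#' CSV files and a JSON catalog keyed by DP and `lg_id`.
NULL

.BOND_FREQ_DEFAULTS <- list(
  spruce = list(
    wood_type = "G-type", sg_ratio = 0, h_fraction = 0,
    bond_freqs = c("beta-O-4" = 0.66, "beta-beta" = 0.09, "beta-5" = 0.15,
                   "4-O-5" = 0.05, "5-5" = 0.025, "dbdo" = 0.025),
    bond_freqs_low_dp = c("beta-O-4" = 0.50, "beta-beta" = 0.20, "beta-5" = 0.25,
                          "4-O-5" = 0.03, "5-5" = 0.01, "dbdo" = 0.01),
    freq_anchor_dp = 20L,
    branch_schedule = list(plateau = 0.80, midpoint = 7, scale = 1)
  ),
  birch = list(
    wood_type = "SG-type", sg_ratio = 1.8, h_fraction = 0,
    bond_freqs = c("beta-O-4" = 0.65, "beta-beta" = 0.14, "beta-5" = 0.10,
                   "4-O-5" = 0.09, "5-5" = 0.012, "dbdo" = 0.008),
    bond_freqs_low_dp = c("beta-O-4" = 0.50, "beta-beta" = 0.28, "beta-5" = 0.12,
                          "4-O-5" = 0.08, "5-5" = 0.01, "dbdo" = 0.01),
    freq_anchor_dp = 18L,
    branch_schedule = list(plateau = 0.22, midpoint = 7, scale = 1)
  )
)

#' Build a generation configuration
#'
#' `preset_config("spruce")` models softwood (G-type, pure guaiacyl) milled
#' wood lignin; `preset_config("birch")` models hardwood (SG-type, S/G = 1.8)
#' lignin. Bond-frequency targets are DP-dependent (interpolated between a
#' DP-3 anchor and the preset's reference-DP anchor) because the beta-O-4
#' share grows with chain length. All fields can be overridden by named
#' arguments.
#'
#' @param preset `"spruce"` or `"birch"`.
#' @param ... overrides of any configuration field (e.g. `dp_values`,
#'   `structures_per_dp`, `seed`, `bond_freqs`, `output_dir`, `formats`).
#' @return a validated `generation_config`.
#' @export
preset_config <- function(preset = c("spruce", "birch"), ...) {
  preset <- match.arg(preset)
  cfg <- c(.BOND_FREQ_DEFAULTS[[preset]], list(
    preset = preset,
    dp_values = 3:25,
    structures_per_dp = 20L,
    seed = 1L,
    enumeration_cap = 2000L,
    max_attempts = 25L,
    attempts_factor = 20L,
    keep_structures = FALSE,
    canonicalize = TRUE,
    output_dir = NULL,
    formats = c("json", "csv", "mol"),
    mol_dims = 3,
    verbose = TRUE
  ))
  over <- list(...)
  unknown <- setdiff(names(over), c(names(cfg)))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Load a generation configuration from YAML
#'
#' The file may name a `preset` (`spruce`/`birch`) and override any field;
#' `dp_values` accepts either a list or a `"3-25"` range shorthand.
#'
#' @param path YAML file.
#' @return a validated `generation_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config error: top level must be a mapping", call. = FALSE)
  preset <- raw$preset %||% "spruce"
  raw$preset <- NULL
  if (!is.null(raw$dp_values) && is.character(raw$dp_values) &&
      grepl("^\\s*\\d+\\s*-\\s*\\d+\\s*$", raw$dp_values)) {
    ends <- as.integer(strsplit(raw$dp_values, "-", fixed = TRUE)[[1L]])
    raw$dp_values <- ends[1L]:ends[2L]
  }
  for (f in c("bond_freqs", "bond_freqs_low_dp"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(preset_config, c(list(preset = preset), raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a generation configuration
#' @param cfg configuration list.
#' @return the config, classed `generation_config`; errors list every
#'   offending key.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, key, why) if (!isTRUE(ok)) problems <<- c(problems, paste0(key, ": ", why))
  chk(cfg$wood_type %in% c("G-type", "SG-type", "custom"), "wood_type",
      "must be G-type, SG-type or custom")
  chk(is.numeric(cfg$sg_ratio) && cfg$sg_ratio >= 0, "sg_ratio", "must be >= 0")
  chk(is.numeric(cfg$h_fraction) && cfg$h_fraction >= 0 && cfg$h_fraction < 1,
      "h_fraction", "must be in [0, 1)")
  for (f in c("bond_freqs", "bond_freqs_low_dp")) {
    chk(is.numeric(cfg[[f]]) && all(LINKAGE_NAMES %in% names(cfg[[f]])) &&
          all(cfg[[f]] >= 0), f, "must be non-negative and name all six linkages")
    if (is.numeric(cfg[[f]]) && all(LINEAR_LINKAGES %in% names(cfg[[f]])))
      chk(sum(cfg[[f]][LINEAR_LINKAGES]) > 0, f,
          "at least one linear linkage must have positive weight")
  }
  chk(is.numeric(cfg$dp_values) && length(cfg$dp_values) > 0 &&
        all(cfg$dp_values >= 3), "dp_values", "must be a non-empty set of DPs >= 3")
  chk(is.numeric(cfg$structures_per_dp) && cfg$structures_per_dp >= 0,
      "structures_per_dp", "must be >= 0")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed", "must be an integer")
  chk(is.numeric(cfg$enumeration_cap) && cfg$enumeration_cap >= 1,
      "enumeration_cap", "must be >= 1")
  if (length(problems))
    stop("config error:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  cfg$dp_values <- as.integer(cfg$dp_values)
  structure(cfg, class = "generation_config")
}

#' DP-dependent bond-frequency targets of a configuration
#'
#' Linear interpolation between the DP-3 anchor and the preset anchor DP,
#' constant outside, renormalized to sum to 1.
#' @param cfg a `generation_config`.
#' @param dp degree of polymerization.
#' @return named frequency vector over the six linkages.
#' @export
bond_freqs_at <- function(cfg, dp) {
  a <- cfg$bond_freqs_low_dp[LINKAGE_NAMES]
  b <- cfg$bond_freqs[LINKAGE_NAMES]
  t <- min(max((dp - 3) / (cfg$freq_anchor_dp - 3), 0), 1)
  f <- (1 - t) * a + t * b
  f / sum(f)
}

.dp_seed <- function(seed, dp) (as.integer(seed) + dp * 100003L) %% 2147483647L

#' Generate a lignin structure dataset
#'
#' Runs the full workflow for every DP level of the configuration, with one
#' RNG stream per DP derived from the master seed (so per-DP output does not
#' depend on the order of `dp_values`). Shortfalls (duplicate SMILES at
#' small DP for pure-G runs, infeasible branchings) are tallied per DP.
#'
#' @param cfg a `generation_config` (see [preset_config()], [load_config()]).
#' @return a `lignin_dataset` list: `summary` (per-DP accept/reject tallies),
#'   `reports` (per-structure [analyze()] rows), `catalog` (nested list keyed
#'   by DP then lg_id), `catalog_path` (if JSON written), and `structures`
#'   when `cfg$keep_structures` is TRUE.
#' @export
generate_dataset <- function(cfg) {
  cfg <- validate_config(cfg)
  out_dir <- cfg$output_dir
  write_any <- !is.null(out_dir) && length(cfg$formats) > 0
  if (write_any && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  wood_tag <- switch(cfg$wood_type, "G-type" = "gt", "SG-type" = "sgt", "custom")
  catalog <- list()
  reports <- list()
  structures <- list()
  summary_rows <- list()

  for (dp in cfg$dp_values) {
    set.seed(.dp_seed(cfg$seed, dp))
    comp <- composition_from_ratio(
      if (cfg$wood_type == "G-type") 0 else cfg$sg_ratio, dp, cfg$h_fraction)
    seqs <- enumerate_unique_sequences(comp, cap = cfg$enumeration_cap)
    targets <- bond_freqs_at(cfg, dp)
    weights <- calibrate_weights(targets, dp, comp)
    quota <- as.integer(cfg$structures_per_dp)
    seen <- seen_smiles()
    tally <- c(accepted = 0L, duplicate = 0L, dp_mismatch = 0L,
               invalid = 0L, fallback_linear = 0L, proposals = 0L)
    dp_entries <- list()
    while (tally[["accepted"]] < quota &&
           tally[["proposals"]] < cfg$attempts_factor * quota) {
      batch_size <- max(quota - tally[["accepted"]], 1L)
      mols <- vector("list", batch_size)
      keys <- character(batch_size)
      for (j in seq_len(batch_size)) {
        sq <- seqs[[if (length(seqs) == 1L) 1L else sample.int(length(seqs), 1L)]]
        plan <- plan_topology(dp, if (cfg$wood_type == "SG-type") "SG-type" else "G-type",
                              cfg$branch_schedule)
        g <- generate_graph(sq, weights, targets, plan$branched, cfg$max_attempts)
        if (attr(g, "fallback")) tally[["fallback_linear"]] <- tally[["fallback_linear"]] + 1L
        mols[[j]] <- build_molecule(g, canonicalize = FALSE)
        keys[j] <- structure_key(g)
      }
      tally[["proposals"]] <- tally[["proposals"]] + batch_size
      if (isTRUE(cfg$canonicalize)) {
        smis <- tryCatch(
          canonical_smiles(vapply(mols, `[[`, character(1), "smiles_kekule")),
          error = function(e) rep(NA_character_, batch_size))
        keys <- smis
      } else smis <- vapply(mols, `[[`, character(1), "smiles_kekule")
      for (j in seq_len(batch_size)) {
        mols[[j]]$smiles <- smis[j]
        v <- validate_structure(mols[[j]], dp, seen, key = keys[j])
        if (!v$accepted) {
          key <- switch(v$reason, duplicate = "duplicate",
                        "dp-mismatch" = "dp_mismatch", "invalid")
          tally[[key]] <- tally[[key]] + 1L
          next
        }
        tally[["accepted"]] <- tally[["accepted"]] + 1L
        lg_id <- sprintf("%s_dp%02d_%04d", wood_tag, dp, tally[["accepted"]])
        mols[[j]]$lg_id <- lg_id
        rep_row <- analyze(mols[[j]])
        rep_row$lg_id <- lg_id
        reports[[length(reports) + 1L]] <- rep_row
        files <- list()
        if (write_any && "csv" %in% cfg$formats) {
          f <- file.path(out_dir, paste0(lg_id, ".csv"))
          write_matrices_csv(to_matrices(mols[[j]]$graph, lg_id), f)
          files$csv <- basename(f)
        }
        if (write_any && "mol" %in% cfg$formats) {
          f <- file.path(out_dir, paste0(lg_id, ".mol"))
          write_mol(mols[[j]], f, dims = cfg$mol_dims)
          files$mol <- basename(f)
        }
        dp_entries[[lg_id]] <- c(
          list(lg_id = lg_id, dp = dp,
               sequence = sequence_string(mols[[j]]$graph$labels),
               smiles = mols[[j]]$smiles,
               formula = mols[[j]]$formula_string,
               mw = round(mols[[j]]$mw, 2),
               sg_ratio = rep_row$sg_ratio_realized,
               branched = rep_row$branched),
          list(bond_counts = stats::setNames(as.list(rep_row[1, .BOND_COLS]),
                                             names(.BOND_COLS)),
               functional_groups = list(
                 oh_phenolic_free = rep_row$oh_phenolic_free,
                 oh_aliphatic_primary = rep_row$oh_aliphatic_primary,
                 oh_aliphatic_secondary = rep_row$oh_aliphatic_secondary,
                 methoxy = rep_row$methoxy,
                 cinnamyl_ends = rep_row$cinnamyl_ends),
               files = if (length(files)) files else NULL)
        )
        if (isTRUE(cfg$keep_structures))
          structures[[lg_id]] <- mols[[j]]
      }
    }
    if (isTRUE(cfg$verbose))
      message(sprintf("DP %2d: accepted %d/%d (duplicates %d, dp-mismatch %d, invalid %d, linear fallbacks %d)",
                      dp, tally[["accepted"]], quota, tally[["duplicate"]],
                      tally[["dp_mismatch"]], tally[["invalid"]],
                      tally[["fallback_linear"]]))
    catalog[[as.character(dp)]] <- dp_entries
    summary_rows[[length(summary_rows) + 1L]] <-
      data.frame(dp = dp, requested = quota, t(tally))
  }

  res <- list(
    summary = do.call(rbind, summary_rows),
    reports = if (length(reports)) do.call(rbind, reports) else NULL,
    catalog = catalog,
    config = cfg
  )
  if (isTRUE(cfg$keep_structures)) res$structures <- structures
  if (write_any && "json" %in% cfg$formats) {
    res$catalog_path <- file.path(out_dir, "catalog.json")
    write_json_catalog(catalog, res$catalog_path, config = cfg)
  }
  class(res) <- "lignin_dataset"
  res
}

#' @export
print.lignin_dataset <- function(x, ...) {
  cat(sprintf("<lignin dataset> %s, %d structure(s) over %d DP level(s)\n",
              x$config$wood_type, sum(x$summary$accepted), nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write the JSON catalog
#'
#' One document keyed by DP then `lg_id`, carrying SMILES, Mw, bond counts
#' and functional-group counts per structure, plus the coupling-rule table
#' and linkage metadata for auditability. No timestamps, so identical runs
#' produce byte-identical catalogs.
#'
#' @param catalog nested entry list (DP -> lg_id -> entry).
#' @param path output path.
#' @param config optional `generation_config` echoed into the payload.
#' @return `path`, invisibly.
#' @export
write_json_catalog <- function(catalog, path, config = NULL) {
  ids <- unlist(lapply(catalog, names), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("integrity error: duplicate lg_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  payload <- list(structures = catalog,
                  coupling_rules = coupling_rule_table(),
                  linkage_types = linkage_types())
  if (!is.null(config))
    payload$config <- list(
      wood_type = config$wood_type, sg_ratio = config$sg_ratio,
      h_fraction = config$h_fraction,
      bond_freqs = as.list(config$bond_freqs),
      bond_freqs_low_dp = as.list(config$bond_freqs_low_dp),
      freq_anchor_dp = config$freq_anchor_dp,
      branch_schedule = config$branch_schedule,
      dp_values = config$dp_values,
      structures_per_dp = config$structures_per_dp,
      seed = config$seed, enumeration_cap = config$enumeration_cap)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON catalog
#' @param path file written by [write_json_catalog()].
#' @return the parsed payload list.
#' @export
read_json_catalog <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
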