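#' @title Structural property analysis
#' @name properties
#' @description
#' Per-structure descriptors are derived from the monomer graph: linkage
#' counts by type (with the biphenyl and dibenzodioxocin counts also pooled,
#' as experimental NMR tables usually report them together), functional-group
#' counts (free phenolic OH; primary aliphatic gamma-OH, consumed by
#' resinol; secondary aliphatic alpha-OH, created by beta-O-4 hydration;
#' methoxy), cinnamyl alcohol end groups, the branched flag (a unit of
#' degree >= 3), and the realized S/G ratio. Batch summaries compare against
#' experimental composition ranges for spruce and birch milled wood lignin.
NULL

.BOND_COLS <- c("beta-O-4" = "bond_beta_O_4", "beta-beta" = "bond_beta_beta",
                "beta-5" = "bond_beta_5", "4-O-5" = "bond_4_O_5",
                "5-5" = "bond_5_5", "dbdo" = "bond_dbdo")

#' Per-structure property report
#'
#' @param struct a `lignin_structure` (from [build_molecule()]) or a bare
#'   `lignin_graph` (mass then comes from the linkage mass balance).
#' @return one-row data.frame: identifiers, mw, linkage counts
#'   (`bond_*`, plus pooled `bond_55_dbdo`), functional-group counts,
#'   `branched`, `cinnamyl_ends`, `sg_ratio_realized`.
#' @export
analyze <- function(struct) {
  if (inherits(struct, "lignin_structure")) {
    g <- struct$graph; mw <- struct$mw; lg_id <- struct$lg_id
  } else if (inherits(struct, "lignin_graph")) {
    g <- struct; mw <- linkage_mass_balance(g); lg_id <- NA_character_
  } else stop("analyze() needs a lignin_structure or lignin_graph", call. = FALSE)
  st <- graph_sites(g)
  n <- length(g$labels)
  counts <- table(factor(g$edges$type, levels = LINKAGE_NAMES))
  n_g <- sum(g$labels == "G"); n_s <- sum(g$labels == "S")
  out <- data.frame(
    lg_id = lg_id, dp = n, mw = mw,
    stringsAsFactors = FALSE
  )
  for (ty in LINKAGE_NAMES) out[[.BOND_COLS[[ty]]]] <- as.integer(counts[[ty]])
  out$bond_55_dbdo <- out$bond_5_5 + out$bond_dbdo
  out$oh_phenolic_free <- sum(st$phenolic_free)
  out$oh_aliphatic_primary <- sum(st$side_state != "resinol")
  out$oh_aliphatic_secondary <- sum(st$side_state == "arylglycerol")
  out$methoxy <- n_g + 2L * n_s
  out$cinnamyl_ends <- sum(st$side_state == "cinnamyl")
  out$branched <- any(st$degree >= 3L)
  out$sg_ratio_realized <- if (n_g == 0L && n_s == 0L) NA_real_ else n_s / n_g
  out
}

#' Analyze a batch of structures
#' @param structs list of `lignin_structure` / `lignin_graph` objects.
#' @return data.frame with one [analyze()] row per structure.
#' @export
analyze_batch <- function(structs) {
  do.call(rbind, lapply(structs, analyze))
}

#' Percentage of branched structures at a DP
#'
#' @param reports data.frame of [analyze()] rows.
#' @param dp degree of polymerization to evaluate.
#' @return percent (0-100).
#' @export
branching_fraction <- function(reports, dp) {
  sel <- reports$dp == dp
  if (!any(sel)) stop("no reports at DP ", dp, call. = FALSE)
  100 * mean(reports$branched[sel])
}

#' Pooled linkage percentages over a batch
#'
#' @param reports data.frame of [analyze()] rows.
#' @return named numeric vector over the six linkages, summing to 100.
#' @export
linkage_percentages <- function(reports) {
  if (nrow(reports) == 0L) stop("empty report batch", call. = FALSE)
  totals <- vapply(.BOND_COLS, function(cl) sum(reports[[cl]]), numeric(1))
  names(totals) <- names(.BOND_COLS)
  100 * totals / sum(totals)
}

#' Experimental and generated-dataset composition ranges
#'
#' Per-structure feature intervals for spruce (DP 20) and birch (DP 18)
#' milled wood lignin: `exp_low`/`exp_high` from experimental
#' characterization, `gen_low`/`gen_high` the corresponding generated-dataset
#' intervals.
#'
#' @param wood `"spruce"` or `"birch"`.
#' @return data.frame of feature intervals (a `reference_ranges`).
#' @export
reference_ranges <- function(wood = c("spruce", "birch")) {
  wood <- match.arg(wood)
  path <- system.file("extdata", "reference_compositions.csv",
                      package = "ligninsmith", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tab[tab$wood == wood, ]
  bad <- with(out, !is.na(exp_low) & exp_low > exp_high) |
    with(out, !is.na(gen_low) & gen_low > gen_high)
  stopifnot(!any(bad))
  rownames(out) <- NULL
  structure(out, class = c("reference_ranges", "data.frame"))
}

#' Linkage and monolignol frequency ranges (percent)
#'
#' Literature frequency intervals (percent per 100 phenylpropane units) for
#' softwood and hardwood milled wood lignin.
#' @param wood_class `"softwood"` or `"hardwood"`.
#' @return data.frame with feature, low, high.
#' @export
reference_frequency_ranges <- function(wood_class = c("softwood", "hardwood")) {
  wood_class <- match.arg(wood_class)
  path <- system.file("extdata", "reference_frequencies.csv",
                      package = "ligninsmith", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tab[tab$wood_class == wood_class, ]
  rownames(out) <- NULL
  out
}

.FEATURE_COLS <- c(
  mw = "mw", dp = "dp",
  "beta-O-4" = "bond_beta_O_4", "beta-beta" = "bond_beta_beta",
  "beta-5" = "bond_beta_5", "4-O-5" = "bond_4_O_5",
  "5-5/dbdo" = "bond_55_dbdo",
  oh_phenolic_free = "oh_phenolic_free",
  oh_aliphatic_primary = "oh_aliphatic_primary",
  oh_aliphatic_secondary = "oh_aliphatic_secondary",
  cinnamyl_end = "cinnamyl_ends"
)

#' Compare a batch to reference composition ranges
#'
#' Summarizes each feature over the batch (median by default; integer counts
#' have skewed small-sample distributions, so the median is more robust than
#' the mean) and flags whether it falls inside the reference interval. The
#' overall match fraction is the share of in-range features among those with
#' a defined interval.
#'
#' @param reports data.frame of [analyze()] rows, all at the reference DP.
#' @param wood `"spruce"` (reference DP 20) or `"birch"` (DP 18).
#' @param interval compare against the `"experimental"` intervals or the
#'   `"generated"` dataset intervals.
#' @param stat batch summary function (default [stats::median()]).
#' @return list with `table` (feature, value, low, high, in_range),
#'   `match_fraction`, `wood`, `dp`, `interval`.
#' @export
compare_to_reference <- function(reports, wood = c("spruce", "birch"),
                                 interval = c("experimental", "generated"),
                                 stat = stats::median) {
  wood <- match.arg(wood)
  interval <- match.arg(interval)
  ranges <- reference_ranges(wood)
  ref_dp <- ranges$ref_dp[1L]
  if (nrow(reports) == 0L) stop("empty report batch", call. = FALSE)
  if (!all(reports$dp == ref_dp))
    stop(sprintf("configuration error: %s reference is defined at DP %d, reports contain other DPs",
                 wood, ref_dp), call. = FALSE)
  lo_col <- if (interval == "experimental") "exp_low" else "gen_low"
  hi_col <- if (interval == "experimental") "exp_high" else "gen_high"
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    feat <- ranges$feature[i]
    v <- stat(reports[[.FEATURE_COLS[[feat]]]])
    lo <- ranges[[lo_col]][i]; hi <- ranges[[hi_col]][i]
    data.frame(feature = feat, value = v, low = lo, high = hi,
               in_range = if (is.na(lo)) NA else v >= lo - 1e-9 & v <= hi + 1e-9,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       match_fraction = mean(tab$in_range, na.rm = TRUE),
       wood = wood, dp = ref_dp, interval = interval)
}
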