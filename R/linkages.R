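#' @title Inter-unit linkage types and coupling rules
#' @name linkages
#' @description
#' Six linkages are modeled. Three extend chains linearly (one unit's beta
#' carbon couples to the next unit): the beta-aryl ether (beta-O-4), the
#' resinol (beta-beta, a fused bis-tetrahydrofuran consuming both gamma
#' oxygens), and the phenylcoumaran (beta-5 with an alpha-O-4 ring closure).
#' Three couple oligomers: the biphenyl (5-5), the diaryl ether (4-O-5), and
#' the dibenzodioxocin (DBDO), an 8-membered ring in which a beta-O-4 donor
#' bridges a 5-5 biphenyl pair through its beta and alpha oxygens.
#'
#' Which couplings are possible depends on the partner labels: the S unit's
#' 5-position carries a methoxy group, so S never participates in 5-5 and
#' never accepts beta-5 or 4-O-5 at its ring. Resinol formation requires two
#' free beta positions and therefore only occurs between a monomer pair (the
#' first junction of a growing fragment).
NULL

LINKAGE_NAMES <- c("beta-O-4", "beta-beta", "beta-5", "4-O-5", "5-5", "dbdo")
LINEAR_LINKAGES <- c("beta-O-4", "beta-beta", "beta-5")
BRANCHED_LINKAGES <- c("4-O-5", "5-5", "dbdo")
COUPLING_CONTEXTS <- c("dimer", "oligomer-monomer", "oligomer-oligomer")

#' Linkage-type metadata
#'
#' @return data.frame with one row per linkage: name, bond category
#'   (C-O, C-C, or mixed), motif (linear or branched), donor and acceptor
#'   site labels.
#' @export
linkage_types <- function() {
  data.frame(
    name = LINKAGE_NAMES,
    category = c("C-O", "mixed", "mixed", "C-O", "C-C", "mixed"),
    motif = c("linear", "linear", "linear", "branched", "branched", "branched"),
    donor_site = c("beta", "beta", "beta", "4-O", "5", "5"),
    acceptor_site = c("4-O", "beta", "5", "5", "5", "5"),
    stringsAsFactors = FALSE
  )
}

.has_free5 <- function(label) !(5L %in% get_template(label)$methoxy_positions)

#' Allowed couplings for a donor/acceptor label pair
#'
#' Transcribes the literature coupling table. `context` distinguishes the
#' first junction of a fragment (`"dimer"`), chain extension
#' (`"oligomer-monomer"`, where resinol is no longer possible), and
#' oligomer cross-coupling (`"oligomer-oligomer"`). Donor-first semantics:
#' the donor contributes its beta (linear contexts) or its phenolic 4-O
#' (4-O-5); the acceptor supplies the 4-O, beta or ring-C5 site. DBDO is
#' possible wherever 5-5 is (the third, beta-donating unit is checked at
#' assembly time).
#'
#' @param context one of `"dimer"`, `"oligomer-monomer"`, `"oligomer-oligomer"`.
#' @param donor,acceptor monomer labels (`"H"`, `"G"`, `"S"`).
#' @return character vector of allowed linkage names (possibly empty).
#' @examples
#' allowed_couplings("dimer", "S", "S")               # beta-O-4, beta-beta
#' allowed_couplings("oligomer-oligomer", "S", "S")   # none
#' @export
allowed_couplings <- function(context, donor, acceptor) {
  context <- match.arg(context, COUPLING_CONTEXTS)
  stopifnot(donor %in% MONOMER_LABELS, acceptor %in% MONOMER_LABELS)
  acc5 <- .has_free5(acceptor)
  switch(context,
    "dimer" = c("beta-O-4", "beta-beta", if (acc5) "beta-5"),
    "oligomer-monomer" = c("beta-O-4", if (acc5) "beta-5"),
    "oligomer-oligomer" = c(
      if (acc5) "4-O-5",
      if (acc5 && .has_free5(donor)) c("5-5", "dbdo")
    )
  )
}

#' The full coupling-rule table
#'
#' All dimer, oligomer-monomer and oligomer cross-coupling rows for S/G
#' pairs, as a machine-readable table (exported to the JSON catalog for
#' auditability).
#'
#' @return data.frame with columns context, donor, acceptor, linkage, allowed.
#' @export
coupling_rule_table <- function() {
  rows <- expand.grid(
    context = COUPLING_CONTEXTS, donor = c("G", "S"), acceptor = c("G", "S"),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    ctx <- rows$context[i]
    cols <- if (ctx == "oligomer-oligomer") c("4-O-5", "5-5") else
      intersect(LINEAR_LINKAGES, if (ctx == "dimer") LINEAR_LINKAGES else c("beta-O-4", "beta-5"))
    ok <- allowed_couplings(ctx, rows$donor[i], rows$acceptor[i])
    data.frame(context = ctx, donor = rows$donor[i], acceptor = rows$acceptor[i],
               linkage = cols, allowed = cols %in% ok, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign linkage types along a monomer sequence
#'
#' Walks the `n - 1` junctions of a sequence and samples one linkage per
#' junction proportionally to `bond_freqs`, restricted to the couplings the
#' junction labels allow. The first junction is a monomer-monomer (dimer)
#' coupling; later junctions are oligomer-monomer couplings in which the
#' chain end donates its beta to the incoming unit. After a resinol
#' (beta-beta) junction the chain end's beta is consumed, so the direction
#' reverses: each subsequent unit donates its beta into the previous unit.
#'
#' @param seq character vector of monomer labels (length >= 2).
#' @param bond_freqs named non-negative weights; at least the three linear
#'   linkages must be present with a positive sum. Draws use the current RNG
#'   stream (`set.seed()` for reproducibility).
#' @return data.frame (`linkage_assignment`) with columns donor, acceptor
#'   (unit indices) and type.
#' @examples
#' set.seed(1)
#' assign_linkages(c("G", "G", "G"), c("beta-O-4" = 1))
#' @export
assign_linkages <- function(seq, bond_freqs) {
  n <- length(seq)
  stopifnot(n >= 2L, all(seq %in% MONOMER_LABELS))
  w <- bond_freqs[intersect(names(bond_freqs), LINEAR_LINKAGES)]
  w <- w[w > 0]
  if (length(w) == 0L)
    stop("bond_freqs must give positive weight to at least one linear linkage",
         call. = FALSE)
  donors <- integer(n - 1L); acceptors <- integer(n - 1L); types <- character(n - 1L)
  flipped <- FALSE
  for (i in seq_len(n - 1L)) {
    ctx <- if (i == 1L) "dimer" else "oligomer-monomer"
    if (!flipped) { d <- i; a <- i + 1L } else { d <- i + 1L; a <- i }
    allowed <- allowed_couplings(ctx, seq[d], seq[a])
    wi <- w[names(w) %in% allowed]
    if (length(wi) == 0L)
      stop(sprintf("infeasible junction %d (%s -> %s): no allowed linkage has positive weight",
                   i, seq[d], seq[a]), call. = FALSE)
    type <- if (length(wi) == 1L) names(wi) else
      sample(names(wi), 1L, prob = wi)
    donors[i] <- d; acceptors[i] <- a; types[i] <- type
    if (type == "beta-beta") flipped <- TRUE   # both betas consumed: reverse growth
  }
  structure(
    data.frame(donor = donors, acceptor = acceptors, type = types,
               stringsAsFactors = FALSE),
    class = c("linkage_assignment", "data.frame")
  )
}

#' Calibrate junction sampling weights to realized linkage targets
#'
#' Junction-level sampling cannot use target linkage fractions directly as
#' weights: resinol competes only at the first junction of each fragment, and
#' junctions onto an S acceptor exclude beta-5, so raw weights systematically
#' under-produce beta-beta and over-produce beta-O-4. This routine solves (by
#' damped fixed-point iteration on an expected-count model) for the sampling
#' weights whose expected realized linkage fractions match the configured
#' targets at a given DP and composition. It is deterministic.
#'
#' @param targets named fractions over the six linkages (summing to ~1); the
#'   three branched-linkage entries set the expected number of oligomer
#'   cross-couplings and are passed through unchanged.
#' @param dp degree of polymerization the weights are calibrated for.
#' @param comp the `monomer_composition` (acceptor-label probabilities).
#' @return named weight vector over the three linear linkages (sums to 1).
#' @export
calibrate_weights <- function(targets, dp, comp) {
  stopifnot(all(LINKAGE_NAMES %in% names(targets)), dp >= 2)
  tl <- targets[LINEAR_LINKAGES]
  k <- .expected_cross_count(targets, dp)
  n_junction <- (dp - 1) - k
  n_first <- min(k + 1, n_junction)        # one dimer-context junction per fragment
  n_later <- n_junction - n_first
  gamma <- sum(comp$counts[c("G", "H")]) / comp$dp   # P(acceptor has a free C5)
  target_counts <- tl / sum(tl) * n_junction
  w <- pmax(tl, 1e-3); w <- w / sum(w)
  for (iter in 1:200) {
    s1 <- w[1] + w[2] + w[3]; s1g <- w[1] + w[2]       # dimer ctx, G/S acceptor
    s2 <- w[1] + w[3]                                   # oligomer-monomer, G acceptor
    e_bb <- n_first * (gamma * w[2] / s1 + (1 - gamma) * w[2] / s1g)
    e_b5 <- n_first * gamma * w[3] / s1 + n_later * gamma * w[3] / s2
    e_bO4 <- n_junction - e_bb - e_b5
    e <- c(e_bO4, e_bb, e_b5)
    ratio <- ifelse(e > 1e-9, target_counts / e, 1)
    ratio <- pmin(pmax(ratio, 0.5), 2)                  # damping
    w_new <- w * ratio
    w_new <- pmax(w_new, 1e-6); w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
    w <- w_new
  }
  names(w) <- LINEAR_LINKAGES
  w
}

# expected number of oligomer cross-couplings at a DP (continuous value)
.expected_cross_count <- function(targets, dp) {
  kbar <- sum(targets[BRANCHED_LINKAGES]) * (dp - 1)
  kmax <- max(0, floor(dp / 2) - 1)
  min(max(kbar, 0), kmax)
}
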