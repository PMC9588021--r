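#' @title Monomer-level graph assembly
#' @name assembly
#' @description
#' A lignin structure is represented at the monomer level as a directed tree:
#' nodes are monomer units, edges are typed inter-unit linkages running from
#' the donor to the acceptor unit. DBDO motifs are annotations on the tree
#' (the alpha-O-4 ring closure is applied when the atom-level molecule is
#' built), so a structure with n units always has exactly n - 1 edges.
#'
#' Linear fragments grow endwise: unit 1 donates its beta into unit 2, so the
#' fragment head (unit 1) keeps the free phenolic 4-OH and the tail keeps the
#' unreacted cinnamyl side chain. Fragments couple through their ring sites
#' (5-5, 4-O-5, DBDO): coupling onto a fragment end preserves a path
#' (linear) topology, coupling onto an interior unit creates a degree-3
#' branch point.
NULL

#' Construct a lignin graph
#' @param labels character vector of monomer labels.
#' @param edges data.frame with donor, acceptor, type.
#' @param dbdo list of DBDO motifs, each `list(x =, a =, b =)`.
#' @param validate run [validate_graph()]?
#' @return a `lignin_graph`.
#' @export
lignin_graph <- function(labels, edges, dbdo = list(), validate = TRUE) {
  g <- structure(
    list(labels = as.character(labels),
         edges = data.frame(donor = as.integer(edges$donor),
                            acceptor = as.integer(edges$acceptor),
                            type = as.character(edges$type),
                            stringsAsFactors = FALSE),
         dbdo = dbdo),
    class = "lignin_graph"
  )
  if (validate) validate_graph(g)
  g
}

#' @export
print.lignin_graph <- function(x, ...) {
  tab <- table(factor(x$edges$type, levels = LINKAGE_NAMES))
  cat(sprintf("<lignin graph> %d units (%s), %d edges [%s]%s\n",
              length(x$labels), sequence_string(x$labels), nrow(x$edges),
              paste(names(tab[tab > 0]), tab[tab > 0], sep = ":", collapse = " "),
              if (length(x$dbdo)) sprintf(", %d DBDO motif(s)", length(x$dbdo)) else ""))
  invisible(x)
}

#' Site usage and derived unit states of a lignin graph
#'
#' States are always derived from the edge list (never stored), so encoding
#' round trips cannot go stale. Side-chain states: `cinnamyl` (unreacted
#' beta, unsaturated propenol chain), `arylglycerol` (ordinary beta-O-4 donor;
#' water adds at alpha giving a secondary alpha-OH), `resinol` (beta-beta
#' pair; both gamma oxygens closed into the furofuran), `coumaran` (beta-5
#' donor; alpha-O-4 closure, gamma-OH retained), `dbdo` (the beta-O-4 donor
#' inside a dibenzodioxocin; alpha closes onto the second biphenyl unit
#' instead of taking water).
#'
#' @param g a `lignin_graph`.
#' @return list of per-unit vectors: `beta_used`, `o4_used`, `c5_used`
#'   (integer use counts), `side_state`, `phenolic_free`, `degree`.
#' @export
graph_sites <- function(g) {
  n <- length(g$labels)
  e <- g$edges
  beta_used <- o4_used <- c5_used <- integer(n)
  degree <- integer(n)
  side_state <- rep("cinnamyl", n)
  add <- function(v, idx) { v[idx] <- v[idx] + 1L; v }

  dbdo_x <- vapply(g$dbdo, `[[`, integer(1), "x")
  for (i in seq_len(nrow(e))) {
    d <- e$donor[i]; a <- e$acceptor[i]; ty <- e$type[i]
    degree <- add(add(degree, d), a)
    switch(ty,
      "beta-O-4" = {
        beta_used <- add(beta_used, d); o4_used <- add(o4_used, a)
        side_state[d] <- if (d %in% dbdo_x) "dbdo" else "arylglycerol"
      },
      "beta-beta" = {
        beta_used <- add(add(beta_used, d), a)
        side_state[c(d, a)] <- "resinol"
      },
      "beta-5" = {
        beta_used <- add(beta_used, d)
        c5_used <- add(c5_used, a); o4_used <- add(o4_used, a)  # alpha-O-4 closure
        side_state[d] <- "coumaran"
      },
      "4-O-5" = {
        o4_used <- add(o4_used, d); c5_used <- add(c5_used, a)
      },
      "5-5" = ,
      "dbdo" = {
        c5_used <- add(add(c5_used, d), a)
      },
      stop("unknown linkage type: ", ty)
    )
  }
  for (m in g$dbdo) o4_used <- add(o4_used, m$b)  # alpha-O-4 onto the second biphenyl unit
  list(beta_used = beta_used, o4_used = o4_used, c5_used = c5_used,
       side_state = side_state, phenolic_free = o4_used == 0L, degree = degree)
}

#' Validate a lignin graph
#'
#' Checks the tree invariant (n - 1 edges, connected), single use of every
#' beta / 4-O / C5 site, the 5-methoxy blocking rule (an S unit's C5 is never
#' bonded), and DBDO motif consistency.
#'
#' @param g a `lignin_graph`.
#' @return `g`, invisibly; stops on violation.
#' @export
validate_graph <- function(g) {
  n <- length(g$labels)
  e <- g$edges
  if (n == 0L) stop("empty graph", call. = FALSE)
  if (!all(g$labels %in% MONOMER_LABELS)) stop("unknown monomer labels", call. = FALSE)
  if (nrow(e) != n - 1L)
    stop(sprintf("not a tree: %d units but %d edges", n, nrow(e)), call. = FALSE)
  if (nrow(e) > 0L && (any(e$donor == e$acceptor) ||
                       any(e$donor < 1L | e$donor > n | e$acceptor < 1L | e$acceptor > n)))
    stop("edge endpoints out of range", call. = FALSE)
  # connectivity by breadth-first search over the undirected edge set
  if (n > 1L) {
    adj <- vector("list", n)
    for (i in seq_len(nrow(e))) {
      adj[[e$donor[i]]] <- c(adj[[e$donor[i]]], e$acceptor[i])
      adj[[e$acceptor[i]]] <- c(adj[[e$acceptor[i]]], e$donor[i])
    }
    seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
    if (!all(seen)) stop("graph is disconnected", call. = FALSE)
  }
  st <- graph_sites(g)
  if (any(st$beta_used > 1L)) stop("a beta position donates more than one bond", call. = FALSE)
  if (any(st$o4_used > 1L)) stop("a 4-O position accepts more than one bond", call. = FALSE)
  if (any(st$c5_used > 1L)) stop("a ring C5 participates in more than one bond", call. = FALSE)
  blocked <- vapply(g$labels, function(l) 5L %in% get_template(l)$methoxy_positions, logical(1))
  if (any(blocked & st$c5_used > 0L))
    stop("5-position bond on a syringyl (5-methoxylated) unit", call. = FALSE)
  for (m in g$dbdo) {
    ok_b04 <- any(e$donor == m$x & e$acceptor == m$a & e$type == "beta-O-4")
    ok_55 <- any(((e$donor == m$a & e$acceptor == m$b) |
                  (e$donor == m$b & e$acceptor == m$a)) & e$type == "dbdo")
    if (!ok_b04 || !ok_55)
      stop("inconsistent DBDO motif annotation", call. = FALSE)
  }
  invisible(g)
}

#' Grow a linear chain from a sequence and a linkage assignment
#'
#' @param seq character vector of monomer labels.
#' @param assign a `linkage_assignment` covering the `n - 1` junctions
#'   (from [assign_linkages()]).
#' @return a path-shaped `lignin_graph`.
#' @examples
#' g <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), c("beta-O-4" = 1)))
#' graph_sites(g)$phenolic_free   # donor free, acceptor etherified
#' @export
grow_linear <- function(seq, assign) {
  n <- length(seq)
  if (nrow(assign) != n - 1L)
    stop("assignment must cover exactly the n - 1 junctions", call. = FALSE)
  lignin_graph(seq, assign)
}

#' Branching probability schedule
#'
#' Monotone piecewise-logistic schedule for the probability that a structure
#' of a given DP contains a true branch point (a degree-3 unit). Linear
#' chains dominate up to DP 4 for both wood types; for G-type (softwood)
#' lignin the free C5 of every guaiacyl ring lets branching rise steeply to a
#' high plateau past DP ~10, while for SG-type (hardwood) the syringyl
#' 5-methoxy caps branching at a moderate plateau.
#'
#' @param dp degree of polymerization.
#' @param wood_type `"G-type"` or `"SG-type"`.
#' @param plateau,midpoint,scale optional overrides of the logistic
#'   parameters (defaults: G-type 0.80/7/1; SG-type 0.22/7/1).
#' @return probability in `[0, 1]` (vectorized over `dp`).
#' @export
branch_probability <- function(dp, wood_type = c("G-type", "SG-type"),
                               plateau = NULL, midpoint = 7, scale = 1) {
  wood_type <- match.arg(wood_type)
  if (is.null(plateau)) plateau <- if (wood_type == "G-type") 0.80 else 0.22
  p <- plateau / (1 + exp(-(dp - midpoint) / scale))
  ifelse(dp <= 4, 0, p)
}

#' Plan the topology of one structure
#'
#' @param dp degree of polymerization (>= 3).
#' @param wood_type `"G-type"` or `"SG-type"`.
#' @param schedule optional list overriding `plateau`, `midpoint`, `scale`.
#' @return list with `branched` (logical draw from the schedule).
#' @export
plan_topology <- function(dp, wood_type = c("G-type", "SG-type"), schedule = list()) {
  stopifnot(dp >= 3)
  wood_type <- match.arg(wood_type)
  p <- do.call(branch_probability, c(list(dp = dp, wood_type = wood_type), schedule))
  list(branched = stats::runif(1) < p, p_branch = p)
}

# enumerate feasible attachment units in `g` for coupling the phenolic head
# of an incoming fragment; `mode` "extend" keeps the path (degree <= 1),
# "branch" creates a degree-3 node (degree >= 2)
.cross_candidates <- function(g, linkage, mode, head_label, head_sites) {
  st <- graph_sites(g)
  n <- length(g$labels)
  free5 <- vapply(g$labels, .has_free5, logical(1))
  deg_ok <- if (mode == "extend") st$degree <= 1L else st$degree >= 2L
  head5 <- .has_free5(head_label) && head_sites$c5 == 0L
  out <- list()
  if (linkage == "5-5") {
    if (head5)
      for (a in which(free5 & st$c5_used == 0L & deg_ok))
        out[[length(out) + 1L]] <- list(a = a, orientation = "a-donor")
  } else if (linkage == "4-O-5") {
    # head as donor (phenolic 4-O-5): acceptor in g needs a free C5
    if (head_sites$o4 == 0L)
      for (a in which(free5 & st$c5_used == 0L & deg_ok))
        out[[length(out) + 1L]] <- list(a = a, orientation = "b-donor")
    # head as acceptor: donor in g needs a free 4-O
    if (head5)
      for (a in which(st$o4_used == 0L & deg_ok))
        out[[length(out) + 1L]] <- list(a = a, orientation = "a-donor")
  } else if (linkage == "dbdo") {
    # biphenyl pair (a, head); the beta-O-4 donor onto `a` bridges the ring,
    # so `a` needs an incoming beta-O-4 from an arylglycerol-state unit and
    # the head needs both a free C5 and a free 4-O for the alpha-O-4 closure
    if (head5 && head_sites$o4 == 0L) {
      used_x <- vapply(g$dbdo, `[[`, integer(1), "x")
      used_a <- vapply(g$dbdo, `[[`, integer(1), "a")
      for (a in which(free5 & st$c5_used == 0L & deg_ok)) {
        inc <- which(g$edges$acceptor == a & g$edges$type == "beta-O-4")
        if (length(inc) != 1L) next
        x <- g$edges$donor[inc]
        if (st$side_state[x] != "arylglycerol" || x %in% used_x || a %in% used_a) next
        out[[length(out) + 1L]] <- list(a = a, orientation = "a-donor", x = x)
      }
    }
  }
  out
}

.head_sites <- function(g, unit = 1L) {
  st <- graph_sites(g)
  list(o4 = st$o4_used[unit], c5 = st$c5_used[unit], beta = st$beta_used[unit])
}

#' Couple two oligomer fragments
#'
#' Joins `g2` (through its phenolic head, unit 1) onto `g1` with a 5-5,
#' 4-O-5 or DBDO linkage. `mode = "extend"` attaches at a fragment end of
#' `g1` and keeps a path topology; `mode = "branch"` attaches at an interior
#' unit, creating a degree-3 branch point. For DBDO the 5-5 pair plus the
#' bridging beta-O-4 donor are registered as a motif; the alpha-O-4 ring
#' closure is applied at molecule build time.
#'
#' @param g1,g2 `lignin_graph` fragments.
#' @param linkage `"5-5"`, `"4-O-5"` or `"dbdo"`.
#' @param mode `"extend"` or `"branch"`.
#' @return the merged `lignin_graph` (`n1 + n2` units, `n1 + n2 - 1` edges).
#' @export
branch_couple <- function(g1, g2, linkage = c("5-5", "4-O-5", "dbdo"),
                          mode = c("extend", "branch")) {
  linkage <- match.arg(linkage)
  mode <- match.arg(mode)
  head_label <- g2$labels[1L]
  head_sites <- .head_sites(g2)
  cand <- .cross_candidates(g1, linkage, mode, head_label, head_sites)
  if (length(cand) == 0L)
    stop(sprintf("branch-infeasible: no eligible %s site (%s mode)", linkage, mode),
         call. = FALSE)
  pick <- cand[[if (length(cand) == 1L) 1L else sample.int(length(cand), 1L)]]
  off <- length(g1$labels)
  e2 <- g2$edges
  e2$donor <- e2$donor + off; e2$acceptor <- e2$acceptor + off
  b <- 1L + off
  new_edge <- if (linkage == "4-O-5" && pick$orientation == "b-donor")
    data.frame(donor = b, acceptor = pick$a, type = "4-O-5", stringsAsFactors = FALSE)
  else
    data.frame(donor = pick$a, acceptor = b,
               type = if (linkage == "dbdo") "dbdo" else linkage,
               stringsAsFactors = FALSE)
  dbdo <- c(g1$dbdo,
            lapply(g2$dbdo, function(m) list(x = m$x + off, a = m$a + off, b = m$b + off)))
  if (linkage == "dbdo")
    dbdo <- c(dbdo, list(list(x = pick$x, a = pick$a, b = b)))
  lignin_graph(c(g1$labels, g2$labels),
               rbind(g1$edges, e2, new_edge), dbdo)
}

#' Assemble one complete structure graph
#'
#' Splits the monomer sequence into `k + 1` fragments (where `k`, the number
#' of oligomer cross-couplings, is a stochastic rounding of the branched
#' linkage target frequencies times `dp - 1`), grows each fragment linearly,
#' and couples them. If `branched` is TRUE the first coupling lands on an
#' interior unit. Infeasible draws (e.g. all-S coupling partners) retry with
#' new split points and reshuffled fragment boundaries; on exhaustion the
#' structure falls back to a single linear chain and the shortfall is
#' recorded in the `"fallback"` attribute.
#'
#' @param seq character vector of monomer labels (length >= 3).
#' @param weights junction sampling weights over the linear linkages
#'   (typically from [calibrate_weights()]).
#' @param cross_freqs named target frequencies of the three branched
#'   linkages (fractions of all linkages).
#' @param branched should the structure contain a degree-3 branch point?
#' @param max_attempts retry budget for infeasible split/coupling draws.
#' @return a `lignin_graph`; attributes: `branched` (realized), `fallback`.
#' @export
generate_graph <- function(seq, weights, cross_freqs, branched = FALSE,
                           max_attempts = 25L) {
  n <- length(seq)
  stopifnot(n >= 3L)
  kbar <- sum(cross_freqs[BRANCHED_LINKAGES], na.rm = TRUE) * (n - 1)
  kmax <- max(0L, floor(n / 2) - 1L)
  k <- min(floor(kbar) + stats::rbinom(1L, 1L, kbar - floor(kbar)), kmax)
  if (branched && kmax >= 1L) k <- max(k, 1L)
  if (kmax < 1L) { k <- 0L; branched <- FALSE }
  cw <- cross_freqs[BRANCHED_LINKAGES]
  cw[is.na(cw)] <- 0

  for (attempt in seq_len(max_attempts)) {
    res <- tryCatch({
      if (k > 0L) {
        lens <- 2L + as.integer(stats::rmultinom(1L, n - 2L * (k + 1L), rep(1, k + 1L)))
      } else lens <- n
      bounds <- cumsum(c(0L, lens))
      frags <- lapply(seq_along(lens), function(i) {
        sub <- seq[(bounds[i] + 1L):bounds[i + 1L]]
        grow_linear(sub, assign_linkages(sub, weights))
      })
      g <- frags[[1L]]
      want_branch <- branched
      for (j in seq_len(k)) {
        f <- frags[[j + 1L]]
        mode <- if (want_branch) "branch" else "extend"
        feas <- Filter(function(ty) {
          cw[[ty]] > 0 &&
            length(.cross_candidates(g, ty, mode, f$labels[1L], .head_sites(f))) > 0
        }, BRANCHED_LINKAGES)
        if (length(feas) == 0L && want_branch) {
          # no interior site available: fall back to a path coupling for this
          # event; the plan's branch flag is dropped for this structure
          mode <- "extend"
          feas <- Filter(function(ty) {
            cw[[ty]] > 0 &&
              length(.cross_candidates(g, ty, mode, f$labels[1L], .head_sites(f))) > 0
          }, BRANCHED_LINKAGES)
        }
        if (length(feas) == 0L) stop("branch-infeasible")
        ty <- if (length(feas) == 1L) feas else sample(feas, 1L, prob = cw[feas])
        g <- branch_couple(g, f, ty, mode)
        if (mode == "branch") want_branch <- FALSE
      }
      g
    }, error = function(e) NULL)
    if (!is.null(res)) {
      st <- graph_sites(res)
      attr(res, "branched") <- any(st$degree >= 3L)
      attr(res, "fallback") <- FALSE
      return(res)
    }
    # reshuffle the sequence before the next attempt (same multiset)
    if (attempt > max_attempts / 2) seq <- sample(seq)
  }
  g <- grow_linear(seq, assign_linkages(seq, weights))
  attr(g, "branched") <- FALSE
  attr(g, "fallback") <- TRUE
  g
}
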