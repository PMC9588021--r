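#' @title Monomer sequence generation
#' @name sequences
#' @description
#' A structure of DP `n` is defined first by its monomer composition (how many
#' H/G/S units) and then by an ordering of those units. The composition is the
#' integer split of the DP closest to the requested S/G ratio; orderings are
#' the unique permutations of the composition multiset. The number of unique
#' orderings is the multinomial coefficient `dp! / prod(count_l!)` - e.g. five
#' units at S/G ratio 1.8 give the composition {S:3, G:2} and exactly 10
#' unique sequences.
NULL

#' Integer monomer composition from an S/G ratio
#'
#' Allocates `round(h_fraction * dp)` units to H, then splits the remainder
#' between S and G so that the integer count ratio S/G is as close as possible
#' to `sg_ratio`. Ties resolve toward more S (hardwood lignins have S >= G).
#' `sg_ratio = 0` yields a pure-G composition.
#'
#' @param sg_ratio non-negative ratio of S to G units; `Inf` gives pure S.
#' @param dp degree of polymerization (>= 2).
#' @param h_fraction fraction of units that are p-coumaryl (H), in `[0, 1)`.
#' @return a `monomer_composition`: list with `counts` (named G/H/S) and `dp`.
#' @examples
#' composition_from_ratio(1.8, 5)  # {S:3, G:2}
#' @export
composition_from_ratio <- function(sg_ratio, dp, h_fraction = 0) {
  if (!is.numeric(dp) || length(dp) != 1L || dp < 2 || dp != round(dp))
    stop("invalid DP: need an integer dp >= 2", call. = FALSE)
  dp <- as.integer(dp)
  if (!is.numeric(sg_ratio) || length(sg_ratio) != 1L || is.na(sg_ratio) || sg_ratio < 0)
    stop("sg_ratio must be a non-negative number", call. = FALSE)
  if (!is.numeric(h_fraction) || h_fraction < 0 || h_fraction >= 1)
    stop("h_fraction must lie in [0, 1)", call. = FALSE)
  h <- as.integer(round(h_fraction * dp))
  m <- dp - h
  if (m < 1L) stop("h_fraction leaves no S/G units", call. = FALSE)
  if (is.infinite(sg_ratio)) {
    s <- m
  } else {
    # distance of each integer split (s, m - s) from the target ratio
    s_cand <- 0:m
    g_cand <- m - s_cand
    ratio <- ifelse(g_cand == 0L, Inf, s_cand / g_cand)
    dist <- ifelse(is.infinite(ratio), Inf, abs(ratio - sg_ratio))
    # ties toward more S: among minima take the largest s
    s <- max(s_cand[dist == min(dist)])
  }
  structure(
    list(counts = c(G = m - s, H = h, S = s), dp = dp),
    class = "monomer_composition"
  )
}

#' @export
print.monomer_composition <- function(x, ...) {
  nz <- x$counts[x$counts > 0L]
  cat(sprintf("<monomer composition> DP %d: {%s}; %s unique sequences\n",
              x$dp, paste(names(nz), nz, sep = ":", collapse = ", "),
              format(count_unique_sequences(x), big.mark = ",")))
  invisible(x)
}

#' Number of unique monomer orderings of a composition
#'
#' The multinomial coefficient `dp! / prod(count_l!)`, i.e. the number of
#' distinct arrangements after filtering duplicate permutations.
#'
#' @param comp a `monomer_composition`.
#' @return a count (double; exact for all DP <= 25 compositions).
#' @examples
#' count_unique_sequences(composition_from_ratio(1.8, 5))  # 10
#' @export
count_unique_sequences <- function(comp) {
  stopifnot(inherits(comp, "monomer_composition"))
  left <- comp$dp
  total <- 1
  for (n in comp$counts) {
    total <- total * choose(left, n)
    left <- left - n
  }
  round(total)
}

# next lexicographic permutation in place; NULL when exhausted.
# operates on integer codes so duplicates are skipped naturally.
.next_perm <- function(x) {
  n <- length(x)
  i <- n - 1L
  while (i >= 1L && x[i] >= x[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (x[j] <= x[i]) j <- j - 1L
  tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  x[(i + 1L):n] <- rev(x[(i + 1L):n])
  x
}

#' Enumerate (or sample) unique monomer sequences
#'
#' If the number of unique orderings is at most `cap`, returns the complete
#' duplicate-free set in lexicographic order (G < H < S). Otherwise draws a
#' seeded uniform sample of `cap` distinct sequences (exhaustive enumeration is
#' infeasible at DP 25, where a balanced composition has ~1e10 unique
#' orderings).
#'
#' @param comp a `monomer_composition`.
#' @param cap maximum number of sequences to return (>= 1).
#' @param seed optional integer seed controlling the sampled branch; the
#'   exhaustive branch is deterministic regardless.
#' @return list of character vectors, each of length `dp`.
#' @examples
#' length(enumerate_unique_sequences(composition_from_ratio(1.8, 5)))  # 10
#' @export
enumerate_unique_sequences <- function(comp, cap = 10000L, seed = NULL) {
  stopifnot(inherits(comp, "monomer_composition"))
  if (!is.numeric(cap) || cap < 1) stop("cap must be >= 1", call. = FALSE)
  n_unique <- count_unique_sequences(comp)
  labels <- rep(names(comp$counts), comp$counts)   # G < H < S already
  if (n_unique <= cap) {
    out <- vector("list", n_unique)
    code <- match(labels, MONOMER_LABELS)          # sorted ascending
    k <- 0L
    while (!is.null(code)) {
      k <- k + 1L
      out[[k]] <- MONOMER_LABELS[code]
      code <- .next_perm(code)
    }
    stopifnot(k == n_unique)
    return(out)
  }
  # seeded rejection sampling of distinct sequences; collision probability is
  # negligible when n_unique >> cap, the loop guards the pathological tail
  runner <- function() {
    seen <- new.env(parent = emptyenv())
    out <- vector("list", cap)
    k <- 0L
    tries <- 0L
    while (k < cap && tries < 200L * cap) {
      tries <- tries + 1L
      s <- sample(labels)
      key <- paste(s, collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        k <- k + 1L
        out[[k]] <- s
      }
    }
    if (k < cap) stop("could not sample ", cap, " distinct sequences", call. = FALSE)
    out
  }
  if (is.null(seed)) runner() else with_local_seed(seed, runner())
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded library calls do not
#' disturb the caller's RNG stream.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Collapse a monomer sequence to its display string
#' @param seq character vector of labels.
#' @return single string, e.g. `"SGSGS"`.
#' @export
sequence_string <- function(seq) paste(seq, collapse = "")
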