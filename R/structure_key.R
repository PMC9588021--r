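#' Canonical structure key of a lignin graph
#'
#' A canonical string encoding of the labeled, typed monomer tree, computed
#' by minimizing a rooted tree code (sorted child codes, AHU style) over all
#' choices of root. Two graphs receive the same key iff they are isomorphic
#' as lignin structures, i.e. describe the same molecule: edge direction is
#' part of the code except for the symmetric 5-5 and beta-beta linkages, and
#' the beta-O-4 bridging a DBDO motif is coded distinctly (its chemistry
#' differs from an ordinary beta-aryl ether). The key is the package's fast
#' uniqueness test for generated structures; its agreement with canonical
#' SMILES equality is asserted in the test suite.
#'
#' @param g a `lignin_graph`.
#' @return a character key.
#' @export
structure_key <- function(g) {
  n <- length(g$labels)
  if (n == 1L) return(g$labels)
  dbdo_keys <- vapply(g$dbdo, function(m) paste(m$x, m$a), character(1))
  sym <- c("5-5", "beta-beta")
  nbr <- vector("list", n)
  for (i in seq_len(nrow(g$edges))) {
    d <- g$edges$donor[i]; a <- g$edges$acceptor[i]; ty <- g$edges$type[i]
    if (ty == "beta-O-4" && paste(d, a) %in% dbdo_keys) ty <- "DB4"
    if (ty %in% sym) {
      nbr[[d]] <- c(nbr[[d]], list(c(a, paste0("=", ty))))
      nbr[[a]] <- c(nbr[[a]], list(c(d, paste0("=", ty))))
    } else {
      nbr[[d]] <- c(nbr[[d]], list(c(a, paste0(">", ty))))
      nbr[[a]] <- c(nbr[[a]], list(c(d, paste0("<", ty))))
    }
  }
  code <- function(v, parent) {
    subs <- character(0)
    for (e in nbr[[v]]) {
      u <- as.integer(e[1L])
      if (u == parent) next
      subs <- c(subs, paste0(e[2L], code(u, v)))
    }
    paste0(g$labels[v], "(", paste(sort(subs), collapse = ","), ")")
  }
  min(vapply(seq_len(n), function(r) code(r, 0L), character(1)))
}
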