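#' @title Atom-level molecule assembly
#' @name molecule
#' @description
#' Expands a monomer-level graph into an explicit atom/bond table. Each unit
#' contributes its aromatic ring (Kekulé alternation), phenolic oxygen,
#' methoxy group(s) and the three side-chain carbons with the gamma oxygen;
#' the side chain's bonding pattern follows the unit's derived state:
#'
#' * cinnamyl end: unreacted propenol chain (alpha=beta double bond, gamma-OH);
#' * arylglycerol (ordinary beta-O-4 donor): water adds at alpha during the
#'   coupling, giving a secondary alpha-OH; beta bonds to the partner 4-O;
#' * resinol (beta-beta): the fused furofuran - beta-beta bond plus
#'   reciprocal gamma-O-alpha ether closures (pinoresinol skeleton);
#' * phenylcoumaran (beta-5 donor): dihydrobenzofuran - beta to the partner
#'   C5 with an alpha-O-4 closure; gamma-OH retained;
#' * DBDO bridge: the donor's beta-O-4 goes to one biphenyl unit and its
#'   alpha-O-4 to the other, closing the 8-membered dioxocin ring (no water
#'   at alpha).
#'
#' Hydrogens are implicit (valence completion); the elemental formula and
#' average molecular mass are computed from the atom table and cross-checked
#' elsewhere against the linkage mass-balance identity. SMILES strings are
#' emitted in Kekulé form by the package's own writer and canonicalized with
#' OpenBabel.
NULL

.VALENCE <- c(C = 4L, O = 2L)

# ring bonds of the Kekulé benzene: position pairs and orders
.RING_BONDS <- cbind(a = 1:6, b = c(2:6, 1L), order = c(2L, 1L, 2L, 1L, 2L, 1L))

#' Expand a lignin graph into an atom-level molecule
#'
#' @param g a `lignin_graph`.
#' @param lg_id optional identifier.
#' @param canonicalize compute the canonical SMILES immediately (set FALSE
#'   when canonicalizing in batch with [canonical_smiles()]).
#' @return a `lignin_structure`: atoms, bonds, per-unit atom maps, Kekulé
#'   SMILES (`smiles_kekule`), canonical SMILES (`smiles`, `NA` until
#'   canonicalized), elemental `formula`, `mw`, `dp`.
#' @examples
#' g <- grow_linear(c("G", "G"), assign_linkages(c("G", "G"), c("beta-O-4" = 1)))
#' mol <- build_molecule(g)
#' mol$formula_string  # "C20H24O7"
#' @export
build_molecule <- function(g, lg_id = NA_character_, canonicalize = TRUE) {
  validate_graph(g)
  st <- graph_sites(g)
  n <- length(g$labels)
  elems <- character(0)
  maps <- vector("list", n)
  bonds <- vector("list", 4L * n)
  nb <- 0L
  add_bond <- function(a, b, order = 1L) {
    nb <<- nb + 1L
    bonds[[nb]] <<- c(a, b, order)
  }
  for (u in seq_len(n)) {
    lab <- g$labels[u]
    state <- st$side_state[u]
    off <- length(elems)
    # ring C1-C6, phenolic O4, side chain CA/CB/CG/OG
    atoms <- c(rep("C", 6L), "O", "C", "C", "C", "O")
    map <- list(ring = off + 1:6, O4 = off + 7L, CA = off + 8L, CB = off + 9L,
                CG = off + 10L, OG = off + 11L)
    for (p in get_template(lab)$methoxy_positions) {
      atoms <- c(atoms, "O", "C")
      map[[paste0("O", p)]] <- off + length(atoms) - 1L
      map[[paste0("C", p, "m")]] <- off + length(atoms)
    }
    if (state == "arylglycerol") {
      atoms <- c(atoms, "O")
      map$OA <- off + length(atoms)
    }
    elems <- c(elems, atoms)
    maps[[u]] <- map
    for (i in seq_len(nrow(.RING_BONDS)))
      add_bond(map$ring[.RING_BONDS[i, "a"]], map$ring[.RING_BONDS[i, "b"]],
               .RING_BONDS[i, "order"])
    add_bond(map$ring[4L], map$O4)
    add_bond(map$ring[1L], map$CA)
    add_bond(map$CA, map$CB, if (state == "cinnamyl") 2L else 1L)
    add_bond(map$CB, map$CG)
    add_bond(map$CG, map$OG)
    for (p in get_template(lab)$methoxy_positions) {
      add_bond(map$ring[p], map[[paste0("O", p)]])
      add_bond(map[[paste0("O", p)]], map[[paste0("C", p, "m")]])
    }
    if (state == "arylglycerol") add_bond(map$CA, map$OA)
  }
  for (i in seq_len(nrow(g$edges))) {
    d <- maps[[g$edges$donor[i]]]; a <- maps[[g$edges$acceptor[i]]]
    switch(g$edges$type[i],
      "beta-O-4" = add_bond(d$CB, a$O4),
      "beta-beta" = {
        add_bond(d$CB, a$CB); add_bond(d$CA, a$OG); add_bond(a$CA, d$OG)
      },
      "beta-5" = { add_bond(d$CB, a$ring[5L]); add_bond(d$CA, a$O4) },
      "4-O-5" = add_bond(d$O4, a$ring[5L]),
      "5-5" = ,
      "dbdo" = add_bond(d$ring[5L], a$ring[5L])
    )
  }
  for (m in g$dbdo) add_bond(maps[[m$x]]$CA, maps[[m$b]]$O4)  # alpha-O-4 closure
  bonds <- do.call(rbind, bonds[seq_len(nb)])
  colnames(bonds) <- c("a", "b", "order")

  # implicit hydrogens by valence completion
  bsum <- integer(length(elems))
  for (i in seq_len(nrow(bonds))) {
    bsum[bonds[i, "a"]] <- bsum[bonds[i, "a"]] + bonds[i, "order"]
    bsum[bonds[i, "b"]] <- bsum[bonds[i, "b"]] + bonds[i, "order"]
  }
  h_implicit <- .VALENCE[elems] - bsum
  if (any(h_implicit < 0L))
    stop("unsatisfiable valence while building unit atoms (unit ",
         which(vapply(maps, function(m) any(unlist(m) %in% bonds[h_implicit < 0, c("a", "b")]),
                      logical(1)))[1L], ")", call. = FALSE)
  formula <- c(C = sum(elems == "C"), H = sum(h_implicit), O = sum(elems == "O"))
  struct <- structure(
    list(lg_id = lg_id, graph = g, atoms = elems, bonds = bonds,
         unit_maps = maps, h_implicit = h_implicit,
         smiles_kekule = graph_to_smiles(elems, bonds),
         smiles = NA_character_,
         formula = formula, formula_string = format_formula(formula),
         mw = formula_mass(formula), dp = n),
    class = "lignin_structure"
  )
  if (canonicalize) struct$smiles <- canonical_smiles(struct$smiles_kekule)
  struct
}

#' @export
print.lignin_structure <- function(x, ...) {
  cat(sprintf("<lignin structure%s> DP %d, %s, Mw %.1f g/mol\n  SMILES: %s\n",
              if (is.na(x$lg_id)) "" else paste0(" ", x$lg_id),
              x$dp, x$formula_string, x$mw,
              if (is.na(x$smiles)) x$smiles_kekule else x$smiles))
  invisible(x)
}

#' Kekulé SMILES for an atom/bond table
#'
#' Depth-first traversal with ring-closure digits for the non-tree bonds;
#' double bonds are written explicitly (`=`), hydrogens stay implicit.
#' @param elems character vector of element symbols.
#' @param bonds matrix with columns a, b, order.
#' @return a SMILES string.
#' @keywords internal
graph_to_smiles <- function(elems, bonds) {
  nat <- length(elems)
  if (nat == 1L) return(elems)
  nbr <- vector("list", nat)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, "a"]; b <- bonds[i, "b"]
    nbr[[a]] <- rbind(nbr[[a]], c(b, bonds[i, "order"], i))
    nbr[[b]] <- rbind(nbr[[b]], c(a, bonds[i, "order"], i))
  }
  visited <- logical(nat)
  bond_used <- logical(nrow(bonds))
  children <- vector("list", nat)   # rows: child, order
  ring_tok <- vector("list", nat)   # rows: digit, order
  digit <- 0L
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    adv <- nbr[[v]]
    advanced <- FALSE
    if (!is.null(adv)) for (r in seq_len(nrow(adv))) {
      u <- adv[r, 1L]; ord <- adv[r, 2L]; bid <- adv[r, 3L]
      if (bond_used[bid]) next
      bond_used[bid] <- TRUE
      if (!visited[u]) {
        visited[u] <- TRUE
        children[[v]] <- rbind(children[[v]], c(u, ord))
        stack <- c(stack, u)
        advanced <- TRUE
        break
      } else {                      # ring closure back to an ancestor
        digit <- digit + 1L
        ring_tok[[v]] <- rbind(ring_tok[[v]], c(digit, ord))
        ring_tok[[u]] <- rbind(ring_tok[[u]], c(digit, ord))
      }
    }
    if (!advanced) stack <- stack[-length(stack)]
  }
  bond_sym <- function(ord) if (ord == 2L) "=" else ""
  digit_tok <- function(d) if (d <= 9L) as.character(d) else sprintf("%%%d", d)
  emit <- function(v) {
    s <- elems[v]
    rt <- ring_tok[[v]]
    if (!is.null(rt)) for (r in seq_len(nrow(rt)))
      s <- paste0(s, bond_sym(rt[r, 2L]), digit_tok(rt[r, 1L]))
    ch <- children[[v]]
    if (!is.null(ch)) for (r in seq_len(nrow(ch))) {
      sub <- paste0(bond_sym(ch[r, 2L]), emit(ch[r, 1L]))
      s <- if (r < nrow(ch)) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }
  emit(1L)
}

#' Canonical SMILES via OpenBabel
#'
#' Vectorized: all strings are canonicalized in a single OpenBabel pass.
#' Identical molecular graphs map to identical strings, distinct
#' constitutional isomers to distinct strings.
#'
#' @param smiles character vector of SMILES strings (Kekulé or aromatic), or
#'   a `lignin_structure`.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  if (inherits(smiles, "lignin_structure")) smiles <- smiles$smiles_kekule
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  src <- paste(paste(smiles, seq_along(smiles)), collapse = "\n")
  out <- ChemmineOB::convertFormat(from = "SMILES", to = "CAN", source = src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(smiles))
  for (p in parts) {
    if (length(p) < 2L) next
    idx <- suppressWarnings(as.integer(trimws(p[2L])))
    if (!is.na(idx)) res[idx] <- trimws(p[1L])
  }
  if (anyNA(res) || any(res == ""))
    stop("canonicalization error: OpenBabel rejected ",
         sum(is.na(res) | res == ""), " SMILES string(s)", call. = FALSE)
  res
}

#' Expected molecular mass from the linkage mass balance
#'
#' Every radical coupling costs two hydrogens; ordinary beta-O-4 couplings
#' additionally hydrate at the alpha carbon (net +O per bond), while the
#' beta-O-4 inside a DBDO motif closes with alpha-O-4 instead and takes no
#' water. This is an independent route to the molecular mass, used to
#' cross-check the atom-table formula.
#'
#' @param g a `lignin_graph`.
#' @return expected mass in g/mol.
#' @export
linkage_mass_balance <- function(g) {
  n_edges <- nrow(g$edges)
  dbdo_keys <- vapply(g$dbdo, function(m) paste(m$x, m$a), character(1))
  bo4 <- g$edges$type == "beta-O-4"
  hydrated <- bo4 & !(paste(g$edges$donor, g$edges$acceptor) %in% dbdo_keys)
  # hydrated beta-O-4: -2H from the radical coupling, +H2O at alpha (net +O);
  # every other coupling (incl. the DBDO-internal beta-O-4): -2H
  sum(monomer_mass(g$labels)) +
    .ATOMIC_MASS[["O"]] * sum(hydrated) -
    2 * .ATOMIC_MASS[["H"]] * (n_edges - sum(hydrated))
}

#' Number of rings implied by a structure's motifs
#'
#' Cycle rank oracle: one benzene ring per unit, two fused tetrahydrofuran
#' rings per resinol, one coumaran ring per beta-5, one dioxocin ring per
#' DBDO motif.
#' @param g a `lignin_graph`.
#' @return expected ring count (cycle rank of the atom graph).
#' @export
expected_ring_count <- function(g) {
  length(g$labels) + 2L * sum(g$edges$type == "beta-beta") +
    sum(g$edges$type == "beta-5") + length(g$dbdo)
}

#' Create an empty seen-SMILES registry
#' @return an environment usable as the `seen` argument of
#'   [validate_structure()].
#' @export
seen_smiles <- function() new.env(parent = emptyenv())

#' Apply the structure acceptance criteria
#'
#' A structure is accepted iff its SMILES is valid (canonicalization
#' succeeded), not yet present in `seen`, and its node count matches the
#' requested degree of polymerization. Accepted keys are added to `seen`.
#' Rejection is a value, not an error.
#'
#' @param struct a `lignin_structure` (canonicalized).
#' @param requested_dp the DP the generation run asked for.
#' @param seen registry from [seen_smiles()].
#' @param key uniqueness key; defaults to the canonical SMILES. Large
#'   statistical runs pass [structure_key()] instead (equivalent, much
#'   faster).
#' @return list with `accepted` (logical) and `reason`
#'   (`"ok"`, `"invalid-smiles"`, `"duplicate"`, `"dp-mismatch"`).
#' @export
validate_structure <- function(struct, requested_dp, seen, key = NULL) {
  if (is.null(key)) key <- struct$smiles
  if (is.na(key) || !nzchar(key))
    return(list(accepted = FALSE, reason = "invalid-smiles"))
  if (struct$dp != requested_dp)
    return(list(accepted = FALSE, reason = "dp-mismatch"))
  if (!is.null(seen[[key]]))
    return(list(accepted = FALSE, reason = "duplicate"))
  seen[[key]] <- TRUE
  list(accepted = TRUE, reason = "ok")
}

#' Write a structure to a V2000 MOL file
#'
#' Coordinates come from OpenBabel's distance-geometry 3D embedding; if the
#' embedding fails the writer falls back to 2D layout with a warning.
#'
#' @param struct a `lignin_structure`.
#' @param path output path.
#' @param dims 3 (default) or 2.
#' @return `path`, invisibly.
#' @export
write_mol <- function(struct, path, dims = 3) {
  smi <- if (!is.na(struct$smiles)) struct$smiles else struct$smiles_kekule
  gen <- if (dims == 3) "gen3D" else "gen2D"
  mol <- tryCatch(
    ChemmineOB::convertFormat(from = "SMILES", to = "MOL", source = smi,
                              options = data.frame(names = gen, args = "")),
    error = function(e) "")
  if (!nzchar(mol) && dims == 3) {
    warning("3D embedding failed; falling back to 2D coordinates", call. = FALSE)
    mol <- ChemmineOB::convertFormat(from = "SMILES", to = "MOL", source = smi,
                                     options = data.frame(names = "gen2D", args = ""))
  }
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1L]]
  if (!is.na(struct$lg_id)) lines[1L] <- struct$lg_id
  writeLines(lines, path)
  invisible(path)
}

#' Canonical SMILES of a MOL file
#' @param path a MOL/SDF file.
#' @return canonical SMILES string.
#' @export
read_mol_smiles <- function(path) {
  out <- ChemmineOB::convertFormat(from = "MOL", to = "CAN",
                                   source = paste(readLines(path), collapse = "\n"))
  trimws(strsplit(out, "\t", fixed = TRUE)[[1L]][1L])
}
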