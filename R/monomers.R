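#' @title Monolignol building blocks
#' @name monomers
#' @description
#' Lignin is assembled from three phenylpropanoid precursors (monolignols):
#' p-coumaryl alcohol (H), coniferyl alcohol (G) and sinapyl alcohol (S).
#' All three share a common scaffold: an aromatic ring numbered 1-6 with the
#' C3 side chain (carbons alpha, beta, gamma, gamma-hydroxyl) at position 1
#' and the phenolic oxygen at position 4. G carries one methoxy group
#' (position 3), S carries two (positions 3 and 5); the methoxy at position 5
#' blocks the C5 coupling site, which is why S units never form 5-5 or
#' beta-5 bonds at their own ring.
NULL

# average atomic masses (polymer-chemistry Mw convention)
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999)

MONOMER_LABELS <- c("G", "H", "S")

.make_template <- function(label, methoxy) {
  sites <- c("beta", "4-O")
  if (!(5L %in% methoxy)) sites <- c(sites, "5")
  structure(
    list(
      label = label,
      ring_atoms = 1:6,               # position 1: side chain; position 4: phenolic O
      side_chain = c("alpha", "beta", "gamma"),
      methoxy_positions = methoxy,
      reactive_sites = sites,
      formula = c(C = 9L + length(methoxy),
                  H = 10L + 2L * length(methoxy),
                  O = 2L + length(methoxy))
    ),
    class = "monomer_template"
  )
}

.MONOMER_TEMPLATES <- list(
  H = .make_template("H", integer(0)),
  G = .make_template("G", 3L),
  S = .make_template("S", c(3L, 5L))
)

#' Retrieve the template for a monolignol
#'
#' @param label one of `"H"`, `"G"`, `"S"`.
#' @return A `monomer_template` with ring/side-chain atom naming, methoxy
#'   positions, reactive sites and the free-monomer elemental formula.
#' @examples
#' get_template("G")$methoxy_positions  # 3
#' get_template("S")$reactive_sites     # no "5": blocked by the 5-methoxy
#' @export
get_template <- function(label) {
  if (!(is.character(label) && length(label) == 1L && label %in% MONOMER_LABELS))
    stop("unknown monomer label: ", paste(label, collapse = ","), call. = FALSE)
  .MONOMER_TEMPLATES[[label]]
}

#' @export
print.monomer_template <- function(x, ...) {
  cat(sprintf("<monolignol %s> formula %s, methoxy at {%s}, reactive sites {%s}\n",
              x$label, format_formula(x$formula),
              paste(x$methoxy_positions, collapse = ","),
              paste(x$reactive_sites, collapse = ",")))
  invisible(x)
}

#' Average molecular mass of a free monolignol
#'
#' @param label one of `"H"`, `"G"`, `"S"` (vectorized).
#' @return mass in g/mol (average atomic masses).
#' @examples
#' monomer_mass("G")  # 180.20
#' @export
monomer_mass <- function(label) {
  vapply(label, function(l) formula_mass(get_template(l)$formula), numeric(1),
         USE.NAMES = length(label) > 1L)
}

#' Mass of an elemental formula
#' @param formula named integer vector over C/H/O.
#' @return mass in g/mol.
#' @keywords internal
formula_mass <- function(formula) {
  sum(.ATOMIC_MASS[names(formula)] * formula)
}

#' Format a C/H/O count vector as a Hill-order formula string
#' @keywords internal
format_formula <- function(formula) {
  paste0(vapply(c("C", "H", "O"), function(el) {
    n <- formula[[el]]
    if (is.na(n) || n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}
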