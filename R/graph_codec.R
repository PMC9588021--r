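#' @title Topological matrix encoding
#' @name graph_codec
#' @description
#' Each structure graph is encoded as a pair of n-by-n matrices: the
#' adjacency matrix (`[i, j] = 1` iff unit i donates a bond to unit j) and
#' the connectivity matrix, whose non-empty cells carry a paired site code
#' `donor-acceptor` naming the occupied bond positions: `B` the beta carbon,
#' `4` the phenolic 4-O, `5` the ring C5. Composite codes mark DBDO motif
#' edges (`DB4` for the bridging beta-O-4, `D55` for the biphenyl pair), so
#' the encoding inverts losslessly.
NULL

.EDGE_CODE <- c("beta-O-4" = "B-4", "beta-beta" = "B-B", "beta-5" = "B-5",
                "4-O-5" = "4-5", "5-5" = "5-5", "dbdo" = "D55")

#' Encode a lignin graph as topological matrices
#'
#' @param g a `lignin_graph`.
#' @return a `topological_matrices` list: `adjacency` (integer), `connectivity`
#'   (character, `""` where no bond), `labels`, `lg_id`.
#' @param lg_id optional structure identifier carried into the CSV header.
#' @export
to_matrices <- function(g, lg_id = NA_character_) {
  validate_graph(g)
  n <- length(g$labels)
  adjacency <- matrix(0L, n, n)
  connectivity <- matrix("", n, n)
  dbdo_x <- vapply(g$dbdo, `[[`, integer(1), "x")
  dbdo_a <- vapply(g$dbdo, `[[`, integer(1), "a")
  for (i in seq_len(nrow(g$edges))) {
    d <- g$edges$donor[i]; a <- g$edges$acceptor[i]; ty <- g$edges$type[i]
    code <- .EDGE_CODE[[ty]]
    if (ty == "beta-O-4" && length(dbdo_x) &&
        any(dbdo_x == d & dbdo_a == a)) code <- "DB4"
    adjacency[d, a] <- 1L
    connectivity[d, a] <- code
  }
  structure(list(adjacency = adjacency, connectivity = connectivity,
                 labels = g$labels, lg_id = lg_id),
            class = "topological_matrices")
}

#' Decode topological matrices back into a lignin graph
#'
#' @param m a `topological_matrices`.
#' @return the `lignin_graph` such that `to_matrices(from_matrices(m))`
#'   reproduces `m`; malformed input (cycles, disconnection, unknown codes)
#'   raises an error.
#' @export
from_matrices <- function(m) {
  n <- length(m$labels)
  if (!is.matrix(m$adjacency) || !all(dim(m$adjacency) == n) ||
      !is.matrix(m$connectivity) || !all(dim(m$connectivity) == n))
    stop("malformed matrices: dimensions do not match the label count", call. = FALSE)
  if (any(diag(m$adjacency) != 0L)) stop("malformed matrices: nonzero diagonal", call. = FALSE)
  if (any((m$adjacency == 1L) != (m$connectivity != "")))
    stop("malformed matrices: adjacency and connectivity disagree", call. = FALSE)
  idx <- which(m$adjacency == 1L, arr.ind = TRUE)
  codes <- m$connectivity[idx]
  rev_code <- c(`B-4` = "beta-O-4", `B-B` = "beta-beta", `B-5` = "beta-5",
                `4-5` = "4-O-5", `5-5` = "5-5", D55 = "dbdo", DB4 = "beta-O-4")
  if (!all(codes %in% names(rev_code)))
    stop("malformed matrices: unknown connectivity code(s): ",
         paste(setdiff(codes, names(rev_code)), collapse = ", "), call. = FALSE)
  edges <- data.frame(donor = idx[, 1L], acceptor = idx[, 2L],
                      type = unname(rev_code[codes]), stringsAsFactors = FALSE)
  # rebuild DBDO motifs: D55 joins the biphenyl pair (a, b); the bridging
  # donor x is the DB4 edge into a
  dbdo <- list()
  for (j in which(codes == "D55")) {
    a <- idx[j, 1L]; b <- idx[j, 2L]
    src <- which(codes == "DB4" & idx[, 2L] == a)
    if (length(src) != 1L)
      stop("malformed matrices: D55 edge without a matching DB4 edge", call. = FALSE)
    dbdo[[length(dbdo) + 1L]] <- list(x = idx[src, 1L], a = a, b = b)
  }
  tryCatch(lignin_graph(m$labels, edges, dbdo),
           error = function(e) stop("malformed matrices: ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write topological matrices to CSV
#'
#' One file per structure, with two labeled blocks (`adjacency`,
#' `connectivity`) sharing a unit-label header, preceded by `lg_id` and
#' `labels` header rows.
#'
#' @param m a `topological_matrices`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrices_csv <- function(m, path) {
  n <- length(m$labels)
  unit <- paste0("u", seq_len(n))
  lines <- c(
    paste0("lg_id,", if (is.na(m$lg_id)) "" else m$lg_id),
    paste0("labels,", paste(m$labels, collapse = ",")),
    "adjacency",
    paste0(",", paste(unit, collapse = ",")),
    vapply(seq_len(n), function(i)
      paste0(unit[i], ",", paste(m$adjacency[i, ], collapse = ",")), character(1)),
    "connectivity",
    paste0(",", paste(unit, collapse = ",")),
    vapply(seq_len(n), function(i)
      paste0(unit[i], ",", paste(m$connectivity[i, ], collapse = ",")), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read topological matrices from CSV
#'
#' @param path file written by [write_matrices_csv()].
#' @return a `topological_matrices`; parse failures report the line number.
#' @export
read_matrices_csv <- function(path) {
  lines <- readLines(path)
  fail <- function(lineno, msg)
    stop(sprintf("CSV format error at line %d of %s: %s", lineno, path, msg),
         call. = FALSE)
  if (length(lines) < 6L || !startsWith(lines[1L], "lg_id,")) fail(1L, "missing lg_id header")
  lg_id <- sub("^lg_id,", "", lines[1L])
  if (lg_id == "") lg_id <- NA_character_
  if (!startsWith(lines[2L], "labels,")) fail(2L, "missing labels header")
  labels <- strsplit(sub("^labels,", "", lines[2L]), ",", fixed = TRUE)[[1L]]
  n <- length(labels)
  if (n < 1L) fail(2L, "no labels")
  if (lines[3L] != "adjacency") fail(3L, "expected 'adjacency' block")
  if (length(lines) < 5L + 2L * n + 1L) fail(length(lines), "truncated file")
  read_block <- function(start) {
    vals <- lapply(seq_len(n), function(i) {
      ln <- start + i
      parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1L]]
      # trailing empty cells are dropped by strsplit; pad
      parts <- c(parts, rep("", n + 1L - length(parts)))
      if (length(parts) != n + 1L) fail(ln, sprintf("expected %d cells", n + 1L))
      parts[-1L]
    })
    do.call(rbind, vals)
  }
  adjacency <- read_block(4L)
  suppressWarnings(storage <- matrix(as.integer(adjacency), n, n))
  if (anyNA(storage)) fail(5L, "non-integer adjacency entry")
  if (lines[4L + n + 1L] != "connectivity") fail(4L + n + 1L, "expected 'connectivity' block")
  connectivity <- read_block(5L + n + 1L)
  m <- structure(list(adjacency = storage, connectivity = connectivity,
                      labels = labels, lg_id = lg_id),
                 class = "topological_matrices")
  from_matrices(m)  # validates; discard result
  m
}
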