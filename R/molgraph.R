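# Valence-annotated molecular graph model and extraction of the
# pi-assignment problem.
#
# Internal representation of a "molgraph": a list with parallel atom
# vectors (element, valence, implicit_h), an optional coordinate matrix,
# and parallel bond vectors (bond_a, bond_b, order).  Bond order 0L means
# UNRESOLVED (an aromatic/pi bond whose final order is not yet known);
# resolved orders are 1, 2 or 3.  Atom indices are 1-based in R.

#' Bond-order code for an unresolved (aromatic) bond
#'
#' Bonds whose final order is to be determined by kekulization carry this
#' order code. Resolved bonds carry 1, 2 or 3.
#' @export
BOND_UNRESOLVED <- 0L

.default_valences <- c(C = 4L, N = 3L, H = 1L)

#' Build a molecular graph from atom and bond tables
#'
#' Constructs a valence-annotated molecular graph.  Hydrogens are normally
#' stored as implicit counts on heavy atoms (`implicit_h`) rather than as
#' graph nodes, but explicit H atoms are permitted.
#'
#' @param atoms data frame with columns `element` (symbol, e.g. `"C"`),
#'   optional `valence` (defaults to the element's standard valence:
#'   C=4, N=3, H=1), optional `implicit_h` (default 0).
#' @param bonds data frame (or 2/3-column matrix) with columns `a`, `b`
#'   (1-based atom indices) and optional `order` (1, 2, 3 or
#'   [BOND_UNRESOLVED]; default unresolved).
#' @param coords optional numeric matrix (n x 3) of coordinates in
#'   Angstroms.
#' @param valences named integer vector extending/overriding the default
#'   element-to-valence map.
#' @return an object of class `molgraph`.
#' @examples
#' benzene <- build_molecule(
#'   data.frame(element = "C", implicit_h = 1)[rep(1, 6), ],
#'   data.frame(a = 1:6, b = c(2:6, 1)))
#' molecular_formula(benzene)
#' @export
build_molecule <- function(atoms, bonds, coords = NULL, valences = NULL) {
  vmap <- .default_valences
  if (!is.null(valences)) vmap[names(valences)] <- as.integer(valences)
  element <- as.character(atoms$element)
  n <- length(element)
  if (n == 0L) stop("molecule must contain at least one atom")
  valence <- if (!is.null(atoms$valence)) as.integer(atoms$valence) else {
    v <- vmap[element]
    if (anyNA(v)) {
      stop("no default valence for element(s): ",
           paste(unique(element[is.na(v)]), collapse = ", "))
    }
    as.integer(v)
  }
  implicit_h <- if (!is.null(atoms$implicit_h)) {
    as.integer(atoms$implicit_h)
  } else {
    integer(n)
  }
  if (any(implicit_h < 0L)) stop("implicit_h must be non-negative")

  if (is.matrix(bonds)) bonds <- as.data.frame(bonds)
  if (is.null(bonds$a) && ncol(bonds) >= 2L) names(bonds)[1:2] <- c("a", "b")
  a <- as.integer(bonds$a)
  b <- as.integer(bonds$b)
  ord <- if (!is.null(bonds$order)) as.integer(bonds$order) else {
    rep(BOND_UNRESOLVED, length(a))
  }
  .validate_bonds(n, a, b, ord)

  g <- structure(list(
    element = element, valence = valence, implicit_h = implicit_h,
    coords = coords, bond_a = a, bond_b = b, order = ord
  ), class = "molgraph")
  .check_valences(g)
  g
}

# sum of bond-order contributions at each atom (unresolved counted at 1)
.bond_load <- function(n, bond_a, bond_b, ord) {
  if (!length(bond_a)) return(integer(n))
  ends <- c(bond_a, bond_b)
  contrib <- tabulate(ends, nbins = n)
  w_extra <- pmax(ord, 1L) - 1L          # 0 except for orders 2 and 3
  hot <- which(w_extra > 0L)
  if (length(hot)) {
    extra_ends <- rep(c(bond_a[hot], bond_b[hot]), rep(w_extra[hot], 2L))
    contrib <- contrib + tabulate(extra_ends, nbins = n)
  }
  contrib
}

.validate_bonds <- function(n, a, b, ord) {
  if (length(a)) {
    if (any(a < 1L | a > n | b < 1L | b > n)) {
      stop("bond endpoint index out of range")
    }
    if (any(a == b)) stop("structural error: bond with identical endpoints")
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) {
      stop("structural error: duplicate bond between an atom pair")
    }
    if (!all(ord %in% c(0L, 1L, 2L, 3L))) {
      stop("bond order must be 1, 2, 3 or BOND_UNRESOLVED")
    }
  }
  invisible(TRUE)
}

# each incident bond contributes at least order 1, so valence must cover
# implicit H plus the incident-bond count
.check_valences <- function(g) {
  n <- length(g$element)
  # resolved bonds contribute their full order; unresolved at least 1
  load <- g$implicit_h + .bond_load(n, g$bond_a, g$bond_b, g$order)
  bad <- which(load > g$valence)
  if (length(bad)) {
    stop("valence error: atom(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " exceed their valence (", g$element[bad[1]], " valence ",
         g$valence[bad[1]], ", load ", load[bad[1]], ")")
  }
  invisible(TRUE)
}

#' Number of atoms in a molecular graph
#' @param graph a `molgraph`.
#' @return integer atom count (explicit atoms only).
#' @export
n_atoms <- function(graph) length(graph$element)

#' Number of bonds in a molecular graph
#' @param graph a `molgraph`.
#' @return integer bond count.
#' @export
n_bonds <- function(graph) length(graph$bond_a)

#' Per-atom pi-deficiency
#'
#' The pi-deficiency of an atom is its valence minus its implicit-hydrogen
#' count minus the bond-order load of its incident bonds, where unresolved
#' bonds are counted at order 1 and resolved bonds at their full order.
#' It is the number of extra bond-order units the atom must receive during
#' kekulization: 1 for an aromatic carbon, 2 for an acetylenic or
#' cumulenic carbon, 0 for a saturated atom or a trivalent nitrogen with
#' three single bonds.
#'
#' @param graph a `molgraph`.
#' @return integer vector of deficiencies, one per atom.
#' @export
pi_deficiency <- function(graph) {
  n <- length(graph$element)
  contrib <- .bond_load(n, graph$bond_a, graph$bond_b, graph$order)
  d <- graph$valence - graph$implicit_h - contrib
  bad <- which(d < 0L | d > 2L)
  if (length(bad)) {
    stop("unsupported hybridization: atom(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " have pi-deficiency outside {0, 1, 2} (got ", d[bad[1]], ")")
  }
  d
}

#' Extract the pi-assignment problem from a molecular graph
#'
#' Collects the atoms with positive pi-deficiency and the unresolved bonds
#' between them into a demand/capacity system: each member atom demands
#' `d` in \{1, 2\} units of extra bond order and each unresolved bond can
#' carry a pi-order of 0, 1 or 2 (final bond order = 1 + pi-order).
#'
#' @param graph a `molgraph`.
#' @return an object of class `pi_system`: a list with `members` (atom
#'   indices into the graph), `d` (their deficiencies), `edges` (indices
#'   of the unresolved bonds in the graph's bond list), `ea`/`eb`
#'   (member-local 1-based endpoints of those edges) and a CSR adjacency
#'   (`ptr`, `adj_edge`, `adj_nbr`, all 0-based) used by the kekulizer.
#' @export
extract_pi_system <- function(graph) {
  d_all <- pi_deficiency(graph)
  members <- which(d_all > 0L)
  unres <- which(graph$order == BOND_UNRESOLVED)
  if (length(unres)) {
    ok <- d_all[graph$bond_a[unres]] > 0L & d_all[graph$bond_b[unres]] > 0L
    if (!all(ok)) {
      stop("inconsistency: unresolved bond incident to an atom with ",
           "pi-deficiency 0 (bond ", unres[which(!ok)[1]], ")")
    }
  }
  local <- integer(length(graph$element))
  local[members] <- seq_along(members)
  ea <- local[graph$bond_a[unres]]
  eb <- local[graph$bond_b[unres]]
  m <- length(members)
  csr <- .build_csr(m, ea, eb)
  structure(c(list(
    members = members, d = d_all[members],
    edges = unres, ea = ea, eb = eb), csr),
    class = "pi_system")
}

# CSR adjacency over m member atoms (0-based, for the C++ kernels)
.build_csr <- function(m, ea, eb) {
  ne <- length(ea)
  deg <- tabulate(c(ea, eb), nbins = m)
  ptr <- c(0L, cumsum(deg))
  adj_edge <- integer(2L * ne)
  adj_nbr <- integer(2L * ne)
  if (ne) {
    at_all <- c(ea, eb)
    nbr_all <- c(eb, ea)
    e_all <- rep.int(seq_len(ne), 2L)
    o <- order(at_all, method = "radix")
    idx <- sequence(tabulate(at_all[o], nbins = m)) + ptr[at_all[o]]
    adj_edge[idx] <- e_all[o] - 1L
    adj_nbr[idx] <- nbr_all[o] - 1L
  }
  list(ptr = ptr, adj_edge = adj_edge, adj_nbr = adj_nbr)
}

#' Validate a pi-order assignment
#'
#' Checks that an assignment of pi-orders to the unresolved bonds of a
#' graph satisfies every member atom's pi-deficiency exactly, i.e. that
#' applying the assignment (final order = 1 + pi-order) satisfies all
#' valences.
#'
#' @param graph a `molgraph`.
#' @param assignment integer vector of pi-orders in \{0, 1, 2\}, one per
#'   unresolved bond, in the edge order of [extract_pi_system()].
#' @return `TRUE` if every member atom's incident pi-orders sum to its
#'   deficiency, else `FALSE`.
#' @export
validate_assignment <- function(graph, assignment) {
  ps <- extract_pi_system(graph)
  if (length(assignment) != length(ps$edges)) {
    stop("assignment must cover all ", length(ps$edges), " pi-system edges")
  }
  assignment <- as.integer(assignment)
  if (!all(assignment %in% 0:2)) return(FALSE)
  m <- length(ps$members)
  got <- tabulate(rep(c(ps$ea, ps$eb), rep(assignment, 2L)), nbins = m)
  all(got == ps$d)
}

#' Resolve a graph's unresolved bonds using a pi-order assignment
#'
#' @param graph a `molgraph`.
#' @param assignment pi-orders as in [validate_assignment()].
#' @return a `molgraph` with all bonds resolved (order = 1 + pi-order for
#'   previously unresolved bonds).
#' @export
apply_assignment <- function(graph, assignment) {
  ps <- extract_pi_system(graph)
  if (!validate_assignment(graph, assignment)) {
    stop("assignment does not satisfy all pi-deficiencies")
  }
  graph$order[ps$edges] <- 1L + as.integer(assignment)
  graph
}

#' Molecular formula of a graph
#'
#' Counts each element, including implicit hydrogens, and formats the
#' result in Hill order (C, H, then other elements alphabetically).
#'
#' @param graph a `molgraph`.
#' @param as_string return the formatted string instead of named counts.
#' @return named integer vector of element counts, or a string such as
#'   `"C20H14N4"`.
#' @export
molecular_formula <- function(graph, as_string = FALSE) {
  counts <- table(graph$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  h_imp <- sum(graph$implicit_h)
  if (h_imp > 0L) {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h_imp
  }
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  counts <- counts[hill]
  if (!as_string) return(counts)
  paste0(vapply(seq_along(counts), function(i) {
    paste0(names(counts)[i], if (counts[i] > 1L) counts[i] else "")
  }, character(1)), collapse = "")
}

#' @export
print.molgraph <- function(x, ...) {
  d <- pi_deficiency(x)
  cat("<molgraph> ", molecular_formula(x, as_string = TRUE), "\n", sep = "")
  cat("  atoms: ", length(x$element), " (", sum(x$implicit_h),
      " implicit H); bonds: ", length(x$bond_a), " (",
      sum(x$order == BOND_UNRESOLVED), " unresolved)\n", sep = "")
  cat("  pi-system: ", sum(d > 0L), " atoms, total deficiency ", sum(d),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.pi_system <- function(x, ...) {
  cat("<pi_system> ", length(x$members), " member atoms (",
      sum(x$d == 1L), " with d=1, ", sum(x$d == 2L), " with d=2), ",
      length(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Expand implicit hydrogens to explicit atoms
#'
#' Returns a graph in which every implicit hydrogen becomes an explicit H
#' atom bonded by a single bond to its heavy atom.  Coordinates, if any,
#' are dropped (hydrogen positions are not modelled).
#'
#' @param graph a `molgraph`.
#' @return a `molgraph` with `implicit_h` all zero.
#' @export
expand_hydrogens <- function(graph) {
  nh <- sum(graph$implicit_h)
  if (nh == 0L) return(graph)
  n <- length(graph$element)
  heavy <- rep(seq_len(n), graph$implicit_h)
  graph$element <- c(graph$element, rep("H", nh))
  graph$valence <- c(graph$valence, rep(1L, nh))
  graph$implicit_h <- c(integer(n) , integer(nh))
  graph$bond_a <- c(graph$bond_a, heavy)
  graph$bond_b <- c(graph$bond_b, n + seq_len(nh))
  graph$order <- c(graph$order, rep(1L, nh))
  graph$coords <- NULL
  graph
}
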