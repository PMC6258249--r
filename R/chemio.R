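# MDL molfile (V2000/V3000) and XYZ input/output.
#
# Conventions: molfile bond type 4 (aromatic/query) maps to
# BOND_UNRESOLVED; types 1/2/3 map to resolved orders.  Atom indices are
# 1-based on file, matching the in-memory 1-based representation.  V2000
# is limited to 999 atoms/bonds by its fixed-width counts line; the
# writer auto-selects V3000 beyond that.

#' Read an MDL molfile
#'
#' Parses a V2000 or V3000 connection table.  Bond type 4 becomes an
#' unresolved bond; types 1-3 become resolved orders.  Implicit hydrogens
#' are inferred from the valence deficit: for an atom with no unresolved
#' bonds the deficit is `valence - sum(bond orders)`; for an atom in the
#' pi-system one unit is reserved for the pi-bond it must receive
#' (aromatic atoms are assumed to have pi-deficiency 1 unless the molfile
#' valence field says otherwise).  Files containing explicit hydrogen
#' atoms are taken to have all hydrogens explicit: H atoms are kept as
#' graph nodes and no implicit inference is applied.
#'
#' @param con a file path or text (character vector of lines or a single
#'   string with newlines).
#' @param valences named integer vector overriding default element
#'   valences (C=4, N=3, H=1).
#' @return a `molgraph`.
#' @export
read_molfile <- function(con, valences = NULL) {
  lines <- .as_lines(con)
  if (length(lines) < 4L) stop("malformed molfile: fewer than 4 lines")
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    return(.read_v3000(lines, valences))
  }
  if (!grepl("V2000", counts, fixed = TRUE)) {
    # tolerate files that omit the version tag but have a counts line
    if (nchar(trimws(counts)) == 0L) stop("malformed counts line")
  }
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed counts line: ", counts)
  if (length(lines) < 4L + na + nb) stop("molfile truncated")
  atom_lines <- lines[5:(4 + na)]
  element <- trimws(substr(atom_lines, 32, 34))
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  z <- as.numeric(substr(atom_lines, 21, 30))
  # valence field (columns 49-51): 0 = default, 15 = zero
  vfield <- suppressWarnings(as.integer(substr(atom_lines, 49, 51)))
  vfield[is.na(vfield)] <- 0L
  bond_a <- integer(0); bond_b <- integer(0); btype <- integer(0)
  if (nb > 0L) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    bond_a <- as.integer(substr(bond_lines, 1, 3))
    bond_b <- as.integer(substr(bond_lines, 4, 6))
    btype <- as.integer(substr(bond_lines, 7, 9))
  }
  .molfile_graph(element, cbind(x, y, z), vfield, bond_a, bond_b, btype,
                 valences)
}

.read_v3000 <- function(lines, valences) {
  grab <- function(tag) grep(tag, lines, fixed = TRUE)
  ctab <- grab("M  V30 COUNTS")
  if (!length(ctab)) stop("malformed V3000: no COUNTS line")
  cnt <- strsplit(trimws(sub("M  V30 COUNTS", "", lines[ctab[1]])), "\\s+")[[1]]
  na <- as.integer(cnt[1]); nb <- as.integer(cnt[2])
  ab <- grab("M  V30 BEGIN ATOM"); ae <- grab("M  V30 END ATOM")
  if (!length(ab) || !length(ae)) stop("malformed V3000: no atom block")
  atom_lines <- lines[(ab[1] + 1L):(ae[1] - 1L)]
  tok <- strsplit(trimws(sub("^M  V30 ", "", atom_lines)), "\\s+")
  idx <- vapply(tok, function(t) as.integer(t[1]), integer(1))
  element <- vapply(tok, function(t) t[2], character(1))
  coords <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3)))
  vfield <- vapply(tok, function(t) {
    m <- grep("^VAL=", t, value = TRUE)
    if (length(m)) as.integer(sub("VAL=", "", m[1])) else 0L
  }, integer(1))
  o <- order(idx)
  element <- element[o]; coords <- coords[o, , drop = FALSE]
  vfield <- vfield[o]
  if (length(element) != na) stop("V3000 atom count mismatch")
  bond_a <- integer(0); bond_b <- integer(0); btype <- integer(0)
  bb <- grab("M  V30 BEGIN BOND"); be <- grab("M  V30 END BOND")
  if (length(bb) && length(be) && be[1] > bb[1] + 1L) {
    bond_lines <- lines[(bb[1] + 1L):(be[1] - 1L)]
    btok <- strsplit(trimws(sub("^M  V30 ", "", bond_lines)), "\\s+")
    btype <- vapply(btok, function(t) as.integer(t[2]), integer(1))
    bond_a <- vapply(btok, function(t) as.integer(t[3]), integer(1))
    bond_b <- vapply(btok, function(t) as.integer(t[4]), integer(1))
  }
  if (length(bond_a) != nb) stop("V3000 bond count mismatch")
  .molfile_graph(element, coords, vfield, bond_a, bond_b, btype, valences)
}

# shared post-processing: map bond types, infer implicit hydrogens
.molfile_graph <- function(element, coords, vfield, bond_a, bond_b, btype,
                           valences) {
  vmap <- .default_valences
  if (!is.null(valences)) vmap[names(valences)] <- as.integer(valences)
  n <- length(element)
  if (length(bond_a)) {
    if (any(is.na(bond_a)) || any(is.na(bond_b)) ||
        any(bond_a < 1L | bond_a > n | bond_b < 1L | bond_b > n)) {
      stop("bond index out of range")
    }
    if (!all(btype %in% 1:4)) {
      stop("unsupported bond type: ",
           paste(unique(btype[!btype %in% 1:4]), collapse = ", "))
    }
  }
  ord <- ifelse(btype == 4L, BOND_UNRESOLVED, btype)
  valence <- unname(vmap[element])
  if (anyNA(valence)) {
    stop("no default valence for element(s): ",
         paste(unique(element[is.na(valence)]), collapse = ", "))
  }
  vexp <- ifelse(vfield == 15L, 0L, ifelse(vfield > 0L, vfield, valence))
  load <- .bond_load(n, bond_a, bond_b, as.integer(ord))
  n_unres <- integer(n)
  if (length(bond_a)) {
    unres_ends <- c(bond_a, bond_b)[c(ord, ord) == BOND_UNRESOLVED]
    n_unres <- tabulate(unres_ends, nbins = n)
  }
  if (any(element == "H")) {
    # explicit-hydrogen file: take hydrogens as given, leave the rest to
    # deficiency logic
    implicit_h <- integer(n)
  } else {
    # reserve one unit of pi-order for atoms that sit in the pi-system
    # (aromatic atoms assumed pi-deficiency 1 unless VAL= says otherwise)
    implicit_h <- pmax(vexp - load - ifelse(n_unres > 0L, 1L, 0L), 0L)
  }
  build_molecule(
    data.frame(element = element, valence = as.integer(vexp),
               implicit_h = as.integer(implicit_h)),
    data.frame(a = bond_a, b = bond_b, order = as.integer(ord)),
    coords = if (all(coords == 0)) NULL else coords)
}

.as_lines <- function(con) {
  if (length(con) == 1L && !grepl("\n", con) && file.exists(con)) {
    lines <- readLines(con, warn = FALSE)
  } else if (length(con) == 1L && grepl("\n", con)) {
    lines <- strsplit(con, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(con)
  }
  sub("\r$", "", lines)   # normalize line endings
}

#' Write an MDL molfile
#'
#' Writes V2000 when the structure fits (at most 999 atoms and bonds),
#' V3000 otherwise; `dialect` can force either (forcing V2000 on a
#' too-large structure is an error directing to V3000).  With
#' `kekulized = TRUE` the writer refuses unresolved bonds, guaranteeing a
#' fully bond-order-assigned file.  Implicit hydrogens can be expanded to
#' explicit atoms with `explicit_h = TRUE`; otherwise the atom valence
#' field (V2000 columns 49-51, V3000 `VAL=`) records non-default
#' valences so that hydrogen counts survive a round trip.
#'
#' @param graph a `molgraph`.
#' @param path optional output file; when `NULL` the text is returned.
#' @param dialect `"auto"`, `"molfile_v2000"` or `"molfile_v3000"`.
#' @param kekulized refuse unresolved bonds (default `FALSE`).
#' @param explicit_h expand implicit hydrogens to explicit atoms.
#' @param title molfile header title line.
#' @return invisibly, the lines written (or the lines, visibly, when
#'   `path` is `NULL`).
#' @export
write_molfile <- function(graph, path = NULL,
                          dialect = c("auto", "molfile_v2000",
                                      "molfile_v3000"),
                          kekulized = FALSE, explicit_h = FALSE,
                          title = "kekule") {
  stopifnot(inherits(graph, "molgraph"))
  dialect <- match.arg(dialect)
  if (kekulized && any(graph$order == BOND_UNRESOLVED)) {
    stop("unresolved bonds remain but kekulized=TRUE was requested; ",
         "run kekulize() and apply_assignment() first")
  }
  if (explicit_h) graph <- expand_hydrogens(graph)
  na <- length(graph$element); nb <- length(graph$bond_a)
  if (dialect == "auto") {
    dialect <- if (na > 999L || nb > 999L) "molfile_v3000" else
      "molfile_v2000"
  }
  if (dialect == "molfile_v2000" && (na > 999L || nb > 999L)) {
    stop("structure exceeds the 999 atom/bond V2000 limit; ",
         "use the V3000 dialect")
  }
  xyz <- graph$coords
  if (is.null(xyz)) xyz <- matrix(0, na, 3)
  btype <- ifelse(graph$order == BOND_UNRESOLVED, 4L, graph$order)
  # record non-default valences so implicit H survive the round trip
  vdef <- unname(.default_valences[graph$element])
  vdef[is.na(vdef)] <- -1L
  vfield <- ifelse(graph$valence == vdef, 0L,
                   ifelse(graph$valence == 0L, 15L, graph$valence))
  header <- c(title, "  kekule  R package", "")
  if (dialect == "molfile_v2000") {
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
    atoms <- sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0%3d  0  0  0  0  0  0",
      xyz[, 1], xyz[, 2], xyz[, 3], graph$element, vfield)
    bonds <- if (nb) sprintf("%3d%3d%3d  0", graph$bond_a, graph$bond_b,
                             btype) else character(0)
    lines <- c(header, counts, atoms, bonds, "M  END")
  } else {
    val <- ifelse(vfield == 0L, "", sprintf(" VAL=%d", vfield))
    atoms <- sprintf("M  V30 %d %s %.4f %.4f %.4f 0%s",
                     seq_len(na), graph$element, xyz[, 1], xyz[, 2],
                     xyz[, 3], val)
    bonds <- if (nb) sprintf("M  V30 %d %d %d %d", seq_len(nb), btype,
                             graph$bond_a, graph$bond_b) else character(0)
    lines <- c(header, "  0  0  0  0  0  0  0  0  0  0999 V3000",
               "M  V30 BEGIN CTAB",
               sprintf("M  V30 COUNTS %d %d 0 0 0", na, nb),
               "M  V30 BEGIN ATOM", atoms, "M  V30 END ATOM",
               "M  V30 BEGIN BOND", bonds, "M  V30 END BOND",
               "M  V30 END CTAB", "M  END")
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path, sep = "\n")
  invisible(lines)
}

#' Write XYZ coordinates
#'
#' XYZ carries only elements and coordinates (no bonds) and is
#' export-only for structures that have coordinates.  Implicit hydrogens
#' are not written (they have no coordinates).
#'
#' @param graph a `molgraph` with coordinates.
#' @param path optional output file; when `NULL` the text is returned.
#' @param comment second-line comment.
#' @return invisibly, the lines written.
#' @export
write_xyz <- function(graph, path = NULL, comment = "") {
  stopifnot(inherits(graph, "molgraph"))
  if (is.null(graph$coords)) {
    stop("XYZ export requires coordinates; this structure has none")
  }
  lines <- c(as.character(length(graph$element)), comment,
             sprintf("%-3s %12.4f %12.4f %12.4f", graph$element,
                     graph$coords[, 1], graph$coords[, 2],
                     graph$coords[, 3]))
  if (is.null(path)) return(lines)
  writeLines(lines, path, sep = "\n")
  invisible(lines)
}

#' Read XYZ coordinates
#'
#' @param con file path or text.
#' @return a coordinates-only record: list with `element` (character)
#'   and `coords` (numeric matrix, Angstroms).  No bonds are perceived.
#' @export
read_xyz <- function(con) {
  lines <- .as_lines(con)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n)) stop("malformed XYZ count line")
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  list(element = vapply(rows, `[`, character(1), 1),
       coords = t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))))
}

#' Read a structure file by extension
#'
#' `.mol`/`.sdf` dispatch to [read_molfile()]; `.cc1` is a niche dialect
#' that is intentionally unsupported and raises an informative error.
#'
#' @param path file path.
#' @return a `molgraph`.
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mol = , sdf = read_molfile(path),
    cc1 = stop("the .cc1 format is not supported; convert to MDL molfile"),
    stop("unsupported structure format: .", ext))
}
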