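# Parametric generators for the benchmark structure families: armchair
# carbon nanotubes, graphene ribbons, graphynes GY1/GY7, graphyne
# nanotubes, fullerenes C20/C60 (+ aza substitution), porphine and
# polycyclopentadienes.
#
# All builders are deterministic and fully vectorized; composition laws:
#   nanotube   C = 144n, H = 48
#   graphene   C = 144n, H = 12n + 26
#   GY1        C = 136n, H = 8n + 66
#   GY7        C = 188n, H = 4n + 82
#   graphyne tube C = 192n, H = 72
#   polycyclopentadiene C = 150n, H = 50n + 4 (linear) / 50n (cyclic, Moebius)

# trusted fast constructor (generators produce valid graphs by design)
.new_molgraph <- function(element, implicit_h, bond_a, bond_b, order,
                          coords = NULL, valence = NULL) {
  if (is.null(valence)) {
    valence <- unname(.default_valences[element])
  }
  structure(list(element = element, valence = as.integer(valence),
                 implicit_h = as.integer(implicit_h), coords = coords,
                 bond_a = as.integer(bond_a), bond_b = as.integer(bond_b),
                 order = as.integer(order)),
            class = "molgraph")
}

#' Generate an armchair (12,12) carbon nanotube
#'
#' Builds a tube of `n` repeat units (144 carbons per unit) as a
#' honeycomb lattice wrapped on a cylinder: 24 atoms around the
#' circumference, `6n` axial columns.  All ring bonds are unresolved
#' (aromatic); consecutive units are joined through them.  Each atom on
#' the two open armchair ends carries one hydrogen, so the hydrogen count
#' is 48 independent of the chain length.
#'
#' @param n chain length (number of repeat units), `n >= 1`.
#' @return a `molgraph` with formula `C(144n)H48` and idealized
#'   cylindrical coordinates.
#' @export
generate_nanotube <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chain length n must be >= 1")
  R <- 24L                      # atoms around the circumference
  M <- 6L * n                   # axial columns
  id <- function(r, c) r + 1L + R * c
  # axial bonds within each circumferential row
  cc <- rep(0:(M - 2L), each = R)
  rr <- rep(0:(R - 1L), M - 1L)
  a1 <- id(rr, cc); b1 <- id(rr, cc + 1L)
  # circumferential bonds: (r,c)-(r+1,c) where r + c is even
  cc2 <- rep(0:(M - 1L), each = R %/% 2L)
  rr2 <- as.vector(vapply(0:(M - 1L), function(c) {
    seq.int(c %% 2L, R - 1L, by = 2L)
  }, integer(R %/% 2L)))
  a2 <- id(rr2, cc2); b2 <- id((rr2 + 1L) %% R, cc2)
  nat <- R * M
  h <- integer(nat)
  col_of <- (seq_len(nat) - 1L) %/% R
  h[col_of == 0L | col_of == M - 1L] <- 1L
  # schematic cylindrical coordinates (topology is what matters)
  r_of <- (seq_len(nat) - 1L) %% R
  theta <- 2 * pi * (r_of + 0.25 * ((r_of + col_of) %% 2)) / R
  rad <- 8.14
  coords <- cbind(rad * cos(theta), rad * sin(theta), 1.278 * col_of)
  .new_molgraph(rep("C", nat), h, c(a1, a2), c(b1, b2),
                rep(BOND_UNRESOLVED, length(a1) + length(a2)), coords)
}

#' Generate a graphene ribbon
#'
#' Builds a sheet of `n` blocks (144 carbons per block) as an open
#' honeycomb strip, 12 rows by `12n` columns.  Each edge carbon carries
#' `3 - degree` hydrogens (one per zigzag-edge atom), and the two
#' degree-1 attachment-point carbons at the terminal edge gain one more
#' hydrogen each, saturating them, for a total of `12n + 26` hydrogens.
#'
#' @param n chain length (number of blocks), `n >= 1`.
#' @return a `molgraph` with formula `C(144n)H(12n+26)` and idealized
#'   planar coordinates.
#' @export
generate_graphene <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chain length n must be >= 1")
  R <- 12L
  M <- 12L * n
  id <- function(r, c) r + 1L + R * c
  cc <- rep(0:(M - 2L), each = R)
  rr <- rep(0:(R - 1L), M - 1L)
  a1 <- id(rr, cc); b1 <- id(rr, cc + 1L)
  # verticals between rows r and r+1 at columns with r + c even
  vr <- rep(0:(R - 2L), times = M)
  vc <- rep(0:(M - 1L), each = R - 1L)
  keep <- (vr + vc) %% 2L == 0L
  vr <- vr[keep]; vc <- vc[keep]
  a2 <- id(vr, vc); b2 <- id(vr + 1L, vc)
  nat <- R * M
  deg <- tabulate(c(a1, a2, b1, b2), nbins = nat)
  h <- 3L - deg
  order <- rep(BOND_UNRESOLVED, length(a1) + length(a2))
  # the two acyclic attachment-point carbons at the right edge (degree 1)
  # are saturated when terminal: their attachment bond is replaced by a
  # hydrogen, leaving a single resolved bond into the sheet
  corners <- c(id(0L, M - 1L), id(R - 1L, M - 1L))
  h[corners] <- h[corners] + 1L
  ba <- c(a1, a2); bb <- c(b1, b2)
  order[ba %in% corners | bb %in% corners] <- 1L
  r_of <- (seq_len(nat) - 1L) %% R
  c_of <- (seq_len(nat) - 1L) %/% R
  coords <- cbind(1.23 * c_of, 2.13 * r_of + 0.355 * ((r_of + c_of) %% 2), 0)
  .new_molgraph(rep("C", nat), h, ba, bb, order, coords)
}

# ---------------------------------------------------------------------------
# gamma-graphyne lattice: benzene rings on a (sheared) triangular
# superlattice, adjacent rings joined by -C#C- (two sp carbons of
# pi-deficiency 2).  Ring (i, j) has 6 vertices assigned to the link
# directions  v0=E(+1,0)  v1=NE(+1,+1)  v2=N(0,+1)  v3=W  v4=SW  v5=S.
# Unlinked, uncapped vertices carry one hydrogen.  `caps` assigns
# terminal groups to selected (ring, vertex) positions:
#   CH3  methyl (single resolved bond, outside the pi-system)
#   CH2  exocyclic methylene =CH2 (pi-deficiency 1)
#   C2H  acetylene stub -C#CH (two sp-type carbons)
.graphyne_lattice <- function(W, Hr, wrap_j = FALSE, caps = NULL) {
  nr <- W * Hr
  ring_of <- function(i, j) j * W + i + 1L      # 1-based ring index
  atom_of <- function(ring, v) (ring - 1L) * 6L + v + 1L
  nring_atoms <- 6L * nr

  # ring perimeter bonds
  rid <- rep(seq_len(nr), each = 6L)
  v <- rep(0:5, nr)
  ring_a <- atom_of(rid, v)
  ring_b <- atom_of(rid, (v + 1L) %% 6L)

  # links in directions E, N, NE
  gi <- rep(0:(W - 1L), times = Hr)
  gj <- rep(0:(Hr - 1L), each = W)
  link_from <- integer(0); link_to <- integer(0)
  add <- function(di, dj, v_from, v_to) {
    ti <- gi + di
    tj <- gj + dj
    if (wrap_j) tj <- tj %% Hr
    ok <- ti >= 0L & ti < W & tj >= 0L & tj < Hr
    list(from = atom_of(ring_of(gi[ok], gj[ok]), v_from),
         to = atom_of(ring_of(ti[ok], tj[ok]), v_to))
  }
  eL <- add(1L, 0L, 0L, 3L)   # E:  v0 -> v3
  nL <- add(0L, 1L, 2L, 5L)   # N:  v2 -> v5
  dL <- add(1L, 1L, 1L, 4L)   # NE: v1 -> v4
  link_from <- c(eL$from, nL$from, dL$from)
  link_to <- c(eL$to, nL$to, dL$to)
  nl <- length(link_from)

  # two sp carbons per link
  s1 <- nring_atoms + 2L * seq_len(nl) - 1L
  s2 <- s1 + 1L
  bond_a <- c(ring_a, link_from, s1, s2)
  bond_b <- c(ring_b, s1, s2, link_to)
  order <- rep(BOND_UNRESOLVED, length(bond_a))
  natoms <- nring_atoms + 2L * nl
  occupied <- logical(nring_atoms)
  occupied[link_from] <- TRUE
  occupied[link_to] <- TRUE

  h_extra <- integer(0)
  if (!is.null(caps) && nrow(caps)) {
    cap_pos <- atom_of(caps$ring, caps$vertex)
    if (any(occupied[cap_pos])) stop("cap position already linked")
    occupied[cap_pos] <- TRUE
    for (t in seq_len(nrow(caps))) {
      type <- caps$type[t]
      if (type == "CH3") {
        natoms <- natoms + 1L
        h_extra <- c(h_extra, 3L)
        bond_a <- c(bond_a, cap_pos[t]); bond_b <- c(bond_b, natoms)
        order <- c(order, 1L)             # methyl C is outside the pi-system
      } else if (type == "CH2") {
        natoms <- natoms + 1L
        h_extra <- c(h_extra, 2L)
        bond_a <- c(bond_a, cap_pos[t]); bond_b <- c(bond_b, natoms)
        order <- c(order, BOND_UNRESOLVED)
      } else if (type == "C2H") {
        natoms <- natoms + 2L
        h_extra <- c(h_extra, 0L, 1L)
        bond_a <- c(bond_a, cap_pos[t], natoms - 1L)
        bond_b <- c(bond_b, natoms - 1L, natoms)
        order <- c(order, BOND_UNRESOLVED, BOND_UNRESOLVED)
      } else {
        stop("unknown cap type: ", type)
      }
    }
  }
  h <- integer(natoms)
  h[seq_len(nring_atoms)][!occupied] <- 1L    # bare ring CH
  if (length(h_extra)) {
    h[(natoms - length(h_extra) + 1L):natoms] <- h_extra
  }
  .new_molgraph(rep("C", natoms), h, bond_a, bond_b, order)
}

#' Generate graphyne GY1
#'
#' A gamma-graphyne ribbon: benzene rings on a triangular superlattice
#' with every adjacent ring pair joined by an acetylene (-C#C-) linker,
#' 6 rings tall and `2n` ring-columns wide (136 carbons per unit).  The
#' 22 junction positions at the two chain ends are terminated with methyl
#' groups, giving `H = 8n + 66`.
#'
#' @param n chain length, `n >= 1`.
#' @return a `molgraph` with formula `C(136n)H(8n+66)`.
#' @export
generate_gy1 <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chain length n must be >= 1")
  W <- 2L * n; Hr <- 6L
  ring_of <- function(i, j) j * W + i + 1L
  left <- data.frame(
    ring = c(ring_of(0L, 0:5), ring_of(0L, 1:5)),
    vertex = c(rep(3L, 6), rep(4L, 5)))
  right <- data.frame(
    ring = c(ring_of(W - 1L, 0:5), ring_of(W - 1L, 0:4)),
    vertex = c(rep(0L, 6), rep(1L, 5)))
  caps <- rbind(left, right)
  caps$type <- "CH3"
  .graphyne_lattice(W, Hr, wrap_j = FALSE, caps = caps)
}

#' Generate graphyne GY7
#'
#' Same lattice family as [generate_gy1()] but 16 rings tall and one
#' ring-column per unit (188 carbons per unit, interior hydrogen slope
#' `4n`).  Each chain end exposes 31 junction positions, terminated with
#' a fixed mix of exocyclic methylene (=CH2) caps, acetylene (-C#CH)
#' stubs and bare CH chosen so that `H = 4n + 82` exactly.
#'
#' @param n chain length, `n >= 1`.
#' @return a `molgraph` with formula `C(188n)H(4n+82)`.
#' @export
generate_gy7 <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chain length n must be >= 1")
  W <- n; Hr <- 16L
  ring_of <- function(i, j) j * W + i + 1L
  left_pos <- data.frame(
    ring = c(ring_of(0L, 0:15), ring_of(0L, 1:15)),
    vertex = c(rep(3L, 16), rep(4L, 15)))
  right_pos <- data.frame(
    ring = c(ring_of(W - 1L, 0:15), ring_of(W - 1L, 0:14)),
    vertex = c(rep(0L, 16), rep(1L, 15)))
  left_pos$type <- c(rep("CH2", 10), rep("C2H", 11), rep("", 10))
  right_pos$type <- c(rep("CH2", 10), rep("C2H", 10), rep("", 11))
  caps <- rbind(left_pos, right_pos)
  caps <- caps[caps$type != "", ]
  .graphyne_lattice(W, Hr, wrap_j = FALSE, caps = caps)
}

#' Generate a graphyne nanotube
#'
#' The GY7 lattice closed into a tube: the vertical boundary positions
#' are joined top-to-bottom by acetylene bridges (the hydrogen atoms of
#' GY7's long edges are replaced by carbons bonded in the vertical
#' direction), adding 4 carbons per unit (192 per unit).  End caps are a
#' symmetric mix of =CH2, -C#CH and bare CH giving `H = 72` independent
#' of the chain length.
#'
#' @param n chain length, `n >= 1`.
#' @return a `molgraph` with formula `C(192n)H72`.
#' @export
generate_graphyne_tube <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chain length n must be >= 1")
  W <- n; Hr <- 16L
  ring_of <- function(i, j) j * W + i + 1L
  side <- function(i, vmain, vdiag) {
    data.frame(ring = c(ring_of(i, 0:15), ring_of(i, 0:15)),
               vertex = c(rep(vmain, 16), rep(vdiag, 16)),
               type = c(rep("CH2", 4), rep("C2H", 14), rep("", 14)))
  }
  caps <- rbind(side(0L, 3L, 4L), side(W - 1L, 0L, 1L))
  caps <- caps[caps$type != "", ]
  .graphyne_lattice(W, Hr, wrap_j = TRUE, caps = caps)
}

#' Generate a polycyclopentadiene
#'
#' A chain of `30n` cyclopentadiene (C5) rings; consecutive rings are
#' joined by junctions carrying 2, 1, 2, 2, 1, 2, ... bonds (period
#' three), which yields 150 carbons and 50 hydrogens per chain-length
#' unit.  `linear` leaves the two chain ends free (their four freed
#' valences are hydrogen-capped, H = 50n + 4); `cyclic` joins the last
#' ring back to the first with a straight two-bond junction (H = 50n);
#' `moebius` joins them crisscross, producing a single-twist loop with
#' the same formula and degree sequence but a different edge set.
#'
#' @param n chain length (Table-style aggregated units of 30 rings),
#'   `n >= 1`.
#' @param topology one of `"linear"`, `"cyclic"`, `"moebius"`.
#' @return a `molgraph` with formula `C(150n)H(50n+4)` (linear) or
#'   `C(150n)H(50n)` (cyclic, moebius); contains only five-membered
#'   rings.
#' @export
generate_polycyclopentadiene <- function(n, topology = c("linear", "cyclic",
                                                         "moebius")) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chain length n must be >= 1")
  topology <- match.arg(topology)
  nr <- 30L * n
  atom_of <- function(k, v) 5L * k + v + 1L          # k 0-based ring index
  k <- rep(0:(nr - 1L), each = 5L)
  v <- rep(0:4, nr)
  ring_a <- atom_of(k, v)
  ring_b <- atom_of(k, (v + 1L) %% 5L)
  # junctions: ring k -> ring k+1; two bonds except one when k %% 3 == 1
  last_k <- if (topology == "linear") nr - 2L else nr - 1L
  jk <- 0:last_k
  jt <- (jk + 1L) %% nr
  two <- jk %% 3L != 1L
  ja <- c(atom_of(jk, 0L), atom_of(jk[two], 1L))
  jb <- c(atom_of(jt, 3L), atom_of(jt[two], 2L))
  if (topology == "moebius") {
    # crisscross the closing junction (it is a two-bond junction)
    i1 <- which(jk == nr - 1L)                       # v0 -> v3 entry
    i2 <- length(ja)                                 # v1 -> v2 entry (last)
    jb[i1] <- atom_of(0L, 2L)
    jb[i2] <- atom_of(0L, 3L)
  }
  bond_a <- c(ring_a, ja)
  bond_b <- c(ring_b, jb)
  nat <- 5L * nr
  deg <- tabulate(c(bond_a, bond_b), nbins = nat)
  h <- 3L - deg
  .new_molgraph(rep("C", nat), h, bond_a, bond_b,
                rep(BOND_UNRESOLVED, length(bond_a)))
}

#' Generate a fullerene graph
#'
#' `C20` is the regular dodecahedron (20 vertices, 30 edges, 12
#' pentagons); `C60` the truncated icosahedron (60 vertices, 90 edges,
#' 12 pentagons and 20 hexagons).  Both are cubic; every atom has
#' pi-deficiency 1 and there are no hydrogens.  Isomer-specific larger
#' fullerenes (C70/C80/C82) are not generated and must be read from a
#' molfile.
#'
#' @param name `"C20"` or `"C60"`.
#' @return a `molgraph` with polyhedral coordinates (bond length scaled
#'   to 1.42 Angstroms).
#' @export
generate_fullerene <- function(name = c("C20", "C60")) {
  name <- match.arg(name)
  phi <- (1 + sqrt(5)) / 2
  signs <- function(p) {
    s <- as.matrix(expand.grid(lapply(p, function(x) {
      if (x == 0) 0 else c(x, -x)
    })))
    unique(s)
  }
  if (name == "C20") {
    # cube corners plus cyclic permutations of the signed (0, 1/phi, phi)
    # family
    base <- signs(c(0, 1 / phi, phi))
    verts <- rbind(signs(c(1, 1, 1)), base, base[, c(3, 1, 2)],
                   base[, c(2, 3, 1)])
    verts <- unique(round(verts, 9))
    edge_len <- 2 / phi
  } else {
    fam <- function(p) {
      b <- signs(p)
      rbind(b, b[, c(3, 1, 2)], b[, c(2, 3, 1)])
    }
    verts <- rbind(fam(c(0, 1, 3 * phi)),
                   fam(c(1, 2 + phi, 2 * phi)),
                   fam(c(phi, 2, 2 * phi + 1)))
    verts <- unique(round(verts, 9))
    edge_len <- 2
  }
  dm <- as.matrix(stats::dist(verts))
  pairs <- which(dm < edge_len * 1.05 & upper.tri(dm), arr.ind = TRUE)
  coords <- verts * (1.42 / edge_len)
  .new_molgraph(rep("C", nrow(verts)), integer(nrow(verts)),
                pairs[, 1], pairs[, 2],
                rep(BOND_UNRESOLVED, nrow(pairs)), coords)
}

#' Replace carbons with nitrogen (aza substitution)
#'
#' Randomly replaces `k` distinct hydrogen-free carbons with trivalent
#' nitrogen.  A substituted nitrogen's pi-deficiency drops by one; when
#' it reaches zero the nitrogen keeps three single converging bonds,
#' which are resolved to explicit single bonds.  An odd `k` makes the
#' total pi-deficiency odd, so bonds can no longer be alternated and
#' kekulization must fail; a warning is issued in that case.
#'
#' @param graph a `molgraph`.
#' @param k number of carbons to replace (0 allowed).
#' @param seed integer seed making the placement deterministic, or `NULL`
#'   to draw from the session RNG.
#' @return a `molgraph` with `k` carbons replaced by N.
#' @export
substitute_aza <- function(graph, k, seed = NULL) {
  stopifnot(inherits(graph, "molgraph"))
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative")
  if (k == 0L) return(graph)
  d <- pi_deficiency(graph)
  eligible <- which(graph$element == "C" & graph$implicit_h == 0L & d >= 1L)
  if (k > length(eligible)) {
    stop("k exceeds the number of substitutable carbons (",
         length(eligible), ")")
  }
  if (k %% 2L == 1L) {
    warning("odd number of aza substitutions: total pi-deficiency becomes ",
            "odd and no Kekule structure can exist")
  }
  chosen <- .with_seed(seed, sample(eligible, k))
  graph$element[chosen] <- "N"
  graph$valence[chosen] <- 3L
  # nitrogens whose deficiency drops to zero get three explicit single
  # bonds ("three single converging bonds in each node")
  now_zero <- chosen[d[chosen] == 1L]
  if (length(now_zero)) {
    touch <- graph$bond_a %in% now_zero | graph$bond_b %in% now_zero
    graph$order[touch & graph$order == BOND_UNRESOLVED] <- 1L
  }
  graph
}

#' The porphine macrocycle
#'
#' A hardcoded fixture: four five-membered nitrogen-containing (pyrrole
#' type) rings bridged by four methine carbons, formula C20H14N4.  Two
#' nitrogens carry an N-H and have pi-deficiency 0 (their three bonds are
#' explicit singles); the other two are pyridine-type with deficiency 1.
#'
#' @return a `molgraph` with 24 heavy atoms.
#' @export
porphine <- function() {
  # ring r (0..3): N = 5r+1, Ca1 = 5r+2, Cb1 = 5r+3, Cb2 = 5r+4, Ca2 = 5r+5
  # meso carbons: 21..24, meso r bridges ring r's Ca2 to ring (r+1)%%4's Ca1
  element <- c(rep(c("N", "C", "C", "C", "C"), 4), rep("C", 4))
  # rings 0 and 2 are the N-H (pyrrole-type) rings
  h <- integer(24)
  for (r in 0:3) {
    base <- 5L * r
    h[base + 1L] <- if (r %% 2L == 0L) 1L else 0L   # N-H on rings 0, 2
    h[base + 3L] <- 1L                              # beta carbons
    h[base + 4L] <- 1L
  }
  h[21:24] <- 1L                                    # meso CH
  bond_a <- integer(0); bond_b <- integer(0); order <- integer(0)
  for (r in 0:3) {
    base <- 5L * r
    pyrrole <- r %% 2L == 0L
    ring_bonds <- rbind(c(base + 1L, base + 2L),    # N  - Ca1
                        c(base + 2L, base + 3L),    # Ca1- Cb1
                        c(base + 3L, base + 4L),    # Cb1- Cb2
                        c(base + 4L, base + 5L),    # Cb2- Ca2
                        c(base + 5L, base + 1L))    # Ca2- N
    ring_ord <- rep(BOND_UNRESOLVED, 5L)
    if (pyrrole) ring_ord[c(1L, 5L)] <- 1L          # N-H nitrogen: singles
    meso <- 21L + r
    nxt <- 5L * ((r + 1L) %% 4L)
    bond_a <- c(bond_a, ring_bonds[, 1], base + 5L, meso)
    bond_b <- c(bond_b, ring_bonds[, 2], meso, nxt + 2L)
    order <- c(order, ring_ord, BOND_UNRESOLVED, BOND_UNRESOLVED)
  }
  .new_molgraph(element, h, bond_a, bond_b, order)
}

#' Generate a benchmark structure from a family specification
#'
#' Convenience dispatcher over the individual generators, used by the
#' trial driver and the command-line interface.
#'
#' @param family one of `"nanotube"`, `"graphene"`, `"gy1"`, `"gy7"`,
#'   `"graphyne_tube"`, `"polycyclopentadiene"`, `"fullerene"`,
#'   `"porphine"`.
#' @param n chain length (ignored for fullerene/porphine).
#' @param topology polycyclopentadiene topology.
#' @param fullerene_name `"C20"` or `"C60"`.
#' @param aza_count number of carbons to replace with nitrogen (even for
#'   a kekulizable structure).
#' @param seed seed for the aza placement.
#' @return a `molgraph`.
#' @export
generate_structure <- function(family, n = 1L,
                               topology = "linear",
                               fullerene_name = "C60",
                               aza_count = 0L, seed = NULL) {
  g <- switch(family,
    nanotube = generate_nanotube(n),
    graphene = generate_graphene(n),
    gy1 = generate_gy1(n),
    gy7 = generate_gy7(n),
    graphyne_tube = generate_graphyne_tube(n),
    polycyclopentadiene = generate_polycyclopentadiene(n, topology),
    fullerene = generate_fullerene(fullerene_name),
    porphine = porphine(),
    stop("unknown family: ", family))
  if (aza_count > 0L) g <- substitute_aza(g, aza_count, seed = seed)
  g
}
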