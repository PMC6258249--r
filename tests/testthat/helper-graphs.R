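# Fixture builders and the independent brute-force oracle.

# ring of n aromatic CH carbons (all pi-deficiency 1)
make_ring <- function(n) {
  build_molecule(
    data.frame(element = rep("C", n), implicit_h = rep(1L, n)),
    data.frame(a = seq_len(n), b = c(seq_len(n)[-1], 1L)))
}

make_benzene <- function() make_ring(6L)

# open chain of n atoms with prescribed deficiencies (implicit H filled
# so that valence 4 minus H minus degree gives exactly d)
make_chain <- function(d) {
  n <- length(d)
  deg <- c(1L, rep(2L, max(0L, n - 2L)), 1L)[seq_len(n)]
  build_molecule(
    data.frame(element = rep("C", n), implicit_h = 4L - deg - d),
    data.frame(a = seq_len(n - 1L), b = seq_len(n - 1L) + 1L))
}

# random connected molecular graph with <= max_atoms pi-atoms, degrees
# <= 3 and deficiencies in {1, 2} (2 only where the valence allows)
random_pi_graph <- function(max_atoms = 14L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample(4:max_atoms, 1L)
  # random spanning tree with degrees capped at 3
  a <- integer(0); b <- integer(0)
  deg <- integer(n)
  for (v in 2:n) {
    cand <- which(deg[seq_len(v - 1L)] < 3L)
    p <- cand[sample.int(length(cand), 1L)]
    a <- c(a, p); b <- c(b, v)
    deg[p] <- deg[p] + 1L
    deg[v] <- deg[v] + 1L
  }
  # sprinkle extra edges while keeping degrees <= 3 and the graph simple
  extra <- sample.int(n, 1L)
  key <- paste(pmin(a, b), pmax(a, b))
  for (i in seq_len(extra)) {
    uv <- sample.int(n, 2L)
    k <- paste(min(uv), max(uv))
    if (k %in% key || any(deg[uv] >= 3L)) next
    a <- c(a, uv[1]); b <- c(b, uv[2]); key <- c(key, k)
    deg[uv] <- deg[uv] + 1L
  }
  d <- sample(1:2, n, replace = TRUE)
  d <- pmin(d, 4L - deg)          # keep valence feasible
  d <- pmax(d, 1L)                # every atom is a pi-member
  build_molecule(
    data.frame(element = rep("C", n), implicit_h = 4L - deg - d),
    data.frame(a = a, b = b))
}

# Independent oracle: exhaustive enumeration over all pi-order vectors
# in {0,1,2}^E, with infeasible partial sums abandoned early.  Decides
# feasibility and is independent of the package's search heuristics.
brute_force_feasible <- function(graph) {
  ps <- extract_pi_system(graph)
  m <- length(ps$members)
  ne <- length(ps$edges)
  d <- ps$d
  # edges left at each atom as we sweep edges in input order
  left <- tabulate(c(ps$ea, ps$eb), nbins = m)
  got <- integer(m)
  recurse <- function(i) {
    if (i > ne) return(all(got == d))
    ea <- ps$ea[i]; eb <- ps$eb[i]
    left[ea] <<- left[ea] - 1L
    left[eb] <<- left[eb] - 1L
    ok <- FALSE
    for (v in 0:2) {
      got[ea] <<- got[ea] + v
      got[eb] <<- got[eb] + v
      feas <- got[ea] <= d[ea] && got[eb] <= d[eb] &&
        (left[ea] > 0L || got[ea] == d[ea]) &&
        (left[eb] > 0L || got[eb] == d[eb])
      if (feas && recurse(i + 1L)) { ok <- TRUE }
      got[ea] <<- got[ea] - v
      got[eb] <<- got[eb] - v
      if (ok) break
    }
    left[ea] <<- left[ea] + 1L
    left[eb] <<- left[eb] + 1L
    ok
  }
  recurse(1L)
}
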