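# Randomized bond-alternation kekulization with shuffle restarts and an
# exact backtracking fallback.

#' Kekulization configuration
#'
#' @param max_iterations maximum number of random shuffles before deciding
#'   that a Kekule structure does not exist on the approximate path
#'   (default 300).
#' @param seed integer seed for the shuffle stream, or `NULL` to draw from
#'   the session's RNG state.
#' @param exact_fallback run the exact backtracking search when the
#'   shuffle budget is exhausted (default `TRUE`); with `FALSE` the result
#'   reports presumed non-existence and never claims proof.
#' @param augment remove the unmatched atoms left by each pass with
#'   alternating-walk repair (capacitated matching augmentation) before
#'   deciding whether to reshuffle (default `TRUE`).  The unmatched-atom
#'   statistic always reports the count *before* removal.  With `FALSE`
#'   every repair is skipped and the algorithm is pure
#'   shuffle-and-restart.
#' @return a list of class `kekulize_config`.
#' @export
kekulize_config <- function(max_iterations = 300L, seed = NULL,
                            exact_fallback = TRUE, augment = TRUE) {
  max_iterations <- as.integer(max_iterations)
  stopifnot(max_iterations >= 1L)
  structure(list(max_iterations = max_iterations, seed = seed,
                 exact_fallback = isTRUE(exact_fallback),
                 augment = isTRUE(augment)),
            class = "kekulize_config")
}

# run body with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' One bond-alternation pass
#'
#' Performs a single sweep of the alternation algorithm: forced
#' assignments -- atoms whose free capacity exactly equals their
#' remaining demand -- are propagated through a worklist (this is how a
#' placed double bond alternates outward along rings and chains), and
#' whenever nothing is forced the next atom in `order` claims pi-order
#' on an eligible incident edge (the random selection of a double bond
#' in the node), ties among edges broken by `edge_priority`.  A
#' deficiency-2 atom prefers a single pi-order-2 edge (triple bond) when
#' its partner can accept two units, and otherwise places two pi-order-1
#' edges (cumulene).  Atoms whose demand cannot be met are returned as
#' unmatched.  Deterministic given `order` and `edge_priority`.
#'
#' @param pisystem a `pi_system` from [extract_pi_system()].
#' @param order permutation of `seq_along(pisystem$members)` giving the
#'   visiting order (default: natural order).
#' @param edge_priority permutation of `seq_along(pisystem$edges)` used to
#'   break ties among eligible incident edges (smaller wins).
#' @return list with `assignment` (pi-order per edge), `unmatched`
#'   (member-local indices of unsatisfied atoms) and `ops` (number of
#'   edge inspections, an instruction-count proxy).
#' @export
alternate_once <- function(pisystem, order = seq_along(pisystem$members),
                           edge_priority = seq_along(pisystem$edges)) {
  stopifnot(inherits(pisystem, "pi_system"))
  m <- length(pisystem$members)
  if (length(order) != m || anyDuplicated(order) ||
      (m && (min(order) != 1L || max(order) != m))) {
    stop("'order' must be a permutation of the pi-system members")
  }
  res <- cpp_alternate_pass(pisystem$ptr, pisystem$adj_edge,
                            pisystem$adj_nbr, pisystem$d,
                            as.integer(order) - 1L,
                            as.integer(edge_priority))
  list(assignment = res$pi, unmatched = res$unmatched + 1L, ops = res$ops)
}

# alternating-walk repair (capacitated b-matching augmentation); used
# when the augment flag is on
.augment <- function(ps, x, rem) {
  res <- cpp_augment(ps$ptr, ps$adj_edge, ps$adj_nbr, x, rem)
  list(x = res$pi, rem = res$rem)
}

#' Kekulize a molecular graph
#'
#' Repeats randomized alternation passes (each preceded by a fresh
#' Fisher-Yates shuffle of the atom visiting order and of the edge
#' tie-break priorities; one shuffle = one iteration) until no atom is
#' left unmatched, or until `max_iterations` shuffles are consumed.  By
#' default the few atoms left unmatched by a pass are removed by
#' alternating-walk repair before the next reshuffle is charged (see
#' [kekulize_config()]); `unmatched_first_pass` always records the count
#' before removal.  On exhaustion, when `exact_fallback` is on, the
#' exact backtracking search decides existence; otherwise the structure
#' is reported as presumed non-existent.  A pi-system whose total
#' deficiency is odd cannot be satisfied and short-circuits to failure
#' without consuming iterations.
#'
#' @param graph a `molgraph`.
#' @param config a [kekulize_config()].
#' @return an object of class `kekulization`: list with `success`,
#'   `assignment` (pi-order per unresolved bond, present iff success),
#'   `unmatched_first_pass` (unmatched-atom count after the first pass),
#'   `iterations` (shuffles consumed), `used_backtrack`, `ops`
#'   (edge-inspection count over all passes) and `pi_edges` (bond indices
#'   of the pi-system edges in the input graph).
#' @examples
#' benzene <- build_molecule(
#'   data.frame(element = "C", implicit_h = 1)[rep(1, 6), ],
#'   data.frame(a = 1:6, b = c(2:6, 1)))
#' res <- kekulize(benzene, kekulize_config(seed = 1))
#' res$success
#' @export
kekulize <- function(graph, config = kekulize_config()) {
  stopifnot(inherits(graph, "molgraph"), inherits(config, "kekulize_config"))
  ps <- extract_pi_system(graph)
  m <- length(ps$members)
  result <- function(success, assignment, first, iters, backtracked, ops) {
    structure(list(success = success, assignment = assignment,
                   unmatched_first_pass = first, iterations = iters,
                   used_backtrack = backtracked, ops = ops,
                   pi_edges = ps$edges),
              class = "kekulization")
  }
  if (m == 0L) {
    return(result(TRUE, integer(0), 0L, 1L, FALSE, 0))
  }
  if (sum(ps$d) %% 2L == 1L) {
    # parity violation: no assignment can exist.  One diagnostic pass is
    # still run (uncounted) so the unmatched-atom statistic is reported;
    # its count is necessarily odd.
    return(.with_seed(config$seed, {
      perm <- sample.int(m)
      eprio <- if (length(ps$edges)) sample.int(length(ps$edges)) else integer(0)
      res <- cpp_alternate_pass(ps$ptr, ps$adj_edge, ps$adj_nbr, ps$d,
                                perm - 1L, eprio)
      result(FALSE, NULL, length(res$unmatched), 0L, FALSE, res$ops)
    }))
  }
  .with_seed(config$seed, {
    first <- NA_integer_
    total_ops <- 0
    ne <- length(ps$edges)
    for (it in seq_len(config$max_iterations)) {
      perm <- sample.int(m)
      eprio <- if (ne) sample.int(ne) else integer(0)
      res <- cpp_alternate_pass(ps$ptr, ps$adj_edge, ps$adj_nbr, ps$d,
                                perm - 1L, eprio)
      total_ops <- total_ops + res$ops
      n_un <- length(res$unmatched)
      if (is.na(first)) first <- n_un
      if (n_un == 0L) {
        return(result(TRUE, res$pi, first, it, FALSE, total_ops))
      }
      if (config$augment) {
        aug <- .augment(ps, res$pi, res$rem)
        if (all(aug$rem == 0L)) {
          return(result(TRUE, aug$x, first, it, FALSE, total_ops))
        }
      }
    }
    if (config$exact_fallback) {
      bt <- backtrack_exact(ps)
      return(result(bt$exists, if (bt$exists) bt$assignment else NULL,
                    first, config$max_iterations, TRUE, total_ops))
    }
    result(FALSE, NULL, first, config$max_iterations, FALSE, total_ops)
  })
}

#' Exact Kekule-structure decision by backtracking
#'
#' Depth-first search over per-atom demand satisfaction with forward
#' capacity pruning (a branch is cut as soon as any atom's remaining
#' demand exceeds what its remaining unassigned edges can carry) and
#' unique-extension propagation.  Atoms are expanded
#' most-constrained-first (fewest unassigned incident edges).  To avoid
#' getting trapped by an unlucky early commitment on large lattices, the
#' search runs under a geometrically growing node budget: when a budget
#' is exhausted, the pi-system is relabelled with a deterministic shuffle
#' and the search restarts with twice the budget.  The procedure remains
#' exact (a verdict is only ever reported by a completed search) and
#' deterministic.  Worst-case exponential.
#'
#' @param pisystem a `pi_system` (or a `molgraph`, from which the
#'   pi-system is extracted).
#' @param node_limit optional bound on the total number of search nodes
#'   across restarts (default unlimited); exceeding it raises an error.
#' @return list with `exists` (logical) and `assignment` (a witness
#'   pi-order vector when `exists`, else `NULL`).
#' @export
backtrack_exact <- function(pisystem, node_limit = Inf) {
  if (inherits(pisystem, "molgraph")) pisystem <- extract_pi_system(pisystem)
  stopifnot(inherits(pisystem, "pi_system"))
  if (sum(pisystem$d) %% 2L == 1L) {
    return(list(exists = FALSE, assignment = NULL))
  }
  m <- length(pisystem$members)
  ne <- length(pisystem$edges)
  budget <- 20000
  spent <- 0
  attempt <- 0L
  repeat {
    if (attempt == 0L) {
      d <- pisystem$d
      csr <- pisystem[c("ptr", "adj_edge", "adj_nbr")]
      edge_map <- seq_len(ne)
    } else {
      # deterministic relabelling: new atom and edge labels per attempt
      sh <- .with_seed(attempt, {
        list(atom = sample.int(m), edge = sample.int(ne))
      })
      d <- integer(m)
      d[sh$atom] <- pisystem$d
      edge_map <- sh$edge                  # new edge j = old edge_map[j]
      csr <- .build_csr(m, sh$atom[pisystem$ea[edge_map]],
                        sh$atom[pisystem$eb[edge_map]])
    }
    lim <- min(budget, node_limit - spent)
    res <- cpp_backtrack(csr$ptr, csr$adj_edge, csr$adj_nbr, d, ne, lim)
    if (!res$hit_limit) {
      assignment <- NULL
      if (res$exists) {
        assignment <- integer(ne)
        assignment[edge_map] <- res$pi
      }
      return(list(exists = res$exists, assignment = assignment))
    }
    spent <- spent + res$nodes
    if (spent >= node_limit) {
      stop("backtrack search exceeded node_limit (", node_limit, ")")
    }
    attempt <- attempt + 1L
    budget <- budget * 2
  }
}

#' @export
print.kekulization <- function(x, ...) {
  cat("<kekulization> ",
      if (x$success) "Kekule structure found" else
        if (x$used_backtrack) "no Kekule structure exists (proved)" else
          "presumed non-existent",
      "\n", sep = "")
  cat("  iterations (shuffles): ", x$iterations,
      if (x$used_backtrack) " + exact backtrack", "\n", sep = "")
  if (!is.na(x$unmatched_first_pass)) {
    cat("  unmatched after first pass: ", x$unmatched_first_pass, "\n",
        sep = "")
  }
  invisible(x)
}
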