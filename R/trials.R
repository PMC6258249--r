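# Repeated-trial statistics over randomized kekulization runs: the
# unmatched-atom histogram after the first alternation pass, the count of
# structures for which no Kekule structure was found, and shuffle-count
# summaries.

#' Run repeated randomized kekulization trials
#'
#' Kekulizes a structure `n_trials` times, each trial with its own seed
#' derived deterministically from `seed` (counter-based, so trials are
#' independent and order-insensitive), and aggregates statistics: the
#' histogram of unmatched-atom counts after the first alternation pass,
#' the number of trials in which no Kekule structure was found, the
#' number rescued by the exact backtrack after shuffle exhaustion, and
#' the mean/maximum number of shuffles.
#'
#' For aza families the default re-randomizes the nitrogen placement on
#' every trial (`aza_per_trial = TRUE`), so the statistics describe the
#' family of random aza-analogs; with `FALSE` one placement (drawn from
#' `seed`) is frozen for all trials.
#'
#' @param x a `molgraph`, or a family name accepted by
#'   [generate_structure()].
#' @param n_trials number of repeated runs.
#' @param config a [kekulize_config()]; its `seed` field is ignored in
#'   favour of the per-trial derived seeds.
#' @param seed master seed.
#' @param n,topology,fullerene_name,aza_count passed to
#'   [generate_structure()] when `x` is a family name.
#' @param aza_per_trial draw a fresh random aza placement each trial.
#' @return an object of class `trial_stats`.
#' @examples
#' benzene <- build_molecule(
#'   data.frame(element = "C", implicit_h = 1)[rep(1, 6), ],
#'   data.frame(a = 1:6, b = c(2:6, 1)))
#' run_trials(benzene, n_trials = 50, seed = 1)
#' @export
run_trials <- function(x, n_trials = 1000L, config = kekulize_config(),
                       seed = 1L, n = 1L, topology = "linear",
                       fullerene_name = "C60", aza_count = 0L,
                       aza_per_trial = TRUE) {
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 1L)
  from_family <- !inherits(x, "molgraph")
  base <- if (from_family && aza_count > 0L && !aza_per_trial) {
    generate_structure(x, n = n, topology = topology,
                       fullerene_name = fullerene_name,
                       aza_count = aza_count, seed = .trial_seed(seed, 0L))
  } else if (from_family) {
    generate_structure(x, n = n, topology = topology,
                       fullerene_name = fullerene_name, aza_count = 0L)
  } else {
    x
  }
  redo_aza <- from_family && aza_count > 0L && aza_per_trial

  unmatched <- integer(n_trials)
  iters <- integer(n_trials)
  nonexist <- 0L
  rescued <- 0L
  for (t in seq_len(n_trials)) {
    ts <- .trial_seed(seed, t)
    g <- if (redo_aza) {
      suppressWarnings(substitute_aza(base, aza_count, seed = ts))
    } else {
      base
    }
    cfg <- config
    cfg$seed <- ts
    res <- kekulize(g, cfg)
    unmatched[t] <- res$unmatched_first_pass
    iters[t] <- res$iterations
    if (!res$success) nonexist <- nonexist + 1L
    if (res$used_backtrack && res$success) rescued <- rescued + 1L
  }
  tab <- table(unmatched)
  histogram <- stats::setNames(as.integer(tab), names(tab))
  structure(list(
    n_trials = n_trials,
    histogram = histogram,
    n_non_existent = nonexist,
    n_backtrack_rescued = rescued,
    avg_iterations = mean(iters),
    max_iterations_seen = max(iters),
    formula = molecular_formula(base, as_string = TRUE)
  ), class = "trial_stats")
}

# counter-based per-trial seed, kept within 32-bit integer range
.trial_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + counter * 69621) %%
               2147483647)
}

#' Format trial statistics
#'
#' Renders a [run_trials()] result as a human-readable table (columns
#' mirroring the benchmark-table legend: formula, number non-existent,
#' average/maximum shuffle counts, unmatched-atom histogram), as CSV, or
#' as JSON (which round-trips to an equal `trial_stats` via
#' [stats_from_json()]).
#'
#' @param stats a `trial_stats`.
#' @param format `"table"`, `"csv"` or `"json"`.
#' @return character vector of lines (a single string for JSON).
#' @export
report <- function(stats, format = c("table", "csv", "json")) {
  stopifnot(inherits(stats, "trial_stats"))
  format <- match.arg(format)
  if (format == "json") {
    x <- unclass(stats)
    x$histogram <- as.list(x$histogram)   # keep the count keys
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  if (format == "csv") {
    hist_cols <- paste0("unmatched_", names(stats$histogram))
    header <- paste(c("formula", "n_trials", "n_non_existent",
                      "n_backtrack_rescued", "avg_iterations",
                      "max_iterations_seen", hist_cols), collapse = ",")
    row <- paste(c(stats$formula, stats$n_trials, stats$n_non_existent,
                   stats$n_backtrack_rescued,
                   format(stats$avg_iterations, digits = 6),
                   stats$max_iterations_seen,
                   stats$histogram), collapse = ",")
    return(c(header, row))
  }
  c(sprintf("Formula:              %s", stats$formula),
    sprintf("Trials:               %d", stats$n_trials),
    sprintf("No. non-existent:     %d", stats$n_non_existent),
    sprintf("Backtrack rescued:    %d", stats$n_backtrack_rescued),
    sprintf("Avg. no. iterations:  %.2f", stats$avg_iterations),
    sprintf("Max. no. iterations:  %d", stats$max_iterations_seen),
    "Unmatched-atom statistic (count after first pass : trials):",
    paste(sprintf("  %s: %d", names(stats$histogram), stats$histogram),
          collapse = "\n"))
}

#' Rebuild trial statistics from their JSON report
#'
#' @param json a JSON string produced by `report(stats, "json")`.
#' @return a `trial_stats` equal to the original.
#' @export
stats_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(
    n_trials = as.integer(x$n_trials),
    histogram = stats::setNames(as.integer(unlist(x$histogram)),
                                names(x$histogram)),
    n_non_existent = as.integer(x$n_non_existent),
    n_backtrack_rescued = as.integer(x$n_backtrack_rescued),
    avg_iterations = as.numeric(x$avg_iterations),
    max_iterations_seen = as.integer(x$max_iterations_seen),
    formula = as.character(x$formula)
  ), class = "trial_stats")
}

#' @export
print.trial_stats <- function(x, ...) {
  cat(report(x, "table"), sep = "\n")
  invisible(x)
}
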