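#' Strategy fractions and cooperation level
#'
#' `strategy_fractions()` returns the fraction of each of the four
#' strategies in a population. `cooperation_level()` is the fraction of
#' cooperators, CN + CP; for a trajectory it is computed from the
#' trailing-window time average.
#'
#' @param pop A `pd_population` (or square code matrix).
#' @param x A `pd_population`, a `pd_trajectory`, or a named fraction
#'   vector as returned by [strategy_fractions()] / [time_average()].
#' @param ... Passed on to [time_average()] for trajectories.
#' @return `strategy_fractions()`: named numeric vector (`CN`, `DN`,
#'   `CP`, `DP`) summing to 1. `cooperation_level()`: a single fraction
#'   in `[0, 1]`.
#' @examples
#' pop <- make_fixture("quadrants")
#' strategy_fractions(pop)
#' cooperation_level(pop)
#' @export
strategy_fractions <- function(pop) {
  pop <- as_population(pop)
  counts <- tabulate(pop$grid, nbins = 4)
  out <- counts / (pop$L^2)
  names(out) <- STRATEGIES
  out
}

#' @rdname strategy_fractions
#' @export
cooperation_level <- function(x, ...) UseMethod("cooperation_level")

#' @export
cooperation_level.pd_population <- function(x, ...) {
  fr <- strategy_fractions(x)
  unname(fr["CN"] + fr["CP"])
}

#' @export
cooperation_level.pd_trajectory <- function(x, ...) {
  fr <- time_average(x, ...)
  unname(fr["CN"] + fr["CP"])
}

#' @export
cooperation_level.numeric <- function(x, ...) {
  if (is.null(names(x)) || !all(c("CN", "CP") %in% names(x))) {
    stop("expected a named fraction vector with elements CN and CP",
         call. = FALSE)
  }
  unname(x["CN"] + x["CP"])
}

#' Punishment events on a configuration
#'
#' Scans one lattice configuration and accounts for every punishment act
#' (one punisher, one defector within its punishment scope). Each active
#' punisher (CP or DP with at least one defector in scope) contributes a
#' `punisher` row with the number of acts it imposed and its total cost
#' `gamma * acts`; each punished defector (DN or DP with at least one
#' punisher holding it in scope) contributes a `defector` row with the
#' number of acts received and its total fine `beta * acts`. Punishers
#' with no defector in scope and defectors that are never punished are
#' excluded. The scope is the eight first-order neighbors under direct
#' punishment and the sixteen second-order neighbors under indirect
#' punishment; with `mode = "none"` the ledger is empty.
#'
#' Because both scopes are symmetric, the total number of acts imposed
#' always equals the total number received.
#'
#' @param pop A `pd_population`.
#' @param params A [pd_params()] object.
#' @return A data frame with columns `site` (linear index), `role`
#'   (`"punisher"` or `"defector"`), `acts` and `amount` (total cost for
#'   punishers, total fine for defectors; positive magnitudes).
#' @examples
#' p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.01, mode = "direct", L = 7)
#' punishment_event_stats(make_fixture("lone_DN_in_CP"), p)
#' @export
punishment_event_stats <- function(pop, params) {
  pop <- as_population(pop)
  stopifnot(inherits(params, "pd_params"))
  empty <- data.frame(site = integer(0), role = character(0),
                      acts = integer(0), amount = numeric(0))
  if (params$mode == "none") return(empty)
  nt <- neighbor_tables(pop$L)
  scope <- if (params$mode == "direct") nt$first else nt$second
  s <- as.vector(pop$grid)
  punisher <- s >= 3
  defector <- s == 2 | s == 4
  n <- length(s)
  in_scope_def <- matrix(defector[scope], nrow = n)
  in_scope_pun <- matrix(punisher[scope], nrow = n)
  imposed <- rowSums(in_scope_def)
  received <- rowSums(in_scope_pun)
  pi <- which(punisher & imposed > 0)
  di <- which(defector & received > 0)
  rbind(
    data.frame(site = pi, role = rep("punisher", length(pi)),
               acts = imposed[pi], amount = params$gamma * imposed[pi]),
    data.frame(site = di, role = rep("defector", length(di)),
               acts = received[di], amount = params$beta * received[di])
  )
}

#' Detect stabilization of strategy fractions
#'
#' Finds the earliest Monte Carlo step at which every strategy fraction
#' has varied by at most `tol` over the trailing `window` recorded steps
#' (the range, max minus min, of each fraction within the window).
#' Used to delimit the transient over which punishment-event ledgers are
#' pooled.
#'
#' @param traj A `pd_trajectory`, or a numeric matrix / data frame of
#'   per-step strategy fractions (four columns, rows = steps 0, 1, ...).
#' @param window Window length in steps (>= 2).
#' @param tol Maximum allowed variation of any fraction within the
#'   window.
#' @return The earliest qualifying step index, or `NA` if the trajectory
#'   never stabilizes (or is shorter than the window).
#' @export
detect_stabilization <- function(traj, window = 200, tol = 0.005) {
  check_count(window, "window", min = 2)
  check_scalar(tol, "tol", min = 0)
  fr <- if (inherits(traj, "pd_trajectory")) {
    as.matrix(traj$fractions[, c("frac_CN", "frac_DN", "frac_CP",
                                 "frac_DP")])
  } else {
    as.matrix(if (is.data.frame(traj)) {
      traj[, setdiff(names(traj), "step")]
    } else {
      traj
    })
  }
  nstep <- nrow(fr) - 1 # rows are steps 0..nstep
  if (window > nstep) return(NA_integer_)
  ok <- rep(TRUE, nstep - window + 1)
  for (col in seq_len(ncol(fr))) {
    # windows of `window` steps ending at steps window..nstep, i.e. rows
    # (t - window + 2)..(t + 1); step 0 is never part of a window
    e <- embed(fr[-1, col], window)
    rng <- apply(e, 1, max) - apply(e, 1, min)
    ok <- ok & rng <= tol
  }
  hit <- which(ok)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(hit[1] + window - 1)
}

#' Pooled punishment-event distributions of a run
#'
#' Aggregates the per-step punishment ledgers of a trajectory (run with
#' `collect_ledger = TRUE`) over the transient -- all steps before the
#' strategy fractions stabilize -- and returns the frequency
#' distributions of punishment acts imposed per active punisher and
#' received per punished defector, together with the implied total-cost
#' (`gamma * acts`) and total-fine (`beta * acts`) scales.
#'
#' @param traj A `pd_trajectory` run with `collect_ledger = TRUE`.
#' @param until Last step (exclusive) to pool; defaults to the detected
#'   stabilization step, or the whole run if the fractions never
#'   stabilize.
#' @param window,tol Stabilization criterion, see
#'   [detect_stabilization()].
#' @return A list with data frames `imposed` (`acts`, `count`, `cost`)
#'   and `received` (`acts`, `count`, `fine`), for act counts 1..16, and
#'   the pooling bound `until`.
#' @export
punishment_distributions <- function(traj, until = NULL, window = 200,
                                     tol = 0.005) {
  stopifnot(inherits(traj, "pd_trajectory"))
  if (is.null(traj$ledger)) {
    stop("trajectory was run without collect_ledger = TRUE", call. = FALSE)
  }
  nstep <- nrow(traj$ledger$imposed)
  if (is.null(until)) {
    until <- detect_stabilization(traj, window = window, tol = tol)
    if (is.na(until)) until <- nstep
  }
  check_count(until, "until", min = 1)
  rows <- seq_len(min(until, nstep))
  acts <- 1:16
  list(
    imposed = data.frame(
      acts = acts, count = colSums(traj$ledger$imposed[rows, , drop = FALSE]),
      cost = traj$params$gamma * acts),
    received = data.frame(
      acts = acts, count = colSums(traj$ledger$received[rows, , drop = FALSE]),
      fine = traj$params$beta * acts),
    until = until
  )
}
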