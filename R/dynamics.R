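#' Fermi imitation probability
#'
#' Probability that a focal player with total payoff `pi_i` adopts the
#' strategy of a model neighbor with payoff `pi_j`:
#' \deqn{w = 1 / (1 + \exp((\Pi_i - \Pi_j)\,\kappa)).}
#' `kappa` is the imitation strength: at `kappa = 0` the probability is
#' exactly 1/2 regardless of payoffs, and as `kappa` grows imitation
#' becomes deterministic in the sign of the payoff difference. The
#' exponent is clamped at +/- 700 so extreme payoff gaps saturate to 0 or
#' 1 instead of overflowing.
#'
#' @param pi_i,pi_j Total payoffs of the focal and model players
#'   (vectorized).
#' @param kappa Imitation strength (>= 0).
#' @return Imitation probabilities in `[0, 1]`.
#' @examples
#' fermi_probability(1, 1, 10)        # 0.5
#' fermi_probability(0, 0.5, 10)      # 1 / (1 + exp(-5))
#' @export
fermi_probability <- function(pi_i, pi_j, kappa) {
  if (any(kappa < 0)) stop("'kappa' must be >= 0", call. = FALSE)
  x <- pmin(pmax((pi_i - pi_j) * kappa, -700), 700)
  1 / (1 + exp(x))
}

#' One elementary asynchronous update (reference implementation)
#'
#' Draws a focal site uniformly at random, a model player uniformly from
#' its eight first-order neighbors, computes both total payoffs on the
#' current configuration, and copies the model's strategy onto the focal
#' site with the Fermi probability. Only the focal site can change.
#'
#' This pure-R updater consumes exactly three uniform draws per call in
#' the same order as the compiled engine, so `L^2` calls after
#' `set.seed(s)` reproduce one [mc_step()] with the same seed. It is the
#' slow reference path; use [mc_step()] / [run_simulation()] for real
#' runs.
#'
#' @param pop A `pd_population`.
#' @param params A [pd_params()] object.
#' @return A list with `population` (the possibly updated population) and
#'   `record`, a one-row data frame with columns `focal`,
#'   `model_neighbor` (linear site indices), `prob` and `imitated`.
#' @export
elementary_update <- function(pop, params) {
  pop <- as_population(pop)
  n <- pop$L^2
  u <- runif(3)
  i <- min(floor(u[1] * n) + 1, n)
  k <- min(floor(u[2] * 8) + 1, 8)
  j <- neighbor_tables(pop$L)$first[i, k]
  w <- fermi_probability(total_payoff(pop, i, params),
                         total_payoff(pop, j, params), params$kappa)
  imitated <- u[3] < w
  if (imitated && pop$grid[i] != pop$grid[j]) {
    pop$grid[i] <- pop$grid[j]
  }
  list(population = pop,
       record = data.frame(focal = i, model_neighbor = j, prob = w,
                           imitated = imitated))
}

#' Advance a population by whole Monte Carlo steps
#'
#' One Monte Carlo step performs exactly `L^2` elementary updates
#' (focal sites drawn uniformly with replacement), so each player updates
#' once per step on average. Uses the compiled engine and the R RNG
#' stream.
#'
#' @param pop A `pd_population`.
#' @param params A [pd_params()] object.
#' @param steps Number of Monte Carlo steps to perform (default 1).
#' @return The evolved `pd_population`.
#' @export
mc_step <- function(pop, params, steps = 1) {
  pop <- as_population(pop)
  stopifnot(inherits(params, "pd_params"))
  check_count(steps, "steps", min = 0)
  if (pop$L != params$L) {
    stop("population lattice (L = ", pop$L,
         ") does not match params$L = ", params$L, call. = FALSE)
  }
  res <- sim_run_cpp(pop$grid, params$r, params$beta, params$gamma,
                     params$kappa, mode_code(params$mode), as.integer(steps),
                     integer(0), FALSE)
  new_population(res$grid)
}

#' Run a full lattice simulation
#'
#' Initializes a population (uniformly at random, as contiguous strategy
#' blocks, or from a supplied population), evolves it for
#' `params$steps_total` Monte Carlo steps under asynchronous Fermi
#' imitation, and records the four strategy fractions after every step.
#' If `params$seed` is set, the RNG is seeded before initialization so
#' the whole trajectory is reproducible.
#'
#' Monomorphic populations are absorbing (imitation can only copy the
#' single remaining strategy), so once the lattice becomes monomorphic
#' the recorded fractions are constant for the rest of the run.
#'
#' @param params A [pd_params()] object.
#' @param init `"random"` or `"block"`; ignored when `pop` is given.
#' @param pop Optional starting `pd_population`.
#' @param strategies Strategy labels for random initialization (see
#'   [init_random()]).
#' @param layout Block layout for `init = "block"` (see [init_block()]).
#' @param snapshot_steps Integer vector of step indices (0 = initial
#'   state) at which to store full lattice snapshots.
#' @param collect_ledger If `TRUE`, tally punishment events after every
#'   step: how many acts each active punisher imposed and each punished
#'   defector received (see [punishment_distributions()]).
#' @return A `pd_trajectory`: a list with
#'   \describe{
#'     \item{fractions}{data frame `step`, `frac_CN`, `frac_DN`,
#'       `frac_CP`, `frac_DP` for steps `0..steps_total`.}
#'     \item{final}{the final `pd_population`.}
#'     \item{snapshots}{named list of `pd_population` snapshots.}
#'     \item{ledger}{when collected, integer matrices `imposed` and
#'       `received` (`steps_total` rows, columns = act counts 1..16).}
#'     \item{absorbed}{first step at which the population was
#'       monomorphic, or `NA`.}
#'     \item{params}{the parameters used.}
#'   }
#' @examples
#' p <- pd_params(r = 0.05, L = 20, steps_total = 50, steps_average = 10,
#'                mode = "none", seed = 1)
#' traj <- run_simulation(p)
#' cooperation_level(traj)
#' @export
run_simulation <- function(params, init = c("random", "block"), pop = NULL,
                           strategies = strategy_labels(), layout = NULL,
                           snapshot_steps = integer(0),
                           collect_ledger = FALSE) {
  stopifnot(inherits(params, "pd_params"))
  init <- match.arg(init)
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(pop)) {
    pop <- if (init == "random") {
      init_random(params$L, strategies)
    } else {
      init_block(params$L,
                 if (is.null(layout)) default_block_layout() else layout)
    }
  } else {
    pop <- as_population(pop)
    if (pop$L != params$L) {
      stop("population lattice (L = ", pop$L,
           ") does not match params$L = ", params$L, call. = FALSE)
    }
  }
  res <- sim_run_cpp(pop$grid, params$r, params$beta, params$gamma,
                     params$kappa, mode_code(params$mode),
                     params$steps_total, as.integer(snapshot_steps),
                     isTRUE(collect_ledger))
  fr <- res$fractions
  fractions <- data.frame(step = 0:params$steps_total,
                          frac_CN = fr[, 1], frac_DN = fr[, 2],
                          frac_CP = fr[, 3], frac_DP = fr[, 4])
  structure(
    list(fractions = fractions,
         final = new_population(res$grid),
         snapshots = lapply(res$snapshots, new_population),
         ledger = if (isTRUE(collect_ledger)) {
           list(imposed = res$imposed, received = res$received)
         },
         absorbed = if (res$absorbed < 0) NA_integer_ else res$absorbed,
         params = params),
    class = "pd_trajectory")
}

#' Trailing-window time average of strategy fractions
#'
#' Mean of the four strategy fractions over the last `window` recorded
#' Monte Carlo steps of a trajectory, the quantity ensembles and sweeps
#' are built from.
#'
#' @param traj A `pd_trajectory`.
#' @param window Number of trailing steps; defaults to the trajectory's
#'   `steps_average`. If the run is shorter than `window`, all recorded
#'   steps (including the initial state) are used.
#' @return Named numeric vector with elements `CN`, `DN`, `CP`, `DP`.
#' @export
time_average <- function(traj, window = traj$params$steps_average) {
  stopifnot(inherits(traj, "pd_trajectory"))
  check_count(window, "window", min = 1)
  fr <- traj$fractions
  rows <- tail(seq_len(nrow(fr)), window)
  out <- colMeans(fr[rows, c("frac_CN", "frac_DN", "frac_CP", "frac_DP")])
  names(out) <- STRATEGIES
  out
}

#' @export
print.pd_trajectory <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "pd_trajectory: L = %d, mode = %s, r = %g, beta = %g, gamma = %g\n",
    p$L, p$mode, p$r, p$beta, p$gamma))
  cat(sprintf("  %d MC steps%s\n", p$steps_total,
              if (is.na(x$absorbed)) ""
              else sprintf(" (monomorphic from step %d)", x$absorbed)))
  fr <- time_average(x)
  cat("  trailing average:",
      paste(sprintf("%s = %.3f", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}
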