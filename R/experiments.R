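#' Ensemble of independent replicate runs
#'
#' Runs `replicates` independent simulations (replicate k seeded with
#' `params$seed + k` when a seed is set, or with the explicit `seeds`),
#' time-averages each over its trailing window, and returns ensemble
#' means with Monte Carlo standard errors.
#'
#' @param params A [pd_params()] object.
#' @param replicates Number of independent runs (>= 1).
#' @param seeds Optional integer vector of per-replicate seeds
#'   (overrides the `params$seed + k` rule).
#' @param ... Passed to [run_simulation()] (e.g. `init`, `strategies`,
#'   `layout`).
#' @return A `pd_ensemble`: list with `mean` and `se` (named fraction
#'   vectors), `cooperation`, `cooperation_se`, `defection`,
#'   `defection_se`, the per-replicate fraction matrix `replicates`, and
#'   the seeds used.
#' @examples
#' p <- pd_params(r = 0.05, L = 20, steps_total = 100, steps_average = 20,
#'                mode = "none", seed = 1)
#' run_ensemble(p, replicates = 2)
#' @export
run_ensemble <- function(params, replicates = 5, seeds = NULL, ...) {
  stopifnot(inherits(params, "pd_params"))
  check_count(replicates, "replicates", min = 1)
  if (is.null(seeds)) {
    if (!is.null(params$seed)) seeds <- params$seed + seq_len(replicates)
  } else if (length(seeds) != replicates) {
    stop("'seeds' must have one entry per replicate", call. = FALSE)
  }
  per <- matrix(NA_real_, nrow = replicates, ncol = 4,
                dimnames = list(NULL, STRATEGIES))
  for (k in seq_len(replicates)) {
    pk <- params
    pk$seed <- if (is.null(seeds)) NULL else as.integer(seeds[k])
    per[k, ] <- time_average(run_simulation(pk, ...))
  }
  m <- colMeans(per)
  se <- apply(per, 2, sd) / sqrt(replicates)
  coop <- per[, "CN"] + per[, "CP"]
  defe <- per[, "DN"] + per[, "DP"]
  structure(
    list(mean = m, se = se,
         cooperation = mean(coop),
         cooperation_se = sd(coop) / sqrt(replicates),
         defection = mean(defe),
         defection_se = sd(defe) / sqrt(replicates),
         replicates = per, seeds = seeds, params = params),
    class = "pd_ensemble")
}

#' @export
print.pd_ensemble <- function(x, ...) {
  cat(sprintf("pd_ensemble: %d replicates, mode = %s\n",
              nrow(x$replicates), x$params$mode))
  cat("  mean fractions:",
      paste(sprintf("%s = %.3f (SE %.3f)", names(x$mean), x$mean, x$se),
            collapse = ", "), "\n")
  cat(sprintf("  cooperation level %.3f (SE %.3f)\n",
              x$cooperation, x$cooperation_se))
  invisible(x)
}

#' Sweep the punishment cost or fine
#'
#' Runs one ensemble per grid value and punishment mode, holding all
#' other parameters fixed, and collects ensemble-mean strategy
#' fractions, cooperation and defection levels with standard errors.
#' Per-configuration seeds are derived deterministically from
#' `params$seed` so results do not depend on evaluation order.
#'
#' @param params Template [pd_params()]; the swept field and `mode` are
#'   overridden per grid point.
#' @param axis `"gamma"` or `"beta"`: which punishment parameter to
#'   sweep.
#' @param grid Numeric vector of axis values.
#' @param modes Punishment modes to sweep (default: the template's).
#' @param replicates Replicates per grid point.
#' @param ... Passed to [run_simulation()].
#' @return Data frame with one row per (value, mode): columns `mode`,
#'   `gamma`, `beta`, `value`, `frac_*`, `se_*`, `cooperation`,
#'   `se_cooperation`, `defection`, `se_defection`, `replicates`.
#' @export
sweep_parameter <- function(params, axis = c("gamma", "beta"), grid,
                            modes = params$mode, replicates = 5, ...) {
  stopifnot(inherits(params, "pd_params"))
  axis <- match.arg(axis)
  if (length(grid) == 0) stop("'grid' must be nonempty", call. = FALSE)
  rows <- vector("list", length(grid) * length(modes))
  idx <- 0
  for (mode in modes) {
    for (v in grid) {
      idx <- idx + 1
      pk <- params
      pk$mode <- mode
      pk[[axis]] <- v
      pk$seed <- config_seed(params$seed, mode, axis, v)
      ens <- run_ensemble(pk, replicates = replicates, ...)
      rows[[idx]] <- data.frame(
        mode = mode, gamma = pk$gamma, beta = pk$beta, value = v,
        frac_CN = ens$mean[["CN"]], frac_DN = ens$mean[["DN"]],
        frac_CP = ens$mean[["CP"]], frac_DP = ens$mean[["DP"]],
        se_CN = ens$se[["CN"]], se_DN = ens$se[["DN"]],
        se_CP = ens$se[["CP"]], se_DP = ens$se[["DP"]],
        cooperation = ens$cooperation, se_cooperation = ens$cooperation_se,
        defection = ens$defection, se_defection = ens$defection_se,
        replicates = replicates)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Deterministic per-configuration seed, independent of sweep ordering and
# kept within the 32-bit integer range.
config_seed <- function(base, mode, axis, value) {
  if (is.null(base)) return(NULL)
  bytes <- utf8ToInt(paste(mode, axis, format(value, digits = 10),
                           sep = "|"))
  h <- sum(as.numeric(bytes) * seq_along(bytes) * 131) %% 2147483563
  as.integer((as.numeric(base) * 7919 + h) %% 2147483563)
}

#' Cost-fine phase map of cooperation levels
#'
#' Evaluates the long-run cooperation level on a 2-D grid of punishment
#' cost and fine for both punishment scopes and returns per-cell levels
#' and their difference. The sign convention is direct minus indirect,
#' so cells where the spatially indirect form sustains more cooperation
#' are negative.
#'
#' @param params Template [pd_params()].
#' @param gamma_grid,beta_grid Numeric axis grids (nonempty).
#' @param modes The two modes to compare (default direct and indirect).
#' @param replicates Replicates per cell and mode.
#' @param ... Passed to [run_simulation()].
#' @return Data frame with columns `gamma`, `beta`, one
#'   `cooperation_<mode>` / `se_<mode>` pair per mode, and `difference`
#'   (first mode minus second). Carries attribute
#'   `difference_convention`.
#' @export
phase_map <- function(params, gamma_grid, beta_grid,
                      modes = c("direct", "indirect"), replicates = 5,
                      ...) {
  stopifnot(inherits(params, "pd_params"))
  if (length(gamma_grid) == 0 || length(beta_grid) == 0) {
    stop("axis grids must be nonempty", call. = FALSE)
  }
  cells <- expand.grid(gamma = gamma_grid, beta = beta_grid)
  out <- cells
  for (mode in modes) {
    lev <- numeric(nrow(cells))
    se <- numeric(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      pk <- params
      pk$mode <- mode
      pk$gamma <- cells$gamma[i]
      pk$beta <- cells$beta[i]
      pk$seed <- config_seed(params$seed, mode, "phase",
                             cells$gamma[i] * 1000 + cells$beta[i])
      ens <- run_ensemble(pk, replicates = replicates, ...)
      lev[i] <- ens$cooperation
      se[i] <- ens$cooperation_se
    }
    out[[paste0("cooperation_", mode)]] <- lev
    out[[paste0("se_", mode)]] <- se
  }
  if (length(modes) == 2) {
    out$difference <- out[[paste0("cooperation_", modes[1])]] -
      out[[paste0("cooperation_", modes[2])]]
  }
  attr(out, "difference_convention") <-
    paste(modes, collapse = " minus ")
  out
}

#' Locate a threshold along a punishment-parameter axis
#'
#' Scans `grid` (evaluating every point, so non-monotone criteria such
#' as the reentrant fine response under indirect punishment are handled),
#' finds where `criterion` first (or last) holds, and optionally refines
#' the bracketing interval with one finer scan.
#'
#' @param params Template [pd_params()].
#' @param axis `"gamma"` or `"beta"`.
#' @param grid Coarse scan values (ascending).
#' @param criterion Predicate `function(ensemble) TRUE/FALSE` evaluated
#'   on each grid point's [run_ensemble()] result, e.g.
#'   `function(e) e$cooperation < 0.01`.
#' @param pick `"first"`: smallest grid value where the criterion holds;
#'   `"last"`: largest.
#' @param replicates Replicates per grid point.
#' @param refine If `TRUE`, rescan the interval between the located
#'   value and its non-qualifying neighbor at a quarter of the grid
#'   spacing.
#' @param ... Passed to [run_simulation()].
#' @return A list of class `pd_threshold` with the located `value` (`NA`
#'   if the criterion never holds), the scanned `grid`, logical `flags`,
#'   and refinement details.
#' @export
find_threshold <- function(params, axis = c("gamma", "beta"), grid,
                           criterion, pick = c("first", "last"),
                           replicates = 5, refine = FALSE, ...) {
  axis <- match.arg(axis)
  pick <- match.arg(pick)
  if (length(grid) < 2) stop("'grid' needs at least two values",
                             call. = FALSE)
  grid <- sort(grid)
  eval_point <- function(v) {
    pk <- params
    pk[[axis]] <- v
    pk$seed <- config_seed(params$seed, params$mode, axis, v)
    isTRUE(criterion(run_ensemble(pk, replicates = replicates, ...)))
  }
  flags <- vapply(grid, eval_point, logical(1))
  if (!any(flags)) {
    return(structure(list(value = NA_real_, grid = grid, flags = flags,
                          refined = NULL),
                     class = "pd_threshold"))
  }
  i <- if (pick == "first") which(flags)[1] else max(which(flags))
  value <- grid[i]
  refined <- NULL
  nb <- if (pick == "first") i - 1 else i + 1
  if (isTRUE(refine) && nb >= 1 && nb <= length(grid) && !flags[nb]) {
    lo <- min(grid[i], grid[nb])
    hi <- max(grid[i], grid[nb])
    fine <- seq(lo, hi, length.out = 5)[2:4]
    fflags <- vapply(fine, eval_point, logical(1))
    cand <- c(fine[fflags], value)
    value <- if (pick == "first") min(cand) else max(c(fine[fflags],
                                                       grid[i]))
    refined <- list(grid = fine, flags = fflags)
  }
  structure(list(value = value, grid = grid, flags = flags,
                 refined = refined),
            class = "pd_threshold")
}

#' @export
print.pd_threshold <- function(x, ...) {
  if (is.na(x$value)) {
    cat("pd_threshold: criterion never satisfied on the scanned grid\n")
  } else {
    cat(sprintf("pd_threshold: value = %g (grid %g..%g)\n", x$value,
                min(x$grid), max(x$grid)))
  }
  invisible(x)
}

#' Reemergence threshold on a reentrant sweep
#'
#' Under indirect punishment the fine response is reentrant: cooperation
#' is established at small fines, is then degraded at intermediate fines
#' where second-order free-riders (CN) displace the punishers, and
#' reemerges at large fines. Given an ascending sweep of a punishment
#' parameter, this locates the smallest axis value after the intermediate
#' low-cooperation window at which cooperation is back above `low`.
#'
#' The window is taken as the scan points where cooperation is at or
#' below `low`. On small lattices and short runs the dip may stay above
#' `low`; the window is then located at the cooperation minimum of the
#' scan and reemergence additionally requires defection to be eliminated
#' to within `defection_tol`, the signature of restored full cooperation.
#'
#' @param values Ascending axis values of the scan.
#' @param cooperation Ensemble-mean cooperation level per value.
#' @param defection Ensemble-mean defector fraction per value.
#' @param low Cooperation level at or below which a scan point belongs
#'   to the low-cooperation window (default 0.5).
#' @param defection_tol Residual defector fraction tolerated when the
#'   shallow-dip fallback is used (default 0.05).
#' @return The reemergence axis value, or `NA` if cooperation never
#'   recovers within the scan.
#' @export
reemergence_threshold <- function(values, cooperation, defection,
                                  low = 0.5, defection_tol = 0.05) {
  stopifnot(length(values) == length(cooperation),
            length(values) == length(defection),
            !is.unsorted(values))
  win <- which(cooperation <= low)
  if (length(win) > 0) {
    after <- which(seq_along(values) > max(win) & cooperation > low)
  } else {
    dip <- which.min(cooperation)
    after <- which(seq_along(values) > dip & cooperation > low &
                     defection < defection_tol)
  }
  if (length(after) == 0) return(NA_real_)
  values[after[1]]
}

#' Replay a block-invasion experiment
#'
#' Evolves a lattice partitioned into four equal strategy quadrants
#' (default layout `[CN, CP; DN, DP]`) under the given punishment mode,
#' recording strategy fractions, lattice snapshots and the per-step
#' punishment ledger. This is the setting used to study how CP clusters
#' expand or collapse against DN invasion at fixed fine.
#'
#' @param mode `"direct"` or `"indirect"`.
#' @param gamma Punishment cost.
#' @param beta Fine (default 0.2).
#' @param r Dilemma strength (default 0.2).
#' @param kappa Imitation strength (default 10).
#' @param L Lattice side (default 50).
#' @param steps Monte Carlo steps (default 2000).
#' @param seed RNG seed.
#' @param layout Block layout, see [init_block()].
#' @param snapshot_steps Steps at which snapshots are stored.
#' @param collect_ledger Tally punishment events per step (default
#'   `TRUE`).
#' @return A `pd_trajectory` (see [run_simulation()]).
#' @export
replay_block_invasion <- function(mode = c("direct", "indirect"),
                                  gamma, beta = 0.2, r = 0.2, kappa = 10,
                                  L = 50, steps = 2000, seed = 1,
                                  layout = default_block_layout(),
                                  snapshot_steps = c(0, 50, 200, 1000,
                                                     steps),
                                  collect_ledger = TRUE) {
  mode <- match.arg(mode)
  params <- pd_params(r = r, beta = beta, gamma = gamma, kappa = kappa,
                      L = L, mode = mode, steps_total = steps,
                      steps_average = min(500, steps), seed = seed)
  run_simulation(params, init = "block", layout = layout,
                 snapshot_steps = snapshot_steps,
                 collect_ledger = collect_ledger)
}
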