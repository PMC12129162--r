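#' Simulation parameters
#'
#' Collects and validates the full parameter set of one lattice simulation.
#' The first-stage prisoner's dilemma is parametrized by the dilemma
#' strength `r`, giving payoffs R = 1, P = 0, T = 1 + r and S = -r, so
#' that T > R > P > S and 2R > T + S hold for every r > 0. The second
#' stage deducts a fine `beta` from each punished defector and a cost
#' `gamma` from the punisher, per punishment act.
#'
#' @param r Dilemma strength (dimensionless, >= 0). The temptation to
#'   defect is `1 + r` and the sucker's payoff is `-r`.
#' @param beta Fine deducted from a punished defector per punishment act
#'   (payoff units, >= 0).
#' @param gamma Cost paid by the punisher per punishment act (payoff
#'   units, >= 0).
#' @param kappa Imitation strength of the Fermi rule (dimensionless,
#'   >= 0). `kappa = 0` makes imitation random; large `kappa` makes it
#'   strongly payoff-driven. Default 10 (strong imitation).
#' @param L Lattice side length (sites). Must be at least 5 so that the
#'   sixteen second-order neighbors are distinct under the periodic wrap.
#' @param mode Punishment mode: `"direct"` (second stage with the eight
#'   first-order neighbors), `"indirect"` (second stage with the sixteen
#'   second-order neighbors), or `"none"` (no second stage).
#' @param steps_total Number of Monte Carlo steps; each step performs
#'   `L^2` elementary updates.
#' @param steps_average Length of the trailing window (in steps) over
#'   which strategy fractions are time-averaged.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#'   Replicate k of an ensemble uses `seed + k`.
#' @return An object of class `pd_params`: a list with the arguments plus
#'   the derived payoff elements `T`, `S`, `R` and `P`.
#' @examples
#' p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.01, mode = "indirect")
#' p$T  # 1.2
#' @export
pd_params <- function(r, beta = 0, gamma = 0, kappa = 10, L = 50,
                      mode = c("direct", "indirect", "none"),
                      steps_total = 5000, steps_average = 500,
                      seed = NULL) {
  mode <- match.arg(mode)
  check_scalar(r, "r", min = 0)
  check_scalar(beta, "beta", min = 0)
  check_scalar(gamma, "gamma", min = 0)
  check_scalar(kappa, "kappa", min = 0)
  check_count(L, "L", min = 5,
              extra = "(the second-order neighborhood would alias sites)")
  check_count(steps_total, "steps_total", min = 0)
  check_count(steps_average, "steps_average", min = 1)
  if (steps_total > 0 && steps_average > steps_total) {
    stop("steps_average (", steps_average,
         ") must not exceed steps_total (", steps_total, ")", call. = FALSE)
  }
  if (!is.null(seed)) check_count(seed, "seed", min = -2^31 + 1)
  structure(
    list(r = r, beta = beta, gamma = gamma, kappa = kappa, L = as.integer(L),
         mode = mode, steps_total = as.integer(steps_total),
         steps_average = as.integer(steps_average),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         R = 1, P = 0, T = 1 + r, S = -r),
    class = "pd_params"
  )
}

#' @export
print.pd_params <- function(x, ...) {
  cat("Two-stage spatial prisoner's dilemma parameters\n")
  cat(sprintf("  dilemma strength r = %g  (T = %g, S = %g, R = 1, P = 0)\n",
              x$r, x$T, x$S))
  cat(sprintf("  punishment: mode = %s, fine beta = %g, cost gamma = %g\n",
              x$mode, x$beta, x$gamma))
  cat(sprintf("  imitation strength kappa = %g\n", x$kappa))
  cat(sprintf("  lattice %d x %d (%d players), %d MC steps, average last %d\n",
              x$L, x$L, x$L^2, x$steps_total, x$steps_average))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

mode_code <- function(mode) {
  switch(mode, none = 0L, direct = 1L, indirect = 2L,
         stop("unknown punishment mode: ", mode, call. = FALSE))
}

check_scalar <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (x < min) {
    stop("'", name, "' must be >= ", min, " (got ", x, ")", call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min, extra = NULL) {
  check_scalar(x, name)
  if (x != round(x)) stop("'", name, "' must be an integer", call. = FALSE)
  if (x < min) {
    stop("'", name, "' must be >= ", min, " (got ", x, ") ",
         if (is.null(extra)) "" else extra, call. = FALSE)
  }
  invisible(x)
}
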