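# Configuration files, plain-text snapshot and trajectory writers, and
# deterministic test fixtures.

PARAM_KEYS <- c("r", "beta", "gamma", "kappa", "L", "mode", "steps_total",
                "steps_average", "seed")
EXPERIMENT_KEYS <- c("axis", "grid", "gamma_grid", "beta_grid",
                     "replicates", "modes", "init", "layout",
                     "snapshot_steps", "output_dir")

#' Load and validate a run configuration
#'
#' Reads a flat key-value configuration (YAML or JSON, chosen by file
#' extension), fills defaults for any omitted simulation parameters
#' (notably `kappa = 10` and the desk-scale protocol `L = 50`,
#' `steps_total = 5000`, `steps_average = 500`), validates every value
#' through [pd_params()], and rejects unknown keys by name. Experiment
#' settings (grids, replicate counts, output paths, snapshot schedule)
#' live under an optional `experiment` block.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pd_config`: list with `params` (a [pd_params()]) and
#'   `experiment` (a possibly empty list).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("r: 0.2", "beta: 0.2", "gamma: 0.01", "mode: indirect"),
#'            cfg)
#' load_config(cfg)$params$kappa  # default 10
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config must be a key-value mapping",
                          call. = FALSE)
  unknown <- setdiff(names(raw), c(PARAM_KEYS, "experiment"))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!("r" %in% names(raw))) {
    stop("missing required configuration key: r", call. = FALSE)
  }
  experiment <- raw$experiment
  raw$experiment <- NULL
  if (!is.null(experiment)) {
    bad <- setdiff(names(experiment), EXPERIMENT_KEYS)
    if (length(bad) > 0) {
      stop("unknown experiment key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  params <- do.call(pd_params, raw)
  structure(list(params = params,
                 experiment = if (is.null(experiment)) list()
                 else experiment),
            class = "pd_config")
}

#' @rdname load_config
#' @param config A `pd_config` (or bare [pd_params()]) to serialize.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "pd_params")) {
    config <- structure(list(params = config, experiment = list()),
                        class = "pd_config")
  }
  stopifnot(inherits(config, "pd_config"))
  p <- config$params
  out <- p[PARAM_KEYS]
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(config$experiment) > 0) out$experiment <- config$experiment
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

provenance_header <- function(params, extra = NULL) {
  paste0("# spatpunish | ",
         sprintf("r=%g beta=%g gamma=%g kappa=%g L=%d mode=%s ",
                 params$r, params$beta, params$gamma, params$kappa,
                 params$L, params$mode),
         sprintf("steps_total=%d steps_average=%d seed=%s",
                 params$steps_total, params$steps_average,
                 if (is.null(params$seed)) "NA" else params$seed),
         if (is.null(extra)) "" else paste0(" | ", extra))
}

#' Plain-text lattice snapshots
#'
#' Writes a population as one row of single-character strategy codes per
#' lattice row (`C` = CN, `D` = DN, `P` = CP, `Q` = DP), optionally
#' preceded by `#` comment lines carrying the full parameter set for
#' provenance. `read_snapshot()` inverts the format exactly.
#'
#' @param pop A `pd_population`.
#' @param path Output (input) file path.
#' @param params Optional [pd_params()] written into the header comment.
#' @return `write_snapshot()` returns `path` invisibly;
#'   `read_snapshot()` returns a `pd_population`.
#' @export
write_snapshot <- function(pop, path, params = NULL) {
  pop <- as_population(pop)
  chars <- STRATEGY_CHARS[pop$grid]
  lines <- apply(matrix(chars, pop$L, pop$L), 1, paste, collapse = "")
  if (!is.null(params)) {
    lines <- c(provenance_header(params, "snapshot"), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  L <- length(lines)
  rows <- strsplit(lines, "")
  if (any(lengths(rows) != L)) {
    stop("snapshot is not a square character grid", call. = FALSE)
  }
  inv <- match(do.call(rbind, rows), STRATEGY_CHARS)
  if (anyNA(inv)) stop("snapshot contains unknown strategy characters",
                       call. = FALSE)
  as_population(matrix(as.integer(inv), L, L))
}

#' Export a trajectory as CSV
#'
#' Writes the per-step strategy fractions with columns `step`,
#' `frac_CN`, `frac_DN`, `frac_CP`, `frac_DP`, preceded by a `#` header
#' comment with the full parameter set and seed.
#'
#' @param traj A `pd_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pd_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(traj$params, "trajectory"), con)
  write.table(traj$fractions, con, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  read.table(path, sep = ",", header = TRUE, comment.char = "#")
}

#' Deterministic lattice fixtures
#'
#' Hand-specified configurations used in payoff and ledger tests:
#' \describe{
#'   \item{`lone_DN_in_CP`}{7 x 7 all-CP lattice with a single DN at the
#'     center.}
#'   \item{`halves_CP_DN`}{10 x 10 lattice, top half CP, bottom half DN.}
#'   \item{`quadrants`}{8 x 8 four-quadrant block layout
#'     `[CN, CP; DN, DP]`.}
#' }
#'
#' @param name Fixture identifier.
#' @return A `pd_population`.
#' @export
make_fixture <- function(name) {
  switch(name,
    lone_DN_in_CP = {
      g <- matrix(3L, 7, 7)
      g[4, 4] <- 2L
      as_population(g)
    },
    halves_CP_DN = {
      g <- matrix(2L, 10, 10)
      g[1:5, ] <- 3L
      as_population(g)
    },
    quadrants = init_block(8),
    stop("unknown fixture: ", name, call. = FALSE)
  )
}
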