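new_population <- function(grid) {
  structure(list(grid = grid, L = nrow(grid)), class = "pd_population")
}

#' Lattice populations of strategies
#'
#' A `pd_population` is an `L` x `L` toroidal grid of strategy codes
#' (1 = CN, 2 = DN, 3 = CP, 4 = DP). `init_random()` assigns each site one
#' of the given strategies independently and uniformly; `init_block()`
#' partitions the lattice into equal contiguous rectangular blocks, one
#' strategy per block, for invasion experiments. `as_population()` wraps
#' an existing matrix of codes or labels.
#'
#' Random initialization draws from the current RNG stream; call
#' `set.seed()` first (or use [run_simulation()], which seeds from its
#' parameters) for reproducibility.
#'
#' @param L Lattice side length (>= 5).
#' @param strategies Character vector of strategy labels to draw from
#'   with equal probability. Defaults to all four; use
#'   `c("CN", "DN")` for a two-strategy punishment-free population.
#' @param layout Character matrix of strategy labels describing the block
#'   arrangement; each entry becomes one equal rectangular block. The
#'   default is the four-quadrant layout `[CN, CP; DN, DP]` (row-major).
#'   `L` must be divisible by both dimensions of the layout.
#' @param x For `as_population()`, a square integer matrix of codes 1..4
#'   or a character matrix of labels.
#' @return A `pd_population`.
#' @examples
#' set.seed(1)
#' pop <- init_random(10)
#' strategy_fractions(pop)
#' init_block(8)$grid
#' @export
init_random <- function(L, strategies = strategy_labels()) {
  check_count(L, "L", min = 5)
  codes <- strategy_code(strategies)
  grid <- matrix(codes[floor(runif(L * L) * length(codes)) + 1L],
                 nrow = L, ncol = L)
  storage.mode(grid) <- "integer"
  new_population(grid)
}

#' @rdname init_random
#' @export
default_block_layout <- function() {
  matrix(c("CN", "CP", "DN", "DP"), nrow = 2, ncol = 2, byrow = TRUE)
}

#' @rdname init_random
#' @export
init_block <- function(L, layout = default_block_layout()) {
  check_count(L, "L", min = 5)
  if (!is.matrix(layout) || !is.character(layout)) {
    stop("'layout' must be a character matrix of strategy labels",
         call. = FALSE)
  }
  codes <- matrix(strategy_code(layout), nrow = nrow(layout))
  if (L %% nrow(layout) != 0 || L %% ncol(layout) != 0) {
    stop("L = ", L, " is not divisible by the layout dimensions ",
         nrow(layout), " x ", ncol(layout), call. = FALSE)
  }
  bh <- L %/% nrow(layout)
  bw <- L %/% ncol(layout)
  grid <- matrix(0L, L, L)
  for (i in seq_len(nrow(layout))) {
    for (j in seq_len(ncol(layout))) {
      grid[(i - 1) * bh + seq_len(bh), (j - 1) * bw + seq_len(bw)] <-
        codes[i, j]
    }
  }
  new_population(grid)
}

#' @rdname init_random
#' @export
as_population <- function(x) {
  if (inherits(x, "pd_population")) return(x)
  if (is.character(x)) x <- matrix(strategy_code(x), nrow = nrow(x))
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("a population grid must be a square matrix", call. = FALSE)
  }
  if (nrow(x) < 5) stop("lattice side L must be at least 5", call. = FALSE)
  if (!all(x %in% 1:4)) {
    stop("strategy codes must lie in 1..4", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  new_population(x)
}

#' Integer-coded snapshot of a population
#'
#' Returns the grid as integer codes 0..3 (CN = 0, DN = 1, CP = 2,
#' DP = 3), the array export format for snapshots.
#'
#' @param pop A `pd_population`.
#' @return An `L` x `L` integer matrix with values in 0..3.
#' @export
snapshot_codes <- function(pop) {
  pop <- as_population(pop)
  pop$grid - 1L
}

#' @export
print.pd_population <- function(x, ...) {
  fr <- strategy_fractions(x)
  cat(sprintf("pd_population: %d x %d lattice\n", x$L, x$L))
  cat("  fractions:",
      paste(sprintf("%s = %.3f", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}
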