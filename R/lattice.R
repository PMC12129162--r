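# Neighborhood geometry of the periodic square lattice.
#
# Sites are addressed either as (row, col) pairs, 1-based, or as linear
# indices in R's column-major order (site = row + (col - 1) * L).
# Neighbor offsets are enumerated in (dr, dc) lexicographic order
# everywhere (R and compiled code), which fixes the ordering used when a
# model neighbor is drawn during an update.

moore_offsets <- function() {
  off <- expand.grid(dc = -1:1, dr = -1:1)[, c("dr", "dc")]
  off <- off[order(off$dr, off$dc), ]
  as.matrix(off[!(off$dr == 0 & off$dc == 0), ])
}

ring2_offsets <- function() {
  off <- expand.grid(dc = -2:2, dr = -2:2)[, c("dr", "dc")]
  off <- off[order(off$dr, off$dc), ]
  as.matrix(off[pmax(abs(off$dr), abs(off$dc)) == 2, ])
}

#' First- and second-order neighbors on the periodic lattice
#'
#' `moore_neighbors()` returns the eight sites at Chebyshev distance one
#' from `site` (the Moore neighborhood); `second_order_neighbors()`
#' returns the sixteen sites at Chebyshev distance exactly two (the 5x5
#' Chebyshev ball minus the 3x3 ball), i.e. the neighbors of neighbors
#' excluding the focal site and its direct neighbors. Both wrap
#' toroidally.
#'
#' @param site Length-2 integer vector `c(row, col)`, 1-based.
#' @param L Lattice side length; at least 3 for `moore_neighbors()` and at
#'   least 5 for `second_order_neighbors()` (smaller lattices would alias
#'   ring sites under the wrap).
#' @return An 8x2 (respectively 16x2) integer matrix of `(row, col)`
#'   coordinates, in a fixed deterministic order.
#' @examples
#' moore_neighbors(c(1, 1), L = 5)
#' second_order_neighbors(c(3, 3), L = 5)
#' @export
moore_neighbors <- function(site, L) {
  check_site(site, L, min_L = 3)
  wrap_offsets(site, L, moore_offsets())
}

#' @rdname moore_neighbors
#' @export
second_order_neighbors <- function(site, L) {
  check_site(site, L, min_L = 5)
  wrap_offsets(site, L, ring2_offsets())
}

check_site <- function(site, L, min_L) {
  check_count(L, "L", min = min_L)
  if (length(site) != 2 || any(site != round(site)) ||
      any(site < 1) || any(site > L)) {
    stop("'site' must be a (row, col) pair within 1..", L, call. = FALSE)
  }
  invisible(site)
}

wrap_offsets <- function(site, L, off) {
  out <- cbind(row = (site[1] - 1 + off[, 1]) %% L + 1,
               col = (site[2] - 1 + off[, 2]) %% L + 1)
  rownames(out) <- NULL
  out
}

#' Precomputed neighbor index tables
#'
#' Linear-index lookup tables for every site of an `L` x `L` periodic
#' lattice: row `i` of `$first` holds the 8 first-order (Moore) neighbors
#' of site `i`, row `i` of `$second` the 16 second-order neighbors.
#' Indices are 1-based column-major. Tables are cached per `L`.
#'
#' @param L Lattice side length (>= 5).
#' @return A list with integer matrices `first` (`L^2` x 8) and `second`
#'   (`L^2` x 16).
#' @export
neighbor_tables <- function(L) {
  check_count(L, "L", min = 5)
  key <- paste0("nt", L)
  cached <- .spatpunish_env[[key]]
  if (!is.null(cached)) return(cached)
  n <- L * L
  row <- rep(seq_len(L), times = L)
  col <- rep(seq_len(L), each = L)
  idx <- function(off) {
    m <- matrix(0L, nrow = n, ncol = nrow(off))
    for (k in seq_len(nrow(off))) {
      rr <- (row - 1 + off[k, 1]) %% L
      cc <- (col - 1 + off[k, 2]) %% L
      m[, k] <- rr + cc * L + 1L
    }
    m
  }
  out <- list(first = idx(moore_offsets()), second = idx(ring2_offsets()))
  .spatpunish_env[[key]] <- out
  out
}
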