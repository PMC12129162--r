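# Independent brute-force oracles. These deliberately avoid the package's
# neighbor tables and payoff code: neighborhoods come from toroidal
# Chebyshev distances computed over all site pairs, and payoff tables are
# written out literally.

# Toroidal Chebyshev distance between two (row, col) sites.
torus_chebyshev <- function(a, b, L) {
  dr <- abs(a[1] - b[1])
  dc <- abs(a[2] - b[2])
  max(min(dr, L - dr), min(dc, L - dc))
}

# N x N matrix of pairwise toroidal Chebyshev distances (linear
# column-major site order).
torus_distance_matrix <- function(L) {
  coords <- cbind(rep(seq_len(L), times = L), rep(seq_len(L), each = L))
  n <- L * L
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- torus_chebyshev(coords[i, ], coords[j, ], L)
    }
  }
  d
}

# Literal stage tables: rows/cols ordered CN, DN, CP, DP.
oracle_stage1 <- function(r) {
  matrix(c(1, -r, 1, -r,
           1 + r, 0, 1 + r, 0,
           1, -r, 1, -r,
           1 + r, 0, 1 + r, 0),
         nrow = 4, byrow = TRUE)
}

oracle_stage2 <- function(beta, gamma) {
  matrix(c(0, 0, 0, 0,
           0, 0, -beta, -beta,
           0, -gamma, 0, -gamma,
           0, -gamma, -beta, -beta - gamma),
         nrow = 4, byrow = TRUE)
}

# Total payoffs of every site by scanning all ordered pairs.
oracle_total_payoffs <- function(pop, params) {
  L <- pop$L
  d <- torus_distance_matrix(L)
  s <- as.vector(pop$grid)
  a1 <- oracle_stage1(params$r)
  a2 <- oracle_stage2(params$beta, params$gamma)
  n <- L * L
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- 0
    for (j in seq_len(n)) {
      if (d[i, j] == 1) p <- p + a1[s[i], s[j]]
      if (params$mode == "direct" && d[i, j] == 1) p <- p + a2[s[i], s[j]]
      if (params$mode == "indirect" && d[i, j] == 2) p <- p + a2[s[i], s[j]]
    }
    out[i] <- p
  }
  out
}

# Punishment acts by scanning all ordered (punisher, defector) pairs.
oracle_ledger <- function(pop, params) {
  L <- pop$L
  d <- torus_distance_matrix(L)
  s <- as.vector(pop$grid)
  want <- if (params$mode == "direct") 1L else 2L
  n <- L * L
  imposed <- integer(n)
  received <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (d[i, j] == want && s[i] %in% c(3, 4) && s[j] %in% c(2, 4)) {
        imposed[i] <- imposed[i] + 1L
        received[j] <- received[j] + 1L
      }
    }
  }
  list(imposed = imposed, received = received)
}

random_population <- function(L) {
  as_population(matrix(sample.int(4, L * L, replace = TRUE), L, L))
}
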