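#' Stage payoff matrices of the two-stage game
#'
#' Row-player payoff tables for the two stages. Stage 1 is the
#' prisoner's dilemma with R = 1, P = 0, T = 1 + r, S = -r; it depends
#' only on the cooperate/defect component, so the CN and CP rows are
#' identical, as are DN and DP. Stage 2 is the punishment exchange: a
#' punisher (CP, DP) pays `-gamma` against each defector column (DN,
#' DP), a defector (DN, DP) receives `-beta` against each punisher
#' column (CP, DP), and the DP row is the sum of the DN and CP rows.
#'
#' @param params A [pd_params()] object (only `r`, `beta`, `gamma` are
#'   used; the stage-2 table is the same for both punishment scopes).
#' @return A list with two 4x4 numeric matrices, `stage1` and `stage2`,
#'   with strategy labels as dimnames (rows = focal player).
#' @examples
#' payoff_matrices(pd_params(r = 0.2, beta = 0.2, gamma = 0.05))
#' @export
payoff_matrices <- function(params) {
  stopifnot(inherits(params, "pd_params"))
  coop <- unname(COOPERATES)
  pun <- unname(PUNISHES)
  stage1 <- outer(seq_len(4), seq_len(4), function(f, o) {
    ifelse(coop[f],
           ifelse(coop[o], params$R, params$S),
           ifelse(coop[o], params$T, params$P))
  })
  stage2 <- outer(seq_len(4), seq_len(4), function(f, o) {
    -params$gamma * (pun[f] & !coop[o]) - params$beta * (!coop[f] & pun[o])
  })
  dimnames(stage1) <- dimnames(stage2) <- list(STRATEGIES, STRATEGIES)
  list(stage1 = stage1, stage2 = stage2)
}

#' Per-site payoffs on the current configuration
#'
#' `stage1_payoff()` sums the stage-1 table over the eight first-order
#' neighbors. `stage2_payoff()` sums the stage-2 (punishment) table over
#' the punishment scope: the eight first-order neighbors under direct
#' punishment, the sixteen second-order neighbors under indirect
#' punishment, and nothing when `mode = "none"`. `total_payoff()` is
#' their sum, always evaluated on the configuration as passed (no
#' caching across strategy changes).
#'
#' @param pop A `pd_population` (or square code matrix).
#' @param site A length-2 vector is read as a `c(row, col)` pair; any
#'   other vector as linear (column-major) site indices.
#' @param params A [pd_params()] object.
#' @return Numeric payoff value(s), one per site.
#' @examples
#' p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.05, mode = "direct", L = 7)
#' pop <- make_fixture("lone_DN_in_CP")
#' total_payoff(pop, c(4, 4), p)  # the lone defector: 8(1 + r) - 8 beta
#' @export
total_payoff <- function(pop, site, params) {
  stage1_payoff(pop, site, params) + stage2_payoff(pop, site, params)
}

#' @rdname total_payoff
#' @export
stage1_payoff <- function(pop, site, params) {
  pop <- as_population(pop)
  i <- site_index(site, pop$L)
  m <- payoff_matrices(params)$stage1
  nb <- neighbor_tables(pop$L)$first
  s <- as.vector(pop$grid)
  vapply(i, function(ii) sum(m[s[ii], s[nb[ii, ]]]), numeric(1))
}

#' @rdname total_payoff
#' @export
stage2_payoff <- function(pop, site, params) {
  pop <- as_population(pop)
  i <- site_index(site, pop$L)
  if (params$mode == "none") return(numeric(length(i)) + 0)
  m <- payoff_matrices(params)$stage2
  nt <- neighbor_tables(pop$L)
  scope <- if (params$mode == "direct") nt$first else nt$second
  s <- as.vector(pop$grid)
  vapply(i, function(ii) sum(m[s[ii], s[scope[ii, ]]]), numeric(1))
}

# A length-2 vector is read as a (row, col) pair; anything else as linear
# column-major indices.
site_index <- function(site, L) {
  if (length(site) == 2 && is.null(dim(site))) {
    if (any(site < 1) || any(site > L) || any(site != round(site))) {
      stop("'site' (row, col) must lie within 1..", L, call. = FALSE)
    }
    return(as.integer((site[2] - 1L) * L + site[1]))
  }
  site <- as.integer(site)
  if (any(site < 1) || any(site > L * L)) {
    stop("site index out of range", call. = FALSE)
  }
  site
}
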