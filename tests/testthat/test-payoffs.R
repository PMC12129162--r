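test_that("stage tables have the two-stage structure", {
  p <- pd_params(r = 0.2, beta = 0.3, gamma = 0.07)
  m <- payoff_matrices(p)
  # first stage depends only on cooperate/defect
  expect_equal(m$stage1["CN", ], m$stage1["CP", ])
  expect_equal(m$stage1["DN", ], m$stage1["DP", ])
  expect_equal(unname(m$stage1["CN", c("CN", "DN")]), c(1, -0.2))
  expect_equal(unname(m$stage1["DN", c("CN", "DN")]), c(1.2, 0))
  # second stage: CN inert, DN fined by punishers, CP pays to punish
  # defectors, DP row = DN row + CP row
  expect_equal(unname(m$stage2["CN", ]), rep(0, 4))
  expect_equal(unname(m$stage2["DN", ]), c(0, 0, -0.3, -0.3))
  expect_equal(unname(m$stage2["CP", ]), c(0, -0.07, 0, -0.07))
  expect_equal(m$stage2["DP", ], m$stage2["DN", ] + m$stage2["CP", ])
})

test_that("stage payoffs on hand-built configurations match closed forms", {
  L <- 7
  all_cn <- as_population(matrix(1L, L, L))
  p <- pd_params(r = 0.2, beta = 0.1, gamma = 0.05, mode = "direct", L = L)
  expect_equal(stage1_payoff(all_cn, c(4, 4), p), 8)

  # DN focal amid cooperators earns 8T; with punishment it loses 8 beta
  g <- matrix(1L, L, L); g[4, 4] <- 2L
  expect_equal(stage1_payoff(g, c(4, 4), p), 8 * 1.2)
  lone <- make_fixture("lone_DN_in_CP")
  expect_equal(total_payoff(lone, c(4, 4), p), 8 * 1.2 - 8 * 0.1)

  # CN on a cooperator/defector interface at r = 0.05: 5R + 3S
  mid <- as_population(rbind(matrix(1L, 5, 10), matrix(2L, 5, 10)))
  expect_equal(stage1_payoff(mid, c(5, 5), pd_params(r = 0.05, L = 10)),
               5 * 1 + 3 * (-0.05))
})

test_that("stage-2 scope follows the punishment mode", {
  lone <- make_fixture("lone_DN_in_CP")
  pd <- pd_params(r = 0.2, beta = 0.25, gamma = 0.03, mode = "direct",
                  L = 7)
  pi <- pd_params(r = 0.2, beta = 0.25, gamma = 0.03, mode = "indirect",
                  L = 7)
  pn <- pd_params(r = 0.2, beta = 0.25, gamma = 0.03, mode = "none",
                  L = 7)
  # the lone defector is fined once per punisher in scope
  expect_equal(stage2_payoff(lone, c(4, 4), pd), -8 * 0.25)
  expect_equal(stage2_payoff(lone, c(4, 4), pi), -16 * 0.25)
  expect_equal(stage2_payoff(lone, c(4, 4), pn), 0)
  # a CP direct neighbor punishes the defector only in direct mode
  expect_equal(stage2_payoff(lone, c(3, 3), pd), -0.03)
  expect_equal(stage2_payoff(lone, c(3, 3), pi), 0)
  # a CP two sites away punishes only in indirect mode
  expect_equal(stage2_payoff(lone, c(2, 2), pd), 0)
  expect_equal(stage2_payoff(lone, c(2, 2), pi), -0.03)
})

test_that("total payoffs equal the brute-force pair-scan oracle", {
  set.seed(42)
  for (rep in 1:60) {
    pop <- random_population(6)
    for (mode in c("direct", "indirect")) {
      p <- pd_params(r = runif(1, 0, 0.3), beta = runif(1, 0, 0.8),
                     gamma = runif(1, 0, 0.3), mode = mode, L = 6)
      expect_equal(total_payoff(pop, seq_len(36), p),
                   oracle_total_payoffs(pop, p), tolerance = 1e-12)
    }
  }
})

test_that("stage-2 totals account punishment acts exactly", {
  set.seed(7)
  for (rep in 1:20) {
    pop <- random_population(6)
    for (mode in c("direct", "indirect")) {
      p <- pd_params(r = 0.1, beta = 0.4, gamma = 0.15, mode = mode,
                     L = 6)
      acts <- sum(oracle_ledger(pop, p)$imposed)
      expect_equal(sum(stage2_payoff(pop, seq_len(36), p)),
                   -(p$beta + p$gamma) * acts, tolerance = 1e-12)
    }
  }
})

test_that("beta = gamma = 0 reduces totals to first-stage payoffs", {
  set.seed(8)
  pop <- random_population(8)
  for (mode in c("direct", "indirect", "none")) {
    p <- pd_params(r = 0.2, beta = 0, gamma = 0, mode = mode, L = 8)
    expect_equal(total_payoff(pop, seq_len(64), p),
                 stage1_payoff(pop, seq_len(64), p))
  }
  # and makes CP/CN, DP/DN payoff-indistinguishable: relabelling the
  # punishment component changes no payoff
  p <- pd_params(r = 0.15, beta = 0, gamma = 0, mode = "direct", L = 8)
  relab <- pop$grid
  relab[relab == 3L] <- 1L
  relab[relab == 4L] <- 2L
  expect_equal(total_payoff(pop, seq_len(64), p),
               total_payoff(as_population(relab), seq_len(64), p))
})
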