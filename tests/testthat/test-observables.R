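test_that("strategy fractions and cooperation level on fixed lattices", {
  all_cp <- as_population(matrix(3L, 6, 6))
  expect_equal(unname(strategy_fractions(all_cp)), c(0, 0, 1, 0))
  expect_equal(cooperation_level(all_cp), 1)
  expect_equal(cooperation_level(as_population(matrix(2L, 6, 6))), 0)
  expect_equal(unname(strategy_fractions(make_fixture("quadrants"))),
               rep(0.25, 4))
  expect_equal(unname(strategy_fractions(make_fixture("halves_CP_DN"))),
               c(0, 0.5, 0.5, 0))
  stripes <- as_population(rbind(matrix(1L, 3, 6), matrix(4L, 3, 6)))
  expect_equal(cooperation_level(stripes), 0.5)
  set.seed(2)
  expect_equal(sum(strategy_fractions(random_population(9))), 1)
})

test_that("ledger entries on hand-placed configurations", {
  lone <- make_fixture("lone_DN_in_CP")
  pd <- pd_params(r = 0.2, beta = 0.2, gamma = 0.01, mode = "direct",
                  L = 7)
  led <- punishment_event_stats(lone, pd)
  def <- led[led$role == "defector", ]
  expect_equal(nrow(def), 1)
  expect_equal(def$acts, 8)
  expect_equal(def$amount, 8 * 0.2)
  # the 8 surrounding CP each punish once
  pun <- led[led$role == "punisher", ]
  expect_equal(nrow(pun), 8)
  expect_true(all(pun$acts == 1))
  expect_equal(sum(pun$acts), sum(def$acts))

  pi <- pd_params(r = 0.2, beta = 0.2, gamma = 0.01, mode = "indirect",
                  L = 7)
  led2 <- punishment_event_stats(lone, pi)
  def2 <- led2[led2$role == "defector", ]
  expect_equal(def2$acts, 16)
  expect_equal(def2$amount, 16 * 0.2)
  expect_equal(nrow(led2[led2$role == "punisher", ]), 16)

  # all-cooperator lattice and mode = none yield empty ledgers
  all_cp <- as_population(matrix(3L, 7, 7))
  expect_equal(nrow(punishment_event_stats(all_cp, pd)), 0)
  pn <- pd_params(r = 0.2, beta = 0.2, gamma = 0.01, mode = "none", L = 7)
  expect_equal(nrow(punishment_event_stats(lone, pn)), 0)
})

test_that("ledger agrees with the brute-force pair scan and conserves acts", {
  set.seed(31)
  for (rep in 1:15) {
    pop <- random_population(6)
    for (mode in c("direct", "indirect")) {
      p <- pd_params(r = 0.2, beta = 0.3, gamma = 0.04, mode = mode,
                     L = 6)
      led <- punishment_event_stats(pop, p)
      ora <- oracle_ledger(pop, p)
      imp <- led[led$role == "punisher", ]
      rec <- led[led$role == "defector", ]
      expect_equal(sum(imp$acts), sum(rec$acts)) # conservation
      expect_equal(sum(imp$acts), sum(ora$imposed))
      got_imp <- integer(36); got_imp[imp$site] <- imp$acts
      got_rec <- integer(36); got_rec[rec$site] <- rec$acts
      expect_equal(got_imp, ora$imposed)
      expect_equal(got_rec, ora$received)
      cap <- if (mode == "direct") 8 else 16
      expect_true(all(led$acts <= cap))
    }
  }
})

test_that("per-step ledgers from the engine match the configuration scan", {
  p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.02, mode = "indirect",
                 L = 10, steps_total = 5, steps_average = 1, seed = 21)
  traj <- run_simulation(p, snapshot_steps = 0:5, collect_ledger = TRUE)
  for (st in 1:5) {
    led <- punishment_event_stats(traj$snapshots[[as.character(st)]], p)
    imp <- tabulate(led$acts[led$role == "punisher"], nbins = 16)
    rec <- tabulate(led$acts[led$role == "defector"], nbins = 16)
    expect_equal(unname(traj$ledger$imposed[st, ]), imp)
    expect_equal(unname(traj$ledger$received[st, ]), rec)
  }
  pooled <- punishment_distributions(traj, until = 5)
  expect_equal(sum(pooled$imposed$count * pooled$imposed$acts),
               sum(pooled$received$count * pooled$received$acts))
  expect_equal(pooled$imposed$cost, 0.02 * (1:16))
  expect_equal(pooled$received$fine, 0.2 * (1:16))
})

test_that("stabilization detection finds the earliest quiet window", {
  const <- matrix(0.25, nrow = 501, ncol = 4)
  expect_equal(detect_stabilization(const, window = 100, tol = 0.005), 100)

  drift <- cbind(seq(0, 1, length.out = 301),
                 seq(1, 0, length.out = 301), 0, 0)
  expect_true(is.na(detect_stabilization(drift, window = 50,
                                         tol = 0.001)))

  # drifts until step 200 then freezes: first quiet window of 50 steps is
  # the one ending at step 249, entirely inside the frozen stretch
  frozen <- rbind(drift[1:201, ],
                  matrix(rep(drift[201, ], 300), ncol = 4, byrow = TRUE))
  expect_equal(detect_stabilization(frozen, window = 50, tol = 0.001),
               249)

  expect_true(is.na(detect_stabilization(const[1:20, ], window = 100)))
})
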