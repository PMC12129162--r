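test_that("Fermi probability matches its closed form and limits", {
  expect_equal(fermi_probability(1.7, 1.7, 10), 0.5)
  expect_equal(fermi_probability(0, 0.5, 10), 0.9933071490757153)
  expect_equal(fermi_probability(0.5, 0, 10), 1 - 0.9933071490757153)
  # kappa = 0: exactly 1/2 whatever the payoffs
  set.seed(1)
  pi_i <- runif(50, -20, 20)
  pi_j <- runif(50, -20, 20)
  expect_equal(fermi_probability(pi_i, pi_j, 0), rep(0.5, 50))
  # monotone in the payoff gap
  w <- fermi_probability(0, seq(-5, 5, 0.5), 10)
  expect_true(all(diff(w) >= 0))
  # extreme gaps saturate instead of overflowing
  expect_equal(fermi_probability(-1e6, 1e6, 10), 1)
  expect_equal(fermi_probability(1e6, -1e6, 10), 0)
})

test_that("elementary update mutates at most the focal site", {
  set.seed(3)
  p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.05, mode = "direct",
                 L = 6)
  pop <- random_population(6)
  for (k in 1:30) {
    out <- elementary_update(pop, p)
    diff <- which(out$population$grid != pop$grid)
    expect_lte(length(diff), 1)
    if (length(diff) == 1) {
      expect_equal(diff, out$record$focal)
      expect_true(out$record$imitated)
      expect_equal(out$population$grid[diff],
                   pop$grid[out$record$model_neighbor])
    }
    expect_gte(out$record$prob, 0)
    expect_lte(out$record$prob, 1)
    pop <- out$population
  }
})

test_that("one MC step reproduces L^2 reference elementary updates", {
  for (cfg in list(list(L = 5, mode = "direct"),
                    list(L = 6, mode = "indirect"))) {
    p <- pd_params(r = 0.2, beta = 0.3, gamma = 0.06, mode = cfg$mode,
                   L = cfg$L, steps_total = 1, steps_average = 1)
    set.seed(123)
    start <- random_population(cfg$L)
    ref <- start
    for (k in seq_len(cfg$L^2)) {
      ref <- elementary_update(ref, p)$population
    }
    set.seed(123)
    start2 <- random_population(cfg$L)
    expect_identical(start$grid, start2$grid)
    fast <- mc_step(start2, p)
    expect_identical(fast$grid, ref$grid)
  }
})

test_that("monomorphic populations are absorbing", {
  p <- pd_params(r = 0.3, beta = 0.5, gamma = 0.1, mode = "indirect",
                 L = 6, steps_total = 20, steps_average = 5, seed = 4)
  for (code in 1:4) {
    pop <- as_population(matrix(code, 6, 6))
    traj <- run_simulation(p, pop = pop)
    expect_identical(traj$final$grid, pop$grid)
    expect_equal(traj$absorbed, 0)
    lab <- c("CN", "DN", "CP", "DP")[code]
    expect_true(all(traj$fractions[[paste0("frac_", lab)]] == 1))
  }
})

test_that("defectors cannot arise by imitation in an all-cooperator lattice", {
  p <- pd_params(r = 0.2, beta = 0, gamma = 0, mode = "none", L = 10,
                 steps_total = 60, steps_average = 10, seed = 9)
  pop <- init_block(10, matrix(c("CN", "CP"), 1, 2))
  traj <- run_simulation(p, pop = pop)
  expect_equal(traj$fractions$frac_CN + traj$fractions$frac_CP,
               rep(1, 61))
})

test_that("runs are deterministic given a seed and fractions always sum to 1", {
  p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.05, mode = "indirect",
                 L = 12, steps_total = 40, steps_average = 10, seed = 77)
  a <- run_simulation(p)
  b <- run_simulation(p)
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$final$grid, b$final$grid)
  sums <- rowSums(a$fractions[, -1])
  expect_equal(sums, rep(1, nrow(a$fractions)))
})

test_that("zero-step runs keep the initial configuration", {
  p <- pd_params(r = 0.1, L = 8, steps_total = 0, steps_average = 1,
                 mode = "none", seed = 2)
  traj <- run_simulation(p)
  expect_equal(nrow(traj$fractions), 1)
  expect_equal(unname(time_average(traj, 1)),
               unname(strategy_fractions(traj$final)))
})

test_that("snapshots are stored at the requested steps", {
  p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.02, mode = "direct",
                 L = 8, steps_total = 10, steps_average = 2, seed = 5)
  traj <- run_simulation(p, snapshot_steps = c(0, 3, 10))
  expect_named(traj$snapshots, c("0", "3", "10"))
  expect_identical(traj$snapshots[["10"]]$grid, traj$final$grid)
  fr <- strategy_fractions(traj$snapshots[["3"]])
  expect_equal(unname(sum(fr)), 1)
})
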