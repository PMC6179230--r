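test_that("payoff is the exploit term minus the quadratic fairness penalty", {
  expect_equal(payoff(c(1, 0), c(1, 0), alpha = 0.2), 0.8)
  set.seed(1)
  for (n in 2:5) {
    s <- runif(n)
    expect_equal(payoff(s, rep(1 / n, n), alpha = 0.2), mean(s) - 0.2 / n)
    expect_equal(payoff(s, rep(1 / n, n), alpha = 0), mean(s))
  }
  expect_error(payoff(c(1, 0), c(0.9, 0.3)), "simplex")
})

test_that("water-filling matches KKT hand cases", {
  expect_equal(optimal_allocation(c(0.8, 0.6, 0.4), alpha = 0.2),
               c(0.75, 0.25, 0))
  expect_equal(optimal_allocation(c(1, 0), alpha = 1), c(0.75, 0.25))
  expect_equal(optimal_allocation(rep(0.6, 4), alpha = 0.2), rep(0.25, 4))
  # strong leader at low alpha: all the work goes to the best team
  expect_equal(optimal_allocation(c(1, 0, 0, 0), alpha = 0.2), c(1, 0, 0, 0))
  # alpha = 0 degenerates to uniform split over the argmax set
  expect_equal(optimal_allocation(c(0.7, 0.7, 0.1), alpha = 0), c(0.5, 0.5, 0))
})

test_that("water-filling matches the simplex grid-search oracle", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(2:3, 1)
    s <- runif(n)
    alpha <- runif(1, 0.05, 1)
    w <- optimal_allocation(s, alpha)
    expect_true(all(w >= 0) && abs(sum(w) - 1) < 1e-9)
    oracle <- grid_search_allocation(s, alpha, resolution = 1e-3)
    expect_lte(abs(payoff(s, w, alpha) - oracle$value), 1e-5)
    expect_gte(payoff(s, w, alpha), oracle$value - 1e-12)
  }
})

test_that("the allocation maximizes the payoff over random feasible points", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    s <- runif(n); alpha <- runif(1, 0.05, 0.8)
    w <- optimal_allocation(s, alpha)
    best <- payoff(s, w, alpha)
    for (j in 1:100) {
      r <- rexp(n); r <- r / sum(r)
      expect_gte(best + 1e-12, payoff(s, r, alpha))
    }
  }
})

test_that("allocations respond monotonically to score increases", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(3:5, 1)
    s <- runif(n)
    k <- sample(n, 1)
    w1 <- optimal_allocation(s, 0.2)
    s2 <- s; s2[k] <- s2[k] + runif(1, 0.05, 0.3)
    w2 <- optimal_allocation(s2, 0.2)
    expect_gte(w2[k] + 1e-12, w1[k])
  }
})

test_that("policies produce simplex allocations and documented fallbacks", {
  st <- toy_scores(5, 8, seed = 5)
  for (p in c("uniform", "oracle", "naive", "mean", "ls", "clairvoyant")) {
    run <- run_policy(p, st)
    expect_true(all(abs(rowSums(run$omega) - 1) < 1e-9))
    expect_true(all(run$omega >= -1e-12))
    expect_equal(run$cumulative, sum(run$payoffs))
  }
  # uniform is 1/n everywhere; mean at task 1 falls back to uniform
  expect_true(all(run_policy("uniform", st)$omega == 1 / 5))
  expect_equal(unname(run_policy("mean", st)$omega[1, ]), rep(1 / 5, 5))
  expect_equal(unname(run_policy("naive", st)$omega[1, ]), rep(1 / 5, 5))
  expect_error(run_policy("pd", st), "train_scores")
})

test_that("outlier control clips estimates into the epsilon band", {
  # interval-clip arithmetic: mean 0.5, eps 0.3 -> band [0.35, 0.65]
  mk <- 0.5; eps <- 0.3
  clip <- function(x) max((1 - eps) * mk, min((1 + eps) * mk, x))
  expect_equal(clip(0.9), 0.65)
  expect_equal(clip(0.2), 0.35)
  expect_equal(clip(0.5), 0.5)

  st <- toy_scores(6, 8, seed = 6)
  train <- toy_scores(20, 8, seed = 7)
  grid <- data.frame(lambda1 = c(0.05, 0.5), lambda2 = c(0.05, 0.5))
  run <- run_policy("pdoc", st, train_scores = train, lambda_grid = grid)
  for (t in 2:8) {
    mk <- rowMeans(st[, 1:(t - 1), drop = FALSE])
    est <- run$s_est[t, ]
    expect_true(all(est >= (1 - 0.3) * mk - 1e-9))
    expect_true(all(est <= (1 + 0.3) * mk + 1e-9))
  }
})

test_that("the clairvoyant allocation bounds every policy at every task", {
  st <- toy_scores(6, 10, seed = 8)
  bound <- run_policy("clairvoyant", st)$payoffs
  for (p in c("uniform", "oracle", "naive", "mean", "ls"))
    expect_true(all(run_policy(p, st)$payoffs <= bound + 1e-9))
})

test_that("split evaluation reports oracle-relative payoffs", {
  st <- toy_scores(12, 8, seed = 9)
  ev <- evaluate_policies(st, policies = c("uniform", "oracle", "naive"),
                          repeats = 5, seed = 3)
  expect_equal(ev$summary$relative[ev$summary$policy == "oracle"], 1)
  expect_equal(dim(ev$per_split), c(5, 3))
  expect_error(evaluate_policies(score_table(matrix(runif(16), 4, 4)),
                                 repeats = 2, train_frac = 0.9),
               "fewer than 2")
})

test_that("persistent team quality favors informed policies over uniform", {
  spec <- synth_spec(n_teams = 20, noise_sd = 0.05, trend_coupling = 0)
  st <- gen_score_table(spec, seed = 11)
  ev <- evaluate_policies(st, policies = c("uniform", "naive"), repeats = 20,
                          seed = 5)
  s <- ev$summary
  expect_gte(s$mean_cumulative[s$policy == "naive"],
             s$mean_cumulative[s$policy == "uniform"])
})
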