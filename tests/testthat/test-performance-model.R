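test_that("correlation screening reports r, p and the BH decision", {
  set.seed(3)
  x <- rnorm(30)
  feats <- data.frame(team_id = sprintf("t%02d", 1:30),
                      lin = x, noise = rnorm(30))
  y <- 2 * x
  rep <- pearson_screen(feats, y)
  lin <- rep[rep$feature == "lin", ]
  expect_equal(lin$r, 1, tolerance = 1e-12)
  expect_lt(lin$p, 1e-20)
  expect_true(lin$significant && lin$reported)
  # zero-variance features are not tested
  feats$flat <- 1
  rep2 <- pearson_screen(feats, y)
  expect_true(is.na(rep2[rep2$feature == "flat", "r"]))
})

test_that("BH step-up matches the hand-worked and brute-force enumerations", {
  # (0.004, 0.03, 0.04, 0.05) at q = 0.10: all four rejected
  expect_equal(brute_bh_reject(c(0.004, 0.03, 0.04, 0.05), 0.10), rep(TRUE, 4))
  expect_equal(p.adjust(c(0.004, 0.03, 0.04, 0.05), "BH") <= 0.10, rep(TRUE, 4))
  expect_equal(p.adjust(c(0.2, 0.3), "BH") <= 0.10, rep(FALSE, 2))
  set.seed(17)
  for (i in 1:60) {
    p <- runif(sample(1:20, 1))
    q <- sample(c(0.05, 0.1, 0.25), 1)
    expect_equal(p.adjust(p, "BH") <= q, brute_bh_reject(p, q))
  }
})

test_that("the unpenalized limit recovers ordinary least squares", {
  set.seed(4)
  n <- 40; p <- 6
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- rnorm(n)
  fit <- fit_elastic_net(X, y, 0, 0)
  yc <- y - mean(y)
  beta_ols <- solve(crossprod(X), crossprod(X, yc))
  expect_equal(unname(fit$coefficients), as.vector(beta_ols), tolerance = 1e-8)
  expect_equal(fit$intercept, mean(y))
})

test_that("orthonormal designs soft-threshold in closed form", {
  set.seed(6)
  n <- 32; p <- 5
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p)))  # X'X = I
  y <- rnorm(n)
  yc <- y - mean(y)
  b <- as.vector(crossprod(X, yc))
  for (l1 in c(0.05, 0.2, 0.8)) {
    fit <- fit_elastic_net(X, y, l1, 0)
    expect_equal(unname(fit$coefficients),
                 sign(b) * pmax(abs(b) - l1 / 2, 0), tolerance = 1e-6)
  }
})

test_that("a large l1 penalty zeroes the model, which predicts mean(y)", {
  set.seed(7)
  X <- scale(matrix(rnorm(50 * 4), 50, 4))
  y <- rnorm(50)
  l1 <- 2 * max(abs(crossprod(X, y - mean(y)))) + 1
  fit <- fit_elastic_net(X, y, l1, 0)
  expect_true(all(fit$coefficients == 0))
  expect_true(fit$degenerate)
  expect_equal(predict(fit, X), rep(mean(y), 50))
})

test_that("returned solutions beat the zero and OLS points on the objective", {
  set.seed(8)
  for (i in 1:10) {
    n <- 30; p <- sample(3:8, 1)
    X <- scale(matrix(rnorm(n * p), n, p))
    y <- rnorm(n)
    yc <- y - mean(y)
    l1 <- runif(1, 0, 2); l2 <- runif(1, 0, 2)
    fit <- fit_elastic_net(X, y, l1, l2)
    obj <- function(b) sum((yc - X %*% b)^2) + l1 * sum(abs(b)) + l2 * sum(b^2)
    expect_lte(fit$objective, obj(numeric(p)) + 1e-10)
    beta_ols <- as.vector(solve(crossprod(X), crossprod(X, yc)))
    expect_lte(fit$objective, obj(beta_ols) + 1e-10)
  }
})

test_that("fits agree with glmnet under the exact objective re-parameterization", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  n <- 60; p <- 10
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- rnorm(n)
  for (pen in list(c(0.8, 0.2), c(0.3, 0.6), c(1.5, 0))) {
    l1 <- pen[1]; l2 <- pen[2]
    lam <- (l1 + 2 * l2) / (2 * n)
    alpha <- l1 / (l1 + 2 * l2)
    g <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam,
                        standardize = FALSE, thresh = 1e-14)
    fit <- fit_elastic_net(X, y, l1, l2)
    # glmnet's coordinate descent stops at a relative threshold, so the two
    # solvers agree to ~1e-3, not machine precision
    expect_equal(unname(fit$coefficients), as.vector(g$beta), tolerance = 2e-3)
  }
})

test_that("the sparsity filter admits top-heavy models only", {
  expect_true(top_weight_share(c(5, 1, 1, 1, 1, 1, 0.5, 0.5)) >= 0.8)   # 10/11
  expect_false(top_weight_share(rep(1, 10)) >= 0.8)                      # 0.6
  expect_equal(top_weight_share(numeric(8)), 1)  # all-zero passes trivially
})

test_that("model selection returns degenerate mean predictor on pure noise", {
  set.seed(10)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(40, mean = 0.5, sd = 0.05)
  m <- select_model(X, y, lambda_grid = data.frame(lambda1 = c(50, 100),
                                                   lambda2 = 0), seed = 2)
  expect_true(m$degenerate)
  expect_equal(predict(m, X), rep(mean(y), 40))
  expect_gte(m$cv_rmse, 0)
  expect_error(select_model(X, y, lambda_grid = data.frame(lambda1 = numeric(0),
                                                           lambda2 = numeric(0))),
               "empty")
})

test_that("model selection recovers a planted sparse signal", {
  sig <- gen_sparse_signal(n = 68, p = 30, seed = 12)
  m <- select_model(sig$X, sig$y, seed = 12)
  expect_false(m$degenerate)
  top6 <- names(sort(abs(m$coefficients), decreasing = TRUE))[1:6]
  expect_true(all(sig$true_features %in% top6))
  # the winner passed the sparsity rule and carries a CV RMSE
  expect_gte(top_weight_share(m$coefficients), 0.8 - 1e-12)
  expect_true(is.finite(m$cv_rmse))
})

test_that("rmse follows its closed forms", {
  expect_equal(evaluate_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(evaluate_rmse(c(0, 1), c(1, 0)), 1)
  x <- runif(10)
  expect_equal(evaluate_rmse(x + 0.3, x), 0.3)
  expect_error(evaluate_rmse(1:3, 1:4), "equal length")
})
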