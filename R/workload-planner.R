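#' Manager's payoff for a workload allocation
#'
#' On task `t` a manager splits the work over `n` teams according to
#' `omega` on the probability simplex and the teams earn scores `s`; the
#' payoff is
#' \deqn{R = s^\top \omega - \alpha \|\omega\|_2^2,}
#' the exploit term (workload-weighted total score) minus a quadratic
#' uniformity penalty weighted by `alpha` that rewards exploring teams
#' whose ability is still unknown and keeps the allocation fair.
#'
#' @param s numeric score vector in \[0, 1\].
#' @param omega allocation vector: non-negative, summing to 1 (tolerance
#'   1e-9).
#' @param alpha fairness weight in \[0, 1\] (default 0.2).
#' @return The scalar payoff.
#' @examples
#' payoff(c(1, 0), c(1, 0))  # 0.8 at the default alpha
#' @export
payoff <- function(s, omega, alpha = 0.2) {
  stopifnot(length(s) == length(omega), alpha >= 0)
  if (any(omega < -1e-9) || abs(sum(omega) - 1) > 1e-9)
    stop("omega must lie on the probability simplex")
  sum(s * omega) - alpha * sum(omega^2)
}

#' Optimal workload allocation on the simplex
#'
#' Maximizes `s_est' omega - alpha * ||omega||^2` over the probability
#' simplex. For `alpha > 0` the objective is strictly concave and the
#' unique maximizer has the water-filling form
#' `omega_i = max(0, (s_i - mu) / (2 alpha))` with the level `mu` fixed by
#' `sum(omega) = 1`; it is found exactly by sorting the scores and
#' scanning candidate support sets (no numeric optimizer involved). For
#' `alpha = 0` the problem degenerates to a linear program whose solution
#' set is the face spanned by the maximal scores; the uniform split over
#' the argmax entries is returned as the deterministic tie-break.
#'
#' @param s_est numeric vector of (estimated) team scores.
#' @param alpha fairness weight (default 0.2).
#' @return Allocation vector on the simplex.
#' @examples
#' optimal_allocation(c(0.8, 0.6, 0.4), alpha = 0.2)  # (0.75, 0.25, 0)
#' @export
optimal_allocation <- function(s_est, alpha = 0.2) {
  s_est <- as.numeric(s_est)
  stopifnot(all(is.finite(s_est)), alpha >= 0)
  n <- length(s_est)
  if (n == 0L) stop("empty score vector")
  if (alpha == 0) {
    top <- which(s_est == max(s_est))
    omega <- numeric(n)
    omega[top] <- 1 / length(top)
    return(omega)
  }
  ord <- order(s_est, decreasing = TRUE)
  ss <- s_est[ord]
  csum <- cumsum(ss)
  mu <- NA_real_
  for (kk in seq_len(n)) {
    mu_k <- (csum[kk] - 2 * alpha) / kk
    if (ss[kk] > mu_k && (kk == n || ss[kk + 1] <= mu_k)) {
      mu <- mu_k
      break
    }
  }
  omega <- pmax(0, (s_est - mu) / (2 * alpha))
  omega / sum(omega)  # absorb rounding; exact solution already sums to 1
}

#' Run one workload-distribution policy over a task sequence
#'
#' Simulates a manager sequentially allocating `m` tasks to `n` managed
#' teams. At each task `t` the policy forms a score estimate `s_est(t)`
#' from the managed teams' observed history (and, for the model-based
#' policies, from the full score table of previously managed training
#' teams), then allocates by [optimal_allocation()]. Policies:
#'
#' * `uniform` -- always `1/n`, maximally fair.
#' * `oracle` -- non-causal baseline: estimates are full-series means.
#' * `naive`, `mean`, `ls`, `arma` -- per-team extrapolation via
#'   [forecast_score()]; with insufficient history a policy falls back to
#'   `mean`, and `mean` itself at task 1 falls back to the uniform
#'   allocation.
#' * `pd` -- score-dynamics model: for each task `t >= 4` an elastic-net
#'   model ([select_model()]) is trained on the training teams' dynamics
#'   features (prefix tasks `< t`, target task `t`) and applied to the
#'   managed teams' prefixes; earlier tasks fall back to `mean`.
#' * `pdoc` -- `pd` with outlier control: estimates are clipped to within
#'   a fraction `epsilon` of each team's observed mean,
#'   `[(1 - eps) mean_k, (1 + eps) mean_k]`, guarding the allocation
#'   against outlier predictions.
#' * `clairvoyant` -- uses the true scores `s(t)` as estimates; by
#'   construction its per-task payoff bounds every policy's (test bound,
#'   not a realizable policy).
#'
#' @param policy policy name.
#' @param scores [score_table] of the managed teams (complete); rows are
#'   the teams being allocated, columns the task sequence.
#' @param alpha fairness weight (default 0.2).
#' @param epsilon outlier-control fraction for `pdoc` (default 0.3).
#' @param train_scores [score_table] of training teams; required by
#'   `pd`/`pdoc`.
#' @param lambda_grid,cv_seed passed to [select_model()] for `pd`/`pdoc`.
#' @return An object of class `policy_run`: list with `policy`, `omega`
#'   (m x n allocation matrix), `s_est` (m x n estimate matrix), `payoffs`
#'   (per task), `cumulative`.
#' @export
run_policy <- function(policy = c("uniform", "oracle", "naive", "mean", "ls",
                                  "arma", "pd", "pdoc", "clairvoyant"),
                       scores, alpha = 0.2, epsilon = 0.3,
                       train_scores = NULL,
                       lambda_grid = default_lambda_grid(), cv_seed = 1) {
  policy <- match.arg(policy)
  stopifnot(inherits(scores, "score_table"))
  if (anyNA(scores)) stop("managed score table must be complete")
  n <- nrow(scores); m <- ncol(scores)
  if (policy %in% c("pd", "pdoc")) {
    if (is.null(train_scores)) stop(policy, " requires train_scores")
    stopifnot(inherits(train_scores, "score_table"),
              ncol(train_scores) == m)
    ## one model per target task, trained once on the training teams
    models <- vector("list", m)
    for (t in 4:m) {
      feats <- dynamics_feature_table(train_scores, t)
      models[[t]] <- select_model(feats, train_scores[, t],
                                  lambda_grid = lambda_grid, seed = cv_seed)
    }
  }
  omega <- matrix(NA_real_, m, n, dimnames = list(colnames(scores),
                                                  rownames(scores)))
  s_est <- matrix(NA_real_, m, n, dimnames = dimnames(omega))
  payoffs <- numeric(m)
  mean_est <- function(t) {
    if (t == 1L) NULL else rowMeans(scores[, seq_len(t - 1), drop = FALSE])
  }
  for (t in seq_len(m)) {
    est <- NULL
    w <- NULL
    hist_t <- function(i) scores[i, seq_len(t - 1)]
    est <- switch(
      policy,
      uniform = ,
      clairvoyant = NULL,
      oracle = rowMeans(scores),
      naive = if (t < 2L) mean_est(t) else scores[, t - 1],
      mean = mean_est(t),
      ls = if (t < 3L) mean_est(t) else
        vapply(seq_len(n), function(i)
          forecast_score("least_squares", hist_t(i)), numeric(1)),
      arma = if (t < 5L) mean_est(t) else
        vapply(seq_len(n), function(i)
          forecast_score("arma", hist_t(i)), numeric(1)),
      pd = ,
      pdoc = if (t < 4L) mean_est(t) else {
        feats <- dynamics_feature_table(scores, t)
        clip01(predict(models[[t]], feats))
      })
    if (policy == "pdoc" && t >= 2L && !is.null(est)) {
      mk <- rowMeans(scores[, seq_len(t - 1), drop = FALSE])
      est <- pmax((1 - epsilon) * mk, pmin((1 + epsilon) * mk, est))
    }
    if (policy == "clairvoyant") est <- scores[, t]
    if (policy == "uniform" || is.null(est)) {
      w <- rep(1 / n, n)
      est <- rep(NA_real_, n)
    } else {
      w <- optimal_allocation(est, alpha)
    }
    omega[t, ] <- w
    s_est[t, ] <- est
    payoffs[t] <- payoff(scores[, t], w, alpha)
  }
  structure(list(policy = policy, omega = omega, s_est = s_est,
                 payoffs = payoffs, cumulative = sum(payoffs),
                 alpha = alpha, epsilon = epsilon),
            class = "policy_run")
}

#' @export
print.policy_run <- function(x, ...) {
  cat(sprintf("<policy_run> %s: %d tasks x %d teams, cumulative payoff %.4f\n",
              x$policy, nrow(x$omega), ncol(x$omega), x$cumulative))
  invisible(x)
}

#' Evaluate workload policies over repeated team splits
#'
#' Repeatedly splits the teams of a score table into a training fraction
#' (historical teams whose full series feed the model-based policies) and
#' a managed remainder, runs every policy on the managed teams, and
#' averages cumulative payoffs over the splits. Payoffs are also reported
#' relative to the `oracle` baseline policy (per-split ratio, then
#' averaged); `oracle` is always evaluated for scaling even when not
#' requested.
#'
#' @param scores complete [score_table] of all teams.
#' @param policies character vector of policy names (see [run_policy()]).
#' @param train_frac fraction of teams forming the training split
#'   (default 0.75).
#' @param repeats number of random splits (default 100).
#' @param alpha,epsilon payoff and outlier-control parameters.
#' @param seed master seed; split `r` uses the derived sub-seed
#'   `derive_seed(seed, r)`.
#' @param lambda_grid penalty grid for the model-based policies.
#' @return A list of class `policy_evaluation`: `summary` (data frame with
#'   `policy`, `mean_cumulative`, `relative`), `per_split` (matrix splits x
#'   policies of cumulative payoffs), `repeats`, `alpha`.
#' @export
evaluate_policies <- function(scores,
                              policies = c("uniform", "oracle", "naive",
                                           "mean", "ls"),
                              train_frac = 0.75, repeats = 100, alpha = 0.2,
                              epsilon = 0.3, seed = 1,
                              lambda_grid = default_lambda_grid()) {
  stopifnot(inherits(scores, "score_table"), repeats >= 1)
  if (anyNA(scores)) stop("score table must be complete")
  n_all <- nrow(scores)
  n_train <- round(train_frac * n_all)
  n_managed <- n_all - n_train
  if (n_managed < 2L) stop("fewer than 2 managed teams per split")
  pols <- unique(c(policies, "oracle"))
  cum <- matrix(NA_real_, repeats, length(pols),
                dimnames = list(NULL, pols))
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, r))
    tr <- sample(n_all, n_train)
    managed <- scores[setdiff(seq_len(n_all), tr), , drop = FALSE]
    class(managed) <- class(scores)
    train <- scores[tr, , drop = FALSE]
    class(train) <- class(scores)
    for (p in pols) {
      run <- run_policy(p, managed, alpha = alpha, epsilon = epsilon,
                        train_scores = if (p %in% c("pd", "pdoc")) train,
                        lambda_grid = lambda_grid,
                        cv_seed = derive_seed(seed, r + 100003L))
      cum[r, p] <- run$cumulative
    }
  }
  rel <- sweep(cum, 1, cum[, "oracle"], "/")
  summary <- data.frame(policy = pols,
                        mean_cumulative = colMeans(cum),
                        relative = colMeans(rel),
                        row.names = NULL)
  structure(list(summary = summary[summary$policy %in% policies, ],
                 per_split = cum, repeats = repeats, alpha = alpha),
            class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat(sprintf("<policy_evaluation> %d splits, alpha = %g\n", x$repeats, x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
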