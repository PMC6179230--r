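#' Pearson correlation screening with Benjamini--Hochberg control
#'
#' Computes the Pearson correlation of every feature with every target
#' score column, with two-sided p-values, then applies the
#' Benjamini--Hochberg step-up procedure across all tested pairs at false
#' discovery rate `q` (default 10%). Following the reporting convention of
#' the analysis this package implements, a pair is *reported* when it is
#' both BH-significant and has raw `p < p_display` (default 0.05); both
#' knobs are returned so either filter can be inspected on its own.
#' Zero-variance features or pairs with fewer than 3 complete observations
#' yield missing correlations and are not tested.
#'
#' @param features data frame (e.g. a `feature_table`) with a `team_id`
#'   column and numeric feature columns, or a numeric matrix.
#' @param scores a [score_table], or a numeric vector/matrix of targets
#'   aligned with the feature rows.
#' @param q false discovery rate for BH (default 0.10).
#' @param p_display raw p-value display threshold (default 0.05).
#' @return A data frame of class `screening_report` with columns `feature`,
#'   `target`, `r`, `p`, `p_bh`, `significant` (BH at `q`) and `reported`
#'   (`significant & p < p_display`).
#' @export
pearson_screen <- function(features, scores, q = 0.10, p_display = 0.05) {
  if (is.data.frame(features)) {
    ids <- if ("team_id" %in% names(features)) features$team_id else NULL
    X <- as.matrix(features[setdiff(names(features), "team_id")])
    rownames(X) <- ids
  } else X <- as.matrix(features)
  Y <- if (is.null(dim(scores))) matrix(scores, ncol = 1,
                                        dimnames = list(NULL, "target"))
       else as.matrix(scores)
  if (!is.null(rownames(X)) && !is.null(rownames(Y)))
    Y <- Y[rownames(X), , drop = FALSE]
  stopifnot(nrow(X) == nrow(Y))
  grid <- expand.grid(feature = colnames(X), target = colnames(Y),
                      stringsAsFactors = FALSE)
  grid$r <- grid$p <- NA_real_
  for (i in seq_len(nrow(grid))) {
    x <- X[, grid$feature[i]]; y <- Y[, grid$target[i]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                          alternative = "two.sided")
    grid$r[i] <- unname(ct$estimate)
    grid$p[i] <- ct$p.value
  }
  tested <- !is.na(grid$p)
  grid$p_bh <- NA_real_
  grid$p_bh[tested] <- stats::p.adjust(grid$p[tested], method = "BH")
  grid$significant <- !is.na(grid$p_bh) & grid$p_bh <= q
  grid$reported <- grid$significant & grid$p < p_display
  class(grid) <- c("screening_report", "data.frame")
  grid
}

## penalized objective: ||y - Xb||^2 + l1*||b||_1 + l2*||b||^2
## (no 1/n scaling; y already centered, no intercept term)
elnet_objective <- function(X, y, beta, lambda1, lambda2) {
  r <- y - as.vector(X %*% beta)
  sum(r^2) + lambda1 * sum(abs(beta)) + lambda2 * sum(beta^2)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

## cyclic coordinate descent with an active-set KKT polish; X columns are
## expected centered (intercept handled by centering y)
elnet_solve <- function(X, y, lambda1, lambda2, tol = 1e-9, max_iter = 250L,
                        beta0 = NULL) {
  p <- ncol(X)
  if (p == 0L) return(numeric(0))
  if (lambda1 == 0) {
    ## pure ridge / OLS limit: solve the normal equations directly
    b <- tryCatch(
      solve(crossprod(X) + diag(lambda2, p), crossprod(X, y)),
      error = function(e) NULL)
    if (!is.null(b)) return(as.vector(b))
  }
  ## covariance-form coordinate descent: per-coordinate cost O(p)
  XtX <- crossprod(X)
  Xty <- as.vector(crossprod(X, y))
  a <- diag(XtX)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  g <- as.vector(XtX %*% beta)
  scale_ref <- max(1, max(abs(Xty)))
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (a[j] + lambda2 == 0) next
      z <- Xty[j] - g[j] + a[j] * beta[j]
      bj <- soft_threshold(z, lambda1 / 2) / (a[j] + lambda2)
      if (bj != beta[j]) {
        g <- g + XtX[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol * scale_ref) break
  }
  ## polish: with the sign pattern fixed, the optimum solves a linear system
  act <- which(beta != 0)
  if (length(act)) {
    s <- sign(beta[act])
    Xa <- X[, act, drop = FALSE]
    bact <- tryCatch(
      solve(crossprod(Xa) + diag(lambda2, length(act)),
            crossprod(Xa, y) - (lambda1 / 2) * s),
      error = function(e) NULL)
    if (!is.null(bact) && all(sign(bact) == s)) {
      cand <- numeric(p)
      cand[act] <- bact
      ## keep the polished solution only if inactive KKT conditions hold
      rc <- y - as.vector(X %*% cand)
      grad_ok <- all(abs(crossprod(X[, -act, drop = FALSE], rc)) <=
                       lambda1 / 2 + 1e-9 * scale_ref) || length(act) == p
      if (grad_ok &&
          elnet_objective(X, y, cand, lambda1, lambda2) <=
          elnet_objective(X, y, beta, lambda1, lambda2) + 1e-12 * scale_ref)
        beta <- cand
    }
  }
  beta
}

#' Fit an elastic-net regression at fixed penalties
#'
#' Minimizes the penalized least-squares objective
#' \deqn{\hat\beta = \arg\min_\beta \|y - X\beta\|_2^2
#'   + \lambda_1 \|\beta\|_1 + \lambda_2 \|\beta\|_2^2}
#' exactly as written (no `1/2n` rescaling of the residual term), by
#' cyclic coordinate descent followed by an exact solve on the recovered
#' active set. The l1 term sparsifies the model; the l2 term groups
#' correlated features. `X` is expected to be standardized (zero mean, unit
#' variance per column); the intercept then equals `mean(y)`.
#'
#' @param X numeric matrix of standardized features (rows = teams).
#' @param y numeric response (task scores in \[0, 1\]).
#' @param lambda1,lambda2 non-negative penalty weights.
#' @return An object of class `elastic_net_model`: list with
#'   `coefficients` (named by feature), `intercept`, `lambda1`, `lambda2`,
#'   `cv_rmse` (`NA` until cross-validated), `degenerate` (all
#'   coefficients below 1e-6 in magnitude), and `objective`.
#' @export
fit_elastic_net <- function(X, y, lambda1, lambda2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), lambda1 >= 0, lambda2 >= 0)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite entries in X or y")
  yc <- y - mean(y)
  beta <- elnet_solve(X, yc, lambda1, lambda2)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, intercept = mean(y),
                 lambda1 = lambda1, lambda2 = lambda2,
                 cv_rmse = NA_real_,
                 degenerate = all(abs(beta) < 1e-6),
                 objective = elnet_objective(X, yc, beta, lambda1, lambda2),
                 x_center = NULL, x_scale = NULL),
            class = "elastic_net_model")
}

#' @export
print.elastic_net_model <- function(x, ...) {
  nz <- sum(abs(x$coefficients) >= 1e-6)
  cat(sprintf("<elastic_net_model> lambda1 = %.4g, lambda2 = %.4g, %d active features%s%s\n",
              x$lambda1, x$lambda2, nz,
              if (!is.na(x$cv_rmse)) sprintf(", cv_rmse = %.4f", x$cv_rmse) else "",
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Predict from an elastic-net model
#'
#' @param object an `elastic_net_model`.
#' @param newdata numeric matrix or data frame of features on the original
#'   scale when the model stores standardization statistics (as models from
#'   [select_model()] do), or already standardized otherwise.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.elastic_net_model <- function(object, newdata, ...) {
  nm <- names(object$coefficients)
  if (is.data.frame(newdata))
    newdata <- newdata[setdiff(names(newdata), "team_id")]
  X <- if (!is.null(nm) && !is.null(colnames(newdata)))
    as.matrix(newdata[, nm, drop = FALSE])
  else {
    if (ncol(newdata) != length(object$coefficients))
      stop("newdata has the wrong number of feature columns")
    as.matrix(newdata)
  }
  if (!is.null(object$x_center))
    X <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  as.vector(object$intercept + X %*% object$coefficients)
}

#' Top-6 sparsity share of a coefficient vector
#'
#' The model-selection rule admits only models sparse enough that their six
#' largest-magnitude coefficients carry at least 80% of the total
#' coefficient weight `sum(|beta|)` (feature "weight" is `|beta_j|` on
#' standardized features). An all-zero model passes trivially.
#'
#' @param beta numeric coefficient vector.
#' @param top number of leading features (default 6).
#' @return The share in \[0, 1\].
#' @export
top_weight_share <- function(beta, top = 6) {
  ab <- sort(abs(beta), decreasing = TRUE)
  tot <- sum(ab)
  if (tot == 0) return(1)
  sum(ab[seq_len(min(top, length(ab)))]) / tot
}

#' Default penalty grid
#'
#' Mixing ratios `lambda1 : lambda2` of 100:0, 75:25, 50:50, 25:75 and
#' 0:100 crossed with 20 total penalty magnitudes log-spaced between 1e-3
#' and 10.
#'
#' @param n_magnitudes number of magnitudes (default 20).
#' @return Data frame with columns `lambda1`, `lambda2`.
#' @export
default_lambda_grid <- function(n_magnitudes = 20) {
  mix <- c(1, 0.75, 0.5, 0.25, 0)
  total <- 10^seq(-3, 1, length.out = n_magnitudes)
  g <- expand.grid(mix = mix, total = total)
  data.frame(lambda1 = g$mix * g$total, lambda2 = (1 - g$mix) * g$total)
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}

#' Cross-validated, sparsity-filtered elastic-net model selection
#'
#' For every `(lambda1, lambda2)` pair in the grid a model is fitted on the
#' full (standardized) data and kept only if sparse enough -- its top-6
#' coefficient magnitudes must account for at least 80% of the total
#' coefficient weight ([top_weight_share()]). Each surviving candidate is
#' scored by k-fold cross-validated RMSE (pooled out-of-fold predictions;
#' fold standardization statistics are computed on the training folds
#' only), and the candidate with the lowest CV RMSE wins. If no candidate
#' survives, or the winner has all-zero coefficients, a degenerate model
#' predicting `mean(y)` is returned (its CV RMSE is that of the fold-mean
#' predictor).
#'
#' @param features data frame with `team_id` + numeric columns, or numeric
#'   matrix (unstandardized; standardization is handled internally).
#' @param y numeric response vector.
#' @param lambda_grid data frame of candidate penalties (default
#'   [default_lambda_grid()]).
#' @param k number of cross-validation folds (default 10).
#' @param seed integer seed fixing the fold assignment shuffle.
#' @param top,share_min sparsity rule parameters (default: top 6 features,
#'   80% of total weight).
#' @return The winning `elastic_net_model`, with `cv_rmse` filled in and
#'   standardization statistics attached for prediction on raw features.
#' @export
select_model <- function(features, y, lambda_grid = default_lambda_grid(),
                         k = 10, seed = 1, top = 6, share_min = 0.8) {
  if (is.data.frame(features))
    X <- as.matrix(features[setdiff(names(features), "team_id")])
  else X <- as.matrix(features)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (nrow(lambda_grid) == 0L) stop("empty lambda grid")
  if (n < k) stop("need at least k samples for k-fold cross-validation")
  keep <- apply(X, 2, function(col) all(is.finite(col)))
  X <- X[, keep, drop = FALSE]
  if (any(!is.finite(y))) stop("non-finite response values")

  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))

  full <- standardize_fit(X)
  ## full-data fits, warm-started along decreasing total penalty
  ord <- order(-(lambda_grid$lambda1 + lambda_grid$lambda2))
  betas <- vector("list", nrow(lambda_grid))
  warm <- NULL
  yc <- y - mean(y)
  for (i in ord) {
    b <- elnet_solve(full$X, yc, lambda_grid$lambda1[i], lambda_grid$lambda2[i],
                     beta0 = warm)
    betas[[i]] <- b
    warm <- b
  }
  eligible <- vapply(betas, function(b) top_weight_share(b, top) >= share_min - 1e-12,
                     logical(1))

  ## out-of-fold prediction matrix: rows = grid points evaluated, cols = teams
  fold_sets <- split(seq_len(n), folds)
  cv_pred <- matrix(NA_real_, nrow(lambda_grid), n)
  mean_pred <- numeric(n)
  for (fs in fold_sets) {
    tr <- setdiff(seq_len(n), fs)
    st <- standardize_fit(X[tr, , drop = FALSE])
    Xtr <- st$X
    Xte <- sweep(sweep(X[fs, , drop = FALSE], 2, st$center), 2, st$scale, "/")
    ytr <- y[tr]
    ytr_c <- ytr - mean(ytr)
    mean_pred[fs] <- mean(ytr)
    warm <- NULL
    for (i in ord) {
      if (!eligible[i]) next
      b <- elnet_solve(Xtr, ytr_c, lambda_grid$lambda1[i], lambda_grid$lambda2[i],
                       beta0 = warm)
      warm <- b
      cv_pred[i, fs] <- mean(ytr) + as.vector(Xte %*% b)
    }
  }
  cv_rmse <- apply(cv_pred, 1, function(p)
    if (all(is.na(p))) NA_real_ else sqrt(mean((p - y)^2)))
  mean_rmse <- sqrt(mean((mean_pred - y)^2))

  degenerate_model <- function() {
    structure(list(coefficients = stats::setNames(numeric(ncol(X)), colnames(X)),
                   intercept = mean(y), lambda1 = NA_real_, lambda2 = NA_real_,
                   cv_rmse = mean_rmse, degenerate = TRUE,
                   objective = sum(yc^2),
                   x_center = full$center, x_scale = full$scale),
              class = "elastic_net_model")
  }
  if (!any(eligible & !is.na(cv_rmse))) return(degenerate_model())
  cand <- which(eligible & !is.na(cv_rmse))
  best <- cand[which.min(cv_rmse[cand])]
  beta <- stats::setNames(betas[[best]], colnames(X))
  if (all(abs(beta) < 1e-6)) return(degenerate_model())
  structure(list(coefficients = beta, intercept = mean(y),
                 lambda1 = lambda_grid$lambda1[best],
                 lambda2 = lambda_grid$lambda2[best],
                 cv_rmse = cv_rmse[best],
                 degenerate = FALSE,
                 objective = elnet_objective(full$X, yc, beta,
                                             lambda_grid$lambda1[best],
                                             lambda_grid$lambda2[best]),
                 x_center = full$center, x_scale = full$scale),
            class = "elastic_net_model")
}

#' Root mean square error
#'
#' @param predictions,truth equal-length numeric vectors.
#' @return `sqrt(mean((predictions - truth)^2))`.
#' @export
evaluate_rmse <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  if (length(truth) == 0L) stop("need at least one observation")
  sqrt(mean((predictions - truth)^2))
}
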