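#' Score-series forecasting baselines
#'
#' One-step-ahead extrapolators for a single team's task-score series,
#' used both as stand-alone prediction baselines and as the score
#' predictors inside workload-distribution policies:
#'
#' * `mean_oracle` -- non-causal bound: the mean of the team's *full*
#'   series, over both observed and not-yet-observed tasks.
#' * `observed_mean` -- mean of the scores observed so far; with no
#'   history it falls back to the uninformative prior 0.5.
#' * `naive` -- the score of the immediately preceding task.
#' * `least_squares` -- a straight line fitted to the observed series by
#'   least squares, evaluated at the next task index; needs at least 2
#'   observations, else falls back to `observed_mean`.
#' * `arma` -- one-step-ahead mean forecast of an ARMA(1,1) model
#'   estimated by maximum likelihood; needs at least 4 observations, and
#'   falls back to `observed_mean` when history is shorter or estimation
#'   fails (e.g. on a constant series).
#'
#' Since task scores are bounded, forecasts are clipped to \[0, 1\]
#' (disable with `clip = FALSE`); clipping is announced via `message()`
#' when `verbose = TRUE`.
#'
#' @param method one of `"mean_oracle"`, `"observed_mean"`, `"naive"`,
#'   `"least_squares"`, `"arma"`.
#' @param prefix numeric vector of scores observed so far (tasks
#'   `1 .. t-1`); may be empty for `observed_mean`.
#' @param full_series the team's complete score series; required by
#'   `mean_oracle` only.
#' @param clip clip the forecast into \[0, 1\] (default `TRUE`).
#' @param verbose report clipping via `message()` (default `FALSE`).
#' @return A single predicted score.
#' @examples
#' forecast_score("naive", c(0.2, 0.4))          # 0.4
#' forecast_score("observed_mean", c(0.2, 0.4))  # 0.3
#' forecast_score("least_squares", c(0.2, 0.4, 0.6))  # 0.8
#' @export
forecast_score <- function(method = c("mean_oracle", "observed_mean", "naive",
                                      "least_squares", "arma"),
                           prefix, full_series = NULL, clip = TRUE,
                           verbose = FALSE) {
  method <- match.arg(method)
  prefix <- as.numeric(prefix)
  if (any(!is.finite(prefix))) stop("non-finite scores in prefix")
  h <- length(prefix)
  observed_mean <- function() if (h == 0L) 0.5 else mean(prefix)
  pred <- switch(
    method,
    mean_oracle = {
      if (is.null(full_series)) stop("mean_oracle needs the full series")
      if (any(!is.finite(full_series))) stop("non-finite scores in series")
      mean(full_series)
    },
    observed_mean = observed_mean(),
    naive = if (h < 1L) observed_mean() else prefix[h],
    least_squares = {
      if (h < 2L) observed_mean()
      else {
        x <- seq_len(h)
        cf <- stats::lm.fit(cbind(1, x), prefix)$coefficients
        unname(cf[1] + cf[2] * (h + 1))
      }
    },
    arma = {
      if (h < 4L) observed_mean()
      else {
        fit <- tryCatch(
          suppressWarnings(stats::arima(prefix, order = c(1, 0, 1),
                                        method = "ML")),
          error = function(e) NULL)
        if (is.null(fit)) observed_mean()
        else as.numeric(stats::predict(fit, n.ahead = 1)$pred)
      }
    })
  if (clip) {
    clipped <- clip01(pred)
    if (verbose && clipped != pred)
      message(sprintf("forecast %s clipped from %.4f into [0, 1]", method, pred))
    pred <- clipped
  }
  pred
}

#' Per-task forecasting RMSE across teams
#'
#' Evaluates one forecasting baseline on every team of a score table: for
#' each evaluated task `t`, the method forecasts each team's score from
#' its observed prefix (tasks `1 .. t-1`) and the RMSE across teams is
#' reported. History-requiring methods are evaluated from `start_task` on
#' (default 4); earlier tasks report `NA`.
#'
#' @param scores a [score_table] (complete, no missing entries).
#' @param method forecasting method name (see [forecast_score()]).
#' @param start_task first task to evaluate (default 4).
#' @param clip passed to [forecast_score()].
#' @return Named numeric vector of per-task RMSEs (length `ncol(scores)`,
#'   `NA` before `start_task`).
#' @export
rmse_by_task <- function(scores, method, start_task = 4, clip = TRUE) {
  stopifnot(inherits(scores, "score_table"))
  if (anyNA(scores)) stop("score table must be complete")
  m <- ncol(scores)
  out <- stats::setNames(rep(NA_real_, m), colnames(scores))
  for (t in seq.int(start_task, m)) {
    preds <- vapply(seq_len(nrow(scores)), function(i)
      forecast_score(method, scores[i, seq_len(t - 1)],
                     full_series = scores[i, ], clip = clip),
      numeric(1))
    out[t] <- evaluate_rmse(preds, scores[, t])
  }
  out
}

#' RMSE comparison table across forecasting baselines
#'
#' @param scores a [score_table].
#' @param methods methods to evaluate (default all five baselines).
#' @param start_task first evaluated task (default 4).
#' @return Matrix methods x tasks of RMSEs (`NA` for unavailable cells).
#' @export
forecaster_comparison <- function(scores,
                                  methods = c("mean_oracle", "observed_mean",
                                              "naive", "least_squares", "arma"),
                                  start_task = 4) {
  t(vapply(methods, function(m) rmse_by_task(scores, m, start_task),
           numeric(ncol(scores))))
}
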