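#' Score-dynamics features of an observed score prefix
#'
#' Given the scores a team has already earned on tasks `1 .. t-1`, extracts
#' the features describing the historical dynamics of its performance,
#' used to predict the score on task `t`:
#' first and last observed scores; mean and median; standard deviation and
#' variance (sample, n-1 convention); skewness (adjusted Fisher--Pearson)
#' and excess kurtosis; the least-squares best-fit line's ordinates at the
#' first, middle and last task index, its slope in radians
#' (`atan` of the per-task-index slope) and the difference of its last and
#' first ordinates; the numbers of score increases and decreases; and the
#' numbers of score changes above and below the median score change (exact
#' ties with the median count as neither).
#'
#' The abscissa is the task index `1 .. t-1`, not elapsed time; for
#' even-length prefixes the "middle" ordinate is the line's value at
#' `(1 + len) / 2`. Degenerate moments (constant series) yield `NaN`
#' skewness/kurtosis, reported as missing.
#'
#' @param scores numeric vector of observed scores in \[0, 1\], length >= 3
#'   (performance is predicted starting from the fourth task).
#' @return Named numeric vector with elements `first`, `last`, `mean`,
#'   `median`, `std`, `var`, `skewness`, `kurtosis`, `fit_first`,
#'   `fit_mid`, `fit_last`, `fit_slope_rad`, `fit_last_minus_first`,
#'   `n_increases`, `n_decreases`, `n_changes_above_median`,
#'   `n_changes_below_median`.
#' @examples
#' dynamics_features(c(0.2, 0.4, 0.6))
#' @export
dynamics_features <- function(scores) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 3L)
    stop("score prefix must contain at least 3 observed tasks")
  if (any(!is.finite(scores))) stop("scores must be finite")
  x <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, x), scores)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  d <- diff(scores)
  med_d <- stats::median(d)
  tie_tol <- 1e-9  # float-safe "exact tie with the median change" test
  sk <- suppressWarnings(e1071::skewness(scores, type = 2))
  ku <- suppressWarnings(e1071::kurtosis(scores, type = 1))
  c(first = scores[1], last = scores[n],
    mean = mean(scores), median = stats::median(scores),
    std = stats::sd(scores), var = stats::var(scores),
    skewness = if (is.finite(sk)) sk else NA_real_,
    kurtosis = if (is.finite(ku)) ku else NA_real_,
    fit_first = unname(a + b * 1),
    fit_mid = unname(a + b * (1 + n) / 2),
    fit_last = unname(a + b * n),
    fit_slope_rad = unname(atan(b)),
    fit_last_minus_first = unname(b * (n - 1)),
    n_increases = sum(d > 0), n_decreases = sum(d < 0),
    n_changes_above_median = sum(d > med_d + tie_tol),
    n_changes_below_median = sum(d < med_d - tie_tol))
}

#' Dynamics feature block for every team in a score table
#'
#' For target task `t`, each team's features are computed on its observed
#' prefix (tasks `1 .. t-1`) only, honoring the forecasting protocol.
#' Feature names carry the `dyn_` prefix.
#'
#' @param scores a [score_table].
#' @param target_task index of the task to be predicted (>= 4, so at least
#'   3 tasks have been observed).
#' @return Data frame with `team_id` and `dyn_`-prefixed feature columns.
#' @export
dynamics_feature_table <- function(scores, target_task) {
  stopifnot(inherits(scores, "score_table"))
  t <- as.integer(target_task)
  if (t < 4L || t > ncol(scores) + 1L)
    stop("target task must be >= 4 and within the battery")
  rows <- lapply(rownames(scores), function(id) {
    prefix <- scores[id, seq_len(t - 1L)]
    v <- dynamics_features(prefix)
    names(v) <- paste0("dyn_", names(v))
    data.frame(team_id = id, t(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
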