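#' Response time windows
#'
#' Collaboration extraction treats a message `r` as a probable response to
#' an earlier message `m` when `r` comes from a different sender and arrives
#' between `t1` and `t2` seconds after `m`. The default window \[1, 17\]
#' seconds is the calibrated value shipped with the package, obtained by
#' maximizing the F2-score of response classification against manually
#' annotated chat logs.
#'
#' @param t1 lower window bound in seconds, strictly positive.
#' @param t2 upper window bound in seconds, `t2 >= t1`.
#' @return An object of class `response_window` (list with `t1`, `t2`).
#' @export
response_window <- function(t1 = 1, t2 = 17) {
  stopifnot(is.numeric(t1), is.numeric(t2), length(t1) == 1L, length(t2) == 1L)
  if (!(t1 > 0 && t2 >= t1)) stop("need 0 < t1 <= t2")
  structure(list(t1 = as.numeric(t1), t2 = as.numeric(t2)),
            class = "response_window")
}

#' @export
print.response_window <- function(x, ...) {
  cat(sprintf("<response_window> [%g, %g] sec\n", x$t1, x$t2))
  invisible(x)
}

#' Response set of a message
#'
#' R(m): the messages sent by other team members that arrive within the
#' response window after message `m`, i.e. every `r` with
#' `m.time < r.time`, `t1 <= r.time - m.time <= t2` and
#' `r.sender != m.sender`. A message may belong to the response set of
#' several antecedents; equal-timestamp pairs are never responses.
#'
#' @param m index of the antecedent message in `log$messages`.
#' @param log a [chat_log].
#' @param window a [response_window].
#' @return Integer vector of message indices (possibly empty), ascending.
#' @export
response_set <- function(m, log, window = response_window()) {
  stopifnot(inherits(log, "chat_log"), inherits(window, "response_window"))
  m <- as.integer(m)
  tm <- log$messages$time
  if (m < 1L || m > length(tm)) stop("antecedent index out of range")
  dt <- tm - tm[m]
  idx <- which(dt > 0 & dt >= window$t1 & dt <= window$t2 &
                 log$messages$sender != log$messages$sender[m])
  idx
}

#' F-beta score
#'
#' Precision--recall summary weighting recall `beta` times as heavily as
#' precision: `(1 + beta^2) * P * R / (beta^2 * P + R)`. When both precision
#' and recall are zero the score is 0 by convention (a warning is raised,
#' since the formula is undefined there).
#'
#' @param precision,recall values in \[0, 1\], not both zero.
#' @param beta positive recall weight; `beta = 2` is used for response
#'   window calibration.
#' @return F-beta in \[0, 1\].
#' @examples
#' f_beta(0.4, 0.6, beta = 2)  # 1.2 / 2.2
#' @export
f_beta <- function(precision, recall, beta = 2) {
  stopifnot(beta > 0, precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) {
    warning("precision and recall both zero; F-beta set to 0 by convention")
    return(0)
  }
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Classify annotated message pairs under a window
#'
#' A pair (antecedent, candidate) is predicted to be a response exactly when
#' the candidate lies in the antecedent's response set for the window.
#'
#' @keywords internal
classify_pairs <- function(annotations, log, window) {
  tm <- log$messages$time
  sd <- log$messages$sender
  a <- annotations$antecedent
  c <- annotations$candidate
  dt <- tm[c] - tm[a]
  dt > 0 & dt >= window$t1 & dt <= window$t2 & sd[a] != sd[c]
}

#' Default calibration grid of response windows
#'
#' `t1` in 0.5, 1, ..., 5 seconds crossed with `t2` in 5, 6, ..., 30
#' seconds, keeping `t1 <= t2`.
#'
#' @return Data frame with columns `t1`, `t2`.
#' @export
default_window_grid <- function() {
  g <- expand.grid(t1 = seq(0.5, 5, by = 0.5), t2 = 5:30)
  g <- g[g$t1 <= g$t2, ]
  rownames(g) <- NULL
  g
}

#' Calibrate the response window against annotated pairs
#'
#' For every candidate window in the grid, annotated ordered message pairs
#' are classified as response / non-response by the window rule, and the
#' F-beta score of that classification against the human labels is
#' computed. The window maximizing F-beta wins; ties are broken in favor of
#' the narrowest window (smaller `t2`, then larger `t1`).
#'
#' @param annotations data frame with integer columns `antecedent`,
#'   `candidate` (indices into `log$messages`) and a `label` column that is
#'   logical, or character with values `"response"` / `"non_response"`.
#'   Must contain at least one of each label.
#' @param log the [chat_log] the annotation indices refer to.
#' @param grid data frame of candidate windows (columns `t1`, `t2`);
#'   defaults to [default_window_grid()].
#' @param beta recall weight of the F-score (default 2: missing a true
#'   response is costlier than a false alarm).
#' @return A list of class `calibration_result`: `best_window`
#'   ([response_window]), `best_score`, and `grid` (the input grid with
#'   `precision`, `recall`, `f_score` columns).
#' @export
calibrate_window <- function(annotations, log, grid = default_window_grid(),
                             beta = 2) {
  stopifnot(inherits(log, "chat_log"))
  if (nrow(grid) == 0L) stop("empty calibration grid")
  lab <- annotations$label
  if (is.character(lab)) lab <- lab == "response"
  lab <- as.logical(lab)
  if (!any(lab) || !any(!lab))
    stop("annotations must contain both true-response and non-response pairs")
  tm <- log$messages$time
  if (any(tm[annotations$candidate] < tm[annotations$antecedent]))
    stop("candidate messages must not precede their antecedents")
  res <- grid
  res$precision <- res$recall <- res$f_score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    w <- response_window(grid$t1[i], grid$t2[i])
    pred <- classify_pairs(annotations, log, w)
    tp <- sum(pred & lab)
    p <- if (sum(pred) == 0L) 0 else tp / sum(pred)
    r <- tp / sum(lab)
    res$precision[i] <- p
    res$recall[i] <- r
    res$f_score[i] <- if (p == 0 && r == 0) 0 else
      (1 + beta^2) * p * r / (beta^2 * p + r)
  }
  ord <- order(-res$f_score, res$t2, -res$t1)
  best <- ord[1]
  structure(list(
    best_window = response_window(res$t1[best], res$t2[best]),
    best_score = res$f_score[best],
    grid = res
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> best window [%g, %g] sec, F-score %.4f (%d windows)\n",
              x$best_window$t1, x$best_window$t2, x$best_score, nrow(x$grid)))
  invisible(x)
}

#' Read response annotations from CSV
#'
#' Layout: columns `antecedent_index`, `candidate_index`, `label`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `antecedent`, `candidate`, `label`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("antecedent_index", "candidate_index", "label")
  if (!all(need %in% names(df)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  data.frame(antecedent = as.integer(df$antecedent_index),
             candidate = as.integer(df$candidate_index),
             label = df$label, stringsAsFactors = FALSE)
}
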