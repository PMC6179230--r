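#' Score tables
#'
#' A score table holds the per-task performance of every team: a numeric
#' matrix with one row per team and one column per task, in a fixed task
#' order shared by all teams. After normalization all entries lie in
#' \[0, 1\]; missing scores are `NA`.
#'
#' @param scores numeric matrix (teams x tasks).
#' @param team_ids,task_ids optional dimension names; default to existing
#'   dimnames or generated labels.
#' @param normalized logical; when `TRUE` (default) entries are required to
#'   lie in \[0, 1\].
#' @return A numeric matrix of class `score_table` with team ids as row
#'   names and task ids as column names.
#' @export
score_table <- function(scores, team_ids = NULL, task_ids = NULL,
                        normalized = TRUE) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(team_ids)) team_ids <- rownames(scores)
  if (is.null(team_ids)) team_ids <- sprintf("team%02d", seq_len(nrow(scores)))
  if (is.null(task_ids)) task_ids <- colnames(scores)
  if (is.null(task_ids)) task_ids <- sprintf("task%02d", seq_len(ncol(scores)))
  stopifnot(length(team_ids) == nrow(scores), length(task_ids) == ncol(scores))
  if (anyDuplicated(team_ids)) stop("duplicate team ids")
  if (anyDuplicated(task_ids)) stop("duplicate task ids")
  if (normalized) {
    v <- scores[!is.na(scores)]
    if (any(v < 0 | v > 1))
      stop("normalized score table entries must lie in [0, 1]")
  }
  dimnames(scores) <- list(as.character(team_ids), as.character(task_ids))
  class(scores) <- c("score_table", "matrix", "array")
  scores
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d teams x %d tasks\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Read / write a score table
#'
#' The file layout is a rectangular CSV/TSV with a `team_id` first column
#' and one numeric column per task, in battery order. Empty cells are read
#' as missing (`NA`), never as 0. `read_score_table(write_score_table(x))`
#' returns `x`.
#'
#' @param path file path.
#' @param delim delimiter; `NULL` auto-detects comma vs tab on read.
#' @param normalized passed to [score_table()]; set `FALSE` to read raw
#'   (un-normalized) scores.
#' @return `read_score_table`: a [score_table]. `write_score_table`: `path`,
#'   invisibly.
#' @export
read_score_table <- function(path, delim = NULL, normalized = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!"team_id" %in% names(df)) stop("score table needs a team_id column")
  m <- as.matrix(df[setdiff(names(df), "team_id")])
  score_table(m, team_ids = df$team_id, task_ids = colnames(m),
              normalized = normalized)
}

#' @rdname read_score_table
#' @param x a [score_table].
#' @export
write_score_table <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "score_table"))
  df <- data.frame(team_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = TRUE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' Linearly rescale raw task scores to \[0, 1\]
#'
#' Each task has its own scale; scores are mapped task-wise by
#' `(x - min) / (max - min)` so that the scale minimum maps to 0 and the
#' maximum to 1. When a task's range is not supplied, the observed min/max
#' across teams is used (and announced via `message()`), since raw scales
#' are not always known.
#'
#' @param raw numeric matrix or [score_table] (`normalized = FALSE`) of raw
#'   scores, teams x tasks.
#' @param ranges optional data frame with columns `task`, `min`, `max`
#'   giving each task's theoretical scale; tasks absent from it fall back to
#'   observed ranges.
#' @return A normalized [score_table].
#' @examples
#' raw <- matrix(c(0, 5, 10, 2, 4, 8), nrow = 2, byrow = TRUE)
#' normalize_scores(raw, data.frame(task = colnames(score_table(raw, normalized = FALSE)),
#'                                  min = 0, max = 10))
#' @export
normalize_scores <- function(raw, ranges = NULL) {
  raw <- score_table(raw, normalized = FALSE)
  out <- unclass(raw)
  rng <- list()
  if (!is.null(ranges)) {
    stopifnot(all(c("task", "min", "max") %in% names(ranges)))
    rng <- stats::setNames(Map(c, ranges$min, ranges$max), ranges$task)
  }
  for (j in seq_len(ncol(out))) {
    task <- colnames(out)[j]
    if (!is.null(rng[[task]])) {
      lo <- rng[[task]][1]; hi <- rng[[task]][2]
    } else {
      lo <- suppressWarnings(min(out[, j], na.rm = TRUE))
      hi <- suppressWarnings(max(out[, j], na.rm = TRUE))
      message(sprintf("normalize_scores: task '%s' uses observed range [%g, %g]",
                      task, lo, hi))
    }
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
      stop(sprintf("degenerate scale for task '%s': max must exceed min", task))
    v <- out[, j]
    if (any(v < lo | v > hi, na.rm = TRUE))
      stop(sprintf("task '%s' has raw scores outside its declared range", task))
    out[, j] <- (v - lo) / (hi - lo)
  }
  score_table(out)
}
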