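#' Chat log objects
#'
#' A chat log is the record of one team's text conversation during a work
#' session: a sequence of messages, each carrying a timestamp (seconds from
#' session start), the sender's alias, the message text, and optionally a
#' per-message sentiment score in \[-1, 1\]. Messages are kept sorted by
#' time; ties are allowed.
#'
#' @param team_id single string identifying the team.
#' @param messages data frame with columns `time` (non-negative numeric),
#'   `sender` (non-empty character), `text` (character) and optionally
#'   `sentiment` (numeric in \[-1, 1\], `NA` allowed).
#' @param members character vector of member aliases; defaults to the set of
#'   senders appearing in `messages`. Must contain at least two members and
#'   cover every sender.
#' @return An object of class `chat_log`: a list with elements `team_id`,
#'   `members` and `messages` (sorted by time).
#' @examples
#' log <- chat_log("t1", data.frame(
#'   time = c(5, 0, 12), sender = c("b", "a", "a"),
#'   text = c("hi", "hello", "ok")))
#' log$messages$time  # sorted ascending
#' @export
chat_log <- function(team_id, messages, members = NULL) {
  stopifnot(is.character(team_id), length(team_id) == 1L)
  messages <- as.data.frame(messages, stringsAsFactors = FALSE)
  req <- c("time", "sender", "text")
  if (!all(req %in% names(messages)))
    stop("messages must have columns: ", paste(req, collapse = ", "))
  if (nrow(messages) == 0L) stop("chat log has no messages")
  if (any(!is.finite(messages$time)) || any(messages$time < 0))
    stop("message times must be finite and non-negative")
  if (any(!nzchar(messages$sender))) stop("sender aliases must be non-empty")
  if (!"sentiment" %in% names(messages)) messages$sentiment <- NA_real_
  s <- messages$sentiment
  if (any(!is.na(s) & (s < -1 | s > 1)))
    stop("sentiment values must lie in [-1, 1]")
  if (is.null(members)) members <- sort(unique(messages$sender))
  members <- as.character(members)
  if (length(members) < 2L)
    stop("a team needs at least 2 members")
  if (!all(messages$sender %in% members))
    stop("every message sender must be a team member")
  ord <- order(messages$time)
  messages <- messages[ord, c("time", "sender", "text", "sentiment")]
  rownames(messages) <- NULL
  structure(list(team_id = team_id, members = members, messages = messages),
            class = "chat_log")
}

#' @export
print.chat_log <- function(x, ...) {
  cat(sprintf("<chat_log> team %s: %d messages, %d members (%s)\n",
              x$team_id, nrow(x$messages), length(x$members),
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Parse chat timestamps into seconds
#'
#' Accepts raw seconds (`"2198"` or numeric), `"MM:SS"` (minutes may exceed
#' 59 -- logs of hour-long sessions commonly use a running minute counter)
#' and `"HH:MM:SS"`. `"MM:SS"` parses as `60*MM + SS`.
#'
#' @param x character (or numeric) vector of timestamps.
#' @return Numeric vector of seconds from session start.
#' @examples
#' parse_timestamp(c("36:38", "00:00", "1:02:03"))  # 2198 0 3723
#' @export
parse_timestamp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    parts <- strsplit(x[i], ":", fixed = TRUE)[[1]]
    if (length(parts) > 3L || length(parts) == 0L || any(!nzchar(parts)) ||
        any(!grepl("^[0-9]+(\\.[0-9]+)?$", parts)))
      stop(sprintf("malformed timestamp '%s'", x[i]))
    v <- as.numeric(parts)
    if (length(parts) > 1L && any(v[-1] >= 60))
      stop(sprintf("malformed timestamp '%s': trailing fields must be < 60", x[i]))
    out[i] <- sum(v * 60^(rev(seq_along(v)) - 1))
  }
  out
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a chat log from a delimited text file
#'
#' Expects columns `time`, `sender`, `message` (or `text`) and optionally
#' `sentiment`. Timestamps may be raw seconds, `"MM:SS"` or `"HH:MM:SS"`.
#' Rows out of chronological order in the file are sorted on read.
#'
#' @param path path to a CSV/TSV file.
#' @param team_id team identifier; defaults to the file name without
#'   extension.
#' @param delim field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [chat_log] object.
#' @export
read_chat_log <- function(path, team_id = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty chat log file: ", path)
  names(df) <- tolower(names(df))
  if ("message" %in% names(df) && !"text" %in% names(df))
    names(df)[names(df) == "message"] <- "text"
  if (!all(c("time", "sender", "text") %in% names(df)))
    stop("chat log needs columns time, sender, message")
  times <- tryCatch(parse_timestamp(df$time), error = function(e) {
    bad <- which(vapply(as.character(df$time), function(v)
      inherits(tryCatch(parse_timestamp(v), error = identity), "error"),
      logical(1)))[1]
    stop(sprintf("%s: line %d: %s", path, bad + 1L, conditionMessage(e)))
  })
  df$time <- times
  if (is.null(team_id)) team_id <- sub("\\.[^.]*$", "", basename(path))
  chat_log(team_id, df)
}

#' Write a chat log to CSV
#'
#' @param log a [chat_log].
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_chat_log <- function(log, path, delim = ",") {
  stopifnot(inherits(log, "chat_log"))
  df <- log$messages
  names(df)[names(df) == "text"] <- "message"
  if (all(is.na(df$sentiment))) df$sentiment <- NULL
  utils::write.table(df, path, sep = delim, row.names = FALSE, qmethod = "double",
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
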