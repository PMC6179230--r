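#' Specification of the synthetic study generator
#'
#' Bundles the parameters of the synthetic data generator that emulates a
#' small-team study: `n_teams` four-member teams work through an ordered
#' battery of `n_tasks` tasks over an hour-long session, earning bounded
#' scores driven by a latent team quality, while communicating in a text
#' chat whose reply structure follows a planted member-affinity matrix.
#'
#' Defaults mirror the study conditions the package's analyses assume:
#' 68 teams of 4, 15 tasks, hour-long (3600 s) sessions, a true response
#' window of \[1, 17\] seconds. Latent qualities are uniform on
#' `quality_range`; each team's score trend is negatively coupled to its
#' quality (`slope_i = trend_coupling * (quality_ref - q_i) / (n_tasks -
#' 1)`), reproducing the observed pattern that strong teams start strong
#' and stay consistent while weak teams start poorly and improve. Base
#' messages arrive as a Poisson process at `message_rate` per second;
#' after a message by member i, each other member j replies with
#' probability `reply_prob * A_ij` at a lag uniform inside the true
#' window, at most once per (antecedent, member) pair so the planted reply
#' relation stays well-defined.
#'
#' @param n_teams,n_tasks,n_members study dimensions.
#' @param quality_range range of the uniform latent quality distribution.
#' @param quality_ref,trend_coupling trend coupling: quality pivot and
#'   strength of the negative quality--slope link.
#' @param noise_sd score noise standard deviation.
#' @param session_length chat session length, seconds.
#' @param message_rate base (non-reply) message rate, messages/second.
#' @param reply_prob reply probability scale multiplying the affinity.
#' @param true_window numeric `c(t1, t2)`: true reply-lag window, seconds.
#' @param feature_cor named numeric vector of target correlations between
#'   latent quality and the baseline features.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_teams = 68, n_tasks = 15, n_members = 4,
                       quality_range = c(0.25, 0.85),
                       quality_ref = 0.6, trend_coupling = 0.8,
                       noise_sd = 0.1,
                       session_length = 3600, message_rate = 0.04,
                       reply_prob = 0.5, true_window = c(1, 17),
                       feature_cor = c(social_perceptiveness = 0.4,
                                       proportion_female = 0.35,
                                       communication_amount = 0.3,
                                       communication_distribution = -0.3)) {
  stopifnot(n_teams >= 1, n_tasks >= 1, n_members >= 2,
            noise_sd >= 0, message_rate > 0, session_length > 0,
            reply_prob >= 0, reply_prob <= 1,
            true_window[1] > 0, true_window[2] >= true_window[1])
  structure(list(n_teams = n_teams, n_tasks = n_tasks, n_members = n_members,
                 quality_range = quality_range, quality_ref = quality_ref,
                 trend_coupling = trend_coupling, noise_sd = noise_sd,
                 session_length = session_length, message_rate = message_rate,
                 reply_prob = reply_prob, true_window = true_window,
                 feature_cor = feature_cor),
            class = "synth_spec")
}

#' Generate a synthetic score table
#'
#' `s_i(t) = clip(q_i + slope_i (t - 1) + noise, 0, 1)` with latent team
#' quality `q_i` and a slope negatively coupled to quality (see
#' [synth_spec()]). Deterministic for a given seed. The latent qualities
#' are attached as attribute `"quality"`.
#'
#' @param spec a [synth_spec].
#' @param seed integer seed.
#' @return A complete [score_table] with a `"quality"` attribute.
#' @export
gen_score_table <- function(spec = synth_spec(), seed = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(derive_seed(seed, 0))
  q <- stats::runif(spec$n_teams, spec$quality_range[1], spec$quality_range[2])
  denom <- max(1, spec$n_tasks - 1)
  slope <- spec$trend_coupling * (spec$quality_ref - q) / denom
  s <- matrix(NA_real_, spec$n_teams, spec$n_tasks)
  for (t in seq_len(spec$n_tasks))
    s[, t] <- clip01(q + slope * (t - 1) +
                       stats::rnorm(spec$n_teams, sd = spec$noise_sd))
  out <- score_table(s)
  attr(out, "quality") <- q
  out
}

## crude placeholder text: a few random lowercase "words"
gen_text <- function(n) {
  vapply(seq_len(n), function(i) {
    k <- sample(2:8, 1)
    paste(vapply(seq_len(k), function(j)
      paste(sample(letters, sample(2:7, 1), replace = TRUE), collapse = ""),
      character(1)), collapse = " ")
  }, character(1))
}

#' Generate a synthetic chat log with a planted reply structure
#'
#' Base messages arrive with exponential inter-event gaps and uniformly
#' random senders; after each base message by member i, every other member
#' j replies with probability `reply_prob * A_ij` at a lag drawn uniformly
#' inside the true response window (one reply at most per antecedent and
#' member). Replies do not trigger further replies, keeping the planted
#' relation well-defined. Messages carry placeholder text and a sentiment
#' value.
#'
#' The returned log has attributes `"affinity"` (the planted matrix, rows
#' = antecedent sender), `"planted"` (data frame of true
#' antecedent/candidate index pairs) and `"true_window"`.
#'
#' @param spec a [synth_spec].
#' @param seed integer seed.
#' @param team_id team identifier.
#' @param affinity optional `n_members x n_members` non-negative affinity
#'   matrix scaled to \[0, 1\]; drawn uniformly at random when `NULL`.
#' @return A [chat_log] with planted-structure attributes.
#' @export
gen_chat_log <- function(spec = synth_spec(), seed = 1, team_id = "team01",
                         affinity = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(derive_seed(seed, 1))
  nm <- spec$n_members
  members <- sprintf("m%02d", seq_len(nm))
  if (is.null(affinity)) {
    affinity <- matrix(stats::runif(nm * nm), nm, nm)
    diag(affinity) <- 0
  }
  stopifnot(all(dim(affinity) == c(nm, nm)), all(affinity >= 0),
            all(affinity <= 1))
  dimnames(affinity) <- list(members, members)
  ## base arrivals: Poisson process over the session
  gaps <- stats::rexp(ceiling(spec$message_rate * spec$session_length * 2) + 10,
                      rate = spec$message_rate)
  base_t <- cumsum(gaps)
  base_t <- base_t[base_t <= spec$session_length]
  if (!length(base_t)) base_t <- stats::runif(1, 0, spec$session_length)
  base_s <- sample(members, length(base_t), replace = TRUE)
  time <- base_t; sender <- base_s
  reply_of <- rep(NA_integer_, length(base_t))  # index into base messages
  for (b in seq_along(base_t)) {
    i <- match(base_s[b], members)
    for (j in seq_len(nm)[-i]) {
      if (stats::runif(1) < spec$reply_prob * affinity[i, j]) {
        lag <- stats::runif(1, spec$true_window[1], spec$true_window[2])
        time <- c(time, base_t[b] + lag)
        sender <- c(sender, members[j])
        reply_of <- c(reply_of, b)
      }
    }
  }
  n_msg <- length(time)
  ord <- order(time)
  rank_of <- order(ord)  # position of original index after sorting
  msg <- data.frame(time = time[ord], sender = sender[ord],
                    text = gen_text(n_msg),
                    sentiment = round(stats::runif(n_msg, -1, 1), 3),
                    stringsAsFactors = FALSE)
  log <- chat_log(team_id, msg, members = members)
  rep_idx <- which(!is.na(reply_of))
  planted <- data.frame(antecedent = rank_of[reply_of[rep_idx]],
                        candidate = rank_of[rep_idx])
  attr(log, "affinity") <- affinity
  attr(log, "planted") <- planted
  attr(log, "true_window") <- spec$true_window
  log
}

#' Generate response annotations from a planted reply relation
#'
#' Builds an annotated set of ordered cross-sender message pairs from a
#' synthetic log: pairs in the planted reply relation are labeled
#' `"response"`, others `"non_response"`; each label is flipped with
#' probability `flip_noise`. By default, non-planted pairs whose lag falls
#' *inside* the true generating window are excluded from the candidate
#' set: their timing is indistinguishable from a true reply, so a
#' timestamp-only annotator cannot label them consistently, and keeping
#' them would make even the true window's label noise irreducible. Set
#' `include_ambiguous = TRUE` for the fully realistic candidate set.
#'
#' @param log a [chat_log] from [gen_chat_log()] (attributes `"planted"`,
#'   `"true_window"`), or any log with `true_window` given explicitly.
#' @param flip_noise label flip probability in \[0, 0.5).
#' @param horizon only pairs within `horizon` seconds are candidates
#'   (default 40).
#' @param true_window numeric `c(t1, t2)`; defaults to the log's
#'   attribute.
#' @param include_ambiguous keep in-window non-planted pairs (default
#'   `FALSE`).
#' @param seed integer seed for label flips.
#' @return Data frame with columns `antecedent`, `candidate`, `label`.
#' @export
gen_annotations <- function(log, flip_noise = 0, horizon = 40,
                            true_window = attr(log, "true_window"),
                            include_ambiguous = FALSE, seed = 1) {
  stopifnot(inherits(log, "chat_log"), flip_noise >= 0, flip_noise < 0.5,
            !is.null(true_window))
  planted <- attr(log, "planted")
  if (is.null(planted)) planted <- data.frame(antecedent = integer(0),
                                              candidate = integer(0))
  tm <- log$messages$time
  sd <- log$messages$sender
  M <- length(tm)
  if (M < 2L) return(data.frame(antecedent = integer(0),
                                candidate = integer(0),
                                label = character(0)))
  pairs <- expand.grid(antecedent = seq_len(M), candidate = seq_len(M))
  dt <- tm[pairs$candidate] - tm[pairs$antecedent]
  keep <- dt > 0 & dt <= horizon & sd[pairs$antecedent] != sd[pairs$candidate]
  pairs <- pairs[keep, ]
  dt <- dt[keep]
  key <- paste(pairs$antecedent, pairs$candidate)
  is_planted <- key %in% paste(planted$antecedent, planted$candidate)
  if (!include_ambiguous) {
    ambiguous <- !is_planted & dt >= true_window[1] & dt <= true_window[2]
    pairs <- pairs[!ambiguous, ]
    is_planted <- is_planted[!ambiguous]
  }
  set.seed(derive_seed(seed, 2))
  flip <- stats::runif(nrow(pairs)) < flip_noise
  lab <- xor(is_planted, flip)
  data.frame(antecedent = pairs$antecedent, candidate = pairs$candidate,
             label = ifelse(lab, "response", "non_response"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate baseline team features correlated with latent quality
#'
#' Draws each baseline feature from a Gaussian latent correlated with the
#' teams' latent quality at the generator's target correlations
#' (`feature_cor`), then maps it to a natural scale: proportion of female
#' members via the probit link into \[0, 1\] (centered near one half),
#' Big-5 trait averages on a 1--5 scale, social perceptiveness on a 0--36
#' test scale, communication amount and distribution log-normally. Big-5
#' traits other than agreeableness are drawn independent of quality;
#' agreeableness is mildly negatively coupled.
#'
#' @param qualities numeric vector of latent team qualities (e.g. the
#'   `"quality"` attribute of [gen_score_table()]).
#' @param spec a [synth_spec].
#' @param seed integer seed.
#' @return Data frame with `team_id` and the baseline feature columns.
#' @export
gen_baseline_features <- function(qualities, spec = synth_spec(), seed = 1) {
  set.seed(derive_seed(seed, 3))
  n <- length(qualities)
  z <- as.numeric(scale(qualities))
  if (any(!is.finite(z))) z <- rep(0, n)
  latent <- function(r) r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  fc <- spec$feature_cor
  g <- function(name, default = 0) if (name %in% names(fc)) fc[[name]] else default
  big5 <- list(openness = 0, conscientiousness = 0, extraversion = 0,
               agreeableness = -0.2, neuroticism = 0)
  out <- data.frame(
    team_id = sprintf("team%02d", seq_len(n)),
    proportion_female = stats::pnorm(latent(g("proportion_female"))),
    social_perceptiveness = clip01(26 + 4 * latent(g("social_perceptiveness")),
                                   0, 36),
    communication_amount = exp(log(1500) + 0.4 * latent(g("communication_amount"))),
    communication_distribution = exp(log(300) +
      0.4 * latent(g("communication_distribution"))),
    stringsAsFactors = FALSE)
  for (trait in names(big5))
    out[[paste0("big5_", trait)]] <- clip01(3 + 0.6 * latent(big5[[trait]]), 1, 5)
  out
}

#' Generate a matrix of standardized features with a planted sparse signal
#'
#' Utility for parameter-recovery experiments: `n` observations of `p`
#' independent standard-normal features, a response depending on the first
#' `length(beta_true)` of them plus Gaussian noise.
#'
#' @param n,p design dimensions.
#' @param beta_true coefficients of the informative leading features.
#' @param noise_sd response noise (default 0.2).
#' @param seed integer seed.
#' @return List with `X` (n x p matrix, columns `f01..`), `y`, and
#'   `true_features` (column names carrying signal).
#' @export
gen_sparse_signal <- function(n = 68, p = 30, beta_true = c(0.5, -0.4, 0.3),
                              noise_sd = 0.2, seed = 1) {
  set.seed(derive_seed(seed, 4))
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  k <- length(beta_true)
  y <- as.vector(X[, seq_len(k)] %*% beta_true) + stats::rnorm(n, sd = noise_sd)
  list(X = X, y = y, true_features = colnames(X)[seq_len(k)])
}

#' Generate a full synthetic study
#'
#' Convenience wrapper producing every input the pipeline consumes: a
#' score table, one chat log per team (per-team sub-seeds derived from the
#' master seed, so any team is regenerable in isolation), baseline
#' features, and annotations for the first log.
#'
#' @param spec a [synth_spec].
#' @param seed master seed.
#' @return List with `scores`, `logs` (named list of [chat_log]s),
#'   `baseline`, `annotations`, `spec`, `seed`.
#' @export
gen_study <- function(spec = synth_spec(), seed = 1) {
  scores <- gen_score_table(spec, seed)
  logs <- lapply(seq_len(spec$n_teams), function(i)
    gen_chat_log(spec, seed = derive_seed(seed, 1000L + i),
                 team_id = rownames(scores)[i]))
  names(logs) <- rownames(scores)
  baseline <- gen_baseline_features(attr(scores, "quality"), spec, seed)
  baseline$team_id <- rownames(scores)
  annotations <- gen_annotations(logs[[1]], seed = seed)
  list(scores = scores, logs = logs, baseline = baseline,
       annotations = annotations, spec = spec, seed = seed)
}

#' Planted-affinity recovery experiment
#'
#' End-to-end identifiability check of the network-extraction pipeline: a
#' four-member team with a planted affinity matrix is observed over many
#' chat sessions; the time-decay collaboration networks of all sessions
#' are pooled (weights summed) and the Spearman rank correlation between
#' the planted off-diagonal affinities and the recovered edge weights is
#' reported. The planted affinities are a random permutation of twelve
#' evenly spaced values, so the target ordering is well separated; the
#' session regime is sparse (low base message rate), keeping coincidental
#' same-window pairs -- which carry no affinity signal -- rare relative to
#' planted replies.
#'
#' @param seed master seed.
#' @param n_logs number of pooled sessions (default 60).
#' @param message_rate,reply_prob,session_length session regime (defaults:
#'   0.01 messages/s, reply probability scale 0.25, hour-long sessions).
#' @param window,rho network extraction parameters (defaults: the
#'   calibrated \[1, 17\] s window, decay 0.15/s).
#' @return List with `spearman`, `n_messages` (total), `affinity`,
#'   `weights` (pooled matrix).
#' @export
affinity_recovery_experiment <- function(seed = 1, n_logs = 60,
                                         message_rate = 0.01,
                                         reply_prob = 0.25,
                                         session_length = 3600,
                                         window = response_window(),
                                         rho = 0.15) {
  spec <- synth_spec(n_members = 4, message_rate = message_rate,
                     session_length = session_length,
                     reply_prob = reply_prob)
  set.seed(derive_seed(seed, 5))
  A <- matrix(0, 4, 4)
  off <- row(A) != col(A)
  A[off] <- sample(seq(0.05, 0.95, length.out = 12))
  W <- 0
  n_messages <- 0L
  for (k in seq_len(n_logs)) {
    log <- gen_chat_log(spec, seed = derive_seed(seed, 2000L + k),
                        affinity = A)
    W <- W + build_collaboration_network(log, window, rho)$weights
    n_messages <- n_messages + nrow(log$messages)
  }
  list(spearman = stats::cor(A[off], W[off], method = "spearman"),
       n_messages = n_messages, affinity = A, weights = W)
}
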