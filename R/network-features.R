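#' Degree-based network features
#'
#' In- and out-degrees are weighted strengths (sums of incident edge
#' weights); on sparse unweighted networks weights are 0/1, so these reduce
#' to plain degrees. Standard deviations over nodes use the population
#' convention (divide by n), since these are descriptive statistics of one
#' team's network. The `mean - std` combinations summarize how uniformly
#' highly-connected the nodes are: dense, structurally uniform networks
#' score high.
#'
#' @param network a [collab_network] or [sparse_network].
#' @return Named numeric vector: `mean_in`, `std_in`, `mean_out`,
#'   `std_out`, `mean_minus_std_in`, `mean_minus_std_out`.
#' @export
weighted_degree_features <- function(network) {
  W <- weight_matrix(network)
  if (nrow(W) < 1L) stop("network must have at least one node")
  din <- colSums(W)
  dout <- rowSums(W)
  c(mean_in = mean(din), std_in = pop_sd(din),
    mean_out = mean(dout), std_out = pop_sd(dout),
    mean_minus_std_in = mean(din) - pop_sd(din),
    mean_minus_std_out = mean(dout) - pop_sd(dout))
}

#' Mean edge reciprocity
#'
#' For every unordered member pair with any interaction
#' (`max(w_ij, w_ji) > 0`), the pair's reciprocity is
#' `min(w_ij, w_ji) / max(w_ij, w_ji)`: 1 for perfectly mutual interaction,
#' 0 for one-way. The feature is the mean over such pairs; `NA` when no
#' pair communicates.
#'
#' @param network a [collab_network] or [sparse_network].
#' @return Reciprocity in \[0, 1\], or `NA` for an interaction-free network.
#' @export
mean_edge_reciprocity <- function(network) {
  W <- weight_matrix(network)
  n <- nrow(W)
  if (n < 2L) return(NA_real_)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    hi <- max(W[i, j], W[j, i])
    if (hi > 0) vals <- c(vals, min(W[i, j], W[j, i]) / hi)
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Algebraic connectivity (Fiedler value)
#'
#' The smallest positive eigenvalue of the graph Laplacian, a spectral
#' measure of how well-connected and perturbation-robust the network is and
#' how fast diffusive processes (consensus, random walks) mix on it.
#' Directed weights are symmetrized as `(W + t(W)) / 2` before building
#' `L = D - A`; for a connected graph the value equals the Fiedler value
#' (second-smallest Laplacian eigenvalue).
#'
#' @param network a [collab_network] or [sparse_network].
#' @param tol eigenvalues below `tol` count as zero (default 1e-9).
#' @return Smallest eigenvalue exceeding `tol`, or `NA` for an all-zero
#'   network.
#' @examples
#' # complete unweighted K4 has algebraic connectivity 4
#' @export
algebraic_connectivity <- function(network, tol = 1e-9) {
  W <- weight_matrix(network)
  if (nrow(W) < 2L) stop("need at least 2 nodes")
  if (all(W == 0)) return(NA_real_)
  A <- (W + t(W)) / 2
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > tol]
  if (!length(ev)) return(NA_real_)
  min(ev)
}

#' Topological features of a sparse unweighted network
#'
#' Edge density is taken on the digraph (`|E| / (n (n - 1))`), strongly
#' connected components on the digraph, and betweenness on the digraph with
#' `1 / ((n - 1)(n - 2))` normalization, averaged over all nodes. Because
#' sparse digraphs are often not strongly connected, distance-based
#' quantities -- diameter, mean shortest-path length -- and the mean local
#' clustering coefficient are computed on the undirected projection
#' restricted to the largest weakly connected component; nodes of degree
#' < 2 contribute clustering 0. An edgeless network reports `NA` diameter
#' and path length.
#'
#' @param network a [sparse_network] (a [collab_network] is accepted; its
#'   positive-weight skeleton is used).
#' @return Named numeric vector: `density`, `diameter`,
#'   `mean_shortest_path`, `n_weak_components`, `n_strong_components`,
#'   `mean_betweenness`, `mean_clustering`.
#' @export
sparse_topology_features <- function(network) {
  A <- weight_matrix(network) > 0
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "directed")
  dens <- sum(A) / (n * (n - 1))
  weak <- igraph::components(g, mode = "weak")
  strong <- igraph::components(g, mode = "strong")
  betw <- mean(igraph::betweenness(g, directed = TRUE, normalized = TRUE))
  ## largest weak component, undirected projection
  keep <- which(weak$membership == which.max(weak$csize))
  gu <- igraph::as_undirected(igraph::induced_subgraph(g, keep), mode = "collapse")
  if (igraph::ecount(gu) == 0L) {
    diam <- NA_real_; msp <- NA_real_; clus <- 0
  } else {
    diam <- igraph::diameter(gu, unconnected = TRUE)
    msp <- igraph::mean_distance(gu, directed = FALSE, unconnected = TRUE)
    loc <- igraph::transitivity(gu, type = "local", isolates = "zero")
    clus <- mean(loc)
  }
  c(density = dens, diameter = diam, mean_shortest_path = msp,
    n_weak_components = weak$no, n_strong_components = strong$no,
    mean_betweenness = betw, mean_clustering = clus)
}

#' Chat-log summary features
#'
#' Counts and timing statistics extracted directly from one team's log:
#' total characters and words; per-member mean and (population) standard
#' deviation of both, over all team members (members who never wrote count
#' 0); the number of turns taken (maximal runs of consecutive messages by
#' one sender); the mean, median and standard deviation of the delay
#' between adjacent messages; and the mean and standard deviation of
#' per-message sentiment where sentiment is available. A single-message log
#' has missing delay features; a log without sentiment has missing
#' sentiment features (never zero-filled).
#'
#' @param log a [chat_log].
#' @return Named numeric vector with elements `n_characters`, `n_words`,
#'   `chars_per_member_mean`, `chars_per_member_std`,
#'   `words_per_member_mean`, `words_per_member_std`, `n_turns`,
#'   `delay_mean`, `delay_median`, `delay_std`, `sentiment_mean`,
#'   `sentiment_std`.
#' @export
log_features <- function(log) {
  stopifnot(inherits(log, "chat_log"))
  msg <- log$messages
  nchar_i <- nchar(msg$text)
  words_i <- lengths(strsplit(trimws(msg$text), "\\s+"))
  words_i[!nzchar(trimws(msg$text))] <- 0L
  per_member <- function(v) {
    s <- tapply(v, factor(msg$sender, levels = log$members), sum, default = 0)
    as.numeric(s)
  }
  chars_m <- per_member(nchar_i)
  words_m <- per_member(words_i)
  turns <- sum(rle(msg$sender)$lengths > 0)
  delays <- diff(msg$time)
  has_delay <- length(delays) >= 1L
  sent <- msg$sentiment[!is.na(msg$sentiment)]
  has_sent <- length(sent) >= 1L
  c(n_characters = sum(nchar_i), n_words = sum(words_i),
    chars_per_member_mean = mean(chars_m), chars_per_member_std = pop_sd(chars_m),
    words_per_member_mean = mean(words_m), words_per_member_std = pop_sd(words_m),
    n_turns = turns,
    delay_mean = if (has_delay) mean(delays) else NA_real_,
    delay_median = if (has_delay) stats::median(delays) else NA_real_,
    delay_std = if (has_delay) pop_sd(delays) else NA_real_,
    sentiment_mean = if (has_sent) mean(sent) else NA_real_,
    sentiment_std = if (has_sent) pop_sd(sent) else NA_real_)
}

#' All chat-derived features for one team
#'
#' Convenience wrapper running the full per-team extraction: the dense
#' weighted collaboration network (prefix `wn_`), the three sparse
#' unweighted networks with 25/50/75% of lowest-weight edges dropped
#' (prefixes `sn25_`, `sn50_`, `sn75_`) and the raw chat-log summaries
#' (prefix `log_`). Degree, reciprocity and spectral features are computed
#' for every network flavor; topological features only for the sparse
#' ones.
#'
#' @param log a [chat_log].
#' @param window,rho,weighting passed to [build_collaboration_network()].
#' @param drop_fractions sparsification levels (default `c(.25, .5, .75)`).
#' @return Named numeric vector of features for one team.
#' @export
chat_features <- function(log, window = response_window(), rho = 0.15,
                          weighting = "exponential",
                          drop_fractions = c(0.25, 0.5, 0.75)) {
  W <- build_collaboration_network(log, window, rho, weighting)
  net_vec <- function(nw) {
    c(weighted_degree_features(nw),
      reciprocity = mean_edge_reciprocity(nw),
      algebraic_connectivity = algebraic_connectivity(nw))
  }
  out <- stats::setNames(net_vec(W), paste0("wn_", names(net_vec(W))))
  for (f in drop_fractions) {
    S <- sparsify(W, f)
    v <- c(net_vec(S), sparse_topology_features(S))
    names(v) <- paste0(sprintf("sn%d_", round(100 * f)), names(v))
    out <- c(out, v)
  }
  lf <- log_features(log)
  names(lf) <- paste0("log_", names(lf))
  c(out, lf)
}

#' Assemble a feature table from per-source blocks
#'
#' Joins named feature blocks (baseline, chat/network, score-dynamics) by
#' `team_id` into one table with one row per team and uniquely named
#' feature columns. A team missing from a block keeps its row with `NA`s
#' for that block's features. Duplicate feature names across blocks are an
#' error.
#'
#' @param ... data frames, each with a `team_id` column and numeric feature
#'   columns (or a single named list of such data frames).
#' @return A data frame of class `feature_table` (first column `team_id`).
#' @export
assemble_feature_table <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1]]) &&
      !is.data.frame(blocks[[1]])) blocks <- blocks[[1]]
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) stop("no feature blocks supplied")
  for (b in blocks) {
    if (!is.data.frame(b) || !"team_id" %in% names(b))
      stop("every feature block must be a data frame with a team_id column")
  }
  feat_names <- unlist(lapply(blocks, function(b) setdiff(names(b), "team_id")))
  if (anyDuplicated(feat_names))
    stop("duplicate feature names across blocks: ",
         paste(unique(feat_names[duplicated(feat_names)]), collapse = ", "))
  out <- Reduce(function(a, b) merge(a, b, by = "team_id", all = TRUE), blocks)
  out <- out[order(out$team_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Pluggable sentiment scorer interface
#'
#' Sentiment values in this package are consumed as input in \[-1, 1\];
#' quantifying sentiment from text is delegated to a scorer function
#' `function(text) -> numeric in [-1, 1]`. The shipped default is a neutral
#' stub returning 0 for every message, useful for running the pipeline on
#' logs without sentiment annotations.
#'
#' @param log a [chat_log].
#' @param scorer function mapping a character vector of message texts to
#'   sentiment scores in \[-1, 1\].
#' @return The log with its `sentiment` column filled by the scorer.
#' @export
apply_sentiment_scorer <- function(log, scorer = neutral_sentiment_scorer) {
  stopifnot(inherits(log, "chat_log"), is.function(scorer))
  s <- scorer(log$messages$text)
  if (any(!is.na(s) & (s < -1 | s > 1)))
    stop("scorer returned sentiment outside [-1, 1]")
  log$messages$sentiment <- s
  log
}

#' @rdname apply_sentiment_scorer
#' @param text character vector of message texts.
#' @export
neutral_sentiment_scorer <- function(text) rep(0, length(text))
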