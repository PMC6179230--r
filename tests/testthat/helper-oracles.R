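# Independent brute-force oracles and fixture builders used across tests.
# Oracles deliberately avoid the package's own code paths.

# random chat log with arbitrary (sorted) uniform times
random_log <- function(n_messages, n_members = 4, t_max = 600, seed = 1) {
  set.seed(seed)
  members <- sprintf("p%d", seq_len(n_members))
  chat_log("rnd", data.frame(
    time = sort(round(runif(n_messages, 0, t_max), 2)),
    sender = sample(members, n_messages, replace = TRUE),
    text = replicate(n_messages, paste(sample(letters, 5), collapse = "")),
    stringsAsFactors = FALSE), members = members)
}

# O(M^2) double loop straight off the response-set definition
brute_response_pairs <- function(log, t1, t2) {
  msg <- log$messages
  out <- list()
  for (p in seq_len(nrow(msg))) for (q in seq_len(nrow(msg))) {
    dt <- msg$time[q] - msg$time[p]
    if (msg$time[p] < msg$time[q] && dt >= t1 && dt <= t2 &&
        msg$sender[p] != msg$sender[q])
      out[[length(out) + 1L]] <- c(p, q)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# brute-force edge weights from the pair scan
brute_network_weights <- function(log, t1, t2, rho, count = FALSE) {
  members <- log$members
  W <- matrix(0, length(members), length(members),
              dimnames = list(members, members))
  pairs <- brute_response_pairs(log, t1, t2)
  msg <- log$messages
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, 1]; q <- pairs[k, 2]
    W[msg$sender[p], msg$sender[q]] <- W[msg$sender[p], msg$sender[q]] +
      if (count) 1 else exp(-rho * (msg$time[q] - msg$time[p]))
  }
  W
}

# Benjamini-Hochberg step-up rejection set by direct enumeration
brute_bh_reject <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(n)) if (ps[i] <= q * i / n) k <- i
  rej <- rep(FALSE, n)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# exhaustive search over a simplex grid of given resolution (n <= 4),
# vectorized over the innermost coordinate
grid_search_allocation <- function(s, alpha, resolution = 1e-3) {
  n <- length(s)
  steps <- round(1 / resolution)
  best <- -Inf; best_w <- NULL
  if (n == 2) {
    a <- 0:steps
    v <- (s[1] * a + s[2] * (steps - a)) / steps -
      alpha * ((a / steps)^2 + ((steps - a) / steps)^2)
    i <- which.max(v)
    best <- v[i]; best_w <- c(a[i], steps - a[i]) / steps
  } else if (n == 3) {
    for (a in 0:steps) {
      b <- 0:(steps - a)
      cc <- steps - a - b
      v <- (s[1] * a + s[2] * b + s[3] * cc) / steps -
        alpha * ((a / steps)^2 + (b / steps)^2 + (cc / steps)^2)
      i <- which.max(v)
      if (v[i] > best) { best <- v[i]; best_w <- c(a, b[i], cc[i]) / steps }
    }
  } else if (n == 4) {
    for (a in 0:steps) for (b in 0:(steps - a)) {
      rem <- steps - a - b
      cc <- 0:rem
      w4 <- rem - cc
      v <- (s[1] * a + s[2] * b + s[3] * cc + s[4] * w4) / steps -
        alpha * ((a / steps)^2 + (b / steps)^2 + (cc / steps)^2 + (w4 / steps)^2)
      i <- which.max(v)
      if (v[i] > best) { best <- v[i]; best_w <- c(a, b, cc[i], w4[i]) / steps }
    }
  } else stop("grid oracle supports n <= 4")
  list(omega = best_w, value = best)
}

# tiny complete score table fixture
toy_scores <- function(n_teams = 12, n_tasks = 15, seed = 7) {
  set.seed(seed)
  score_table(matrix(round(runif(n_teams * n_tasks), 3), n_teams, n_tasks))
}

path4_network <- function() {
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A[1, 2] <- A[2, 3] <- A[3, 4] <- 1
  A <- pmax(A, t(A))  # undirected path with unit weights
  structure(list(members = letters[1:4], adjacency = A > 0, drop_fraction = 0),
            class = "sparse_network")
}

# random connected undirected 0/1 adjacency: spanning tree + extra edges
random_connected_adjacency <- function(n, extra = 2) {
  A <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    A[u, v] <- A[v, u] <- 1
  }
  free <- which(A == 0 & row(A) < col(A))
  if (length(free) && extra > 0) {
    add <- sample(free, min(extra, length(free)))
    A[add] <- 1
    A <- pmax(A, t(A))
  }
  A
}

complete_network <- function(n) {
  m <- sprintf("v%d", seq_len(n))
  A <- matrix(TRUE, n, n, dimnames = list(m, m)); diag(A) <- FALSE
  structure(list(members = m, adjacency = A, drop_fraction = 0),
            class = "sparse_network")
}

# weighted network object from a raw weight matrix
as_collab <- function(W, rho = 0.15) {
  if (is.null(rownames(W)))
    dimnames(W) <- list(sprintf("n%d", 1:nrow(W)), sprintf("n%d", 1:nrow(W)))
  structure(list(members = rownames(W), weights = W, rho = rho,
                 window = response_window(), weighting = "exponential"),
            class = "collab_network")
}
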