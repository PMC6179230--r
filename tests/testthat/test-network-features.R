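test_that("degree features use weighted strengths and population sd", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
  f <- weighted_degree_features(as_collab(W))
  expect_equal(unname(f["mean_out"]), 1)
  expect_equal(unname(f["std_out"]), 0)
  expect_equal(unname(f["mean_minus_std_out"]), 1)

  # out-strengths (2, 1, 0): population sd sqrt(2/3)
  W3 <- matrix(0, 3, 3); W3[1, 2] <- 2; W3[2, 3] <- 1
  f3 <- weighted_degree_features(as_collab(W3))
  expect_equal(unname(f3["mean_out"]), 1)
  expect_equal(unname(f3["std_out"]), sqrt(2 / 3))

  f0 <- weighted_degree_features(as_collab(matrix(0, 3, 3)))
  expect_true(all(f0 == 0))
})

test_that("mean edge reciprocity is the min/max ratio over communicating pairs", {
  Wsym <- matrix(1, 3, 3); diag(Wsym) <- 0
  expect_equal(mean_edge_reciprocity(as_collab(Wsym)), 1)
  Wone <- matrix(0, 3, 3); Wone[1, 2] <- 1; Wone[1, 3] <- 2
  expect_equal(mean_edge_reciprocity(as_collab(Wone)), 0)
  Wp <- matrix(0, 2, 2); Wp[1, 2] <- 2; Wp[2, 1] <- 1
  expect_equal(mean_edge_reciprocity(as_collab(Wp)), 0.5)
  expect_true(is.na(mean_edge_reciprocity(as_collab(matrix(0, 2, 2)))))
})

test_that("algebraic connectivity matches closed forms", {
  for (n in 3:8)
    expect_equal(algebraic_connectivity(complete_network(n)), n,
                 tolerance = 1e-9)
  expect_equal(algebraic_connectivity(path4_network()), 2 - sqrt(2),
               tolerance = 1e-9)
  # two disjoint unit dyads: spectrum {0, 0, 2, 2}
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  expect_equal(algebraic_connectivity(as_collab(W)), 2, tolerance = 1e-9)
  expect_true(is.na(algebraic_connectivity(as_collab(matrix(0, 3, 3)))))
})

test_that("algebraic connectivity never decreases when an undirected edge is added", {
  # on connected graphs the value is the Fiedler eigenvalue, which is
  # monotone under edge addition; disconnected graphs are excluded since
  # their smallest *positive* Laplacian eigenvalue is a different quantity
  set.seed(8)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    A <- random_connected_adjacency(n, extra = sample(0:3, 1))
    zero <- which(A == 0 & row(A) < col(A))
    if (!length(zero)) next
    A2 <- A
    A2[zero[sample(length(zero), 1)]] <- 1
    A2 <- pmax(A2, t(A2))
    expect_gte(algebraic_connectivity(as_collab(A2)) + 1e-9,
               algebraic_connectivity(as_collab(A)))
  }
})

test_that("sparse topology features match hand-enumerated digraphs", {
  f <- sparse_topology_features(complete_network(4))
  expect_equal(unname(f[c("density", "diameter", "n_weak_components",
                          "n_strong_components", "mean_clustering")]),
               c(1, 1, 1, 1, 1))

  empty <- complete_network(4)
  empty$adjacency[] <- FALSE
  fe <- sparse_topology_features(empty)
  expect_equal(unname(fe["density"]), 0)
  expect_equal(unname(fe["n_weak_components"]), 4)
  expect_true(is.na(fe["diameter"]))

  cyc <- complete_network(3)
  cyc$adjacency[] <- FALSE
  cyc$adjacency[1, 2] <- cyc$adjacency[2, 3] <- cyc$adjacency[3, 1] <- TRUE
  fc <- sparse_topology_features(cyc)
  expect_equal(unname(fc["density"]), 0.5)
  expect_equal(unname(fc["n_strong_components"]), 1)
  expect_equal(unname(fc["diameter"]), 1)  # undirected projection of the 3-cycle
})

test_that("chat-log summary features follow their run-length and delay oracles", {
  log <- chat_log("t", data.frame(
    time = c(0, 10, 30, 40),
    sender = c("a", "a", "b", "a"),
    text = c("one two", "three", "four five six", ""),
    sentiment = c(0, 0, NA, 0)))
  f <- log_features(log)
  expect_equal(unname(f["n_turns"]), 3)  # runs a,a | b | a
  expect_equal(unname(f["n_words"]), 6)
  expect_equal(unname(f["n_characters"]), sum(nchar(c("one two", "three",
                                                      "four five six", ""))))
  expect_equal(unname(f["delay_mean"]), mean(c(10, 20, 10)))
  expect_equal(unname(f["delay_median"]), 10)
  expect_equal(unname(f["sentiment_mean"]), 0)
  expect_equal(unname(f["sentiment_std"]), 0)

  # delays over the whole log: times (0, 10, 30) -> mean 15, median 15
  l3 <- chat_log("t", data.frame(time = c(0, 10, 30), sender = c("a", "b", "a"),
                                 text = c("x", "y", "z")))
  f3 <- log_features(l3)
  expect_equal(unname(f3[c("delay_mean", "delay_median")]), c(15, 15))

  # missing sentiment stays missing; single message has no delays
  l1 <- chat_log("t", data.frame(time = 0, sender = "a", text = "hi"),
                 members = c("a", "b"))
  f1 <- log_features(l1)
  expect_true(all(is.na(f1[c("delay_mean", "delay_median", "delay_std",
                             "sentiment_mean", "sentiment_std")])))
})

test_that("feature assembly joins by team and rejects name collisions", {
  a <- data.frame(team_id = c("t1", "t2"), x = 1:2)
  b <- data.frame(team_id = c("t2", "t1"), y = c(5, 6))
  ft <- assemble_feature_table(a, b)
  expect_equal(names(ft), c("team_id", "x", "y"))
  expect_equal(ft$y[ft$team_id == "t1"], 6)
  # missing block rows keep the team with NA features
  c2 <- data.frame(team_id = "t1", z = 9)
  ft2 <- assemble_feature_table(a, c2)
  expect_true(is.na(ft2$z[ft2$team_id == "t2"]))
  expect_error(assemble_feature_table(a, data.frame(team_id = "t1", x = 0)),
               "duplicate")
})

test_that("chat_features emits prefixed blocks for every network flavor", {
  log <- random_log(80, seed = 10)
  f <- chat_features(log)
  expect_true(all(c("wn_mean_out", "wn_reciprocity", "wn_algebraic_connectivity",
                    "sn25_density", "sn50_mean_betweenness", "sn75_n_weak_components",
                    "log_n_turns") %in% names(f)))
  expect_false(anyDuplicated(names(f)) > 0)
  expect_true(f["sn25_density"] >= 0 && f["sn25_density"] <= 1)
})

test_that("uniform out-degree and algebraic connectivity rise together across densities", {
  # ensemble of networks of increasing density: the rescaled degree feature
  # and the Fiedler value should be strongly rank-correlated
  set.seed(21)
  feat <- t(vapply(1:40, function(i) {
    p <- runif(1, 0.15, 0.95)
    n <- 6
    A <- matrix(rbinom(n * n, 1, p) * runif(n * n, 0.5, 1), n, n)
    diag(A) <- 0
    nw <- as_collab(A)
    c(deg = unname(weighted_degree_features(nw)["mean_minus_std_out"]),
      ac = {
        v <- algebraic_connectivity(nw)
        if (is.na(v)) 0 else v
      })
  }, numeric(2)))
  expect_gt(cor(feat[, "deg"], feat[, "ac"], method = "spearman"), 0.7)
})

test_that("the sentiment scorer interface fills the sentiment column", {
  log <- chat_log("t", data.frame(time = c(0, 5), sender = c("a", "b"),
                                  text = c("x", "y")))
  neutral <- apply_sentiment_scorer(log)
  expect_equal(neutral$messages$sentiment, c(0, 0))
  expect_error(apply_sentiment_scorer(log, function(tx) rep(2, length(tx))),
               "\\[-1, 1\\]")
})
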