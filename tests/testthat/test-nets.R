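test_that("identity-mode round reproduces the hand trace on a 2-node path", {
  g <- structure(list(
    n_nodes = 2L,
    node_features = matrix(c(1, 2), 2, 1),
    edges = rbind(c(1L, 2L), c(2L, 1L)),
    edge_features = matrix(c(5, 5), 2, 1),
    schema_version = "1"), class = "mp_graph")
  st <- mp_message_passing_round(g)
  expect_equal(st$messages[1, ], c(5, 1, 2))   # m_12 = (e, x_1, x_2)
  expect_equal(st$messages[2, ], c(5, 2, 1))   # m_21
  expect_equal(st$node_messages[1, ], c(5, 2, 1))  # m_1 = m_21
  expect_equal(st$node_messages[2, ], c(5, 1, 2))
  expect_equal(st$x, cbind(matrix(c(1, 2), 2, 1), st$node_messages))
  expect_equal(st$e, cbind(matrix(c(5, 5), 2, 1), st$messages))
})

test_that("isolated nodes receive the zero message", {
  g <- structure(list(n_nodes = 2L,
                      node_features = matrix(c(1, 3), 2, 1),
                      edges = matrix(integer(0), 0, 2),
                      edge_features = matrix(numeric(0), 0, 1),
                      schema_version = "1"), class = "mp_graph")
  st <- mp_message_passing_round(g)
  expect_equal(st$node_messages, matrix(0, 2, 3))
})

test_that("identity rounds match the brute-force edge-dictionary oracle", {
  set.seed(42)
  for (i in 1:50) {
    g <- random_graph(sample(2:8, 1))
    st <- list(x = g$node_features, e = g$edge_features)
    ours <- mp_message_passing_round(g, st)
    oracle <- oracle_identity_round(g, st)
    expect_identical(ours$x, oracle$x)
    expect_identical(unname(ours$node_messages), unname(oracle$node_messages))
    if (nrow(g$edges) > 0) expect_identical(ours$e, oracle$e)
    # second round on the grown state
    st2 <- list(x = ours$x, e = ours$e)
    expect_identical(mp_message_passing_round(g, st2)$x,
                     oracle_identity_round(g, st2)$x)
  }
})

test_that("encoding is invariant under node relabeling", {
  set.seed(7)
  cfg <- mp_mp_config(rounds = 2, test_mode_identity = TRUE)
  for (i in 1:20) {
    g <- random_graph(sample(3:8, 1))
    perm <- sample(g$n_nodes)
    gp <- g
    gp$node_features <- g$node_features[order(perm), , drop = FALSE]
    gp$edges <- matrix(perm[g$edges], ncol = 2)
    emb <- mp_dmpnn_encode(g, config = cfg)
    embp <- mp_dmpnn_encode(gp, config = cfg)
    expect_equal(emb, embp, tolerance = 1e-12)
  }
})

test_that("readout identities hold", {
  H <- rbind(c(1, 0), c(0, 1))
  expect_equal(drop(mp_readout(H, "sum")), c(1, 1))
  expect_equal(drop(mp_readout(rbind(c(2, 3), c(2, 3)), "mean")), c(2, 3))
  set.seed(1)
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(mp_readout(H, "mean"), mp_readout(H, "sum") / 4)
  gid <- c(1L, 1L, 2L, 2L)
  expect_equal(mp_readout(H, "sum", gid)[1, ], colSums(H[1:2, ]))
  expect_error(mp_readout(H[0, , drop = FALSE]), "empty")
})

test_that("T = 1 encoding equals one manual round plus readout", {
  g <- mp_mol_graph("CCO")
  cfg <- mp_mp_config(rounds = 1, test_mode_identity = TRUE)
  manual <- mp_message_passing_round(g)
  expect_equal(mp_dmpnn_encode(g, config = cfg),
               drop(mp_readout(manual$x, "mean")))
})

test_that("trained-mode encoding is deterministic and edge-blind at zero init", {
  g <- mp_mol_graph("CCO")
  cfg <- mp_mp_config(hidden_dim = 5, rounds = 2)
  p <- mp_init_dmpnn(ncol(g$node_features), ncol(g$edge_features), cfg, seed = 3)
  expect_identical(mp_dmpnn_encode(g, p, cfg), mp_dmpnn_encode(g, p, cfg))
  # two parseings of the same molecule give equal embeddings
  g2 <- mp_mol_graph("OCC")
  expect_equal(mp_dmpnn_encode(g, p, cfg), mp_dmpnn_encode(g2, p, cfg),
               tolerance = 1e-10)
  # zeroed parameters: output is independent of edge features
  p0 <- lapply(p, function(m) m * 0)
  galt <- g
  galt$edge_features <- galt$edge_features + 10
  expect_equal(mp_dmpnn_encode(g, p0, cfg), mp_dmpnn_encode(galt, p0, cfg))
  # the directed-exclusion variant changes the result but stays finite
  cfgx <- mp_mp_config(hidden_dim = 5, rounds = 2, directed_exclusion = TRUE)
  embx <- mp_dmpnn_encode(g, p, cfgx)
  expect_true(all(is.finite(embx)))
})

test_that("attention reduces correctly on degenerate keys", {
  # single key/value: output equals V regardless of Q
  out <- mp_attention(Q = matrix(3.7), K = matrix(0.2), V = matrix(11))
  expect_equal(as.numeric(out), 11)
  # identical keys: uniform weights, output = mean of values
  out2 <- mp_attention(Q = matrix(1), K = matrix(c(2, 2), 2, 1),
                       V = matrix(c(10, 30), 2, 1))
  expect_equal(as.numeric(out2), 20)
  w <- attr(out2, "weights")[[1]]
  expect_equal(drop(w), c(0.5, 0.5))
})

test_that("scaled dot-product attention matches direct evaluation", {
  out <- mp_attention(Q = matrix(1), K = matrix(c(1, 2), 2, 1),
                      V = matrix(c(10, 20), 2, 1))
  wts <- exp(c(1, 2)) / sum(exp(c(1, 2)))
  expect_equal(as.numeric(out), sum(wts * c(10, 20)), tolerance = 1e-6)
  expect_equal(as.numeric(out), 17.31, tolerance = 1e-3)
  # softmax rows sum to 1, and the 1/sqrt(d_k) scaling is applied
  set.seed(3)
  Q <- matrix(rnorm(8), 2, 4); K <- matrix(rnorm(12), 3, 4)
  V <- matrix(rnorm(12), 3, 4)
  o1 <- mp_attention(Q, K, V, n_heads = 2)
  for (w in attr(o1, "weights")) expect_equal(rowSums(w), rep(1, 2),
                                              tolerance = 1e-8)
  d_k <- 2
  S <- Q[, 1:2] %*% t(K[, 1:2])
  manual <- macroperm:::softmax_rows(S / sqrt(d_k)) %*% V[, 1:2]
  expect_equal(o1[, 1:2], manual, tolerance = 1e-10)
})
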