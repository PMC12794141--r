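# shared fixtures, built in code

# small labeled record set: alcohols (HBD, permeable) vs alkanes/arenes
toy_records <- function() {
  pos <- c("CCO", "CCCO", "CC(C)O", "CCCCO", "OCCO", "CC(O)CO", "CCC(O)C",
           "OCCCO", "CC(C)(C)O", "CCCCCO")
  neg <- c("CCC", "CCCC", "CC(C)C", "CCCCC", "c1ccccc1", "Cc1ccccc1",
           "CCc1ccccc1", "CC(C)CC", "CCCCCC", "Cc1ccc(C)cc1")
  tibble::tibble(smiles = c(pos, neg), assay = "PAMPA",
                 y = rep(c(1L, 0L), each = 10))
}

tiny_config <- function(...) {
  args <- list(...)
  base <- list(hidden_dim = 8, rounds = 2, d_expert = 8, epochs = 30,
               batch_size = 8, patience = 30, lr = 3e-3)
  base[names(args)] <- args
  do.call(mp_model_config, base)
}

# random identity-mode test graph with scalar-ish features
random_graph <- function(n, d_node = 2, d_edge = 1, p_edge = 0.5) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  ne <- nrow(keep)
  edges <- matrix(0L, 2 * ne, 2)
  if (ne > 0) {
    edges[seq(1, 2 * ne, 2), ] <- keep
    edges[seq(2, 2 * ne, 2), ] <- keep[, 2:1, drop = FALSE]
  }
  ef <- matrix(stats::rnorm(ne * d_edge), ne, d_edge)
  structure(list(
    n_nodes = n,
    node_features = matrix(stats::rnorm(n * d_node), n, d_node),
    edges = edges,
    edge_features = ef[rep(seq_len(ne), each = 2), , drop = FALSE],
    schema_version = "1"), class = "mp_graph")
}

# dictionary-of-edges brute-force identity-mode round (independent oracle)
oracle_identity_round <- function(graph, state) {
  n <- graph$n_nodes
  msgs <- list()
  for (e in seq_len(nrow(graph$edges))) {
    u <- graph$edges[e, 1]; v <- graph$edges[e, 2]
    msgs[[e]] <- c(state$e[e, ], state$x[u, ], state$x[v, ])
  }
  agg <- lapply(seq_len(n), function(v) {
    inc <- which(graph$edges[, 2] == v)
    if (length(inc) == 0) {
      numeric(ncol(state$e) + 2 * ncol(state$x))
    } else {
      Reduce(`+`, msgs[inc])
    }
  })
  list(x = cbind(state$x, do.call(rbind, agg)),
       e = if (length(msgs)) cbind(state$e, do.call(rbind, msgs))
           else state$e,
       messages = if (length(msgs)) do.call(rbind, msgs) else NULL,
       node_messages = do.call(rbind, agg))
}
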