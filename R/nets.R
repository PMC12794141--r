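#' @title Message-passing encoder and attention primitives
#' @description
#' The message-passing encoder follows the printed update rule exactly:
#' per-edge messages m_uv = MLP(e_uv + x_u + x_v concatenated), summed over
#' neighbors into each node, with separate MLP updates of the edge and node
#' states and a mean (or sum) readout after T rounds. A
#' `directed_exclusion` flag offers the canonical directed variant in which
#' the context for the edge update excludes the reverse edge's message. An
#' identity test mode replaces every MLP with identity-on-concatenation so
#' rounds can be traced by hand and checked against a brute-force oracle.
#' @name nets
NULL

#' Message-passing configuration
#'
#' @param hidden_dim hidden width of all message/update MLPs.
#' @param rounds number of message-passing rounds T (>= 1).
#' @param readout `"mean"` or `"sum"` pooling over nodes.
#' @param test_mode_identity replace MLPs by identity-on-concatenation
#'   (feature dims grow each round; for oracle tests only).
#' @param directed_exclusion use the canonical directed edge-update context
#'   (aggregate at the source node minus the reverse edge's message)
#'   instead of the printed per-edge message.
#' @return an `mp_mp_config` object.
#' @export
mp_mp_config <- function(hidden_dim = 300, rounds = 3, readout = c("mean", "sum"),
                         test_mode_identity = FALSE, directed_exclusion = FALSE) {
  readout <- match.arg(readout)
  stopifnot(rounds >= 1, hidden_dim >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim), rounds = as.integer(rounds),
                 readout = readout, test_mode_identity = test_mode_identity,
                 directed_exclusion = directed_exclusion),
            class = "mp_mp_config")
}

# scatter-add rows of M into an N-row matrix by index
agg_rows <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  if (nrow(M) > 0) {
    rs <- rowsum(M, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# --- hand-traceable single round ------------------------------------------

#' One message-passing round
#'
#' In identity test mode the three MLPs are the identity on their
#' concatenated inputs: the message along edge (u,v) is (e_uv, x_u, x_v),
#' node aggregates are sums of incoming messages, the edge state becomes
#' (e_uv, m_uv) and the node state (x_v, m_v). With `params` given, the
#' trained MLP round is applied instead (state dims must match
#' `config$hidden_dim`).
#'
#' @param graph an `mp_graph` (supplies the edge list).
#' @param state list with `x` (|V| x d) and `e` (|E| x d_e) matrices;
#'   defaults to the graph's features.
#' @param config an [mp_mp_config()].
#' @param params trained parameters (internal layout) or NULL for identity
#'   mode.
#' @return list with updated `x`, `e`, per-edge `messages`, and per-node
#'   aggregates `node_messages`.
#' @export
mp_message_passing_round <- function(graph, state = NULL,
                                     config = mp_mp_config(test_mode_identity = TRUE),
                                     params = NULL) {
  state <- state %||% list(x = graph$node_features, e = graph$edge_features)
  src <- graph$edges[, 1]
  dst <- graph$edges[, 2]
  n <- graph$n_nodes
  if (config$test_mode_identity) {
    M <- cbind(state$e, state$x[src, , drop = FALSE], state$x[dst, , drop = FALSE])
    A <- agg_rows(M, dst, n)
    list(x = cbind(state$x, A), e = cbind(state$e, M),
         messages = M, node_messages = A)
  } else {
    if (is.null(params)) abort("`params` required outside identity test mode")
    st <- mp_round_fwd(state$x, state$e, src, dst, rev_index(graph), n, params, config)
    list(x = st$H, e = st$G, messages = st$M, node_messages = st$A)
  }
}

rev_index <- function(graph) {
  ne <- nrow(graph$edges)
  if (ne == 0) return(integer(0))
  as.vector(rbind(seq(2, ne, by = 2), seq(1, ne, by = 2)))
}

#' Pool node states into a graph embedding
#'
#' @param h matrix of node states (|V| x d).
#' @param mode `"mean"` or `"sum"`; both are permutation invariant and
#'   `mean = sum / |V|`.
#' @param graph_id optional integer vector assigning rows to graphs; NULL
#'   treats all rows as one graph.
#' @return embedding matrix (one row per graph).
#' @export
mp_readout <- function(h, mode = c("mean", "sum"), graph_id = NULL) {
  mode <- match.arg(mode)
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  if (nrow(h) == 0) abort("cannot read out an empty graph")
  graph_id <- graph_id %||% rep(1L, nrow(h))
  out <- agg_rows(h, graph_id, max(graph_id))
  if (mode == "mean") {
    counts <- tabulate(graph_id, nbins = max(graph_id))
    out <- out / counts
  }
  out
}

#' Encode a molecular graph with the message-passing network
#'
#' Runs exactly T rounds followed by the configured readout. In identity
#' test mode no parameters are involved and the result is the readout of
#' the concatenation-grown node states; otherwise `params` (from
#' [mp_init_dmpnn()] or a fitted model) are used.
#'
#' @param graph an `mp_graph`.
#' @param params encoder parameters or NULL in identity mode.
#' @param config an [mp_mp_config()].
#' @return numeric embedding vector.
#' @export
mp_dmpnn_encode <- function(graph, params = NULL, config = mp_mp_config()) {
  if (graph$n_nodes == 0) abort("cannot encode an empty graph")
  if (config$test_mode_identity) {
    st <- list(x = graph$node_features, e = graph$edge_features)
    for (t in seq_len(config$rounds)) {
      up <- mp_message_passing_round(graph, st, config)
      st <- list(x = up$x, e = up$e)
    }
    return(drop(mp_readout(st$x, config$readout)))
  }
  if (is.null(params)) abort("`params` required outside identity test mode")
  bg <- build_batch_graph(list(graph))
  drop(dmpnn_fwd(bg, params, config)$hG)
}

#' Initialize message-passing encoder parameters
#'
#' Glorot-uniform initialization, seeded for reproducibility.
#'
#' @param d_node,d_edge input feature dimensions.
#' @param config an [mp_mp_config()].
#' @param seed integer seed.
#' @return named list of parameter matrices.
#' @export
mp_init_dmpnn <- function(d_node, d_edge, config = mp_mp_config(), seed = 1) {
  h <- config$hidden_dim
  with_seed(seed, list(
    W_in_n = glorot(d_node, h), b_in_n = numeric(h),
    W_in_e = glorot(d_edge, h), b_in_e = numeric(h),
    W_msg = glorot(3 * h, h), b_msg = numeric(h),
    W_eup = glorot(2 * h, h), b_eup = numeric(h),
    W_nup = glorot(2 * h, h), b_nup = numeric(h)
  ))
}

# --- batched trainable encoder --------------------------------------------

build_batch_graph <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offsets <- c(0L, cumsum(n_nodes))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  E <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  src <- dst <- integer(0)
  rev <- integer(0)
  e_off <- 0L
  for (i in seq_along(graphs)) {
    ed <- graphs[[i]]$edges
    if (nrow(ed) > 0) {
      src <- c(src, ed[, 1] + offsets[i])
      dst <- c(dst, ed[, 2] + offsets[i])
      rev <- c(rev, rev_index(graphs[[i]]) + e_off)
      e_off <- e_off + nrow(ed)
    }
  }
  list(X = X, E = E, src = src, dst = dst, rev = rev,
       graph_id = rep(seq_along(graphs), n_nodes),
       n_nodes = n_nodes, B = length(graphs), N = sum(n_nodes))
}

mp_round_fwd <- function(H, G, src, dst, rev, n, params, config) {
  Min <- cbind(G, H[src, , drop = FALSE], H[dst, , drop = FALSE])
  M <- relu(lin_fwd(Min, params$W_msg, params$b_msg))
  A <- agg_rows(M, dst, n)
  Gctx <- if (config$directed_exclusion && length(rev) > 0) {
    A[src, , drop = FALSE] - M[rev, , drop = FALSE]
  } else M
  Ein <- cbind(G, Gctx)
  Gnew <- relu(lin_fwd(Ein, params$W_eup, params$b_eup))
  Nin <- cbind(H, A)
  Hnew <- relu(lin_fwd(Nin, params$W_nup, params$b_nup))
  list(H = Hnew, G = Gnew, M = M, A = A, Min = Min, Ein = Ein, Nin = Nin)
}

dmpnn_fwd <- function(bg, params, config) {
  H0 <- relu(lin_fwd(bg$X, params$W_in_n, params$b_in_n))
  G0 <- if (nrow(bg$E) > 0) relu(lin_fwd(bg$E, params$W_in_e, params$b_in_e))
        else matrix(0, 0, config$hidden_dim)
  H <- H0; G <- G0
  rounds <- vector("list", config$rounds)
  for (t in seq_len(config$rounds)) {
    st <- mp_round_fwd(H, G, bg$src, bg$dst, bg$rev, bg$N, params, config)
    rounds[[t]] <- c(st, list(H_in = H, G_in = G))
    H <- st$H; G <- st$G
  }
  hG <- agg_rows(H, bg$graph_id, bg$B)
  if (config$readout == "mean") hG <- hG / bg$n_nodes
  list(hG = hG, cache = list(H0 = H0, G0 = G0, rounds = rounds, H_final = H))
}

# --- multi-head attention --------------------------------------------------

#' Scaled dot-product multi-head attention
#'
#' Per head i, Attention(Q_i, K_i, V_i) = softmax(Q_i K_i' / sqrt(d_k)) V_i;
#' head outputs are concatenated and (optionally) projected by `W_o`. Every
#' softmax row sums to one.
#'
#' @param Q,K,V matrices whose columns are split evenly across `n_heads`
#'   (d_k = ncol / n_heads per head); Q may be a vector (one query).
#' @param n_heads number of attention heads.
#' @param W_o optional output projection applied to the concatenated heads.
#' @return matrix of attended outputs (rows align with Q's rows) with the
#'   per-head attention weights in attribute `"weights"`.
#' @export
mp_attention <- function(Q, K, V, n_heads = 1, W_o = NULL) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  if (is.null(dim(K))) K <- matrix(K, ncol = ncol(Q))
  if (is.null(dim(V))) V <- matrix(V, nrow = nrow(K))
  if (ncol(Q) %% n_heads != 0) abort("ncol(Q) must be divisible by n_heads")
  if (nrow(K) != nrow(V)) abort("K and V must have the same number of rows")
  d_k <- ncol(Q) / n_heads
  d_v <- ncol(V) / n_heads
  outs <- vector("list", n_heads)
  wts <- vector("list", n_heads)
  for (i in seq_len(n_heads)) {
    qc <- ((i - 1) * d_k + 1):(i * d_k)
    vc <- ((i - 1) * d_v + 1):(i * d_v)
    S <- Q[, qc, drop = FALSE] %*% t(K[, qc, drop = FALSE]) / sqrt(d_k)
    P <- softmax_rows(S)
    outs[[i]] <- P %*% V[, vc, drop = FALSE]
    wts[[i]] <- P
  }
  out <- do.call(cbind, outs)
  if (!is.null(W_o)) out <- out %*% W_o
  attr(out, "weights") <- wts
  out
}

init_attention <- function(h, n_heads, d_k) {
  list(W_q = glorot(h, n_heads * d_k), W_k = glorot(h, n_heads * d_k),
       W_v = glorot(h, n_heads * d_k), W_ao = glorot(n_heads * d_k, h))
}

# self-attention over node states within each graph (used by the regressor)
attention_fwd <- function(H, graph_id, params, n_heads) {
  d_k <- ncol(params$W_q) / n_heads
  Q <- H %*% params$W_q; K <- H %*% params$W_k; V <- H %*% params$W_v
  Hout <- matrix(0, nrow(H), ncol(params$W_ao))
  caches <- list()
  for (b in unique(graph_id)) {
    rows <- which(graph_id == b)
    heads <- vector("list", n_heads)
    Ps <- vector("list", n_heads)
    for (i in seq_len(n_heads)) {
      cc <- ((i - 1) * d_k + 1):(i * d_k)
      S <- Q[rows, cc, drop = FALSE] %*% t(K[rows, cc, drop = FALSE]) / sqrt(d_k)
      P <- softmax_rows(S)
      heads[[i]] <- P %*% V[rows, cc, drop = FALSE]
      Ps[[i]] <- P
    }
    O <- do.call(cbind, heads)
    Hout[rows, ] <- O %*% params$W_ao
    caches[[as.character(b)]] <- list(rows = rows, P = Ps, O = O)
  }
  list(H = Hout, Q = Q, K = K, V = V, caches = caches, n_heads = n_heads, d_k = d_k)
}

attention_bwd <- function(H, graph_id, params, cache, dHout) {
  n_heads <- cache$n_heads; d_k <- cache$d_k
  dQ <- matrix(0, nrow(H), ncol(params$W_q))
  dK <- dQ; dV <- dQ
  dW_ao <- params$W_ao * 0
  for (cb in cache$caches) {
    rows <- cb$rows
    dO <- dHout[rows, , drop = FALSE] %*% t(params$W_ao)
    dW_ao <- dW_ao + crossprod(cb$O, dHout[rows, , drop = FALSE])
    for (i in seq_len(n_heads)) {
      cc <- ((i - 1) * d_k + 1):(i * d_k)
      dOi <- dO[, cc, drop = FALSE]
      P <- cb$P[[i]]
      dV[rows, cc] <- dV[rows, cc] + crossprod(P, dOi)
      dP <- dOi %*% t(cache$V[rows, cc, drop = FALSE])
      dS <- softmax_rows_bwd(P, dP) / sqrt(d_k)
      dQ[rows, cc] <- dQ[rows, cc] + dS %*% cache$K[rows, cc, drop = FALSE]
      dK[rows, cc] <- dK[rows, cc] + crossprod(dS, cache$Q[rows, cc, drop = FALSE])
    }
  }
  list(dH = dQ %*% t(params$W_q) + dK %*% t(params$W_k) + dV %*% t(params$W_v),
       grads = list(W_q = crossprod(H, dQ), W_k = crossprod(H, dK),
                    W_v = crossprod(H, dV), W_ao = dW_ao))
}
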