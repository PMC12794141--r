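#' @title Mixture-of-experts permeability model
#' @description
#' The classifier fuses four representation experts — the message-passing
#' graph embedding, physicochemical descriptors, ECFP and MACCS
#' fingerprints — through a softmax gating network; the gated combination
#' feeds a linear head producing one permeability logit. The regression
#' variant adds multi-head self-attention over node states before readout
#' and appends assay/physiological-condition encodings as graph-level
#' global features. Training is Adam on binary cross-entropy (squared
#' error for regression) with early stopping on validation loss.
#' @name macro_pp
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Softmax gate weights
#'
#' Turns per-expert correlation scores (logits) into a probability simplex:
#' weights are strictly positive and each row sums to one.
#'
#' @param logits numeric vector (one sample) or matrix (samples x experts).
#' @return weights with the same shape as `logits`.
#' @export
mp_gate_weights <- function(logits) {
  if (is.null(dim(logits))) {
    drop(softmax_rows(matrix(logits, nrow = 1)))
  } else {
    softmax_rows(logits)
  }
}

#' Combine expert outputs with gate weights
#'
#' o = sum_i g_i e_i; linear in the expert outputs.
#'
#' @param experts list of expert outputs (equal-shape vectors or matrices).
#' @param gate numeric vector of length `length(experts)`, or a matrix with
#'   one row per sample and one column per expert.
#' @return the gated combination.
#' @export
mp_moe_combine <- function(experts, gate) {
  n <- length(experts)
  if (is.null(dim(gate))) {
    if (length(gate) != n) abort("gate length must equal the number of experts")
    out <- experts[[1]] * gate[1]
    if (n > 1) for (i in 2:n) out <- out + experts[[i]] * gate[i]
  } else {
    if (ncol(gate) != n) abort("gate must have one column per expert")
    out <- experts[[1]] * gate[, 1]
    if (n > 1) for (i in 2:n) out <- out + experts[[i]] * gate[, i]
  }
  out
}

#' Model configuration
#'
#' @param hidden_dim,rounds,readout,directed_exclusion message-passing
#'   encoder settings (see [mp_mp_config()]).
#' @param d_expert output width shared by all experts.
#' @param experts representations to fuse (subset of graph/desc/ecfp/maccs).
#' @param shared_input if TRUE every expert sees the full concatenated
#'   input (the literal reading of the mixture equations) instead of its
#'   own representation.
#' @param lr,batch_size,epochs,patience Adam learning rate, minibatch size,
#'   epoch cap, and early-stopping patience on validation loss.
#' @param weight_decay L2 penalty coefficient on weight matrices (biases
#'   exempt); discourages redundant-channel reliance, sharpening the
#'   masking-based importance analysis.
#' @param n_heads attention heads for the regression variant.
#' @return an `mp_model_config` object.
#' @export
mp_model_config <- function(hidden_dim = 300, rounds = 3, readout = "mean",
                            directed_exclusion = FALSE, d_expert = 32,
                            experts = c("graph", "desc", "ecfp", "maccs"),
                            shared_input = FALSE, lr = 1e-3, batch_size = 32,
                            epochs = 100, patience = 10, n_heads = 2,
                            weight_decay = 0) {
  experts <- match.arg(experts, several.ok = TRUE)
  structure(list(
    mp = mp_mp_config(hidden_dim, rounds, readout,
                      directed_exclusion = directed_exclusion),
    d_expert = as.integer(d_expert), experts = experts,
    shared_input = shared_input, lr = lr, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    n_heads = as.integer(n_heads), weight_decay = weight_decay),
    class = "mp_model_config")
}

#' @export
print.mp_model_config <- function(x, ...) {
  cat(sprintf("<mp_model_config> h=%d T=%d experts=%s d_expert=%d\n",
              x$mp$hidden_dim, x$mp$rounds,
              paste(x$experts, collapse = "+"), x$d_expert))
  invisible(x)
}

# --- global (graph-level) features ----------------------------------------

PH_BREAKS <- c(-Inf, 6.5, 7.0, 7.5, Inf)
TEMP_BREAKS <- c(-Inf, 30, 38, Inf)

#' Encode assay identity and physiological conditions as global features
#'
#' Assay identity becomes a one-hot block over the known assays. Conditions
#' are encoded either as standardized raw values (`"GLOBAL"`) or binned
#' one-hots (`"ONEHOT"`); missing pH/temperature are imputed to 7.4 / 37 C
#' with a missingness indicator bit.
#'
#' @param data record tibble (columns `assay`, optionally `ph`,
#'   `temperature`).
#' @param assay_onehot include the assay one-hot block.
#' @param condition_mode `"NONE"`, `"GLOBAL"`, or `"ONEHOT"`.
#' @param stats standardization statistics from a previous (training) call,
#'   or NULL to fit them.
#' @return list with `x` (matrix, possibly 0 columns) and `stats`.
#' @export
mp_global_features <- function(data, assay_onehot = FALSE,
                               condition_mode = c("NONE", "GLOBAL", "ONEHOT"),
                               stats = NULL) {
  condition_mode <- match.arg(condition_mode)
  data <- as_tibble(data)
  n <- nrow(data)
  blocks <- list()
  if (assay_onehot) {
    a <- factor(data$assay, levels = ASSAY_LEVELS)
    m <- matrix(0, n, length(ASSAY_LEVELS))
    m[cbind(seq_len(n), as.integer(a))] <- 1
    blocks$assay <- m
  }
  if (condition_mode != "NONE") {
    ph <- if ("ph" %in% names(data)) data$ph else rep(NA_real_, n)
    tmp <- if ("temperature" %in% names(data)) data$temperature else rep(NA_real_, n)
    miss_ph <- as.numeric(is.na(ph)); miss_tmp <- as.numeric(is.na(tmp))
    ph[is.na(ph)] <- 7.4; tmp[is.na(tmp)] <- 37
    if (condition_mode == "GLOBAL") {
      raw <- cbind(ph = ph, temperature = tmp)
      std <- mp_standardize(raw, stats)
      stats <- std[c("center", "scale")]
      blocks$cond <- cbind(std$x, miss_ph, miss_tmp)
    } else {
      phb <- as.integer(cut(ph, PH_BREAKS)); tmb <- as.integer(cut(tmp, TEMP_BREAKS))
      mph <- matrix(0, n, length(PH_BREAKS) - 1)
      mph[cbind(seq_len(n), phb)] <- 1
      mtm <- matrix(0, n, length(TEMP_BREAKS) - 1)
      mtm[cbind(seq_len(n), tmb)] <- 1
      blocks$cond <- cbind(mph, mtm, miss_ph, miss_tmp)
    }
  }
  x <- if (length(blocks)) do.call(cbind, blocks) else matrix(0, n, 0)
  dimnames(x) <- NULL
  list(x = x, stats = stats)
}

# --- parameter initialization ---------------------------------------------

init_model_params <- function(d_node, d_edge, d_desc, d_ecfp, d_maccs,
                              n_global, config, seed, attention = FALSE) {
  h <- config$mp$hidden_dim
  rep_dims <- c(graph = h + n_global, desc = d_desc, ecfp = d_ecfp, maccs = d_maccs)
  d_cat <- sum(rep_dims)
  with_seed(seed, {
    p <- mp_init_dmpnn(d_node, d_edge, config$mp, seed = derive_seed(seed, "enc"))
    for (nm in config$experts) {
      d_in <- if (config$shared_input) d_cat else rep_dims[[nm]]
      p[[paste0("W_ex_", nm)]] <- glorot(d_in, config$d_expert)
      p[[paste0("b_ex_", nm)]] <- numeric(config$d_expert)
    }
    p$W_gate <- glorot(d_cat, length(config$experts))
    p$b_gate <- numeric(length(config$experts))
    p$W_head <- glorot(config$d_expert, 1L)
    p$b_head <- numeric(1L)
    if (attention) {
      d_k <- max(2L, ceiling(h / config$n_heads))
      p <- c(p, init_attention(h, config$n_heads, d_k))
    }
    p
  })
}

# --- forward / backward ----------------------------------------------------

# column layout of xcat: graph block (hG | globals), desc, ecfp, maccs
xcat_offsets <- function(h, n_global, d_desc, d_ecfp, d_maccs) {
  widths <- c(graph = h + n_global, desc = d_desc, ecfp = d_ecfp, maccs = d_maccs)
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  lapply(stats::setNames(names(widths), names(widths)),
         function(nm) seq.int(starts[[nm]], ends[[nm]]))
}

model_fwd <- function(params, bg, desc, ecfp, maccs, globals, config,
                      attention = FALSE) {
  enc <- dmpnn_fwd(bg, params, config$mp)
  Hr <- enc$cache$H_final
  att <- NULL
  if (attention) {
    att <- attention_fwd(Hr, bg$graph_id, params, config$n_heads)
    Hr <- att$H
  }
  hG <- agg_rows(Hr, bg$graph_id, bg$B)
  if (config$mp$readout == "mean") hG <- hG / bg$n_nodes
  reps <- list(graph = cbind(hG, globals), desc = desc, ecfp = ecfp, maccs = maccs)
  xcat <- do.call(cbind, unname(reps))
  inputs <- if (config$shared_input) {
    stats::setNames(rep(list(xcat), length(config$experts)), config$experts)
  } else reps[config$experts]
  E <- stats::setNames(lapply(config$experts, function(nm) {
    relu(lin_fwd(inputs[[nm]], params[[paste0("W_ex_", nm)]],
                 params[[paste0("b_ex_", nm)]]))
  }), config$experts)
  L <- lin_fwd(xcat, params$W_gate, params$b_gate)
  g <- softmax_rows(L)
  o <- mp_moe_combine(E, g)
  z <- drop(lin_fwd(o, params$W_head, params$b_head))
  list(z = z, gate = g, experts = E, o = o, hG = hG, enc = enc, att = att,
       xcat = xcat, inputs = inputs, Hr_dim = ncol(Hr))
}

model_bwd <- function(params, bg, fw, dz, desc, ecfp, maccs, globals, config,
                      attention = FALSE) {
  h <- ncol(fw$hG)
  offs <- xcat_offsets(h, ncol(globals), ncol(desc), ncol(ecfp), ncol(maccs))
  dzm <- matrix(dz, ncol = 1)
  lb <- lin_bwd(fw$o, params$W_head, dzm)
  grads <- list(W_head = lb$dW, b_head = lb$db)
  do <- lb$dx
  dg <- matrix(0, bg$B, length(config$experts))
  dxcat <- fw$xcat * 0
  for (i in seq_along(config$experts)) {
    nm <- config$experts[i]
    dEi <- do * fw$gate[, i]
    dg[, i] <- rowSums(do * fw$experts[[i]])
    dpre <- relu_bwd(fw$experts[[i]], dEi)
    le <- lin_bwd(fw$inputs[[nm]], params[[paste0("W_ex_", nm)]], dpre)
    grads <- acc_grads(grads,
      stats::setNames(list(le$dW, le$db), paste0(c("W_ex_", "b_ex_"), nm)))
    if (config$shared_input) {
      dxcat <- dxcat + le$dx
    } else {
      dxcat[, offs[[nm]]] <- dxcat[, offs[[nm]]] + le$dx
    }
  }
  dL <- softmax_rows_bwd(fw$gate, dg)
  lg <- lin_bwd(fw$xcat, params$W_gate, dL)
  grads <- acc_grads(grads, list(W_gate = lg$dW, b_gate = lg$db))
  dxcat <- dxcat + lg$dx

  dhG <- dxcat[, offs$graph[seq_len(h)], drop = FALSE]
  if (config$mp$readout == "mean") dhG <- dhG / bg$n_nodes
  dHr <- dhG[bg$graph_id, , drop = FALSE]
  if (attention) {
    ab <- attention_bwd(fw$enc$cache$H_final, bg$graph_id, params, fw$att, dHr)
    grads <- acc_grads(grads, ab$grads)
    dHr <- ab$dH
  }
  # dmpnn_bwd expects the gradient on hG pre-expansion; feed node-level
  # gradient by bypassing its own readout expansion
  genc <- dmpnn_bwd_nodes(bg, params, config$mp, fw$enc$cache, dHr)
  acc_grads(grads, genc)
}

# like dmpnn_bwd but taking a per-node gradient on the final node states
dmpnn_bwd_nodes <- function(bg, params, config, cache, dH) {
  h <- config$hidden_dim
  dG <- matrix(0, nrow(bg$E), h)
  grads <- list()
  for (t in rev(seq_len(config$rounds))) {
    st <- cache$rounds[[t]]
    dHpre <- relu_bwd(st$H, dH)
    lb <- lin_bwd(st$Nin, params$W_nup, dHpre)
    grads <- acc_grads(grads, list(W_nup = lb$dW, b_nup = lb$db))
    dH_in <- lb$dx[, 1:h, drop = FALSE]
    dA <- lb$dx[, (h + 1):(2 * h), drop = FALSE]

    dGpre <- relu_bwd(st$G, dG)
    le <- lin_bwd(st$Ein, params$W_eup, dGpre)
    grads <- acc_grads(grads, list(W_eup = le$dW, b_eup = le$db))
    dG_in <- le$dx[, 1:h, drop = FALSE]
    dGctx <- le$dx[, (h + 1):(2 * h), drop = FALSE]

    dM <- matrix(0, nrow(bg$E), h)
    if (config$directed_exclusion && length(bg$rev) > 0) {
      dA <- dA + agg_rows(dGctx, bg$src, bg$N)
      dM <- dM - dGctx[bg$rev, , drop = FALSE]
    } else {
      dM <- dM + dGctx
    }
    if (length(bg$dst) > 0) dM <- dM + dA[bg$dst, , drop = FALSE]

    dMpre <- relu_bwd(st$M, dM)
    lm <- lin_bwd(st$Min, params$W_msg, dMpre)
    grads <- acc_grads(grads, list(W_msg = lm$dW, b_msg = lm$db))
    dG <- dG_in + lm$dx[, 1:h, drop = FALSE]
    dH <- dH_in +
      agg_rows(lm$dx[, (h + 1):(2 * h), drop = FALSE], bg$src, bg$N) +
      agg_rows(lm$dx[, (2 * h + 1):(3 * h), drop = FALSE], bg$dst, bg$N)
  }
  dH0pre <- relu_bwd(cache$H0, dH)
  ln <- lin_bwd(bg$X, params$W_in_n, dH0pre)
  grads <- acc_grads(grads, list(W_in_n = ln$dW, b_in_n = ln$db))
  if (nrow(bg$E) > 0) {
    dG0pre <- relu_bwd(cache$G0, dG)
    lg <- lin_bwd(bg$E, params$W_in_e, dG0pre)
    grads <- acc_grads(grads, list(W_in_e = lg$dW, b_in_e = lg$db))
  } else {
    grads <- acc_grads(grads, list(W_in_e = params$W_in_e * 0,
                                   b_in_e = params$b_in_e * 0))
  }
  grads
}

# --- training core ---------------------------------------------------------

# assemble per-index model inputs from an mp_features object
slice_inputs <- function(feats, globals, idx) {
  list(bg = build_batch_graph(feats$graphs[idx]),
       desc = feats$desc_std[idx, , drop = FALSE],
       ecfp = feats$ecfp[idx, , drop = FALSE],
       maccs = feats$maccs[idx, , drop = FALSE],
       globals = globals[idx, , drop = FALSE])
}

fwd_on <- function(params, si, config, attention) {
  model_fwd(params, si$bg, si$desc, si$ecfp, si$maccs, si$globals, config,
            attention = attention)
}

# task: "classify" (y in {0,1}), "regress" (numeric target). For
# distillation, `soft` carries teacher probabilities at temperature T and
# the distillation settings.
fit_core <- function(feats, y, globals, config, seed, task = "classify",
                     val_idx, soft = NULL, trace = FALSE) {
  n <- length(feats$graphs)
  stopifnot(length(y) == n, nrow(globals) == n)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(val_idx) == 0) abort("validation set must be non-empty")
  if (task == "classify" && length(unique(y[train_idx])) < 2) {
    abort("training set contains a single class")
  }
  if (task == "regress" && stats::sd(y[train_idx]) == 0) {
    warn("all training targets are equal; fit is degenerate")
  }
  attention <- task == "regress"
  params <- init_model_params(
    ncol(feats$graphs[[1]]$node_features), ncol(feats$graphs[[1]]$edge_features),
    ncol(feats$desc_std), ncol(feats$ecfp), ncol(feats$maccs), ncol(globals),
    config, seed = derive_seed(seed, "init"), attention = attention)
  opt <- adam_init(params)
  val_si <- slice_inputs(feats, globals, val_idx)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- list()
  bad_epochs <- 0L

  loss_and_grad_scale <- function(z, yb, softb) {
    if (task == "regress") {
      list(loss = mean((z - yb)^2), dz = 2 * (z - yb) / length(z))
    } else {
      loss <- bce_with_logits(z, yb)
      dz <- (sigmoid(z) - yb) / length(z)
      if (!is.null(softb)) {
        Tt <- softb$temperature
        p_s <- sigmoid(z / Tt)
        if (softb$divergence == "BINARY_KL") {
          sc <- if (softb$t_squared_scaling) Tt else 1 / Tt
          loss <- loss + softb$lambda * mean(binary_kl(softb$p_teacher, p_s)) *
            (if (softb$t_squared_scaling) Tt^2 else 1)
          dz <- dz + softb$lambda * sc * (p_s - softb$p_teacher) / length(z)
        } else {  # MSE_LOGITS
          loss <- loss + softb$lambda * mean(0.5 * (z - softb$z_teacher)^2)
          dz <- dz + softb$lambda * (z - softb$z_teacher) / length(z)
        }
      }
      list(loss = loss, dz = dz)
    }
  }

  eval_loss <- function(params, si, yb, softb) {
    fw <- fwd_on(params, si, config, attention)
    loss_and_grad_scale(fw$z, yb, softb)$loss
  }

  soft_slice <- function(idx) {
    if (is.null(soft)) return(NULL)
    c(soft[c("temperature", "lambda", "divergence", "t_squared_scaling")],
      list(p_teacher = soft$p_teacher[idx], z_teacher = soft$z_teacher[idx]))
  }

  with_seed(derive_seed(seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bidx in batches) {
        si <- slice_inputs(feats, globals, bidx)
        fw <- fwd_on(params, si, config, attention)
        lg <- loss_and_grad_scale(fw$z, y[bidx], soft_slice(bidx))
        grads <- model_bwd(params, si$bg, fw, lg$dz, si$desc, si$ecfp,
                           si$maccs, si$globals, config, attention = attention)
        wd <- config$weight_decay %||% 0
        if (wd > 0) {
          for (nm in names(grads)) {
            if (startsWith(nm, "W")) grads[[nm]] <- grads[[nm]] + wd * params[[nm]]
          }
        }
        upd <- adam_step(params, grads, opt, lr = config$lr)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + lg$loss * length(bidx)
      }
      val_loss <- eval_loss(params, val_si, y[val_idx], soft_slice(val_idx))
      log[[epoch]] <- tibble(epoch = epoch,
                             train_loss = ep_loss / length(train_idx),
                             val_loss = val_loss)
      if (trace) message(sprintf("epoch %d train %.4f val %.4f", epoch,
                                 ep_loss / length(train_idx), val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) break
      }
    }
  })
  list(params = best$params, best_epoch = best$epoch, val_loss = best$loss,
       log = bind_rows(log), attention = attention)
}

binary_kl <- function(p_t, p_s, eps = 1e-7) {
  p_t <- pmin(pmax(p_t, eps), 1 - eps)
  p_s <- pmin(pmax(p_s, eps), 1 - eps)
  p_t * log(p_t / p_s) + (1 - p_t) * log((1 - p_t) / (1 - p_s))
}

# --- user-facing fit / predict --------------------------------------------

prepare_features <- function(data, schema, feats = NULL, desc_stats = NULL) {
  feats <- feats %||% mp_featurize(data, schema)
  std <- mp_standardize(feats$desc, desc_stats)
  feats$desc_std <- std$x
  feats$desc_stats <- std[c("center", "scale")]
  feats
}

new_macro_pp <- function(fit, config, schema, task, desc_stats, globals_spec,
                         cond_stats, seed, n_train) {
  structure(list(params = fit$params, config = config, schema = schema,
                 task = task, desc_stats = desc_stats,
                 globals_spec = globals_spec, cond_stats = cond_stats,
                 seed = seed, log = fit$log, best_epoch = fit$best_epoch,
                 val_loss = fit$val_loss, n_train = n_train,
                 attention = fit$attention),
            class = "macro_pp")
}

#' Fit the mixture-of-experts permeability classifier
#'
#' Trains on binary swing labels (`y` of 1 = permeable, 0 = impermeable;
#' records excluded by the swing range must be removed first) by Adam on
#' binary cross-entropy, early-stopping on validation loss.
#'
#' @param train,val record tibbles with `smiles` and `y` columns (and
#'   `assay` when `assay_onehot`).
#' @param config an [mp_model_config()].
#' @param seed integer seed (initialization and batch order).
#' @param schema feature schema.
#' @param assay_onehot append the assay one-hot as a graph-level feature
#'   (used by the multi-assay teacher).
#' @param features,val_features optional precomputed [mp_featurize()]
#'   bundles (to reuse across fits).
#' @param trace print per-epoch losses.
#' @return a fitted `macro_pp` object.
#' @export
mp_fit_classifier <- function(train, val, config = mp_model_config(), seed = 1,
                              schema = mp_feature_schema(), assay_onehot = FALSE,
                              features = NULL, val_features = NULL,
                              trace = FALSE) {
  train <- as_tibble(train); val <- as_tibble(val)
  if (nrow(val) == 0) abort("validation set must be non-empty")
  if (anyNA(train$y) || anyNA(val$y)) {
    abort("EXCLUDED (NA) labels must be removed before fitting")
  }
  data <- bind_rows(train, val)
  feats <- combine_features(data, schema, features, val_features, nrow(train))
  gl <- mp_global_features(data, assay_onehot = assay_onehot)
  fit <- fit_core(feats, data$y, gl$x, config, seed, task = "classify",
                  val_idx = nrow(train) + seq_len(nrow(val)), trace = trace)
  new_macro_pp(fit, config, schema, "classify", feats$desc_stats,
               list(assay_onehot = assay_onehot, condition_mode = "NONE"),
               NULL, seed, nrow(train))
}

combine_features <- function(data, schema, features, val_features, n_train) {
  feats <- features %||% mp_featurize(data, schema)
  if (!is.null(features) && !is.null(val_features)) {
    feats <- list(graphs = c(features$graphs, val_features$graphs),
                  desc = rbind(features$desc, val_features$desc),
                  ecfp = rbind(features$ecfp, val_features$ecfp),
                  maccs = rbind(features$maccs, val_features$maccs),
                  smiles = c(features$smiles, val_features$smiles),
                  schema = features$schema)
    class(feats) <- "mp_features"
  } else if (!is.null(features)) {
    feats <- features
  }
  stopifnot(length(feats$graphs) == nrow(data))
  std <- mp_standardize(feats$desc[seq_len(n_train), , drop = FALSE])
  all_std <- mp_standardize(feats$desc, std[c("center", "scale")])
  feats$desc_std <- all_std$x
  feats$desc_stats <- std[c("center", "scale")]
  feats
}

#' Fit the condition-aware permeability regressor
#'
#' Predicts continuous -log10(Papp) with multi-head self-attention over
#' node states before readout and physiological conditions appended as
#' global features. Trained with squared-error loss.
#'
#' @param train,val record tibbles with `smiles` and `neg_log_papp` (plus
#'   `ph`/`temperature` when conditions are encoded).
#' @param encoding `"GLOBAL"` (standardized raw values), `"ONEHOT"`
#'   (binned), or `"NONE"`.
#' @inheritParams mp_fit_classifier
#' @return a fitted `macro_pp` object with `task = "regress"`.
#' @export
mp_fit_regressor <- function(train, val, encoding = c("GLOBAL", "ONEHOT", "NONE"),
                             config = mp_model_config(), seed = 1,
                             schema = mp_feature_schema(), assay_onehot = FALSE,
                             features = NULL, val_features = NULL,
                             trace = FALSE) {
  encoding <- match.arg(encoding)
  train <- as_tibble(train); val <- as_tibble(val)
  if (nrow(val) == 0) abort("validation set must be non-empty")
  assert_finite(c(train$neg_log_papp, val$neg_log_papp), "neg_log_papp")
  data <- bind_rows(train, val)
  feats <- combine_features(data, schema, features, val_features, nrow(train))
  gl_train <- mp_global_features(train, assay_onehot, encoding)
  gl <- mp_global_features(data, assay_onehot, encoding, stats = gl_train$stats)
  fit <- fit_core(feats, data$neg_log_papp, gl$x, config, seed,
                  task = "regress", val_idx = nrow(train) + seq_len(nrow(val)),
                  trace = trace)
  new_macro_pp(fit, config, schema, "regress", feats$desc_stats,
               list(assay_onehot = assay_onehot, condition_mode = encoding),
               gl_train$stats, seed, nrow(train))
}

#' Predict with a fitted permeability model
#'
#' @param object a fitted `macro_pp`.
#' @param newdata record tibble with `smiles` (+ `assay`/conditions as the
#'   model requires).
#' @param features optional precomputed [mp_featurize()] bundle for
#'   `newdata`.
#' @param ... unused.
#' @return tibble with `logit` and, for classifiers, `prob` columns.
#' @export
predict.macro_pp <- function(object, newdata, features = NULL, ...) {
  newdata <- as_tibble(newdata)
  feats <- features %||% mp_featurize(newdata, object$schema)
  if (!identical(feats$schema$version, object$schema$version)) {
    abort(sprintf("feature schema mismatch: model v%s vs data v%s",
                  object$schema$version, feats$schema$version))
  }
  std <- mp_standardize(feats$desc, object$desc_stats)
  feats$desc_std <- std$x
  gl <- mp_global_features(newdata, object$globals_spec$assay_onehot,
                           object$globals_spec$condition_mode,
                           stats = object$cond_stats)
  si <- slice_inputs(feats, gl$x, seq_len(nrow(newdata)))
  fw <- fwd_on(object$params, si, object$config, object$attention)
  out <- tibble(logit = as.numeric(fw$z))
  if (object$task == "classify") out$prob <- sigmoid(out$logit)
  if (object$task == "regress") out$prediction <- out$logit
  out
}

#' @export
print.macro_pp <- function(x, ...) {
  cat(sprintf("<macro_pp %s> %s experts, h=%d, T=%d; best epoch %d, val loss %.4f\n",
              x$task, paste(x$config$experts, collapse = "+"),
              x$config$mp$hidden_dim, x$config$mp$rounds, x$best_epoch,
              x$val_loss))
  invisible(x)
}

#' @describeIn mp_fit_classifier per-epoch training/validation losses.
#' @param x a fitted `macro_pp`.
#' @method tidy macro_pp
#' @export
tidy.macro_pp <- function(x, ...) x$log

#' @describeIn mp_fit_classifier one-row fit summary.
#' @method glance macro_pp
#' @export
glance.macro_pp <- function(x, ...) {
  tibble(task = x$task, n_train = x$n_train,
         epochs_run = nrow(x$log), best_epoch = x$best_epoch,
         val_loss = x$val_loss,
         n_parameters = sum(vapply(x$params, length, integer(1))))
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a plain R serialization of the parameters, feature
#' schema, standardization statistics, configuration and training log;
#' reloading reproduces predictions bit-identically on the same platform.
#'
#' @param object a fitted `macro_pp`.
#' @param path file path (.rds).
#' @return `path` (save) / the restored `macro_pp` (load).
#' @export
mp_save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "macro_pp"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname mp_save_checkpoint
#' @export
mp_load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "macro_pp")) abort("not a macro_pp checkpoint")
  obj
}
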