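test_that("gate weights form a probability simplex", {
  expect_equal(mp_gate_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(mp_gate_weights(c(1000, 0, 0)), c(1, 0, 0), tolerance = 1e-12)
  g <- mp_gate_weights(c(1, 2))
  expect_equal(g, c(exp(1), exp(2)) / (exp(1) + exp(2)))
  expect_equal(g, c(0.2689, 0.7311), tolerance = 1e-4)
  set.seed(2)
  gm <- mp_gate_weights(matrix(rnorm(40, sd = 5), 10, 4))
  expect_equal(rowSums(gm), rep(1, 10))
  expect_true(all(gm > 0))
})

test_that("expert combination is the gate-weighted sum and is linear", {
  expect_equal(mp_moe_combine(list(c(3, 4)), 1), c(3, 4))
  expect_equal(mp_moe_combine(list(c(2, 0), c(0, 2)), c(0.5, 0.5)), c(1, 1))
  set.seed(4)
  E <- lapply(1:3, function(i) matrix(rnorm(10), 5, 2))
  g <- mp_gate_weights(matrix(rnorm(15), 5, 3))
  o <- mp_moe_combine(E, g)
  brute <- matrix(0, 5, 2)
  for (b in 1:5) for (i in 1:3) brute[b, ] <- brute[b, ] + g[b, i] * E[[i]][b, ]
  expect_equal(o, brute, tolerance = 1e-10)
  a <- 2.5
  expect_equal(mp_moe_combine(lapply(E, function(e) a * e), g), a * o,
               tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences end to end", {
  df <- toy_records()[c(1:3, 11:13), ]
  feats <- macroperm:::prepare_features(df, mp_feature_schema())
  cfg <- mp_model_config(hidden_dim = 6, rounds = 2, d_expert = 5,
                         n_heads = 2)
  gl <- mp_global_features(df, assay_onehot = TRUE)
  y <- df$y
  params <- macroperm:::init_model_params(
    ncol(feats$graphs[[1]]$node_features),
    ncol(feats$graphs[[1]]$edge_features),
    ncol(feats$desc_std), ncol(feats$ecfp), ncol(feats$maccs), ncol(gl$x),
    cfg, seed = 7, attention = FALSE)
  si <- macroperm:::slice_inputs(feats, gl$x, 1:3)
  lossfn <- function(p) {
    fw <- macroperm:::model_fwd(p, si$bg, si$desc, si$ecfp, si$maccs,
                                si$globals, cfg)
    macroperm:::bce_with_logits(fw$z, y[1:3])
  }
  fw <- macroperm:::model_fwd(params, si$bg, si$desc, si$ecfp, si$maccs,
                              si$globals, cfg)
  dz <- (macroperm:::sigmoid(fw$z) - y[1:3]) / 3
  gr <- macroperm:::model_bwd(params, si$bg, fw, dz, si$desc, si$ecfp,
                              si$maccs, si$globals, cfg)
  set.seed(9)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (j in idx) {
      eps <- 1e-5
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      denom <- max(abs(num) + abs(gr[[nm]][j]), 1e-4)
      expect_lt(abs(num - gr[[nm]][j]) / denom, 1e-4)
    }
  }
})

test_that("a linearly separable toy set is fit to near-zero loss", {
  df <- toy_records()
  tr <- df[c(1:8, 11:18), ]
  va <- df[c(9:10, 19:20), ]
  fit <- mp_fit_classifier(tr, va, tiny_config(epochs = 60), seed = 5)
  expect_lt(min(fit$log$train_loss), 0.05)
  p <- predict(fit, va)
  expect_true(all((p$prob > 0.5) == (va$y == 1)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$task, "classify")
})

test_that("fits are seed-deterministic and checkpoints reload bit-identically", {
  df <- toy_records()[c(1:5, 11:15), ]
  tr <- df[c(1:4, 6:9), ]; va <- df[c(5, 10), ]
  cfg <- tiny_config(epochs = 6)
  f1 <- mp_fit_classifier(tr, va, cfg, seed = 8)
  f2 <- mp_fit_classifier(tr, va, cfg, seed = 8)
  expect_identical(f1$params, f2$params)
  f3 <- mp_fit_classifier(tr, va, cfg, seed = 9)
  expect_false(identical(f3$params, f1$params))
  ck <- withr::local_tempfile(fileext = ".rds")
  mp_save_checkpoint(f1, ck)
  re <- mp_load_checkpoint(ck)
  expect_identical(predict(re, va)$logit, predict(f1, va)$logit)
  # zeroed head: logit equals the bias for every input
  fz <- f1
  fz$params$W_head <- fz$params$W_head * 0
  fz$params$b_head <- 0.37
  expect_equal(predict(fz, df)$logit, rep(0.37, nrow(df)))
})

test_that("degenerate training inputs are rejected", {
  df <- toy_records()
  expect_error(mp_fit_classifier(df[1:5, ], df[0, ], tiny_config()),
               "non-empty")
  expect_error(mp_fit_classifier(df[1:5, ], df[6, ], tiny_config()),
               "single class")
  bad <- df[c(1, 11), ]
  bad$y[1] <- NA
  expect_error(mp_fit_classifier(bad, df[2, ], tiny_config()), "EXCLUDED")
})

test_that("the regressor learns a realizable linear target", {
  set.seed(3)
  smi <- c(toy_records()$smiles, "CCOC", "CCCN", "CCOCC", "NCCO", "CCCCN",
           "COC", "CCNC", "OCCOC", "CCCOC", "CNCCO")
  d <- mp_descriptors(smi)
  df <- tibble::tibble(smiles = smi, assay = "PAMPA",
                       neg_log_papp = 4 + 0.3 * d[, "n_heavy"])
  vi <- seq(1, 30, by = 5)            # validation spread over target range
  tr <- df[-vi, ]; va <- df[vi, ]
  cfg <- tiny_config(epochs = 250, patience = 250, lr = 1e-2,
                     experts = c("graph", "desc"))
  fit <- mp_fit_regressor(tr, va, encoding = "NONE", config = cfg, seed = 2)
  p <- predict(fit, va)
  expect_gt(mp_r_squared(va$neg_log_papp, p$prediction), 0.95)
  fit2 <- mp_fit_regressor(tr, va, encoding = "NONE",
                           config = tiny_config(epochs = 5), seed = 2)
  fit3 <- mp_fit_regressor(tr, va, encoding = "NONE",
                           config = tiny_config(epochs = 5), seed = 2)
  expect_identical(fit2$params, fit3$params)
})

test_that("condition-aware encoding exploits a planted pH effect", {
  set.seed(6)
  base <- toy_records()$smiles
  ph <- rep(c(5, 9), each = 10)
  # target depends on pH more than on structure
  df <- tibble::tibble(smiles = rep(base, 2)[1:20], assay = "PAMPA",
                       ph = ph, temperature = 37,
                       neg_log_papp = 6 + 0.9 * (ph - 7) / 2 +
                         rep(rnorm(10, 0, 0.05), 2))
  tr_i <- c(1:8, 11:18); va_i <- c(9, 10, 19, 20)
  cfg <- tiny_config(epochs = 60, lr = 5e-3)
  mses <- sapply(1:3, function(s) {
    fg <- mp_fit_regressor(df[tr_i, ], df[va_i, ], encoding = "GLOBAL",
                           config = cfg, seed = s)
    fn <- mp_fit_regressor(df[tr_i, ], df[va_i, ], encoding = "NONE",
                           config = cfg, seed = s)
    c(global = mean((predict(fg, df[va_i, ])$prediction -
                       df$neg_log_papp[va_i])^2),
      none = mean((predict(fn, df[va_i, ])$prediction -
                     df$neg_log_papp[va_i])^2))
  })
  expect_lt(median(mses["global", ]), median(mses["none", ]))
})
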