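#' @title Knowledge distillation from the multi-assay teacher
#' @description
#' A teacher is trained on the large, pooled multi-assay set (assay
#' identity as a one-hot global feature); its temperature-softened
#' probabilities ("dark knowledge") are cached for the task molecules and
#' added to the student's loss, L = L_true + lambda * L_soft, where L_soft
#' is a binary KL divergence between temperature-scaled sigmoid
#' probabilities (with the standard T^2 gradient scaling) or, optionally,
#' a squared distance on logits.
#' @name distill
NULL

#' Distillation configuration
#'
#' @param temperature softening temperature T > 0 for both teacher and
#'   student probabilities.
#' @param lambda weight of the soft-label term (>= 0); 0 recovers plain
#'   supervised training exactly.
#' @param divergence `"BINARY_KL"` (KL between temperature-scaled sigmoid
#'   probabilities) or `"MSE_LOGITS"` (squared distance on raw logits).
#' @param t_squared_scaling multiply the KL term by T^2 so its gradient
#'   magnitude stays comparable across temperatures.
#' @return an `mp_distill_config` object.
#' @export
mp_distill_config <- function(temperature = 2, lambda = 0.5,
                              divergence = c("BINARY_KL", "MSE_LOGITS"),
                              t_squared_scaling = TRUE) {
  divergence <- match.arg(divergence)
  if (temperature <= 0) abort("`temperature` must be > 0")
  if (lambda < 0) abort("`lambda` must be >= 0")
  structure(list(temperature = temperature, lambda = lambda,
                 divergence = divergence,
                 t_squared_scaling = t_squared_scaling),
            class = "mp_distill_config")
}

#' Temperature-scaled sigmoid probability
#'
#' p(z, T) = exp(z/T) / (1 + exp(z/T)), computed in a numerically stable
#' form; strictly increasing in z, approaching 1/2 for every z as T grows.
#'
#' @param z logit(s).
#' @param temperature T > 0.
#' @return probabilities strictly inside (0, 1).
#' @export
mp_soft_probability <- function(z, temperature = 1) {
  if (temperature <= 0) abort("`temperature` must be > 0")
  sigmoid(z / temperature)
}

#' Distillation divergence between teacher and student probabilities
#'
#' Binary KL, p_t log(p_t/p_s) + (1-p_t) log((1-p_t)/(1-p_s)), optionally
#' scaled by T^2; non-negative and zero iff the probabilities agree.
#' Probabilities at exactly 0 or 1 are clamped to 1e-7 with a warning.
#' With `divergence = "MSE_LOGITS"` the squared distance of logits
#' recovered from the probabilities is used instead.
#'
#' @param p_teacher,p_student probabilities in (0, 1).
#' @param config an [mp_distill_config()].
#' @return non-negative divergence, elementwise.
#' @export
mp_distill_divergence <- function(p_teacher, p_student,
                                  config = mp_distill_config(t_squared_scaling = FALSE)) {
  eps <- 1e-7
  if (any(p_teacher <= 0 | p_teacher >= 1 | p_student <= 0 | p_student >= 1)) {
    warn("probabilities at the {0,1} boundary clamped to 1e-7")
  }
  p_t <- pmin(pmax(p_teacher, eps), 1 - eps)
  p_s <- pmin(pmax(p_student, eps), 1 - eps)
  if (config$divergence == "MSE_LOGITS") {
    zt <- stats::qlogis(p_t); zs <- stats::qlogis(p_s)
    return(0.5 * (zt - zs)^2)
  }
  d <- binary_kl(p_t, p_s)
  if (config$t_squared_scaling) d <- d * config$temperature^2
  d
}

#' Student loss: supervised term plus weighted soft-label term
#'
#' L = BCE(y, p_hard) + lambda * mean divergence of the temperature-scaled
#' pair; continuous and non-decreasing in lambda.
#'
#' @param y binary labels in \{0, 1\}.
#' @param p_hard student probabilities at T = 1.
#' @param p_teacher,p_student teacher/student probabilities at the
#'   configured temperature.
#' @param config an [mp_distill_config()].
#' @return scalar loss, with components in attribute `"components"`.
#' @export
mp_student_loss <- function(y, p_hard, p_teacher, p_student,
                            config = mp_distill_config(t_squared_scaling = FALSE)) {
  l_true <- mp_bce(y, p_hard)
  l_soft <- mean(mp_distill_divergence(p_teacher, p_student, config))
  total <- l_true + config$lambda * l_soft
  attr(total, "components") <- c(l_true = l_true, l_soft = l_soft)
  total
}

#' Train the multi-assay teacher
#'
#' Fits the mixture-of-experts classifier on the pooled large set with the
#' assay identity appended as a one-hot global feature, so a single teacher
#' spans Caco-2/MDCK/RRCK/PAMPA records.
#'
#' @param large labeled record tibble (`smiles`, `assay`, `y`).
#' @param config an [mp_model_config()].
#' @param seed integer seed.
#' @param schema feature schema.
#' @param val_fraction fraction held out (seeded) for early stopping.
#' @param features optional precomputed [mp_featurize()] bundle for `large`.
#' @param trace print per-epoch losses.
#' @return a fitted `macro_pp` teacher.
#' @export
mp_train_teacher <- function(large, config = mp_model_config(), seed = 1,
                             schema = mp_feature_schema(), val_fraction = 0.1,
                             features = NULL, trace = FALSE) {
  large <- as_tibble(large)
  n <- nrow(large)
  val_idx <- with_seed(derive_seed(seed, "teacher_val"),
                       sort(sample(n, max(1, round(val_fraction * n)))))
  feats <- combine_features(large, schema, features, NULL,
                            n_train = n - length(val_idx))
  # reorder so validation rows sit at the end (fit layout)
  ord <- c(setdiff(seq_len(n), val_idx), val_idx)
  feats_o <- list(graphs = feats$graphs[ord], desc = feats$desc[ord, , drop = FALSE],
                  ecfp = feats$ecfp[ord, , drop = FALSE],
                  maccs = feats$maccs[ord, , drop = FALSE],
                  smiles = feats$smiles[ord], schema = feats$schema)
  class(feats_o) <- "mp_features"
  mp_fit_classifier(large[setdiff(seq_len(n), val_idx), ], large[val_idx, ],
                    config = config, seed = seed, schema = schema,
                    assay_onehot = TRUE, features = feats_o, trace = trace)
}

#' Distill the teacher into a task-specific student
#'
#' Teacher logits are computed once for every task molecule (teacher
#' frozen); the student then minimizes BCE plus the weighted soft-label
#' divergence. With `lambda = 0` and a shared seed, the result is
#' parameter-for-parameter identical to [mp_fit_classifier()] on the task
#' data alone.
#'
#' @param teacher a fitted multi-assay `macro_pp` teacher.
#' @param train,val task record tibbles (`smiles`, `assay`, `y`).
#' @param distill an [mp_distill_config()].
#' @param config student [mp_model_config()].
#' @param seed integer seed.
#' @param schema feature schema (must match the teacher's).
#' @param features,val_features optional precomputed feature bundles.
#' @param teacher_logits optional numeric vector overriding the teacher's
#'   logits for `rbind(train, val)` (in row order). Intended for control
#'   experiments, e.g. permuting the logits to form an uninformative
#'   teacher while preserving their distribution.
#' @param trace print per-epoch losses.
#' @return a fitted `macro_pp` student carrying the distillation settings.
#' @export
mp_distill_student <- function(teacher, train, val,
                               distill = mp_distill_config(),
                               config = mp_model_config(), seed = 1,
                               schema = mp_feature_schema(),
                               features = NULL, val_features = NULL,
                               teacher_logits = NULL, trace = FALSE) {
  stopifnot(inherits(teacher, "macro_pp"))
  if (!identical(teacher$schema$version, schema$version)) {
    abort(sprintf("feature schema mismatch: teacher v%s vs student v%s",
                  teacher$schema$version, schema$version))
  }
  train <- as_tibble(train); val <- as_tibble(val)
  if (nrow(val) == 0) abort("validation set must be non-empty")
  data <- bind_rows(train, val)
  feats <- combine_features(data, schema, features, val_features, nrow(train))
  z_t <- teacher_logits %||% predict(teacher, data, features = feats)$logit
  stopifnot(length(z_t) == nrow(data))
  soft <- c(unclass(distill),
            list(z_teacher = z_t,
                 p_teacher = mp_soft_probability(z_t, distill$temperature)))
  gl <- mp_global_features(data, assay_onehot = FALSE)
  fit <- fit_core(feats, data$y, gl$x, config, seed, task = "classify",
                  val_idx = nrow(train) + seq_len(nrow(val)), soft = soft,
                  trace = trace)
  out <- new_macro_pp(fit, config, schema, "classify", feats$desc_stats,
                      list(assay_onehot = FALSE, condition_mode = "NONE"),
                      NULL, seed, nrow(train))
  out$distill <- distill
  out
}
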