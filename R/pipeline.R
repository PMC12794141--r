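#' @title End-to-end pipeline and command-line entry point
#' @description
#' One driver wiring simulate -> curate -> split -> teacher -> distill ->
#' evaluate, writing every artifact (records, folds, checkpoints, metric
#' reports, resolved configuration) under an output directory; two runs
#' with the same resolved configuration and seed produce byte-identical
#' artifacts. `macroperm_main()` exposes the same steps as subcommands for
#' the thin `inst/cli/macroperm.R` script.
#' @name pipeline
NULL

#' Run the full pipeline on a synthetic benchmark
#'
#' Generates the benchmark, curates the task set with the configured swing,
#' assigns leakage-free folds, trains the multi-assay teacher, distills the
#' student, evaluates both on the held-out task fold, and writes all
#' artifacts plus a resolved-config snapshot to `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param spec an [mp_synthetic_spec()].
#' @param task_swing swing halfwidth for task-set labeling.
#' @param config an [mp_model_config()].
#' @param distill an [mp_distill_config()].
#' @param split_mode fold-assignment mode for the task set.
#' @param k number of folds (fold 0 is held out for evaluation).
#' @param seed integer master seed.
#' @return (invisibly) list with the fitted models, the metric tibble, and
#'   the written file paths.
#' @export
mp_run_pipeline <- function(out_dir, spec = mp_synthetic_spec(),
                            task_swing = 0.5, config = mp_model_config(),
                            distill = mp_distill_config(),
                            split_mode = "SMILES", k = 5, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  log_path <- pth("run_log.jsonl")
  unlink(log_path)
  log_step <- function(step, ...) {
    cat(jsonlite::toJSON(c(list(step = step, seed = seed), list(...)),
                         auto_unbox = TRUE), "\n", file = log_path, append = TRUE)
  }

  resolved <- list(seed = seed, task_swing = task_swing, split_mode = split_mode,
                   k = k, spec = unclass(spec)[setdiff(names(unclass(spec)), "side_chains")],
                   model = list(hidden_dim = config$mp$hidden_dim,
                                rounds = config$mp$rounds,
                                d_expert = config$d_expert,
                                experts = config$experts, lr = config$lr,
                                batch_size = config$batch_size,
                                epochs = config$epochs, patience = config$patience),
                   distill = unclass(distill))
  yaml::write_yaml(resolved, pth("resolved_config.yaml"))

  bench <- mp_make_benchmark(spec, task_swing = task_swing)
  mp_write_dataset(bench$large, pth("large.csv"))
  mp_write_dataset(bench$task, pth("task.csv"))
  mp_write_dataset(bench$truth, pth("truth.csv"))
  log_step("simulate", n_large = nrow(bench$large), n_task = nrow(bench$task))

  task <- bench$task[!is.na(bench$task$y), ]
  folds <- mp_assign_folds(task, mode = split_mode, k = k, seed = seed)
  mp_write_dataset(folds[, c("inchikey", "fold")], pth("folds.csv"))
  log_step("split", mode = split_mode, k = k)

  teacher <- mp_train_teacher(bench$large[!is.na(bench$large$y), ],
                              config = config, seed = seed)
  mp_save_checkpoint(teacher, pth("teacher.ckpt"))
  log_step("train_teacher", val_loss = teacher$val_loss)

  test <- folds[folds$fold == 0, ]
  train_all <- folds[folds$fold != 0, ]
  val_n <- max(1L, round(0.2 * nrow(train_all)))
  val_rows <- with_seed(derive_seed(seed, "pipe_val"),
                        sort(sample(nrow(train_all), val_n)))
  tr <- train_all[-val_rows, ]; va <- train_all[val_rows, ]

  student <- mp_distill_student(teacher, tr, va, distill = distill,
                                config = config, seed = seed)
  mp_save_checkpoint(student, pth("multiddpp.ckpt"))
  plain <- mp_fit_classifier(tr, va, config = config, seed = seed)
  log_step("distill", val_loss = student$val_loss)

  metrics <- bind_rows(
    eval_on(student, test, "distilled"),
    eval_on(plain, test, "plain"),
    eval_on(teacher, test, "teacher"))
  mp_write_dataset(metrics, pth("metrics.csv"))
  jsonlite::write_json(split(metrics, metrics$model), pth("metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  log_step("evaluate")

  invisible(list(teacher = teacher, student = student, plain = plain,
                 metrics = metrics, bench = bench,
                 files = list.files(out_dir, full.names = TRUE)))
}

eval_on <- function(model, test, tag) {
  p <- predict(model, test)$prob
  yhat <- as.integer(p >= 0.5)
  cm <- mp_confusion_metrics(sum(yhat == 1 & test$y == 1),
                             sum(yhat == 0 & test$y == 0),
                             sum(yhat == 1 & test$y == 0),
                             sum(yhat == 0 & test$y == 1))
  rk <- if (length(unique(test$y)) == 2) mp_ranking_metrics(test$y, p)
        else tibble(auc = NA_real_, pr_auc = NA_real_)
  tibble(model = tag, n = nrow(test), acc = cm$acc, mcc = cm$mcc,
         auc = rk$auc, pr_auc = rk$pr_auc, bce = mp_bce(test$y, p))
}

# --- command-line interface -----------------------------------------------

cli_usage <- "usage: macroperm <command> [--key value ...]

commands:
  simulate   --out-dir DIR [--n-large N] [--n-task N] [--noise-sd X] [--seed N]
  curate     --input CSV --out CSV [--report JSON] [--swing X] [--center X]
  split      --input CSV --out CSV [--mode SMILES|SCAFFOLD|CLUSTER|RANDOM]
             [--k N] [--seed N]
  train      --input CSV --out CKPT [--task classify|regress] [--seed N]
             [--hidden N] [--rounds N] [--epochs N] [--val-fraction X]
  distill    --teacher CKPT --input CSV --out CKPT [--temperature X]
             [--lambda X] [--seed N] [--hidden N] [--rounds N] [--epochs N]
  predict    --ckpt CKPT --input CSV --out CSV
  evaluate   --ckpt CKPT --input CSV --out JSON
  explain    --ckpt CKPT --input CSV --out CSV
  geom       --sdf SDF --report JSON
  pipeline   --out-dir DIR [--seed N] [--swing X]
"

cli_opts <- function(argv) {
  opts <- list()
  i <- 1
  while (i <= length(argv)) {
    if (!startsWith(argv[i], "--")) {
      abort(sprintf("unexpected argument: %s", argv[i]))
    }
    key <- gsub("-", "_", sub("^--", "", argv[i]))
    if (i + 1 > length(argv)) abort(sprintf("missing value for --%s", key))
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  opts
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}
opt_chr <- function(opts, key, default = NULL) {
  opts[[key]] %||% default %||% abort(sprintf("missing required --%s",
                                              gsub("_", "-", key)))
}

cli_model_config <- function(opts) {
  mp_model_config(hidden_dim = opt_num(opts, "hidden", 32),
                  rounds = opt_num(opts, "rounds", 2),
                  d_expert = opt_num(opts, "d_expert", 16),
                  epochs = opt_num(opts, "epochs", 30),
                  patience = opt_num(opts, "patience", 8),
                  batch_size = opt_num(opts, "batch_size", 32))
}

split_train_val <- function(data, val_fraction, seed) {
  n <- nrow(data)
  vi <- with_seed(derive_seed(seed, "cli_val"),
                  sort(sample(n, max(1, round(val_fraction * n)))))
  list(train = data[-vi, ], val = data[vi, ])
}

#' Command-line entry point
#'
#' Dispatches the subcommands documented in the usage text; designed to be
#' called by the thin `inst/cli/macroperm.R` script but usable directly.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 success, 2 usage error), invisibly.
#' @export
macroperm_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage)
    return(invisible(0L))
  }
  cmd <- argv[1]
  known <- c("simulate", "curate", "split", "train", "distill", "predict",
             "evaluate", "explain", "geom", "pipeline")
  if (!cmd %in% known) {
    cat(cli_usage)
    message(sprintf("unknown command: %s", cmd))
    return(invisible(2L))
  }
  code <- tryCatch({
    opts <- cli_opts(argv[-1])
    seed <- as.integer(opt_num(opts, "seed", 1))
    switch(cmd,
      simulate = {
        spec <- mp_synthetic_spec(n_large = opt_num(opts, "n_large", 2000),
                                  n_task = opt_num(opts, "n_task", 200),
                                  noise_sd = opt_num(opts, "noise_sd", 0.4),
                                  seed = seed)
        out_dir <- opt_chr(opts, "out_dir")
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        bench <- mp_make_benchmark(spec, task_swing = opt_num(opts, "swing", 0.5))
        mp_write_dataset(bench$large, file.path(out_dir, "large.csv"))
        mp_write_dataset(bench$task, file.path(out_dir, "task.csv"))
        mp_write_dataset(bench$truth, file.path(out_dir, "truth.csv"))
      },
      curate = {
        rec <- mp_read_dataset(opt_chr(opts, "input"))
        cur <- mp_curate(rec, center = opt_num(opts, "center", 6),
                         halfwidth = opt_num(opts, "swing", 0.5))
        mp_write_dataset(cur, opt_chr(opts, "out"))
        if (!is.null(opts$report)) {
          jsonlite::write_json(as.list(mp_report(cur)), opts$report,
                               auto_unbox = TRUE, digits = NA)
        }
      },
      split = {
        rec <- ensure_keys(mp_read_dataset(opt_chr(opts, "input")))
        fa <- mp_assign_folds(rec, mode = opt_chr(opts, "mode", "SMILES"),
                              k = opt_num(opts, "k", 10), seed = seed)
        mp_write_dataset(fa[, c("inchikey", "fold")], opt_chr(opts, "out"))
      },
      train = {
        rec <- mp_read_dataset(opt_chr(opts, "input"))
        rec <- mp_curate(rec, halfwidth = opt_num(opts, "swing", 0))
        rec <- rec[!is.na(rec$y), ]
        sp <- split_train_val(rec, opt_num(opts, "val_fraction", 0.15), seed)
        cfg <- cli_model_config(opts)
        task <- opt_chr(opts, "task", "classify")
        fit <- if (task == "regress") {
          mp_fit_regressor(sp$train, sp$val, config = cfg, seed = seed)
        } else if (length(unique(rec$assay)) > 1) {
          mp_train_teacher(rec, config = cfg, seed = seed)
        } else {
          mp_fit_classifier(sp$train, sp$val, config = cfg, seed = seed)
        }
        mp_save_checkpoint(fit, opt_chr(opts, "out"))
      },
      distill = {
        teacher <- mp_load_checkpoint(opt_chr(opts, "teacher"))
        rec <- mp_read_dataset(opt_chr(opts, "input"))
        rec <- mp_curate(rec, halfwidth = opt_num(opts, "swing", 0.5))
        rec <- rec[!is.na(rec$y), ]
        sp <- split_train_val(rec, opt_num(opts, "val_fraction", 0.15), seed)
        dcfg <- mp_distill_config(temperature = opt_num(opts, "temperature", 2),
                                  lambda = opt_num(opts, "lambda", 0.5))
        fit <- mp_distill_student(teacher, sp$train, sp$val, distill = dcfg,
                                  config = cli_model_config(opts), seed = seed)
        mp_save_checkpoint(fit, opt_chr(opts, "out"))
      },
      predict = {
        model <- mp_load_checkpoint(opt_chr(opts, "ckpt"))
        rec <- mp_read_dataset(opt_chr(opts, "input"))
        mp_write_dataset(bind_cols(rec, predict(model, rec)),
                         opt_chr(opts, "out"))
      },
      evaluate = {
        model <- mp_load_checkpoint(opt_chr(opts, "ckpt"))
        rec <- mp_read_dataset(opt_chr(opts, "input"))
        rec <- mp_curate(rec, halfwidth = opt_num(opts, "swing", 0))
        rec <- rec[!is.na(rec$y), ]
        jsonlite::write_json(as.list(eval_on(model, rec, "model")),
                             opt_chr(opts, "out"), auto_unbox = TRUE, digits = NA)
      },
      explain = {
        model <- mp_load_checkpoint(opt_chr(opts, "ckpt"))
        rec <- mp_read_dataset(opt_chr(opts, "input"))
        rec <- mp_curate(rec, halfwidth = opt_num(opts, "swing", 0))
        rec <- rec[!is.na(rec$y), ]
        mp_write_dataset(mp_channel_importance(model, rec), opt_chr(opts, "out"))
      },
      geom = {
        confs <- mp_read_conformers(opt_chr(opts, "sdf"))
        jsonlite::write_json(as.list(mp_polar_exposure(confs)),
                             opt_chr(opts, "report"), auto_unbox = TRUE,
                             digits = NA)
      },
      pipeline = {
        spec <- mp_synthetic_spec(n_large = opt_num(opts, "n_large", 300),
                                  n_task = opt_num(opts, "n_task", 80),
                                  seed = seed)
        mp_run_pipeline(opt_chr(opts, "out_dir"), spec,
                        task_swing = opt_num(opts, "swing", 0.5),
                        config = cli_model_config(opts), seed = seed)
      })
    0L
  }, error = function(e) {
    message(sprintf("macroperm %s failed: %s", cmd, conditionMessage(e)))
    2L
  })
  invisible(code)
}
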