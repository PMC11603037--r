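#' Build the model input for a variant from prepared data
#'
#' Tabular variants aggregate the (imputed, scaled) dynamic tensor with the
#' matching aggregation and append the static features without aggregation;
#' sequence variants consume the tensor directly; hybrid variants consume the
#' tensor in the sequence branch and the static matrix in the tabular branch.
#'
#' @param variant model variant name.
#' @param side one element (`train` or `test`) of [prepare_sequences()]
#'   output.
#' @return a matrix, [seq_tensor()], or list(seq=, tab=) suitable for
#'   [predict.pod_model()].
#' @export
variant_inputs <- function(variant, side) {
  tab_of <- function() {
    agg <- switch(variant,
                  MLP_TAB_P = tab_p(side$tensor),
                  MLP_TAB_F = tab_f(side$tensor),
                  MLP_TAB_T = tab_t(side$tensor))
    if (!is.null(side$statics)) cbind(agg, side$statics) else agg
  }
  switch(variant,
         MLP_TAB_P = , MLP_TAB_F = , MLP_TAB_T = tab_of(),
         LSTM_SEQ = , TRAN_SEQ = side$tensor,
         MLP_LSTM_SEQTAB = , MLP_TRAN_SEQTAB = {
           if (is.null(side$statics)) {
             stop("hybrid variants need static features")
           }
           list(seq = side$tensor, tab = side$statics)
         },
         stop("unknown model variant: ", variant))
}

#' Train one model variant end to end on prepared data
#'
#' Splits the training patients into an inner train/validation split (for
#' early stopping), standardizes tabular aggregations on the training rows,
#' builds and trains the model, and scores the test surgeries.
#'
#' @param prep output of [prepare_sequences()].
#' @param labels labelled surgeries covering all prepared surgeries.
#' @param config a [model_config()].
#' @param val_fraction fraction of training patients held out for early
#'   stopping.
#' @param verbose print training progress.
#' @return list with `model`, `scores` (test), `y_test`, `variant`.
#' @export
train_variant <- function(prep, labels, config, val_fraction = 0.25,
                          verbose = FALSE) {
  variant <- config$variant
  y_of <- function(ids) labels$Y[match(ids, labels$surgery_id)]
  train_ids <- prep$train$surgery_ids
  train_lab <- labels[match(train_ids, labels$surgery_id), ]
  inner <- split_by_patient(train_lab, test_fraction = val_fraction,
                            seed = config$seed + 17L)
  fit_rows <- train_lab$patient_id %in% inner$train_patient_ids

  x_train_all <- variant_inputs(variant, prep$train)
  x_test <- if (!is.null(prep$test)) variant_inputs(variant, prep$test)

  # standardize tabular aggregations with statistics from the fitting rows
  if (is.matrix(x_train_all)) {
    sc <- fit_scaler(x_train_all[fit_rows, , drop = FALSE])
    x_train_all <- apply_scaler(x_train_all, sc)
    if (!is.null(x_test)) x_test <- apply_scaler(x_test, sc)
  }

  subset_x <- function(x, rows) {
    if (inherits(x, "seq_tensor")) {
      seq_tensor(x$values[rows, , , drop = FALSE],
                 x$mask[rows, , , drop = FALSE],
                 x$channel_names, x$surgery_ids[rows], x$interval_min,
                 x$window)
    } else if (is.matrix(x)) {
      x[rows, , drop = FALSE]
    } else {
      list(seq = subset_x(x$seq, rows), tab = x$tab[rows, , drop = FALSE])
    }
  }
  x_fit <- subset_x(x_train_all, fit_rows)
  x_val <- subset_x(x_train_all, !fit_rows)
  y_fit <- y_of(train_ids[fit_rows])
  y_val <- y_of(train_ids[!fit_rows])

  shape <- list()
  if (inherits(x_train_all, "seq_tensor")) {
    shape <- list(k = dim(x_train_all)[2], n = dim(x_train_all)[3])
  } else if (is.matrix(x_train_all)) {
    shape <- list(p = ncol(x_train_all))
  } else {
    shape <- list(k = dim(x_train_all$seq)[2], n = dim(x_train_all$seq)[3],
                  p = ncol(x_train_all$tab))
  }
  model <- if (is_hybrid_variant(variant)) {
    seq_cfg <- config
    seq_cfg$variant <- if (variant == "MLP_LSTM_SEQTAB") "LSTM_SEQ" else "TRAN_SEQ"
    mlp_cfg <- config
    mlp_cfg$variant <- "MLP_TAB_P"
    build_hybrid(seq_cfg, mlp_cfg, shape)
  } else {
    build_model(config, shape)
  }
  model <- train_with_early_stopping(model, x_fit, y_fit, x_val, y_val,
                                     verbose = verbose)
  scores <- if (!is.null(x_test)) predict(model, x_test)
  list(model = model, scores = scores,
       y_test = if (!is.null(prep$test)) y_of(prep$test$surgery_ids),
       variant = variant)
}

#' Read / write experiment configurations
#'
#' Plain YAML round-trip of the experiment settings consumed by
#' [run_experiment()].
#'
#' @param path YAML file.
#' @return named list of settings.
#' @export
read_experiment_config <- function(path) yaml::read_yaml(path)

#' @rdname read_experiment_config
#' @param config named list of settings.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run a configured end-to-end experiment
#'
#' Pipeline: simulate (or load) a cohort, label and split by patient,
#' preprocess into tensors, train the requested model variants, evaluate with
#' bootstrap CIs, compare all variant pairs with the corrected t-test, derive
#' decision-threshold scenarios, and screen features univariately on the
#' training split. Reports are written as JSON/CSV into `out_dir`; each stage
#' appends a log line with its seed and wall time. Deterministic stages are
#' bit-identical across reruns with the same config.
#'
#' @param config named list (or YAML path) with entries: `seed`, `out_dir`,
#'   `sim` (arguments for [sim_config()], plus optional `scenario` =
#'   `"null"`, `"slope"` or `"missingness"` and `delta`), `window` (string,
#'   e.g. `"0:30"`), `interval_min`, `test_fraction`, `variants` (character
#'   vector), `model` (overrides for [model_config()]), `bootstrap_B`,
#'   `caseload`, `prevalence`.
#' @return list with `metrics`, `comparisons`, `scenarios`, `screen`, and
#'   file paths; invisibly.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("experiment")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "stages.log")
  log_stage <- function(stage, t0) {
    cat(sprintf("%s seed=%d wall=%.1fs\n", stage, seed,
                as.numeric(Sys.time()) - t0),
        file = log_path, append = TRUE)
  }

  # --- simulate ---
  t0 <- as.numeric(Sys.time())
  sim_args <- config$sim %||% list()
  scenario <- sim_args$scenario %||% "slope"
  delta <- sim_args$delta %||% 1
  sim_args$scenario <- NULL; sim_args$delta <- NULL
  scfg <- do.call(sim_config, c(sim_args, list(seed = seed)))
  cohort <- switch(scenario,
                   null = generate_cohort(scfg, seed = seed),
                   slope = make_mean_matched_slope_cohort(scfg,
                                                          delta_slope = delta,
                                                          seed = seed),
                   missingness = make_missingness_cohort(scfg,
                                                         delta_log_obs_rate = -abs(delta),
                                                         seed = seed),
                   stop("unknown simulation scenario: ", scenario))
  log_stage("simulate", t0)

  # --- label + split ---
  t0 <- as.numeric(Sys.time())
  labels <- label_pod(cohort$nudesc, cohort$truth$surgeries)
  split <- split_by_patient(labels, config$test_fraction %||% 0.3,
                            seed = seed + 1L)
  log_stage("split", t0)

  # --- preprocess ---
  t0 <- as.numeric(Sys.time())
  specs <- feature_spec(scfg$feature_menu$name, missing_indicator = TRUE)
  static_specs <- feature_spec(scfg$static_menu$name, time_variance = "static")
  specs <- validate_feature_spec(rbind(specs, static_specs))
  surgeries <- data.frame(surgery_id = cohort$truth$surgeries$surgery_id,
                          patient_id = cohort$truth$surgeries$patient_id,
                          t_end = cohort$truth$surgeries$length_min)
  window <- parse_window(config$window %||% "0:30")
  prep <- prepare_sequences(cohort$events, surgeries, specs, window,
                            interval_min = config$interval_min %||% 3,
                            train_patient_ids = split$train_patient_ids,
                            statics = cohort$statics)
  log_stage("preprocess", t0)

  # --- train + evaluate ---
  variants <- config$variants %||% c("TRAN_SEQ", "MLP_TAB_P")
  known <- eval(formals(model_config)$variant)
  if (length(setdiff(variants, known)) > 0) {
    stop("unknown model variant: ",
         paste(setdiff(variants, known), collapse = ", "))
  }
  B <- config$bootstrap_B %||% 200
  fits <- list(); boots <- list(); metrics <- list()
  for (v in variants) {
    t0 <- as.numeric(Sys.time())
    mc <- do.call(model_config,
                  c(list(variant = v), config$model %||% list(),
                    list(seed = seed + 3L)))
    fit <- train_variant(prep, labels, mc)
    bt <- bootstrap_metrics(fit$scores, fit$y_test, B = B, seed = seed + 5L)
    fits[[v]] <- fit; boots[[v]] <- bt
    metrics[[v]] <- list(auroc = unname(bt$mean["auroc"]),
                         auroc_ci = unname(bt$ci["auroc", ]),
                         auprc = unname(bt$mean["auprc"]),
                         auprc_ci = unname(bt$ci["auprc", ]))
    log_stage(paste0("train:", v), t0)
  }

  # --- pairwise corrected t-tests ---
  t0 <- as.numeric(Sys.time())
  n_train <- sum(labels$patient_id %in% split$train_patient_ids)
  n_test <- sum(labels$patient_id %in% split$test_patient_ids)
  comp <- list()
  if (length(variants) > 1) {
    pairs <- utils::combn(variants, 2, simplify = FALSE)
    comp <- lapply(pairs, function(pr) {
      ct <- corrected_t_test(boots[[pr[1]]]$auroc, boots[[pr[2]]]$auroc,
                             n_train, n_test)
      data.frame(model_a = pr[1], model_b = pr[2], t = ct$t, p = ct$p,
                 D_bar = ct$D_bar, stringsAsFactors = FALSE)
    })
    comp <- do.call(rbind, comp)
  }
  log_stage("compare", t0)

  # --- scenarios (best variant by AUPRC) ---
  t0 <- as.numeric(Sys.time())
  best <- variants[which.max(vapply(metrics, function(mm) mm$auprc, numeric(1)))]
  scen <- threshold_scenarios(fits[[best]]$scores, fits[[best]]$y_test)
  scen_conf <- lapply(seq_len(nrow(scen)), function(i) {
    tryCatch(as.list(scale_confusion(scen$recall[i],
                                     max(scen$precision[i], 1e-6),
                                     config$caseload %||% 100,
                                     config$prevalence %||% 0.09)),
             error = function(e) NULL)
  })
  log_stage("scenario", t0)

  # --- univariate screening on the training split ---
  t0 <- as.numeric(Sys.time())
  train_surg <- surgeries[surgeries$patient_id %in% split$train_patient_ids, ]
  summ <- window_summaries(cohort$events, train_surg, list(w = window),
                           interval_min = config$interval_min %||% 3)
  screen <- spearman_screen(summ, labels)
  log_stage("stats", t0)

  # --- attention (if a transformer was trained) ---
  attn <- NULL
  tran_variant <- intersect(variants, c("TRAN_SEQ", "MLP_TRAN_SEQTAB"))
  if (length(tran_variant) > 0) {
    t0 <- as.numeric(Sys.time())
    v <- tran_variant[1]
    nd <- variant_inputs(v, prep$test)
    am <- extract_attention(fits[[v]]$model, nd)
    attn <- aggregate_attention_report(am, seed = seed + 7L)
    log_stage("attention", t0)
  }

  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(comp) > 0) {
    utils::write.csv(comp, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  scen_out <- cbind(scen, do.call(rbind, lapply(scen_conf, function(x) {
    if (is.null(x)) data.frame(TP = NA, FP = NA, TN = NA, FN = NA)
    else as.data.frame(x[c("TP", "FP", "TN", "FN")])
  })))
  utils::write.csv(scen_out, file.path(out_dir, "scenarios.csv"),
                   row.names = FALSE)
  utils::write.csv(screen, file.path(out_dir, "screen.csv"), row.names = FALSE)
  if (!is.null(attn)) {
    jsonlite::write_json(list(feature_importance = as.list(attn$feature_importance),
                              time_profile = attn$time_profile),
                         file.path(out_dir, "attention.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(list(metrics = metrics, comparisons = comp, scenarios = scen_out,
                 screen = screen, attention = attn, fits = fits,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
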