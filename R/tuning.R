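#' Patient-grouped nested cross-validation plan
#'
#' Patients are partitioned into `k_outer` outer folds of near-equal size;
#' within each outer fold the remaining (outer-training) patients are
#' partitioned again into `k_inner` inner folds. Hyperparameters are searched
#' on the inner folds and validated on the outer folds, and because folds are
#' patient-disjoint no surgery of a patient can appear on both sides of any
#' split.
#'
#' @param labels labelled surgeries (`surgery_id, patient_id, Y`).
#' @param k_outer,k_inner fold counts (3 x 3 in the study design).
#' @param seed integer seed.
#' @return object of class `cv_plan`: list with `outer` (each element:
#'   `val_patients`, `train_patients`, `inner` = list of `k_inner` patient
#'   sets partitioning `train_patients`) and `seed`.
#' @export
make_cv_plan <- function(labels, k_outer = 3L, k_inner = 3L, seed = 1L) {
  patients <- sort(unique(labels$patient_id))
  if (length(patients) < k_outer * k_inner) {
    stop("need at least ", k_outer * k_inner, " patients, got ",
         length(patients))
  }
  shuffled <- local_seed(seed, sample(patients))
  outer_id <- rep_len(seq_len(k_outer), length(patients))
  outer <- vector("list", k_outer)
  for (o in seq_len(k_outer)) {
    val <- shuffled[outer_id == o]
    train <- setdiff(shuffled, val)
    inner_id <- rep_len(seq_len(k_inner), length(train))
    inner <- split(train, inner_id)
    names(inner) <- NULL
    outer[[o]] <- list(val_patients = sort(val),
                       train_patients = sort(train),
                       inner = lapply(inner, sort))
  }
  structure(list(outer = outer, k_outer = k_outer, k_inner = k_inner,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Exhaustive grid search over a hyperparameter space
#'
#' Evaluates every combination of the axes on all inner folds of the plan and
#' ranks configurations by mean inner-fold AUPRC (the selection metric of
#' choice under class imbalance, where AUROC saturates).
#'
#' @param space named list of axes, each a vector of candidate values (e.g.
#'   `list(loss = c("weighted_ce", "focal"), interval = c(3, 5),
#'   learning_rate = c(1e-4, 1e-5), batch_size = c(32, 64))`).
#' @param evaluate_fn `function(config, train_patients, val_patients)`
#'   returning a named list/vector with at least `auprc` and `auroc`.
#' @param plan a [make_cv_plan()].
#' @return `data.frame` of trials, ranked by decreasing mean AUPRC, with the
#'   configuration columns and `mean_auprc`, `mean_auroc`, `n_folds`.
#' @export
grid_search <- function(space, evaluate_fn, plan) {
  stopifnot(length(space) > 0, all(lengths(space) > 0))
  grid <- expand.grid(space, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    config <- as.list(grid[i, , drop = FALSE])
    scores <- list()
    for (o in seq_along(plan$outer)) {
      fold <- plan$outer[[o]]
      for (j in seq_along(fold$inner)) {
        val <- fold$inner[[j]]
        train <- setdiff(fold$train_patients, val)
        scores[[length(scores) + 1L]] <- evaluate_fn(config, train, val)
      }
    }
    res[[i]] <- data.frame(
      grid[i, , drop = FALSE],
      mean_auprc = mean(vapply(scores, function(s) s[["auprc"]], numeric(1))),
      mean_auroc = mean(vapply(scores, function(s) s[["auroc"]], numeric(1))),
      n_folds = length(scores))
  }
  out <- do.call(rbind, res)
  out[order(-out$mean_auprc, -out$mean_auroc), , drop = FALSE]
}

#' Successive-halving hyperparameter search
#'
#' The rung logic at the core of bandit-style search: all candidate
#' configurations start at a small epoch budget; after each rung only the top
#' `1/eta` fraction (by AUPRC) survives to be retrained with an `eta`-fold
#' larger budget, until the full `budget_epochs` is spent on the survivors.
#'
#' @param space named list of axes (candidates are the full cross product).
#' @param evaluate_fn `function(config, epochs)` returning a named
#'   list/vector with `auprc` and `auroc`.
#' @param budget_epochs epoch budget of the final rung.
#' @param eta halving factor.
#' @return `data.frame` of the trials evaluated at the final rung, ranked by
#'   decreasing AUPRC, with an `epochs` column.
#' @export
successive_halving <- function(space, evaluate_fn, budget_epochs, eta = 3) {
  stopifnot(budget_epochs >= eta, eta > 1)
  grid <- expand.grid(space, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  n_rungs <- if (n == 1) 1L else ceiling(log(n) / log(eta)) + 1L
  alive <- seq_len(n)
  epochs <- max(1L, floor(budget_epochs / eta^(n_rungs - 1)))
  if (epochs < 1) stop("budget too small for one rung")
  result <- NULL
  for (r in seq_len(n_rungs)) {
    perf <- vapply(alive, function(i) {
      s <- evaluate_fn(as.list(grid[i, , drop = FALSE]), epochs)
      c(s[["auprc"]], s[["auroc"]])
    }, numeric(2))
    result <- data.frame(grid[alive, , drop = FALSE],
                         mean_auprc = perf[1, ], mean_auroc = perf[2, ],
                         epochs = epochs)
    if (length(alive) == 1 || r == n_rungs) break
    keep <- max(1L, floor(length(alive) / eta))
    alive <- alive[order(-perf[1, ])[seq_len(keep)]]
    epochs <- min(budget_epochs, epochs * eta)
  }
  result[order(-result$mean_auprc, -result$mean_auroc), , drop = FALSE]
}

#' Select the best configuration from ranked trials
#'
#' Argmax of mean AUPRC; ties broken by mean AUROC, then by a deterministic
#' hash of the configuration (so selection never depends on row order).
#'
#' @param trials `data.frame` from [grid_search()] or
#'   [successive_halving()].
#' @return the chosen row as a one-row `data.frame`.
#' @export
select_best <- function(trials) {
  stopifnot(nrow(trials) >= 1)
  cfg_cols <- setdiff(names(trials), c("mean_auprc", "mean_auroc",
                                       "n_folds", "epochs"))
  key <- apply(trials[, cfg_cols, drop = FALSE], 1,
               function(r) paste(r, collapse = "|"))
  ord <- order(-trials$mean_auprc, -trials$mean_auroc, key)
  trials[ord[1], , drop = FALSE]
}
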