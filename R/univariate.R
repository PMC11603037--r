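#' Per-window feature summaries
#'
#' For every surgery, feature and analysis window: the mean of the observed
#' grid-bin values (missing when the feature was never observed inside the
#' window) and the missingness rate, defined as the fraction of grid bins
#' without any observation. The denominator is the resampled grid, keeping
#' the definition consistent with the model inputs. Surgeries for which a
#' window does not resolve (e.g. a 60-90 min window on a 50-min surgery) are
#' skipped for that window and recorded in the `skipped` attribute.
#'
#' @param events cleaned long-format event table.
#' @param surgeries `data.frame` with `surgery_id`, `t_end`.
#' @param windows named list of [observation_window()]s (names label the
#'   output).
#' @param interval_min grid interval in minutes.
#' @param channels features to summarize (default: all in `events`).
#' @return long `data.frame`: `surgery_id, feature, window, mean_value,
#'   missing_rate, n_bins`.
#' @export
window_summaries <- function(events, surgeries, windows, interval_min = 3,
                             channels = unique(events$feature_name)) {
  if (is.null(names(windows))) {
    names(windows) <- vapply(windows, format, character(1))
  }
  ev <- data.table::as.data.table(events)
  ev <- ev[feature_name %in% channels & !is.na(value)]
  out <- vector("list", length(windows))
  skipped <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    bounds <- lapply(surgeries$t_end, function(te) {
      tryCatch(resolve_window(w, te), error = function(e) NULL)
    })
    ok <- !vapply(bounds, is.null, logical(1))
    skipped[[names(windows)[wi]]] <- surgeries$surgery_id[!ok]
    surg <- surgeries[ok, , drop = FALSE]
    start <- vapply(bounds[ok], `[`, numeric(1), 1)
    end <- vapply(bounds[ok], `[`, numeric(1), 2)
    n_bins <- pmax(1L, floor((end - start) / interval_min))
    si <- match(ev$surgery_id, surg$surgery_id)
    keep <- !is.na(si)
    evw <- ev[keep]
    sw <- si[keep]
    evw[, bin := floor((t_offset_min - start[sw]) / interval_min)]
    evw <- evw[bin >= 0 & bin < n_bins[sw]]
    binmeans <- evw[, .(value = mean(value)),
                    by = .(surgery_id, feature_name, bin)]
    summ <- binmeans[, .(mean_value = mean(value), n_obs_bins = .N),
                     by = .(surgery_id, feature_name)]
    full <- data.table::CJ(surgery_id = surg$surgery_id,
                           feature_name = channels, unique = TRUE)
    summ <- summ[full, on = c("surgery_id", "feature_name")]
    summ[is.na(n_obs_bins), n_obs_bins := 0L]
    summ[, `:=`(n_bins = n_bins[match(surgery_id, surg$surgery_id)])]
    summ[, `:=`(missing_rate = 1 - n_obs_bins / n_bins)]
    out[[wi]] <- data.frame(surgery_id = summ$surgery_id,
                            feature = summ$feature_name,
                            window = names(windows)[wi],
                            mean_value = summ$mean_value,
                            missing_rate = summ$missing_rate,
                            n_bins = summ$n_bins,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}

#' Spearman correlation of a feature summary with the POD label
#'
#' Average-rank Spearman correlation on the available (observed) pairs, with
#' significance from the t approximation
#' `t = r_s * sqrt((n - 2) / (1 - r_s^2))`, two-sided. The absolute
#' coefficient is reported with the effect direction stored separately.
#' Constant inputs (or fewer than 3 pairs) are flagged undefined and later
#' excluded from FDR correction.
#'
#' @param x numeric feature summary per surgery (NA = not observed).
#' @param y binary POD labels aligned with `x`.
#' @return list: `r_s` (absolute), `direction` (-1/0/1), `p`, `n`,
#'   `defined`.
#' @export
spearman_pod <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
    return(list(r_s = NA_real_, direction = 0, p = NA_real_, n = n,
                defined = FALSE))
  }
  rs <- stats::cor(rank(x[ok]), rank(y[ok]))
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    t_stat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(r_s = abs(rs), direction = sign(rs), p = p, n = n, defined = TRUE)
}

#' Benjamini-Hochberg FDR correction, optionally within groups
#'
#' Applies the step-up FDR procedure separately within each group (the study
#' corrects per analysis window) and reports monotone q-values plus the
#' rejection mask at `alpha`.
#'
#' @param p p-values in `[0, 1]` (NA allowed, passed through).
#' @param alpha nominal FDR level.
#' @param groups optional grouping vector (same length as `p`).
#' @return list with `q` and logical `reject`.
#' @export
fdr_correct <- function(p, alpha = 0.05, groups = NULL) {
  q <- rep(NA_real_, length(p))
  if (is.null(groups)) groups <- rep(1L, length(p))
  for (g in unique(groups)) {
    idx <- which(groups == g & !is.na(p))
    if (length(idx) > 0) q[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Windowed univariate Spearman screening
#'
#' Correlates per-window feature means (and missingness rates) with the POD
#' label across surgeries, then FDR-corrects separately within each window.
#'
#' @param summaries output of [window_summaries()].
#' @param labels labelled surgeries (`surgery_id`, `Y`).
#' @param dependent `"mean_value"` or `"missing_rate"`.
#' @param alpha FDR level.
#' @return `data.frame`: feature, window, `r_s` (absolute), direction, p, q,
#'   n, reject.
#' @export
spearman_screen <- function(summaries, labels, dependent = c("mean_value",
                                                             "missing_rate"),
                            alpha = 0.05) {
  dependent <- match.arg(dependent)
  y <- labels$Y[match(summaries$surgery_id, labels$surgery_id)]
  groups <- split(seq_len(nrow(summaries)),
                  list(summaries$feature, summaries$window), drop = TRUE)
  rows <- lapply(groups, function(idx) {
    r <- spearman_pod(summaries[[dependent]][idx], y[idx])
    data.frame(feature = summaries$feature[idx[1]],
               window = summaries$window[idx[1]],
               r_s = r$r_s, direction = r$direction, p = r$p, n = r$n,
               defined = r$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fdr <- fdr_correct(out$p, alpha = alpha, groups = out$window)
  out$q <- fdr$q
  out$reject <- fdr$reject
  out
}

#' Mixed linear effects model for one feature
#'
#' Fits `dependent ~ target + time + target:time + (1 | pat_id/op_id)`: fixed
#' effects for the binary POD outcome (treatment-coded), the numeric window
#' index (1-3 for three consecutive 30-min intraoperative windows) and their
#' interaction, with nested random intercepts for patient and
#' surgery-within-patient to absorb the patient-surgery hierarchy. The
#' dependent variable is min-max normalized to `[0, 1]` by default so
#' coefficients are comparable across features; p-values are Wald t tests
#' (Satterthwaite degrees of freedom).
#'
#' @param data `data.frame` with columns `value`, `target` (0/1), `time`
#'   (numeric), `pat_id`, `op_id`; one row per surgery-window.
#' @param normalize min-max normalize `value` before fitting.
#' @return list: `coef` (named vector: `c_target`, `c_time`,
#'   `c_time_target`), `p` (matching p-values), `converged`, `n`, `fit`
#'   (the `lmerMod` object).
#' @export
fit_mlem <- function(data, normalize = TRUE) {
  stopifnot(all(c("value", "target", "time", "pat_id", "op_id") %in%
                  names(data)))
  data <- data[stats::complete.cases(data[, c("value", "target", "time")]), ]
  v <- data$value
  if (normalize) {
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  }
  df <- data.frame(value = v, target = data$target, time = data$time,
                   pat_id = factor(data$pat_id), op_id = factor(data$op_id))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ target + time + target:time +
                       (1 | pat_id / op_id), data = df)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(coef = c(c_target = NA_real_, c_time = NA_real_,
                         c_time_target = NA_real_),
                p = c(c_target = NA_real_, c_time = NA_real_,
                      c_time_target = NA_real_),
                converged = FALSE, n = nrow(df), fit = NULL))
  }
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- !any(grepl("failed to converge", msgs))
  sm <- summary(fit)$coefficients
  pick <- function(nm, col) if (nm %in% rownames(sm)) sm[nm, col] else NA_real_
  list(coef = c(c_target = pick("target", "Estimate"),
                c_time = pick("time", "Estimate"),
                c_time_target = pick("target:time", "Estimate")),
       p = c(c_target = pick("target", "Pr(>|t|)"),
             c_time = pick("time", "Pr(>|t|)"),
             c_time_target = pick("target:time", "Pr(>|t|)")),
       converged = converged, n = nrow(df), fit = fit)
}

#' Mixed-model screening across features
#'
#' Builds, per feature, the surgery-by-window dataset from
#' [window_summaries()] over three consecutive begin-anchored 30-min windows
#' (time index 1-3), drops surgeries missing any window listwise, fits
#' [fit_mlem()] for the chosen dependent, and FDR-corrects the `c_target`
#' p-values across features. Non-converged fits are excluded and flagged.
#'
#' @param summaries output of [window_summaries()] for the three windows, in
#'   time order.
#' @param labels labelled surgeries (`surgery_id`, `patient_id`, `Y`).
#' @param dependent `"mean_value"` or `"missing_rate"`.
#' @param alpha FDR level.
#' @return `data.frame`: feature, c_target, c_time, c_time_target, their
#'   p-values, q (FDR on c_target), converged, n.
#' @export
mlem_screen <- function(summaries, labels, dependent = c("mean_value",
                                                         "missing_rate"),
                        alpha = 0.05) {
  dependent <- match.arg(dependent)
  wins <- unique(summaries$window)
  time_idx <- setNames(seq_along(wins), wins)
  lab_i <- match(summaries$surgery_id, labels$surgery_id)
  base <- data.frame(feature = summaries$feature,
                     value = summaries[[dependent]],
                     target = labels$Y[lab_i],
                     time = as.numeric(time_idx[summaries$window]),
                     pat_id = labels$patient_id[lab_i],
                     op_id = summaries$surgery_id,
                     stringsAsFactors = FALSE)
  rows <- lapply(split(base, base$feature), function(d) {
    keep_ops <- names(which(table(d$op_id[!is.na(d$value)]) == length(wins)))
    d <- d[d$op_id %in% keep_ops, ]
    if (nrow(d) == 0) return(NULL)
    r <- fit_mlem(d[, -1], normalize = TRUE)
    data.frame(feature = d$feature[1],
               c_target = r$coef["c_target"], c_time = r$coef["c_time"],
               c_time_target = r$coef["c_time_target"],
               p_target = r$p["c_target"], p_time = r$p["c_time"],
               p_time_target = r$p["c_time_target"],
               converged = r$converged, n = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  p_use <- ifelse(out$converged, out$p_target, NA_real_)
  fdr <- fdr_correct(p_use, alpha = alpha)
  out$q <- fdr$q
  out$reject <- fdr$reject
  out
}
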