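#' Intraoperative observation windows
#'
#' A window `W = [Tx, Ty]` is an interval inside the intraoperative phase,
#' each endpoint given in minutes relative either to the beginning of
#' anesthesia induction (`T_begin`, anchor `"begin"`) or to the end of
#' anesthesia (`T_end`, anchor `"end"`). In the string notation accepted by
#' [parse_window()], a non-negative number is relative to `T_begin`, a
#' negative number is relative to `T_end`, and the words `begin` / `end`
#' denote the phase boundaries themselves; `"full"` is the whole phase.
#'
#' @param t_x,t_y endpoint offsets in minutes.
#' @param anchor_x,anchor_y `"begin"` or `"end"`.
#' @return object of class `observation_window`.
#' @examples
#' observation_window(0, 30)              # first intraoperative 30 minutes
#' parse_window("-30:end")                # last 30 minutes
#' parse_window("full")                   # whole intraoperative phase
#' @export
observation_window <- function(t_x, t_y, anchor_x = "begin",
                               anchor_y = "begin") {
  stopifnot(anchor_x %in% c("begin", "end"), anchor_y %in% c("begin", "end"))
  w <- list(anchor_x = anchor_x, t_x = as.numeric(t_x),
            anchor_y = anchor_y, t_y = as.numeric(t_y))
  class(w) <- "observation_window"
  w
}

#' @rdname observation_window
#' @param spec window in string notation, e.g. `"0:30"`, `"-30:end"`,
#'   `"full"`.
#' @export
parse_window <- function(spec) {
  spec <- trimws(spec)
  if (identical(spec, "full")) return(observation_window(0, 0, "begin", "end"))
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("window spec must be 'a:b' or 'full': ", spec)
  parse_end <- function(p) {
    if (p == "begin") return(list(anchor = "begin", t = 0))
    if (p == "end") return(list(anchor = "end", t = 0))
    v <- suppressWarnings(as.numeric(p))
    if (is.na(v)) stop("bad window endpoint: ", p)
    if (v < 0) list(anchor = "end", t = v) else list(anchor = "begin", t = v)
  }
  a <- parse_end(parts[1]); b <- parse_end(parts[2])
  observation_window(a$t, b$t, a$anchor, b$anchor)
}

#' @export
format.observation_window <- function(x, ...) {
  fmt <- function(anchor, t) {
    if (anchor == "begin" && t == 0) "T_begin"
    else if (anchor == "end" && t == 0) "T_end"
    else if (anchor == "begin") as.character(t)
    else paste0(t, " (from T_end)")
  }
  paste0("[", fmt(x$anchor_x, x$t_x), ", ", fmt(x$anchor_y, x$t_y), "]")
}

#' @export
print.observation_window <- function(x, ...) {
  cat("observation window", format(x), "\n")
  invisible(x)
}

#' Resolve a window to absolute minutes for one surgery
#'
#' @param window an [observation_window()].
#' @param t_end the surgery's anesthesia end in minutes after `T_begin`.
#' @return numeric `c(start, end)`, a half-open interval `[start, end)`.
#' @export
resolve_window <- function(window, t_end) {
  stopifnot(inherits(window, "observation_window"), t_end > 0)
  s <- if (window$anchor_x == "begin") window$t_x else t_end + window$t_x
  e <- if (window$anchor_y == "begin") window$t_y else t_end + window$t_y
  if (s >= e) {
    stop("window ", format(window), " resolves to an empty interval [",
         s, ", ", e, ") at t_end = ", t_end)
  }
  if (s < 0 || e > t_end) {
    stop("window ", format(window), " resolves to [", s, ", ", e,
         "), outside the intraoperative phase [0, ", t_end, "]")
  }
  c(start = s, end = e)
}

# fixed window length shared by all surgeries; NA when it depends on t_end
fixed_window_length <- function(window) {
  if (window$anchor_x == window$anchor_y) window$t_y - window$t_x else NA_real_
}

#' Sequence tensors
#'
#' The model-ready container for time-dynamic data: a surgeries x channels x
#' steps value array plus an identically shaped observation mask (`1` = no
#' observation fell into the grid bin before imputation). Bins are left-closed
#' half-open intervals of `interval_min` minutes anchored at the window start.
#'
#' @param values,mask numeric arrays `m x k x n`.
#' @param channel_names length-`k` character vector.
#' @param surgery_ids length-`m` character vector.
#' @param interval_min grid interval in minutes.
#' @param window the [observation_window()] the tensor was built from.
#' @return object of class `seq_tensor`.
#' @export
seq_tensor <- function(values, mask, channel_names, surgery_ids,
                       interval_min, window = NULL) {
  stopifnot(length(dim(values)) == 3, all(dim(values) == dim(mask)),
            dim(values)[1] == length(surgery_ids),
            dim(values)[2] == length(channel_names),
            all(mask %in% c(0, 1)))
  dimnames(values) <- list(surgery_ids, channel_names, NULL)
  dimnames(mask) <- dimnames(values)
  x <- list(values = values, mask = mask, channel_names = channel_names,
            surgery_ids = surgery_ids, interval_min = interval_min,
            window = window)
  class(x) <- "seq_tensor"
  x
}

#' @export
print.seq_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("seq_tensor:", d[1], "surgeries x", d[2], "channels x", d[3],
      "steps @", x$interval_min, "min",
      if (!is.null(x$window)) paste0(" window ", format(x$window)), "\n")
  cat("missing fraction:", round(mean(x$mask), 3), "\n")
  invisible(x)
}

#' @export
dim.seq_tensor <- function(x) dim(x$values)

#' Resample irregular events onto a regular grid
#'
#' Bin `b` of a surgery covers `[start + b*interval, start + (b+1)*interval)`
#' minutes; its value is the aggregate (`mean` for measurements, `sum` for
#' administered doses) of the observations falling into it, and `NA` with
#' mask 1 when no observation fell into the bin. The number of steps is
#' `floor(window_length / interval_min)`, so the window must resolve to the
#' same length for every surgery.
#'
#' @param events cleaned long-format event table.
#' @param surgeries `data.frame` with `surgery_id` and `t_end` (minutes);
#'   defines row order of the tensor.
#' @param window an [observation_window()].
#' @param interval_min sampling interval in minutes (the study grids are 3
#'   and 5).
#' @param channels feature names to include, in channel order.
#' @param agg `"mean"` or `"sum"` per-bin aggregation.
#' @return an (unimputed) [seq_tensor()].
#' @export
resample_to_grid <- function(events, surgeries, window, interval_min = 3,
                             channels, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  w_len <- fixed_window_length(window)
  if (is.na(w_len)) {
    lens <- vapply(surgeries$t_end,
                   function(te) diff(resolve_window(window, te)), numeric(1))
    if (length(unique(round(lens, 9))) > 1) {
      stop("window ", format(window),
           " has surgery-dependent length; a common grid needs a fixed-length window")
    }
    w_len <- lens[1]
  }
  if (w_len < interval_min) stop("window shorter than one interval")
  n <- floor(w_len / interval_min)
  m <- nrow(surgeries)
  k <- length(channels)

  starts <- vapply(surgeries$t_end,
                   function(te) resolve_window(window, te)[1], numeric(1))
  ev <- data.table::as.data.table(events)
  ev <- ev[feature_name %in% channels & !is.na(value)]
  ev[, `:=`(start = starts[match(surgery_id, surgeries$surgery_id)])]
  ev <- ev[!is.na(start)]
  ev[, bin := floor((t_offset_min - start) / interval_min)]
  ev <- ev[bin >= 0 & bin < n]
  fun <- if (agg == "mean") mean else sum
  agg_dt <- ev[, .(value = fun(value)), by = .(surgery_id, feature_name, bin)]

  values <- array(NA_real_, c(m, k, n))
  mask <- array(1, c(m, k, n))
  si <- match(agg_dt$surgery_id, surgeries$surgery_id)
  ci <- match(agg_dt$feature_name, channels)
  idx <- cbind(si, ci, agg_dt$bin + 1L)
  values[idx] <- agg_dt$value
  mask[idx] <- 0
  seq_tensor(values, mask, channels, surgeries$surgery_id, interval_min, window)
}

#' Append composite feature streams
#'
#' A composite feature (e.g. pooled non-invasive and invasive mean blood
#' pressure) is the plain concatenation of its member event rows under the
#' composite's name; the member streams are kept alongside it, so binning the
#' composite averages whatever members were observed in each bin.
#'
#' @param events long-format event table.
#' @param specs `feature_spec` table declaring composites via `composite_of`.
#' @return event table with composite rows appended.
#' @export
merge_composites <- function(events, specs) {
  members <- composite_members(specs)
  if (length(members) == 0) return(events)
  extra <- lapply(names(members), function(comp) {
    rows <- events[events$feature_name %in% members[[comp]], , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    rows$feature_name <- comp
    rows
  })
  extra <- extra[!vapply(extra, is.null, logical(1))]
  rbind(events, do.call(rbind, extra))
}

#' Running sum of administered doses
#'
#' `cumulative_doses()` turns per-bin administered totals into a running sum:
#' bins before the first administration are 0 and the channel is never
#' missing. `add_cumulative_channels()` appends one such channel (named
#' `<feature>_cum`) per cumulative-flagged feature, computing per-bin totals
#' from the raw events with sum aggregation.
#'
#' @param bin_totals numeric vector of per-bin administered totals (`NA` =
#'   nothing administered).
#' @return numeric vector of the same length, the running sum.
#' @export
cumulative_doses <- function(bin_totals) {
  if (any(!is.na(bin_totals) & bin_totals < 0)) {
    stop("negative dose in cumulative channel")
  }
  x <- ifelse(is.na(bin_totals), 0, bin_totals)
  cumsum(x)
}

#' @rdname cumulative_doses
#' @param tensor a [seq_tensor()].
#' @param events,surgeries,specs as in [resample_to_grid()];
#'   cumulative-flagged features are read from `specs`.
#' @export
add_cumulative_channels <- function(tensor, events, surgeries, specs) {
  cum_feats <- intersect(specs$name[specs$cumulative], tensor$channel_names)
  if (length(cum_feats) == 0) return(tensor)
  dose <- resample_to_grid(events, surgeries, tensor$window,
                           tensor$interval_min, cum_feats, agg = "sum")
  d <- dim(tensor$values)
  n_new <- length(cum_feats)
  values <- array(NA_real_, c(d[1], d[2] + n_new, d[3]))
  mask <- array(1, dim(values))
  values[, seq_len(d[2]), ] <- tensor$values
  mask[, seq_len(d[2]), ] <- tensor$mask
  for (j in seq_len(n_new)) {
    values[, d[2] + j, ] <- t(apply(dose$values[, j, , drop = FALSE], 1,
                                    function(v) cumulative_doses(as.numeric(v))))
    mask[, d[2] + j, ] <- 0
  }
  seq_tensor(values, mask, c(tensor$channel_names, paste0(cum_feats, "_cum")),
             tensor$surgery_ids, tensor$interval_min, tensor$window)
}

#' Append binary missingness-indicator channels
#'
#' For every feature flagged `missing_indicator` in the spec, a channel named
#' `<feature>_miss` equal to the observation mask (1 = bin unobserved) is
#' appended. Domains where absence is not informative (e.g. medical history)
#' simply leave the flag unset. Indicator channels are themselves fully
#' observed (mask 0).
#'
#' @param tensor an unimputed [seq_tensor()].
#' @param specs `feature_spec` table.
#' @return tensor with indicator channels appended.
#' @export
add_missing_indicators <- function(tensor, specs) {
  flagged <- intersect(specs$name[specs$missing_indicator], tensor$channel_names)
  if (length(flagged) == 0) return(tensor)
  d <- dim(tensor$values)
  n_new <- length(flagged)
  values <- array(NA_real_, c(d[1], d[2] + n_new, d[3]))
  mask <- array(1, dim(values))
  values[, seq_len(d[2]), ] <- tensor$values
  mask[, seq_len(d[2]), ] <- tensor$mask
  ci <- match(flagged, tensor$channel_names)
  for (j in seq_len(n_new)) {
    values[, d[2] + j, ] <- tensor$mask[, ci[j], ]
    mask[, d[2] + j, ] <- 0
  }
  seq_tensor(values, mask, c(tensor$channel_names, paste0(flagged, "_miss")),
             tensor$surgery_ids, tensor$interval_min, tensor$window)
}

#' Train-split statistics for imputation and z-scaling
#'
#' All statistics are computed on the training split only and then applied
#' unchanged to validation and test data. For a sequence tensor the
#' imputation means are per-channel means of the observed (pre-imputation)
#' bin values; the scaling mean and standard deviation are computed after
#' imputation. For plain matrices (tabular aggregations, static features)
#' the column means serve both purposes.
#'
#' @param x a [seq_tensor()] or a numeric matrix of training data.
#' @param ... unused.
#' @return object of class `scaler_stats` with `impute_mean`, `center`,
#'   `scale` per channel/column.
#' @export
fit_scaler <- function(x, ...) UseMethod("fit_scaler")

#' @export
fit_scaler.seq_tensor <- function(x, ...) {
  k <- dim(x$values)[2]
  impute_mean <- vapply(seq_len(k), function(j) {
    v <- x$values[, j, ][x$mask[, j, ] == 0]
    if (length(v) == 0) 0 else mean(v)
  }, numeric(1))
  names(impute_mean) <- x$channel_names
  imp <- impute(x, list(impute_mean = impute_mean))
  center <- vapply(seq_len(k), function(j) mean(imp$values[, j, ]), numeric(1))
  scale <- vapply(seq_len(k), function(j) stats::sd(imp$values[, j, ]), numeric(1))
  scale[is.na(scale)] <- 0
  out <- list(impute_mean = impute_mean,
              center = setNames(center, x$channel_names),
              scale = setNames(scale, x$channel_names),
              kind = "seq_tensor")
  class(out) <- "scaler_stats"
  out
}

#' @export
fit_scaler.matrix <- function(x, ...) {
  impute_mean <- colMeans(x, na.rm = TRUE)
  impute_mean[is.na(impute_mean)] <- 0
  xi <- x
  for (j in seq_len(ncol(x))) xi[is.na(xi[, j]), j] <- impute_mean[j]
  scale <- apply(xi, 2, stats::sd)
  scale[is.na(scale)] <- 0
  out <- list(impute_mean = impute_mean, center = colMeans(xi), scale = scale,
              kind = "matrix")
  class(out) <- "scaler_stats"
  out
}

#' Impute a sequence tensor by LOCF plus training means
#'
#' Within each surgery-by-channel series the last observed value is carried
#' forward; bins before the first observation (and fully unobserved series)
#' receive the training-split channel mean. The mask is left untouched, so
#' missingness-indicator channels built from it are unaffected.
#'
#' @param tensor a [seq_tensor()].
#' @param scaler `scaler_stats` fitted on the training split (only
#'   `impute_mean` is used).
#' @return tensor with no missing values.
#' @export
impute <- function(tensor, scaler) {
  mu <- scaler$impute_mean
  missing_ch <- setdiff(tensor$channel_names, names(mu))
  if (length(missing_ch) > 0) {
    stop("scaler lacks imputation means for channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  d <- dim(tensor$values)
  out <- tensor$values
  for (j in seq_len(d[2])) {
    slab <- out[, j, , drop = FALSE]
    dim(slab) <- c(d[1], d[3])
    slab <- t(apply(slab, 1, locf_fill, lead = mu[[tensor$channel_names[j]]]))
    out[, j, ] <- slab
  }
  tensor$values <- out
  tensor
}

# carry last observation forward; leading NAs get `lead`
locf_fill <- function(v, lead) {
  obs <- !is.na(v)
  if (!any(obs)) return(rep(lead, length(v)))
  idx <- cummax(ifelse(obs, seq_along(v), 0L))
  out <- ifelse(idx == 0L, lead, v[pmax(idx, 1L)])
  out
}

#' Apply train-split z-scaling
#'
#' `(x - mean) / sd` per channel/column with training statistics;
#' zero-variance channels map to 0.
#'
#' @param x an imputed [seq_tensor()] or a numeric matrix.
#' @param scaler `scaler_stats` from [fit_scaler()].
#' @return standardized object of the same shape.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "scaler_stats"))
  if (inherits(x, "seq_tensor")) {
    d <- dim(x$values)
    for (j in seq_len(d[2])) {
      ch <- x$channel_names[j]
      s <- scaler$scale[[ch]]
      x$values[, j, ] <- if (s > 0) (x$values[, j, ] - scaler$center[[ch]]) / s
      else 0
    }
    x
  } else {
    for (j in seq_len(ncol(x))) {
      nm <- colnames(x)[j]
      key <- if (!is.null(nm) && nm %in% names(scaler$scale)) nm else j
      x[is.na(x[, j]), j] <- scaler$impute_mean[[key]]
      s <- scaler$scale[[key]]
      x[, j] <- if (s > 0) (x[, j] - scaler$center[[key]]) / s else 0
    }
    x
  }
}

#' Broadcast static features along the time axis
#'
#' Each static feature becomes a constant-in-time channel so it can be fed to
#' sequence models next to the dynamic channels.
#'
#' @param statics numeric matrix surgeries x static features (aligned with the
#'   companion tensor's rows).
#' @param n number of time steps.
#' @param interval_min,window,surgery_ids metadata for the resulting tensor.
#' @return a fully observed [seq_tensor()] `m x k_static x n`.
#' @export
broadcast_static <- function(statics, n, interval_min = 3, window = NULL,
                             surgery_ids = rownames(statics)) {
  m <- nrow(statics); k <- ncol(statics)
  values <- array(rep(as.numeric(statics), n), c(m, k, n))
  mask <- array(0, c(m, k, n))
  if (is.null(surgery_ids)) surgery_ids <- as.character(seq_len(m))
  seq_tensor(values, mask, colnames(statics), surgery_ids, interval_min, window)
}

#' Stack two sequence tensors along the channel axis
#'
#' @param a,b tensors with identical surgeries and step counts.
#' @return combined [seq_tensor()].
#' @export
bind_channels <- function(a, b) {
  stopifnot(identical(a$surgery_ids, b$surgery_ids),
            dim(a$values)[3] == dim(b$values)[3])
  values <- array(NA_real_, dim(a$values) + c(0, dim(b$values)[2], 0))
  mask <- array(1, dim(values))
  ka <- dim(a$values)[2]
  values[, seq_len(ka), ] <- a$values; mask[, seq_len(ka), ] <- a$mask
  values[, ka + seq_len(dim(b$values)[2]), ] <- b$values
  mask[, ka + seq_len(dim(b$values)[2]), ] <- b$mask
  seq_tensor(values, mask, c(a$channel_names, b$channel_names),
             a$surgery_ids, a$interval_min, a$window)
}

#' Full preprocessing pipeline: events to model-ready tensors
#'
#' Fixed stage order: range cleaning, composite streams, grid resampling,
#' cumulative dose channels, missingness indicators, LOCF + training-mean
#' imputation, z-scaling with training statistics. Imputation and scaling
#' statistics are fitted on the training surgeries only.
#'
#' @param events long-format event table.
#' @param surgeries `data.frame` with `surgery_id`, `patient_id`, `t_end`.
#' @param specs `feature_spec` table.
#' @param window an [observation_window()].
#' @param interval_min grid interval (3 or 5 minutes).
#' @param train_patient_ids patients whose surgeries form the training split.
#' @param statics optional per-surgery static table; static features are
#'   z-scaled and returned as a matrix (and can be broadcast with
#'   [broadcast_static()]).
#' @param scale_indicators logical; also z-scale indicator channels (default
#'   `TRUE`).
#' @return list with `train` and `test` (each: `tensor`, `statics` matrix or
#'   `NULL`, `surgery_ids`), the fitted `scaler`, and `removed` (out-of-range
#'   counts).
#' @export
prepare_sequences <- function(events, surgeries, specs, window,
                              interval_min = 3, train_patient_ids,
                              statics = NULL, scale_indicators = TRUE) {
  cleaned <- clean_valid_ranges(events, specs)
  ev <- merge_composites(cleaned$events, specs)
  dyn <- specs$name[specs$time_variance == "dynamic"]
  channels <- intersect(unique(c(dyn)), unique(ev$feature_name))

  build_side <- function(ids) {
    surg <- surgeries[surgeries$patient_id %in% ids, , drop = FALSE]
    tens <- resample_to_grid(ev, surg, window, interval_min, channels)
    tens <- add_cumulative_channels(tens, ev, surg, specs)
    add_missing_indicators(tens, specs)
  }
  train_raw <- build_side(train_patient_ids)
  test_ids <- setdiff(unique(surgeries$patient_id), train_patient_ids)
  test_raw <- if (length(test_ids) > 0) build_side(test_ids) else NULL

  scaler <- fit_scaler(train_raw)
  if (!scale_indicators) {
    ind <- grepl("_miss$", names(scaler$scale))
    scaler$center[ind] <- 0
    scaler$scale[ind] <- 1
  }
  finish <- function(raw) {
    if (is.null(raw)) return(NULL)
    tens <- apply_scaler(impute(raw, scaler), scaler)
    st <- NULL
    if (!is.null(statics)) {
      cols <- intersect(specs$name[specs$time_variance == "static"],
                        names(statics))
      st <- as.matrix(statics[match(raw$surgery_ids, statics$surgery_id),
                              cols, drop = FALSE])
      rownames(st) <- raw$surgery_ids
    }
    list(tensor = tens, statics = st, surgery_ids = raw$surgery_ids)
  }
  out <- list(train = finish(train_raw), test = finish(test_raw),
              scaler = scaler, removed = cleaned$removed)
  if (!is.null(statics) && !is.null(out$train$statics)) {
    st_scaler <- fit_scaler(out$train$statics)
    out$train$statics <- apply_scaler(out$train$statics, st_scaler)
    if (!is.null(out$test)) {
      out$test$statics <- apply_scaler(out$test$statics, st_scaler)
    }
    out$static_scaler <- st_scaler
  }
  out
}

#' Persist / load a sequence tensor as plain text
#'
#' Values and mask are written as CSV (one row per surgery, channels nested in
#' time-major order) with a JSON sidecar holding channel names, surgery ids
#' and grid metadata.
#'
#' @param tensor a [seq_tensor()].
#' @param path base path; writes `<path>_values.csv`, `<path>_mask.csv`,
#'   `<path>.json`.
#' @return base path, invisibly.
#' @export
write_tensor <- function(tensor, path) {
  d <- dim(tensor$values)
  flat <- function(a) {
    m <- matrix(a, nrow = d[1])
    colnames(m) <- as.vector(outer(tensor$channel_names, seq_len(d[3]),
                                   function(ch, t) paste0(ch, "_t", t)))
    m
  }
  utils::write.csv(data.frame(surgery_id = tensor$surgery_ids,
                              flat(tensor$values), check.names = FALSE),
                   paste0(path, "_values.csv"), row.names = FALSE)
  utils::write.csv(data.frame(surgery_id = tensor$surgery_ids,
                              flat(tensor$mask), check.names = FALSE),
                   paste0(path, "_mask.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(channel_names = tensor$channel_names,
         surgery_ids = tensor$surgery_ids,
         interval_min = tensor$interval_min,
         n_steps = d[3],
         window = if (!is.null(tensor$window)) format(tensor$window) else NULL),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- utils::read.csv(paste0(path, "_values.csv"), check.names = FALSE)
  mk <- utils::read.csv(paste0(path, "_mask.csv"), check.names = FALSE)
  m <- nrow(v); k <- length(meta$channel_names); n <- meta$n_steps
  seq_tensor(array(as.matrix(v[, -1]), c(m, k, n)),
             array(as.matrix(mk[, -1]), c(m, k, n)),
             meta$channel_names, v$surgery_id, meta$interval_min)
}
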