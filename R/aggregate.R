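#' Percentile aggregation (TAB_P)
#'
#' Summarizes each imputed dynamic channel by its 10th, 50th and 90th
#' percentiles across the window (linear interpolation between order
#' statistics). Cumulative dose channels (suffix `_cum`) additionally
#' contribute their end-of-window total.
#'
#' @param tensor an imputed [seq_tensor()].
#' @return numeric matrix surgeries x derived features, with `surgery_ids`
#'   row names and columns named `<channel>_p10/_p50/_p90` (and
#'   `<channel>_total`).
#' @export
tab_p <- function(tensor) {
  d <- dim(tensor$values)
  if (d[3] < 1) stop("tensor has no time steps")
  cols <- list()
  for (j in seq_len(d[2])) {
    ch <- tensor$channel_names[j]
    slab <- matrix(tensor$values[, j, ], nrow = d[1])
    qs <- t(apply(slab, 1, stats::quantile, probs = c(0.1, 0.5, 0.9),
                  names = FALSE, type = 7))
    colnames(qs) <- paste0(ch, c("_p10", "_p50", "_p90"))
    cols[[length(cols) + 1L]] <- qs
    if (grepl("_cum$", ch)) {
      tot <- matrix(slab[, d[3]], ncol = 1,
                    dimnames = list(NULL, paste0(ch, "_total")))
      cols[[length(cols) + 1L]] <- tot
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- tensor$surgery_ids
  out
}

#' Hjorth parameters of a series
#'
#' Activity is the population (1/n) variance; mobility is
#' `sqrt(var(diff(x)) / var(x))`; complexity is the mobility of the first
#' difference divided by the mobility of the series. A zero-variance series
#' returns `(0, 0, 0)`.
#'
#' @param series numeric vector, length >= 3.
#' @return named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth <- function(series) {
  n <- length(series)
  if (n < 3) stop("Hjorth parameters need a series of length >= 3")
  pvar <- function(x) mean((x - mean(x))^2)
  a <- pvar(series)
  if (a == 0) {
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(series)
  d2 <- diff(d1)
  mob <- sqrt(pvar(d1) / a)
  mob_d <- if (pvar(d1) == 0) 0 else sqrt(pvar(d2) / pvar(d1))
  comp <- if (mob == 0) 0 else mob_d / mob
  c(activity = a, mobility = mob, complexity = comp)
}

#' Orthonormal Haar wavelet coefficients
#'
#' The series is padded to the next power of two by repeating its last value
#' and transformed with the full-depth orthonormal Haar transform
#' (`s = (a+b)/sqrt(2)`, `d = (a-b)/sqrt(2)` applied recursively to the
#' approximation). Coefficients are returned in level order: the final
#' approximation first, then detail coefficients from coarsest to finest.
#' Orthonormality preserves energy: the sum of squared coefficients equals
#' the sum of squared padded samples.
#'
#' @param series numeric vector, length >= 1.
#' @return numeric vector of `2^ceiling(log2(length(series)))` coefficients.
#' @export
haar_coeffs <- function(series) {
  n <- length(series)
  if (n < 1) stop("empty series")
  npad <- 2^ceiling(log2(max(n, 1)))
  if (npad > n) series <- c(series, rep(series[n], npad - n))
  approx <- series
  details <- list()
  while (length(approx) > 1) {
    odd <- approx[seq(1, length(approx), by = 2)]
    even <- approx[seq(2, length(approx), by = 2)]
    details[[length(details) + 1L]] <- (odd - even) / sqrt(2)
    approx <- (odd + even) / sqrt(2)
  }
  c(approx, unlist(rev(details)))
}

#' Signal-feature aggregation (TAB_F)
#'
#' Concatenates, per channel, the three Hjorth parameters and the full Haar
#' coefficient vector: with `n` steps padded to `p = 2^ceiling(log2(n))`,
#' each channel yields `3 + p` columns.
#'
#' @param tensor an imputed [seq_tensor()].
#' @return numeric matrix surgeries x derived features.
#' @export
tab_f <- function(tensor) {
  d <- dim(tensor$values)
  if (d[3] < 3) stop("TAB_F needs at least 3 time steps")
  npad <- 2^ceiling(log2(d[3]))
  cols <- vector("list", d[2])
  for (j in seq_len(d[2])) {
    ch <- tensor$channel_names[j]
    slab <- matrix(tensor$values[, j, ], nrow = d[1])
    hj <- t(apply(slab, 1, hjorth))
    hw <- t(apply(slab, 1, haar_coeffs))
    block <- cbind(hj, hw)
    colnames(block) <- c(paste0(ch, c("_activity", "_mobility", "_complexity")),
                         paste0(ch, "_haar", seq_len(npad)))
    cols[[j]] <- block
  }
  out <- do.call(cbind, cols)
  rownames(out) <- tensor$surgery_ids
  out
}

#' Vectorized time-series aggregation (TAB_T)
#'
#' Flattens the tensor channel-major, time-minor: channel `f` at steps
#' `1..n` becomes columns `<f>_t1 .. <f>_tn`, e.g. a blood pressure series
#' over 30 min at a 3-min grid becomes the 10 columns `[BP_t1, ..., BP_t10]`.
#'
#' @param tensor an imputed [seq_tensor()].
#' @return numeric matrix surgeries x (channels * steps).
#' @export
tab_t <- function(tensor) {
  d <- dim(tensor$values)
  out <- matrix(NA_real_, d[1], d[2] * d[3])
  nm <- character(d[2] * d[3])
  for (j in seq_len(d[2])) {
    idx <- (j - 1) * d[3] + seq_len(d[3])
    out[, idx] <- matrix(tensor$values[, j, ], nrow = d[1])
    nm[idx] <- paste0(tensor$channel_names[j], "_t", seq_len(d[3]))
  }
  colnames(out) <- nm
  rownames(out) <- tensor$surgery_ids
  out
}

#' Invert [tab_t()] back into a value array
#'
#' @param mat matrix produced by [tab_t()].
#' @param k,n channel and step counts.
#' @return array `m x k x n`.
#' @export
untab_t <- function(mat, k, n) {
  stopifnot(ncol(mat) == k * n)
  out <- array(NA_real_, c(nrow(mat), k, n))
  for (j in seq_len(k)) out[, j, ] <- mat[, (j - 1) * n + seq_len(n)]
  out
}
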