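# finite-difference gradient machinery for checking the hand-written backprop

nn_flat_idx <- function(p, path = character()) {
  if (is.list(p)) {
    out <- list()
    for (nm in seq_along(p)) {
      if (is.null(p[[nm]])) next
      out <- c(out, nn_flat_idx(p[[nm]], c(path, nm)))
    }
    out
  } else {
    lapply(seq_along(p), function(i) list(path = path, i = i))
  }
}

nn_get_at <- function(p, path, i) {
  for (k in path) p <- p[[as.integer(k)]]
  p[i]
}

nn_set_at <- function(p, path, i, v) {
  if (length(path) == 0) { p[i] <- v; return(p) }
  k <- as.integer(path[1])
  p[[k]] <- nn_set_at(p[[k]], path[-1], i, v)
  p
}

nn_num_grad <- function(f, params, eps = 1e-5) {
  idx <- nn_flat_idx(params)
  g <- numeric(length(idx))
  for (j in seq_along(idx)) {
    pa <- idx[[j]]$path; i <- idx[[j]]$i
    v0 <- nn_get_at(params, pa, i)
    g[j] <- (f(nn_set_at(params, pa, i, v0 + eps)) -
               f(nn_set_at(params, pa, i, v0 - eps))) / (2 * eps)
  }
  list(idx = idx, g = g)
}

nn_flatten <- function(gr, idx) {
  vapply(idx, function(e) nn_get_at(gr, e$path, e$i), numeric(1))
}

# a linearly separable toy sequence classification set
toy_seq_data <- function(m = 50, n = 6, k = 2, seed = 3) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = m)
  X <- array(rnorm(m * n * k, sd = 0.3), c(m, n, k))
  for (i in seq_len(m)) {
    if (y[i] == 1) X[i, , 1] <- X[i, , 1] + seq(-1, 1, length.out = n)
  }
  list(X = X, y = y)
}
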