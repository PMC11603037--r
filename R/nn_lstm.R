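# Stacked LSTM with full backpropagation through time. Gate order in the
# combined weight matrix is [input, forget, candidate, output]; the forget
# gate bias is initialized to 1 (standard remedy against early vanishing
# memory).

lstm_init <- function(input_dim, hidden, n_layers = 1L) {
  layers <- vector("list", n_layers)
  p <- input_dim
  for (l in seq_len(n_layers)) {
    W <- matrix(rnorm((p + hidden) * 4 * hidden, 0, sqrt(1 / (p + hidden))),
                p + hidden, 4 * hidden)
    b <- rep(0, 4 * hidden)
    b[hidden + seq_len(hidden)] <- 1
    layers[[l]] <- list(W = W, b = b)
    p <- hidden
  }
  layers
}

lstm_forward <- function(layers, X) {
  B <- dim(X)[1]; n <- dim(X)[2]
  caches <- vector("list", length(layers))
  inp <- X
  for (l in seq_along(layers)) {
    W <- layers[[l]]$W; b <- layers[[l]]$b
    h <- ncol(W) / 4
    H <- array(0, c(B, n, h))
    hp <- matrix(0, B, h); cp <- matrix(0, B, h)
    steps <- vector("list", n)
    for (t in seq_len(n)) {
      xt <- matrix(inp[, t, ], nrow = B)
      zin <- cbind(xt, hp)
      z <- zin %*% W + matrix(b, B, 4 * h, byrow = TRUE)
      ig <- sigmoid(z[, seq_len(h), drop = FALSE])
      fg <- sigmoid(z[, h + seq_len(h), drop = FALSE])
      gg <- tanh(z[, 2 * h + seq_len(h), drop = FALSE])
      og <- sigmoid(z[, 3 * h + seq_len(h), drop = FALSE])
      cc <- fg * cp + ig * gg
      tc <- tanh(cc)
      hh <- og * tc
      steps[[t]] <- list(zin = zin, i = ig, f = fg, g = gg, o = og,
                         c_prev = cp, tc = tc)
      hp <- hh; cp <- cc
      H[, t, ] <- hh
    }
    caches[[l]] <- list(steps = steps, h = h)
    inp <- H
  }
  list(out = hp, seq = inp, caches = caches)
}

# dLast: gradient on the final hidden state of the top layer (B x h)
lstm_backward <- function(layers, cache, dLast) {
  L <- length(layers)
  B <- nrow(dLast)
  n <- length(cache$caches[[1]]$steps)
  grads <- vector("list", L)
  dH_seq <- NULL  # gradient on the current layer's output sequence
  for (l in rev(seq_len(L))) {
    W <- layers[[l]]$W
    h <- cache$caches[[l]]$h
    p <- nrow(W) - h
    steps <- cache$caches[[l]]$steps
    gW <- W * 0; gb <- rep(0, 4 * h)
    dh_next <- matrix(0, B, h); dc_next <- matrix(0, B, h)
    dX <- array(0, c(B, n, p))
    for (t in rev(seq_len(n))) {
      st <- steps[[t]]
      dh <- dh_next
      if (l == L && t == n) dh <- dh + dLast
      if (!is.null(dH_seq)) dh <- dh + matrix(dH_seq[, t, ], nrow = B)
      dc <- dh * st$o * (1 - st$tc^2) + dc_next
      dzi <- (dc * st$g) * st$i * (1 - st$i)
      dzf <- (dc * st$c_prev) * st$f * (1 - st$f)
      dzg <- (dc * st$i) * (1 - st$g^2)
      dzo <- (dh * st$tc) * st$o * (1 - st$o)
      dz <- cbind(dzi, dzf, dzg, dzo)
      gW <- gW + crossprod(st$zin, dz)
      gb <- gb + colSums(dz)
      dzin <- dz %*% t(W)
      dX[, t, ] <- dzin[, seq_len(p), drop = FALSE]
      dh_next <- dzin[, p + seq_len(h), drop = FALSE]
      dc_next <- dc * st$f
    }
    grads[[l]] <- list(W = gW, b = gb)
    dH_seq <- dX
  }
  list(grads = grads, dX = dH_seq)
}
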