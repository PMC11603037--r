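# Encoder-only transformer for sequence classification, written out with
# explicit gradients. The encoder state is kept as a (B*n) x d matrix in
# sample-major row blocks; attention works per sample on n x d blocks.
# Post-norm residual blocks as in the original encoder design:
#   x <- LayerNorm(x + SelfAttention(x)); x <- LayerNorm(x + FFN(x))
# followed by mean-pooling over time and a sigmoid-activated MLP head.

sinusoidal_encoding <- function(n, d) {
  pe <- matrix(0, n, d)
  pos <- seq_len(n) - 1
  for (j in seq_len(d)) {
    i <- (j - 1) %/% 2
    ang <- pos / 10000^(2 * i / d)
    pe[, j] <- if (j %% 2 == 1) sin(ang) else cos(ang)
  }
  pe
}

tran_init <- function(k, n, d, n_layers = 1L, d_ff = 2L * d,
                      pos_encoding = c("sinusoidal", "learnable")) {
  pos_encoding <- match.arg(pos_encoding)
  params <- list(
    proj = list(W = matrix(rnorm(k * d, 0, sqrt(1 / k)), k, d), b = rep(0, d)),
    layers = lapply(seq_len(n_layers), function(l) list(
      Wq = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bq = rep(0, d),
      Wk = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bk = rep(0, d),
      Wv = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bv = rep(0, d),
      Wo = matrix(rnorm(d * d, 0, sqrt(1 / d)), d, d), bo = rep(0, d),
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      W1 = matrix(rnorm(d * d_ff, 0, sqrt(1 / d)), d, d_ff), b1 = rep(0, d_ff),
      W2 = matrix(rnorm(d_ff * d, 0, sqrt(1 / d_ff)), d_ff, d), b2 = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d)
    ))
  )
  if (pos_encoding == "learnable") {
    params$pos <- matrix(rnorm(n * d, 0, 0.02), n, d)
  }
  attr(params, "pos_encoding") <- pos_encoding
  params
}

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, g, `*`)
  Y <- sweep(Y, 2, b, `+`)
  list(out = Y, xhat = xhat, inv = inv)
}

layernorm_backward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

# single-head scaled dot-product self-attention over sample-major blocks
attention_forward <- function(X, lp, B, n) {
  d <- ncol(X)
  Q <- X %*% lp$Wq + matrix(lp$bq, nrow(X), d, byrow = TRUE)
  K <- X %*% lp$Wk + matrix(lp$bk, nrow(X), d, byrow = TRUE)
  V <- X %*% lp$Wv + matrix(lp$bv, nrow(X), d, byrow = TRUE)
  O <- matrix(0, nrow(X), d)
  A_all <- array(0, c(B, n, n))
  sc <- 1 / sqrt(d)
  for (b in seq_len(B)) {
    rows <- (b - 1) * n + seq_len(n)
    S <- Q[rows, , drop = FALSE] %*% t(K[rows, , drop = FALSE]) * sc
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    A_all[b, , ] <- A
    O[rows, ] <- A %*% V[rows, , drop = FALSE]
  }
  out <- O %*% lp$Wo + matrix(lp$bo, nrow(X), d, byrow = TRUE)
  list(out = out, Q = Q, K = K, V = V, O = O, A = A_all)
}

attention_backward <- function(dOut, cache, X, lp, B, n) {
  d <- ncol(X)
  sc <- 1 / sqrt(d)
  dO <- dOut %*% t(lp$Wo)
  gWo <- crossprod(cache$O, dOut)
  gbo <- colSums(dOut)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- (b - 1) * n + seq_len(n)
    A <- matrix(cache$A[b, , ], n, n)
    dOb <- dO[rows, , drop = FALSE]
    dV[rows, ] <- crossprod(A, dOb)
    dA <- dOb %*% t(cache$V[rows, , drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))
    dQ[rows, ] <- dS %*% cache$K[rows, , drop = FALSE] * sc
    dK[rows, ] <- crossprod(dS, cache$Q[rows, , drop = FALSE]) * sc
  }
  dX <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  list(dX = dX,
       grads = list(Wq = crossprod(X, dQ), bq = colSums(dQ),
                    Wk = crossprod(X, dK), bk = colSums(dK),
                    Wv = crossprod(X, dV), bv = colSums(dV),
                    Wo = gWo, bo = gbo))
}

# X: array B x n x k -> list(out = (B*n) x d final encoder state, caches)
tran_forward <- function(params, X) {
  B <- dim(X)[1]; n <- dim(X)[2]; k <- dim(X)[3]
  d <- ncol(params$proj$W)
  Xm <- matrix(aperm(X, c(2, 1, 3)), B * n, k)  # sample-major blocks of n rows
  H <- Xm %*% params$proj$W + matrix(params$proj$b, B * n, d, byrow = TRUE)
  pe <- if (!is.null(params$pos)) params$pos else sinusoidal_encoding(n, d)
  H <- H + pe[rep(seq_len(n), B), , drop = FALSE]
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    lp <- params$layers[[l]]
    att <- attention_forward(H, lp, B, n)
    r1 <- H + att$out
    ln1 <- layernorm_forward(r1, lp$ln1_g, lp$ln1_b)
    Z1 <- ln1$out %*% lp$W1 + matrix(lp$b1, B * n, length(lp$b1), byrow = TRUE)
    A1 <- pmax(Z1, 0)
    F2 <- A1 %*% lp$W2 + matrix(lp$b2, B * n, d, byrow = TRUE)
    r2 <- ln1$out + F2
    ln2 <- layernorm_forward(r2, lp$ln2_g, lp$ln2_b)
    caches[[l]] <- list(H_in = H, att = att, ln1 = ln1, Z1 = Z1, A1 = A1,
                        ln1_out = ln1$out)
    H <- ln2$out
    caches[[l]]$ln2 <- ln2
  }
  list(out = H, caches = caches, Xm = Xm, B = B, n = n)
}

tran_backward <- function(params, cache, dH) {
  B <- cache$B; n <- cache$n
  grads <- list(proj = NULL, layers = vector("list", length(params$layers)))
  for (l in rev(seq_along(params$layers))) {
    lp <- params$layers[[l]]
    cl <- cache$caches[[l]]
    ln2b <- layernorm_backward(dH, cl$ln2, lp$ln2_g)
    dr2 <- ln2b$dX
    dF2 <- dr2
    gW2 <- crossprod(cl$A1, dF2); gb2 <- colSums(dF2)
    dA1 <- dF2 %*% t(lp$W2)
    dZ1 <- dA1 * (cl$Z1 > 0)
    gW1 <- crossprod(cl$ln1_out, dZ1); gb1 <- colSums(dZ1)
    dln1_out <- dr2 + dZ1 %*% t(lp$W1)
    ln1b <- layernorm_backward(dln1_out, cl$ln1, lp$ln1_g)
    dr1 <- ln1b$dX
    attb <- attention_backward(dr1, cl$att, cl$H_in, lp, B, n)
    dH <- dr1 + attb$dX
    grads$layers[[l]] <- c(attb$grads,
                           list(ln1_g = ln1b$dg, ln1_b = ln1b$db,
                                W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                                ln2_g = ln2b$dg, ln2_b = ln2b$db))
  }
  if (!is.null(params$pos)) {
    dpos <- matrix(0, n, ncol(dH))
    for (t in seq_len(n)) {
      dpos[t, ] <- colSums(dH[seq(t, B * n, by = n), , drop = FALSE])
    }
    grads$pos <- dpos
  }
  grads$proj <- list(W = crossprod(cache$Xm, dH), b = colSums(dH))
  list(grads = grads, dX = dH %*% t(params$proj$W))
}

# mean-pool the (B*n) x d encoder state over time -> B x d
pool_mean <- function(H, B, n) {
  d <- ncol(H)
  out <- matrix(0, B, d)
  for (b in seq_len(B)) out[b, ] <- colMeans(H[(b - 1) * n + seq_len(n), , drop = FALSE])
  out
}

pool_mean_backward <- function(dP, B, n) {
  dH <- matrix(0, B * n, ncol(dP))
  for (b in seq_len(B)) {
    dH[(b - 1) * n + seq_len(n), ] <- matrix(dP[b, ] / n, n, ncol(dP),
                                             byrow = TRUE)
  }
  dH
}
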