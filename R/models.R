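#' Model configurations for the POD model zoo
#'
#' Seven variants are supported. `MLP_TAB_P` / `MLP_TAB_F` / `MLP_TAB_T` are
#' fully connected networks with logistic sigmoid hidden units fed with the
#' corresponding tabular aggregation. `LSTM_SEQ` stacks recurrent modules and
#' feeds the last hidden state to an MLP head. `TRAN_SEQ` is the encoder-only
#' transformer: a per-step linear projection into a `tran_linear_dim`-wide
#' learnable space, positional encoding, `tran_encoder_layers` single-head
#' self-attention blocks with feed-forward sublayers, residual connections and
#' layer normalization, mean-pooling over time, and an MLP head. The hybrid
#' variants (`MLP_LSTM_SEQTAB`, `MLP_TRAN_SEQTAB`) run a sequence branch on
#' the dynamic tensor and an MLP branch on the static matrix and fuse the two
#' pre-sigmoid scalars with a linear combiner. Every variant outputs one score
#' in `[0, 1]` per surgery.
#'
#' @param variant one of `"MLP_TAB_P"`, `"MLP_TAB_F"`, `"MLP_TAB_T"`,
#'   `"LSTM_SEQ"`, `"TRAN_SEQ"`, `"MLP_LSTM_SEQTAB"`, `"MLP_TRAN_SEQTAB"`.
#' @param mlp_neurons_per_layer hidden sizes of the MLP (tabular) branch.
#' @param lstm_hidden,lstm_layers LSTM hidden width and number of stacked
#'   modules.
#' @param tran_linear_dim linear projection width; defaults to 32 for
#'   `TRAN_SEQ` and 128 for the combined transformer.
#' @param tran_heads attention heads (the study configuration keeps a single
#'   head; only 1 is supported).
#' @param tran_encoder_layers number of encoder blocks.
#' @param tran_ff_dim feed-forward sublayer width (default `2 *
#'   tran_linear_dim`).
#' @param head_neurons hidden sizes of the MLP head on top of the encoder /
#'   recurrent module.
#' @param pos_encoding `"sinusoidal"` (fixed) or `"learnable"`.
#' @param pooling `"mean"` over time (default) or `"flatten"`.
#' @param loss `"weighted_ce"` or `"focal"`.
#' @param focal_gamma,focal_alpha focal-loss parameters.
#' @param pos_weight positive-class weight for weighted cross-entropy;
#'   `NULL` = use `N_neg / N_pos` of the training fold.
#' @param learning_rate,batch_size optimizer settings (Adam).
#' @param max_epochs,patience early-stopping settings.
#' @param seed seed for weight initialization and batch shuffling.
#' @return list of class `model_config`.
#' @export
model_config <- function(variant = c("TRAN_SEQ", "LSTM_SEQ", "MLP_TAB_P",
                                     "MLP_TAB_F", "MLP_TAB_T",
                                     "MLP_LSTM_SEQTAB", "MLP_TRAN_SEQTAB"),
                         mlp_neurons_per_layer = c(16, 8),
                         lstm_hidden = 16, lstm_layers = 1L,
                         tran_linear_dim = NULL, tran_heads = 1L,
                         tran_encoder_layers = 1L, tran_ff_dim = NULL,
                         head_neurons = 8,
                         pos_encoding = c("sinusoidal", "learnable"),
                         pooling = c("mean", "flatten"),
                         loss = c("weighted_ce", "focal"),
                         focal_gamma = 2, focal_alpha = 0.25,
                         pos_weight = NULL,
                         learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 100L, patience = 10L, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(tran_linear_dim)) {
    tran_linear_dim <- if (variant == "MLP_TRAN_SEQTAB") 128L else 32L
  }
  if (is.null(tran_ff_dim)) tran_ff_dim <- 2L * tran_linear_dim
  if (tran_heads != 1L) {
    stop("only a single attention head is supported (the tuned study configuration)")
  }
  stopifnot(all(mlp_neurons_per_layer >= 1), all(head_neurons >= 1),
            lstm_hidden >= 1, lstm_layers >= 1, tran_encoder_layers >= 1)
  cfg <- list(variant = variant,
              mlp_neurons_per_layer = mlp_neurons_per_layer,
              lstm_hidden = lstm_hidden, lstm_layers = lstm_layers,
              tran_linear_dim = tran_linear_dim, tran_heads = tran_heads,
              tran_encoder_layers = tran_encoder_layers,
              tran_ff_dim = tran_ff_dim, head_neurons = head_neurons,
              pos_encoding = match.arg(pos_encoding),
              pooling = match.arg(pooling),
              loss = match.arg(loss), focal_gamma = focal_gamma,
              focal_alpha = focal_alpha, pos_weight = pos_weight,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

is_seq_variant <- function(variant) variant %in% c("LSTM_SEQ", "TRAN_SEQ")
is_hybrid_variant <- function(variant) {
  variant %in% c("MLP_LSTM_SEQTAB", "MLP_TRAN_SEQTAB")
}

#' Build an untrained model from a configuration
#'
#' @param config a [model_config()].
#' @param input_shape list describing the inputs: `k` (channels) and `n`
#'   (steps) for sequence models, `p` (columns) for tabular models, both for
#'   hybrids.
#' @return object of class `pod_model` with seeded initial weights.
#' @export
build_model <- function(config, input_shape) {
  stopifnot(inherits(config, "model_config"))
  v <- config$variant
  params <- local_seed(config$seed, {
    if (v %in% c("MLP_TAB_P", "MLP_TAB_F", "MLP_TAB_T")) {
      stopifnot(!is.null(input_shape$p))
      list(head = dense_init(input_shape$p, config$mlp_neurons_per_layer, 1L))
    } else if (v == "LSTM_SEQ") {
      stopifnot(!is.null(input_shape$k), !is.null(input_shape$n))
      list(lstm = lstm_init(input_shape$k, config$lstm_hidden,
                            config$lstm_layers),
           head = dense_init(config$lstm_hidden, config$head_neurons, 1L))
    } else if (v == "TRAN_SEQ") {
      stopifnot(!is.null(input_shape$k), !is.null(input_shape$n))
      d <- config$tran_linear_dim
      head_in <- if (config$pooling == "mean") d else d * input_shape$n
      list(tran = tran_init(input_shape$k, input_shape$n, d,
                            config$tran_encoder_layers, config$tran_ff_dim,
                            config$pos_encoding),
           head = dense_init(head_in, config$head_neurons, 1L))
    } else {
      stop("use build_hybrid() for combined variants")
    }
  })
  structure(list(config = config, params = params, input_shape = input_shape,
                 trained = FALSE),
            class = "pod_model")
}

#' Build a hybrid (sequence + tabular) fusion model
#'
#' Each branch emits a pre-sigmoid scalar; a 2-weight-plus-bias linear
#' combiner followed by the logistic sigmoid yields the final score.
#'
#' @param seq_config [model_config()] for the sequence branch (`LSTM_SEQ` or
#'   `TRAN_SEQ`).
#' @param mlp_config [model_config()] for the tabular branch (any MLP
#'   variant).
#' @param input_shape list with `k`, `n` (sequence) and `p` (tabular).
#' @return object of class `pod_model` with a hybrid variant name.
#' @export
build_hybrid <- function(seq_config, mlp_config, input_shape) {
  stopifnot(is_seq_variant(seq_config$variant))
  seq_model <- build_model(seq_config,
                           input_shape[c("k", "n")])
  tab_model <- build_model(mlp_config, list(p = input_shape$p))
  variant <- if (seq_config$variant == "LSTM_SEQ") "MLP_LSTM_SEQTAB"
  else "MLP_TRAN_SEQTAB"
  cfg <- seq_config
  cfg$variant <- variant
  params <- list(seq_branch = seq_model$params, tab_branch = tab_model$params,
                 comb = list(w = c(0.5, 0.5), b = 0))
  structure(list(config = cfg, seq_config = seq_config,
                 mlp_config = mlp_config, params = params,
                 input_shape = input_shape, trained = FALSE),
            class = "pod_model")
}

# batch: list(seq = B x n x k array or NULL, tab = B x p matrix or NULL)
forward_pod <- function(model, batch, keep_attention = FALSE) {
  v <- model$config$variant
  p <- model$params
  if (v %in% c("MLP_TAB_P", "MLP_TAB_F", "MLP_TAB_T")) {
    fw <- dense_forward(p$head, batch$tab)
    list(logit = as.numeric(fw$out), cache = list(head = fw))
  } else if (v == "LSTM_SEQ") {
    lf <- lstm_forward(p$lstm, batch$seq)
    hf <- dense_forward(p$head, lf$out)
    list(logit = as.numeric(hf$out), cache = list(lstm = lf, head = hf))
  } else if (v == "TRAN_SEQ") {
    tf <- tran_forward(p$tran, batch$seq)
    B <- tf$B; n <- tf$n
    pooled <- if (model$config$pooling == "mean") pool_mean(tf$out, B, n)
    else matrix(t(matrix(tf$out, ncol = ncol(tf$out))), B, byrow = TRUE)
    hf <- dense_forward(p$head, pooled)
    out <- list(logit = as.numeric(hf$out),
                cache = list(tran = tf, head = hf, pooled = pooled))
    if (keep_attention) {
      L <- length(tf$caches)
      out$attention <- tf$caches[[L]]$att$A
    }
    out
  } else {
    seq_model <- list(config = model$seq_config, params = p$seq_branch)
    tab_model <- list(config = model$mlp_config, params = p$tab_branch)
    class(seq_model) <- class(tab_model) <- "pod_model"
    sf <- forward_pod(seq_model, batch, keep_attention)
    tf <- forward_pod(tab_model, batch)
    logit <- p$comb$w[1] * sf$logit + p$comb$w[2] * tf$logit + p$comb$b
    out <- list(logit = logit, cache = list(seq = sf, tab = tf))
    if (!is.null(sf$attention)) out$attention <- sf$attention
    out
  }
}

backward_pod <- function(model, batch, cache, dlogit) {
  v <- model$config$variant
  p <- model$params
  if (v %in% c("MLP_TAB_P", "MLP_TAB_F", "MLP_TAB_T")) {
    hb <- dense_backward(p$head, cache$head, matrix(dlogit, ncol = 1))
    list(head = hb$grads)
  } else if (v == "LSTM_SEQ") {
    hb <- dense_backward(p$head, cache$head, matrix(dlogit, ncol = 1))
    lb <- lstm_backward(p$lstm, cache$lstm, hb$dX)
    list(lstm = lb$grads, head = hb$grads)
  } else if (v == "TRAN_SEQ") {
    hb <- dense_backward(p$head, cache$head, matrix(dlogit, ncol = 1))
    B <- cache$tran$B; n <- cache$tran$n
    dH <- if (model$config$pooling == "mean") {
      pool_mean_backward(hb$dX, B, n)
    } else {
      d <- ncol(cache$tran$out)
      m <- matrix(0, B * n, d)
      for (b in seq_len(B)) {
        m[(b - 1) * n + seq_len(n), ] <- matrix(hb$dX[b, ], n, d, byrow = TRUE)
      }
      m
    }
    tb <- tran_backward(p$tran, cache$tran, dH)
    list(tran = tb$grads, head = hb$grads)
  } else {
    seq_model <- list(config = model$seq_config, params = p$seq_branch)
    tab_model <- list(config = model$mlp_config, params = p$tab_branch)
    class(seq_model) <- class(tab_model) <- "pod_model"
    gseq <- backward_pod(seq_model, batch, cache$seq$cache,
                         dlogit * p$comb$w[1])
    gtab <- backward_pod(tab_model, batch, cache$tab$cache,
                         dlogit * p$comb$w[2])
    list(seq_branch = gseq, tab_branch = gtab,
         comb = list(w = c(sum(dlogit * cache$seq$logit),
                           sum(dlogit * cache$tab$logit)),
                     b = sum(dlogit)))
  }
}

# seq_tensor -> B x n x k array in model orientation
tensor_to_input <- function(tensor) aperm(tensor$values, c(1, 3, 2))

as_model_batch <- function(model, newdata) {
  if (inherits(newdata, "seq_tensor")) {
    batch <- list(seq = tensor_to_input(newdata), tab = NULL)
  } else if (is.matrix(newdata)) {
    batch <- list(seq = NULL, tab = newdata)
  } else if (is.array(newdata) && length(dim(newdata)) == 3) {
    batch <- list(seq = newdata, tab = NULL)
  } else {
    batch <- newdata
    if (inherits(batch$seq, "seq_tensor")) batch$seq <- tensor_to_input(batch$seq)
  }
  shp <- model$input_shape
  if (!is.null(batch$seq) && !is.null(shp$k) && dim(batch$seq)[3] != shp$k) {
    stop("sequence input has ", dim(batch$seq)[3], " channels but the model",
         " expects ", shp$k)
  }
  if (!is.null(batch$tab) && !is.null(shp$p) && ncol(batch$tab) != shp$p) {
    stop("tabular input has ", ncol(batch$tab), " columns but the model",
         " expects ", shp$p)
  }
  batch
}

#' Predict POD scores
#'
#' @param object a `pod_model`.
#' @param newdata a [seq_tensor()], a tabular matrix, or a list with `seq`
#'   and/or `tab` components (hybrids need both).
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`, one per surgery.
#' @export
predict.pod_model <- function(object, newdata, ...) {
  batch <- as_model_batch(object, newdata)
  sigmoid(forward_pod(object, batch)$logit)
}

slice_batch <- function(batch, idx) {
  list(seq = if (!is.null(batch$seq)) batch$seq[idx, , , drop = FALSE],
       tab = if (!is.null(batch$tab)) batch$tab[idx, , drop = FALSE])
}

#' Train a model with early stopping
#'
#' Mini-batch Adam on the configured loss. Training stops when the validation
#' loss has not improved (decreased) for `patience` consecutive epochs; the
#' weights from the best epoch are restored. The positive-class weight for
#' weighted cross-entropy defaults to `N_neg / N_pos` of the training fold.
#'
#' @param model a `pod_model` from [build_model()] / [build_hybrid()].
#' @param x,y training inputs (see [predict.pod_model()]) and binary labels.
#' @param val_x,val_y validation inputs and labels (drive early stopping).
#' @param max_epochs,patience override the config settings.
#' @param verbose print per-epoch losses.
#' @return the trained `pod_model`; `$log` holds per-epoch train/validation
#'   loss and `$best_epoch` the restored epoch.
#' @export
train_with_early_stopping <- function(model, x, y, val_x, val_y,
                                      max_epochs = model$config$max_epochs,
                                      patience = model$config$patience,
                                      verbose = FALSE) {
  stopifnot(patience >= 1)
  cfg <- model$config
  train_batch <- as_model_batch(model, x)
  val_batch <- as_model_batch(model, val_x)
  if (length(val_y) == 0) stop("empty validation set")
  m <- length(y)
  pos_weight <- cfg$pos_weight
  if (is.null(pos_weight)) {
    pos_weight <- if (sum(y == 1) > 0) sum(y == 0) / sum(y == 1) else 1
  }
  loss_args <- list(loss = cfg$loss, pos_weight = pos_weight,
                    gamma = cfg$focal_gamma, alpha = cfg$focal_alpha)
  eval_loss <- function(params, batch, labels) {
    mdl <- model; mdl$params <- params
    z <- forward_pod(mdl, batch)$logit
    do.call(loss_and_grad, c(list(z = z, y = labels), loss_args))$value
  }

  params <- model$params
  opt <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  wait <- 0L
  local_seed(cfg$seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(m)
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        mdl <- model; mdl$params <- params
        bb <- slice_batch(train_batch, bi)
        fw <- forward_pod(mdl, bb)
        lg <- do.call(loss_and_grad, c(list(z = fw$logit, y = y[bi]), loss_args))
        gr <- backward_pod(mdl, bb, fw$cache, lg$grad)
        up <- adam_update(params, gr, opt, lr = cfg$learning_rate)
        params <- up$params; opt <- up$state
        ep_loss <- ep_loss + lg$value * length(bi)
      }
      vl <- eval_loss(params, val_batch, val_y)
      log[nrow(log) + 1L, ] <- list(epoch, ep_loss / m, vl)
      if (verbose) message(sprintf("epoch %3d train %.4f val %.4f",
                                   epoch, ep_loss / m, vl))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$log <- log
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$loss
  model$pos_weight <- pos_weight
  model
}

#' Parameter counts per model component
#'
#' @param model a `pod_model`.
#' @return named integer vector of parameter counts (and `total`).
#' @export
describe_model <- function(model) {
  count <- function(x) {
    if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  }
  comps <- vapply(model$params, count, numeric(1))
  c(comps, total = sum(comps))
}

#' Extract and aggregate attention weights
#'
#' Runs the encoder on a batch and returns, from the final encoder block's
#' single head: the raw query-by-key attention matrix averaged over
#' surgeries; the per-time attention mass `a_t` (mean attention received by
#' each time index, per surgery and averaged); and the feature-by-time
#' saliency `S[f, t] = w_f * a_t`, where `w_f` is the L1-normalized magnitude
#' of the input-projection weights for channel `f`. Attention rows are
#' softmax-normalized, so every row of the raw matrix sums to 1 and `S` is
#' non-negative.
#'
#' @param model a trained `TRAN_SEQ` (or combined transformer) `pod_model`.
#' @param newdata a [seq_tensor()] (or hybrid input list).
#' @return object of class `attention_matrix`: list with `attention` (n x n),
#'   `time_profile` (length n), `per_surgery_time` (m x n), `saliency`
#'   (k x n), `channel_names`, `time_min`.
#' @export
extract_attention <- function(model, newdata) {
  v <- model$config$variant
  if (!(v %in% c("TRAN_SEQ", "MLP_TRAN_SEQTAB"))) {
    stop("attention extraction requires a transformer variant, got ", v)
  }
  tensor <- if (inherits(newdata, "seq_tensor")) newdata else newdata$seq
  batch <- as_model_batch(model, newdata)
  fw <- forward_pod(model, batch, keep_attention = TRUE)
  A <- fw$attention  # B x n x n
  B <- dim(A)[1]; n <- dim(A)[2]
  A_mean <- apply(A, c(2, 3), mean)
  per_surgery <- t(apply(A, 1, function(a) colMeans(matrix(a, n, n))))
  proj_W <- if (v == "TRAN_SEQ") model$params$tran$proj$W
  else model$params$seq_branch$tran$proj$W
  w_f <- rowSums(abs(proj_W))
  w_f <- w_f / sum(w_f)
  a_t <- colMeans(A_mean)
  S <- outer(w_f, a_t)
  ch <- if (!is.null(tensor)) tensor$channel_names else rownames(proj_W)
  rownames(S) <- ch
  interval <- if (!is.null(tensor)) tensor$interval_min else NA
  structure(list(attention = A_mean, time_profile = a_t,
                 per_surgery_time = per_surgery, saliency = S,
                 channel_names = ch,
                 time_min = seq_len(n) * interval),
            class = "attention_matrix")
}
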