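#' Classifier hyperparameters
#'
#' Defaults follow the published settings for this architecture: Adam, batch
#' size 32, 100 epochs, dropout 0.5 on the pooled feature vector, learning
#' rate 2e-4, two self-attention layers, convolution windows 2/3/4 with 100
#' filters each.
#'
#' @param epochs Training epochs.
#' @param batch_size Samples per Adam update.
#' @param learning_rate Adam step size.
#' @param dropout Dropout rate applied to the pooled feature vector Z before
#'   the fully connected layer (training only).
#' @param n_filters Convolution filters per window size.
#' @param windows Integer vector of convolution window widths.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return An object of class `"sac_config"`.
#' @export
sac_config <- function(epochs = 100, batch_size = 32, learning_rate = 2e-4,
                       dropout = 0.5, n_filters = 100, windows = c(2, 3, 4),
                       seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            dropout >= 0, dropout < 1, n_filters >= 1, all(windows >= 1))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 n_filters = as.integer(n_filters),
                 windows = as.integer(sort(windows)),
                 seed = as.integer(seed)),
            class = "sac_config")
}

#' Initialize classifier parameters
#'
#' All weights start uniform in (-0.1, 0.1); biases at zero. Attention
#' query/key/value maps are square (`k x k`) so the two layers compose.
#'
#' @param k Row dimension of the input relation matrix (embedding dimension).
#' @param m Number of indicators (columns of the relation matrix).
#' @param config A [sac_config()].
#' @return A list of parameter matrices (two attention layers, one filter
#'   bank per window size, fully connected weights).
#' @export
init_sac_params <- function(k, m, config = sac_config()) {
  if (m < max(config$windows)) {
    stop("need at least as many indicators as the largest window size",
         call. = FALSE)
  }
  set.seed(config$seed)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)
  conv <- lapply(config$windows, function(h) {
    list(W = u(config$n_filters, h * k), b = rep(0, config$n_filters),
         h = as.integer(h))
  })
  n_total <- length(config$windows) * config$n_filters
  list(wq1 = u(k, k), wk1 = u(k, k), wv1 = u(k, k),
       wq2 = u(k, k), wk2 = u(k, k), wv2 = u(k, k),
       conv = conv, fc_w = u(2, n_total), fc_b = rep(0, 2))
}

col_softmax <- function(S) {
  S <- sweep(S, 2, apply(S, 2, max))
  E <- exp(S)
  sweep(E, 2, colSums(E), "/")
}

#' One self-attention layer
#'
#' Maps the input matrix `E` (columns = indicator positions) through
#' `Q = w_q E`, `K = w_k E`, `V = w_v E` and returns
#' `V %*% softmax(K'Q / sqrt(D_k))`, where the softmax normalizes each column
#' and `D_k` is the query dimension. Every output column is therefore a convex
#' combination of the columns of `V`.
#'
#' @param E `k x m` input matrix.
#' @param w_q,w_k,w_v Projection matrices with `k` columns.
#' @return The `v x m` output matrix, with the `m x m` attention weight matrix
#'   (columns = query positions) attached as attribute `"weights"`.
#' @export
attention_layer <- function(E, w_q, w_k, w_v) {
  if (ncol(w_q) != nrow(E) || ncol(w_k) != nrow(E) || ncol(w_v) != nrow(E)) {
    stop("attention projection shapes do not match the input", call. = FALSE)
  }
  Q <- w_q %*% E
  K <- w_k %*% E
  V <- w_v %*% E
  A <- col_softmax(crossprod(K, Q) / sqrt(nrow(Q)))
  H <- V %*% A
  attr(H, "weights") <- A
  H
}

#' Apply the stacked self-attention block
#'
#' The second layer consumes the first layer's output; no residual connections
#' or normalization layers are inserted between them.
#'
#' @param E `k x m` input matrix.
#' @param params Parameter list from [init_sac_params()].
#' @return The `k x m` attended matrix, with the first layer's weight matrix
#'   attached as attribute `"weights1"`.
#' @export
stack_attention <- function(E, params) {
  H1 <- attention_layer(E, params$wq1, params$wk1, params$wv1)
  A1 <- attr(H1, "weights")
  H2 <- attention_layer(H1, params$wq2, params$wk2, params$wv2)
  attr(H2, "weights") <- NULL
  attr(H2, "weights1") <- A1
  H2
}

#' Multi-window convolution with max-over-positions pooling
#'
#' Treats the `m` columns of the attended matrix as a sequence; each filter of
#' window width `h` produces a feature map of length `m - h + 1` by
#' `relu(<filter, flattened window> + bias)`, which is max-pooled to a single
#' value. The pooled values are concatenated window-by-window (filters within
#' a window in order) into the feature vector `Z`.
#'
#' @param E_attn `d x m` attended matrix.
#' @param conv The `conv` component of a parameter list from
#'   [init_sac_params()].
#' @return Numeric vector `Z` of length `sum(filters per window)`.
#' @export
conv_pool <- function(E_attn, conv) {
  m <- ncol(E_attn)
  out <- lapply(conv, function(cw) {
    h <- cw$h
    if (m < h) {
      stop("input has fewer columns (", m, ") than window size ", h,
           call. = FALSE)
    }
    n_pos <- m - h + 1L
    X <- vapply(seq_len(n_pos),
                function(p) as.vector(E_attn[, p:(p + h - 1L)]),
                numeric(h * nrow(E_attn)))
    maps <- pmax(cw$W %*% X + cw$b, 0)
    apply(maps, 1, max)
  })
  unlist(out, use.names = FALSE)
}

#' Output layer: scores and class probabilities
#'
#' Affine map of the pooled feature vector to a length-2 score vector,
#' followed by a softmax.
#'
#' @param Z Pooled feature vector.
#' @param fc_w `2 x length(Z)` weight matrix.
#' @param fc_b Length-2 bias.
#' @return A list with `scores` (length 2), `probs` (length 2, summing to 1).
#' @export
predict_scores <- function(Z, fc_w, fc_b) {
  if (ncol(fc_w) != length(Z)) {
    stop("fully connected weights do not match |Z|", call. = FALSE)
  }
  s <- drop(fc_w %*% Z + fc_b)
  e <- exp(s - max(s))
  list(scores = s, probs = e / sum(e))
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum(y*log(p) + (1-y)*log(1-p))`, with `p` the predicted
#' probability of the positive class. Probabilities are clamped to
#' `[eps, 1 - eps]` to avoid `log(0)`.
#'
#' @param p Predicted probabilities of class 1.
#' @param y Binary labels (0/1).
#' @param eps Clamp width (default 1e-7).
#' @return Nonnegative scalar loss.
#' @export
cross_entropy_loss <- function(p, y, eps = 1e-7) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# full single-sample forward pass in R (definitional reference path)
sac_forward_r <- function(E, params) {
  H2 <- stack_attention(E, params)
  Z <- conv_pool(H2, params$conv)
  out <- predict_scores(Z, params$fc_w, params$fc_b)
  out$Z <- Z
  out$attention1 <- attr(H2, "weights1")
  out
}

#' Train the attention-convolution classifier
#'
#' Minimizes the cross-entropy loss by Adam with minibatches, applying
#' inverted dropout to the pooled feature vector during training. Per-epoch
#' mean training loss (and test loss, when a held-out set is supplied) is
#' recorded. Deterministic given `config$seed`.
#'
#' @param E `k x m x n` array of encoded patients (from [encode_cohort()] or
#'   `encode_learned()$E`).
#' @param y Binary labels (0/1), length `n`; both classes must be present.
#' @param config A [sac_config()].
#' @param test Optional list `list(E =, y =)` of held-out data for the loss
#'   history.
#' @param table Optional `n_entities x k` embedding table to train jointly
#'   with the classifier (the learned-embedding ablation); requires `index`.
#' @param index Optional `m x n` 1-based entity index matrix from
#'   [encode_learned()] (and `test$index` when `test` is given).
#' @return An object of class `"sac_model"`: trained parameters, loss
#'   history, configuration, and (in the ablation) the trained table.
#' @export
train_sac <- function(E, y, config = sac_config(), test = NULL,
                      table = NULL, index = NULL) {
  stopifnot(length(dim(E)) == 3, dim(E)[3] == length(y),
            all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; both classes are required",
         call. = FALSE)
  }
  k <- dim(E)[1]; m <- dim(E)[2]
  params <- init_sac_params(k, m, config)
  order <- dimnames(E)[[2]]
  use_table <- !is.null(table)
  if (use_table && is.null(index)) {
    stop("joint table training requires the entity index matrix",
         call. = FALSE)
  }
  if (config$epochs == 0L) {
    return(new_sac_model(params, history = NULL, config, order, table))
  }
  set.seed(config$seed + 1L)
  has_test <- !is.null(test)
  fit <- sac_train_cpp(
    E = E, y = as.integer(y), params = params,
    epochs = config$epochs, batch_size = config$batch_size,
    lr = config$learning_rate, dropout = config$dropout,
    E_test = if (has_test) test$E else array(0, c(k, m, 0)),
    y_test = if (has_test) as.integer(test$y) else integer(0),
    use_table = use_table,
    index = if (use_table) index else matrix(0L, 0, 0),
    index_test = if (use_table && has_test) test$index else matrix(0L, 0, 0),
    table = if (use_table) table else matrix(0, 0, 0))
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = drop(fit$train_loss))
  if (has_test) history$test_loss <- drop(fit$test_loss)
  new_sac_model(fit$params, history, config, order,
                if (use_table) fit$table else NULL)
}

new_sac_model <- function(params, history, config, order, table = NULL) {
  structure(list(params = params, history = history, config = config,
                 indicator_order = order, table = table),
            class = "sac_model")
}

#' @export
print.sac_model <- function(x, ...) {
  k <- nrow(x$params$wq1)
  cat(sprintf("<sac_model> k = %d, %d filters, %s\n", k,
              ncol(x$params$fc_w),
              if (is.null(x$history)) "untrained"
              else sprintf("trained %d epochs (final loss %.4f)",
                           nrow(x$history),
                           x$history$train_loss[nrow(x$history)])))
  invisible(x)
}

#' Predict class probabilities for encoded patients
#'
#' @param object A trained `sac_model`.
#' @param E `k x m x n` array of encoded patients.
#' @param threshold Decision threshold on the probability of class 1.
#' @param ... Unused.
#' @return A data frame with `prob0`, `prob1`, and `class` (0/1 at the
#'   threshold).
#' @export
predict.sac_model <- function(object, E, threshold = 0.5, ...) {
  fwd <- sac_forward_cpp(E, object$params)
  probs <- fwd$probs
  data.frame(prob0 = probs[, 1], prob1 = probs[, 2],
             class = as.integer(probs[, 2] > threshold))
}

#' Export mean attention weights
#'
#' Averages the first attention layer's `m x m` weight matrix over a dataset
#' and orients it so that rows index the querying indicator and columns the
#' attended indicator; each row sums to 1.
#'
#' @param model A trained `sac_model`.
#' @param E `k x m x n` array of encoded patients.
#' @return `m x m` matrix of mean attention weights, with indicator names as
#'   dimnames when available.
#' @export
export_attention <- function(model, E) {
  if (is.null(model$history)) {
    stop("model has not been trained", call. = FALSE)
  }
  fwd <- sac_forward_cpp(E, model$params)
  W <- t(fwd$mean_attention1)  # rows = query indicator
  nms <- model$indicator_order
  if (!is.null(nms)) dimnames(W) <- list(nms, nms)
  W
}
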