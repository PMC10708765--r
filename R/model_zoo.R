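# The nine-member fusion model zoo: {early, intermediate, late} fusion x
# {Bi-LSTM, window-block LSTM, transformer} backbones, with additive
# attention pooling and sigmoid prediction heads.
#
# Early fusion feeds all 40 features to one backbone. Intermediate fusion
# runs one backbone + attention pool per feature group (Pose, Gaze, AU_r,
# AU_c), concatenates the pooled vectors and applies one head. Late fusion
# runs a complete per-group model to a per-group probability and averages
# the four probabilities.

FUSIONS <- c("early", "intermediate", "late")
BACKBONES <- c("bilstm", "window_block_lstm", "transformer")

default_group_hidden <- function(backbone) {
  if (backbone == "bilstm") {
    c(Pose = 64, Gaze = 16, AU_r = 128, AU_c = 128)
  } else {
    c(Pose = 32, Gaze = 32, AU_r = 64, AU_c = 64)
  }
}

default_head_widths <- function(fusion, backbone) {
  base <- switch(backbone,
    bilstm = switch(fusion, early = c(64, 32, 1),
                    intermediate = c(128, 64, 1), late = c(128, 64, 1)),
    window_block_lstm = switch(fusion, early = c(32, 16, 1),
                               intermediate = c(128, 64, 32, 16, 1),
                               late = c(128, 64, 32, 16, 1)),
    transformer = c(64, 32, 1)
  )
  if (fusion == "late") { # late heads double the intermediate widths
    base <- c(2 * base[-length(base)], 1)
  }
  base
}

#' Configure a fusion classifier
#'
#' Captures the architecture of one model-zoo member. Defaults follow the
#' reference design: early Bi-LSTM has 128 hidden units with head
#' (64, 32, 1); intermediate Bi-LSTM group widths are
#' Pose/Gaze/AU_r/AU_c = 64/16/128/128; intermediate window-block LSTM group
#' widths are 32/32/64/64 with head (128, 64, 32, 16, 1); window-block
#' models reshape the horizon into consecutive 30-frame (1 s) windows
#' (660 x 30 at the 19,800-frame clinical horizon); the transformer uses one
#' block with key/query size 512, a single head and a 2048-unit feed-forward
#' layer after mean-pooling every 15 frames; late-fusion heads double the
#' intermediate widths.
#'
#' @param fusion One of `"early"`, `"intermediate"`, `"late"`.
#' @param backbone One of `"bilstm"`, `"window_block_lstm"`, `"transformer"`.
#' @param horizon Input sequence length in frames.
#' @param group_hidden Named per-group recurrent widths (intermediate/late);
#'   for early fusion a single width may be given.
#' @param head_widths Feed-forward unit list, terminating in 1.
#' @param window_len Window length in frames for window-block models.
#' @param transformer List with `blocks`, `head_size`, `n_heads`, `ff_dim`,
#'   `pool_stride`.
#' @param attn_dim Projection width of the additive attention scorer.
#' @return A `model_config`.
#' @export
model_config <- function(fusion = c("intermediate", "early", "late"),
                         backbone = c("window_block_lstm", "bilstm", "transformer"),
                         horizon = 19800L,
                         group_hidden = NULL,
                         head_widths = NULL,
                         window_len = 30L,
                         transformer = list(blocks = 1L, head_size = 512L,
                                            n_heads = 1L, ff_dim = 2048L,
                                            pool_stride = 15L),
                         attn_dim = 32L) {
  fusion <- match.arg(fusion)
  backbone <- match.arg(backbone)
  if (is.null(group_hidden)) {
    group_hidden <- if (fusion == "early") {
      c(all = if (backbone == "bilstm") 128 else 64)
    } else {
      default_group_hidden(backbone)
    }
  }
  if (fusion == "early" && is.null(names(group_hidden))) {
    names(group_hidden) <- "all"
  }
  if (is.null(head_widths)) head_widths <- default_head_widths(fusion, backbone)
  if (utils::tail(head_widths, 1L) != 1L) {
    stop("head_widths must terminate in 1")
  }
  if (backbone == "window_block_lstm" && horizon %% window_len != 0) {
    stop("horizon must be divisible by window_len")
  }
  if (backbone == "transformer" && horizon %% transformer$pool_stride != 0) {
    stop("horizon must be divisible by the transformer pool stride")
  }
  structure(list(fusion = fusion, backbone = backbone,
                 horizon = as.integer(horizon),
                 group_hidden = group_hidden, head_widths = head_widths,
                 window = list(window_len = as.integer(window_len),
                               n_windows = as.integer(horizon %/% window_len)),
                 transformer = transformer, attn_dim = as.integer(attn_dim)),
            class = "model_config")
}

## ---- parameter initialization ---------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_lstm <- function(f, h) {
  b <- matrix(0, 1L, 4L * h)
  b[1L, (h + 1L):(2L * h)] <- 1 # forget-gate bias at 1 eases gradient flow
  list(Wx = glorot(f, 4L * h), Wh = glorot(h, 4L * h), b = b)
}

init_attention <- function(d, a) {
  list(W = glorot(d, a), b = matrix(0, 1L, a), v = glorot(a, 1L))
}

init_transformer <- function(f, tcfg) {
  dk <- tcfg$head_size
  list(Wq = glorot(f, dk), Wk = glorot(f, dk), Wv = glorot(f, dk),
       Wo = glorot(dk, f),
       ln1_g = matrix(1, 1L, f), ln1_b = matrix(0, 1L, f),
       W1 = glorot(f, tcfg$ff_dim), b1 = matrix(0, 1L, tcfg$ff_dim),
       W2 = glorot(tcfg$ff_dim, f), b2 = matrix(0, 1L, f),
       ln2_g = matrix(1, 1L, f), ln2_b = matrix(0, 1L, f))
}

init_head <- function(k, widths) {
  dims <- c(k, widths)
  lapply(seq_along(widths), function(j) {
    list(W = glorot(dims[j], dims[j + 1L]), b = matrix(0, 1L, dims[j + 1L]))
  })
}

branch_group_cols <- function(config) {
  if (config$fusion == "early") list(all = 1:40) else feature_group_slices()
}

branch_out_dim <- function(config, f, h) {
  switch(config$backbone,
         bilstm = 2L * h,
         window_block_lstm = h,
         transformer = f)
}

init_branch <- function(config, f, h) {
  p <- switch(config$backbone,
    bilstm = list(fw = init_lstm(f, h), bw = init_lstm(f, h)),
    window_block_lstm = list(lstm = init_lstm(f, h)),
    transformer = list(tf = init_transformer(f, config$transformer))
  )
  d <- branch_out_dim(config, f, h)
  p$att <- init_attention(d, config$attn_dim)
  if (config$backbone == "window_block_lstm") {
    p$att2 <- init_attention(d, config$attn_dim) # pool over the 660 windows
  }
  p
}

#' Build a trainable fusion classifier
#'
#' Initializes all weights (Glorot-uniform, forget-gate bias 1) under the
#' given seed and returns a classifier mapping a `(T x 40)` feature series
#' to a depressed-probability in `[0, 1]`.
#'
#' @param config A `model_config`.
#' @param seed Integer seed for weight initialization.
#' @return A `fusion_model` with elements `config` and `params`.
#' @export
build_model <- function(config, seed = 42L) {
  stopifnot(inherits(config, "model_config"))
  groups <- branch_group_cols(config)
  with_seed(seed, {
    params <- list(branches = list(), heads = list())
    for (g in names(groups)) {
      f <- length(groups[[g]])
      h <- config$group_hidden[[g]]
      params$branches[[g]] <- init_branch(config, f, h)
    }
    if (config$fusion == "late") {
      for (g in names(groups)) {
        d <- branch_out_dim(config, length(groups[[g]]), config$group_hidden[[g]])
        params$heads[[g]] <- init_head(d, config$head_widths)
      }
    } else {
      k <- sum(vapply(names(groups), function(g) {
        branch_out_dim(config, length(groups[[g]]), config$group_hidden[[g]])
      }, numeric(1)))
      params$heads[["all"]] <- init_head(k, config$head_widths)
    }
    structure(list(config = config, params = params, scaler = NULL),
              class = "fusion_model")
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s fusion, %s backbone, horizon %d, %d parameters\n",
              x$config$fusion, x$config$backbone, x$config$horizon, n_params(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `fusion_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), sum, numeric(1)))
}

## ---- forward pass ----------------------------------------------------------

# Wrap every parameter matrix of `params` in tape leaves (same nesting).
param_leaves <- function(tape, params, requires = TRUE) {
  rapply(params, function(p) ag_leaf(tape, p, requires = requires),
         classes = c("matrix", "numeric", "array"), how = "replace")
}

# Collect accumulated leaf gradients back into the params nesting (zeros
# where a leaf never received gradient).
collect_grads <- function(leaves) {
  rapply(leaves, function(nd) {
    if (is.null(nd$grad)) array(0, dim(nd$value)) else nd$grad
  }, classes = "environment", how = "replace")
}

sinusoidal_pe <- function(t_len, d) {
  pos <- seq_len(t_len) - 1L
  pe <- matrix(0, t_len, d)
  for (j in seq_len(d)) {
    k <- (j - 1L) %/% 2L
    ang <- pos / (10000^(2 * k / d))
    pe[, j] <- if (j %% 2L == 1L) sin(ang) else cos(ang)
  }
  pe
}

forward_branch_bilstm <- function(x, bp) {
  hf <- ag_lstm(x, bp$fw$Wx, bp$fw$Wh, bp$fw$b)
  hb <- ag_reverse_time(ag_lstm(ag_reverse_time(x), bp$bw$Wx, bp$bw$Wh, bp$bw$b))
  h <- ag_concat_feat(hf, hb)
  ag_attention(h, bp$att$W, bp$att$b, bp$att$v)
}

forward_branch_wblstm <- function(x, bp, config, batch) {
  xw <- ag_time_to_windows(x, config$window$window_len)
  n_win <- dim(x$value)[3] %/% config$window$window_len
  h <- ag_lstm(xw, bp$lstm$Wx, bp$lstm$Wh, bp$lstm$b)
  ctx_w <- ag_attention(h, bp$att$W, bp$att$b, bp$att$v) # (B*n_win, H)
  hw <- ag_windows_to_cube(ctx_w, batch, n_win)          # (B, H, n_win)
  ag_attention(hw, bp$att2$W, bp$att2$b, bp$att2$v)
}

forward_branch_transformer <- function(x, bp, config, tape) {
  tcfg <- config$transformer
  pooled <- ag_avgpool_time(x, tcfg$pool_stride)
  d <- dim(pooled$value)
  pe <- ag_leaf(tape, sinusoidal_pe(d[3], d[2]))
  dk <- tcfg$head_size
  tf <- bp$tf
  ctxs <- lapply(seq_len(d[1]), function(b) {
    xb <- ag_add(ag_slice_sample(pooled, b), pe)
    for (blk in seq_len(tcfg$blocks)) {
      a <- ag_layernorm_rows(xb, tf$ln1_g, tf$ln1_b)
      q <- ag_matmul(a, tf$Wq)
      k <- ag_matmul(a, tf$Wk)
      v <- ag_matmul(a, tf$Wv)
      w <- ag_softmax_rows(ag_scale(ag_matmul_bt(q, k), 1 / sqrt(dk)))
      x1 <- ag_add(xb, ag_matmul(ag_matmul(w, v), tf$Wo))
      a2 <- ag_layernorm_rows(x1, tf$ln2_g, tf$ln2_b)
      ff <- ag_add(ag_matmul(ag_relu(ag_add(ag_matmul(a2, tf$W1), tf$b1)),
                             tf$W2), tf$b2)
      xb <- ag_add(x1, ff)
    }
    u <- ag_tanh(ag_add(ag_matmul(xb, bp$att$W), bp$att$b))
    s <- ag_transpose(ag_matmul(u, bp$att$v))
    ag_matmul(ag_softmax_rows(s), xb) # (1, F)
  })
  ag_stack_rows(ctxs)
}

forward_branch <- function(x, bp, config, batch, tape) {
  switch(config$backbone,
         bilstm = forward_branch_bilstm(x, bp),
         window_block_lstm = forward_branch_wblstm(x, bp, config, batch),
         transformer = forward_branch_transformer(x, bp, config, tape))
}

forward_head <- function(x, head) {
  for (j in seq_along(head)) {
    x <- ag_add(ag_matmul(x, head[[j]]$W), head[[j]]$b)
    if (j < length(head)) x <- ag_relu(x)
  }
  x # (B, 1) logit
}

# Full forward pass on a (B, 40, T) batch cube. Returns the tape, the
# probability node, the logit node (NULL for late fusion, whose output is a
# mean of per-group probabilities), the input leaf and the parameter leaves.
forward_fusion <- function(model, X, input_grad = FALSE) {
  config <- model$config
  tape <- ag_tape()
  leaves <- param_leaves(tape, model$params)
  xin <- ag_leaf(tape, X, requires = input_grad)
  groups <- branch_group_cols(config)
  batch <- dim(X)[1]
  if (config$fusion == "late") {
    probs <- lapply(names(groups), function(g) {
      xg <- ag_slice_feat(xin, groups[[g]])
      ctx <- forward_branch(xg, leaves$branches[[g]], config, batch, tape)
      ag_sigmoid(forward_head(ctx, leaves$heads[[g]]))
    })
    prob <- ag_scale(ag_add(ag_add(probs[[1]], probs[[2]]),
                            ag_add(probs[[3]], probs[[4]])), 1 / 4)
    list(tape = tape, prob = prob, logit = NULL, xin = xin, leaves = leaves)
  } else {
    ctxs <- lapply(names(groups), function(g) {
      xg <- if (config$fusion == "early") xin else ag_slice_feat(xin, groups[[g]])
      forward_branch(xg, leaves$branches[[g]], config, batch, tape)
    })
    ctx <- if (length(ctxs) == 1L) ctxs[[1]] else ag_concat_cols(ctxs)
    logit <- forward_head(ctx, leaves$heads[["all"]])
    list(tape = tape, prob = ag_sigmoid(logit), logit = logit, xin = xin,
         leaves = leaves)
  }
}

# Stack cohort samples into a (B, 40, T) cube (features x time transposed
# per sample).
samples_to_cube <- function(samples) {
  T <- nrow(samples[[1]]$series$values)
  X <- array(0, c(length(samples), 40L, T))
  for (i in seq_along(samples)) X[i, , ] <- t(samples[[i]]$series$values)
  X
}

#' Predict depressed probabilities
#'
#' Runs the forward pass in memory-bounded chunks and thresholds at 0.5.
#'
#' @param object A `fusion_model`.
#' @param samples List of `cohort_sample` (or a `(B, 40, T)` numeric array).
#' @param chunk Maximum batch rows per forward pass.
#' @param ... Unused.
#' @return Data frame with columns `p` and `decision` (hard 0/1 at 0.5).
#' @export
predict.fusion_model <- function(object, samples, chunk = 32L, ...) {
  X <- if (is.array(samples) && length(dim(samples)) == 3L) {
    samples
  } else {
    samples_to_cube(samples)
  }
  n <- dim(X)[1]
  p <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    fw <- forward_fusion(object, X[lo:hi, , , drop = FALSE])
    p[lo:hi] <- as.numeric(fw$prob$value)
  }
  data.frame(p = p, decision = as.integer(p >= 0.5))
}

## ---- standalone numeric building blocks ------------------------------------

#' Reshape a series into consecutive windows
#'
#' Splits a `T x F` series into `T / window_len` consecutive, non-overlapping
#' windows, e.g. the 19,800-frame horizon becomes a `660 x 30 x F` array at
#' the 1-second window length. [window_flatten()] inverts it exactly.
#'
#' @param series Numeric `T x F` matrix.
#' @param window_len Window length in frames.
#' @return `(T/window_len) x window_len x F` array.
#' @export
window_reshape <- function(series, window_len = 30L) {
  series <- as.matrix(series)
  T <- nrow(series)
  if (T %% window_len != 0) {
    stop("series length ", T, " not divisible by window length ", window_len)
  }
  nw <- T %/% window_len
  aperm(array(series, c(window_len, nw, ncol(series))), c(2L, 1L, 3L))
}

#' Invert [window_reshape()]
#'
#' @param windows `(n_win, window_len, F)` array.
#' @return `T x F` matrix with `T = n_win * window_len`.
#' @export
window_flatten <- function(windows) {
  d <- dim(windows)
  x <- aperm(windows, c(2L, 1L, 3L))
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

#' Additive attention pooling of a hidden-state sequence
#'
#' Scores each timestep as `v . tanh(W h_t + b)`, softmaxes the scores over
#' time and returns the weighted sum of hidden states. With the default
#' parameters (identity projection, zero bias, unit context vector) the
#' scoring is deterministic; supply learned `W`, `b`, `v` to reproduce a
#' model's pooling.
#'
#' @param hidden_states Numeric `T x H` matrix.
#' @param W `H x A` projection.
#' @param b Length-`A` bias.
#' @param v Length-`A` context vector.
#' @return Length-`H` pooled vector with attribute `"weights"` (length `T`,
#'   non-negative, summing to 1).
#' @export
attention_pool <- function(hidden_states, W = diag(ncol(hidden_states)),
                           b = rep(0, ncol(W)), v = rep(1, ncol(W))) {
  h <- as.matrix(hidden_states)
  stopifnot(nrow(h) >= 1L)
  scores <- tanh(sweep(h %*% W, 2L, b, "+")) %*% v
  w <- exp(scores - max(scores))
  w <- as.numeric(w / sum(w))
  out <- as.numeric(crossprod(h, w))
  attr(out, "weights") <- w
  out
}

#' Mean-pool a series along time
#'
#' Non-overlapping average pooling: every `stride` consecutive frames are
#' replaced by their mean, shortening the series `stride`-fold (19,800
#' frames -> 1,320 at the default transformer stride of 15).
#'
#' @param series Numeric `T x F` matrix with `T` divisible by `stride`.
#' @param stride Pooling stride in frames.
#' @return `(T/stride) x F` matrix.
#' @export
avg_pool_series <- function(series, stride = 15L) {
  series <- as.matrix(series)
  T <- nrow(series)
  if (T %% stride != 0) stop("series length not divisible by stride")
  if (stride == 1L) return(series)
  w <- window_reshape(series, stride)
  apply(w, c(1L, 3L), mean)
}

#' Run the transformer branch on one series
#'
#' Applies the stride-15 mean pooling, sinusoidal positional encoding, the
#' configured transformer block(s) and the attention pooling of one branch,
#' as used inside transformer-backbone fusion models.
#'
#' @param series Numeric `T x F` matrix.
#' @param config A `model_config` with `backbone = "transformer"`.
#' @param params Optional branch parameter list (as built by [build_model()]
#'   for one branch); fresh Glorot weights under `seed` are used if omitted.
#' @param seed Seed for fresh parameter initialization.
#' @return List with `pooled` (the `(T/stride) x F` pooled series) and
#'   `representation` (length-`F` pooled branch output).
#' @export
transformer_branch <- function(series, config = model_config(backbone = "transformer",
                                                             horizon = nrow(series)),
                               params = NULL, seed = 42L) {
  series <- as.matrix(series)
  f <- ncol(series)
  if (is.null(params)) {
    params <- with_seed(seed, {
      p <- list(tf = init_transformer(f, config$transformer))
      p$att <- init_attention(f, config$attn_dim)
      p
    })
  }
  X <- array(t(series), c(1L, f, nrow(series)))
  tape <- ag_tape()
  leaves <- param_leaves(tape, params, requires = FALSE)
  xin <- ag_leaf(tape, X)
  out <- forward_branch_transformer(xin, leaves, config, tape)
  list(pooled = avg_pool_series(series, config$transformer$pool_stride),
       representation = as.numeric(out$value))
}

#' Average per-group probabilities (late fusion)
#'
#' @param group_probs Numeric vector of per-group probabilities in `[0, 1]`.
#' @return A `prediction` list with `p` (their arithmetic mean) and
#'   `decision` (hard label at 0.5).
#' @export
late_fusion_aggregate <- function(group_probs) {
  stopifnot(all(group_probs >= 0 & group_probs <= 1))
  p <- mean(group_probs)
  list(p = p, decision = as.integer(p >= 0.5))
}
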