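# Minimal reverse-mode automatic differentiation on an explicit tape.
#
# Values are matrices or 3-d arrays; a batch of sequences is stored as a
# (batch, feature, time) array to match the compiled LSTM/attention kernels.
# Each op appends a node holding its value, its parents and a closure that
# maps the node's output gradient to the parents' gradients. Backward walks
# the tape once in reverse creation order, which is always a valid reverse
# topological order.

.ag_state <- new.env(parent = emptyenv())

# Creating a tape makes it the active tape; ops append to the active tape.
ag_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- vector("list", 256L)
  env$n <- 0L
  .ag_state$tape <- env
  env
}

ag_node <- function(tape, value, parents = list(), back = NULL,
                    requires = NULL) {
  if (is.null(tape)) tape <- .ag_state$tape
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$back <- back
  node$grad <- NULL
  if (is.null(requires)) {
    requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  }
  node$requires <- requires
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- node
  node$pid <- tape$n
  node
}

ag_leaf <- function(tape, value, requires = FALSE) {
  ag_node(tape, value, requires = requires)
}

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Seed the output node with `seed` (same shape as its value) and propagate.
ag_backward <- function(tape, out, seed) {
  out$grad <- seed
  for (k in seq(out$pid, 1L)) {
    node <- tape$nodes[[k]]
    if (is.null(node$grad) || !length(node$parents) || !node$requires) next
    gs <- node$back(node$grad, node)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (p$requires && !is.null(gs[[j]])) ag_accum(p, gs[[j]])
    }
    node$grad <- NULL # free interior gradients as soon as they are consumed
  }
  invisible(NULL)
}

## ---- matrix ops -----------------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(NULL, a$value %*% b$value, list(a, b),
          back = function(g, node) {
            list(g %*% t(node$parents[[2]]$value),
                 t(node$parents[[1]]$value) %*% g)
          })
}

# a %*% t(b)
ag_matmul_bt <- function(a, b) {
  ag_node(NULL, tcrossprod(a$value, b$value), list(a, b),
          back = function(g, node) {
            list(g %*% node$parents[[2]]$value,
                 t(g) %*% node$parents[[1]]$value)
          })
}

# Elementwise add; `b` may be a 1 x n bias row broadcast over the rows of `a`.
ag_add <- function(a, b) {
  av <- a$value; bv <- b$value
  broadcast <- is.matrix(av) && is.matrix(bv) &&
    nrow(bv) == 1L && nrow(av) > 1L
  val <- if (broadcast) sweep(av, 2L, as.numeric(bv), "+") else av + bv
  ag_node(NULL, val, list(a, b),
          back = function(g, node) {
            gb <- if (broadcast) matrix(colSums(g), 1L) else g
            list(g, gb)
          })
}

ag_mul <- function(a, b) {
  ag_node(NULL, a$value * b$value, list(a, b),
          back = function(g, node) {
            list(g * node$parents[[2]]$value,
                 g * node$parents[[1]]$value)
          })
}

ag_scale <- function(a, k) {
  ag_node(NULL, a$value * k, list(a),
          back = function(g, node) list(g * k))
}

ag_sigmoid <- function(a) {
  s <- stats::plogis(a$value)
  node <- ag_node(NULL, s, list(a),
                  back = function(g, node) list(g * node$cache * (1 - node$cache)))
  node$cache <- s
  node
}

ag_tanh <- function(a) {
  s <- tanh(a$value)
  node <- ag_node(NULL, s, list(a),
                  back = function(g, node) list(g * (1 - node$cache^2)))
  node$cache <- s
  node
}

ag_relu <- function(a) {
  m <- a$value > 0
  node <- ag_node(NULL, a$value * m, list(a),
                  back = function(g, node) list(g * node$cache))
  node$cache <- m
  node
}

# Row-wise softmax of a matrix.
ag_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  s <- e / rowSums(e)
  node <- ag_node(NULL, s, list(a),
                  back = function(g, node) {
                    s <- node$cache
                    list(s * (g - rowSums(g * s)))
                  })
  node$cache <- s
  node
}

# Layer normalization across each row, with learned gain/bias rows g1, b1.
ag_layernorm_rows <- function(a, gain, bias, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  val <- sweep(sweep(xhat, 2L, as.numeric(gain$value), "*"),
               2L, as.numeric(bias$value), "+")
  node <- ag_node(NULL, val, list(a, gain, bias),
                  back = function(g, node) {
                    ch <- node$cache
                    n <- ncol(g)
                    dxhat <- sweep(g, 2L, as.numeric(node$parents[[2]]$value), "*")
                    dx <- ch$inv * (dxhat - rowMeans(dxhat) -
                                      ch$xhat * rowMeans(dxhat * ch$xhat))
                    list(dx,
                         matrix(colSums(g * ch$xhat), 1L),
                         matrix(colSums(g), 1L))
                  })
  node$cache <- list(xhat = xhat, inv = inv)
  node
}

ag_transpose <- function(a) {
  ag_node(NULL, t(a$value), list(a), back = function(g, node) list(t(g)))
}

ag_concat_cols <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  node <- ag_node(NULL, do.call(cbind, lapply(nodes, function(n) n$value)),
                  nodes,
                  back = function(g, node) {
                    ends <- cumsum(node$cache)
                    starts <- c(1L, head(ends, -1L) + 1L)
                    lapply(seq_along(ends), function(j) {
                      g[, starts[j]:ends[j], drop = FALSE]
                    })
                  })
  node$cache <- widths
  node
}

ag_stack_rows <- function(nodes) {
  heights <- vapply(nodes, function(n) nrow(n$value), integer(1))
  node <- ag_node(NULL, do.call(rbind, lapply(nodes, function(n) n$value)),
                  nodes,
                  back = function(g, node) {
                    ends <- cumsum(node$cache)
                    starts <- c(1L, head(ends, -1L) + 1L)
                    lapply(seq_along(ends), function(j) {
                      g[starts[j]:ends[j], , drop = FALSE]
                    })
                  })
  node$cache <- heights
  node
}

## ---- sequence (cube) ops --------------------------------------------------

# Full LSTM chain over a (B, F, T) cube, returning the (B, H, T) hidden cube.
ag_lstm <- function(x, Wx, Wh, b) {
  fw <- .lstm_forward_cpp(x$value, Wx$value, Wh$value, as.numeric(b$value))
  node <- ag_node(NULL, fw$H, list(x, Wx, Wh, b),
                  back = function(g, node) {
                    p <- node$parents
                    bw <- .lstm_backward_cpp(g, p[[1]]$value, node$cache$H,
                                             node$cache$C, node$cache$G,
                                             p[[2]]$value, p[[3]]$value)
                    list(bw$dX, bw$dWx, bw$dWh, matrix(bw$db, 1L))
                  })
  node$cache <- fw
  node
}

# Additive attention pool over time: (B, D, T) cube -> (B, D) matrix.
ag_attention <- function(h, W, b, v) {
  fw <- .attn_forward_cpp(h$value, W$value, as.numeric(b$value),
                          as.numeric(v$value))
  node <- ag_node(NULL, fw$ctx, list(h, W, b, v),
                  back = function(g, node) {
                    p <- node$parents
                    bw <- .attn_backward_cpp(g, p[[1]]$value, node$cache$U,
                                             node$cache$wgt, p[[2]]$value,
                                             as.numeric(p[[4]]$value))
                    list(bw$dH, bw$dW, matrix(bw$db, 1L),
                         matrix(bw$dv, ncol = 1L))
                  })
  node$cache <- fw
  node
}

ag_reverse_time <- function(a) {
  T <- dim(a$value)[3]
  node <- ag_node(NULL, a$value[, , T:1, drop = FALSE], list(a),
                  back = function(g, node) {
                    T <- dim(g)[3]
                    list(g[, , T:1, drop = FALSE])
                  })
  node
}

# Concatenate two (B, *, T) cubes along the feature axis.
ag_concat_feat <- function(a, b) {
  da <- dim(a$value); db_ <- dim(b$value)
  val <- array(0, c(da[1], da[2] + db_[2], da[3]))
  val[, seq_len(da[2]), ] <- a$value
  val[, da[2] + seq_len(db_[2]), ] <- b$value
  node <- ag_node(NULL, val, list(a, b),
                  back = function(g, node) {
                    k <- node$cache
                    list(g[, seq_len(k), , drop = FALSE],
                         g[, k + seq_len(dim(g)[2] - k), , drop = FALSE])
                  })
  node$cache <- da[2]
  node
}

# Regroup a (B*n_win, H) matrix of per-window vectors (window-major blocks of
# B rows) into a (B, H, n_win) cube so windows become a pooled time axis.
ag_windows_to_cube <- function(a, batch, n_win) {
  h <- ncol(a$value)
  val <- array(a$value, c(batch, n_win, h)) # rows vary fastest: batch, then window
  val <- aperm(val, c(1L, 3L, 2L))
  node <- ag_node(NULL, val, list(a),
                  back = function(g, node) {
                    d <- dim(g) # (B, H, n_win)
                    gm <- aperm(g, c(1L, 3L, 2L))
                    list(matrix(gm, d[1] * d[3], d[2]))
                  })
  node
}

# Non-overlapping mean pooling along time: (B, F, T) -> (B, F, T/stride).
ag_avgpool_time <- function(a, stride) {
  d <- dim(a$value)
  stopifnot(d[3] %% stride == 0)
  tp <- d[3] %/% stride
  val <- array(a$value, c(d[1] * d[2], stride, tp))
  val <- array(colMeans(aperm(val, c(2L, 1L, 3L))), c(d[1], d[2], tp))
  node <- ag_node(NULL, val, list(a),
                  back = function(g, node) {
                    d0 <- node$cache
                    gg <- g[, , rep(seq_len(dim(g)[3]), each = stride),
                            drop = FALSE] / stride
                    list(array(gg, d0))
                  })
  node$cache <- d
  node
}

# Select feature columns of a (B, F, T) cube.
ag_slice_feat <- function(a, cols) {
  node <- ag_node(NULL, a$value[, cols, , drop = FALSE], list(a),
                  back = function(g, node) {
                    out <- array(0, node$cache$d)
                    out[, node$cache$cols, ] <- g
                    list(out)
                  })
  node$cache <- list(d = dim(a$value), cols = cols)
  node
}

# Split the time axis of a (B, F, T) cube into consecutive windows:
# result is a (B * n_win, F, window_len) cube whose rows are window-major
# blocks of B (row (w-1)*B + b holds window w of sample b).
ag_time_to_windows <- function(a, window_len) {
  d <- dim(a$value)
  if (d[3] %% window_len != 0) {
    stop("sequence length ", d[3], " not divisible by window length ", window_len)
  }
  nw <- d[3] %/% window_len
  y <- aperm(array(a$value, c(d[1], d[2], window_len, nw)), c(1L, 4L, 2L, 3L))
  dim(y) <- c(d[1] * nw, d[2], window_len)
  node <- ag_node(NULL, y, list(a),
                  back = function(g, node) {
                    d <- node$cache$d; nw <- node$cache$nw; wl <- node$cache$wl
                    dim(g) <- c(d[1], nw, d[2], wl)
                    g <- aperm(g, c(1L, 3L, 4L, 2L))
                    dim(g) <- d
                    list(g)
                  })
  node$cache <- list(d = d, nw = nw, wl = window_len)
  node
}

# Extract sample `i` of a (B, F, T) cube as a (T, F) matrix.
ag_slice_sample <- function(a, i) {
  d <- dim(a$value)
  val <- t(matrix(a$value[i, , ], d[2], d[3]))
  node <- ag_node(NULL, val, list(a),
                  back = function(g, node) {
                    d <- node$cache$d
                    out <- array(0, d)
                    out[node$cache$i, , ] <- t(g)
                    list(out)
                  })
  node$cache <- list(d = d, i = i)
  node
}

`%||%` <- function(a, b) if (is.null(a)) b else a
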