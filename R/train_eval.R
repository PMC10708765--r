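# Training loop (Adam on binary cross-entropy against smoothed targets) and
# the evaluation report: confusion counts plus accuracy and macro /
# support-weighted precision, recall and F1 in percent.
#
# Note on naming: the weighted columns reproduce the reference tables'
# "Micro (%)" columns, which are support-weighted averages, not textbook
# micro-averaging (micro-averaged P and R would both equal accuracy in a
# binary task, contradicting the printed 91.63 vs 91.67).

#' Metrics from confusion counts
#'
#' Builds the full evaluation row from the four confusion counts (positive
#' class = depressed): accuracy, macro (unweighted two-class mean) and
#' support-weighted precision/recall/F1, all in percent. A class with zero
#' predicted positives gets precision 0 with a warning.
#'
#' @param tp,fn,tn,fp Non-negative integer confusion counts.
#' @return An `eval_report`.
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty evaluation: all confusion counts are zero")
  prec <- function(num, den, cls) {
    if (den == 0) {
      warning("no predicted ", cls, " samples; precision defined as 0")
      0
    } else {
      num / den
    }
  }
  p_pos <- prec(tp, tp + fp, "positive")
  p_neg <- prec(tn, tn + fn, "negative")
  r_pos <- if (tp + fn > 0) tp / (tp + fn) else 0
  r_neg <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  f_pos <- f1(p_pos, r_pos)
  f_neg <- f1(p_neg, r_neg)
  sup_pos <- tp + fn
  sup_neg <- tn + fp
  wavg <- function(a, b) (sup_pos * a + sup_neg * b) / total
  metrics <- c(
    accuracy = (tp + tn) / total,
    macro_precision = (p_pos + p_neg) / 2,
    macro_recall = (r_pos + r_neg) / 2,
    macro_f1 = (f_pos + f_neg) / 2,
    weighted_precision = wavg(p_pos, p_neg),
    weighted_recall = wavg(r_pos, r_neg),
    weighted_f1 = wavg(f_pos, f_neg)
  ) * 100
  structure(list(counts = c(TP = tp, FN = fn, TN = tn, FP = fp),
                 metrics = metrics,
                 per_class = list(
                   positive = c(precision = p_pos, recall = r_pos, f1 = f_pos),
                   negative = c(precision = p_neg, recall = r_neg, f1 = f_neg))),
            class = "eval_report")
}

#' Evaluate hard predictions against hard labels
#'
#' @param predictions Data frame from [predict.fusion_model()] (its
#'   `decision` column is used) or a 0/1 vector of hard predictions.
#' @param targets 0/1 vector of hard labels (1 = depressed).
#' @return An `eval_report`.
#' @export
evaluate_predictions <- function(predictions, targets) {
  pred <- if (is.data.frame(predictions)) predictions$decision else predictions
  if (!length(pred)) stop("empty evaluation input")
  if (length(pred) != length(targets)) {
    stop("predictions and targets differ in length")
  }
  stopifnot(all(pred %in% c(0, 1)), all(targets %in% c(0, 1)))
  metrics_from_counts(sum(pred == 1 & targets == 1),
                      sum(pred == 0 & targets == 1),
                      sum(pred == 0 & targets == 0),
                      sum(pred == 1 & targets == 0))
}

#' @export
print.eval_report <- function(x, ...) {
  print(format_metric_table(list(x)), row.names = FALSE)
  invisible(x)
}

#' Render evaluation reports as a metric table
#'
#' One row per report in the reference column order (TP, FN, TN, FP,
#' accuracy, macro P/R/F1, weighted P/R/F1), percentages rounded to two
#' decimals.
#'
#' @param reports An `eval_report` or list of them.
#' @param labels Optional row labels.
#' @param format `"data.frame"`, `"markdown"` or `"csv"` (a string).
#' @return Data frame or character string.
#' @export
format_metric_table <- function(reports, labels = NULL,
                                format = c("data.frame", "markdown", "csv")) {
  format <- match.arg(format)
  if (inherits(reports, "eval_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    data.frame(TP = r$counts[["TP"]], FN = r$counts[["FN"]],
               TN = r$counts[["TN"]], FP = r$counts[["FP"]],
               acc = round(r$metrics[["accuracy"]], 2),
               macro_precision = round(r$metrics[["macro_precision"]], 2),
               macro_recall = round(r$metrics[["macro_recall"]], 2),
               macro_f1 = round(r$metrics[["macro_f1"]], 2),
               weighted_precision = round(r$metrics[["weighted_precision"]], 2),
               weighted_recall = round(r$metrics[["weighted_recall"]], 2),
               weighted_f1 = round(r$metrics[["weighted_f1"]], 2))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(labels)) tab <- cbind(model = labels, tab)
  if (format == "data.frame") return(tab)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- apply(tab, 1L, function(r) {
    paste0("| ", paste(trimws(format(r)), collapse = " | "), " |")
  })
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Training hyperparameters
#'
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience on validation loss.
#' @param shuffle Shuffle the training order each epoch.
#' @return A `training_recipe`.
#' @export
training_recipe <- function(lr = 1e-3, batch_size = 8L, epochs = 30L,
                            patience = 10L, shuffle = TRUE) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 shuffle = shuffle),
            class = "training_recipe")
}

## ---- Adam over nested parameter trees --------------------------------------

tree_zeros <- function(params) {
  rapply(params, function(p) array(0, dim(p)),
         classes = c("matrix", "array"), how = "replace")
}

adam_update <- function(params, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  walk <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (k in seq_along(p)) {
        res <- walk(p[[k]], g[[k]], mm[[k]], vv[[k]])
        out_p[[k]] <- res$p; out_m[[k]] <- res$m; out_v[[k]] <- res$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      mm <- beta1 * mm + (1 - beta1) * g
      vv <- beta2 * vv + (1 - beta2) * g * g
      mhat <- mm / (1 - beta1^t)
      vhat <- vv / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
    }
  }
  walk(params, grads, m, v)
}

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(1 - eps, pmax(eps, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Validation loss is computed against the hard labels: label smoothing is a
# training-time regularizer, and smoothed targets floor the BCE at the
# smoothing entropy, masking real differences between checkpoints.
eval_loss <- function(model, samples, chunk = 32L) {
  X <- samples_to_cube(samples)
  y <- vapply(samples, function(s) as.numeric(s$y), numeric(1))
  n <- dim(X)[1]
  p <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    fw <- forward_fusion(model, X[lo:hi, , , drop = FALSE])
    p[lo:hi] <- as.numeric(fw$prob$value)
  }
  list(loss = bce_loss(p, y), p = p)
}

#' Train a fusion classifier
#'
#' Minimizes binary cross-entropy against the samples' smoothed targets with
#' Adam, evaluating validation loss (against the hard validation labels —
#' smoothing is a training regularizer) each epoch; the best-validation-loss
#' parameters are restored at the end and training stops early after
#' `patience` epochs without improvement. Runs are deterministic under the
#' seed. Non-finite loss aborts with a diagnostic.
#'
#' @param model A `fusion_model` from [build_model()].
#' @param train List of `cohort_sample` (balanced, smoothed training split).
#' @param val List of `cohort_sample` (validation split).
#' @param recipe A [training_recipe()].
#' @param seed Integer seed for shuffling.
#' @param verbose Print per-epoch progress.
#' @return The trained `fusion_model`, with a `history` data frame (epoch,
#'   train_loss, val_loss, val_acc) attached as `model$history`.
#' @export
fit_model <- function(model, train, val, recipe = training_recipe(),
                      seed = 42L, verbose = FALSE) {
  stopifnot(inherits(model, "fusion_model"), length(train) > 0, length(val) > 0)
  y_tr <- vapply(train, function(s) s$y_ls, numeric(1))
  y_val_hard <- vapply(val, function(s) s$y, integer(1))
  Xtr <- samples_to_cube(train)
  n <- length(train)
  m <- tree_zeros(model$params)
  v <- tree_zeros(model$params)
  late <- model$config$fusion == "late"
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- vector("list", recipe$epochs)
  t_adam <- 0L
  with_seed(seed, {
    for (epoch in seq_len(recipe$epochs)) {
      ord <- if (recipe$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0
      for (lo in seq(1L, n, by = recipe$batch_size)) {
        idx <- ord[lo:min(n, lo + recipe$batch_size - 1L)]
        Xb <- Xtr[idx, , , drop = FALSE]
        yb <- y_tr[idx]
        fw <- forward_fusion(model, Xb)
        p <- as.numeric(fw$prob$value)
        loss <- bce_loss(p, yb)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        ep_loss <- ep_loss + loss * length(idx)
        if (late) {
          pc <- pmin(1 - 1e-6, pmax(1e-6, p))
          seed_grad <- matrix((pc - yb) / (pc * (1 - pc)) / length(idx), ncol = 1L)
          ag_backward(fw$tape, fw$prob, seed_grad)
        } else {
          seed_grad <- matrix((p - yb) / length(idx), ncol = 1L)
          ag_backward(fw$tape, fw$logit, seed_grad)
        }
        grads <- collect_grads(fw$leaves)
        t_adam <- t_adam + 1L
        upd <- adam_update(model$params, grads, m, v, recipe$lr, t_adam)
        model$params <- upd$p; m <- upd$m; v <- upd$v
      }
      vl <- eval_loss(model, val)
      val_acc <- mean(as.integer(vl$p >= 0.5) == y_val_hard)
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                     val_loss = vl$loss, val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f, val %.4f, val acc %.3f",
                        epoch, ep_loss / n, vl$loss, val_acc))
      }
      if (vl$loss < best$loss) {
        best <- list(loss = vl$loss, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= recipe$patience) {
        break
      }
    }
  })
  model$params <- best$params
  model$history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  model
}

#' Sweep the label-smoothing coefficient
#'
#' Trains one model per smoothing coefficient on identical splits and seeds
#' and evaluates each on the test split, emitting one metric row per alpha
#' (the layout of the reference label-smoothing table).
#'
#' @param config A `model_config`.
#' @param train,val,test Lists of `cohort_sample` (train already balanced).
#' @param alpha_grid Smoothing coefficients; defaults to the ten swept values
#'   `0, 0.1, ..., 0.9`.
#' @param recipe A [training_recipe()].
#' @param seed Seed used for every cell (weights and shuffling).
#' @return Data frame: `alpha`, `soft_neg`, `soft_pos` plus the metric
#'   columns of [format_metric_table()]; the full `eval_report`s are attached
#'   as attribute `"reports"`.
#' @export
sweep_label_smoothing <- function(config, train, val, test,
                                  alpha_grid = label_smoothing_grid()$alpha,
                                  recipe = training_recipe(), seed = 42L) {
  y_test <- vapply(test, function(s) s$y, integer(1))
  reports <- lapply(alpha_grid, function(alpha) {
    tr <- set_label_smoothing(train, alpha)
    va <- set_label_smoothing(val, alpha)
    mdl <- fit_model(build_model(config, seed = seed), tr, va, recipe, seed = seed)
    evaluate_predictions(predict(mdl, test), y_test)
  })
  tab <- format_metric_table(reports)
  out <- cbind(data.frame(alpha = alpha_grid, soft_neg = alpha_grid / 2,
                          soft_pos = 1 - alpha_grid / 2), tab)
  attr(out, "reports") <- reports
  out
}
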