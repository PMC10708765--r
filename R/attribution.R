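# Integrated-gradient attribution for the time-series classifiers, with the
# reporting aggregation: signed per-feature mean for direction (positive ->
# pushes toward depressed) and absolute mean for importance ranking.

#' Integrated gradients of a trained classifier
#'
#' Computes path-integral attributions from the all-zero baseline series to
#' the input: `IG_i = x_i * mean_k dF(s_k * x)/dx_i` over `n_steps` midpoint
#' interpolation scales `s_k = (k - 0.5)/n_steps`, where `F` is the model's
#' depressed probability (the pre-threshold sigmoid output). Satisfies the
#' completeness axiom `sum(IG) ~ F(x) - F(0)` with error shrinking in
#' `n_steps`. Interpolation steps are batched through the forward pass in
#' chunks to bound memory.
#'
#' @param model A trained `fusion_model`, or any differentiable forward
#'   function `f(X, input_grad)` taking a `(B, F, T)` cube and returning a
#'   list with elements `tape`, `prob` (scalar-output node, one row per
#'   batch sample) and `xin` (the input leaf).
#' @param input A `feature_series` or numeric `T x F` matrix.
#' @param n_steps Number of interpolation steps (>= 2).
#' @param chunk Interpolation steps per forward/backward pass.
#' @return An `attribution_map`: list with `values` (`T x 40` matrix),
#'   `n_steps`, `original_length`, `prediction` (`F(x)`) and
#'   `baseline_prediction` (`F(0)`).
#' @export
integrated_gradients <- function(model, input, n_steps = 64L, chunk = 16L) {
  stopifnot(n_steps >= 2L)
  fwd <- if (is.function(model)) {
    model
  } else {
    function(X, input_grad) forward_fusion(model, X, input_grad)
  }
  orig_len <- if (inherits(input, "feature_series")) input$original_length else nrow(input)
  x <- if (inherits(input, "feature_series")) input$values else as.matrix(input)
  xt <- t(x) # (40, T)
  d <- dim(xt)
  scales <- (seq_len(n_steps) - 0.5) / n_steps
  grad_sum <- array(0, d)
  for (lo in seq(1L, n_steps, by = chunk)) {
    sc <- scales[lo:min(n_steps, lo + chunk - 1L)]
    B <- length(sc)
    X <- array(0, c(B, d[1], d[2]))
    for (b in seq_len(B)) X[b, , ] <- xt * sc[b]
    fw <- fwd(X, input_grad = TRUE)
    ag_backward(fw$tape, fw$prob, matrix(1, B, 1L))
    g <- fw$xin$grad
    if (!all(is.finite(g))) {
      bad <- which(!apply(is.finite(g), 1L, all))[1]
      stop("non-finite gradient at interpolation step ", lo + bad - 1L)
    }
    grad_sum <- grad_sum + apply(g, c(2L, 3L), sum)
  }
  values <- x * t(grad_sum / n_steps)
  if (ncol(values) == 40L) colnames(values) <- selected_feature_names()
  f_x <- as.numeric(fwd(array(xt, c(1L, d[1], d[2])), input_grad = FALSE)$prob$value)
  f_0 <- as.numeric(fwd(array(0, c(1L, d[1], d[2])), input_grad = FALSE)$prob$value)
  structure(list(values = values, n_steps = as.integer(n_steps),
                 original_length = as.integer(orig_len),
                 prediction = f_x, baseline_prediction = f_0),
            class = "attribution_map")
}

#' Summarize attribution maps over a split
#'
#' Per feature, computes the signed mean attribution (direction: positive
#' pushes the model toward the depressed class) and the absolute mean
#' (importance), averaging over timesteps and samples. Temporal means divide
#' by each sample's real (unpadded) length so padding never dilutes
#' importance; padded frames carry exactly zero attribution under the zero
#' baseline. The importance rank is the descending order of the absolute
#' mean, ties broken by canonical column order. Group roll-ups average over
#' each group's columns.
#'
#' @param maps List of `attribution_map` (typically one per test sample).
#' @return An `attribution_summary`: data frame `feature`, `group`,
#'   `signed_mean`, `abs_mean`, `rank`, with a `groups` attribute holding
#'   the per-group roll-up.
#' @export
summarize_attributions <- function(maps) {
  if (inherits(maps, "attribution_map")) maps <- list(maps)
  if (!length(maps)) stop("no attribution maps to summarize")
  dims <- vapply(maps, function(m) dim(m$values), integer(2))
  if (any(dims[2, ] != 40L) || length(unique(dims[1, ])) != 1L) {
    stop("attribution maps have mismatching shapes")
  }
  signed <- rowMeans(vapply(maps, function(m) {
    colSums(m$values[seq_len(m$original_length), , drop = FALSE]) / m$original_length
  }, numeric(40)))
  absm <- rowMeans(vapply(maps, function(m) {
    colSums(abs(m$values[seq_len(m$original_length), , drop = FALSE])) / m$original_length
  }, numeric(40)))
  ord <- order(-absm, seq_along(absm))
  rank <- integer(40)
  rank[ord] <- seq_len(40)
  slices <- feature_group_slices()
  group <- character(40)
  for (g in names(slices)) group[slices[[g]]] <- g
  out <- data.frame(feature = selected_feature_names(), group = group,
                    signed_mean = signed, abs_mean = absm, rank = rank,
                    stringsAsFactors = FALSE)
  roll <- do.call(rbind, lapply(names(slices), function(g) {
    data.frame(group = g, signed_mean = mean(signed[slices[[g]]]),
               abs_mean = mean(absm[slices[[g]]]))
  }))
  roll <- roll[order(-roll$abs_mean), ]
  roll$rank <- seq_len(nrow(roll))
  attr(out, "groups") <- roll
  class(out) <- c("attribution_summary", "data.frame")
  out
}

impact_barplot <- function(values, names_, main, signed) {
  ord <- order(abs(values), decreasing = FALSE)
  vals <- values[ord]
  cols <- if (signed) ifelse(vals >= 0, "#2166ac", "#b2182b") else "#4d4d4d"
  graphics::par(mar = c(4, 8, 3, 1))
  graphics::barplot(vals, names.arg = names_[ord], horiz = TRUE, las = 1,
                    col = cols, border = NA, main = main,
                    xlab = if (signed) "impact on output" else
                      "impact on model output magnitude",
                    cex.names = 0.7)
}

#' Render the feature-impact report
#'
#' Writes per-group signed-impact and importance-magnitude bar charts (8
#' panels), the all-features pair (2 panels) and the summary CSV. Signed
#' bars follow the convention blue = positive effect (pushes toward
#' depressed), red = negative effect (pushes toward non-depressed).
#'
#' @param summary An `attribution_summary`.
#' @param out_dir Output directory (created if needed).
#' @param device `"pdf"` (default; always available), `"png"` or `"svg"`.
#' @return Character vector of written file paths, invisibly.
#' @export
render_impact_report <- function(summary, out_dir, device = c("pdf", "png", "svg")) {
  device <- match.arg(device)
  stopifnot(inherits(summary, "attribution_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  open_dev <- function(path) {
    switch(device,
           pdf = grDevices::pdf(path, width = 7, height = 6),
           png = grDevices::png(path, width = 700, height = 600),
           svg = grDevices::svg(path, width = 7, height = 6))
  }
  files <- character(0)
  emit <- function(stem, values, names_, main, signed) {
    path <- file.path(out_dir, paste0(stem, ".", device))
    open_dev(path)
    impact_barplot(values, names_, main, signed)
    grDevices::dev.off()
    files <<- c(files, path)
  }
  for (g in names(feature_group_slices())) {
    sub <- summary[summary$group == g, ]
    emit(paste0("impact_", g), sub$signed_mean, sub$feature,
         paste(g, "impact on model output"), signed = TRUE)
    emit(paste0("magnitude_", g), sub$abs_mean, sub$feature,
         paste(g, "impact magnitude"), signed = FALSE)
  }
  emit("impact_all", summary$signed_mean, summary$feature,
       "All features: impact on model output", signed = TRUE)
  emit("magnitude_all", summary$abs_mean, summary$feature,
       "All features: impact magnitude", signed = FALSE)
  csv <- file.path(out_dir, "attribution_summary.csv")
  utils::write.csv(as.data.frame(summary)[, c("feature", "group", "signed_mean",
                                              "abs_mean", "rank")],
                   csv, row.names = FALSE)
  files <- c(files, csv)
  invisible(files)
}
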