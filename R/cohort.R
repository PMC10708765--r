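# Cohort assembly: 4-level severity -> binary depression target, label
# smoothing, stratified 80:10:10 splitting, and duplication balancing of the
# training split.

#' Severity levels of the depression rating
#'
#' The four clinician-assigned severity levels (7-item Hamilton scale), in
#' increasing order. `normal` and `mild` map to the non-depressed class,
#' `moderate` and `severe` to the depressed class.
#'
#' @return Character vector of the four levels.
#' @export
severity_levels <- function() c("normal", "mild", "moderate", "severe")

check_severity <- function(level) {
  level <- as.character(level)
  bad <- !level %in% severity_levels()
  if (any(bad)) {
    stop("unknown severity level(s): ", paste(unique(level[bad]), collapse = ", "))
  }
  level
}

#' Map severity to the binary depression target
#'
#' `normal` and `mild` are non-depressed (0); `moderate` and `severe` are
#' depressed (1).
#'
#' @param level Character vector of severity levels.
#' @return Integer vector of 0/1 hard labels.
#' @export
binarize_severity <- function(level) {
  level <- check_severity(level)
  as.integer(level %in% c("moderate", "severe"))
}

#' Smooth hard binary labels
#'
#' Label smoothing replaces a hard one-hot target with
#' `y_LS = y * (1 - alpha) + alpha / K` (here `K = 2` classes), so a hard
#' positive becomes `1 - alpha/2` and a hard negative `alpha/2`. `alpha = 0`
#' is the identity.
#'
#' @param y Numeric/integer vector of hard 0/1 labels.
#' @param alpha Smoothing coefficient in `[0, 1)`.
#' @param K Number of classes (2 for this binary task).
#' @return Numeric vector of smoothed targets.
#' @export
smooth_labels <- function(y, alpha, K = 2L) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha >= 1) {
    stop("alpha must be a single value in [0, 1)")
  }
  stopifnot(all(y %in% c(0, 1)))
  y * (1 - alpha) + alpha / K
}

#' The label-smoothing sweep grid
#'
#' The ten soft-target pairs `(alpha/2, 1 - alpha/2)` swept in the
#' label-smoothing experiment, driven by `alpha = 0, 0.1, ..., 0.9`.
#'
#' @return Data frame with columns `alpha`, `soft_neg`, `soft_pos`.
#' @export
label_smoothing_grid <- function() {
  alpha <- seq(0, 0.9, by = 0.1)
  data.frame(alpha = alpha, soft_neg = alpha / 2, soft_pos = 1 - alpha / 2)
}

#' Construct a cohort sample
#'
#' @param series A `feature_series`.
#' @param severity One of `severity_levels()`.
#' @param alpha Label-smoothing coefficient used to derive the soft target.
#' @return A `cohort_sample`: list with `series`, `severity`, `y` (hard 0/1)
#'   and `y_ls` (smoothed target).
#' @export
cohort_sample <- function(series, severity, alpha = 0) {
  severity <- check_severity(severity)
  y <- binarize_severity(severity)
  structure(
    list(series = series, severity = severity, y = y,
         y_ls = smooth_labels(y, alpha), alpha = alpha),
    class = "cohort_sample"
  )
}

#' Re-smooth the targets of a cohort
#'
#' @param samples List of `cohort_sample`.
#' @param alpha Smoothing coefficient in `[0, 1)`.
#' @return The list with every `y_ls` recomputed at `alpha`.
#' @export
set_label_smoothing <- function(samples, alpha) {
  lapply(samples, function(s) {
    s$y_ls <- smooth_labels(s$y, alpha)
    s$alpha <- alpha
    s
  })
}

# Largest-remainder apportionment of `total` across strata proportional to
# `sizes` (each allocation capped by its stratum size).
apportion <- function(sizes, total) {
  if (total <= 0 || sum(sizes) == 0) return(integer(length(sizes)))
  quota <- total * sizes / sum(sizes)
  alloc <- pmin(floor(quota), sizes)
  left <- total - sum(alloc)
  rem <- quota - floor(quota)
  ord <- order(rem, sizes, decreasing = TRUE)
  for (j in ord) {
    if (left <= 0) break
    if (alloc[j] < sizes[j]) {
      alloc[j] <- alloc[j] + 1L
      left <- left - 1L
    }
  }
  as.integer(alloc)
}

#' Stratified train/validation/test split
#'
#' Splits a labeled cohort into train/validation/test in the given ratios,
#' independently within each severity stratum. The test allocation is
#' `ceiling(ratio_test * N)` overall, apportioned across strata by largest
#' remainder; validation is allocated the same way from the remainder. With
#' the 106/234/112/22 severity composition this reproduces the reference
#' 84/186/90/18 train, 11/24/11/2 validation and 11/24/11/2 test counts for
#' any seed. Shuffling within strata is Fisher-Yates under the given seed and
#' samples are sorted by participant id first, so the split is invariant to
#' input order.
#'
#' @param samples List of `cohort_sample`.
#' @param ratios Length-3 numeric vector (train, validation, test) summing to 1.
#' @param seed Integer RNG seed.
#' @return A `split_manifest` data frame with columns `participant_id`,
#'   `severity`, `y`, `split` plus a `counts` attribute (per-split,
#'   per-severity table).
#' @export
stratified_split <- function(samples, ratios = c(0.8, 0.1, 0.1), seed = 42L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  ids <- vapply(samples, function(s) s$series$participant_id, character(1))
  sev <- vapply(samples, function(s) s$severity, character(1))
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("sample_", which(is.na(ids)))
  if (anyDuplicated(ids)) stop("duplicate participant ids in cohort")
  ord <- order(ids)
  ids <- ids[ord]; sev <- sev[ord]
  sev <- factor(check_severity(sev), levels = severity_levels())
  sizes <- as.integer(table(sev))
  small <- sizes > 0L & sizes < 3L
  if (any(small)) {
    warning("stratum(s) with fewer than 3 members assigned entirely to train: ",
            paste(severity_levels()[small], collapse = ", "))
  }
  elig <- ifelse(small, 0L, sizes)
  n_test <- apportion(elig, ceiling(ratios[3] * sum(elig)))
  remain <- elig - n_test
  n_val <- apportion(remain, ceiling(ratios[2] / (1 - ratios[3]) * sum(remain)))

  split <- character(length(ids))
  set.seed(as.integer(seed))
  for (k in seq_along(severity_levels())) {
    idx <- which(sev == severity_levels()[k])
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    lab <- rep("train", length(idx))
    if (n_test[k] > 0) lab[seq_len(n_test[k])] <- "test"
    if (n_val[k] > 0) lab[n_test[k] + seq_len(n_val[k])] <- "validation"
    split[idx] <- lab
  }
  out <- data.frame(participant_id = ids, severity = as.character(sev),
                    y = binarize_severity(as.character(sev)), split = split,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$split, out$severity)
  class(out) <- c("split_manifest", "data.frame")
  out
}

#' Select the samples of one split
#'
#' @param samples List of `cohort_sample` (the full cohort).
#' @param manifest A `split_manifest` from [stratified_split()].
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @return List of `cohort_sample`, tagged with the split name.
#' @export
split_samples <- function(samples, manifest, split = c("train", "validation", "test")) {
  split <- match.arg(split)
  ids <- vapply(samples, function(s) s$series$participant_id, character(1))
  keep <- ids %in% manifest$participant_id[manifest$split == split]
  out <- samples[keep]
  attr(out, "split") <- split
  out
}

#' Balance the training split by duplicating the depressed class
#'
#' Every depressed (minority-class) training sample is duplicated once, so
#' the depressed count exactly doubles (e.g. 108 -> 216 under the reference
#' composition) while the non-depressed majority is untouched. Validation and
#' test splits must never be balanced.
#'
#' @param train_split List of `cohort_sample` tagged as the train split (as
#'   returned by [split_samples()]); passing another split is an error.
#' @return The balanced list of `cohort_sample`.
#' @export
balance_by_duplication <- function(train_split) {
  tag <- attr(train_split, "split")
  if (!is.null(tag) && !identical(tag, "train")) {
    stop("duplication balancing must only be applied to the train split, got '",
         tag, "'")
  }
  y <- vapply(train_split, function(s) s$y, integer(1))
  if (!any(y == 1L)) {
    warning("no depressed samples in train split; nothing to duplicate")
    return(train_split)
  }
  out <- c(train_split, train_split[y == 1L])
  attr(out, "split") <- "train"
  out
}

#' Write a split manifest to CSV
#'
#' Emits `participant_id`, `split` and `duplicate_count` (2 for depressed
#' training samples under duplication balancing, 1 otherwise).
#'
#' @param manifest A `split_manifest`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(manifest, path) {
  out <- data.frame(
    participant_id = manifest$participant_id,
    split = manifest$split,
    duplicate_count = ifelse(manifest$split == "train" & manifest$y == 1L, 2L, 1L)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
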