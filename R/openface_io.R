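# Ingestion of OpenFace-dialect per-frame feature CSVs: schema mapping,
# per-participant segment joining, the 49 -> 40 feature selection, horizon
# padding, and train-statistics z-scaling.

# The 17 action units OpenFace scores for intensity (0-5).
AU_INTENSITY_IDS <- c("01", "02", "04", "05", "06", "07", "09", "10", "12",
                      "14", "15", "17", "20", "23", "25", "26", "45")
# The 18 action units OpenFace scores for presence (0/1): the 17 above + AU28.
AU_PRESENCE_IDS <- c("01", "02", "04", "05", "06", "07", "09", "10", "12",
                     "14", "15", "17", "20", "23", "25", "26", "28", "45")

#' Canonical OpenFace feature columns
#'
#' Returns the 49 canonical per-frame feature column names grouped the way
#' the pipeline consumes them: head-pose rotation (pitch/yaw/roll, radians),
#' head-pose location (mm), per-eye 3-d gaze direction vectors, gaze angles
#' (radians), action-unit intensities (0-5) and action-unit presences (0/1).
#'
#' @param selected If `TRUE`, return only the 40 columns retained after
#'   feature selection (rotation + gaze angles + AU intensity + AU presence).
#' @return Named list of character vectors, one per feature group.
#' @export
openface_feature_columns <- function(selected = FALSE) {
  cols <- list(
    pose_rotation = c("pose_Rx", "pose_Ry", "pose_Rz"),
    pose_location = c("pose_Tx", "pose_Ty", "pose_Tz"),
    gaze_vectors  = c("gaze_0_x", "gaze_0_y", "gaze_0_z",
                      "gaze_1_x", "gaze_1_y", "gaze_1_z"),
    gaze_angles   = c("gaze_angle_x", "gaze_angle_y"),
    au_intensity  = paste0("AU", AU_INTENSITY_IDS, "_r"),
    au_presence   = paste0("AU", AU_PRESENCE_IDS, "_c")
  )
  if (selected) {
    cols[c("pose_rotation", "gaze_angles", "au_intensity", "au_presence")]
  } else {
    cols
  }
}

openface_all_columns <- function() unlist(openface_feature_columns(), use.names = FALSE)

# Column index partition of the 40 selected features, in canonical order
# Pose(3), Gaze(2), AU_r(17), AU_c(18).
feature_group_slices <- function() {
  list(Pose = 1:3, Gaze = 4:5, AU_r = 6:22, AU_c = 23:40)
}

selected_feature_names <- function() {
  unlist(openface_feature_columns(selected = TRUE), use.names = FALSE)
}

#' Read one OpenFace-dialect feature CSV
#'
#' Parses a comma-separated per-frame feature file with a header row and maps
#' its columns onto the canonical 49-feature schema (case-insensitive, with
#' surrounding whitespace in header names tolerated, as written by OpenFace
#' 2.x). Extra columns such as `confidence`, `success` or facial landmarks
#' are dropped with a notice; frames are kept as-is (no success filtering).
#'
#' @param path Path to the CSV file.
#' @return A `raw_feature_table`: a data frame with `frame`, `timestamp` and
#'   the 49 canonical feature columns.
#' @export
read_openface_csv <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  names(raw) <- trimws(names(raw))
  canon <- openface_all_columns()
  idx <- match(tolower(canon), tolower(names(raw)))
  if (anyNA(idx)) {
    stop("OpenFace schema error in '", basename(path),
         "': missing column(s) ", paste(canon[is.na(idx)], collapse = ", "))
  }
  keep_meta <- match(c("frame", "timestamp"), tolower(names(raw)))
  extra <- setdiff(names(raw), c(names(raw)[idx], names(raw)[keep_meta[!is.na(keep_meta)]]))
  if (length(extra)) {
    message("read_openface_csv: dropping ", length(extra),
            " unrecognized column(s): ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ...")
  }
  out <- raw[, idx, drop = FALSE]
  names(out) <- canon
  n <- nrow(out)
  out <- cbind(
    frame = if (!is.na(keep_meta[1])) raw[[keep_meta[1]]] else seq_len(n) - 1L,
    timestamp = if (!is.na(keep_meta[2])) raw[[keep_meta[2]]] else (seq_len(n) - 1L) / 30,
    out
  )
  validate_raw_feature_table(out, path)
  class(out) <- c("raw_feature_table", "data.frame")
  out
}

validate_raw_feature_table <- function(tab, path = "<table>") {
  if (nrow(tab) && any(diff(tab$frame) <= 0)) {
    stop("frame index not strictly increasing in ", basename(path))
  }
  pres <- as.matrix(tab[, openface_feature_columns()$au_presence, drop = FALSE])
  if (nrow(tab) && !all(pres %in% c(0, 1))) {
    stop("AU presence columns must be 0/1 in ", basename(path))
  }
  invisible(tab)
}

as_raw_feature_table <- function(df) {
  stopifnot(all(openface_all_columns() %in% names(df)))
  df <- df[, c("frame", "timestamp", openface_all_columns())]
  class(df) <- c("raw_feature_table", "data.frame")
  df
}

#' Join per-question feature segments of one participant
#'
#' Clinical interviews record one video per question, so one participant has
#' several extracted feature files. This concatenates them row-wise in the
#' given order and renumbers `frame` consecutively from 0 (timestamps are
#' rebuilt at 30 fps from the new frame index).
#'
#' @param tables List of `raw_feature_table` objects, in playback order.
#' @param fps Frames per second used to rebuild timestamps.
#' @return One `raw_feature_table` with `sum(nrow)` rows.
#' @export
join_participant_segments <- function(tables, fps = 30) {
  if (!length(tables)) stop("no segments to join")
  cols <- lapply(tables, names)
  if (!all(vapply(cols, identical, logical(1), y = cols[[1]]))) {
    stop("segment schema mismatch: all segments must share the 49-column schema")
  }
  out <- do.call(rbind, lapply(tables, as.data.frame))
  out$frame <- seq_len(nrow(out)) - 1L
  out$timestamp <- out$frame / fps
  class(out) <- c("raw_feature_table", "data.frame")
  out
}

#' Select the 40 model-input features
#'
#' Drops the 3 head-pose location columns and the 6 per-eye gaze vector
#' columns (redundant with the rotation and gaze-angle groups), keeping
#' 40 features partitioned as Pose(3), Gaze(2), AU_r(17), AU_c(18) in fixed
#' canonical order. Applying it to an already-selected `feature_series` is a
#' no-op.
#'
#' @param table A `raw_feature_table` (or an already-selected
#'   `feature_series`, returned unchanged).
#' @param participant_id Identifier stored on the result.
#' @return A `feature_series`.
#' @export
select_features <- function(table, participant_id = NA_character_) {
  UseMethod("select_features")
}

#' @export
select_features.feature_series <- function(table, participant_id = NA_character_) {
  table
}

#' @export
select_features.raw_feature_table <- function(table, participant_id = NA_character_) {
  vals <- as.matrix(as.data.frame(table)[, selected_feature_names()])
  feature_series(vals, participant_id = participant_id)
}

#' Construct a feature series
#'
#' @param values Numeric `T x 40` matrix with columns in canonical order.
#' @param participant_id Identifier string.
#' @param original_length Number of real (non-padding) frames; defaults to
#'   `nrow(values)`.
#' @return A `feature_series`: list with `values`, `group_slices`,
#'   `participant_id`, `original_length`.
#' @export
feature_series <- function(values, participant_id = NA_character_,
                           original_length = nrow(values)) {
  values <- as.matrix(values)
  if (ncol(values) != 40L) {
    stop("feature_series requires 40 columns, got ", ncol(values))
  }
  colnames(values) <- selected_feature_names()
  structure(
    list(values = values, group_slices = feature_group_slices(),
         participant_id = participant_id,
         original_length = as.integer(original_length)),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> participant=%s frames=%d (%d real) x %d features\n",
              x$participant_id, nrow(x$values), x$original_length,
              ncol(x$values)))
  invisible(x)
}

#' Zero-pad a feature series to a fixed horizon
#'
#' Appends all-zero rows until the series has `horizon` frames. The default
#' horizon corresponds to the longest supported recording: 11 min at 30 fps,
#' i.e. `11 * 60 * 30 = 19800` frames. The original (unpadded) length is kept
#' so later stages can ignore padding.
#'
#' @param series A `feature_series`.
#' @param horizon Target number of frames.
#' @return The padded `feature_series`.
#' @export
pad_to_horizon <- function(series, horizon = 19800L) {
  stopifnot(inherits(series, "feature_series"))
  n <- nrow(series$values)
  if (n > horizon) {
    stop("series has ", n, " frames, longer than the ", horizon,
         "-frame horizon")
  }
  if (n < horizon) {
    pad <- matrix(0, horizon - n, ncol(series$values))
    series$values <- rbind(series$values, pad)
    colnames(series$values) <- selected_feature_names()
  }
  series
}

#' Fit a per-feature z-scaler on training series
#'
#' Computes per-column mean and standard deviation over the real (non-padded)
#' frames of the supplied training series. Constant columns get unit scale.
#'
#' @param series_list List of `feature_series` from the training split only.
#' @return A `feature_scaler` with `center` and `scale` vectors (length 40).
#' @export
fit_feature_scaler <- function(series_list) {
  stacked <- do.call(rbind, lapply(series_list, function(s) {
    s$values[seq_len(s$original_length), , drop = FALSE]
  }))
  center <- colMeans(stacked)
  scale <- apply(stacked, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' Apply a fitted z-scaler to a feature series
#'
#' Only the first `original_length` rows are transformed, so zero padding
#' stays exactly zero (the normalization is conceptually applied before
#' padding).
#'
#' @param series A `feature_series`.
#' @param scaler A `feature_scaler` from [fit_feature_scaler()].
#' @return The normalized `feature_series`.
#' @export
apply_feature_scaler <- function(series, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  idx <- seq_len(series$original_length)
  x <- series$values[idx, , drop = FALSE]
  series$values[idx, ] <- sweep(sweep(x, 2L, scaler$center, "-"),
                                2L, scaler$scale, "/")
  series
}

#' Load a cohort from a participant manifest
#'
#' Reads a manifest CSV with columns `participant_id`, `file_path`,
#' `severity` (one of normal/mild/moderate/severe) and optionally `order`.
#' Per participant, every listed file is read, segments are joined
#' (lexicographically by file name unless `order` is given), the 40-feature
#' selection is applied, and the series is optionally padded.
#'
#' @param manifest_path Path to the manifest CSV; relative `file_path`
#'   entries are resolved against the manifest's directory.
#' @param horizon Padding horizon in frames, or `NULL` to skip padding.
#' @return List of `cohort_sample` objects.
#' @export
load_cohort <- function(manifest_path, horizon = 19800L) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("participant_id", "file_path", "severity")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  ids <- unique(man$participant_id)
  lapply(ids, function(id) {
    rows <- man[man$participant_id == id, , drop = FALSE]
    sev <- unique(rows$severity)
    if (length(sev) != 1L) stop("conflicting severities for participant ", id)
    rows <- if ("order" %in% names(rows)) {
      rows[order(rows$order), , drop = FALSE]
    } else {
      rows[order(basename(rows$file_path)), , drop = FALSE]
    }
    paths <- ifelse(file.exists(rows$file_path), rows$file_path,
                    file.path(base, rows$file_path))
    tabs <- lapply(paths, read_openface_csv)
    series <- select_features(join_participant_segments(tabs),
                              participant_id = as.character(id))
    if (!is.null(horizon)) series <- pad_to_horizon(series, horizon)
    cohort_sample(series, sev)
  })
}
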