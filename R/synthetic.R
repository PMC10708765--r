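# Synthetic OpenFace-like cohorts with planted, effect-size-controlled
# depression signatures, so the full pipeline (ingestion -> fusion models ->
# attribution) is testable without clinical recordings.
#
# Temporal model per participant:
#   * head pose rotation: mean-reverting (AR(1)/OU) jitter, plus Poisson-timed
#     raised-cosine yaw excursions ("head turning"); the excursion rate grows
#     with depression severity.
#   * gaze angles: OU random walk whose stationary sd grows with severity
#     ("no specific gaze") and whose reversion speed shrinks with severity
#     ("slow eye movement"); bounded to [-pi/2, pi/2].
#   * AU intensities: Gamma noise around a class mean, smoothed by a circular
#     moving average (mean-preserving, so planted shifts have a closed form);
#     AU07/AU20/AU26 shift up with severity, AU06/AU12/AU25 shift down.
#   * AU presences: per-frame Bernoulli with rate increasing in the matched
#     intensity, so presence columns inherit the planted signal.
# Severity scales every shift by 0 (normal), 1/3 (mild), 2/3 (moderate),
# 1 (severe), giving sub-threshold signal on the control side.

severity_multiplier <- function(level) {
  c(normal = 0, mild = 1 / 3, moderate = 2 / 3, severe = 1)[check_severity(level)]
}

#' Specify planted depression signatures
#'
#' Effect descriptors are the depressed-vs-control shifts at full severity
#' (`severe`); intermediate severities get the fraction given by
#' `severity_multiplier`. All shifts at 0 (and speed scale 1) make every
#' severity level distributionally identical.
#'
#' @param yaw_turn_rate Extra yaw-excursion events per minute at full
#'   severity (baseline 1/min).
#' @param gaze_wander_sd Extra stationary sd of the gaze-angle walk at full
#'   severity, radians (baseline 0.1).
#' @param eye_movement_speed_scale Multiplier (< 1 slows) on the gaze
#'   mean-reversion speed at full severity.
#' @param au_up Named shifts (0-5 intensity scale) added to AU means with
#'   severity; defaults to the lid tightener / lip stretcher / jaw drop trio.
#' @param au_down Named shifts subtracted from AU means with severity;
#'   defaults to the cheek raiser / lip corner puller / lips part trio.
#' @param noise_sd Named per-group noise scales (`pose` jitter sd in radians,
#'   `au` Gamma sd in intensity units).
#' @param between_sd Named between-participant random-effect scales: `au` is
#'   the sd (intensity units) of per-participant baseline offsets on each
#'   AU intensity mean, `yaw` and `gaze` are log-normal sds multiplying the
#'   participant's yaw excursion rate and gaze wander sd. These emulate
#'   individual expressiveness differences; without them, temporal averaging
#'   over a long recording makes any constant mean shift almost noiselessly
#'   separable, which no real cohort exhibits. Set them to 0 to recover the
#'   pure within-participant process (used by the closed-form tests).
#' @param fps Frames per second.
#' @param duration_s Sequence duration in seconds (default 60 s keeps
#'   desk-scale runtimes; the 11-min clinical horizon is `660`).
#' @return A `signature_spec` list.
#' @export
signature_spec <- function(yaw_turn_rate = 6,
                           gaze_wander_sd = 0.15,
                           eye_movement_speed_scale = 0.5,
                           au_up = c(AU07 = 0.6, AU20 = 0.6, AU26 = 0.8),
                           au_down = c(AU06 = 0.4, AU12 = 0.4, AU25 = 0.4),
                           noise_sd = c(pose = 0.05, au = 0.5),
                           between_sd = c(au = 0.5, yaw = 0.3, gaze = 0.2),
                           fps = 30, duration_s = 60) {
  stopifnot(yaw_turn_rate >= 0, gaze_wander_sd >= 0,
            eye_movement_speed_scale > 0, all(au_up >= 0), all(au_down >= 0),
            all(between_sd >= 0), fps > 0)
  structure(list(yaw_turn_rate = yaw_turn_rate,
                 gaze_wander_sd = gaze_wander_sd,
                 eye_movement_speed_scale = eye_movement_speed_scale,
                 au_up = au_up, au_down = au_down, noise_sd = noise_sd,
                 between_sd = between_sd,
                 fps = fps, duration_s = duration_s),
            class = "signature_spec")
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Stationary AR(1) path: exact discretization of an OU process with mean
# `mu`, stationary sd `sd_stat` and reversion speed `theta` (1/s).
ou_path <- function(n, mu, sd_stat, theta, dt) {
  if (sd_stat <= 0) return(rep(mu, n))
  phi <- exp(-theta * dt)
  innov <- rnorm(n, 0, sd_stat * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd_stat)
  mu + as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Circular moving average: preserves the mean exactly.
smooth_ma <- function(x, w) {
  w <- min(w, length(x))
  if (w <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), method = "convolution",
                           sides = 2L, circular = TRUE))
}

# Sum of Poisson-timed raised-cosine excursions (1 s wide, alternating sign).
yaw_excursions <- function(n, rate_per_min, fps, amplitude = 0.6) {
  out <- numeric(n)
  n_ev <- rpois(1, rate_per_min * n / (fps * 60))
  if (n_ev == 0) return(out)
  centers <- sort(runif(n_ev, 1, n))
  half <- fps / 2 # half-width: 0.5 s
  signs <- sample(c(-1, 1), n_ev, replace = TRUE)
  for (k in seq_len(n_ev)) {
    lo <- max(1L, floor(centers[k] - half))
    hi <- min(n, ceiling(centers[k] + half))
    t <- lo:hi
    out[t] <- out[t] + signs[k] * amplitude *
      0.5 * (1 + cos(pi * (t - centers[k]) / half))
  }
  out
}

au_mean_for <- function(au_id, m, spec, base = 1) {
  mu <- base
  key <- paste0("AU", au_id)
  if (key %in% names(spec$au_up)) mu <- mu + spec$au_up[[key]] * m
  if (key %in% names(spec$au_down)) mu <- mu - spec$au_down[[key]] * m
  max(mu, 0.05)
}

#' Generate one synthetic participant
#'
#' Draws a `T = fps * duration_s` frame, 49-column OpenFace-like feature
#' table whose distributions are shifted according to the participant's
#' severity level and the planted signature spec. Regeneration with the same
#' seed is bit-identical.
#'
#' @param label Severity level (one of `severity_levels()`).
#' @param spec A `signature_spec`.
#' @param seed Integer seed for this participant.
#' @return A `raw_feature_table`.
#' @export
generate_participant <- function(label, spec = signature_spec(), seed = 1L) {
  if (spec$duration_s <= 0) stop("duration_s must be positive")
  m <- severity_multiplier(label)
  n <- as.integer(round(spec$fps * spec$duration_s))
  dt <- 1 / spec$fps
  bsd <- spec$between_sd %||% c(au = 0, yaw = 0, gaze = 0)
  with_seed(seed, {
    # participant-level random effects, drawn once up front so the RNG
    # stream of the frame-level processes is unaffected by their values
    au_offset <- stats::setNames(rnorm(length(AU_INTENSITY_IDS), 0, bsd[["au"]]),
                                 AU_INTENSITY_IDS)
    yaw_mult <- exp(rnorm(1, 0, bsd[["yaw"]]))
    gaze_mult <- exp(rnorm(1, 0, bsd[["gaze"]]))

    pose_sd <- spec$noise_sd[["pose"]]
    pitch <- ou_path(n, 0.02, pose_sd, 1.5, dt)
    roll <- ou_path(n, 0, pose_sd, 1.5, dt)
    yaw <- ou_path(n, 0, pose_sd, 1.5, dt) +
      yaw_excursions(n, (1 + spec$yaw_turn_rate * m) * yaw_mult, spec$fps)

    tx <- ou_path(n, 0, 8, 0.5, dt)
    ty <- ou_path(n, 0, 8, 0.5, dt)
    tz <- ou_path(n, 600, 15, 0.5, dt)

    gaze_sd <- (0.1 + spec$gaze_wander_sd * m) * gaze_mult
    speed <- 1 - (1 - spec$eye_movement_speed_scale) * m
    theta_g <- 2 * speed
    ax <- pmax(-pi / 2, pmin(pi / 2, ou_path(n, 0, gaze_sd, theta_g, dt)))
    ay <- pmax(-pi / 2, pmin(pi / 2, ou_path(n, 0, gaze_sd, theta_g, dt)))

    gaze_vec <- function(ax, ay, eps) {
      vx <- sin(ax) + rnorm(n, 0, eps)
      vy <- sin(ay) + rnorm(n, 0, eps)
      vz <- -sqrt(pmax(1e-6, 1 - pmin(0.999, vx^2 + vy^2)))
      nrm <- sqrt(vx^2 + vy^2 + vz^2)
      cbind(vx, vy, vz) / nrm
    }
    g0 <- gaze_vec(ax, ay, 0.01)
    g1 <- gaze_vec(ax, ay, 0.01)

    au_sd <- spec$noise_sd[["au"]]
    au_r <- sapply(AU_INTENSITY_IDS, function(id) {
      mu <- max(au_mean_for(id, m, spec) + au_offset[[id]], 0.05)
      x <- smooth_ma(rgamma(n, shape = (mu / au_sd)^2, scale = au_sd^2 / mu), 15L)
      pmin(5, pmax(0, x))
    })
    au_c <- sapply(AU_PRESENCE_IDS, function(id) {
      p <- if (id == "28") {
        rep(0.1, n) # no intensity counterpart; fixed base rate
      } else {
        pmin(0.98, pmax(0.02, au_r[, match(id, AU_INTENSITY_IDS)] / 5))
      }
      rbinom(n, 1L, p)
    })

    out <- data.frame(frame = seq_len(n) - 1L, timestamp = (seq_len(n) - 1L) * dt,
                      pose_Rx = pitch, pose_Ry = yaw, pose_Rz = roll,
                      pose_Tx = tx, pose_Ty = ty, pose_Tz = tz,
                      gaze_0_x = g0[, 1], gaze_0_y = g0[, 2], gaze_0_z = g0[, 3],
                      gaze_1_x = g1[, 1], gaze_1_y = g1[, 2], gaze_1_z = g1[, 3],
                      gaze_angle_x = ax, gaze_angle_y = ay)
    au_r <- as.data.frame(au_r); names(au_r) <- paste0("AU", AU_INTENSITY_IDS, "_r")
    au_c <- as.data.frame(au_c); names(au_c) <- paste0("AU", AU_PRESENCE_IDS, "_c")
    out <- cbind(out, au_r, au_c)
    class(out) <- c("raw_feature_table", "data.frame")
    out
  })
}

#' Generate a synthetic cohort
#'
#' Per-participant seeds are derived deterministically from the master seed,
#' so the cohort is reproducible and individual participants can be
#' regenerated in isolation.
#'
#' @param n_per_level Named (or length-4 positional) integer counts for
#'   normal, mild, moderate, severe.
#' @param spec A `signature_spec`.
#' @param seed Master integer seed.
#' @return A `synthetic_cohort`: list with `samples` (each a list of `table`,
#'   `severity`, `participant_id`), `seed` and `spec`.
#' @export
generate_cohort <- function(n_per_level = c(normal = 106, mild = 234,
                                            moderate = 112, severe = 22),
                            spec = signature_spec(), seed = 1L) {
  if (is.null(names(n_per_level))) names(n_per_level) <- severity_levels()
  stopifnot(all(names(n_per_level) %in% severity_levels()), all(n_per_level >= 0))
  levels <- rep(names(n_per_level), times = n_per_level)
  n <- length(levels)
  child_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  samples <- lapply(seq_len(n), function(i) {
    list(table = generate_participant(levels[i], spec, child_seeds[i]),
         severity = levels[i],
         participant_id = sprintf("P%04d", i))
  })
  structure(list(samples = samples, seed = seed, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  sev <- vapply(x$samples, `[[`, character(1), "severity")
  cat("<synthetic_cohort> ", length(x$samples), " participants (",
      paste(sprintf("%s=%d", names(table(sev)), as.integer(table(sev))),
            collapse = ", "),
      "), ", x$spec$duration_s, " s @ ", x$spec$fps, " fps\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort as OpenFace-dialect CSVs plus manifest
#'
#' Writes one or more per-participant CSV segment files and a manifest CSV
#' (`participant_id`, `file_path`, `severity`), so the synthetic path
#' exercises [load_cohort()] exactly like real extracted data. With
#' `segments > 1` each participant's series is split into consecutive files,
#' exercising segment joining.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param segments Number of per-participant segment files.
#' @return The manifest path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, segments = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$samples) {
    tab <- as.data.frame(s$table)
    n <- nrow(tab)
    cuts <- unique(round(seq(0, n, length.out = segments + 1L)))
    for (k in seq_len(length(cuts) - 1L)) {
      seg <- tab[(cuts[k] + 1L):cuts[k + 1L], , drop = FALSE]
      seg$frame <- seq_len(nrow(seg)) - 1L # each segment is its own recording
      fn <- sprintf("%s_q%02d.csv", s$participant_id, k)
      utils::write.csv(seg, file.path(dir, fn), row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = s$participant_id, file_path = fn,
        severity = s$severity, order = k)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Convert an in-memory synthetic cohort to cohort samples
#'
#' Fast path that skips the CSV round-trip: applies the 40-feature selection
#' and optional padding directly to the generated tables.
#'
#' @param cohort A `synthetic_cohort`.
#' @param horizon Padding horizon in frames, or `NULL` to skip padding.
#' @return List of `cohort_sample`.
#' @export
cohort_to_samples <- function(cohort, horizon = NULL) {
  lapply(cohort$samples, function(s) {
    series <- select_features(s$table, participant_id = s$participant_id)
    if (!is.null(horizon)) series <- pad_to_horizon(series, horizon)
    cohort_sample(series, s$severity)
  })
}
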