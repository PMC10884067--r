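# Scoring of tracking-based assays: novel object recognition (NOR),
# elevated plus maze (EPM), and time-binned behavior-event counts.

#' Object exploration time from a nose/body trajectory
#'
#' A frame counts as exploration of an object when the nose is within
#' `threshold_px` pixels of the object centre AND the body centre is outside
#' the object area (a disk of `area_radius` around the centre) -- sitting on
#' the object is not exploration. Time is frames / fps.
#'
#' @param traj Tibble with columns `frame`, `nose_x`, `nose_y`, `body_x`,
#'   `body_y` (pixels, origin top-left).
#' @param objects Tibble with columns `object_id`, `center_x`, `center_y`,
#'   `area_radius`.
#' @param object_id Which object to score.
#' @param fps Frames per second.
#' @param threshold_px Nose-to-centre distance threshold, inclusive
#'   (default 8).
#' @param max_missing Maximum tolerated fraction of frames with missing nose
#'   coordinates (default 0.1); more raises a data-quality error.
#' @return Exploration time in seconds.
#' @export
exploration_time <- function(traj, objects, object_id, fps,
                             threshold_px = 8, max_missing = 0.1) {
  check_columns(traj, c("frame", "nose_x", "nose_y", "body_x", "body_y"),
                "traj")
  check_columns(objects, c("object_id", "center_x", "center_y", "area_radius"),
                "objects")
  obj <- objects[objects$object_id == object_id, ]
  if (nrow(obj) != 1) {
    stop_data(sprintf("object `%s` not found (or duplicated)", object_id))
  }
  if (!is.finite(fps) || fps <= 0) stop_data("`fps` must be positive")
  miss <- !is.finite(traj$nose_x) | !is.finite(traj$nose_y)
  if (mean(miss) > max_missing) {
    stop_data(sprintf(
      "nose coordinates missing on %.1f%% of frames (tolerance %.0f%%)",
      100 * mean(miss), 100 * max_missing
    ))
  }
  nose_d <- sqrt((traj$nose_x - obj$center_x)^2 +
                   (traj$nose_y - obj$center_y)^2)
  body_d <- sqrt((traj$body_x - obj$center_x)^2 +
                   (traj$body_y - obj$center_y)^2)
  qual <- !miss & nose_d <= threshold_px & body_d > obj$area_radius
  sum(qual, na.rm = TRUE) / fps
}

#' Discrimination index
#'
#' DI = (time exploring the novel object - time exploring the old object) /
#' total exploration time. Positive values indicate intact recognition
#' memory; DI lies in [-1, 1].
#'
#' @param t_novel,t_old Exploration times in seconds.
#' @return DI, or `NA` with a warning when total exploration is zero.
#' @export
discrimination_index <- function(t_novel, t_old) {
  total <- t_novel + t_old
  out <- (t_novel - t_old) / total
  zero <- !is.na(total) & total <= 0
  if (any(zero)) {
    warn("zero total exploration time; DI undefined, set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Score a novel-object-recognition trial
#'
#' @param traj Trajectory tibble (see [exploration_time()]).
#' @param objects Object geometry with `object_id` values `"novel"` and
#'   `"old"`.
#' @param fps Frames per second.
#' @param threshold_px Nose-distance threshold in pixels (default 8).
#' @return One-row tibble: `t_novel`, `t_old`, `di`.
#' @export
nor_score <- function(traj, objects, fps, threshold_px = 8) {
  t_novel <- exploration_time(traj, objects, "novel", fps, threshold_px)
  t_old <- exploration_time(traj, objects, "old", fps, threshold_px)
  tibble::tibble(
    t_novel = t_novel, t_old = t_old,
    di = discrimination_index(t_novel, t_old)
  )
}

#' Elevated-plus-maze zone geometry
#'
#' Axis-aligned rectangular zones (two open arms, two closed arms, centre).
#' The default lays out a 500 x 500 px maze with 100 px-wide arms: open arms
#' horizontal, closed arms vertical.
#'
#' @param arm_length Arm length in px (default 200).
#' @param arm_width Arm width in px (default 100).
#' @return Tibble with `zone` (`open`, `closed`, `center`), `xmin`, `xmax`,
#'   `ymin`, `ymax` (one row per rectangle).
#' @export
epm_geometry <- function(arm_length = 200, arm_width = 100) {
  c0 <- arm_length
  c1 <- arm_length + arm_width
  tibble::tribble(
    ~zone,    ~xmin,        ~xmax,            ~ymin,        ~ymax,
    "center", c0,           c1,               c0,           c1,
    "open",   0,            c0,               c0,           c1,
    "open",   c1,           c1 + arm_length,  c0,           c1,
    "closed", c0,           c1,               0,            c0,
    "closed", c0,           c1,               c1,           c1 + arm_length
  )
}

#' Elevated-plus-maze metrics from a body-centre trajectory
#'
#' Assigns each frame to a zone by the body centre (standard EPM
#' convention), returning per-zone dwell times, latency to first open-arm
#' entry (trial duration if never), and the closed-arm fraction of the
#' trial. Frames falling outside every zone are assigned to the nearest
#' zone and their count reported.
#'
#' @param traj Tibble with columns `frame`, `body_x`, `body_y`.
#' @param geometry Zone rectangles as from [epm_geometry()].
#' @param fps Frames per second.
#' @param trial_duration Trial length in seconds (default `n_frames / fps`).
#' @return One-row tibble: `t_open`, `t_closed`, `t_center`, `open_latency`,
#'   `closed_fraction` (%), `n_outside_frames`.
#' @export
epm_metrics <- function(traj, geometry = epm_geometry(), fps,
                        trial_duration = NULL) {
  check_columns(traj, c("frame", "body_x", "body_y"), "traj")
  check_columns(geometry, c("zone", "xmin", "xmax", "ymin", "ymax"),
                "geometry")
  if (!is.finite(fps) || fps <= 0) stop_data("`fps` must be positive")
  n <- nrow(traj)
  trial_duration <- trial_duration %||% (n / fps)

  # distance from each frame to each rectangle (0 if inside)
  dists <- vapply(seq_len(nrow(geometry)), function(j) {
    g <- geometry[j, ]
    dx <- pmax(g$xmin - traj$body_x, 0, traj$body_x - g$xmax)
    dy <- pmax(g$ymin - traj$body_y, 0, traj$body_y - g$ymax)
    sqrt(dx^2 + dy^2)
  }, numeric(n))
  nearest <- apply(dists, 1, which.min)
  outside <- dists[cbind(seq_len(n), nearest)] > 0
  zone <- geometry$zone[nearest]

  t_zone <- function(z) sum(zone == z) / fps
  open_frames <- which(zone == "open")
  open_latency <- if (length(open_frames) == 0) {
    trial_duration
  } else {
    (open_frames[1] - 1) / fps
  }
  tibble::tibble(
    t_open = t_zone("open"),
    t_closed = t_zone("closed"),
    t_center = t_zone("center"),
    open_latency = open_latency,
    closed_fraction = 100 * t_zone("closed") / trial_duration,
    n_outside_frames = sum(outside)
  )
}

#' Time-binned behavior-event counts
#'
#' Counts time-stamped behavior events in half-open bins
#' `[k w, (k + 1) w)`; totals are conserved for any bin width.
#'
#' @param events Tibble with columns `t_seconds` and `behavior`.
#' @param bin_width Bin width in seconds (default 600 = 10 min).
#' @param session_duration Session length in seconds; defaults to the last
#'   event time rounded up to a whole bin.
#' @return Tibble with `behavior`, `bin` (0-based), `t_start`, `count`,
#'   complete over all bins and observed behaviors (zeros included).
#' @export
bin_counts <- function(events, bin_width = 600, session_duration = NULL) {
  check_columns(events, c("t_seconds", "behavior"), "events")
  if (any(events$t_seconds < 0)) {
    stop_data("negative event timestamps are not allowed")
  }
  session_duration <- session_duration %||%
    (if (nrow(events) == 0) bin_width else
       ceiling(max(events$t_seconds) / bin_width) * bin_width)
  if (nrow(events) > 0 && max(events$t_seconds) > session_duration) {
    stop_data("events fall outside the session duration")
  }
  n_bins <- max(1L, as.integer(ceiling(session_duration / bin_width)))
  if (nrow(events) > 0) {
    # an event exactly at the session end belongs to the next half-open bin
    n_bins <- max(n_bins, as.integer(floor(max(events$t_seconds) / bin_width)) + 1L)
  }
  behaviors <- sort(unique(as.character(events$behavior)))
  if (length(behaviors) == 0) behaviors <- NA_character_
  grid <- tidyr::expand_grid(
    behavior = behaviors, bin = seq_len(n_bins) - 1L
  )
  counted <- events |>
    dplyr::mutate(
      bin = as.integer(floor(.data$t_seconds / bin_width)),
      behavior = as.character(.data$behavior)
    ) |>
    dplyr::count(.data$behavior, .data$bin, name = "count")
  grid |>
    dplyr::left_join(counted, by = c("behavior", "bin")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      t_start = .data$bin * bin_width
    ) |>
    dplyr::select("behavior", "bin", "t_start", "count")
}
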