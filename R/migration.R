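#' Preprocess a migration track: burn-in removal and gap handling
#'
#' Drops all samples earlier than `burn_in_min` minutes (the settling
#' period of the slice in the imaging chamber) and re-zeroes time to the
#' first retained sample. Missed detections are bridged by linear
#' interpolation when at most `max_gap_frames` consecutive frames are
#' missing; longer gaps raise an error (split such tracks upstream).
#'
#' @param track data.frame with columns `t_min`, `x_um`, `y_um` (one
#'   track).
#' @param burn_in_min burn-in duration in minutes (default 60).
#' @param max_gap_frames largest run of missing frames bridged by linear
#'   interpolation.
#' @return the preprocessed track, times re-zeroed.
#' @export
preprocess_track <- function(track, burn_in_min = 60, max_gap_frames = 2) {
  if (is.null(track) || nrow(track) == 0) stop("empty track", call. = FALSE)
  track <- track[order(track$t_min), , drop = FALSE]
  if (anyDuplicated(track$t_min)) {
    stop("duplicate timestamps in track", call. = FALSE)
  }
  keep <- track$t_min >= burn_in_min
  if (sum(keep) < 2) {
    stop("track excluded: fewer than 2 samples after burn-in removal",
         call. = FALSE)
  }
  track <- track[keep, , drop = FALSE]
  dts <- diff(track$t_min)
  dt <- min(dts)
  if (any(dts > (max_gap_frames + 1) * dt + 1e-9)) {
    stop("track has a gap longer than ", max_gap_frames,
         " frames; split it before analysis", call. = FALSE)
  }
  if (any(dts > dt + 1e-9)) {
    full_t <- seq(track$t_min[1], track$t_min[nrow(track)], by = dt)
    track <- data.frame(
      t_min = full_t,
      x_um = approx(track$t_min, track$x_um, xout = full_t)$y,
      y_um = approx(track$t_min, track$y_um, xout = full_t)$y
    )
  }
  track$t_min <- track$t_min - track$t_min[1]
  rownames(track) <- NULL
  track
}

#' Migration metrics of one track
#'
#' Computes path length (sum of consecutive Euclidean steps, um), net
#' displacement (first-to-last distance, um), duration (hours), speed
#' (path length divided by duration, um/h) and directional persistence
#' (net displacement divided by path length, in [0, 1]; 0 with a
#' `stationary` flag when the cell never moves).
#'
#' @param track preprocessed track data.frame (`t_min`, `x_um`, `y_um`),
#'   at least 2 samples.
#' @return one-row data.frame: `speed`, `persistence`, `path_length`,
#'   `net_displacement`, `duration`, `stationary`.
#' @export
track_metrics <- function(track) {
  if (nrow(track) < 2) stop("track needs at least 2 samples", call. = FALSE)
  if (anyDuplicated(track$t_min)) {
    stop("duplicate timestamps in track", call. = FALSE)
  }
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  path <- sum(steps)
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
              (track$y_um[nrow(track)] - track$y_um[1])^2)
  duration <- (track$t_min[nrow(track)] - track$t_min[1]) / 60
  stationary <- path == 0
  data.frame(
    speed = path / duration,
    persistence = if (stationary) 0 else net / path,
    path_length = path,
    net_displacement = net,
    duration = duration,
    stationary = stationary
  )
}

#' Metrics for every track in a long-format table
#'
#' Convenience wrapper: splits a `track_id`-keyed table, preprocesses
#' each track and computes its metrics. Tracks excluded by preprocessing
#' (e.g. entirely within the burn-in window) are reported in the
#' `excluded` attribute with the reason.
#'
#' @param tracks data.frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um` and optionally `group`.
#' @param burn_in_min passed to [preprocess_track()].
#' @return data.frame of per-track metrics (with `track_id` and, if
#'   present, `group`), attribute `excluded`.
#' @export
tracks_metrics <- function(tracks, burn_in_min = 60) {
  ids <- unique(tracks$track_id)
  excluded <- character(0)
  rows <- list()
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    m <- tryCatch(track_metrics(preprocess_track(tr, burn_in_min)),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) {
      excluded[id] <- m
      next
    }
    m$track_id <- id
    if ("group" %in% names(tr)) m$group <- tr$group[1]
    rows[[id]] <- m
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Compare migration metrics between two graft groups
#'
#' Per metric (speed and persistence): group means, standard errors of
#' the mean, and a two-sided unpaired Student's t-test
#' (pooled-variance by default, Welch via `var_equal = FALSE`). When
#' both groups are constant and equal the comparison is reported with
#' `t = 0, p = 1`.
#'
#' @param metrics_a,metrics_b per-track metric data.frames (from
#'   [track_metrics()] / [tracks_metrics()]), >= 2 tracks each.
#' @param metrics which metric columns to compare.
#' @param var_equal pooled-variance t-test (classic unpaired Student)
#'   when `TRUE`.
#' @return data.frame with one row per metric: `mean_a`, `sem_a`,
#'   `mean_b`, `sem_b`, `t`, `df`, `p`.
#' @export
compare_groups <- function(metrics_a, metrics_b,
                           metrics = c("speed", "persistence"),
                           var_equal = TRUE) {
  if (nrow(metrics_a) < 2 || nrow(metrics_b) < 2) {
    stop("each group needs at least 2 tracks", call. = FALSE)
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  rows <- lapply(metrics, function(mname) {
    a <- metrics_a[[mname]]; b <- metrics_b[[mname]]
    tt <- tryCatch(t.test(a, b, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      tstat <- 0; p <- 1; df <- length(a) + length(b) - 2
      if (!isTRUE(all.equal(mean(a), mean(b)))) {
        ## constant but unequal groups: infinite evidence of a difference
        tstat <- Inf * sign(mean(a) - mean(b)); p <- 0
      }
    } else {
      tstat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
    }
    data.frame(metric = mname,
               mean_a = mean(a), sem_a = sem(a),
               mean_b = mean(b), sem_b = sem(b),
               t = tstat, df = df, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
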