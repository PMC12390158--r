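# Task segmentation: hop-burst detection, task-session candidates, task /
# repetition windows, and activity-label up-sampling.

#' Detect hop bursts from an acceleration-magnitude series
#'
#' A burst is a group of threshold crossings of the rectified gravity
#' deviation `| |acc| - 1 g |` with at least `min_crossings` crossings
#' (both directions count) and quiet margins (deviation below threshold)
#' of at least `quiet_s` before and after.
#'
#' @param time Timestamps (s).
#' @param accel_mag Acceleration magnitude (g).
#' @param thresh_g Deviation threshold (g), > 0; default 0.5.
#' @param quiet_s Required quiet margin (s).
#' @param min_crossings Minimum number of threshold crossings per burst.
#' @return data.frame of hop events: start_s, end_s, n_crossings.
#' @export
detect_hops <- function(time, accel_mag, thresh_g = 0.5, quiet_s = 2,
                        min_crossings = 4) {
  if (thresh_g <= 0) stop("threshold must be > 0")
  dev <- abs(accel_mag - 1)
  above <- dev > thresh_g
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_crossings = integer(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- data.frame(start_i = starts_i[r$values], end_i = ends_i[r$values])
  # group above-threshold runs separated by less than quiet_s into bursts
  gap <- time[runs$start_i[-1]] - time[runs$end_i[-nrow(runs)]]
  grp <- cumsum(c(1, as.integer(gap >= quiet_s)))
  rows <- list()
  for (g in unique(grp)) {
    rr <- runs[grp == g, , drop = FALSE]
    # each run contributes an upward and a downward crossing (edges at the
    # record boundary do not count)
    n_cross <- 2L * nrow(rr)
    i0 <- rr$start_i[1]; i1 <- rr$end_i[nrow(rr)]
    if (i0 == 1) n_cross <- n_cross - 1L
    if (i1 == length(dev)) n_cross <- n_cross - 1L
    if (n_cross < min_crossings) next
    # quiet margins must exist (and be quiet) before and after the burst
    t0 <- time[i0]; t1 <- time[i1]
    if (t0 - time[1] < quiet_s) next
    if (time[length(time)] - t1 < quiet_s) next
    pre <- time >= t0 - quiet_s & time < t0
    post <- time > t1 & time <= t1 + quiet_s
    if (any(dev[pre] > thresh_g) || any(dev[post] > thresh_g)) next
    rows[[length(rows) + 1]] <- data.frame(start_s = t0, end_s = t1,
                                           n_crossings = n_cross)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Find candidate standardized-task sessions from hop events
#'
#' Maximal time windows containing at least `min_bursts` hop events whose
#' first and last events lie within `span_s` of each other.
#'
#' @param hops data.frame from [detect_hops()], time-ordered.
#' @param min_bursts Minimum number of hop events per session.
#' @param span_s Maximum span (s) from first to last event in the window.
#' @return data.frame of candidate sessions: start_s, end_s, n_bursts.
#' @export
find_task_sessions <- function(hops, min_bursts = 10, span_s = 3600) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_bursts = integer(0))
  n <- nrow(hops)
  if (n < min_bursts) return(empty)
  t <- hops$start_s
  wins <- list()
  for (i in seq_len(n - min_bursts + 1)) {
    j <- max(which(t - t[i] <= span_s))
    if (j - i + 1 >= min_bursts) wins[[length(wins) + 1]] <- c(i, j)
  }
  if (!length(wins)) return(empty)
  # merge windows that overlap in time into maximal sessions
  wins <- wins[order(vapply(wins, `[`, 0, 1))]
  merged <- list(wins[[1]])
  for (w in wins[-1]) {
    last <- merged[[length(merged)]]
    if (w[1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], w[2]))
    else merged[[length(merged) + 1]] <- w
  }
  do.call(rbind, lapply(merged, function(w) data.frame(
    start_s = hops$start_s[w[1]], end_s = hops$end_s[w[2]],
    n_bursts = w[2] - w[1] + 1L)))
}

#' Segment a candidate session into task windows
#'
#' Three marker modes stand in for the study's manual review:
#' `markers = "auto"` binds each protocol task to the interval between
#' consecutive hop bursts (protocol order assumed), splitting 3-rep tasks
#' into equal thirds; a marker data.frame (`task_id, start_s, end_s`,
#' optional `rep_index`) is passed through as reviewed windows; a flag
#' data.frame (`event_time_s, flag_type` with paired start/end flags) yields
#' windows equal to the flag intervals.
#'
#' @param session One row of [find_task_sessions()] (or any list with
#'   start_s / end_s), used in auto mode.
#' @param hops Hop events within the session (auto mode).
#' @param markers `"auto"`, a marker data.frame, or a flag data.frame.
#' @param protocol Protocol table ([default_protocol()]).
#' @param condition Condition label attached to the windows.
#' @return data.frame of task windows: task_id, condition, start_s, end_s,
#'   provenance; with attribute `reps` (task_id, rep, start_s, end_s).
#' @export
segment_tasks <- function(session = NULL, hops = NULL, markers = "auto",
                          protocol = default_protocol(),
                          condition = "rw") {
  rep_tasks <- protocol$task_id[protocol$kind == "rom"]
  reps <- NULL
  if (is.data.frame(markers) && all(c("event_time_s", "flag_type") %in%
                                    names(markers))) {
    st <- markers$event_time_s[markers$flag_type == "start"]
    en <- markers$event_time_s[markers$flag_type == "end"]
    if (length(st) != nrow(protocol) || length(en) != nrow(protocol))
      stop(sprintf("flag/task count mismatch: %d starts, %d ends for %d tasks",
                   length(st), length(en), nrow(protocol)))
    win <- data.frame(task_id = protocol$task_id, condition = condition,
                      start_s = sort(st), end_s = sort(en),
                      provenance = "flag")
  } else if (is.data.frame(markers)) {
    if (!all(c("task_id", "start_s", "end_s") %in% names(markers)))
      stop("marker file must have task_id, start_s, end_s")
    if (!setequal(unique(markers$task_id), protocol$task_id))
      stop(sprintf("marker/task mismatch: %d tasks marked, %d in protocol",
                   length(unique(markers$task_id)), nrow(protocol)))
    if (!"rep_index" %in% names(markers)) markers$rep_index <- NA
    base <- markers[is.na(markers$rep_index), ]
    win <- data.frame(task_id = base$task_id, condition = condition,
                      start_s = base$start_s, end_s = base$end_s,
                      provenance = "manual")
    mk_reps <- markers[!is.na(markers$rep_index), ]
    if (nrow(mk_reps))
      reps <- data.frame(task_id = mk_reps$task_id, rep = mk_reps$rep_index,
                         start_s = mk_reps$start_s, end_s = mk_reps$end_s)
  } else if (identical(markers, "auto")) {
    if (is.null(hops)) stop("auto mode needs hop events")
    h <- hops[hops$start_s >= session$start_s - 1 &
              hops$end_s <= session$end_s + 1, , drop = FALSE]
    if (nrow(h) != nrow(protocol))
      stop(sprintf("auto mode: %d hop bursts for %d protocol tasks",
                   nrow(h), nrow(protocol)))
    h <- h[order(h$start_s), ]
    # task k runs from just after burst k to just before burst k+1; the
    # last task (no following burst) gets its nominal protocol duration
    starts <- h$end_s + BURST_MARGIN_S
    last <- nrow(protocol)
    nominal_last <- if (protocol$kind[last] %in% c("static", "timed"))
      protocol$duration_s[last]
    else protocol$reps[last] * (2 * ROM_RAMP_S + ROM_HOLD_S) +
      (protocol$reps[last] - 1) * ROM_PAUSE_S
    ends <- c(h$start_s[-1] - BURST_MARGIN_S,
              starts[nrow(h)] + nominal_last + 1)
    win <- data.frame(task_id = protocol$task_id, condition = condition,
                      start_s = starts, end_s = ends, provenance = "hop")
  } else {
    stop("markers must be 'auto', a marker data.frame, or a flag data.frame")
  }
  if (any(win$start_s >= win$end_s)) stop("task windows must have start < end")
  win <- win[match(protocol$task_id, win$task_id), ]
  rownames(win) <- NULL
  if (is.null(reps)) {
    # equal thirds for 3-rep tasks
    reps <- do.call(rbind, lapply(which(win$task_id %in% rep_tasks), function(i) {
      br <- seq(win$start_s[i], win$end_s[i], length.out = 4)
      data.frame(task_id = win$task_id[i], rep = 1:3,
                 start_s = br[1:3], end_s = br[2:4])
    }))
    if (is.null(reps)) reps <- data.frame(task_id = character(0),
                                          rep = integer(0),
                                          start_s = numeric(0),
                                          end_s = numeric(0))
  }
  attr(win, "reps") <- reps
  win
}

#' Up-sample 1 Hz activity labels to the sensor rate
#'
#' Each second's label is held constant over its samples; seconds without a
#' label become `"unknown"`.
#'
#' @param labels data.frame with `time_s` (integer seconds) and `activity`.
#' @param time Target sample timestamps (s).
#' @return Character vector of per-sample labels, same length as `time`.
#' @export
upsample_labels <- function(labels, time) {
  sec <- floor(time)
  idx <- match(sec, labels$time_s)
  out <- labels$activity[idx]
  n_unknown <- sum(is.na(out))
  if (n_unknown > 0) {
    out[is.na(out)] <- "unknown"
    message(sprintf("upsample_labels: %d samples without a label set to 'unknown'",
                    n_unknown))
  }
  out
}
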