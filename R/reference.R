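# Reference-posture ("zero") estimation: five strategies differing in which
# data define the zero angle, and their application to joint-angle series.
#
# Data model: a participant's data is a named list of *condition entries*
# ("lab", "rw1", "rw2"), each a list with
#   joint   - joint_angle_series for that condition's span
#   tasks   - task-window data.frame (attr "reps" for 3-rep tasks)
#   labels  - per-sample activity labels (character), optional
#   mask    - quality_mask, optional (masked samples excluded from all
#             reference estimates)
#   session - sensor-set / recording session the condition belongs to
#             ("lab" for the lab set; "rw" for both real-world days)

REFERENCE_METHODS <- c("lab", "session", "day", "composite", "median_standing")

# Unmasked sample selector for a condition entry.
usable_idx <- function(entry) {
  if (is.null(entry$mask)) rep(TRUE, length(entry$joint$time))
  else !entry$mask$exclude
}

# Per-axis statistic over samples of a condition entry within [t0, t1].
window_stat <- function(entry, t0, t1, stat = mean) {
  idx <- entry$joint$time >= t0 & entry$joint$time <= t1 & usable_idx(entry)
  if (!any(idx)) return(NULL)
  list(offset = apply(entry$joint$angles[idx, , drop = FALSE], 2, stat),
       n = sum(idx))
}

standing_offset <- function(entry) {
  w <- entry$tasks[entry$tasks$task_id == "standing", , drop = FALSE]
  if (nrow(w) == 0)
    stop("method-unavailable: no standing task window in condition")
  res <- window_stat(entry, w$start_s[1], w$end_s[1], mean)
  if (is.null(res))
    stop("method-unavailable: standing task fully masked")
  res
}

#' Compute reference postures for one participant
#'
#' Five strategies:
#' \describe{
#'   \item{lab}{Mean joint angle over the laboratory standardized standing
#'     task, applied globally.}
#'   \item{session}{The same statistic from each recording session's own
#'     standing task (the real-world session is anchored on its first
#'     standing task, i.e. day 1's).}
#'   \item{day}{A separate standing-task reference per day (the lab session
#'     counts as its own day).}
#'   \item{composite}{Median over all samples within all standardized task
#'     windows of the session.}
#'   \item{median_standing}{Median over all samples labelled standing in the
#'     session (stepping and masked samples excluded).}
#' }
#' Masked samples are excluded from every estimate.
#'
#' @param method One of `"lab"`, `"session"`, `"day"`, `"composite"`,
#'   `"median_standing"`.
#' @param conditions Named list of condition entries (see file header);
#'   typically `lab`, `rw1`, `rw2`.
#' @return An object of class `reference_posture`: data.frame with method,
#'   scope_type (global/session/day), scope, per-axis offsets (deg) and
#'   source-sample counts.
#' @export
compute_reference <- function(method, conditions) {
  method <- match.arg(method, REFERENCE_METHODS)
  rows <- list()
  add <- function(scope_type, scope, res)
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, scope_type = scope_type, scope = scope,
      latflex = res$offset[["latflex"]], flexext = res$offset[["flexext"]],
      rot = res$offset[["rot"]], n_samples = res$n)

  sessions <- split(names(conditions),
                    vapply(conditions, function(e) e$session, ""))
  if (method == "lab") {
    if (!"lab" %in% names(conditions))
      stop("method-unavailable: lab method needs a lab condition")
    add("global", "all", standing_offset(conditions[["lab"]]))
  } else if (method == "session") {
    for (s in names(sessions))
      add("session", s, standing_offset(conditions[[sessions[[s]][1]]]))
  } else if (method == "day") {
    for (d in names(conditions))
      add("day", d, standing_offset(conditions[[d]]))
  } else if (method == "composite") {
    for (s in names(sessions)) {
      vals <- list(); n <- 0
      for (d in sessions[[s]]) {
        entry <- conditions[[d]]
        for (i in seq_len(nrow(entry$tasks))) {
          idx <- entry$joint$time >= entry$tasks$start_s[i] &
            entry$joint$time <= entry$tasks$end_s[i] & usable_idx(entry)
          if (any(idx)) {
            vals[[length(vals) + 1]] <- entry$joint$angles[idx, , drop = FALSE]
            n <- n + sum(idx)
          }
        }
      }
      if (!length(vals))
        stop("method-unavailable: all task windows masked in session ", s)
      pooled <- do.call(rbind, vals)
      add("session", s, list(offset = apply(pooled, 2, stats::median), n = n))
    }
  } else if (method == "median_standing") {
    for (s in names(sessions)) {
      vals <- list(); n <- 0
      for (d in sessions[[s]]) {
        entry <- conditions[[d]]
        if (is.null(entry$labels))
          stop("method-unavailable: median_standing needs activity labels")
        idx <- entry$labels == "standing" & usable_idx(entry)
        if (any(idx)) {
          vals[[length(vals) + 1]] <- entry$joint$angles[idx, , drop = FALSE]
          n <- n + sum(idx)
        }
      }
      if (!length(vals))
        stop("method-unavailable: no usable standing samples in session ", s)
      pooled <- do.call(rbind, vals)
      add("session", s, list(offset = apply(pooled, 2, stats::median), n = n))
    }
  }
  structure(do.call(rbind, rows), class = c("reference_posture", "data.frame"))
}

#' Apply a reference posture to a participant's joint-angle series
#'
#' Subtracts the per-axis offsets over each reference row's scope.
#'
#' @param conditions Named list of condition entries.
#' @param ref A [compute_reference()] result.
#' @return The conditions list with `joint$angles` shifted.
#' @export
apply_reference <- function(conditions, ref) {
  for (i in seq_len(nrow(ref))) {
    row <- ref[i, ]
    targets <- switch(row$scope_type,
      global = names(conditions),
      session = names(conditions)[vapply(conditions, function(e)
        identical(e$session, row$scope), TRUE)],
      day = row$scope)
    if (!length(targets) || any(!targets %in% names(conditions)))
      stop("reference scope '", row$scope, "' does not cover the data")
    off <- c(row$latflex, row$flexext, row$rot)
    for (d in targets) {
      # keep the raw angles: relative measures (ROM) are mathematically
      # invariant to the reference and are computed from them exactly
      if (is.null(conditions[[d]]$joint$raw))
        conditions[[d]]$joint$raw <- conditions[[d]]$joint$angles
      conditions[[d]]$joint$angles <-
        sweep(conditions[[d]]$joint$angles, 2, off)
    }
  }
  conditions
}

#' Write a reference-posture table as delimited text
#' @param refs A `reference_posture` (or rbind of several).
#' @param path Output path. @param participant Optional id column value.
#' @export
write_reference_table <- function(refs, path, participant = NA) {
  out <- cbind(participant = participant, as.data.frame(refs))
  data.table::fwrite(out, path)
  invisible(path)
}
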