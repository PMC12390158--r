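# Outcome measures (range of motion, starting posture), repetition
# averaging, and the two-way random-effects absolute-agreement
# average-measures intraclass correlation ICC(A,k).

#' Range of motion over a task window
#'
#' Max minus min of the chosen angle axis over unmasked samples.
#'
#' @param joint A [joint_angle_series()].
#' @param start_s,end_s Window bounds (s).
#' @param mask Optional `quality_mask` (its union flags are honored).
#' @param axis Angle axis, default `"flexext"`.
#' @return ROM in degrees, or NA if fewer than 2 unmasked samples.
#' @export
range_of_motion <- function(joint, start_s, end_s, mask = NULL,
                            axis = "flexext") {
  idx <- joint$time >= start_s & joint$time <= end_s
  if (!is.null(mask)) idx <- idx & !mask$exclude
  # use the pre-reference angles when available: a constant offset cancels
  # in max - min, so this is the same quantity without rounding noise
  ang <- if (!is.null(joint$raw)) joint$raw else joint$angles
  v <- ang[idx, axis]
  if (length(v) < 2) return(NA_real_)
  max(v) - min(v)
}

#' Starting posture of a task window
#'
#' Mean of the angle over the first `n_samples` unmasked samples of the
#' window (masked samples are skipped and the window extended).
#'
#' @inheritParams range_of_motion
#' @param n_samples Number of initial samples to average (default 5).
#' @return Starting posture in degrees, or NA if fewer than `n_samples`
#'   unmasked samples exist in the window.
#' @export
starting_posture <- function(joint, start_s, end_s, mask = NULL,
                             axis = "flexext", n_samples = 5) {
  idx <- which(joint$time >= start_s & joint$time <= end_s)
  if (!is.null(mask)) idx <- idx[!mask$exclude[idx]]
  if (length(idx) < n_samples) return(NA_real_)
  mean(joint$angles[idx[seq_len(n_samples)], axis])
}

#' Average an outcome across repetitions
#'
#' @param values Numeric vector of per-repetition values (NAs = missing
#'   reps).
#' @return Mean of the available values with attributes `n_used` and
#'   `incomplete`; NA if none are available.
#' @export
aggregate_reps <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) return(structure(NA_real_, n_used = 0L, incomplete = TRUE))
  structure(mean(values[ok]), n_used = sum(ok),
            incomplete = any(!ok))
}

#' Two-way random-effects absolute-agreement average-measures ICC
#'
#' ICC(A,k) of McGraw & Wong: `(MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' where MSR, MSC and MSE are the rows (targets), columns (conditions) and
#' error mean squares of the two-way ANOVA without replication.  Rows with
#' any missing value are removed (listwise deletion).  Negative estimates
#' are reported as-is.
#'
#' @param x Numeric matrix, participants (targets) in rows, conditions in
#'   columns.
#' @return An object of class `icc_result`: list(icc, MSR, MSC, MSE, n, k,
#'   band, method).
#' @export
icc_2k <- function(x) {
  x <- as.matrix(x)
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("insufficient data: fewer than 2 complete rows")
  if (k < 2) stop("need at least 2 conditions")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  SST <- sum((x - grand)^2)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (MSC - MSE) / n
  icc <- if (denom == 0) NA_real_ else (MSR - MSE) / denom
  structure(list(icc = icc, MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k,
                 band = if (is.na(icc)) NA_character_ else interpret_icc(icc),
                 method = "ICC(A,k): two-way random, absolute agreement, average measures"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.3f (%s; n = %d)\n", x$k, x$icc, x$band, x$n))
  invisible(x)
}

#' F-based confidence interval for ICC(A,k)
#'
#' Computed for completeness (the headline analyses report point estimates).
#'
#' @param res An [icc_2k()] result. @param level Confidence level.
#' @return Length-2 vector (lower, upper).
#' @export
icc_2k_ci <- function(res, level = 0.95) {
  n <- res$n; k <- res$k
  MSR <- res$MSR; MSC <- res$MSC; MSE <- res$MSE
  # single-measures estimate and its F-based bounds (Satterthwaite dof),
  # then Spearman-Brown step-up to average measures
  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  Fl <- stats::qf(1 - (1 - level) / 2, n - 1, v)
  Fu <- stats::qf(1 - (1 - level) / 2, v, n - 1)
  L1 <- n * (MSR - Fl * MSE) /
    (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  U1 <- n * (Fu * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  c(lower = sb(L1), upper = sb(U1))
}

#' Interpretation band for an ICC value
#'
#' poor < 0.5 <= moderate <= 0.75 < good <= 0.9 < excellent.
#'
#' @param value Finite ICC value.
#' @return One of "poor", "moderate", "good", "excellent".
#' @export
interpret_icc <- function(value) {
  if (!is.finite(value)) stop("ICC value must be finite")
  if (value < 0.5) "poor"
  else if (value <= 0.75) "moderate"
  else if (value <= 0.9) "good"
  else "excellent"
}

#' Compute the outcome table for a cohort of participants
#'
#' For every participant, task and condition: the repetition-averaged range
#' of motion on the task's primary axis, and the starting posture on the
#' flexion-extension axis.
#'
#' @param cohort_conditions Named list (by participant id) of condition
#'   lists as used by [compute_reference()].
#' @param protocol Protocol table (for each task's primary axis).
#' @return data.frame: participant, task_id, condition, measure, axis,
#'   value.
#' @export
outcome_table <- function(cohort_conditions, protocol = default_protocol()) {
  rows <- list()
  for (pid in names(cohort_conditions)) {
    conds <- cohort_conditions[[pid]]
    for (cond in names(conds)) {
      entry <- conds[[cond]]
      reps <- attr(entry$tasks, "reps")
      for (i in seq_len(nrow(entry$tasks))) {
        tid <- entry$tasks$task_id[i]
        axis <- protocol$axis[protocol$task_id == tid]
        if (!length(axis)) axis <- "flexext"
        rr <- reps[reps$task_id == tid, , drop = FALSE]
        rom <- if (nrow(rr)) {
          aggregate_reps(vapply(seq_len(nrow(rr)), function(j)
            range_of_motion(entry$joint, rr$start_s[j], rr$end_s[j],
                            entry$mask, axis), numeric(1)))
        } else {
          range_of_motion(entry$joint, entry$tasks$start_s[i],
                          entry$tasks$end_s[i], entry$mask, axis)
        }
        start <- starting_posture(entry$joint, entry$tasks$start_s[i],
                                  entry$tasks$end_s[i], entry$mask,
                                  axis = "flexext")
        rows[[length(rows) + 1]] <- data.frame(
          participant = pid, task_id = tid, condition = cond,
          measure = c("ROM", "start"), axis = c(axis, "flexext"),
          value = c(as.numeric(rom), start))
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-task ICC repeatability report
#'
#' One ICC(A,k) per (task, measure) across participants x conditions, plus
#' the unweighted mean and s.d. across tasks.  Participants missing any
#' condition for a task are dropped listwise; tasks with fewer than 2
#' complete participants are omitted and listed.
#'
#' @param outcomes An [outcome_table()] result (computed under one
#'   reference method).
#' @param measure `"start"` or `"ROM"`.
#' @return An object of class `repeatability_report`: data.frame of per-task
#'   ICCs with attributes `mean`, `sd` and `omitted`.
#' @export
repeatability_report <- function(outcomes, measure = "start") {
  oo <- outcomes[outcomes$measure == measure, ]
  tasks <- unique(oo$task_id)
  conds <- sort(unique(oo$condition))
  rows <- list(); omitted <- character(0)
  for (tid in tasks) {
    sub <- oo[oo$task_id == tid, ]
    m <- matrix(NA_real_, length(unique(sub$participant)), length(conds),
                dimnames = list(unique(sub$participant), conds))
    for (i in seq_len(nrow(sub)))
      m[sub$participant[i], sub$condition[i]] <- sub$value[i]
    res <- tryCatch(icc_2k(m), error = function(e) NULL)
    if (is.null(res) || is.na(res$icc)) { omitted <- c(omitted, tid); next }
    rows[[length(rows) + 1]] <- data.frame(
      task_id = tid, measure = measure, icc = res$icc, n = res$n,
      k = res$k, band = res$band)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(task_id = character(0), measure = character(0),
               icc = numeric(0), n = integer(0), k = integer(0),
               band = character(0))
  attr(out, "mean") <- mean(out$icc)
  attr(out, "sd") <- stats::sd(out$icc)
  attr(out, "omitted") <- omitted
  class(out) <- c("repeatability_report", "data.frame")
  out
}

#' @export
print.repeatability_report <- function(x, ...) {
  print.data.frame(x)
  cat(sprintf("Mean ICC across tasks: %.3f (sd %.3f)\n",
              attr(x, "mean"), attr(x, "sd")))
  if (length(attr(x, "omitted")))
    cat("Omitted tasks:", paste(attr(x, "omitted"), collapse = ", "), "\n")
  invisible(x)
}
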