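# Data-quality exclusion: magnetic disturbance (magnitude / sustained /
# inclination rules), seated transport with padding, non-physiological
# joint angles, and combined exclusion accounting.

#' Estimate the expected Earth-field reference for one sensor
#'
#' Magnitude is the median magnetometer norm over stillness samples;
#' inclination is the median dip of the magnetometer vector against the
#' accelerometer's gravity direction during stillness.  Requires at least
#' `min_still_s` seconds of usable stillness unless a user reference is
#' supplied.
#'
#' @param stream A [sensor_stream()].
#' @param stillness A [detect_stillness()] result.
#' @param user Optional `c(magnitude, inclination_deg)` supplied reference,
#'   returned verbatim.
#' @param min_still_s Minimum total stillness (s).
#' @return An object of class `field_reference`: list(magnitude,
#'   inclination_deg, n_samples, provenance).
#' @export
estimate_field_reference <- function(stream, stillness = NULL, user = NULL,
                                     min_still_s = 30) {
  if (!is.null(user)) {
    if (user[[1]] <= 0) stop("field magnitude must be > 0")
    return(structure(list(magnitude = user[[1]],
                          inclination_deg = user[[2]],
                          n_samples = 0L, provenance = "user"),
                     class = "field_reference"))
  }
  if (is.null(stillness) ||
      sum(stillness$end_s - stillness$start_s) < min_still_s)
    stop("configuration error: need >= ", min_still_s,
         " s of stillness or a user-supplied field reference")
  idx <- logical(length(stream$time))
  for (i in seq_len(nrow(stillness)))
    idx <- idx | (stream$time >= stillness$start_s[i] &
                  stream$time <= stillness$end_s[i])
  m <- stream$mag[idx, , drop = FALSE]
  a <- stream$acc[idx, , drop = FALSE]
  mnorm <- sqrt(rowSums(m^2))
  anorm <- sqrt(rowSums(a^2))
  incl <- -asin(pmin(1, pmax(-1, rowSums(m * a) / (mnorm * anorm))))
  structure(list(magnitude = stats::median(mnorm),
                 inclination_deg = rad2deg(stats::median(incl)),
                 n_samples = sum(idx), provenance = "stillness-median"),
            class = "field_reference")
}

#' @export
print.field_reference <- function(x, ...) {
  cat(sprintf("<field_reference> magnitude %.3f, inclination %.1f deg (%s, n=%d)\n",
              x$magnitude, x$inclination_deg, x$provenance, x$n_samples))
  invisible(x)
}

#' Check two spine sensors' field references for consistency
#'
#' If the two magnitudes disagree by more than `tol` (relative), one of them
#' was probably estimated inside a disturbance; a warning is raised.
#'
#' @param ref_a,ref_b `field_reference` objects.
#' @param tol Relative magnitude tolerance.
#' @return TRUE (consistent) or FALSE, invisibly, with a warning when FALSE.
#' @export
check_field_consistency <- function(ref_a, ref_b, tol = 0.10) {
  rel <- abs(ref_a$magnitude - ref_b$magnitude) /
    mean(c(ref_a$magnitude, ref_b$magnitude))
  if (rel > tol) {
    warning(sprintf(
      "spine sensors disagree on field magnitude by %.0f%%: a reference may be biased by a disturbance",
      100 * rel))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

# Single-pole low-pass (applied forward then backward for zero phase).
lowpass <- function(x, rate, cutoff_hz) {
  alpha <- 2 * pi * cutoff_hz / rate
  alpha <- alpha / (1 + alpha)
  fwd <- as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                                  init = x[1]))
  rev(as.numeric(stats::filter(alpha * rev(fwd), 1 - alpha,
                               method = "recursive", init = fwd[length(fwd)])))
}

#' Flag magnetically disturbed samples for one sensor
#'
#' Three rules, all strict inequalities: instantaneous relative deviation of
#' the field magnitude above `inst_frac`; sustained relative deviation above
#' `sust_frac` for at least `sust_s` seconds (the whole run is flagged); and
#' deviation of the field inclination from the reference by more than
#' `incl_deg` degrees.  Inclination is measured against the accelerometer
#' gravity direction low-passed at `grav_cutoff_hz` (not the fused
#' orientation, which itself consumes the magnetometer).
#'
#' @param stream A [sensor_stream()].
#' @param ref A [estimate_field_reference()] result.
#' @param inst_frac,sust_frac,sust_s,incl_deg Rule thresholds.
#' @param grav_cutoff_hz Gravity low-pass cutoff (Hz).
#' @return Logical vector of per-sample flags with attribute `rules`
#'   (n x 3 logical matrix: instant, sustained, inclination).
#' @export
detect_magnetic_disturbance <- function(stream, ref, inst_frac = 0.30,
                                        sust_frac = 0.15, sust_s = 30,
                                        incl_deg = 30,
                                        grav_cutoff_hz = 0.5) {
  mnorm <- sqrt(rowSums(stream$mag^2))
  dev <- abs(mnorm - ref$magnitude) / ref$magnitude
  inst <- dev > inst_frac

  # sustained: any maximal run with dev > sust_frac lasting >= sust_s
  over <- dev > sust_frac
  sust <- logical(length(over))
  r <- rle(over)
  ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
  for (k in which(r$values)) {
    if (stream$time[ends_i[k]] - stream$time[starts_i[k]] >= sust_s)
      sust[starts_i[k]:ends_i[k]] <- TRUE
  }

  g <- vapply(1:3, function(j) lowpass(stream$acc[, j], stream$rate,
                                       grav_cutoff_hz),
              numeric(length(mnorm)))
  gnorm <- sqrt(rowSums(g^2))
  incl <- -asin(pmin(1, pmax(-1, rowSums(stream$mag * g) / (mnorm * gnorm))))
  incl_flag <- abs(rad2deg(incl) - ref$inclination_deg) > incl_deg

  flags <- inst | sust | incl_flag
  attr(flags, "rules") <- cbind(instant = inst, sustained = sust,
                                inclination = incl_flag)
  flags
}

#' Flag samples during (padded) seated transport
#'
#' @param labels Per-sample activity labels (after [upsample_labels()]).
#' @param time Per-sample timestamps (s).
#' @param pad_s Padding on each side of every transport episode (s).
#' @return Logical per-sample flag vector.
#' @export
exclude_transport <- function(labels, time, pad_s = 300) {
  flag <- labels == "transport"
  if (!any(flag)) return(flag)
  r <- rle(flag)
  ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
  out <- logical(length(flag))
  for (k in which(r$values)) {
    t0 <- time[starts_i[k]] - pad_s
    t1 <- time[ends_i[k]] + pad_s
    out <- out | (time >= t0 & time <= t1)
  }
  out
}

#' Flag non-physiological lumbar angles
#'
#' Strictly more flexed than `flex_deg` or strictly more extended than
#' `ext_deg` on the flexion-extension axis.
#'
#' @param joint A [joint_angle_series()] (flexion positive).
#' @param flex_deg Upper flexion limit (deg).
#' @param ext_deg Extension limit (deg, magnitude).
#' @return Logical per-sample flag vector.
#' @export
exclude_nonphysiological <- function(joint, flex_deg = 70, ext_deg = 50) {
  fe <- joint$angles[, "flexext"]
  fe > flex_deg | fe < -ext_deg
}

#' Combine exclusion flags into a quality mask
#'
#' @param magnetic,transport,nonphysiological Logical per-sample flag
#'   vectors of equal length (missing reasons may be NULL).
#' @param time Optional per-sample timestamps, used to report flagged
#'   intervals.
#' @return An object of class `quality_mask`: `exclude` (union flags),
#'   per-reason `flags` matrix, per-reason and union `fractions`, and
#'   `overlap` (share of transport-flagged samples also magnetically
#'   flagged).
#' @export
combine_masks <- function(magnetic = NULL, transport = NULL,
                          nonphysiological = NULL, time = NULL) {
  parts <- list(magnetic = magnetic, transport = transport,
                nonphysiological = nonphysiological)
  lens <- vapply(parts[!vapply(parts, is.null, TRUE)], length, 0L)
  if (length(unique(lens)) > 1) stop("flag series lengths differ")
  n <- lens[1]
  flags <- vapply(parts, function(p) if (is.null(p)) logical(n) else
    as.logical(p), logical(n))
  union_flag <- rowSums(flags) > 0
  fractions <- c(colMeans(flags), union = mean(union_flag))
  overlap <- if (any(flags[, "transport"]))
    mean(flags[flags[, "transport"], "magnetic"]) else NA_real_
  structure(list(exclude = union_flag, flags = flags,
                 fractions = fractions, overlap_transport_magnetic = overlap,
                 time = time, n = n),
            class = "quality_mask")
}

#' @export
print.quality_mask <- function(x, ...) {
  f <- x$fractions * 100
  cat(sprintf(
    "<quality_mask> magnetic %.1f%%, transport %.1f%%, non-physiological %.1f%%, union %.1f%% of %d samples\n",
    f[["magnetic"]], f[["transport"]], f[["nonphysiological"]],
    f[["union"]], x$n))
  invisible(x)
}

# Flagged intervals (start_s, end_s, reason) from a quality mask.
mask_intervals <- function(mask) {
  if (is.null(mask$time)) stop("mask has no timestamps")
  out <- list()
  for (reason in colnames(mask$flags)) {
    f <- mask$flags[, reason]
    if (!any(f)) next
    r <- rle(f)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
    for (k in which(r$values))
      out[[length(out) + 1]] <- data.frame(
        start_s = mask$time[starts_i[k]], end_s = mask$time[ends_i[k]],
        reason = reason)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               reason = character(0))
}

#' Write a quality report as structured text
#' @param mask A `quality_mask`. @param path Output path (JSON).
#' @export
write_quality_report <- function(mask, path) {
  jsonlite::write_json(list(
    fractions = as.list(mask$fractions),
    overlap_transport_magnetic = mask$overlap_transport_magnetic,
    n_samples = mask$n,
    intervals = if (!is.null(mask$time)) mask_intervals(mask) else NULL),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
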