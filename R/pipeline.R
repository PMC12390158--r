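# Pipeline orchestration: simulate -> sync -> bias -> orient -> segment ->
# quality -> reference -> outcomes, with artifact persistence and a run
# manifest.

#' Pipeline configuration
#'
#' Every processing threshold is a named key defaulting to the analysis
#' chain's stated value: 30% instantaneous / 15% over 30 s sustained
#' magnetic deviation, 30 deg inclination deviation, +/-5 min transport
#' padding, 70 deg flexion / 50 deg extension physiological limits, 5-sample
#' starting posture, 3 repetitions, >= 4 hop crossings with 2 s quiet
#' margins, >= 10 bursts within an hour, 5 s stillness.
#'
#' @param methods Reference methods to run (subset of the five).
#' @param gain Orientation filter gain beta (1/s).
#' @param reference_sensor Sensor whose clock is the master grid.
#' @param checkpoint_interval_s,sync_window_s,sync_max_lag_s,sync_min_peak
#'   Clock-sync parameters.
#' @param stillness_thresh_dps,stillness_min_s Gyro stillness detection.
#' @param hop_thresh_g,hop_quiet_s,hop_min_crossings Hop-burst detection.
#' @param session_min_bursts,session_span_s Task-session candidate rule.
#' @param mag_inst_frac,mag_sust_frac,mag_sust_s,mag_incl_deg Magnetic
#'   disturbance rules.
#' @param transport_pad_s Transport exclusion padding (s).
#' @param flex_limit_deg,ext_limit_deg Physiological angle limits (deg).
#' @param start_n_samples Samples averaged for the starting posture.
#' @param out_dir Output directory for artifacts (NULL = no files).
#' @param seed Integer seed recorded in the manifest.
#' @export
pipeline_config <- function(methods = REFERENCE_METHODS, gain = 0.1,
                            reference_sensor = "l5s1",
                            checkpoint_interval_s = 3600,
                            sync_window_s = 60, sync_max_lag_s = 10,
                            sync_min_peak = 0.5,
                            stillness_thresh_dps = 3, stillness_min_s = 5,
                            hop_thresh_g = 0.5, hop_quiet_s = 2,
                            hop_min_crossings = 4,
                            session_min_bursts = 10, session_span_s = 3600,
                            mag_inst_frac = 0.30, mag_sust_frac = 0.15,
                            mag_sust_s = 30, mag_incl_deg = 30,
                            transport_pad_s = 300,
                            flex_limit_deg = 70, ext_limit_deg = 50,
                            start_n_samples = 5,
                            out_dir = NULL, seed = 1) {
  bad <- setdiff(methods, REFERENCE_METHODS)
  if (length(bad))
    stop("validation error: unknown reference method(s): ",
         paste(bad, collapse = ", "))
  pos <- c(gain = gain, checkpoint_interval_s = checkpoint_interval_s,
           sync_window_s = sync_window_s, sync_max_lag_s = sync_max_lag_s,
           stillness_thresh_dps = stillness_thresh_dps,
           stillness_min_s = stillness_min_s, hop_thresh_g = hop_thresh_g,
           hop_quiet_s = hop_quiet_s, mag_inst_frac = mag_inst_frac,
           mag_sust_frac = mag_sust_frac, mag_sust_s = mag_sust_s,
           mag_incl_deg = mag_incl_deg, flex_limit_deg = flex_limit_deg,
           ext_limit_deg = ext_limit_deg)
  if (any(pos <= 0))
    stop("validation error: thresholds must be positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  structure(mget(names(formals(pipeline_config)), envir = environment()),
            class = "pipeline_config")
}

#' Process one recording's raw streams into an analyzed condition entry
#'
#' Runs the single-recording part of the chain: synchronization onto the
#' reference sensor's clock, gyro-bias removal, orientation fusion, joint
#' angles, task segmentation (experimenter flags when available, otherwise
#' hop-burst detection), label up-sampling, and quality masking.
#'
#' @param streams Named list of [sensor_stream()]s including `t12l1` and
#'   `l5s1`.
#' @param labels_1hz data.frame (time_s, activity) at 1 Hz, or NULL.
#' @param flags Optional experimenter-flag data.frame (event_time_s,
#'   flag_type) for laboratory sessions.
#' @param condition Condition label ("lab", "rw1", "rw2").
#' @param session Sensor-set session the condition belongs to.
#' @param config A [pipeline_config()].
#' @return A condition entry (joint, tasks, labels, mask, session) plus
#'   stage artifacts (`sync_model`, `bias_models`, `field_refs`, `counts`).
#' @export
process_recording <- function(streams, labels_1hz = NULL, flags = NULL,
                              condition = "rw1", session = "rw",
                              config = pipeline_config()) {
  stopifnot(all(c("t12l1", "l5s1") %in% names(streams)))
  counts <- list(read = vapply(streams, length, 0L))

  sync <- synchronize_streams(streams, reference = config$reference_sensor,
                              checkpoint_interval_s = config$checkpoint_interval_s,
                              window_s = config$sync_window_s,
                              max_lag_s = config$sync_max_lag_s,
                              min_peak = config$sync_min_peak)
  streams <- sync$streams
  counts$synced <- length(streams[[config$reference_sensor]])

  bias <- lapply(streams[c("l5s1", "t12l1")], correct_gyro_bias,
                 gyro_thresh_dps = config$stillness_thresh_dps,
                 min_duration_s = config$stillness_min_s)
  lower <- estimate_orientation(bias$l5s1$stream, gain = config$gain)
  upper <- estimate_orientation(bias$t12l1$stream, gain = config$gain)
  joint <- joint_angles(upper, lower)

  labels <- if (!is.null(labels_1hz)) upsample_labels(labels_1hz, joint$time)
            else rep("unknown", length(joint$time))

  if (!is.null(flags)) {
    tasks <- segment_tasks(markers = flags, condition = condition)
  } else {
    amag <- sqrt(rowSums(streams$l5s1$acc^2))
    hops <- detect_hops(streams$l5s1$time, amag,
                        thresh_g = config$hop_thresh_g,
                        quiet_s = config$hop_quiet_s,
                        min_crossings = config$hop_min_crossings)
    sessions <- find_task_sessions(hops,
                                   min_bursts = config$session_min_bursts,
                                   span_s = config$session_span_s)
    if (nrow(sessions) == 0)
      stop("segmentation: no candidate task session found in ", condition)
    tasks <- segment_tasks(sessions[1, ], hops, markers = "auto",
                           condition = condition)
  }

  refs <- lapply(c(l5s1 = "l5s1", t12l1 = "t12l1"), function(nm) {
    st <- bias[[nm]]$stream
    tryCatch(estimate_field_reference(st, bias[[nm]]$intervals),
             error = function(e) estimate_field_reference(st, user = c(1, -60)))
  })
  check_field_consistency(refs$l5s1, refs$t12l1)
  mag_flags <- detect_magnetic_disturbance(bias$l5s1$stream, refs$l5s1,
                                           config$mag_inst_frac,
                                           config$mag_sust_frac,
                                           config$mag_sust_s,
                                           config$mag_incl_deg) |
    detect_magnetic_disturbance(bias$t12l1$stream, refs$t12l1,
                                config$mag_inst_frac, config$mag_sust_frac,
                                config$mag_sust_s, config$mag_incl_deg)
  transport <- exclude_transport(labels, joint$time,
                                 pad_s = config$transport_pad_s)
  nonphys <- exclude_nonphysiological(joint, config$flex_limit_deg,
                                      config$ext_limit_deg)
  mask <- combine_masks(magnetic = mag_flags, transport = transport,
                        nonphysiological = nonphys, time = joint$time)
  counts$masked <- sum(mask$exclude)
  counts$analyzed <- counts$synced - counts$masked

  list(condition = condition, session = session, joint = joint,
       tasks = tasks, labels = labels, mask = mask,
       sync_model = sync$model,
       bias_models = lapply(bias, `[[`, "model"),
       field_refs = refs, counts = counts)
}

#' Run the full pipeline over a simulated or file-based cohort
#'
#' Executes all stages for every participant and condition, computes the
#' outcome table and per-task ICC report under each requested reference
#' method, persists intermediate artifacts under `config$out_dir`, and
#' returns a run manifest.
#'
#' @param cohort A [make_cohort()] result at `level = "imu"`, or a
#'   directory written by `make_cohort(..., dir = )`.
#' @param config A [pipeline_config()].
#' @return List with `conditions` (per participant), `references`,
#'   `outcomes` (per method), `icc` (per method / measure), `quality`
#'   (per-recording exclusion fractions) and `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  artifacts <- character(0)
  out_dir <- config$out_dir
  save_csv <- function(x, ...) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(x, p)
    artifacts <<- c(artifacts, p)
  }
  save_json <- function(x, ...) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", force = TRUE)
    artifacts <<- c(artifacts, p)
  }

  cohort_conditions <- list()
  quality <- list()
  for (p in cohort$participants) {
    conds <- list()
    for (rec in p$recordings) {
      cond <- rec$condition
      session <- if (cond == "lab") "lab" else "rw"
      entry <- tryCatch(
        process_recording(rec$streams, rec$truth$labels, rec$flags,
                          condition = cond, session = session,
                          config = config),
        error = function(e)
          stop(sprintf("[stage:%s/%s] %s", p$id, cond, conditionMessage(e)),
               call. = FALSE))
      conds[[cond]] <- entry
      quality[[paste(p$id, cond, sep = "/")]] <- entry$mask$fractions
      if (!is.null(out_dir)) {
        base <- file.path(p$id, cond)
        dir.create(file.path(out_dir, base), recursive = TRUE,
                   showWarnings = FALSE)
        write_joint_angles(entry$joint,
                           file.path(out_dir, base, "joint_angles.csv"))
        artifacts <- c(artifacts, file.path(out_dir, base, "joint_angles.csv"))
        save_csv(entry$tasks, base, "task_windows.csv")
        wq <- file.path(out_dir, base, "quality.json")
        write_quality_report(entry$mask, wq)
        artifacts <- c(artifacts, wq)
        wd <- file.path(out_dir, base, "drift_model.json")
        write_drift_model(entry$sync_model, wd)
        artifacts <- c(artifacts, wd)
      }
    }
    cohort_conditions[[p$id]] <- conds
  }

  references <- list(); outcomes <- list(); icc <- list()
  for (method in config$methods) {
    normed <- list()
    for (pid in names(cohort_conditions)) {
      ref <- compute_reference(method, cohort_conditions[[pid]])
      references[[method]][[pid]] <- ref
      normed[[pid]] <- apply_reference(cohort_conditions[[pid]], ref)
      save_csv(cbind(participant = pid, as.data.frame(ref)),
               "references", paste0(method, "_", pid, ".csv"))
    }
    oo <- outcome_table(normed)
    outcomes[[method]] <- oo
    save_csv(oo, "outcomes", paste0(method, ".csv"))
    icc[[method]] <- list(start = repeatability_report(oo, "start"),
                          ROM = repeatability_report(oo, "ROM"))
    for (ms in c("start", "ROM"))
      save_csv(as.data.frame(icc[[method]][[ms]]), "icc",
               paste0(method, "_", ms, ".csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spinewear")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    participants = names(cohort_conditions),
    methods = config$methods,
    quality_fractions = quality,
    stage_counts = lapply(cohort_conditions, function(cs)
      lapply(cs, `[[`, "counts")),
    artifacts = artifacts)
  save_json(manifest, "manifest.json")
  list(conditions = cohort_conditions, references = references,
       outcomes = outcomes, icc = icc, quality = quality,
       manifest = manifest)
}

#' Read a cohort directory written by [make_cohort()]
#'
#' @param dir Cohort directory containing per-participant subdirectories
#'   and `truth_manifest.json`.
#' @return A cohort bundle usable by [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "truth_manifest.json"),
                            simplifyVector = TRUE)
  participants <- list()
  for (pid in list.dirs(dir, recursive = FALSE, full.names = FALSE)) {
    recs <- list()
    for (cond in list.dirs(file.path(dir, pid), recursive = FALSE,
                           full.names = FALSE)) {
      rdir <- file.path(dir, pid, cond)
      sfiles <- list.files(rdir, pattern = "^(l5s1|t12l1|thigh)\\.csv$")
      streams <- lapply(sfiles, function(f)
        read_sensor_table(file.path(rdir, f)))
      names(streams) <- sub("\\.csv$", "", sfiles)
      labels <- as.data.frame(data.table::fread(file.path(rdir, "labels.csv")))
      recs[[cond]] <- list(condition = cond, streams = streams,
                           truth = list(labels = labels))
    }
    participants[[pid]] <- list(id = pid, recordings = recs)
  }
  list(spec = mf$spec, participants = participants)
}
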