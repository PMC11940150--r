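#' Simulation configuration for a two-class mobility cohort
#'
#' The simulator emulates the clinical protocol of five mobility tasks
#' recorded by a single lower-back inertial unit at 100 Hz: a 32-foot
#' walk, 20 s of quiet standing with eyes open and with eyes closed, two
#' trials of the Timed Up and Go (TUG), and two trials of the cognitive
#' TUG. The default cohort is 260 majority-class ("pd") and 18
#' minority-class ("nonpd") participants.
#'
#' Class effects are applied to the minority class only, as multipliers
#' on kinematic template parameters: `transition_dur` scales
#' sit-to-stand / stand-to-sit duration, `turn_velocity` scales peak turn
#' angular velocity (total turn angle is preserved, so turns slow down
#' and lengthen), `sway_power` scales the variance of mediolateral and
#' anteroposterior stance sway, and `gait_harmonic` scales the amplitude
#' of the second gait harmonic. A multiplier of 1 means no effect.
#' `effect_scale` raises every multiplier to the given power
#' (0 = no class difference, 1 = full effect), and `effect_tasks`
#' restricts which tasks carry the class effect (all tasks by default;
#' set to `"tug"` to plant the class signal in the TUG alone).
#'
#' @param n_majority,n_minority class sizes (majority >= minority >= 2).
#' @param tasks task roster each participant performs (default: the
#'   full five-task protocol). Restricting the roster (for example to
#'   `"tug"`) simulates a reduced protocol; feature-table columns of
#'   absent tasks are left missing and dropped by preprocessing.
#' @param sample_rate sampling rate in Hz.
#' @param effect named list of minority-class multipliers (all > 0).
#' @param effect_scale exponent applied to every effect multiplier.
#' @param effect_tasks tasks whose recordings carry the class effect.
#' @param noise_sd additive white sensor noise, `c(acc = , gyr = )`,
#'   in g and degrees/s.
#' @param seed integer RNG seed.
#' @param kinematics template parameters, see [kinematics_defaults()].
#' @param subject_sd log-normal between-participant standard deviations
#'   for baseline kinematics.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_majority = 260L, n_minority = 18L,
                       tasks = TASKS,
                       sample_rate = 100,
                       effect = list(transition_dur = 1.5,
                                     turn_velocity = 0.7,
                                     sway_power = 1.5,
                                     gait_harmonic = 1.0),
                       effect_scale = 1,
                       effect_tasks = TASKS,
                       noise_sd = c(acc = 0.005, gyr = 0.5),
                       seed = 1L,
                       kinematics = kinematics_defaults(),
                       subject_sd = c(transition_dur = 0.12,
                                      turn_velocity = 0.12,
                                      sway_power = 0.25,
                                      gait_amp = 0.12,
                                      step_freq = 0.04)) {
  if (n_majority < n_minority || n_minority < 2)
    stop_pdm("need n_majority >= n_minority >= 2", "pdm_config_error")
  if (sample_rate <= 2 * 20)
    stop_pdm("sample_rate must exceed twice the 20 Hz filter cutoff",
             "pdm_config_error")
  eff <- unlist(effect)
  if (any(eff <= 0))
    stop_pdm("effect multipliers must be > 0", "pdm_config_error")
  if (!all(effect_tasks %in% TASKS) || !all(tasks %in% TASKS))
    stop_pdm("unknown task in tasks/effect_tasks", "pdm_config_error")
  if (length(tasks) == 0)
    stop_pdm("task roster must be non-empty", "pdm_config_error")
  structure(list(n_majority = as.integer(n_majority),
                 n_minority = as.integer(n_minority),
                 tasks = tasks,
                 sample_rate = sample_rate, effect = as.list(eff),
                 effect_scale = effect_scale, effect_tasks = effect_tasks,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 kinematics = kinematics, subject_sd = subject_sd),
            class = "sim_config")
}

#' Kinematic template defaults
#'
#' Durations in seconds, angles in degrees, accelerations in g,
#' angular velocities in degrees/s. The TUG template is
#' sit-to-stand, walk out, 180 degree turn, walk back, 180 degree turn,
#' stand-to-sit, flanked by 1 s of quiet sitting/standing; the cognitive
#' TUG uses the same template with larger trial-to-trial duration
#' variability to mimic dual-task cost.
#'
#' @return Named list of template parameters.
#' @export
kinematics_defaults <- function() {
  list(margin_s = 1.0,
       sts_dur = 1.4, sts_angle = 45,
       walk_leg_dur = 3.0,
       turn_dur = 2.0, turn_angle = 180,
       walk32_dur = 8.0, stance_dur = 20.0,
       step_freq = 1.9,
       acc_v_amp = 0.22, acc_ap_amp = 0.13, acc_ml_amp = 0.05,
       harmonic2 = 0.4,
       gyr_ml_walk = 8, gyr_v_walk = 4, gyr_ap_walk = 6,
       trans_acc_ap = 0.20, trans_acc_v = 0.15,
       sway_sd = 0.03, quiet_sd = 0.008,
       dur_cv = 0.05, dur_cv_cog = 0.12)
}

# Raised-cosine pulse of length n integrating (by time) to `angle`
# degrees given sample rate fs: peak = 2 * angle / duration.
raised_cosine <- function(n, angle, fs) {
  dur <- n / fs
  peak <- 2 * angle / dur
  t <- seq_len(n) - 0.5
  peak * 0.5 * (1 - cos(2 * pi * t / n))
}

# Band-limited (about 0-2 Hz) noise rescaled to an exact target sd.
sway_noise <- function(n, sd_target, fs) {
  if (sd_target <= 0 || n < 8) return(numeric(n))
  bf <- signal::butter(2, min(2 / (fs / 2), 0.9), type = "low")
  x <- as.numeric(signal::filter(bf, rnorm(n + 200)))[-(1:200)]
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_target
}

zero_block <- function(n) {
  m <- matrix(0, n, length(CHANNELS))
  colnames(m) <- CHANNELS
  m
}

gen_quiet <- function(n, k, fs) {
  m <- zero_block(n)
  m[, "acc_ml"] <- sway_noise(n, k$quiet_sd, fs)
  m[, "acc_ap"] <- sway_noise(n, k$quiet_sd, fs)
  m[, "acc_v"] <- sway_noise(n, k$quiet_sd / 2, fs)
  m
}

gen_stance <- function(n, k, fs, sway_mult) {
  m <- zero_block(n)
  s <- k$sway_sd * sqrt(sway_mult)
  m[, "acc_ml"] <- sway_noise(n, s, fs)
  m[, "acc_ap"] <- sway_noise(n, s, fs)
  m[, "acc_v"] <- sway_noise(n, s / 3, fs)
  m[, GYR_CHANNELS] <- replicate(3, sway_noise(n, 0.3, fs))
  m
}

gen_walk <- function(n, k, fs, gait_amp, harm_mult, step_freq) {
  m <- zero_block(n)
  t <- (seq_len(n) - 1) / fs
  f <- step_freq
  m[, "acc_v"] <- gait_amp * k$acc_v_amp *
    (sin(2 * pi * f * t) + k$harmonic2 * harm_mult * sin(4 * pi * f * t + 0.5))
  m[, "acc_ap"] <- gait_amp * k$acc_ap_amp * sin(2 * pi * f * t + 1.0)
  m[, "acc_ml"] <- gait_amp * k$acc_ml_amp * sin(pi * f * t)
  m[, "gyr_ml"] <- k$gyr_ml_walk * sin(2 * pi * f * t + 0.3)
  m[, "gyr_v"] <- k$gyr_v_walk * sin(pi * f * t + 0.7)
  m[, "gyr_ap"] <- k$gyr_ap_walk * sin(pi * f * t)
  m
}

gen_turn <- function(n, k, fs) {
  m <- zero_block(n)
  m[, "gyr_v"] <- raised_cosine(n, k$turn_angle, fs)
  m[, "acc_ml"] <- 0.05 * raised_cosine(n, k$turn_angle, fs) / max(
    raised_cosine(n, k$turn_angle, fs))
  m
}

gen_transition <- function(n, k, fs, sign) {
  m <- zero_block(n)
  pulse <- raised_cosine(n, k$sts_angle, fs)
  m[, "gyr_ml"] <- sign * pulse
  shape <- pulse / max(pulse)
  m[, "acc_ap"] <- sign * k$trans_acc_ap * shape
  m[, "acc_v"] <- k$trans_acc_v * shape
  m
}

# Segment plan for one task: data.frame(label, type, dur).
task_plan <- function(task, k, cp, jitter_cv) {
  j <- function(d) d * exp(rnorm(1, 0, jitter_cv))
  if (task %in% c("tug", "cogtug")) {
    data.frame(
      label = c("quiet_stance", "sit_to_stand", "walk", "turn", "walk",
                "turn", "stand_to_sit", "quiet_stance"),
      type = c("quiet", "sts", "walk", "turn", "walk", "turn", "sit",
               "quiet"),
      dur = c(k$margin_s,
              j(k$sts_dur * cp$transition_dur),
              j(k$walk_leg_dur),
              j(k$turn_dur / cp$turn_velocity),
              j(k$walk_leg_dur),
              j(k$turn_dur / cp$turn_velocity),
              j(k$sts_dur * cp$transition_dur),
              k$margin_s))
  } else if (task == "walk32ft") {
    data.frame(label = c("quiet_stance", "walk", "quiet_stance"),
               type = c("quiet", "walk", "quiet"),
               dur = c(k$margin_s, j(k$walk32_dur), k$margin_s))
  } else if (task %in% c("stand_eo", "stand_ec")) {
    data.frame(label = "quiet_stance", type = "stance",
               dur = k$stance_dur)
  } else {
    stop_pdm(paste0("unknown task descriptor: ", task), "pdm_config_error")
  }
}

#' Simulate one recording of one mobility task
#'
#' Channels are built from a piecewise kinematic template: raised-cosine
#' trunk yaw pulses for the 180 degree turns (one pulse integrates to the
#' full turn angle), raised-cosine trunk pitch pulses for the postural
#' transitions, harmonic gait oscillation near 2 Hz on the vertical and
#' anteroposterior accelerometer during walking, and band-limited
#' low-amplitude sway during quiet stance -- plus additive white Gaussian
#' sensor noise. The returned recording carries its `ground_truth`
#' attribute: a data frame of true segment labels with 0-based half-open
#' sample boundaries.
#'
#' @param task one of `"walk32ft"`, `"stand_eo"`, `"stand_ec"`, `"tug"`,
#'   `"cogtug"`.
#' @param class_params kinematic multipliers for this participant
#'   (fields `transition_dur`, `turn_velocity`, `sway_power`,
#'   `gait_harmonic`, optionally `gait_amp`, `step_freq`).
#' @param seed RNG seed, or `NULL` to draw from the current RNG stream.
#' @param sample_rate Hz.
#' @param noise_sd `c(acc = , gyr = )` additive noise standard deviations.
#' @param kinematics template parameters.
#' @param trial trial number recorded in the marker.
#' @return A `sensor_recording` with a `ground_truth` attribute.
#' @export
simulate_recording <- function(task, class_params = list(), seed = NULL,
                               sample_rate = 100,
                               noise_sd = c(acc = 0.005, gyr = 0.5),
                               kinematics = kinematics_defaults(),
                               trial = 1L) {
  if (!task %in% TASKS)
    stop_pdm(paste0("unknown task descriptor: ", task), "pdm_config_error")
  if (!is.null(seed)) return(with_seed(seed, simulate_recording(
    task, class_params, NULL, sample_rate, noise_sd, kinematics, trial)))
  cp <- utils::modifyList(
    list(transition_dur = 1, turn_velocity = 1, sway_power = 1,
         gait_harmonic = 1, gait_amp = 1, step_freq = NULL),
    as.list(class_params))
  k <- kinematics
  fs <- sample_rate
  step_freq <- cp$step_freq %||% k$step_freq
  jitter_cv <- if (task == "cogtug") k$dur_cv_cog else k$dur_cv
  plan <- task_plan(task, k, cp, jitter_cv)
  ns <- pmax(2L, as.integer(round(plan$dur * fs)))
  blocks <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    blocks[[i]] <- switch(plan$type[i],
      quiet = gen_quiet(ns[i], k, fs),
      stance = gen_stance(ns[i], k, fs, cp$sway_power),
      walk = gen_walk(ns[i], k, fs, cp$gait_amp, cp$gait_harmonic,
                      step_freq),
      turn = gen_turn(ns[i], k, fs),
      sts = gen_transition(ns[i], k, fs, +1),
      sit = gen_transition(ns[i], k, fs, -1))
  }
  ch <- do.call(rbind, blocks)
  n <- nrow(ch)
  if (noise_sd[["acc"]] > 0)
    ch[, ACC_CHANNELS] <- ch[, ACC_CHANNELS] +
      matrix(rnorm(3 * n, 0, noise_sd[["acc"]]), n, 3)
  if (noise_sd[["gyr"]] > 0)
    ch[, GYR_CHANNELS] <- ch[, GYR_CHANNELS] +
      matrix(rnorm(3 * n, 0, noise_sd[["gyr"]]), n, 3)
  ends <- cumsum(ns)
  truth <- data.frame(label = plan$label,
                      start = c(0L, ends[-length(ends)]),
                      end = ends)
  rec <- sensor_recording(
    ch, fs, data.frame(task = task, trial = as.integer(trial),
                       start = 0L, end = n))
  attr(rec, "ground_truth") <- truth
  rec
}

#' Simulate a full two-class cohort
#'
#' Every participant performs all five protocol tasks, with two trials of
#' the TUG and two of the cognitive TUG. Class effect multipliers are
#' applied to minority-class participants only, on the tasks listed in
#' `config$effect_tasks`; per-participant baseline kinematics vary
#' log-normally around the template so the two classes overlap.
#'
#' @param config a [sim_config()].
#' @return A `pdm_cohort`: list of participants, each with `id`, `label`
#'   (`"pd"` majority / `"nonpd"` minority), and a named list
#'   `recordings` (keys `walk32ft_1`, `stand_eo_1`, `stand_ec_1`,
#'   `tug_1`, `tug_2`, `cogtug_1`, `cogtug_2`), each recording carrying
#'   its ground truth.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_majority + config$n_minority
    labels <- c(rep("pd", config$n_majority),
                rep("nonpd", config$n_minority))
    ssd <- config$subject_sd
    lam <- config$effect_scale
    roster <- c(walk32ft_1 = "walk32ft", stand_eo_1 = "stand_eo",
                stand_ec_1 = "stand_ec", tug_1 = "tug", tug_2 = "tug",
                cogtug_1 = "cogtug", cogtug_2 = "cogtug")
    trials <- c(1L, 1L, 1L, 1L, 2L, 1L, 2L)
    keep <- roster %in% config$tasks
    roster <- roster[keep]
    trials <- trials[keep]
    participants <- vector("list", n)
    for (i in seq_len(n)) {
      base <- list(
        transition_dur = exp(rnorm(1, 0, ssd[["transition_dur"]])),
        turn_velocity = exp(rnorm(1, 0, ssd[["turn_velocity"]])),
        sway_power = exp(rnorm(1, 0, ssd[["sway_power"]])),
        gait_amp = exp(rnorm(1, 0, ssd[["gait_amp"]])),
        gait_harmonic = 1,
        step_freq = config$kinematics$step_freq *
          exp(rnorm(1, 0, ssd[["step_freq"]])))
      recs <- vector("list", length(roster))
      names(recs) <- names(roster)
      for (r in seq_along(roster)) {
        task <- roster[[r]]
        cp <- base
        if (labels[i] == "nonpd" && task %in% config$effect_tasks) {
          e <- config$effect
          cp$transition_dur <- cp$transition_dur * e$transition_dur^lam
          cp$turn_velocity <- cp$turn_velocity * e$turn_velocity^lam
          cp$sway_power <- cp$sway_power * e$sway_power^lam
          cp$gait_harmonic <- cp$gait_harmonic * e$gait_harmonic^lam
        }
        recs[[r]] <- simulate_recording(
          task, cp, seed = NULL, sample_rate = config$sample_rate,
          noise_sd = config$noise_sd, kinematics = config$kinematics,
          trial = trials[r])
      }
      participants[[i]] <- list(id = sprintf("P%03d", i),
                                label = labels[i], recordings = recs)
    }
    structure(list(participants = participants, config = config),
              class = "pdm_cohort")
  })
}

#' @export
print.pdm_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<pdm_cohort> %d participants (%d pd / %d nonpd), %d recordings each\n",
              length(x$participants), sum(lab == "pd"),
              sum(lab == "nonpd"),
              length(x$participants[[1]]$recordings)))
  invisible(x)
}

#' Class labels of a simulated cohort
#' @param cohort a `pdm_cohort`.
#' @return Character vector, one label per participant.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$participants, `[[`, character(1), "label")
}

#' Participant ids of a simulated cohort
#' @param cohort a `pdm_cohort`.
#' @return Character vector of ids.
#' @export
cohort_ids <- function(cohort) {
  vapply(cohort$participants, `[[`, character(1), "id")
}

#' Write a cohort to disk as per-participant CSV recordings
#'
#' One CSV (plus JSON marker/ground-truth sidecar) per recording, and a
#' cohort `manifest.csv` with participant id, class label, task, trial
#' and file path.
#'
#' @param cohort a `pdm_cohort`.
#' @param dir output directory (created if absent).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in cohort$participants) {
    for (nm in names(p$recordings)) {
      rec <- p$recordings[[nm]]
      path <- file.path(dir, paste0(p$id, "_", nm, ".csv"))
      write_recording(rec, path)
      rows[[length(rows) + 1]] <- data.frame(
        id = p$id, label = p$label, task = rec$markers$task[1],
        trial = rec$markers$trial[1], file = basename(path))
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `manifest.csv`.
#' @return A `pdm_cohort` (without a simulation config).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  ids <- unique(manifest$id)
  participants <- lapply(ids, function(id) {
    sub <- manifest[manifest$id == id, , drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(sub))) {
      key <- paste0(sub$task[i], "_", sub$trial[i])
      recs[[key]] <- read_recording(file.path(dir, sub$file[i]))
    }
    list(id = id, label = sub$label[1], recordings = recs)
  })
  structure(list(participants = participants, config = NULL),
            class = "pdm_cohort")
}
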