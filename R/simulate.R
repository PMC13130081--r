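#' Motion specification for the trial simulator
#'
#' Describes the noise-free kinematic archetype of one exergame trial.
#' Each exergame drives one waveform family:
#' * AIRPLANE: sinusoidal mediolateral trunk sway (amplitude in degrees of
#'   trunk tilt), arms held in a static T-pose;
#' * SKI: seated alternating knee flexion (amplitude in degrees of knee
#'   angle excursion), antiphase between legs;
#' * PIANO: rhythmic arm elevation (point-and-hold raises) with a key press
#'   at each elevation peak;
#' * GYM_FRONTAL / GYM_LATERAL: rhythmic bilateral arm raises in the
#'   sagittal / frontal plane; coordination mode ALT moves the arms in
#'   antiphase, SING and SIM in phase.
#'
#' The right-to-left amplitude ratio `asymmetry_ratio` (r) scales the
#' right side's amplitude-type parameter; on noise-free input the
#' amplitude-type Symmetry Index recovered downstream equals `|r - 1|`
#' exactly.
#'
#' @param exergame one of AIRPLANE, SKI, PIANO, GYM_FRONTAL, GYM_LATERAL
#' @param amplitude waveform amplitude in degrees (> 0; trunk tilt for
#'   AIRPLANE, knee excursion for SKI, arm elevation for PIANO/GYM)
#' @param frequency movement frequency in Hz, in (0, 2] (the
#'   voluntary-movement band)
#' @param baseline baseline posture angle in degrees (arm elevation for
#'   T-pose/raises, knee angle for SKI)
#' @param asymmetry_ratio right-to-left amplitude ratio r > 0
#' @param duration trial duration in seconds (>= 1)
#' @param mode GYM coordination mode (SING, ALT, SIM)
#' @param elbow_angle static elbow angle in degrees (180 = straight)
#' @return object of class `motion_spec`
#' @export
motion_spec <- function(exergame, amplitude = NULL, frequency = NULL,
                        baseline = NULL, asymmetry_ratio = 1,
                        duration = 30, mode = NULL, elbow_angle = 155) {
  exergame <- match.arg(exergame, EXERGAMES)
  defaults <- switch(progression_game(exergame),
    AIRPLANE = list(amplitude = 15, frequency = 0.25, baseline = 90),
    SKI = list(amplitude = 20, frequency = 0.4, baseline = 60),
    PIANO = list(amplitude = 45, frequency = 0.2, baseline = 40),
    GYM = list(amplitude = 90, frequency = 0.25, baseline = 15)
  )
  amplitude <- amplitude %||% defaults$amplitude
  frequency <- frequency %||% defaults$frequency
  baseline <- baseline %||% defaults$baseline
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (frequency <= 0 || frequency > 2) stop("frequency must lie in (0, 2] Hz")
  if (asymmetry_ratio <= 0) stop("asymmetry_ratio must be > 0")
  if (duration < 1) stop("duration must be at least 1 s")
  if (progression_game(exergame) == "GYM" && is.null(mode)) mode <- "SIM"
  structure(list(exergame = exergame, amplitude = amplitude,
                 frequency = frequency, baseline = baseline,
                 asymmetry_ratio = asymmetry_ratio, duration = duration,
                 mode = mode, elbow_angle = elbow_angle),
            class = "motion_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise specification for the trial simulator
#'
#' Emulates the disturbance structure of webcam-based markerless tracking:
#' per-coordinate white Gaussian jitter, sparse impulsive spikes (tracking
#' outliers), and a narrow-band high-frequency interference component
#' (tremor/jitter band, constrained above 7.5 Hz) added to the arm
#' landmarks. The band default (12 Hz) sits above the 10 Hz conditioning
#' cutoff, matching the band the pre-processing chain is designed to
#' remove. All magnitudes are engineering choices (the acquisition noise of
#' the deployed system is not published) and are documented as such.
#'
#' @param jitter_sd white-noise SD per coordinate, meters
#' @param spike_rate impulsive outlier rate, events per second
#' @param spike_magnitude spike displacement magnitude, meters
#' @param tremor_amp high-frequency band amplitude, meters
#' @param tremor_freq high-frequency band frequency in Hz (> 7.5)
#' @param dropout_rate rate of flagged (non-finite) frames, events/s
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(jitter_sd = 0.003, spike_rate = 0.2,
                       spike_magnitude = 0.15, tremor_amp = 0.004,
                       tremor_freq = 12, dropout_rate = 0) {
  if (any(c(jitter_sd, spike_rate, spike_magnitude, tremor_amp,
            dropout_rate) < 0)) {
    stop("noise parameters must be non-negative")
  }
  if (tremor_amp > 0 && tremor_freq <= 7.5) {
    stop("tremor_freq must exceed 7.5 Hz")
  }
  structure(list(jitter_sd = jitter_sd, spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude, tremor_amp = tremor_amp,
                 tremor_freq = tremor_freq, dropout_rate = dropout_rate),
            class = "noise_spec")
}

#' Zero-noise specification
#' @return a [noise_spec()] with all disturbances off
#' @export
noise_free <- function() {
  noise_spec(jitter_sd = 0, spike_rate = 0, spike_magnitude = 0,
             tremor_amp = 0, tremor_freq = 12, dropout_rate = 0)
}

# --- skeleton geometry ------------------------------------------------------
# Fixed articulated stick model: segment lengths (m) from standard
# anthropometry. Only the landmarks entering the joint table need kinematic
# fidelity; face/hand/foot landmarks ride rigidly on their parent segment.
SKEL <- list(
  trunk = 0.50, shoulder_halfwidth = 0.18, hip_halfwidth = 0.10,
  upper_arm = 0.28, forearm = 0.26, hand = 0.08,
  thigh = 0.42, shank = 0.42, foot = 0.20,
  hip_height_stand = 0.95, hip_height_sit = 0.55, head = 0.25
)

deg2rad <- function(d) d * pi / 180

# Build the L x 33 x 3 position array from framewise angle channels.
# Angle channels (degrees): sway (trunk lateral tilt), arm_l/arm_r
# (elevation from the trunk-down axis), knee_l/knee_r, leg_l/leg_r
# (hip-knee vs world-down), plus the raise plane ("lateral"/"frontal").
build_skeleton <- function(t, ang, plane, seated, elbow_angle) {
  L <- length(t)
  nm <- pose_landmark_names()
  pos <- array(0, dim = c(L, 33, 3))
  set <- function(name, mat) pos[, match(name, nm), ] <<- mat

  hip_h <- if (seated) SKEL$hip_height_sit else SKEL$hip_height_stand
  phi <- deg2rad(ang$sway)
  trunk_u <- cbind(sin(phi), cos(phi), 0)          # trunk long axis (up)
  lat_u <- cbind(cos(phi), -sin(phi), 0)           # trunk lateral axis (+x = left)
  mid_hip <- cbind(0, hip_h, 0)[rep(1, L), , drop = FALSE]
  mid_sho <- mid_hip + SKEL$trunk * trunk_u
  set("left_hip", mid_hip + SKEL$hip_halfwidth * lat_u)
  set("right_hip", mid_hip - SKEL$hip_halfwidth * lat_u)
  sho_l <- mid_sho + SKEL$shoulder_halfwidth * lat_u
  sho_r <- mid_sho - SKEL$shoulder_halfwidth * lat_u
  set("left_shoulder", sho_l)
  set("right_shoulder", sho_r)

  # head block rides on the trunk
  nose <- mid_sho + SKEL$head * trunk_u
  set("nose", nose)
  face <- list(left_eye_inner = c(0.02, 0.03, 0.02),
               left_eye = c(0.03, 0.03, 0.02),
               left_eye_outer = c(0.04, 0.03, 0.02),
               right_eye_inner = c(-0.02, 0.03, 0.02),
               right_eye = c(-0.03, 0.03, 0.02),
               right_eye_outer = c(-0.04, 0.03, 0.02),
               left_ear = c(0.07, 0.01, 0), right_ear = c(-0.07, 0.01, 0),
               mouth_left = c(0.02, -0.02, 0.03),
               mouth_right = c(-0.02, -0.02, 0.03))
  for (f in names(face)) {
    off <- face[[f]]
    set(f, nose + off[1] * lat_u + off[2] * trunk_u +
          matrix(c(0, 0, off[3]), L, 3, byrow = TRUE))
  }

  # arms: elevation theta from the trunk-down axis within the raise plane
  down_u <- -trunk_u
  arm_chain <- function(sho, theta_deg, side_sign) {
    th <- deg2rad(theta_deg)
    e <- if (plane == "lateral") side_sign * lat_u
         else matrix(c(0, 0, 1), L, 3, byrow = TRUE)
    a_dir <- sin(th) * e + cos(th) * down_u
    elbow <- sho + SKEL$upper_arm * a_dir
    eta <- deg2rad(180 - elbow_angle)
    f_dir <- sin(th + eta) * e + cos(th + eta) * down_u
    wrist <- elbow + SKEL$forearm * f_dir
    hand <- wrist + SKEL$hand * f_dir
    list(elbow = elbow, wrist = wrist, hand = hand)
  }
  al <- arm_chain(sho_l, ang$arm_l, +1)
  ar <- arm_chain(sho_r, ang$arm_r, -1)
  set("left_elbow", al$elbow); set("right_elbow", ar$elbow)
  set("left_wrist", al$wrist); set("right_wrist", ar$wrist)
  for (h in c("pinky", "index", "thumb")) {
    set(paste0("left_", h), al$hand)
    set(paste0("right_", h), ar$hand)
  }

  # legs: hip-knee direction at angle gamma1 from world-down (toward +z),
  # knee angle kappa closes the chain (gamma2 = 180 - kappa - gamma1)
  leg_chain <- function(hip, gamma1_deg, kappa_deg) {
    g1 <- deg2rad(gamma1_deg)
    thigh_dir <- cbind(0, -cos(g1), sin(g1))
    knee <- hip + SKEL$thigh * thigh_dir
    g2 <- deg2rad(180 - kappa_deg - gamma1_deg)
    shank_dir <- cbind(0, -cos(g2), -sin(g2))
    ankle <- knee + SKEL$shank * shank_dir
    list(knee = knee, ankle = ankle,
         heel = ankle + cbind(0, 0, rep(-0.05, L)),
         toe = ankle + cbind(0, -0.05, rep(SKEL$foot, L)))
  }
  ll <- leg_chain(pos[, match("left_hip", nm), ], ang$leg_l, ang$knee_l)
  lr <- leg_chain(pos[, match("right_hip", nm), ], ang$leg_r, ang$knee_r)
  set("left_knee", ll$knee); set("right_knee", lr$knee)
  set("left_ankle", ll$ankle); set("right_ankle", lr$ankle)
  set("left_heel", ll$heel); set("right_heel", lr$heel)
  set("left_foot_index", ll$toe); set("right_foot_index", lr$toe)
  pos
}

# Noise-free angle channels per exergame (degrees), plus ground-truth
# summaries. Returns list(ang = <channel list>, truth = <list>).
motion_channels <- function(motion, t) {
  A <- motion$amplitude
  f <- motion$frequency
  r <- motion$asymmetry_ratio
  base <- motion$baseline
  L <- length(t)
  const <- function(v) rep(v, L)
  game <- progression_game(motion$exergame)
  ang <- list(sway = const(0), arm_l = const(30), arm_r = const(30),
              knee_l = const(180), knee_r = const(180),
              leg_l = const(0), leg_r = const(0))
  truth <- list(asymmetry_ratio = r, si_amplitude = abs(r - 1),
                n_reps = floor(motion$duration * f))
  if (game == "AIRPLANE") {
    ang$sway <- A * sin(2 * pi * f * t)
    ang$arm_l <- const(base)
    ang$arm_r <- const(min(178, base * r))
    truth$T_ANG <- abs(ang$sway)
    truth$ARM_ANG_L <- ang$arm_l
    truth$ARM_ANG_R <- ang$arm_r
  } else if (game == "SKI") {
    ang$knee_l <- base + A * sin(2 * pi * f * t)
    ang$knee_r <- base + r * A * sin(2 * pi * f * t + pi)
    ang$leg_l <- 95 + (ang$knee_l - base) / 3
    ang$leg_r <- 95 + (ang$knee_r - base) / 3
    ang$arm_l <- const(30)
    ang$arm_r <- const(30)
    truth$KNEE_ANG_L <- ang$knee_l
    truth$KNEE_ANG_R <- ang$knee_r
    truth$LEG_ANG_L <- ang$leg_l
    truth$LEG_ANG_R <- ang$leg_r
    truth$rom <- c(R = 2 * r * A, L = 2 * A)
  } else if (game == "PIANO") {
    raise <- (1 - cos(2 * pi * f * t)) / 2
    ang$arm_l <- base + A * raise
    ang$arm_r <- base + r * A * raise
    truth$ARM_ANG_L <- ang$arm_l
    truth$ARM_ANG_R <- ang$arm_r
    truth$rom <- c(R = r * A, L = A)
  } else { # GYM
    raise_l <- (1 - cos(2 * pi * f * t)) / 2
    raise_r <- if (identical(motion$mode, "ALT")) {
      (1 - cos(2 * pi * f * t + pi)) / 2
    } else {
      raise_l
    }
    ang$arm_l <- base + A * raise_l
    ang$arm_r <- base + r * A * raise_r
    truth$ARM_ANG_L <- ang$arm_l
    truth$ARM_ANG_R <- ang$arm_r
    truth$rom <- c(R = r * A, L = A)
    truth$peak_speed <- c(R = r * A * pi * f, L = A * pi * f)
  }
  list(ang = ang, truth = truth)
}

#' Simulate one exergame trial
#'
#' Generates a 30-fps trial recording (landmark trajectory + event log)
#' whose noise-free underlying joint-angle series is known and attached as a
#' ground-truth channel (`$ground_truth`): the exact angle series, the
#' per-side amplitude-type values, and the expected Symmetry Index
#' `|r - 1|`. The event log is consistent with the waveform: one
#' `movement_valid` and one `point` event per completed repetition, a
#' `key_press` at each elevation peak for PIANO, and a final
#' `level_complete` event.
#'
#' @param motion a [motion_spec()]
#' @param noise a [noise_spec()] (default: realistic webcam tracking noise;
#'   use [noise_free()] for exact ground-truth recovery)
#' @param seed integer seed; equal seeds give identical trials
#' @param subject_id,level,session_index,completed trial identity fields
#' @param fps acquisition frame rate in Hz
#' @param theoretical_max per-game level maxima for validation
#' @return a `trial_record` with an extra `ground_truth` element
#' @export
simulate_trial <- function(motion, noise = noise_spec(), seed = 1L,
                           subject_id = "SYN01", level = 0L,
                           session_index = 1L, completed = TRUE, fps = 30,
                           theoretical_max = default_theoretical_max()) {
  stopifnot(inherits(motion, "motion_spec"), inherits(noise, "noise_spec"))
  if (motion$duration < 1) stop("duration must be at least 1 s")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  L <- as.integer(round(motion$duration * fps)) + 1L
  t <- seq(0, by = 1 / fps, length.out = L)
  mc <- motion_channels(motion, t)
  seated <- progression_game(motion$exergame) == "SKI"
  plane <- if (identical(motion$exergame, "GYM_FRONTAL")) "frontal" else "lateral"
  pos <- build_skeleton(t, mc$ang, plane, seated, motion$elbow_angle)

  # --- disturbances ---
  if (noise$jitter_sd > 0) {
    pos <- pos + array(stats::rnorm(length(pos), 0, noise$jitter_sd), dim = dim(pos))
  }
  if (noise$tremor_amp > 0) {
    arm_lm <- match(c("left_elbow", "right_elbow", "left_wrist", "right_wrist",
                      "left_pinky", "right_pinky", "left_index", "right_index",
                      "left_thumb", "right_thumb"), pose_landmark_names())
    ph <- stats::runif(length(arm_lm), 0, 2 * pi)
    for (k in seq_along(arm_lm)) {
      band <- noise$tremor_amp * sin(2 * pi * noise$tremor_freq * t + ph[k])
      pos[, arm_lm[k], 1] <- pos[, arm_lm[k], 1] + band
      pos[, arm_lm[k], 2] <- pos[, arm_lm[k], 2] + band * 0.5
    }
  }
  if (noise$spike_rate > 0) {
    n_sp <- stats::rpois(1, noise$spike_rate * motion$duration)
    if (n_sp > 0) {
      fr <- sample.int(L, n_sp, replace = TRUE)
      lm <- sample.int(33, n_sp, replace = TRUE)
      for (k in seq_len(n_sp)) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pos[fr[k], lm[k], ] <- pos[fr[k], lm[k], ] + noise$spike_magnitude * dir
      }
    }
  }
  if (noise$dropout_rate > 0) {
    n_dp <- stats::rpois(1, noise$dropout_rate * motion$duration)
    if (n_dp > 0) {
      fr <- sample.int(L, min(n_dp, max(0L, L - 8L)), replace = FALSE)
      fr <- setdiff(fr, c(1L, L))  # keep endpoints finite for resampling
      pos[fr, sample.int(33, 1), 1] <- NaN
    }
  }

  # --- events ---
  f <- motion$frequency
  t_end <- t[L]
  rep_times <- seq_len(floor(t_end * f)) / f
  rep_times <- rep_times[rep_times <= t_end]
  kinds <- c(rep(c("movement_valid", "point"), each = length(rep_times)))
  times <- c(rep_times, rep_times)
  if (progression_game(motion$exergame) == "PIANO") {
    key_times <- (seq_len(ceiling(t_end * f)) - 0.5) / f
    key_times <- key_times[key_times <= t_end]
    kinds <- c(kinds, rep("key_press", length(key_times)))
    times <- c(times, key_times)
  }
  if (isTRUE(completed)) {
    kinds <- c(kinds, "level_complete")
    times <- c(times, t_end)
  }
  events <- game_events(kinds, times)

  traj <- landmark_trajectory(t, pos, nominal_fps = fps)
  trial <- trial_record(subject_id = subject_id, exergame = motion$exergame,
                        level = level, session_index = session_index,
                        completed = completed, trajectory = traj,
                        events = events, mode = motion$mode,
                        theoretical_max = theoretical_max)
  trial$ground_truth <- c(mc$truth, list(seed = as.integer(seed),
                                         motion = motion, noise = noise))
  trial
}

#' Cohort specification for the simulator
#'
#' Defines a synthetic study cohort: per-subject impairment scores in
#' \[0, 1\] drive both the simulated MDS-UPDRS items (monotone increasing)
#' and the speed of level progression through a monotone non-increasing
#' link: the expected session of first mastery of a game is
#' `1 + floor(impairment * (max_sessions - 1))`, plus rounded Gaussian
#' noise (`link_noise_sd`), clipped to the subject's attended sessions.
#' Session attendance follows the study pattern (about 70% of subjects
#' attend all `max_sessions`, the rest 7 or 5).
#'
#' @param n_subjects number of subjects
#' @param max_sessions protocol length in sessions (default 10)
#' @param impairment optional numeric vector in \[0, 1\] (default: uniform
#'   draws)
#' @param link_noise_sd SD of the progression-link noise, sessions
#' @param theoretical_max named per-game level maxima
#' @param trial_duration per-trial duration in seconds used when
#'   trajectories are materialized
#' @param with_trajectories also generate full landmark trajectories for
#'   every trial (slow for large cohorts; level/progression analyses only
#'   need the metadata)
#' @param seed master seed; all generation is reproducible from it
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 14, max_sessions = 10,
                        impairment = NULL, link_noise_sd = 0.5,
                        theoretical_max = default_theoretical_max(),
                        trial_duration = 12, with_trajectories = FALSE,
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (max_sessions < 1 || max_sessions > 10) {
    stop("max_sessions must lie in 1..10")
  }
  if (!is.null(impairment)) {
    if (length(impairment) != n_subjects ||
        any(impairment < 0 | impairment > 1)) {
      stop("impairment must have one value in [0, 1] per subject")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 max_sessions = as.integer(max_sessions),
                 impairment = impairment, link_noise_sd = link_noise_sd,
                 theoretical_max = theoretical_max,
                 trial_duration = trial_duration,
                 with_trajectories = isTRUE(with_trajectories),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a study cohort
#'
#' Generates per-subject session sequences for the four exergames (one
#' trial per game per session; the Gym game contributes one frontal and one
#' lateral trial, cycling through the coordination modes), clinical
#' assessments whose item scores increase with impairment, and per-session
#' questionnaire responses whose satisfaction/well-being answers are
#' positively (and fatigue negatively) linked to progression.
#'
#' The achieved level in session `s` of a game with maximum `M` and
#' first-mastery session `s*` is `floor(M * min(s / s*, 1))`, so the level
#' schedule rises monotonically to `M` at `s*`. The returned
#' `progression` table is the generator's own ground truth, computed from
#' the level schedules independently of [extract_progression()].
#'
#' @param spec a [cohort_spec()]
#' @return list with `trials` (metadata tibble; column `trial_seed` allows
#'   re-materializing any single trial), `records` (list of
#'   `trial_record`, if `with_trajectories`), `clinical`, `questionnaire`,
#'   `progression` (ground truth), `impairment`
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  subj <- sprintf("S%02d", seq_len(n))
  u <- spec$impairment %||% stats::runif(n)
  names(u) <- subj

  # session attendance: study-like pattern (70% full, 15% seven, 15% five)
  n_sess <- vapply(seq_len(n), function(i) {
    q <- i / n
    if (q <= 0.72 || spec$max_sessions <= 7) spec$max_sessions
    else if (q <= 0.86) min(7L, spec$max_sessions)
    else min(5L, spec$max_sessions)
  }, integer(1))

  games <- c("AIRPLANE", "SKI", "PIANO", "GYM")
  tmax <- spec$theoretical_max

  # First-mastery session from the impairment link; a subject whose mastery
  # session exceeds their attendance never reaches the maximum level (the
  # level schedule is truncated, not accelerated), so the link stays
  # monotone across subjects with different attendance.
  trial_rows <- list()
  prog_rows <- list()
  for (i in seq_len(n)) {
    for (g in games) {
      s_star <- 1 + floor(u[i] * (spec$max_sessions - 1))
      if (spec$link_noise_sd > 0) {
        s_star <- s_star + round(stats::rnorm(1, 0, spec$link_noise_sd))
      }
      s_star <- min(max(1, s_star), spec$max_sessions)
      s_idx <- seq_len(n_sess[i])
      levels <- floor(tmax[[g]] * pmin(s_idx / s_star, 1))
      max_lv <- max(levels)
      prog_rows[[length(prog_rows) + 1L]] <- tibble(
        subject_id = subj[i], game = g, max_level = as.integer(max_lv),
        first_session = as.integer(min(which(levels == max_lv))),
        theoretical_max = as.integer(tmax[[g]])
      )
      exgs <- if (g == "GYM") c("GYM_FRONTAL", "GYM_LATERAL") else g
      trial_rows[[length(trial_rows) + 1L]] <- tibble(
        subject_id = subj[i],
        exergame = rep(exgs, each = n_sess[i]),
        mode = if (g == "GYM") rep(GYM_MODES[(s_idx - 1L) %% 3L + 1L],
                                   times = length(exgs))
               else NA_character_,
        level = as.integer(rep(levels, times = length(exgs))),
        session_index = as.integer(rep(s_idx, times = length(exgs))),
        completed = TRUE
      )
    }
  }
  trials <- dplyr::bind_rows(trial_rows)
  trials$trial_seed <- as.integer(
    (as.numeric(spec$seed) * 1009 + seq_len(nrow(trials))) %% 2147483647)
  progression <- dplyr::bind_rows(prog_rows)

  # clinical assessments: item scores rise monotonically with impairment;
  # staggered per-item difficulties spread the total over its range
  ids <- updrs_item_ids()
  # staggered per-item difficulties; the offset keeps simulated UPDRS III
  # totals on the scale of a mild-to-moderate PD cohort
  difficulty <- seq(0.20, 1.10, length.out = length(ids))
  clinical <- lapply(seq_len(n), function(i) {
    sc <- 4 * stats::plogis((u[i] - difficulty) / 0.15)
    if (spec$link_noise_sd > 0) {
      sc <- sc + stats::rnorm(length(sc), 0, spec$link_noise_sd)
    }
    sc <- pmin(4, pmax(0, round(sc)))
    names(sc) <- ids
    clinical_assessment(subj[i], hy = min(5, max(1, round(1.5 + 2.5 * u[i]))),
                        items = sc)
  })
  names(clinical) <- subj

  # questionnaires: satisfaction/well-being/usability rise and fatigue
  # falls with milder impairment (planted links recovered downstream)
  q_rows <- lapply(seq_len(n), function(i) {
    s_idx <- seq_len(n_sess[i])
    eps <- function() stats::rnorm(length(s_idx), 0, 0.4)
    clamp15 <- function(v) pmin(5L, pmax(1L, as.integer(round(v))))
    questionnaire_response(
      subject_id = subj[i], session_index = s_idx,
      q1 = clamp15(2.5 + 2.0 * (1 - u[i]) + eps()),
      q2 = clamp15(2.5 + 2.2 * (1 - u[i]) + eps()),
      q3 = clamp15(4.0 + 0.8 * (1 - u[i]) + eps()),
      q4 = clamp15(1.5 + 2.8 * u[i] + eps()),
      q5 = clamp15(2.5 + 1.8 * (1 - u[i]) + eps())
    )
  })
  questionnaire <- dplyr::bind_rows(q_rows)

  records <- NULL
  if (spec$with_trajectories) {
    records <- lapply(seq_len(nrow(trials)), function(k) {
      row <- trials[k, ]
      materialize_trial(row, impairment = u[[row$subject_id]],
                        duration = spec$trial_duration,
                        theoretical_max = tmax)
    })
  }

  list(trials = trials, records = records, clinical = clinical,
       questionnaire = questionnaire, progression = progression,
       impairment = u, spec = spec)
}

#' Materialize the trajectory of one cohort trial
#'
#' Regenerates the full `trial_record` for a row of the cohort metadata
#' table from its recorded seed. Impairment lowers movement amplitude and
#' raises bilateral asymmetry.
#'
#' @param row one row of the cohort `trials` tibble
#' @param impairment the subject's impairment in \[0, 1\]
#' @param duration trial duration in seconds
#' @param theoretical_max per-game level maxima
#' @return a `trial_record`
#' @export
materialize_trial <- function(row, impairment = 0.5, duration = 12,
                              theoretical_max = default_theoretical_max()) {
  motion <- motion_spec(row$exergame,
                        asymmetry_ratio = 1 + 0.3 * impairment,
                        duration = duration,
                        mode = if (is.na(row$mode)) NULL else row$mode)
  motion$amplitude <- motion$amplitude * (1 - 0.3 * impairment)
  # lateral raises happen outside the visual field and are executed with a
  # reduced excursion relative to frontal ones
  if (identical(row$exergame, "GYM_LATERAL")) {
    motion$amplitude <- motion$amplitude * 0.85
  }
  simulate_trial(motion, noise = noise_spec(), seed = row$trial_seed,
                 subject_id = row$subject_id, level = row$level,
                 session_index = row$session_index,
                 completed = row$completed,
                 theoretical_max = theoretical_max)
}
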