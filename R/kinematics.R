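#' Angle between two body segments
#'
#' The angle between two 3D segment vectors via the normalized dot product,
#' `acos(v1 . v2 / (|v1| |v2|))`, clamped into \[-1, 1\] before the arccos
#' and returned in degrees (range \[0, 180\]). Symmetric in its arguments
#' and invariant to positive scaling of either vector.
#'
#' @param v1,v2 numeric 3-vectors (non-zero)
#' @return angle in degrees
#' @export
segment_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("segment vectors must be non-zero")
  c_ <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Bilateral Symmetry Index
#'
#' `SI = |P_R / P_L - 1|` for a bilateral functional parameter measured on
#' the right (`p_right`) and left (`p_left`) side. 0 indicates perfect
#' bilateral symmetry; larger values an increasing functional gap between
#' the two sides. The ratio divides by the left side, so the metric is not
#' symmetric under swapping sides; it is invariant under common positive
#' scaling of both sides.
#'
#' @param p_right,p_left parameter values for the two sides (same units,
#'   finite; `p_left` must be non-zero)
#' @return dimensionless SI >= 0
#' @export
symmetry_index <- function(p_right, p_left) {
  if (any(!is.finite(p_right)) || any(!is.finite(p_left))) {
    stop("symmetry index requires finite inputs")
  }
  if (any(p_left == 0)) {
    stop("symmetry index undefined: left-side parameter is zero")
  }
  abs(p_right / p_left - 1)
}

#' Default joint-angle definitions
#'
#' The joint table maps named angles to landmark segment pairs:
#' * `ARM_ANG` (per side): shoulder-to-elbow vs the trunk's longitudinal
#'   axis (mid-shoulder to mid-hip);
#' * `ELB_ANG`: elbow-to-shoulder vs elbow-to-wrist (180 deg = straight arm);
#' * `LEG_ANG`: hip-to-knee vs the world vertical (down);
#' * `KNEE_ANG`: knee-to-hip vs knee-to-ankle;
#' * `T_ANG`: mid-hip-to-mid-shoulder vs the world vertical (up);
#'   0 deg = upright trunk.
#'
#' These defaults are provisional engineering choices (the deployed games'
#' exact landmark pairs are configurable); every exergame profile accepts an
#' overriding table.
#'
#' @return tibble with columns `name`, `side` (left/right/axial),
#'   `a_from`, `a_to`, `b_from`, `b_to`
#' @export
default_joint_table <- function() {
  dplyr::bind_rows(
    tibble(name = "ARM_ANG_R", side = "right", a_from = "right_shoulder",
           a_to = "right_elbow", b_from = "mid_shoulder", b_to = "mid_hip"),
    tibble(name = "ARM_ANG_L", side = "left", a_from = "left_shoulder",
           a_to = "left_elbow", b_from = "mid_shoulder", b_to = "mid_hip"),
    tibble(name = "ELB_ANG_R", side = "right", a_from = "right_elbow",
           a_to = "right_shoulder", b_from = "right_elbow",
           b_to = "right_wrist"),
    tibble(name = "ELB_ANG_L", side = "left", a_from = "left_elbow",
           a_to = "left_shoulder", b_from = "left_elbow",
           b_to = "left_wrist"),
    tibble(name = "LEG_ANG_R", side = "right", a_from = "right_hip",
           a_to = "right_knee", b_from = "world", b_to = "down"),
    tibble(name = "LEG_ANG_L", side = "left", a_from = "left_hip",
           a_to = "left_knee", b_from = "world", b_to = "down"),
    tibble(name = "KNEE_ANG_R", side = "right", a_from = "right_knee",
           a_to = "right_hip", b_from = "right_knee", b_to = "right_ankle"),
    tibble(name = "KNEE_ANG_L", side = "left", a_from = "left_knee",
           a_to = "left_hip", b_from = "left_knee", b_to = "left_ankle"),
    tibble(name = "T_ANG", side = "axial", a_from = "mid_hip",
           a_to = "mid_shoulder", b_from = "world", b_to = "up")
  )
}

#' Joint-angle time series from a trajectory
#'
#' Applies [segment_angle()] framewise to the joint's two segment vectors.
#' Frames in which either segment is degenerate (zero length or non-finite)
#' yield `NA` and are excluded from summaries.
#'
#' @param trajectory a `landmark_trajectory` (typically conditioned)
#' @param joint one row of a joint table (see [default_joint_table()])
#' @return numeric vector of angles in degrees, one per frame
#' @export
joint_angle_series <- function(trajectory, joint) {
  pos <- trajectory$positions
  va <- resolve_segment(pos, joint$a_from, joint$a_to)
  vb <- resolve_segment(pos, joint$b_from, joint$b_to)
  na_ <- sqrt(rowSums(va^2))
  nb_ <- sqrt(rowSums(vb^2))
  cth <- rowSums(va * vb) / (na_ * nb_)
  cth[na_ == 0 | nb_ == 0 | !is.finite(cth)] <- NA_real_
  acos(pmin(1, pmax(-1, cth))) * 180 / pi
}

#' Range of motion of an angle series
#'
#' `max - min` of the series (degrees). When repetition windows are
#' supplied, the ROM is computed per repetition and averaged, which is how
#' trial-level ROM summaries are reported.
#'
#' @param series numeric angle series (NA frames ignored)
#' @param reps optional list of index ranges (integer vectors) defining
#'   repetition windows
#' @return ROM in degrees (>= 0)
#' @export
range_of_motion <- function(series, reps = NULL) {
  series <- series[is.finite(series)]
  if (!length(series)) stop("angle series is empty")
  if (is.null(reps) || length(reps) < 1) {
    return(max(series) - min(series))
  }
  mean(vapply(reps, function(idx) {
    s <- series[idx]
    s <- s[is.finite(s)]
    if (!length(s)) return(NA_real_)
    max(s) - min(s)
  }, numeric(1)), na.rm = TRUE)
}

#' Angular velocity of an angle series
#'
#' Central finite differences on the uniform grid (one-sided at the ends),
#' in degrees per second.
#'
#' @param series numeric angle series (length >= 3)
#' @param rate sampling rate in Hz
#' @return numeric velocity series, same length as `series`
#' @export
angular_velocity <- function(series, rate) {
  L <- length(series)
  if (L < 3) stop("series must have at least 3 samples")
  v <- numeric(L)
  v[1] <- (series[2] - series[1]) * rate
  v[L] <- (series[L] - series[L - 1]) * rate
  v[seq(2, L - 1)] <- (series[seq(3, L)] - series[seq(1, L - 2)]) * rate / 2
  v
}

#' Repetition segmentation by peak detection
#'
#' Local maxima of the angle series with a minimum topographic prominence
#' and a minimum temporal separation; greedy selection keeps the higher peak
#' when two candidates are closer than `min_separation`. Used to segment
#' rhythmic movements into repetitions for per-repetition ROM / peak-speed
#' summaries and for the Peaks-Per-Minute game metric.
#'
#' @param series numeric angle series
#' @param rate sampling rate in Hz
#' @param min_prominence minimum peak prominence in degrees (default 10)
#' @param min_separation minimum peak separation in seconds (default 0.4)
#' @return integer vector of peak indices (possibly empty)
#' @export
find_repetition_peaks <- function(series, rate, min_prominence = 10,
                                  min_separation = 0.4) {
  L <- length(series)
  if (L < 3) return(integer())
  x <- series
  x[!is.finite(x)] <- -Inf
  cand <- which(x[2:(L - 1)] > x[1:(L - 2)] & x[2:(L - 1)] >= x[3:L]) + 1L
  cand <- cand[is.finite(series[cand])]
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= L && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    # peaks bounded by the series edge on one side keep that side's minimum
    h - max(lmin, rmin, na.rm = TRUE)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer())
  min_gap <- max(1L, as.integer(round(min_separation * rate)))
  keep <- integer()
  for (i in cand[order(series[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

# Repetition windows: consecutive peak-to-peak index ranges; a single peak
# (or none) yields no windows and summaries fall back to the whole series.
repetition_windows <- function(peaks, L) {
  if (length(peaks) < 2) return(list())
  lapply(seq_len(length(peaks) - 1L), function(k) {
    seq.int(peaks[k], peaks[k + 1L])
  })
}

#' Exergame feature profiles
#'
#' The per-game mapping from joint definitions to the motor functional
#' parameter (MFP) set reported for that game:
#' * AIRPLANE: `ARM_ANG`, `ELB_ANG`, `ARM_SI`, `ELB_SI`, `T_ANG`
#' * SKI: `LEG_ANG`, `KNEE_ANG`, `LEG_SI`, `KNEE_SI`, `T_ANG`
#' * PIANO: `ARM_ANG`, `T_ANG`
#' * GYM (both directions): `ROM_ANG`, `ARM_VEL`, `ANG_SI`, `VEL_SI`
#'
#' Summary rules: bilateral angles are reported as the mean over sides of
#' the per-repetition maxima (mean of extrema); `T_ANG` as the series mean
#' (mean trunk deviation from vertical); `ROM_ANG` as the mean over sides of
#' per-repetition ROM; `ARM_VEL` as the mean over sides of per-repetition
#' peak angular speed. SIs compare the right and left summary values.
#' Repetitions are segmented on the game's driving angle (`segmentation`).
#'
#' @param exergame one of AIRPLANE, SKI, PIANO, GYM_FRONTAL, GYM_LATERAL
#' @param joint_table overriding joint table (default
#'   [default_joint_table()])
#' @param min_prominence,min_separation peak-detection thresholds passed to
#'   [find_repetition_peaks()]
#' @return list of class `exergame_profile`
#' @export
exergame_profile <- function(exergame,
                             joint_table = default_joint_table(),
                             min_prominence = 10, min_separation = 0.4) {
  exergame <- match.arg(exergame, EXERGAMES)
  prof <- switch(progression_game(exergame),
    AIRPLANE = list(
      bilateral_angles = c("ARM_ANG", "ELB_ANG"),
      si = c(ARM_SI = "ARM_ANG", ELB_SI = "ELB_ANG"),
      axial = "T_ANG",
      segmentation = "T_ANG",
      columns = c("ARM_ANG", "ELB_ANG", "ARM_SI", "ELB_SI", "T_ANG")
    ),
    SKI = list(
      bilateral_angles = c("LEG_ANG", "KNEE_ANG"),
      si = c(LEG_SI = "LEG_ANG", KNEE_SI = "KNEE_ANG"),
      axial = "T_ANG",
      segmentation = "KNEE_ANG",
      columns = c("LEG_ANG", "KNEE_ANG", "LEG_SI", "KNEE_SI", "T_ANG")
    ),
    PIANO = list(
      bilateral_angles = "ARM_ANG",
      si = character(),
      axial = "T_ANG",
      segmentation = "ARM_ANG",
      columns = c("ARM_ANG", "T_ANG")
    ),
    GYM = list(
      rom = "ARM_ANG", velocity = "ARM_ANG",
      si = c(ANG_SI = "ROM_ANG", VEL_SI = "ARM_VEL"),
      segmentation = "ARM_ANG",
      columns = c("ROM_ANG", "ARM_VEL", "ANG_SI", "VEL_SI")
    )
  )
  prof$exergame <- exergame
  prof$joint_table <- joint_table
  prof$min_prominence <- min_prominence
  prof$min_separation <- min_separation
  class(prof) <- "exergame_profile"
  prof
}

joint_row <- function(joint_table, name) {
  row <- joint_table[joint_table$name == name, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("joint definition missing for '", name, "' in the joint table")
  }
  as.list(row)
}

# Per-repetition summary of a series: FUN over each repetition window,
# averaged; falls back to FUN over the whole series with < 2 peaks.
per_rep_summary <- function(series, reps, FUN) {
  if (length(reps) < 1) return(FUN(series[is.finite(series)]))
  mean(vapply(reps, function(idx) {
    s <- series[idx]
    FUN(s[is.finite(s)])
  }, numeric(1)), na.rm = TRUE)
}

#' Extract motor functional parameters from a conditioned trial
#'
#' Computes the full MFP set of the trial's exergame profile: summary joint
#' angles, range of motion and angular velocity where applicable, and
#' Symmetry Indices for all bilateral parameters. Every angle lies in
#' \[0, 180\] and every SI and ROM is non-negative (asserted).
#'
#' @param trial a (preferably preprocessed) `trial_record`
#' @param profile an [exergame_profile()]; defaults to the trial's game
#' @return named numeric vector (the MfpSet); its names equal the profile's
#'   reported column set
#' @export
extract_mfp <- function(trial, profile = exergame_profile(trial$exergame)) {
  tr <- trial$trajectory
  rate <- tr$nominal_fps
  jt <- profile$joint_table
  angle_of <- function(name) joint_angle_series(tr, joint_row(jt, name))

  seg_base <- profile$segmentation
  seg_series <- if (seg_base == "T_ANG") {
    angle_of("T_ANG")
  } else {
    # segment on the side with the larger excursion (the driving side)
    sr <- angle_of(paste0(seg_base, "_R"))
    sl <- angle_of(paste0(seg_base, "_L"))
    if (diff(range(sr, na.rm = TRUE)) >= diff(range(sl, na.rm = TRUE))) sr else sl
  }
  peaks <- find_repetition_peaks(seg_series, rate,
                                 profile$min_prominence,
                                 profile$min_separation)
  reps <- repetition_windows(peaks, length(seg_series))

  out <- c()
  side_summaries <- list()

  if (!is.null(profile$bilateral_angles)) {
    for (ang in profile$bilateral_angles) {
      sr <- angle_of(paste0(ang, "_R"))
      sl <- angle_of(paste0(ang, "_L"))
      vr <- per_rep_summary(sr, reps, max)
      vl <- per_rep_summary(sl, reps, max)
      side_summaries[[ang]] <- c(R = vr, L = vl)
      out[ang] <- mean(c(vr, vl))
    }
  }
  if (!is.null(profile$rom)) {
    sr <- angle_of(paste0(profile$rom, "_R"))
    sl <- angle_of(paste0(profile$rom, "_L"))
    rom_r <- range_of_motion(sr, reps)
    rom_l <- range_of_motion(sl, reps)
    side_summaries[["ROM_ANG"]] <- c(R = rom_r, L = rom_l)
    out["ROM_ANG"] <- mean(c(rom_r, rom_l))
  }
  if (!is.null(profile$velocity)) {
    vr_series <- abs(angular_velocity(angle_of(paste0(profile$velocity, "_R")), rate))
    vl_series <- abs(angular_velocity(angle_of(paste0(profile$velocity, "_L")), rate))
    vel_r <- per_rep_summary(vr_series, reps, max)
    vel_l <- per_rep_summary(vl_series, reps, max)
    side_summaries[["ARM_VEL"]] <- c(R = vel_r, L = vel_l)
    out["ARM_VEL"] <- mean(c(vel_r, vel_l))
  }
  for (si_name in names(profile$si)) {
    base <- profile$si[[si_name]]
    ss <- side_summaries[[base]]
    out[si_name] <- symmetry_index(ss[["R"]], ss[["L"]])
  }
  if (!is.null(profile$axial)) {
    out[profile$axial] <- mean(angle_of(profile$axial), na.rm = TRUE)
  }
  out <- out[profile$columns]
  names(out) <- profile$columns

  ang_cols <- grepl("_ANG$|^T_ANG$", names(out)) & !grepl("ROM", names(out))
  stopifnot(all(out[ang_cols] >= 0 - 1e-9 & out[ang_cols] <= 180 + 1e-9))
  stopifnot(all(out[grepl("_SI$", names(out))] >= 0))
  if ("ROM_ANG" %in% names(out)) stopifnot(out[["ROM_ANG"]] >= 0)
  attr(out, "n_repetitions") <- length(peaks)
  out
}
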