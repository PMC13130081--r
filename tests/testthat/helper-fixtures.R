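# Fixtures are built in code; nothing is read from disk.

# Minimal hand-built trial: `n_frames` frames of a static skeleton.
make_minimal_trial <- function(n_frames = 2, n_events = 0, fps = 30) {
  t <- seq(0, by = 1 / fps, length.out = n_frames)
  pos <- array(0, dim = c(n_frames, 33, 3))
  # place every landmark somewhere non-degenerate
  base <- matrix(seq_len(33 * 3) / 100, nrow = 33)
  for (i in seq_len(n_frames)) pos[i, , ] <- base
  ev <- if (n_events > 0) {
    game_events(rep("point", n_events),
                seq(0, t[length(t)], length.out = n_events))
  } else {
    game_events()
  }
  trial_record("T01", "AIRPLANE", level = 0, session_index = 1,
               completed = TRUE,
               trajectory = landmark_trajectory(t, pos, nominal_fps = fps),
               events = ev)
}

# Random valid trial via the simulator (for round-trip properties).
make_random_trial <- function(seed, exergame = "PIANO", duration = 3) {
  simulate_trial(motion_spec(exergame, duration = duration),
                 noise_spec(jitter_sd = 0.002, spike_rate = 0.5,
                            spike_magnitude = 0.1, tremor_amp = 0.002,
                            tremor_freq = 11),
                 seed = seed)
}

# Brute-force sliding median oracle using the package's stated window
# convention (window [i - floor(w/2), i + w - 1 - floor(w/2)], replicate
# padding, even-count median = mean of middle two).
oracle_median_filter <- function(x, w) {
  L <- length(x)
  lw <- w %/% 2
  sapply(seq_len(L), function(i) {
    idx <- (i - lw):(i + w - 1 - lw)
    idx[idx < 1] <- 1
    idx[idx > L] <- L
    stats::median(x[idx])
  })
}

# Tiny clinical fixture: all items equal `score`.
make_assessment <- function(id = "S01", score = 1, hy = 2) {
  items <- stats::setNames(rep(score, length(updrs_item_ids())),
                           updrs_item_ids())
  clinical_assessment(id, hy, items)
}

# All permutations of 1..n (tiny n), by insertion.
gtools_like_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(out[, seq_len(pos - 1), drop = FALSE], k,
            out[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  out
}

# Amplitude of frequency f in series x sampled at `rate` (sin/cos fit).
tone_amplitude <- function(x, rate, f) {
  t <- seq_along(x) / rate
  fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
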