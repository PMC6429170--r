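# Synthetic familiarity-experiment EEG sessions.
#
# The generator emulates the structure of a 6-code PIN familiarity
# experiment: on every trial one of six 4-digit codes is flashed; the code
# with tag 1 is the user's real PIN and elicits an extra P300-like
# familiarity component over parietal electrodes, on top of a generic
# visual evoked response shared by all tags, 1/f-plus-white background
# noise, and occasional eye blinks visible on two EOG channels.

#' Standard 32-channel 10-10 montage plus two EOG channels
#'
#' @return Character vector of 34 channel labels; the last two are the
#'   periocular (`EOG1`, `EOG2`) channels.
#' @export
eeg_montage <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz",
    "EOG1", "EOG2")
}

# channels carrying the familiarity (P300-like) component, with relative
# scalp weights: parietal/occipital emphasis (P7/P8 dominant)
.familiarity_topography <- c(
  P7 = 1.00, P8 = 0.90, Pz = 0.70, O1 = 0.45, O2 = 0.45,
  PO3 = 0.35, PO4 = 0.35, P3 = 0.30, P4 = 0.30
)

# frontal bleed-through weights of an eye blink (fraction of EOG amplitude)
.blink_bleed <- c(
  Fp1 = 0.30, Fp2 = 0.30, AF3 = 0.22, AF4 = 0.22,
  F7 = 0.10, F8 = 0.10, F3 = 0.12, F4 = 0.12, Fz = 0.12
)

#' Create a synthetic user profile
#'
#' A profile bundles everything user-specific: a baseline evoked response
#' common to all six codes, a familiarity component (Gaussian bump in
#' time, parietal topography) added only for the real-PIN tag, the
#' background-noise level and spectrum, and optionally a "parasitic" tag
#' that receives a scaled copy of the familiarity component (emulating a
#' random code that happens to be familiar to the user).
#'
#' @param seed Integer seed; profiles are bit-identical given the seed.
#' @param amplitude Peak amplitude of the familiarity component, microvolt.
#' @param latency Latency of the familiarity peak, ms post stimulus onset.
#' @param width Gaussian SD of the component in time, ms.
#' @param parasitic_tag Optional tag index in `2..n_tags` receiving a
#'   scaled familiarity component, or `NULL`.
#' @param parasitic_scale Scale in `[0, 1]` of the parasitic copy.
#' @param noise_sd Total background-noise standard deviation, microvolt
#'   (split evenly in power between 1/f^alpha and white components).
#' @param noise_alpha Exponent of the 1/f^alpha noise component.
#' @param epoch_len Epoch length in samples.
#' @param fs Sampling rate, Hz.
#' @return An object of class `user_profile`.
#' @examples
#' p <- make_user_profile(seed = 1)
#' dim(familiarity_template(p))
#' @export
make_user_profile <- function(seed, amplitude = 5, latency = 400, width = 60,
                              parasitic_tag = NULL, parasitic_scale = 1,
                              noise_sd = 10, noise_alpha = 1,
                              epoch_len = 1000, fs = 1000) {
  window_ms <- epoch_len / fs * 1000
  if (amplitude < 0) err("amplitude must be >= 0", "erpleak_param_error")
  if (latency < 0 || latency >= window_ms)
    err("latency must lie in [0, epoch window)", "erpleak_param_error")
  if (latency + 3 * width > window_ms)
    err(sprintf(
      "familiarity component exceeds the epoch: latency + 3*width = %.0f ms > %.0f ms window",
      latency + 3 * width, window_ms), "erpleak_param_error")
  if (!is.null(parasitic_tag)) {
    if (parasitic_tag < 2) err("parasitic_tag must be >= 2", "erpleak_param_error")
    if (parasitic_scale < 0 || parasitic_scale > 1)
      err("parasitic_scale must lie in [0, 1]", "erpleak_param_error")
  }
  if (noise_sd < 0) err("noise_sd must be >= 0", "erpleak_param_error")

  channels <- eeg_montage()
  nch <- length(channels)
  t_ms <- (seq_len(epoch_len) - 1) / fs * 1000

  prof <- with_seed(seed, {
    # generic visual evoked response: two rank-one smooth components
    comp <- numeric(epoch_len)
    for (k in 1:3) {
      mu <- stats::runif(1, 100, min(550, window_ms * 0.6))
      s  <- stats::runif(1, 40, 110)
      f  <- stats::runif(1, 2, 7)
      a  <- stats::runif(1, 0.8, 2.4)
      comp <- comp + a * exp(-(t_ms - mu)^2 / (2 * s^2)) *
        cos(2 * pi * f * (t_ms - mu) / 1000 + stats::runif(1, 0, 2 * pi))
    }
    gains <- stats::runif(nch, 0.2, 1)
    gains[channels %in% c("EOG1", "EOG2")] <- 0.05
    baseline <- outer(gains, comp)

    w <- numeric(nch)
    names(w) <- channels
    topo <- .familiarity_topography
    w[names(topo)] <- topo * exp(stats::rnorm(length(topo), 0, 0.15))
    list(baseline_erp = baseline, familiarity_weights = w)
  })

  structure(list(
    user_id = NA_integer_,
    seed = as.integer(seed),
    baseline_erp = prof$baseline_erp,
    amplitude = amplitude, latency = latency, width = width,
    familiarity_weights = prof$familiarity_weights,
    parasitic_tag = parasitic_tag, parasitic_scale = parasitic_scale,
    noise_sd = noise_sd, noise_alpha = noise_alpha,
    epoch_len = as.integer(epoch_len), fs = fs,
    channel_names = channels
  ), class = "user_profile")
}

#' Familiarity (P300-like) template of a profile
#'
#' The deterministic channels-by-samples waveform added to real-PIN
#' epochs: a Gaussian bump in time scaled by the profile's parietal
#' channel weights.
#'
#' @param profile A [make_user_profile()] object.
#' @return Matrix `n_channels x epoch_len`, microvolt.
#' @export
familiarity_template <- function(profile) {
  t_ms <- (seq_len(profile$epoch_len) - 1) / profile$fs * 1000
  bump <- profile$amplitude *
    exp(-(t_ms - profile$latency)^2 / (2 * profile$width^2))
  outer(unname(profile$familiarity_weights), bump)
}

#' Session configuration
#'
#' Defaults reproduce the experiment geometry the analysis assumes: six
#' codes shown 150 times each (900 epochs), 1000 Hz sampling, 1 s epochs
#' cut from a 1.009 s stimulus onset asynchrony, 32 scalp + 2 EOG
#' channels.
#'
#' @param n_tags Number of distinct codes (tag 1 is the real PIN).
#' @param reps_per_tag Presentations per code.
#' @param fs Sampling rate, Hz.
#' @param epoch_len Epoch length in samples; must not exceed `soa * fs`.
#' @param soa Stimulus onset asynchrony, seconds.
#' @param blink_rate Per-epoch probability of an eye blink.
#' @param blink_amplitude Typical blink peak on the EOG channels, microvolt.
#' @param seed Integer seed for the session's noise, schedule and blinks.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_tags = 6L, reps_per_tag = 150L, fs = 1000,
                           epoch_len = 1000L, soa = 1.009,
                           blink_rate = 0.05, blink_amplitude = 250,
                           seed = 1L) {
  if (n_tags < 2) err("n_tags must be >= 2", "erpleak_config_error")
  if (reps_per_tag < 1) err("reps_per_tag must be >= 1", "erpleak_config_error")
  if (epoch_len > soa * fs)
    err("epoch_len must be <= soa * fs (epochs cannot overlap)",
        "erpleak_config_error")
  if (blink_rate < 0 || blink_rate > 1)
    err("blink_rate must lie in [0, 1]", "erpleak_config_error")
  structure(list(
    n_tags = as.integer(n_tags), reps_per_tag = as.integer(reps_per_tag),
    fs = fs, epoch_len = as.integer(epoch_len), soa = soa,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude,
    seed = as.integer(seed)
  ), class = "session_config")
}

# Constrained tag schedule: every pair of equal tags is separated by at
# least `min_gap` other events. Sequential constrained draw (probability
# proportional to remaining quota), restarting on dead ends.
sample_schedule <- function(n_tags, reps_per_tag, min_gap = 2L,
                            max_restarts = 1000L) {
  if (n_tags <= min_gap)
    err(sprintf(
      "cannot schedule %d tags with a separation of %d other events",
      n_tags, min_gap), "erpleak_config_error")
  n <- n_tags * reps_per_tag
  for (r in seq_len(max_restarts)) {
    counts <- rep(reps_per_tag, n_tags)
    out <- integer(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      recent <- out[max(1L, i - min_gap):max(1L, i - 1L)]
      if (i == 1L) recent <- integer(0)
      allowed <- which(counts > 0L & !(seq_len(n_tags) %in% recent))
      if (!length(allowed)) { ok <- FALSE; break }
      pick <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = counts[allowed])
      out[i] <- pick
      counts[pick] <- counts[pick] - 1L
    }
    if (ok) return(out)
  }
  err("failed to sample a feasible tag schedule", "erpleak_config_error")
}

# 1/f^alpha noise: shape white Gaussian noise in the frequency domain.
# Returns an n_samples x n_cols matrix with (marginal) SD ~ sd.
pink_noise <- function(n, m, alpha, sd) {
  if (sd <= 0) return(matrix(0, n, m))
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # two-sided frequency index
  h <- c(0, f[-1]^(-alpha / 2))  # no DC
  h <- h / sqrt(mean(h^2))       # unit output variance for unit input
  w <- matrix(stats::rnorm(n * m), n, m)
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n
  x * sd
}

#' Simulate one experimental session
#'
#' Generates `n_tags * reps_per_tag` epochs: baseline evoked response for
#' every tag, plus the profile's familiarity component for tag 1 (and a
#' scaled copy for the parasitic tag, if set), plus seeded 1/f + white
#' noise, plus eye-blink artifacts injected on the EOG and frontal
#' channels with probability `blink_rate` per epoch and recorded in
#' `artifact_truth`.
#'
#' @param profile A [make_user_profile()] object.
#' @param config A [session_config()] object; its `fs`/`epoch_len` must
#'   match the profile's.
#' @return An object of class `epoch_set` with fields `data` (array
#'   `epochs x channels x samples`, microvolt), `tags`, `user_id`, `fs`,
#'   `channel_names`, `artifact_truth`.
#' @examples
#' p <- make_user_profile(seed = 1, epoch_len = 250, fs = 250,
#'                        latency = 400, width = 60)
#' s <- simulate_session(p, session_config(reps_per_tag = 5, fs = 250,
#'                                         epoch_len = 250, seed = 2))
#' dim(s$data)
#' @export
simulate_session <- function(profile, config = session_config()) {
  stopifnot(inherits(profile, "user_profile"),
            inherits(config, "session_config"))
  if (profile$epoch_len != config$epoch_len || profile$fs != config$fs)
    err("profile and config disagree on fs / epoch_len",
        "erpleak_config_error")

  channels <- profile$channel_names
  nch <- length(channels)
  n_epochs <- config$n_tags * config$reps_per_tag
  ns <- config$epoch_len
  fam <- familiarity_template(profile)

  with_seed(config$seed, {
    tags <- sample_schedule(config$n_tags, config$reps_per_tag)

    data <- array(0, dim = c(n_epochs, nch, ns))
    sd_each <- profile$noise_sd / sqrt(2)
    for (c in seq_len(nch)) {
      noise <- pink_noise(ns, n_epochs, profile$noise_alpha, sd_each) +
        matrix(stats::rnorm(ns * n_epochs, 0, sd_each), ns, n_epochs)
      base <- profile$baseline_erp[c, ]
      data[, c, ] <- t(noise + base)
    }
    idx1 <- which(tags == 1L)
    for (c in seq_len(nch)) if (any(fam[c, ] != 0))
      data[idx1, c, ] <- data[idx1, c, ] +
        matrix(fam[c, ], length(idx1), ns, byrow = TRUE)
    if (!is.null(profile$parasitic_tag) &&
        profile$parasitic_tag <= config$n_tags) {
      idxp <- which(tags == profile$parasitic_tag)
      for (c in seq_len(nch)) if (any(fam[c, ] != 0))
        data[idxp, c, ] <- data[idxp, c, ] +
          profile$parasitic_scale *
          matrix(fam[c, ], length(idxp), ns, byrow = TRUE)
    }

    # eye blinks: biphasic deflection on EOG1/EOG2, attenuated frontal copy
    blink <- stats::runif(n_epochs) < config$blink_rate
    if (any(blink)) {
      t_ms <- (seq_len(ns) - 1) / config$fs * 1000
      i_eog1 <- match("EOG1", channels); i_eog2 <- match("EOG2", channels)
      bleed_ix <- match(names(.blink_bleed), channels)
      for (e in which(blink)) {
        t0 <- stats::runif(1, 0.2, 0.75) * (ns / config$fs * 1000)
        a <- config$blink_amplitude * stats::runif(1, 0.7, 1.3)
        wav <- a * (exp(-(t_ms - t0)^2 / (2 * 50^2)) -
                      0.4 * exp(-(t_ms - t0 - 120)^2 / (2 * 70^2)))
        data[e, i_eog1, ] <- data[e, i_eog1, ] + wav
        data[e, i_eog2, ] <- data[e, i_eog2, ] - 0.8 * wav
        for (j in seq_along(bleed_ix))
          data[e, bleed_ix[j], ] <- data[e, bleed_ix[j], ] +
            .blink_bleed[j] * wav
      }
    }

    structure(list(
      data = data, tags = tags, user_id = profile$user_id,
      fs = config$fs, channel_names = channels,
      artifact_truth = blink, epoch_len = ns,
      config = config
    ), class = "epoch_set")
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  cat("  tags:", paste(sprintf("%d:%d", seq_along(tabulate(x$tags)),
                               tabulate(x$tags)), collapse = " "), "\n")
  cat(sprintf("  artifacts (truth): %d\n", sum(x$artifact_truth)))
  invisible(x)
}

#' Simulate a cohort of users
#'
#' Draws user-specific profiles (amplitude, latency, width, noise level
#' and topography jitter scaled by `spread`) and one session per user.
#' With `spread = 0` all users share one profile (sessions still differ
#' in their noise realizations), the upper-bound fixture for model
#' portability.
#'
#' @param n_users Number of users (>= 2).
#' @param seed Master seed; per-user seeds are derived deterministically.
#' @param spread Non-negative scale of inter-user variability (1 =
#'   default variability, 0 = identical profiles).
#' @param config A [session_config()]; its `seed` field is ignored
#'   (per-user seeds are derived from `seed`).
#' @param amplitude,latency,width,noise_sd Population-centre profile
#'   parameters, passed to [make_user_profile()].
#' @return List of `n_users` elements, each `list(profile, session)`.
#' @export
simulate_cohort <- function(n_users, seed, spread = 1,
                            config = session_config(),
                            amplitude = 5, latency = 400, width = 60,
                            noise_sd = 10) {
  if (n_users < 2) err("n_users must be >= 2", "erpleak_param_error")
  if (spread < 0) err("spread must be >= 0", "erpleak_param_error")
  pars <- with_seed(derive_seed(seed, 1L), {
    list(amp = amplitude * exp(spread * stats::rnorm(n_users, 0, 0.35)),
         lat = pmax(100, latency + spread * stats::rnorm(n_users, 0, 30)),
         wid = width * exp(spread * stats::rnorm(n_users, 0, 0.20)),
         nsd = noise_sd * exp(spread * stats::rnorm(n_users, 0, 0.10)))
  })
  lapply(seq_len(n_users), function(u) {
    profile_seed <- if (spread > 0) derive_seed(seed, 100L + u)
                    else derive_seed(seed, 100L)
    prof <- make_user_profile(
      seed = profile_seed,
      amplitude = pars$amp[u], latency = pars$lat[u], width = pars$wid[u],
      noise_sd = pars$nsd[u],
      epoch_len = config$epoch_len, fs = config$fs)
    prof$user_id <- u
    cfg <- config
    cfg$seed <- derive_seed(seed, 200L + u)
    list(profile = prof, session = simulate_session(prof, cfg))
  })
}
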