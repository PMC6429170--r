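# Preprocessing: zero-phase bandpass, EOG artifact rejection, electrode
# selection / observation-vector construction.

# Squared 4th-order Butterworth magnitude pair (high-pass at lo, low-pass
# at hi), i.e. the steady-state response of forward-backward filtering.
butterworth_gain <- function(f, lo, hi, order = 4) {
  g <- 1 / (1 + (f / hi)^(2 * order))
  hp <- ifelse(f > 0, 1 / (1 + (lo / f)^(2 * order)), 0)
  g * hp
}

#' Zero-phase bandpass filter
#'
#' Applies the squared magnitude response of a 4th-order Butterworth
#' high-pass/low-pass pair (the steady-state equivalent of
#' forward-backward filtering) in the frequency domain, on a mirrored
#' extension of each epoch. Zero phase, so ERP component latencies are
#' preserved; exactly linear; the DC gain is exactly zero.
#'
#' @param epochs An `epoch_set`.
#' @param lo Low cutoff, Hz (default 0.5: removes slow drifts).
#' @param hi High cutoff, Hz (default 30: removes muscle artifacts and
#'   50 Hz line noise).
#' @param order Butterworth order of each edge (default 4).
#' @return An `epoch_set` of identical shape with all channels filtered
#'   identically.
#' @export
bandpass <- function(epochs, lo = 0.5, hi = 30, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    err("need 0 < lo < hi < fs/2", "erpleak_param_error")
  n <- dim(epochs$data)[3]
  min_len <- ceiling(3 * fs / (2 * pi * lo))
  if (n < min_len)
    err(sprintf(
      "epoch too short for stable filtering at lo = %g Hz: need >= %d samples, have %d",
      lo, min_len, n), "erpleak_param_error")

  # mirror extension (length 2n) makes the periodic signal continuous
  nfft <- 2L * n
  f <- pmin(0:(nfft - 1), nfft - (0:(nfft - 1))) * fs / nfft
  gain <- butterworth_gain(f, lo, hi, order)

  out <- epochs
  n_epochs <- dim(epochs$data)[1]
  for (ch in seq_len(dim(epochs$data)[2])) {
    x <- t(epochs$data[, ch, , drop = TRUE])      # samples x epochs
    if (n_epochs == 1L) x <- matrix(epochs$data[1, ch, ], ncol = 1L)
    ext <- rbind(x, x[n:1, , drop = FALSE])
    y <- Re(stats::mvfft(stats::mvfft(ext) * gain, inverse = TRUE)) / nfft
    out$data[, ch, ] <- t(y[seq_len(n), , drop = FALSE])
  }
  out
}

#' Reject epochs contaminated by eye blinks
#'
#' Removes epochs whose peak-to-peak amplitude on any EOG channel exceeds
#' `threshold`; surviving epochs are untouched.
#'
#' @param epochs An `epoch_set`.
#' @param eog_channels Labels of the EOG channels.
#' @param threshold Peak-to-peak rejection threshold, microvolt.
#' @return List with `epochs` (the surviving `epoch_set`), `rejected_ids`
#'   (indices into the input), and `surviving_per_tag` (named counts).
#' @export
reject_artifacts <- function(epochs, eog_channels = c("EOG1", "EOG2"),
                             threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  ix <- match(eog_channels, epochs$channel_names)
  if (anyNA(ix))
    err(paste0("EOG channel(s) not found: ",
               paste(eog_channels[is.na(ix)], collapse = ", ")),
        "erpleak_channel_error")
  ptp <- apply(epochs$data[, ix, , drop = FALSE], c(1, 2),
               function(v) diff(range(v)))
  bad <- which(apply(ptp > threshold, 1, any))
  if (length(bad) == dim(epochs$data)[1])
    err("all epochs rejected; downstream analysis undefined",
        "erpleak_rejection_error")
  out <- epochs
  if (length(bad)) {
    out$data <- epochs$data[-bad, , , drop = FALSE]
    out$tags <- epochs$tags[-bad]
    out$artifact_truth <- epochs$artifact_truth[-bad]
  }
  counts <- tabulate(out$tags, nbins = max(epochs$tags))
  names(counts) <- paste0("tag", seq_along(counts))
  list(epochs = out, rejected_ids = bad, surviving_per_tag = counts)
}

#' Build observation vectors from selected electrodes
#'
#' Concatenates the selected channels of every epoch, in the given order,
#' into one long vector per epoch (for the defaults, 2 x 1000 samples =
#' 2000 values). Values are copied exactly, no rescaling.
#'
#' @param epochs An `epoch_set`.
#' @param channels Channel labels to concatenate (default `P7`, `P8`, the
#'   parietal pair carrying the most regular familiarity information).
#' @return An object of class `observation_set`: fields `vectors`
#'   (epochs x D matrix), `tags`, `user_id`, `channels`, `epoch_len`.
#' @export
select_concat <- function(epochs, channels = c("P7", "P8")) {
  stopifnot(inherits(epochs, "epoch_set"))
  ix <- match(channels, epochs$channel_names)
  if (anyNA(ix))
    err(paste0("unknown channel label(s): ",
               paste(channels[is.na(ix)], collapse = ", "),
               "; available: ", paste(epochs$channel_names, collapse = ", ")),
        "erpleak_channel_error")
  n_epochs <- dim(epochs$data)[1]
  ns <- dim(epochs$data)[3]
  vectors <- matrix(0, n_epochs, length(ix) * ns)
  for (j in seq_along(ix))
    vectors[, (j - 1) * ns + seq_len(ns)] <- epochs$data[, ix[j], ]
  structure(list(
    vectors = vectors, tags = epochs$tags, user_id = epochs$user_id,
    channels = channels, epoch_len = ns
  ), class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d epochs x %d dims (channels %s)\n",
              nrow(x$vectors), ncol(x$vectors),
              paste(x$channels, collapse = "+")))
  invisible(x)
}
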