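# Session I/O: EDF for the signals (16-bit, per-channel physical
# scaling), CSV for the event table, JSON for profiles, PCA bases and
# density models. The EDF layout maps one data record to one epoch, so
# the events CSV carries 0-based onset samples into the concatenated
# stream and epochs round-trip exactly up to 16-bit quantization.

.edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf("%-*s", width, s)
}

#' Write a session to EDF + events CSV (+ profile JSON)
#'
#' @param session An `epoch_set`.
#' @param edf_path Output EDF file.
#' @param events_path Output events CSV (columns `onset_sample` (0-based),
#'   `tag`, `artifact_truth`).
#' @param profile Optional `user_profile` to serialize alongside.
#' @param profile_path JSON path for `profile`.
#' @return Invisibly, `edf_path`.
#' @export
write_session <- function(session, edf_path, events_path,
                          profile = NULL, profile_path = NULL) {
  stopifnot(inherits(session, "epoch_set"))
  d <- session$data
  n_epochs <- dim(d)[1]; nch <- dim(d)[2]; ns <- dim(d)[3]

  phys_min <- phys_max <- numeric(nch)
  for (ch in seq_len(nch)) {
    rng <- range(d[, ch, ])
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    pad <- diff(rng) * 0.001
    phys_min[ch] <- rng[1] - pad
    phys_max[ch] <- rng[2] + pad
  }
  dig_min <- -32768; dig_max <- 32767

  con <- file(edf_path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(sprintf("user %s", session$user_id), 80),
    .edf_pad("erpleak synthetic session", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + nch), 8),
    .edf_pad("", 44),
    .edf_pad(n_epochs, 8),
    .edf_pad(format(ns / session$fs, digits = 8), 8),
    .edf_pad(nch, 4),
    paste(vapply(session$channel_names, .edf_pad, "", width = 16),
          collapse = ""),
    paste(rep(.edf_pad("AgAgCl electrode", 80), nch), collapse = ""),
    paste(rep(.edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(phys_min, function(v) .edf_pad(signif(v, 7), 8), ""),
          collapse = ""),
    paste(vapply(phys_max, function(v) .edf_pad(signif(v, 7), 8), ""),
          collapse = ""),
    paste(rep(.edf_pad(dig_min, 8), nch), collapse = ""),
    paste(rep(.edf_pad(dig_max, 8), nch), collapse = ""),
    paste(rep(.edf_pad("none", 80), nch), collapse = ""),
    paste(rep(.edf_pad(ns, 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 32), nch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (e in seq_len(n_epochs)) for (ch in seq_len(nch)) {
    dig <- round((d[e, ch, ] - phys_min[ch]) / scale[ch] + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2L, endian = "little")
  }

  events <- data.frame(onset_sample = (seq_len(n_epochs) - 1L) * ns,
                       tag = session$tags,
                       artifact_truth = as.integer(session$artifact_truth))
  utils::write.csv(events, events_path, row.names = FALSE)

  if (!is.null(profile)) {
    if (is.null(profile_path))
      err("profile_path required when profile is given", "erpleak_io_error")
    write_profile(profile, profile_path)
  }
  invisible(edf_path)
}

# read `n` ASCII bytes from an open EDF connection
.edf_str <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))
.edf_num <- function(con, n) as.numeric(.edf_str(con, n))

#' Read a session from EDF + events CSV
#'
#' Epochs are cut as `[onset, onset + epoch_len)` from the concatenated
#' sample stream; `epoch_len` defaults to the EDF samples-per-record.
#'
#' @param edf_path EDF file written by [write_session()].
#' @param events_path Events CSV (`onset_sample` 0-based, `tag`,
#'   `artifact_truth`).
#' @param epoch_len Epoch length in samples (`NULL`: samples per record).
#' @return An `epoch_set`.
#' @export
read_session <- function(edf_path, events_path, epoch_len = NULL) {
  con <- file(edf_path, "rb")
  on.exit(close(con))
  .edf_str(con, 8)                       # version
  .edf_str(con, 80); .edf_str(con, 80)   # patient, recording
  .edf_str(con, 8); .edf_str(con, 8)     # date, time
  .edf_num(con, 8)                       # header bytes
  .edf_str(con, 44)
  n_rec <- .edf_num(con, 8)
  rec_dur <- .edf_num(con, 8)
  nch <- .edf_num(con, 4)
  labels <- vapply(seq_len(nch), function(i) .edf_str(con, 16), "")
  for (i in seq_len(nch)) .edf_str(con, 80)   # transducer
  for (i in seq_len(nch)) .edf_str(con, 8)    # phys dim
  phys_min <- vapply(seq_len(nch), function(i) .edf_num(con, 8), 0)
  phys_max <- vapply(seq_len(nch), function(i) .edf_num(con, 8), 0)
  dig_min <- vapply(seq_len(nch), function(i) .edf_num(con, 8), 0)
  dig_max <- vapply(seq_len(nch), function(i) .edf_num(con, 8), 0)
  for (i in seq_len(nch)) .edf_str(con, 80)   # prefilter
  spr <- vapply(seq_len(nch), function(i) .edf_num(con, 8), 0)
  for (i in seq_len(nch)) .edf_str(con, 32)
  if (length(unique(spr)) != 1)
    err("channels with unequal sampling are not supported",
        "erpleak_io_error")
  spr <- spr[1]
  fs <- spr / rec_dur

  total <- n_rec * spr
  signal <- matrix(0, nch, total)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = nch * spr, size = 2L,
                     endian = "little")
    if (length(block) < nch * spr)
      err("truncated EDF data record", "erpleak_io_error")
    for (ch in seq_len(nch))
      signal[ch, (r - 1) * spr + seq_len(spr)] <-
        (block[(ch - 1) * spr + seq_len(spr)] - dig_min[ch]) * scale[ch] +
        phys_min[ch]
  }

  events <- utils::read.csv(events_path)
  need <- c("onset_sample", "tag")
  if (!all(need %in% names(events)))
    err("events CSV must have onset_sample and tag columns",
        "erpleak_io_error")
  if (nrow(events) == 0) err("no epochs in events file", "erpleak_io_error")
  if (is.unsorted(events$onset_sample, strictly = TRUE))
    err("event onsets must be strictly increasing", "erpleak_io_error")
  if (is.null(epoch_len)) epoch_len <- spr
  if (max(events$onset_sample) + epoch_len > total)
    err("event onset beyond end of recording", "erpleak_io_error")

  n_epochs <- nrow(events)
  data <- array(0, dim = c(n_epochs, nch, epoch_len))
  for (e in seq_len(n_epochs))
    data[e, , ] <- signal[, events$onset_sample[e] + seq_len(epoch_len)]
  art <- if ("artifact_truth" %in% names(events))
    as.logical(events$artifact_truth) else rep(FALSE, n_epochs)
  structure(list(data = data, tags = events$tag, user_id = NA_integer_,
                 fs = fs, channel_names = labels, artifact_truth = art,
                 epoch_len = as.integer(epoch_len)),
            class = "epoch_set")
}

#' Serialize a user profile to JSON
#' @param profile A `user_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "user_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Serialize a PCA basis to JSON (for portability attacks)
#' @param basis A `projection_basis`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "projection_basis"))
  jsonlite::write_json(list(components = basis$components,
                            center = basis$center, source = basis$source,
                            explained_variance = basis$explained_variance),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a PCA basis from JSON
#' @param path JSON written by [write_basis()].
#' @return A `projection_basis`.
#' @export
read_basis <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_basis(as.matrix(j$components), as.numeric(j$center), j$source,
            as.numeric(j$explained_variance))
}

#' Serialize a fitted density model to JSON
#' @param model A `class_density`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_density_model <- function(model, path) {
  stopifnot(inherits(model, "class_density"))
  jsonlite::write_json(
    list(classes = model$classes, models = model$models,
         priors = model$priors, backend = model$backend,
         n_dim = model$n_dim),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted density model from JSON
#' @param path JSON written by [write_density_model()].
#' @return A `class_density`.
#' @export
read_density_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  backend <- j$backend
  models <- lapply(j$models, function(cls) lapply(cls, function(par) {
    if (backend == "kde")
      list(samples = as.numeric(unlist(par$samples)),
           h = as.numeric(par$h))
    else
      list(mean = as.numeric(par$mean), sd = as.numeric(par$sd))
  }))
  priors <- vapply(j$priors, as.numeric, numeric(1))
  structure(list(classes = unlist(j$classes), models = models,
                 priors = priors, backend = backend,
                 n_dim = as.integer(j$n_dim)), class = "class_density")
}
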