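#' Epoched EEG data
#'
#' Container for stimulus-locked EEG epochs: a trials x channels x samples
#' array in microvolts, a time axis in milliseconds with the stimulus at 0 ms,
#' and per-trial condition labels. Time windows throughout the package are
#' half-open `[start, end)` so adjacent windows never double-count a sample.
#'
#' @param data numeric array, trials x channels x samples, microvolts.
#' @param times numeric vector of per-sample latencies in ms, strictly
#'   increasing and uniformly spaced at `1000/fs`.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (length = dim 2).
#' @param condition character vector of per-trial condition labels, typically
#'   `"active"` or `"sham"` (length = dim 1).
#' @param participant,session,target identifiers carried as metadata.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, fs, channels, condition,
                       participant = "P01", session = "S1", target = "target") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("data must be a trials x channels x samples array")
  times <- as.numeric(times)
  if (length(times) != dim(data)[3L])
    stop("length(times) must equal the sample dimension of data")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1000 / fs)) > 1e-6))
    stop("times must be strictly increasing with spacing 1000/fs ms")
  if (length(channels) != dim(data)[2L])
    stop("length(channels) must equal the channel dimension of data")
  condition <- as.character(condition)
  if (length(condition) == 1L) condition <- rep(condition, dim(data)[1L])
  if (length(condition) != dim(data)[1L])
    stop("length(condition) must equal the trial dimension of data")
  structure(list(data = data, times = times, fs = as.numeric(fs),
                 channels = as.character(channels), condition = condition,
                 participant = as.character(participant),
                 session = as.character(session),
                 target = as.character(target)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1L], " trials x ", dim(x$data)[2L],
      " channels x ", dim(x$data)[3L], " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  time [", x$times[1L], ", ",
      x$times[length(x$times)] + 1000 / x$fs, ") ms; conditions: ",
      paste(sprintf("%s=%d", names(table(x$condition)), table(x$condition)),
            collapse = ", "), "\n", sep = "")
  cat("  participant ", x$participant, ", session ", x$session, ", target ",
      x$target, "\n", sep = "")
  invisible(x)
}

#' Evoked (trial-averaged) potential
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param times time axis in ms (stimulus at 0).
#' @param fs sampling rate Hz.
#' @param channels channel labels.
#' @param n_trials number of trials averaged (> 0).
#' @param condition `"active"`, `"sham"` or `"cleaned"` (active minus sham).
#' @param participant,session,target metadata.
#' @return An object of class `eeg_evoked`.
#' @export
eeg_evoked <- function(data, times, fs, channels, n_trials, condition,
                       participant = "P01", session = "S1", target = "target") {
  data <- as.matrix(data)
  if (nrow(data) != length(channels) || ncol(data) != length(times))
    stop("data must be channels x samples matching channels/times")
  if (n_trials <= 0) stop("n_trials must be > 0")
  structure(list(data = data, times = as.numeric(times), fs = as.numeric(fs),
                 channels = as.character(channels),
                 n_trials = as.integer(n_trials),
                 condition = as.character(condition),
                 participant = as.character(participant),
                 session = as.character(session),
                 target = as.character(target)),
            class = "eeg_evoked")
}

#' @export
print.eeg_evoked <- function(x, ...) {
  cat("<eeg_evoked> ", x$condition, ": ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$fs, " Hz (", x$n_trials, " trials)\n",
      sep = "")
  invisible(x)
}

# sample indices of the half-open window [start, end) ms
window_index <- function(times, window) {
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("window must be c(start, end) with end > start")
  which(times >= window[1L] - 1e-9 & times < window[2L] - 1e-9)
}

#' Crop epochs to a time window
#'
#' Keeps samples with latency in the half-open window `[start, end)` ms.
#'
#' @param epochs an [eeg_epochs()].
#' @param window numeric `c(start, end)` in ms.
#' @return Cropped [eeg_epochs()].
#' @export
crop_epochs <- function(epochs, window) {
  idx <- window_index(epochs$times, window)
  if (!length(idx)) stop("window [", window[1L], ", ", window[2L],
                         ") contains no samples")
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$times <- epochs$times[idx]
  epochs
}

#' Write / read epoched data as HDF5
#'
#' The on-disk layout is language-agnostic and documented in the README:
#' datasets `/data` (trials x channels x samples, float64, microvolts),
#' `/times` (ms), `/channels` (labels), `/condition` (per-trial labels), and
#' root attributes `fs`, `participant`, `session`, `target`. A write-read
#' round trip reproduces arrays bit-exactly and all metadata.
#'
#' @param epochs an [eeg_epochs()].
#' @param path HDF5 file path (overwritten if present).
#' @return `write_epochs`: `path` invisibly; `read_epochs`: an
#'   [eeg_epochs()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$times, path, "times")
  rhdf5::h5write(epochs$channels, path, "channels")
  rhdf5::h5write(epochs$condition, path, "condition")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(epochs$fs, fid, "fs")
  rhdf5::h5writeAttribute(epochs$participant, fid, "participant")
  rhdf5::h5writeAttribute(epochs$session, fid, "session")
  rhdf5::h5writeAttribute(epochs$target, fid, "target")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  need <- c("data", "times", "channels", "condition")
  missing <- setdiff(need, ls$name[ls$group == "/"])
  if (length(missing))
    stop("HDF5 file ", path, " lacks dataset(s): ",
         paste0("/", missing, collapse = ", "))
  data <- rhdf5::h5read(path, "data")
  times <- as.numeric(rhdf5::h5read(path, "times"))
  channels <- as.character(rhdf5::h5read(path, "channels"))
  condition <- as.character(rhdf5::h5read(path, "condition"))
  if (length(dim(data)) != 3L || dim(data)[3L] != length(times))
    stop("shape mismatch between /data and /times in ", path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  att <- function(name) {
    v <- rhdf5::h5readAttributes(fid, "/")[[name]]
    if (is.null(v)) stop("missing root attribute '", name, "' in ", path)
    v
  }
  eeg_epochs(data, times, as.numeric(att("fs")), channels, condition,
             participant = as.character(att("participant")),
             session = as.character(att("session")),
             target = as.character(att("target")))
}
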