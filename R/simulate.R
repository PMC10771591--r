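#' Simulation configuration
#'
#' Describes a synthetic sham-controlled TMS-EEG study: multiple participants,
#' repeated sessions, and two stimulation conditions per session. Both
#' conditions contain an identical peripheral evoked potential (PEP; the
#' auditory/somatosensory N100-P200-like complex elicited by the click and
#' scalp sensation, which a well-matched realistic sham reproduces), while only
#' the active condition additionally contains a smaller early (< 90 ms)
#' transcranial evoked potential (TEP) centered near the stimulation target.
#' The generator therefore encodes the design premise that the sham condition
#' saturates the peripheral response, so the active-minus-sham difference
#' equals the TEP in expectation.
#'
#' Components are separable Gaussian space x time templates (see
#' [make_component()]). Amplitude defaults (PEP 8 and 6 microvolts at 100 and
#' 200 ms; TEP 3, 2.5 and 2 microvolts at 30, 45 and 60 ms) are
#' order-of-magnitude choices for scalp evoked potentials, deliberately making
#' the PEP overshadow the TEP. Trial noise emulates the residual background
#' activity left after heavy artifact suppression: spatially correlated,
#' temporally low-passed noise (0.5 microvolts per trial) plus white sensor
#' noise (0.25 microvolts). These defaults are calibrated so that a single
#' default-size session recovers the planted TEP from the active-minus-sham
#' difference with correlation above 0.9 over the 20-300 ms analysis window;
#' raw (uncleaned) trial EEG noise is one to two orders of magnitude larger,
#' and both SDs are ordinary configuration fields.
#'
#' @param n_participants,n_sessions study size (defaults 24 and 3).
#' @param n_trials_active,n_trials_sham trials per condition and session
#'   (default 150 each).
#' @param fs sampling rate Hz (default 1000; 5000 exercises resampling).
#' @param epoch_window epoch limits in ms, half-open (default `c(-1000, 1000)`).
#' @param montage an [eeg_montage()] (default [montage_63()]).
#' @param target label of the electrode over the stimulation target
#'   (default `"P3"`, a left-parietal site).
#' @param pep,tep lists of component specifications; each component is a list
#'   with fields `center` (electrode label), `latency` (ms), `width` (Gaussian
#'   SD, ms), `amplitude` (microvolts, > 0), `sign` (+1/-1) and
#'   `spatial_scale` (Gaussian SD over scalp distance, m). TEP latencies must
#'   lie before 90 ms where the peripheral complex has not yet peaked.
#' @param participant_scale_sd SD of the log-normal per-participant amplitude
#'   scale (default 0.2).
#' @param session_latency_jitter SD (ms) of the per-session latency shift of
#'   each component (default 2).
#' @param session_amp_jitter SD of the log-normal per-session amplitude jitter
#'   (default 0.1).
#' @param noise list: `white_sd`, `corr_sd` (microvolts per trial),
#'   `spatial_scale` (m, channel-covariance Gaussian SD), `temporal_smooth`
#'   (ms, Gaussian SD of the low-pass kernel for the correlated part).
#' @param artifacts list: `enabled`, `decay_amp` (microvolts), `decay_tau`
#'   (ms), `decay_channels` (labels; `NULL` = channels within 3 cm of the
#'   target), `drift_sd` (microvolts, SD of random cubic drift coefficients).
#' @param pep_scale_sham multiplier on the sham-condition PEP (default 1 =
#'   perfectly matched sham; < 1 models residual PEP mismatch).
#' @param shared_templates if `FALSE`, every session draws fresh random
#'   component centers and latencies, destroying inter-session reliability
#'   (used as the negative control for reliability mapping).
#' @param seed master seed; all participant/session substreams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 24, n_sessions = 3,
                       n_trials_active = 150, n_trials_sham = 150,
                       fs = 1000, epoch_window = c(-1000, 1000),
                       montage = montage_63(), target = "P3",
                       pep = NULL, tep = NULL,
                       participant_scale_sd = 0.2,
                       session_latency_jitter = 2,
                       session_amp_jitter = 0.1,
                       noise = list(white_sd = 0.25, corr_sd = 0.5,
                                    spatial_scale = 0.04, temporal_smooth = 5),
                       artifacts = list(enabled = FALSE, decay_amp = 30,
                                        decay_tau = 50, decay_channels = NULL,
                                        drift_sd = 2),
                       pep_scale_sham = 1,
                       shared_templates = TRUE,
                       seed = 1) {
  if (is.null(pep))
    pep <- list(
      list(center = "Cz", latency = 100, width = 18, amplitude = 8,
           sign = -1, spatial_scale = 0.07),
      list(center = "Cz", latency = 200, width = 30, amplitude = 6,
           sign = 1, spatial_scale = 0.08))
  if (is.null(tep))
    tep <- list(
      list(center = target, latency = 30, width = 10, amplitude = 3,
           sign = 1, spatial_scale = 0.05),
      list(center = target, latency = 45, width = 12, amplitude = 2.5,
           sign = -1, spatial_scale = 0.05),
      list(center = target, latency = 60, width = 15, amplitude = 2,
           sign = 1, spatial_scale = 0.055))
  stopifnot(n_trials_active > 0, n_trials_sham > 0,
            inherits(montage, "eeg_montage"))
  noise_def <- list(white_sd = 0.25, corr_sd = 0.5, spatial_scale = 0.04,
                    temporal_smooth = 5)
  noise <- utils::modifyList(noise_def, noise)
  art_def <- list(enabled = FALSE, decay_amp = 30, decay_tau = 50,
                  decay_channels = NULL, drift_sd = 2)
  artifacts <- utils::modifyList(art_def, artifacts)
  if (noise$white_sd < 0 || noise$corr_sd < 0)
    stop("noise SDs must be >= 0")
  for (comp in tep)
    if (comp$latency <= 0 || comp$latency >= epoch_window[2L])
      stop("TEP latencies must lie inside the post-stimulus epoch")
  if (!target %in% montage$labels)
    stop("target electrode '", target, "' not in montage")
  structure(list(n_participants = n_participants, n_sessions = n_sessions,
                 n_trials_active = n_trials_active,
                 n_trials_sham = n_trials_sham, fs = fs,
                 epoch_window = epoch_window, montage = montage,
                 target = target, pep = pep, tep = tep,
                 participant_scale_sd = participant_scale_sd,
                 session_latency_jitter = session_latency_jitter,
                 session_amp_jitter = session_amp_jitter,
                 noise = noise, artifacts = artifacts,
                 pep_scale_sham = pep_scale_sham,
                 shared_templates = shared_templates, seed = seed),
            class = "sim_config")
}

config_times <- function(config) {
  seq(config$epoch_window[1L], config$epoch_window[2L] - 1000 / config$fs,
      by = 1000 / config$fs)
}

#' Separable space x time component template
#'
#' Builds a channels x samples template with a Gaussian time course
#' `exp(-(t - latency)^2 / (2 width^2))` and a Gaussian spatial weight
#' `exp(-d^2 / (2 spatial_scale^2))` over Euclidean scalp distance `d` from the
#' center electrode, scaled so that the peak absolute value at the center
#' electrode equals `amplitude` (with the given `sign`).
#'
#' @param montage an [eeg_montage()].
#' @param times time axis in ms.
#' @param center center electrode label (must exist in the montage).
#' @param latency peak latency ms, inside the time axis.
#' @param width Gaussian temporal SD in ms (> 0).
#' @param amplitude peak amplitude in microvolts (>= 0).
#' @param sign +1 or -1.
#' @param spatial_scale Gaussian spatial SD in meters.
#' @return channels x samples numeric matrix.
#' @export
make_component <- function(montage, times, center, latency, width, amplitude,
                           sign = 1, spatial_scale = 0.05) {
  stopifnot(inherits(montage, "eeg_montage"), width > 0)
  k <- match(center, montage$labels)
  if (is.na(k)) stop("unknown center electrode: ", center)
  if (latency < times[1L] || latency > times[length(times)])
    stop("latency ", latency, " ms outside the epoch")
  d <- sqrt(colSums((t(montage$positions) - montage$positions[k, ])^2))
  spatial <- exp(-d^2 / (2 * spatial_scale^2))
  temporal <- exp(-(times - latency)^2 / (2 * width^2))
  unname(sign * amplitude * outer(spatial, temporal))
}

# sum of component templates, applying a latency shift (ms) and amplitude
# scale to every component
template_from_components <- function(montage, times, comps, lat_shift = 0,
                                     amp_scale = 1) {
  out <- matrix(0, length(montage$labels), length(times))
  for (comp in comps) {
    lat <- min(max(comp$latency + lat_shift, times[1L]), times[length(times)])
    out <- out + make_component(montage, times, comp$center, lat, comp$width,
                                comp$amplitude * amp_scale, comp$sign,
                                comp$spatial_scale)
  }
  out
}

# Gaussian low-pass kernel, normalized to unit output variance for white input
gauss_kernel_unitvar <- function(sd_samples) {
  if (sd_samples <= 0) return(1)
  h <- ceiling(3 * sd_samples)
  k <- exp(-(seq(-h, h))^2 / (2 * sd_samples^2))
  k / sqrt(sum(k^2))
}

# trial noise for one session: array (samples, trials, channels) -- a layout
# in which both the temporal filtering and the channel mixing are single
# contiguous operations. White part plus spatially correlated, temporally
# low-passed part; the correlated part is white noise smoothed in time
# (unit-variance kernel) and mixed across channels through the Cholesky
# factor of a distance-Gaussian channel covariance with unit diagonal.
sim_noise_stc <- function(n_trials, n_ch, n_samp, noise, chol_upper,
                          fs = 1000) {
  out <- array(0, c(n_samp, n_trials, n_ch))
  if (noise$white_sd > 0)
    out <- out + stats::rnorm(n_samp * n_trials * n_ch,
                              sd = noise$white_sd)
  if (noise$corr_sd > 0) {
    sd_samples <- noise$temporal_smooth * fs / 1000
    k <- gauss_kernel_unitvar(sd_samples)
    h <- (length(k) - 1L) %/% 2L
    # columns = independent trial*channel series; filter once, trim padding
    x <- matrix(stats::rnorm((n_samp + 2L * h) * n_trials * n_ch),
                n_samp + 2L * h, n_trials * n_ch)
    if (length(k) > 1L) {
      x <- stats::filter(x, k, sides = 2L)
      x <- x[(h + 1L):(h + n_samp), , drop = FALSE]
    }
    # mix across channels: i.i.d. rows -> y = x %*% R has cov R'R = K
    dim(x) <- c(n_samp * n_trials, n_ch)
    x <- x %*% chol_upper
    dim(x) <- c(n_samp, n_trials, n_ch)
    out <- out + noise$corr_sd * x
  }
  out
}

channel_chol <- function(montage, spatial_scale) {
  d <- as.matrix(stats::dist(montage$positions))
  K <- exp(-d^2 / (2 * spatial_scale^2))
  diag(K) <- diag(K) + 1e-6
  chol(K)
}

# deterministic per-(participant, session) seed table plus participant scales
sim_streams <- function(config) {
  set.seed(config$seed)
  scales <- exp(stats::rnorm(config$n_participants,
                             sd = config$participant_scale_sd))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             config$n_participants * config$n_sessions),
                  config$n_participants, config$n_sessions)
  list(scales = scales, seeds = seeds)
}

# realized per-session component sets and jitters (RNG state must be set by
# the caller to the session substream before calling)
session_templates <- function(config, scale) {
  draw_comps <- function(comps, lat_range) {
    lapply(comps, function(comp) {
      if (!config$shared_templates) {
        # fresh topography, latency and polarity per session: a proper
        # no-reliability null with mean-zero cross-session agreement
        comp$center <- sample(config$montage$labels, 1L)
        comp$latency <- stats::runif(1L, lat_range[1L], lat_range[2L])
        comp$sign <- sample(c(-1, 1), 1L)
      }
      comp
    })
  }
  pep <- draw_comps(config$pep, c(80, 220))
  tep <- draw_comps(config$tep, c(25, 85))
  lat_shift <- stats::rnorm(1L, sd = config$session_latency_jitter)
  amp_scale <- scale * exp(stats::rnorm(1L, sd = config$session_amp_jitter))
  times <- config_times(config)
  list(
    pep = template_from_components(config$montage, times, pep, lat_shift,
                                   amp_scale),
    tep = template_from_components(config$montage, times, tep, lat_shift,
                                   amp_scale),
    jitters = list(lat_shift = lat_shift, amp_scale = amp_scale))
}

#' Generate a synthetic sham-controlled TMS-EEG dataset
#'
#' For every requested participant x session, sham trials are PEP + noise and
#' active trials are PEP + TEP + noise, with the PEP identical across
#' conditions within a session (optionally scaled by `pep_scale_sham` in the
#' sham condition). Per-participant amplitude scales and per-session
#' latency/amplitude jitters are drawn once from the configured distributions.
#' Everything is reproducible from `config$seed`; each participant x session
#' uses its own deterministic substream, so generating a subset yields
#' bit-identical data to generating everything.
#'
#' @param config a [sim_config()].
#' @param participants,sessions integer indices to generate (defaults: all).
#'   A full default-size dataset is large; callers that only need one
#'   participant or session at a time should pass subsets.
#' @return A list with `epochs` (nested list `[[participant]][[session]]` of
#'   [eeg_epochs()] holding both conditions), `ground_truth` (same nesting:
#'   noise-free `pep`/`tep` templates, realized `jitters`, injected artifact
#'   parameters) and `config`.
#' @export
generate_dataset <- function(config,
                             participants = seq_len(config$n_participants),
                             sessions = seq_len(config$n_sessions)) {
  stopifnot(inherits(config, "sim_config"))
  streams <- sim_streams(config)
  times <- config_times(config)
  n_ch <- length(config$montage$labels)
  n_samp <- length(times)
  chol_upper <- if (config$noise$corr_sd > 0)
    channel_chol(config$montage, config$noise$spatial_scale) else NULL
  n_a <- config$n_trials_active
  n_s <- config$n_trials_sham
  epochs <- list()
  truth <- list()
  for (p in participants) {
    pkey <- sprintf("P%02d", p)
    epochs[[pkey]] <- list()
    truth[[pkey]] <- list()
    for (s in sessions) {
      skey <- sprintf("S%d", s)
      set.seed(streams$seeds[p, s])
      tmpl <- session_templates(config, streams$scales[p])
      stc <- sim_noise_stc(n_a + n_s, n_ch, n_samp, config$noise,
                           chol_upper, config$fs)
      active_t <- t(tmpl$pep + tmpl$tep)             # samples x channels
      sham_t <- t(config$pep_scale_sham * tmpl$pep)
      for (ci in seq_len(n_ch)) {
        stc[, seq_len(n_a), ci] <- stc[, seq_len(n_a), ci] + active_t[, ci]
        stc[, n_a + seq_len(n_s), ci] <- stc[, n_a + seq_len(n_s), ci] +
          sham_t[, ci]
      }
      dat <- aperm(stc, c(2L, 3L, 1L))
      ep <- eeg_epochs(dat, times, config$fs, config$montage$labels,
                       c(rep("active", n_a), rep("sham", n_s)),
                       participant = pkey, session = skey,
                       target = config$target)
      art_params <- NULL
      if (isTRUE(config$artifacts$enabled)) {
        inj <- inject_artifacts(ep, config$artifacts, config$montage)
        ep <- inj$epochs
        art_params <- inj$params
      }
      epochs[[pkey]][[skey]] <- ep
      truth[[pkey]][[skey]] <- list(pep = tmpl$pep, tep = tmpl$tep,
                                    jitters = tmpl$jitters,
                                    artifacts = art_params)
    }
  }
  list(epochs = epochs, ground_truth = truth, config = config)
}

#' Generate condition-averaged evoked data directly
#'
#' Shortcut that draws each condition average in one step instead of averaging
#' `n_trials` simulated trials: for Gaussian trial noise the two are
#' distributionally identical (the evoked noise SD is the trial SD divided by
#' `sqrt(n_trials)`), and the planted templates are bit-identical to those of
#' [generate_dataset()] under the same seed. Artifacts are not injected.
#' Intended for studies of the statistical stages (reliability, contrast)
#' where trial-level structure is irrelevant and full trial simulation would
#' dominate runtime.
#'
#' @inheritParams generate_dataset
#' @return A list with `evoked` (nested list `[[participant]][[session]]` of
#'   lists with elements `active`, `sham`, `cleaned` [eeg_evoked()]),
#'   `ground_truth` and `config`.
#' @export
simulate_evoked <- function(config,
                            participants = seq_len(config$n_participants),
                            sessions = seq_len(config$n_sessions)) {
  stopifnot(inherits(config, "sim_config"))
  streams <- sim_streams(config)
  times <- config_times(config)
  n_ch <- length(config$montage$labels)
  n_samp <- length(times)
  chol_upper <- if (config$noise$corr_sd > 0)
    channel_chol(config$montage, config$noise$spatial_scale) else NULL
  evoked <- list()
  truth <- list()
  for (p in participants) {
    pkey <- sprintf("P%02d", p)
    evoked[[pkey]] <- list()
    truth[[pkey]] <- list()
    for (s in sessions) {
      skey <- sprintf("S%d", s)
      set.seed(streams$seeds[p, s])
      tmpl <- session_templates(config, streams$scales[p])
      mk <- function(template, n_trials, condition) {
        nz <- config$noise
        nz$white_sd <- nz$white_sd / sqrt(n_trials)
        nz$corr_sd <- nz$corr_sd / sqrt(n_trials)
        noise <- t(sim_noise_stc(1L, n_ch, n_samp, nz, chol_upper,
                                 config$fs)[, 1L, ])
        eeg_evoked(template + noise, times, config$fs,
                   config$montage$labels, n_trials, condition,
                   participant = pkey, session = skey,
                   target = config$target)
      }
      act <- mk(tmpl$pep + tmpl$tep, config$n_trials_active, "active")
      shm <- mk(config$pep_scale_sham * tmpl$pep, config$n_trials_sham, "sham")
      evoked[[pkey]][[skey]] <- list(active = act, sham = shm,
                                     cleaned = subtract_sham(act, shm))
      truth[[pkey]][[skey]] <- list(pep = tmpl$pep, tep = tmpl$tep,
                                    jitters = tmpl$jitters)
    }
  }
  list(evoked = evoked, ground_truth = truth, config = config)
}

#' Inject decay and drift artifacts
#'
#' Adds a post-stimulus exponential decay `a * exp(-(t - t0) / tau)` for
#' `t >= t0` on a channel subset (emulating residual electrode polarization
#' after the pulse) and a random third-order polynomial drift on every
#' channel (emulating slow potential wander). Returns the modified copy and a
#' record of everything injected.
#'
#' @param epochs an [eeg_epochs()].
#' @param spec artifact list as in [sim_config()] (`decay_amp`, `decay_tau`,
#'   `decay_channels`, `drift_sd`); `t0` optional, default 0 ms.
#' @param montage montage used to resolve `decay_channels = NULL` to channels
#'   within 3 cm of the target electrode (optional otherwise).
#' @return list with `epochs` (modified copy) and `params` (injected decay
#'   channels/amplitude/tau/t0 and the drift coefficient array).
#' @export
inject_artifacts <- function(epochs, spec, montage = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  spec <- utils::modifyList(list(decay_amp = 0, decay_tau = 50,
                                 decay_channels = NULL, drift_sd = 0,
                                 t0 = 0), spec)
  if (spec$decay_tau <= 0) stop("decay tau must be > 0")
  n_tr <- dim(epochs$data)[1L]
  n_ch <- dim(epochs$data)[2L]
  ch_idx <- integer(0)
  if (spec$decay_amp != 0) {
    chans <- spec$decay_channels
    if (is.null(chans)) {
      if (is.null(montage))
        stop("montage required to resolve default decay channels")
      tgt <- montage$positions[match(epochs$target, montage$labels), ]
      chans <- select_channels_near(montage, tgt, radius = 0.03)
    }
    ch_idx <- match(chans, epochs$channels)
    if (anyNA(ch_idx)) stop("unknown decay channel(s)")
    tpost <- epochs$times >= spec$t0
    decay <- spec$decay_amp *
      exp(-(epochs$times[tpost] - spec$t0) / spec$decay_tau)
    for (ci in ch_idx)
      epochs$data[, ci, tpost] <- epochs$data[, ci, tpost] +
        matrix(decay, n_tr, sum(tpost), byrow = TRUE)
  }
  drift_coef <- NULL
  if (spec$drift_sd > 0) {
    x <- 2 * (seq_along(epochs$times) - 1) / (length(epochs$times) - 1) - 1
    basis <- cbind(x, x^2, x^3)
    drift_coef <- array(stats::rnorm(n_tr * n_ch * 3L, sd = spec$drift_sd),
                        c(n_tr, n_ch, 3L))
    for (tr in seq_len(n_tr))
      epochs$data[tr, , ] <- epochs$data[tr, , ] +
        drift_coef[tr, , ] %*% t(basis)
  }
  list(epochs = epochs,
       params = list(decay_channels = epochs$channels[ch_idx],
                     decay_amp = spec$decay_amp, decay_tau = spec$decay_tau,
                     t0 = spec$t0, drift_coef = drift_coef))
}
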