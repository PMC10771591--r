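# internal: view the trials x channels x samples array as a
# (trial*channel) x sample matrix (no copy beyond the reshape)
flat_ts <- function(data) {
  d <- dim(data)
  matrix(data, d[1L] * d[2L], d[3L])
}

unflat_ts <- function(m, d) array(m, d)

#' Preprocessing configuration
#'
#' Bundles the parameters of the sensor-space cleaning chain. Both stimulation
#' conditions are processed jointly with identical parameters so that no
#' processing asymmetry can masquerade as a condition difference. Defaults:
#' baseline window -1000..-5 ms, 3rd-order robust detrend excluding the
#' -20..600 ms evoked interval, re-segmentation to -1000..1000 ms, decay fit
#' over 18..400 ms, pulse excision -4..17 ms, resampling to 1000 Hz.
#'
#' @param baseline_window,detrend_exclude,resegment_window,pulse_window,
#'   decay_fit_window ms windows, half-open.
#' @param detrend_order polynomial order for detrending.
#' @param resample_fs target sampling rate Hz.
#' @param decay_fit logical, run exponential decay removal.
#' @param bad_channels channel labels to replace by spherical-spline
#'   interpolation (replaces manual visual rejection, for reproducibility).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_window = c(-1000, -5),
                              detrend_order = 3,
                              detrend_exclude = c(-20, 600),
                              resegment_window = c(-1000, 1000),
                              decay_fit = TRUE,
                              decay_fit_window = c(18, 400),
                              pulse_window = c(-4, 17),
                              resample_fs = 1000,
                              bad_channels = character(0)) {
  structure(list(baseline_window = baseline_window,
                 detrend_order = detrend_order,
                 detrend_exclude = detrend_exclude,
                 resegment_window = resegment_window,
                 decay_fit = decay_fit,
                 decay_fit_window = decay_fit_window,
                 pulse_window = pulse_window,
                 resample_fs = resample_fs,
                 bad_channels = bad_channels),
            class = "preprocess_config")
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the baseline window from
#' the whole epoch.
#'
#' @param epochs an [eeg_epochs()].
#' @param window baseline window ms, half-open (default `c(-1000, -5)`).
#' @return Corrected [eeg_epochs()].
#' @export
baseline_correct <- function(epochs, window = c(-1000, -5)) {
  idx <- window_index(epochs$times, window)
  if (length(idx) < 2L) stop("baseline window holds fewer than 2 samples")
  m <- flat_ts(epochs$data)
  m <- m - rowMeans(m[, idx, drop = FALSE])
  epochs$data <- unflat_ts(m, dim(epochs$data))
  epochs
}

#' Robust polynomial detrending with evoked-window exclusion
#'
#' Fits, per trial and channel, a polynomial of the given order by least
#' squares to the samples *outside* the exclusion window (so the evoked
#' response cannot drag the trend estimate), evaluates it over the whole
#' epoch, and subtracts it. Robustness comes entirely from the exclusion;
#' the fit itself is ordinary least squares, which keeps the stage
#' deterministic.
#'
#' @param epochs an [eeg_epochs()].
#' @param order polynomial order (default 3).
#' @param exclude ms window excluded from fitting (default `c(-20, 600)`).
#' @return Detrended [eeg_epochs()].
#' @export
robust_detrend <- function(epochs, order = 3, exclude = c(-20, 600)) {
  if (order < 0) stop("order must be >= 0")
  t01 <- 2 * (epochs$times - epochs$times[1L]) /
    (epochs$times[length(epochs$times)] - epochs$times[1L]) - 1
  basis <- outer(t01, 0:order, `^`)
  incl <- setdiff(seq_along(epochs$times), window_index(epochs$times, exclude))
  if (length(incl) < order + 1L)
    stop("not enough samples outside the exclusion window for order ", order)
  Bi <- basis[incl, , drop = FALSE]
  # coefficient operator: y_incl -> coefficients, then evaluate everywhere
  proj <- solve(crossprod(Bi), t(Bi))       # (order+1) x n_incl
  m <- flat_ts(epochs$data)
  coef <- m[, incl, drop = FALSE] %*% t(proj)
  m <- m - coef %*% t(basis)
  epochs$data <- unflat_ts(m, dim(epochs$data))
  epochs
}

# profiled least-squares fit of a*exp(-(t - t0)/tau) + c to the rows of Y
# over times tw: tau on a log grid with parabolic refinement, a and c in
# closed form given tau. Returns a, tau and the relative RMS improvement.
fit_decay_rows <- function(Y, tw, t0, tau_bounds, n_tau) {
  taus <- exp(seq(log(tau_bounds[1L]), log(tau_bounds[2L]),
                  length.out = n_tau))
  E <- exp(-outer(1 / taus, tw - t0))      # n_tau x n_win
  n <- length(tw)
  se <- rowSums(E)
  se2 <- rowSums(E^2)
  sy <- rowSums(Y)
  syy <- rowSums(Y^2)
  cross <- Y %*% t(E)                      # signals x n_tau
  sse_of <- function(a, cc, se_, se2_, cr) {
    syy + a^2 * se2_ + n * cc^2 - 2 * a * cr - 2 * cc * sy + 2 * a * cc * se_
  }
  denom <- n * se2 - se^2
  a <- (n * cross - outer(sy, se)) / matrix(denom, nrow(cross), n_tau,
                                            byrow = TRUE)
  cc <- (sy - a * matrix(se, nrow(a), n_tau, byrow = TRUE)) / n
  sse <- sse_of(a, cc, matrix(se, nrow(a), n_tau, byrow = TRUE),
                matrix(se2, nrow(a), n_tau, byrow = TRUE), cross)
  best <- max.col(-sse, ties.method = "first")
  pick <- cbind(seq_len(nrow(a)), best)
  tau_hat <- taus[best]
  # parabolic refinement on log(tau) where the minimum is interior
  interior <- best > 1L & best < n_tau
  if (any(interior)) {
    i <- which(interior)
    lt <- log(taus)
    s0 <- sse[cbind(i, best[i] - 1L)]
    s1 <- sse[cbind(i, best[i])]
    s2 <- sse[cbind(i, best[i] + 1L)]
    h <- lt[2L] - lt[1L]
    denom2 <- s0 - 2 * s1 + s2
    shift <- ifelse(denom2 > 0, 0.5 * h * (s0 - s2) / denom2, 0)
    shift <- pmin(pmax(shift, -h), h)
    tau_hat[i] <- exp(lt[best[i]] + shift)
  }
  # recompute a, c, sse at the refined tau
  Er <- exp(-outer(1 / tau_hat, tw - t0))
  ser <- rowSums(Er)
  se2r <- rowSums(Er^2)
  crossr <- rowSums(Y * Er)
  a_hat <- (n * crossr - sy * ser) / (n * se2r - ser^2)
  c_hat <- (sy - a_hat * ser) / n
  sse_r <- sse_of(a_hat, c_hat, ser, se2r, crossr)
  worse <- sse_r > sse[pick]
  if (any(worse)) {  # fall back to the grid optimum
    tau_hat[worse] <- taus[best[worse]]
    a_hat[worse] <- a[pick][worse]
    sse_r[worse] <- sse[pick][worse]
  }
  rms0 <- sqrt(pmax(syy, 0) / n)
  rms1 <- sqrt(pmax(sse_r, 0) / n)
  list(a = a_hat, tau = tau_hat,
       improve = ifelse(rms0 > 0, (rms0 - rms1) / rms0, 0))
}

#' Exponential decay-artifact removal
#'
#' Removes residual electrode-polarization decay after the pulse by fitting
#' the model `a * exp(-(t - t0)/tau) + c` over the fit window by least squares
#' (tau profiled over a dense logarithmic grid within `tau_bounds` with
#' parabolic refinement; amplitude and offset in closed form given tau) and
#' subtracting the fitted exponential term for all `t >= t0`. Channels whose
#' fit reduces the RMS over the fit window by less than `min_improve` are left
#' untouched, so decay-free data pass through unchanged.
#'
#' In the default mode (`by = "average"`) one decay per channel is estimated
#' from the trial average pooled across *both* conditions and subtracted
#' identically from every trial: the decay is stimulus-locked and common to
#' active and sham, and a common subtraction cannot introduce a spurious
#' condition difference (evoked energy absorbed by the fit cancels exactly in
#' the active-minus-sham subtraction). `by = "trial"` fits each trial and
#' channel separately; it tracks trial-varying decay but, on data containing
#' evoked responses, the per-condition fits absorb evoked energy
#' asymmetrically and can distort the cleaned difference, so it is not the
#' default.
#'
#' @param epochs an [eeg_epochs()].
#' @param fit_window post-stimulus ms window used for fitting
#'   (default `c(18, 400)`); `t0` is its start.
#' @param tau_bounds tau search range ms (default `c(1, 500)`).
#' @param min_improve minimum relative RMS improvement to accept the fit
#'   (default 0.05).
#' @param n_tau grid resolution (default 120).
#' @param by `"average"` (one fit per channel on the pooled trial average) or
#'   `"trial"` (one fit per trial and channel).
#' @return [eeg_epochs()] with an attribute `decay_fits`: data.frame of
#'   fitted `a`, `tau`, relative improvement and whether the fit was applied.
#' @export
remove_decay <- function(epochs, fit_window = c(18, 400),
                         tau_bounds = c(1, 500), min_improve = 0.05,
                         n_tau = 120, by = c("average", "trial")) {
  by <- match.arg(by)
  if (fit_window[1L] < 0) stop("fit window must be post-stimulus")
  idx <- window_index(epochs$times, fit_window)
  if (length(idx) < 4L) stop("fit window too short")
  t0 <- fit_window[1L]
  tw <- epochs$times[idx]
  d <- dim(epochs$data)
  post <- which(epochs$times >= t0)
  if (by == "average") {
    avg <- colMeans(epochs$data)             # channels x samples
    fit <- fit_decay_rows(avg[, idx, drop = FALSE], tw, t0, tau_bounds, n_tau)
    apply_fit <- is.finite(fit$improve) & fit$improve >= min_improve
    if (any(apply_fit)) {
      decay <- fit$a[apply_fit] *
        exp(-outer(1 / fit$tau[apply_fit], epochs$times[post] - t0))
      for (k in seq_along(which(apply_fit)))
        epochs$data[, which(apply_fit)[k], post] <-
          epochs$data[, which(apply_fit)[k], post] -
          matrix(decay[k, ], d[1L], length(post), byrow = TRUE)
    }
    fits <- data.frame(trial = NA_integer_, channel = epochs$channels,
                       a = fit$a, tau = fit$tau, improve = fit$improve,
                       applied = apply_fit)
  } else {
    m <- flat_ts(epochs$data)
    fit <- fit_decay_rows(m[, idx, drop = FALSE], tw, t0, tau_bounds, n_tau)
    apply_fit <- is.finite(fit$improve) & fit$improve >= min_improve
    if (any(apply_fit)) {
      decay_basis <- exp(-outer(1 / fit$tau[apply_fit],
                                epochs$times[post] - t0))
      m[apply_fit, post] <- m[apply_fit, post] -
        fit$a[apply_fit] * decay_basis
    }
    epochs$data <- unflat_ts(m, d)
    fits <- data.frame(trial = rep(seq_len(d[1L]), d[2L]),
                       channel = rep(epochs$channels, each = d[1L]),
                       a = fit$a, tau = fit$tau, improve = fit$improve,
                       applied = apply_fit)
  }
  attr(epochs, "decay_fits") <- fits
  epochs
}

#' Pulse-artifact excision with cubic interpolation
#'
#' Replaces all samples in the pulse window by the cubic polynomial through
#' two flanking anchor samples on each side; all other samples are untouched.
#'
#' @param epochs an [eeg_epochs()].
#' @param window ms window to excise, half-open (default `c(-4, 17)`).
#' @return [eeg_epochs()] with the window interpolated.
#' @export
excise_pulse <- function(epochs, window = c(-4, 17)) {
  idx <- window_index(epochs$times, window)
  if (!length(idx)) stop("pulse window contains no samples")
  anchors <- c(min(idx) - 2L, min(idx) - 1L, max(idx) + 1L, max(idx) + 2L)
  if (anchors[1L] < 1L || anchors[4L] > length(epochs$times))
    stop("pulse window too close to the epoch edge for cubic anchors")
  ta <- epochs$times[anchors]
  tw <- epochs$times[idx]
  # Lagrange cubic weights: value at tw = sum_j w_j * y(anchor_j)
  W <- sapply(seq_len(4L), function(j) {
    others <- setdiff(seq_len(4L), j)
    apply(outer(tw, ta[others], `-`), 1, prod) /
      prod(ta[j] - ta[others])
  })
  m <- flat_ts(epochs$data)
  m[, idx] <- m[, anchors, drop = FALSE] %*% t(W)
  epochs$data <- unflat_ts(m, dim(epochs$data))
  epochs
}

#' Anti-aliased resampling
#'
#' Downsamples by an integer factor using a zero-phase (symmetric, centrally
#' applied) windowed-sinc anti-alias FIR filter with cutoff at 80 percent of
#' the output Nyquist frequency, keeping `t = 0` as a sample. The filter is
#' normalized to unit DC gain, so constant signals pass exactly.
#'
#' @param epochs an [eeg_epochs()].
#' @param fs_out target rate Hz; `fs / fs_out` must be an integer.
#' @return Resampled [eeg_epochs()].
#' @export
resample_epochs <- function(epochs, fs_out) {
  if (fs_out > epochs$fs) stop("fs_out must be <= the current rate")
  if (abs(epochs$fs %% fs_out) > 1e-9)
    stop("fs_out must divide the current sampling rate (", epochs$fs, " Hz)")
  q <- as.integer(round(epochs$fs / fs_out))
  if (q == 1L) return(epochs)
  k <- as.numeric(signal::fir1(8L * q, 0.8 / q))
  k <- k / sum(k)
  h <- (length(k) - 1L) %/% 2L
  m <- flat_ts(epochs$data)
  # replicate-pad the edges, centered convolution => zero phase
  mp <- cbind(m[, rep(1L, h), drop = FALSE], m,
              m[, rep(ncol(m), h), drop = FALSE])
  filt <- t(stats::filter(t(mp), k, sides = 2L))
  m <- filt[, (h + 1L):(h + ncol(m)), drop = FALSE]
  i0 <- which.min(abs(epochs$times))
  keep <- which((seq_along(epochs$times) - i0) %% q == 0L)
  d <- dim(epochs$data)
  epochs$data <- unflat_ts(m[, keep, drop = FALSE],
                           c(d[1L], d[2L], length(keep)))
  epochs$times <- epochs$times[keep]
  epochs$fs <- fs_out
  epochs
}

#' Average re-referencing
#'
#' Subtracts the instantaneous mean over all channels from every channel, so
#' the channel mean is zero at every trial and time point. Idempotent.
#'
#' @param epochs an [eeg_epochs()].
#' @return Re-referenced [eeg_epochs()].
#' @export
rereference_average <- function(epochs) {
  d <- dim(epochs$data)
  if (d[2L] < 2L) stop("average reference needs >= 2 channels")
  mu <- colMeans(aperm(epochs$data, c(2L, 1L, 3L)))   # trials x samples
  epochs$data <- epochs$data - aperm(array(mu, c(d[1L], d[3L], d[2L])),
                                     c(1L, 3L, 2L))
  epochs
}

# Perrin-style spherical-spline kernel: g(cosine) truncated Legendre series
spline_g <- function(x, order = 4, degree = 7) {
  x <- pmin(pmax(x, -1), 1)
  out <- 0
  p_nm1 <- rep(1, length(x))   # P_0
  p_n <- x                     # P_1
  for (n in seq_len(degree)) {
    out <- out + (2 * n + 1) / (n * (n + 1))^order * p_n
    p_np1 <- ((2 * n + 1) * x * p_n - n * p_nm1) / (n + 1)
    p_nm1 <- p_n
    p_n <- p_np1
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels' time series by spherical-spline interpolation
#' (order-4 spline, Legendre expansion truncated at degree 7, ridge
#' regularization 1e-5) from the remaining channels, with all electrodes
#' projected to the unit sphere. Good channels are untouched; the spline
#' reproduces constant fields exactly.
#'
#' @param epochs an [eeg_epochs()].
#' @param bad character vector of channel labels to interpolate.
#' @param montage an [eeg_montage()] covering all channels.
#' @param order,degree,lambda spline parameters.
#' @return [eeg_epochs()] with bad channels replaced.
#' @export
interpolate_channels_spherical <- function(epochs, bad, montage,
                                           order = 4, degree = 7,
                                           lambda = 1e-5) {
  if (!length(bad)) return(epochs)
  bad_idx <- match(bad, epochs$channels)
  if (anyNA(bad_idx)) stop("bad channel(s) not in data")
  good_idx <- setdiff(seq_along(epochs$channels), bad_idx)
  if (length(good_idx) < 4L)
    stop("spherical interpolation needs >= 4 good channels")
  pos <- montage$positions[match(epochs$channels, montage$labels), ,
                           drop = FALSE]
  if (anyNA(pos)) stop("montage does not cover all data channels")
  u <- pos / sqrt(rowSums(pos^2))
  cosang <- tcrossprod(u)
  Ggg <- spline_g(cosang[good_idx, good_idx], order, degree)
  Gbg <- spline_g(cosang[bad_idx, good_idx, drop = FALSE], order, degree)
  ng <- length(good_idx)
  M <- rbind(cbind(Ggg + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  A <- cbind(Gbg, rep(1, length(bad_idx))) %*% solve(M)
  A <- A[, seq_len(ng), drop = FALSE]      # bad x good linear operator
  d <- dim(epochs$data)
  gm <- matrix(aperm(epochs$data[, good_idx, , drop = FALSE], c(2L, 1L, 3L)),
               ng, d[1L] * d[3L])
  interp <- A %*% gm                        # bad x (trials*samples)
  for (b in seq_along(bad_idx))
    epochs$data[, bad_idx[b], ] <- matrix(interp[b, ], d[1L], d[3L])
  epochs
}

#' Condition average
#'
#' Sample-wise trial mean over all trials with the given condition label.
#'
#' @param epochs an [eeg_epochs()].
#' @param condition condition label to average (`"active"` or `"sham"`).
#' @return An [eeg_evoked()].
#' @export
average_evoked <- function(epochs, condition) {
  sel <- epochs$condition == condition
  if (!any(sel)) stop("no trials with condition '", condition, "'")
  avg <- colMeans(epochs$data[sel, , , drop = FALSE])
  eeg_evoked(avg, epochs$times, epochs$fs, epochs$channels,
             n_trials = sum(sel), condition = condition,
             participant = epochs$participant, session = epochs$session,
             target = epochs$target)
}

#' Active-minus-sham subtraction
#'
#' The matched realistic sham reproduces the peripheral (auditory and
#' somatosensory) co-stimulation of active TMS, so subtracting the sham evoked
#' potential from the active one cancels the PEP and leaves the "cleaned"
#' transcranial evoked potential.
#'
#' @param active,sham [eeg_evoked()] objects on identical channels and times.
#' @return An [eeg_evoked()] with condition `"cleaned"`.
#' @export
subtract_sham <- function(active, sham) {
  stopifnot(inherits(active, "eeg_evoked"), inherits(sham, "eeg_evoked"))
  if (!identical(active$channels, sham$channels) ||
      length(active$times) != length(sham$times) ||
      max(abs(active$times - sham$times)) > 1e-9)
    stop("active and sham evoked must share channels and time axis")
  eeg_evoked(active$data - sham$data, active$times, active$fs,
             active$channels, n_trials = min(active$n_trials, sham$n_trials),
             condition = "cleaned", participant = active$participant,
             session = active$session, target = active$target)
}

#' Run the full preprocessing chain
#'
#' Executes, jointly and identically for both conditions: baseline correction,
#' robust detrending, re-segmentation, decay removal, pulse excision,
#' resampling, average re-referencing, bad-channel interpolation, condition
#' averaging, and active-minus-sham subtraction. The stage order and
#' parameters are recorded in a provenance log.
#'
#' @param epochs an [eeg_epochs()] containing both conditions.
#' @param config a [preprocess_config()].
#' @param montage montage (needed when `bad_channels` is non-empty).
#' @return A list with `active`, `sham`, `cleaned` ([eeg_evoked()]) and `log`
#'   (ordered list of stages with their parameters).
#' @export
run_preprocess <- function(epochs, config = preprocess_config(),
                           montage = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            inherits(config, "preprocess_config"))
  if (!all(c("active", "sham") %in% epochs$condition))
    stop("both conditions must be present")
  log <- list()
  note <- function(stage, ...) log[[length(log) + 1L]] <<- c(list(stage = stage),
                                                             list(...))
  epochs <- baseline_correct(epochs, config$baseline_window)
  note("baseline_correct", window = config$baseline_window)
  epochs <- robust_detrend(epochs, config$detrend_order,
                           config$detrend_exclude)
  note("robust_detrend", order = config$detrend_order,
       exclude = config$detrend_exclude)
  epochs <- crop_epochs(epochs, config$resegment_window)
  note("resegment", window = config$resegment_window)
  if (isTRUE(config$decay_fit)) {
    epochs <- remove_decay(epochs, config$decay_fit_window)
    note("remove_decay", fit_window = config$decay_fit_window)
  }
  epochs <- excise_pulse(epochs, config$pulse_window)
  note("excise_pulse", window = config$pulse_window)
  if (config$resample_fs < epochs$fs) {
    epochs <- resample_epochs(epochs, config$resample_fs)
    note("resample", fs_out = config$resample_fs)
  }
  epochs <- rereference_average(epochs)
  note("rereference_average")
  if (length(config$bad_channels)) {
    if (is.null(montage)) stop("montage required to interpolate bad channels")
    epochs <- interpolate_channels_spherical(epochs, config$bad_channels,
                                             montage)
    note("interpolate_channels_spherical", bad = config$bad_channels)
  }
  active <- average_evoked(epochs, "active")
  sham <- average_evoked(epochs, "sham")
  note("average_evoked")
  cleaned <- subtract_sham(active, sham)
  note("subtract_sham")
  list(active = active, sham = sham, cleaned = cleaned, log = log)
}
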