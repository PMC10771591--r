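#' Global mean field amplitude
#'
#' The GMFA at time `t` is the population standard deviation (divisor `K`) of
#' the voltage across the `K` electrodes:
#' `sqrt(sum_i (V_i(t) - V_mean(t))^2 / K)`. It is invariant to adding a
#' common offset to all channels and scales with `|alpha|` under `alpha * V`.
#'
#' @param evoked an [eeg_evoked()] (or a channels x samples matrix).
#' @return Numeric vector of per-sample GMFA values (class `gmfa_trace`, with
#'   attribute `times` when available).
#' @export
gmfa <- function(evoked) {
  data <- if (inherits(evoked, "eeg_evoked")) evoked$data else as.matrix(evoked)
  k <- nrow(data)
  if (k < 2L) stop("GMFA needs at least 2 channels")
  mu <- colMeans(data)
  vals <- sqrt(colSums((data - matrix(mu, k, ncol(data), byrow = TRUE))^2) / k)
  structure(vals, class = "gmfa_trace",
            times = if (inherits(evoked, "eeg_evoked")) evoked$times else NULL)
}

# local maxima with minimum separation and minimum prominence.
# Prominence of a peak: height above the higher of the two deepest valleys
# separating it from a higher point (or the trace edge). Ties in prominence
# are broken toward earlier latency for determinism.
find_peaks <- function(x, min_separation = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  # plateaus: rising then flat then falling
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- x[seq_len(i)]
    higher_l <- which(left > x[i])
    base_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- x[i:n]
    higher_r <- which(right > x[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    x[i] - max(base_l, base_r)
  }, numeric(1))
  ok <- prom >= min_prominence
  keep <- cand[ok]
  prom <- prom[ok]
  if (!length(keep)) return(integer(0))
  # enforce separation: greedily accept in order of decreasing prominence,
  # earlier latency wins ties
  ord <- order(-prom, keep)
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(keep[i] - sel) >= min_separation))
      sel <- c(sel, keep[i])
  sel <- sort(sel)
  structure(sel, prominence = prom[match(sel, keep)])
}

#' Time-windows-of-interest from GMFA peaks
#'
#' Segments the post-stimulus analysis window (default 20-300 ms) into
#' `n_tois` contiguous, non-overlapping half-open windows anchored at the most
#' prominent GMFA peaks, with window boundaries at the GMFA minima between
#' adjacent peaks. The GMFA used here should be the mean of the sham- and
#' active-condition GMFAs, so that window selection is independent of the
#' condition contrast evaluated inside the windows.
#'
#' Early deflections may be too small to raise the global field; if fewer than
#' `n_tois` peaks are found, missing peaks are taken as extrema (peaks or
#' troughs, i.e. peaks of the absolute value) of `fallback_trace`, typically
#' the evoked potential averaged over electrodes near the stimulation target.
#'
#' @param mean_gmfa a `gmfa_trace` (or numeric vector) with a `times`
#'   attribute, or supply `times`.
#' @param times time axis ms (taken from `mean_gmfa` if absent).
#' @param window analysis window ms (default `c(20, 300)`).
#' @param n_tois number of windows (default 5).
#' @param fallback_trace optional numeric vector on the same time axis.
#' @param min_separation minimum peak separation ms (default 15).
#' @param min_prominence_frac minimum prominence as a fraction of the trace
#'   range inside the window (default 0.05).
#' @return A `toi_set`: data.frame with columns `start`, `end`,
#'   `peak_latency`, `source` (`"gmfa"` or `"fallback"`).
#' @export
detect_tois <- function(mean_gmfa, times = attr(mean_gmfa, "times"),
                        window = c(20, 300), n_tois = 5,
                        fallback_trace = NULL,
                        min_separation = 15, min_prominence_frac = 0.05) {
  x <- as.numeric(mean_gmfa)
  if (is.null(times)) stop("supply times (or a gmfa_trace with times)")
  idx <- window_index(times, window)
  if (length(idx) < 3L) stop("analysis window holds too few samples")
  xi <- x[idx]
  ti <- times[idx]
  dt <- mean(diff(ti))
  sep <- max(1L, round(min_separation / dt))
  peaks <- find_peaks(xi, sep, min_prominence_frac * diff(range(xi)))
  proms <- attr(peaks, "prominence")
  peaks <- as.integer(peaks)
  src <- rep("gmfa", length(peaks))
  if (length(peaks) < n_tois && !is.null(fallback_trace)) {
    fb <- abs(as.numeric(fallback_trace)[idx])
    fpeaks <- find_peaks(fb, sep, min_prominence_frac * diff(range(fb)))
    fprom <- attr(fpeaks, "prominence")
    fpeaks <- as.integer(fpeaks)
    # keep fallback extrema not already represented by a GMFA peak
    new <- !vapply(fpeaks, function(i)
      any(abs(i - peaks) < sep), logical(1))
    fpeaks <- fpeaks[new]
    fprom <- fprom[new]
    if (length(fpeaks)) {
      need <- n_tois - length(peaks)
      take <- order(-fprom)[seq_len(min(need, length(fpeaks)))]
      fpeaks <- fpeaks[take]
      fprom <- fprom[take]
      ord <- order(c(peaks, fpeaks))
      src <- c(src, rep("fallback", length(fpeaks)))[ord]
      # fallback prominences are on the evoked scale; rank them below every
      # retained GMFA peak rather than comparing across scales
      proms <- c(proms, rep(-Inf, length(fpeaks)))[ord]
      peaks <- sort(c(peaks, fpeaks))
    }
  }
  if (!length(peaks))
    stop("no detectable extrema in the GMFA or fallback trace")
  if (length(peaks) > n_tois) {
    # keep the n most prominent, earlier latency breaking ties,
    # preserving latency order in the output
    keep <- sort(order(-proms, peaks)[seq_len(n_tois)])
    src <- src[keep]
    peaks <- peaks[keep]
  }
  lat <- ti[peaks]
  bounds <- numeric(0)
  if (length(peaks) > 1L)
    bounds <- vapply(seq_len(length(peaks) - 1L), function(j) {
      seg <- peaks[j]:peaks[j + 1L]
      ti[seg[which.min(xi[seg])]]
    }, numeric(1))
  starts <- c(window[1L], bounds)
  ends <- c(bounds, window[2L])
  out <- data.frame(start = starts, end = ends, peak_latency = lat,
                    source = src, stringsAsFactors = FALSE)
  class(out) <- c("toi_set", "data.frame")
  out
}

#' @export
print.toi_set <- function(x, ...) {
  cat("<toi_set> ", nrow(x), " windows over [", x$start[1L], ", ",
      x$end[nrow(x)], ") ms\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
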