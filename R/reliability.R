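#' Concordance correlation coefficient
#'
#' Lin's concordance correlation coefficient between two equal-length vectors,
#' `2*cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with moments
#' computed with divisor `n` (the population form of Lin's estimator;
#' `divisor_n = FALSE` switches to `n - 1`). Unlike the Pearson correlation it
#' penalizes mean and variance shifts, so it measures agreement, not just
#' association: it is 1 only for elementwise identity (with nonzero variance)
#' and satisfies `|CCC| <= |r|`.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @param divisor_n use divisor-`n` moments (default `TRUE`).
#' @return A value in `[-1, 1]`, or `NA` when both variances are zero and the
#'   means are equal (agreement undefined for two identical constants).
#' @export
ccc <- function(x, y, divisor_n = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  mx <- mean(x)
  my <- mean(y)
  div <- if (divisor_n) n else n - 1L
  vx <- sum((x - mx)^2) / div
  vy <- sum((y - my)^2) / div
  cxy <- sum((x - mx) * (y - my)) / div
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(NA_real_)
  2 * cxy / denom
}

#' Fisher z-transformation and inverse
#'
#' `fisher_z` is `atanh` with inputs clipped to `1 - 1e-12` in absolute value
#' (so perfect agreement on noise-free data maps to a finite z);
#' `fisher_z_inverse` is `tanh`. The round trip is the identity to 1e-12 for
#' `|c| <= 0.999999`.
#'
#' @param c CCC-like value(s) in `[-1, 1]`.
#' @param z z-space value(s).
#' @return Transformed numeric vector; `NA` passes through.
#' @export
fisher_z <- function(c) {
  if (any(abs(c) > 1 + 1e-9, na.rm = TRUE)) stop("|c| must be <= 1")
  atanh(pmin(pmax(c, -1 + 1e-12), 1 - 1e-12))
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Spatial reliability: per-time-point CCC across electrodes
#'
#' At each time point, the CCC between the two sessions' electrode-amplitude
#' vectors.
#'
#' @param evoked_a,evoked_b [eeg_evoked()] from two sessions, identical
#'   channels and times.
#' @return Numeric vector, one CCC per time point.
#' @export
spatial_ccc <- function(evoked_a, evoked_b) {
  check_matched_evoked(evoked_a, evoked_b)
  vapply(seq_along(evoked_a$times),
         function(j) ccc(evoked_a$data[, j], evoked_b$data[, j]),
         numeric(1))
}

#' Temporal reliability: per-electrode CCC across time, by TOI
#'
#' For every electrode, the CCC between the two sessions' time courses within
#' each time window of interest, plus the whole analysis window as the last
#' column.
#'
#' @param evoked_a,evoked_b [eeg_evoked()] from two sessions.
#' @param tois a `toi_set` from [detect_tois()].
#' @param whole_window ms window for the whole-window column
#'   (default `c(20, 300)`).
#' @return Matrix K x (n_tois + 1); last column named `"whole"`.
#' @export
temporal_ccc <- function(evoked_a, evoked_b, tois, whole_window = c(20, 300)) {
  check_matched_evoked(evoked_a, evoked_b)
  windows <- c(lapply(seq_len(nrow(tois)),
                      function(i) c(tois$start[i], tois$end[i])),
               list(whole_window))
  out <- sapply(windows, function(w) {
    idx <- window_index(evoked_a$times, w)
    if (!length(idx)) stop("TOI [", w[1L], ", ", w[2L],
                           ") outside the evoked time range")
    vapply(seq_len(nrow(evoked_a$data)),
           function(k) ccc(evoked_a$data[k, idx], evoked_b$data[k, idx]),
           numeric(1))
  })
  dimnames(out) <- list(evoked_a$channels,
                        c(sprintf("TOI%d", seq_len(nrow(tois))), "whole"))
  out
}

check_matched_evoked <- function(a, b) {
  if (!identical(a$channels, b$channels) ||
      length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("evoked objects must share channels and time axis")
  invisible(TRUE)
}

#' Reliability maps across participants and session pairs
#'
#' Computes z-transformed CCC maps for every participant and every unordered
#' session pair (S1-S2, S1-S3, S2-S3, ...), in the spatial mode (one element
#' per time point) or the temporal mode (one element per electrode x TOI
#' window).
#'
#' @param evoked nested list `[[participant]][[session]]` of [eeg_evoked()],
#'   all on identical channels/times (e.g. one condition of
#'   [simulate_evoked()] output, or preprocessed real data).
#' @param mode `"spatial"` or `"temporal"`.
#' @param tois `toi_set`, required for the temporal mode.
#' @param whole_window whole-window column for the temporal mode.
#' @return A `ccc_map`: list with `z` (participants x pairs x elements array),
#'   `mode`, `session_pairs`, `element_names`, and for spatial mode `times`.
#' @export
reliability_maps <- function(evoked, mode = c("spatial", "temporal"),
                             tois = NULL, whole_window = c(20, 300)) {
  mode <- match.arg(mode)
  if (mode == "temporal" && is.null(tois))
    stop("temporal mode needs a toi_set")
  participants <- names(evoked)
  sessions <- names(evoked[[1L]])
  if (length(sessions) < 2L) stop("need at least 2 sessions")
  pairs <- utils::combn(sessions, 2L)
  pair_names <- apply(pairs, 2L, paste, collapse = "-")
  one <- function(a, b) {
    if (mode == "spatial") spatial_ccc(a, b)
    else as.numeric(temporal_ccc(a, b, tois, whole_window))
  }
  first <- one(evoked[[1L]][[sessions[1L]]], evoked[[1L]][[sessions[2L]]])
  n_el <- length(first)
  z <- array(NA_real_, c(length(participants), ncol(pairs), n_el),
             dimnames = list(participants, pair_names, NULL))
  for (p in seq_along(participants))
    for (q in seq_len(ncol(pairs)))
      z[p, q, ] <- fisher_z(one(evoked[[p]][[pairs[1L, q]]],
                                evoked[[p]][[pairs[2L, q]]]))
  el_names <- if (mode == "spatial") {
    as.character(evoked[[1L]][[1L]]$times)
  } else {
    ev <- evoked[[1L]][[1L]]
    as.character(outer(ev$channels,
                       c(sprintf("TOI%d", seq_len(nrow(tois))), "whole"),
                       paste, sep = ":"))
  }
  structure(list(z = z, mode = mode, session_pairs = pair_names,
                 element_names = el_names,
                 times = if (mode == "spatial") evoked[[1L]][[1L]]$times),
            class = "ccc_map")
}

#' Group-level reliability
#'
#' Averages z-transformed CCCs element-wise across participants and session
#' pairs (missing values dropped per element), and back-transforms the means
#' for display. Per-pair group traces are also returned, since per-pair
#' averages are what reliability figures typically plot.
#'
#' @param map a `ccc_map` from [reliability_maps()].
#' @return List with `z_mean`, `ccc` (back-transformed), `z_mean_by_pair`
#'   (pairs x elements), `ccc_by_pair`, `participant_z` (participants x
#'   elements, averaged over pairs), and `element_names`.
#' @export
group_reliability <- function(map) {
  stopifnot(inherits(map, "ccc_map"))
  z <- map$z
  z_pair <- apply(z, c(2L, 3L), mean, na.rm = TRUE)
  z_part <- apply(z, c(1L, 3L), mean, na.rm = TRUE)
  z_mean <- colMeans(z_part, na.rm = TRUE)
  all_na <- apply(is.na(z), 3L, all)
  z_mean[all_na] <- NA_real_
  list(z_mean = z_mean, ccc = fisher_z_inverse(z_mean),
       z_mean_by_pair = z_pair, ccc_by_pair = fisher_z_inverse(z_pair),
       participant_z = z_part, element_names = map$element_names)
}

#' One-sample sign-flip permutation t-tests with t-max correction
#'
#' Tests, for every element of a participants x elements matrix, the null
#' hypothesis that the participant values are symmetrically distributed about
#' zero, by one-sample t-statistics whose null distribution is built by random
#' sign flips of each participant's whole map (so the spatial/temporal
#' correlation structure is preserved). Family-wise error is controlled by the
#' t-max method: each permutation contributes its maximum `|t|` over elements,
#' and the corrected two-tailed p-value of an element is
#' `(1 + #(max|t_perm| >= |t_obs|)) / (1 + n_perm)`. When `2^n <= n_perm` the
#' full sign-flip set is enumerated instead of sampled.
#'
#' @param x numeric matrix participants x elements (e.g. `participant_z` from
#'   [group_reliability()]).
#' @param alpha significance level (default 0.05).
#' @param n_perm number of permutations (default 2000).
#' @param seed RNG seed (required for reproducibility).
#' @return A `permutation_result`: list with `t_obs`, `p_corrected`,
#'   `significant` (`p < alpha`), `max_t_dist`, `n_perm`, `alpha`, `seed`.
#' @export
tmax_permutation_test <- function(x, alpha = 0.05, n_perm = 2000, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 participants")
  if (n_perm < 100L) warning("n_perm < 100 gives coarse p-values")
  t_of <- function(m, ss) {
    # column means m and fixed column sums of squares ss; sd from divisor n-1
    v <- (ss - n * m^2) / (n - 1L)
    m / sqrt(pmax(v, 0) / n)
  }
  ss <- colSums(x^2)
  t_obs <- t_of(colMeans(x), ss)
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(signs)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  M <- (signs %*% x) / n                    # permuted column means
  Tm <- M / sqrt(pmax(sweep(-n * M^2, 2, ss, `+`), 0) / (n - 1L) / n)
  max_t <- apply(abs(Tm), 1L, max)
  p <- vapply(abs(t_obs), function(to) (1 + sum(max_t >= to)) / (1 + n_perm),
              numeric(1))
  structure(list(t_obs = t_obs, p_corrected = p, significant = p < alpha,
                 max_t_dist = max_t, n_perm = n_perm, alpha = alpha,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", length(x$t_obs), " elements, ", x$n_perm,
      " permutations, alpha ", x$alpha, "\n  significant: ",
      sum(x$significant), " element(s); min p ", signif(min(x$p_corrected), 3),
      "\n", sep = "")
  invisible(x)
}

#' Interpret a CCC on the Shrout reliability scale
#'
#' 0.00-0.10 "virtually no reliability", 0.11-0.40 "slight", 0.41-0.60 "fair",
#' 0.61-0.80 "moderate", 0.81-1.00 "substantial"; negative values are labeled
#' "virtually no reliability".
#'
#' @param c CCC value(s) in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
classify_shrout <- function(c) {
  if (any(abs(c) > 1 + 1e-9, na.rm = TRUE)) stop("CCC must lie in [-1, 1]")
  labels <- c("virtually no reliability", "slight", "fair", "moderate",
              "substantial")
  idx <- findInterval(c, c(-1, 0.105, 0.405, 0.605, 0.805),
                      rightmost.closed = TRUE)
  out <- labels[idx]
  out[is.na(c)] <- NA_character_
  out
}
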