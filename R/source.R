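#' Random source grid inside the inner skull
#'
#' Draws source positions uniformly inside a ball and fixed orientations
#' uniformly on the unit sphere. A desk-scale stand-in for a cortical mesh:
#' it has no anatomy, but supports the same linear inverse machinery.
#'
#' @param n number of sources (default 200).
#' @param radius ball radius in meters (default 0.075, inside the default
#'   inner-skull shell).
#' @param seed RNG seed (grid is fixed once drawn).
#' @return List of class `source_grid`: `positions` (n x 3, m),
#'   `orientations` (n x 3, unit norm).
#' @export
source_grid <- function(n = 200, radius = 0.075, seed = 42) {
  set.seed(seed)
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- radius * stats::runif(n)^(1 / 3)
  ori <- matrix(stats::rnorm(3 * n), n, 3)
  ori <- ori / sqrt(rowSums(ori^2))
  structure(list(positions = dir * r, orientations = ori),
            class = "source_grid")
}

# Legendre P_n(x) and associated P_n^1(x) = sin(theta) * dP_n/dx (positive
# convention), advanced jointly by stable three-term recurrences.
# Used internally by the spherical forward models.

#' Closed-form homogeneous-sphere scalp potential
#'
#' Exact surface potential of a current dipole inside a homogeneous conducting
#' sphere with an insulating exterior, from the closed-form summation of the
#' Legendre series (no truncation). Serves as the independent oracle for the
#' layered-sphere series solution in its equal-conductivity limit.
#'
#' @param elec_pos electrode positions (m x 3), projected internally to the
#'   sphere surface.
#' @param src_pos length-3 dipole position, strictly inside the sphere.
#' @param src_ori length-3 dipole moment direction.
#' @param radius sphere radius (m).
#' @param conductivity S/m.
#' @return Potential per unit dipole moment (V per A*m) at each electrode
#'   (not average-referenced).
#' @export
sphere_potential_homogeneous <- function(elec_pos, src_pos, src_ori,
                                         radius = 0.1, conductivity = 0.33) {
  elec_pos <- as.matrix(elec_pos)
  e_u <- elec_pos / sqrt(rowSums(elec_pos^2))
  r0 <- sqrt(sum(src_pos^2))
  if (r0 >= radius) stop("source must lie strictly inside the sphere")
  if (r0 == 0) stop("source at the center is not supported")
  r0_u <- src_pos / r0
  t <- r0 / radius
  x <- as.numeric(e_u %*% r0_u)
  s <- sqrt(pmax(1 - x^2, 0))
  h <- sqrt(1 - 2 * t * x + t^2)
  q_r <- sum(src_ori * r0_u)
  # tangential unit vector in the (source, electrode) plane toward electrode
  et <- e_u - outer(x, r0_u)
  et_norm <- sqrt(rowSums(et^2))
  q_t <- ifelse(et_norm > 1e-12,
                as.numeric((et / pmax(et_norm, 1e-12)) %*% src_ori), 0)
  rad_part <- 2 * (x - t) / h^3 + (1 / h - 1) / t
  tan_part <- s * (2 / h^3 + (h + 1) / (h * (1 - t * x + h)))
  (q_r * rad_part + q_t * tan_part) / (4 * pi * conductivity * radius^2)
}

# per-degree surface coefficient of the layered sphere: solves the radial
# boundary-value problem for the homogeneous solution added to the primary
# (infinite-medium) dipole term. Radii pre-scaled so the scalp radius is 1.
layer_surface_coef <- function(n, c_n, radii, cond) {
  r1 <- radii[1L]; r2 <- radii[2L]; r3 <- radii[3L]
  s1 <- cond[1L]; s2 <- cond[2L]; s3 <- cond[3L]
  # unknowns A1, A2, B2, A3, B3
  A <- matrix(0, 5L, 5L)
  b <- numeric(5L)
  np1 <- n + 1
  # continuity of V at r1
  A[1L, ] <- c(r1^n, -r1^n, -r1^(-np1), 0, 0)
  b[1L] <- -c_n * r1^(-np1)
  # continuity of sigma dV/dr at r1
  A[2L, ] <- c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1),
               s2 * np1 * r1^(-n - 2), 0, 0)
  b[2L] <- s1 * np1 * c_n * r1^(-n - 2)
  # continuity of V at r2
  A[3L, ] <- c(0, r2^n, r2^(-np1), -r2^n, -r2^(-np1))
  # continuity of sigma dV/dr at r2
  A[4L, ] <- c(0, s2 * n * r2^(n - 1), -s2 * np1 * r2^(-n - 2),
               -s3 * n * r2^(n - 1), s3 * np1 * r2^(-n - 2))
  # insulating scalp surface at r3
  A[5L, ] <- c(0, 0, 0, n * r3^(n - 1), -np1 * r3^(-n - 2))
  sol <- solve(A, b)
  sol[4L] * r3^n + sol[5L] * r3^(-np1)
}

#' Leadfield for the analytic three-shell spherical head model
#'
#' Scalp potentials from fixed-orientation dipoles inside three concentric
#' spherical shells (brain/inner skull, skull, scalp) with piecewise-constant
#' conductivities, computed from the exact Legendre series solution of the
#' layered-sphere boundary-value problem, truncated when the remaining terms
#' fall below `tol` relative to the running sum. Electrodes are projected
#' radially onto the scalp sphere and the gain matrix is average-referenced,
#' so every gain row sums to zero across channels.
#'
#' @param montage an [eeg_montage()].
#' @param grid a [source_grid()]; all sources must lie strictly inside the
#'   inner shell.
#' @param radii shell outer radii in meters, inner skull / outer skull /
#'   scalp (default `c(0.087, 0.092, 0.100)`, conventional adult values).
#' @param conductivities S/m per compartment (default
#'   `c(0.33, 0.0041, 0.33)`).
#' @param tol relative truncation tolerance (default 1e-8).
#' @param n_max hard cap on series degree.
#' @return A `leadfield`: list with `gain` (sources x channels, V per A*m),
#'   `grid`, `radii`, `conductivities`, `montage`.
#' @export
build_spherical_leadfield <- function(montage, grid,
                                      radii = c(0.087, 0.092, 0.100),
                                      conductivities = c(0.33, 0.0041, 0.33),
                                      tol = 1e-8, n_max = 400L) {
  stopifnot(inherits(montage, "eeg_montage"), inherits(grid, "source_grid"))
  L <- radii[3L]
  rs <- radii / L
  pos <- grid$positions / L
  rr <- sqrt(rowSums(pos^2))
  if (any(rr >= rs[1L]))
    stop("all sources must lie strictly inside the inner shell")
  e_u <- montage$positions / sqrt(rowSums(montage$positions^2))
  n_src <- nrow(pos)
  n_ch <- nrow(e_u)
  gain <- matrix(0, n_src, n_ch)
  for (si in seq_len(n_src)) {
    r0 <- rr[si]
    r0_u <- pos[si, ] / r0
    x <- as.numeric(e_u %*% r0_u)
    s <- sqrt(pmax(1 - x^2, 0))
    q <- grid$orientations[si, ]
    q_r <- sum(q * r0_u)
    et <- e_u - outer(x, r0_u)
    et_norm <- sqrt(rowSums(et^2))
    q_t <- ifelse(et_norm > 1e-12,
                  as.numeric((et / pmax(et_norm, 1e-12)) %*% q), 0)
    # Legendre recurrences
    p_nm1 <- rep(1, n_ch)        # P_0
    p_n <- x                     # P_1
    a_nm1 <- rep(0, n_ch)        # P_0^1
    a_n <- s                     # P_1^1
    acc <- numeric(n_ch)
    for (n in seq_len(n_max)) {
      c_n <- r0^(n - 1) / (4 * pi * conductivities[1L])
      S_n <- layer_surface_coef(n, c_n, rs, conductivities)
      term <- S_n * (n * q_r * p_n + q_t * a_n)
      acc <- acc + term
      if (n >= 10L && max(abs(term)) < tol * max(abs(acc), 1e-300)) break
      p_np1 <- ((2 * n + 1) * x * p_n - n * p_nm1) / (n + 1)
      a_np1 <- if (n == 1L) 3 * x * s else
        ((2 * n + 1) * x * a_n - (n + 1) * a_nm1) / n
      p_nm1 <- p_n; p_n <- p_np1
      a_nm1 <- a_n; a_n <- a_np1
    }
    gain[si, ] <- acc / L^2
  }
  gain <- gain - rowMeans(gain)
  structure(list(gain = gain, grid = grid, radii = radii,
                 conductivities = conductivities, montage = montage),
            class = "leadfield")
}

#' Distance-Gaussian source covariance
#'
#' Prior source covariance in which nearby sources are more correlated than
#' distant ones: `C_ij = exp(-d_ij^2 / (2 lambda^2))`, with a 1e-10 diagonal
#' jitter to keep the matrix numerically positive semi-definite.
#'
#' @param positions source positions (n x 3, m) or a [source_grid()].
#' @param lambda correlation length scale in meters (default 0.01).
#' @return n x n covariance matrix.
#' @export
source_covariance <- function(positions, lambda = 0.01) {
  if (inherits(positions, "source_grid")) positions <- positions$positions
  if (lambda <= 0) stop("lambda must be > 0")
  d <- as.matrix(stats::dist(positions))
  C <- exp(-d^2 / (2 * lambda^2))
  diag(C) <- diag(C) + 1e-10
  C
}

#' Minimum-norm inverse estimate
#'
#' Linear l2-minimum-norm inverse with a distance-Gaussian source-covariance
#' prior and Tikhonov regularization:
#' `W = C G' (G C G' + lambda2 N)^-1`, with
#' `lambda2 = trace(G C G') / (trace(N) * snr^2)`. The noise covariance `N`
#' is estimated from the evoked baseline samples and shrunk toward its
#' diagonal by a loading factor of 0.1; if the baseline is exactly silent
#' (noise-free simulations), the identity is used instead. The estimate is
#' linear in the data.
#'
#' @param evoked an [eeg_evoked()] on the leadfield's channels.
#' @param lf a `leadfield` from [build_spherical_leadfield()].
#' @param C source covariance (default: [source_covariance()] of the grid).
#' @param snr assumed amplitude signal-to-noise ratio (default 3).
#' @param baseline_window ms window for noise-covariance estimation
#'   (default `c(-600, -100)`).
#' @param noise_loading diagonal shrinkage factor (default 0.1).
#' @return A `source_estimate`: list with `data` (sources x samples, current
#'   density), `times`, `grid`, `normalized = FALSE`, `lambda2`.
#' @export
mne_inverse <- function(evoked, lf, C = NULL, snr = 3,
                        baseline_window = c(-600, -100),
                        noise_loading = 0.1) {
  stopifnot(inherits(evoked, "eeg_evoked"), inherits(lf, "leadfield"))
  if (!identical(evoked$channels, lf$montage$labels))
    stop("evoked channels must match the leadfield montage")
  if (is.null(C)) C <- source_covariance(lf$grid)
  G <- t(lf$gain)                             # channels x sources
  GC <- G %*% C
  gram <- GC %*% t(G)                         # G C G'
  idx <- window_index(evoked$times, baseline_window)
  if (length(idx) < 2L) stop("baseline window holds fewer than 2 samples")
  N <- stats::cov(t(evoked$data[, idx, drop = FALSE]))
  if (sum(diag(N)) <= 0) {
    N <- diag(nrow(G))
  } else {
    N <- (1 - noise_loading) * N + noise_loading * diag(diag(N))
  }
  lambda2 <- sum(diag(gram)) / (sum(diag(N)) * snr^2)
  K <- gram + lambda2 * N
  W <- t(GC) %*% solve(K)
  if (!all(is.finite(W))) stop("singular regularized gram matrix")
  structure(list(data = W %*% evoked$data, times = evoked$times,
                 grid = lf$grid, normalized = FALSE, lambda2 = lambda2,
                 baseline_window = NULL),
            class = "source_estimate")
}

#' Baseline z-normalization of a source estimate
#'
#' Per source: subtract the baseline mean and divide by the baseline standard
#' deviation, so post-stimulus current density is expressed in units of
#' baseline variability. Sources with zero baseline variability are set to
#' `NA` and reported in a warning.
#'
#' @param est a `source_estimate`.
#' @param window baseline window ms (default `c(-600, -100)`).
#' @return The z-normalized `source_estimate` (`normalized = TRUE`).
#' @export
znorm_baseline <- function(est, window = c(-600, -100)) {
  stopifnot(inherits(est, "source_estimate"))
  idx <- window_index(est$times, window)
  if (length(idx) < 2L) stop("baseline window holds fewer than 2 samples")
  mu <- rowMeans(est$data[, idx, drop = FALSE])
  sd <- apply(est$data[, idx, drop = FALSE], 1L, stats::sd)
  bad <- sd <= 0 | !is.finite(sd)
  if (any(bad))
    warning(sum(bad), " source(s) with zero baseline variability set to NA")
  sd[bad] <- NA_real_
  est$data <- (est$data - mu) / sd
  est$normalized <- TRUE
  est$baseline_window <- window
  est
}

#' ROI-average source time series
#'
#' @param est a `source_estimate`.
#' @param rois named list of source index vectors.
#' @return Matrix, one row per ROI.
#' @export
roi_timeseries <- function(est, rois) {
  stopifnot(inherits(est, "source_estimate"), is.list(rois))
  if (is.null(names(rois)) || any(!nzchar(names(rois))))
    stop("rois must be a named list")
  out <- t(vapply(rois, function(ix) {
    if (!length(ix)) stop("empty ROI")
    colMeans(est$data[ix, , drop = FALSE])
  }, numeric(ncol(est$data))))
  rownames(out) <- names(rois)
  out
}
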