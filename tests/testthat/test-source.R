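lf_cache <- new.env()
get_leadfield <- function() {
  if (is.null(lf_cache$lf)) {
    lf_cache$grid <- source_grid(200, seed = 42)
    lf_cache$lf <- build_spherical_leadfield(fixture_montage, lf_cache$grid)
  }
  lf_cache$lf
}

test_that("gain rows are average-referenced and attenuate with depth", {
  lf <- get_leadfield()
  expect_lt(max(abs(rowSums(lf$gain))), 1e-10)
  one_src <- function(pos) build_spherical_leadfield(
    fixture_montage,
    structure(list(positions = matrix(pos, 1),
                   orientations = matrix(c(0, 1, 0), 1)),
              class = "source_grid"))
  shallow <- one_src(c(0.08, 0, 0))
  deep <- one_src(c(0.03, 0, 0))
  expect_gt(sqrt(sum(shallow$gain^2)), sqrt(sum(deep$gain^2)))
  expect_error(one_src(c(0.09, 0, 0)), "inner shell")
})

test_that("equal-conductivity shells match the homogeneous closed form", {
  grid <- source_grid(20, radius = 0.075, seed = 7)
  lf <- build_spherical_leadfield(fixture_montage, grid,
                                  conductivities = c(0.33, 0.33, 0.33))
  for (i in 1:20) {
    v <- sphere_potential_homogeneous(fixture_montage$positions,
                                      grid$positions[i, ],
                                      grid$orientations[i, ],
                                      radius = 0.1, conductivity = 0.33)
    v <- v - mean(v)
    rel <- sqrt(mean((lf$gain[i, ] - v)^2)) / sqrt(mean(v^2))
    expect_lt(rel, 0.001)
  }
})

test_that("source covariance is a unit-diagonal distance Gaussian", {
  set.seed(30)
  pos <- matrix(rnorm(50 * 3, sd = 0.03), 50)
  C <- source_covariance(pos, lambda = 0.01)
  expect_equal(unname(diag(C)), rep(1 + 1e-10, 50))
  i <- 1; j <- 2
  d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
  expect_equal(C[i, j], exp(-d^2 / (2 * 0.01^2)) , tolerance = 1e-12)
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  # two sources lambda*sqrt(2) apart correlate at exp(-1)
  p2 <- rbind(c(0, 0, 0), c(0.01 * sqrt(2), 0, 0))
  expect_equal(source_covariance(p2, 0.01)[1, 2], exp(-1), tolerance = 1e-9)
})

test_that("the minimum-norm inverse is linear and recovers a point source", {
  lf <- get_leadfield()
  grid <- lf_cache$grid
  times <- seq(-700, 299)
  # cortically plausible test source: nearest grid point to a location
  # 0.065 m along the P3 direction
  p3 <- fixture_montage$positions["P3", ]
  ref <- p3 / sqrt(sum(p3^2)) * 0.065
  src <- which.min(colSums((t(grid$positions) - ref)^2))
  tc <- 10 * exp(-(times - 60)^2 / (2 * 15^2))
  ev <- eeg_evoked(outer(lf$gain[src, ], tc), times, 1000,
                   fixture_montage$labels, 100, "cleaned")
  est <- mne_inverse(ev, lf)
  # linearity
  zero <- ev; zero$data[] <- 0
  expect_true(all(mne_inverse(zero, lf)$data == 0))
  ev2 <- ev; ev2$data <- 2 * ev2$data
  expect_equal(mne_inverse(ev2, lf)$data, 2 * est$data, tolerance = 1e-9)
  # localization at the source or one of its 6 nearest grid neighbors
  act <- rowMeans(abs(est$data[, times >= 20 & times < 120]))
  top <- which.max(act)
  nn <- order(colSums((t(grid$positions) - grid$positions[src, ])^2))[2:7]
  expect_true(top == src || top %in% nn)
})

test_that("the inverse is continuous in the regularization strength", {
  lf <- get_leadfield()
  grid <- lf_cache$grid
  times <- seq(-700, 299)
  set.seed(31)
  ev <- eeg_evoked(outer(lf$gain[10, ], exp(-(times - 50)^2 / 200)) +
                     matrix(rnorm(63 * 1000, sd = 1e-4), 63),
                   times, 1000, fixture_montage$labels, 100, "cleaned")
  C <- source_covariance(grid)
  base <- mne_inverse(ev, lf, C, snr = 3)
  for (f in c(sqrt(1.01), 1 / sqrt(1.01))) {
    # snr enters as lambda2 ~ 1/snr^2: scale snr to perturb lambda2 by 1%
    pert <- mne_inverse(ev, lf, C, snr = 3 / f)
    expect_equal(pert$lambda2 / base$lambda2, f^2, tolerance = 1e-9)
    rel <- sqrt(mean((pert$data - base$data)^2)) / sqrt(mean(base$data^2))
    expect_lt(rel, 0.05)
  }
})

test_that("baseline z-normalization standardizes and is scale-free", {
  lf <- get_leadfield()
  times <- seq(-700, 299)
  set.seed(32)
  ev <- eeg_evoked(matrix(rnorm(63 * 1000, sd = 0.5), 63), times, 1000,
                   fixture_montage$labels, 100, "cleaned")
  est <- mne_inverse(ev, lf)
  z <- znorm_baseline(est)
  idx <- times >= -600 & times < -100
  expect_lt(max(abs(rowMeans(z$data[, idx]))), 1e-10)
  expect_equal(unname(apply(z$data[, idx], 1, sd)), rep(1, 200),
               tolerance = 1e-10)
  est2 <- est; est2$data <- 2 * est2$data
  expect_equal(znorm_baseline(est2)$data, z$data, tolerance = 1e-9)
  # constant traces are flagged, not silently standardized
  estc <- est; estc$data[5, ] <- 3
  expect_warning(zc <- znorm_baseline(estc), "zero baseline")
  expect_true(all(is.na(zc$data[5, ])))
})

test_that("ROI averaging picks out the active region", {
  lf <- get_leadfield()
  grid <- lf_cache$grid
  times <- seq(-700, 299)
  est <- structure(list(data = matrix(rnorm(200 * 1000, sd = 0.1), 200),
                        times = times, grid = grid, normalized = FALSE),
                   class = "source_estimate")
  expect_equal(roi_timeseries(est, list(one = 7))["one", ], est$data[7, ])
  expect_error(roi_timeseries(est, list(empty = integer(0))), "empty")
  expect_error(roi_timeseries(est, list(1:3)), "named")
  # planted source: its ROI dominates a distant ROI across noise draws
  p3 <- fixture_montage$positions["P3", ]
  ref <- p3 / sqrt(sum(p3^2)) * 0.065
  src <- which.min(colSums((t(grid$positions) - ref)^2))
  roiA <- which(colSums((t(grid$positions) - ref)^2) < 0.03^2)
  roiB <- order(colSums((t(grid$positions) - ref)^2),
                decreasing = TRUE)[1:8]
  tc <- 10 * exp(-(times - 60)^2 / (2 * 15^2))
  sens <- outer(lf$gain[src, ], tc)
  sig_rms <- sqrt(mean(sens^2))
  set.seed(33)
  hits <- 0
  for (r in 1:25) {
    ev <- eeg_evoked(sens + matrix(rnorm(63 * 1000, sd = sig_rms / 3), 63),
                     times, 1000, fixture_montage$labels, 100, "cleaned")
    z <- znorm_baseline(mne_inverse(ev, lf))
    rt <- roi_timeseries(z, list(A = roiA, B = roiB))
    pk <- apply(abs(rt[, times >= 20 & times < 120]), 1, max)
    hits <- hits + (pk["A"] > pk["B"])
  }
  expect_gte(hits, 24)
})
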