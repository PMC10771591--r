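test_that("baseline correction zeroes the baseline and preserves shape", {
  ep <- quick_epochs(array(5, c(1, 2, 300)), t_start = -200)
  out <- baseline_correct(ep, c(-200, -5))
  expect_true(all(out$data == 0))
  # bump riding on an offset is preserved, shifted
  bump <- exp(-(ep$times - 50)^2 / 50)
  ep$data[1, 1, ] <- 2 + bump
  out <- baseline_correct(ep, c(-200, -5))
  expect_equal(out$data[1, 1, ], bump, tolerance = 1e-10)
  set.seed(1)
  epr <- quick_epochs(array(rnorm(4 * 3 * 300), c(4, 3, 300)),
                      t_start = -200)
  outr <- baseline_correct(epr, c(-200, -5))
  idx <- outr$times >= -200 & outr$times < -5
  means <- apply(outr$data[, , idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(means)), 1e-10)
  expect_error(baseline_correct(ep, c(500, 600)), "window")
})

test_that("robust detrending removes its model class exactly", {
  ep <- quick_epochs(array(0, c(1, 1, 2000)), t_start = -1000)
  x <- seq(-1, 1, length.out = 2000)
  ep$data[1, 1, ] <- 7 * x^3 - 3 * x^2 + 2 * x - 1
  out <- robust_detrend(ep)
  expect_lt(sqrt(mean(out$data^2)), 1e-6 * sqrt(mean(ep$data^2)))
  zero <- quick_epochs(array(0, c(1, 1, 2000)), t_start = -1000)
  expect_true(all(robust_detrend(zero)$data == 0))
  expect_error(robust_detrend(ep, order = -1), "order")
})

test_that("detrending spares an evoked bump inside the exclusion window", {
  ep <- quick_epochs(array(0, c(1, 1, 2000)), t_start = -1000)
  x <- seq(-1, 1, length.out = 2000)
  bump <- 5 * exp(-(ep$times - 100)^2 / (2 * 15^2))
  ep$data[1, 1, ] <- 4 * x^3 - 2 * x + bump
  out <- robust_detrend(ep, 3, c(-20, 600))
  peak_err <- abs(max(out$data[1, 1, ]) - 5)
  expect_lt(peak_err, 0.05)
})

test_that("decay removal round-trips an injected exponential", {
  ep <- quick_epochs(array(0, c(2, 3, 2000)), t_start = -1000,
                     channels = c("Cz", "C3", "C4"))
  ep$condition <- c("active", "sham")
  inj <- inject_artifacts(ep, list(decay_amp = 50, decay_tau = 20,
                                   decay_channels = "Cz", drift_sd = 0))
  out <- remove_decay(inj$epochs)
  win <- ep$times >= 18 & ep$times < 400
  pre <- sqrt(mean(inj$epochs$data[1, 1, win]^2))
  post <- sqrt(mean(out$data[1, 1, win]^2))
  expect_lt(post / pre, 0.02)
  # decay-free channels untouched (guard clause)
  expect_identical(out$data[, 2:3, ], inj$epochs$data[, 2:3, ])
  fits <- attr(out, "decay_fits")
  expect_false(any(fits$applied[fits$channel != "Cz"]))
})

test_that("decay time constant is recovered within 10% at high SNR", {
  set.seed(11)
  taus <- c(10, 30, 80)
  for (tau in taus) {
    ep <- quick_epochs(array(rnorm(6 * 1 * 2000, sd = 2), c(6, 1, 2000)),
                       t_start = -1000, channels = "Cz")
    ep$condition <- rep(c("active", "sham"), 3)
    inj <- inject_artifacts(ep, list(decay_amp = 60, decay_tau = tau,
                                     decay_channels = "Cz", drift_sd = 0))
    out <- remove_decay(inj$epochs)
    fit <- attr(out, "decay_fits")
    expect_lt(abs(fit$tau[1] - tau) / tau, 0.10)
  }
})

test_that("per-trial decay mode matches the average mode on pure decay", {
  ep <- quick_epochs(array(0, c(2, 1, 2000)), t_start = -1000,
                     channels = "Cz")
  inj <- inject_artifacts(ep, list(decay_amp = 40, decay_tau = 35,
                                   decay_channels = "Cz", drift_sd = 0))
  win <- ep$times >= 18 & ep$times < 400
  for (mode in c("average", "trial")) {
    out <- remove_decay(inj$epochs, by = mode)
    expect_lt(sqrt(mean(out$data[1, 1, win]^2)),
              0.02 * sqrt(mean(inj$epochs$data[1, 1, win]^2)))
  }
})

test_that("pulse excision interpolates only inside the window", {
  # a globally linear trace is reproduced exactly by the cubic
  ep <- quick_epochs(array(0, c(1, 1, 400)), t_start = -200)
  ep$data[1, 1, ] <- 0.05 * ep$times + 3
  out <- excise_pulse(ep)
  expect_equal(out$data, ep$data, tolerance = 1e-12)
  # a spike inside the window disappears on a constant trace
  ep$data[1, 1, ] <- 1
  ep$data[1, 1, ep$times == 5] <- 1000
  out <- excise_pulse(ep)
  expect_equal(out$data[1, 1, ], rep(1, 400), tolerance = 1e-9)
  # smooth cosine: interpolation error under 5% of amplitude
  ep$data[1, 1, ] <- cos(2 * pi * 8 * ep$times / 1000)
  out <- excise_pulse(ep)
  win <- ep$times >= -4 & ep$times < 17
  expect_lt(max(abs(out$data[1, 1, win] - ep$data[1, 1, win])), 0.05)
  # samples outside the window are bit-identical
  expect_identical(out$data[1, 1, !win], ep$data[1, 1, !win])
  expect_error(excise_pulse(ep, c(-200, -180)), "edge")
})

test_that("resampling preserves DC, amplitude and the t = 0 sample", {
  t5 <- seq(-1000, 999.8, by = 0.2)
  dc <- quick_epochs(array(4, c(1, 2, length(t5))), fs = 5000,
                     t_start = -1000)
  out <- resample_epochs(dc, 1000)
  expect_equal(out$data, array(4, c(1, 2, 2000)), tolerance = 1e-9)
  expect_equal(out$fs, 1000)
  expect_true(any(out$times == 0))
  sine <- sin(2 * pi * 10 * t5 / 1000)
  eps <- quick_epochs(array(rep(sine, each = 2), c(1, 2, length(t5))),
                      fs = 5000, t_start = -1000)
  outs <- resample_epochs(eps, 1000)
  expect_equal(dim(outs$data)[3L], 2000L)
  expect_lt(abs(max(outs$data[1, 1, ]) - 1), 0.01)
  expect_error(resample_epochs(dc, 1500), "divide")
})

test_that("average reference zeroes channel means and is idempotent", {
  ep <- quick_epochs(array(c(3, 1), c(1, 2, 1)))
  out <- rereference_average(ep)
  expect_equal(as.numeric(out$data), c(1, -1))
  set.seed(2)
  epr <- quick_epochs(array(rnorm(5 * 8 * 100), c(5, 8, 100)))
  o1 <- rereference_average(epr)
  expect_lt(max(abs(apply(o1$data, c(1, 3), mean))), 1e-10)
  o2 <- rereference_average(o1)
  expect_equal(o2$data, o1$data, tolerance = 1e-12)
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  # constant field reproduced at the interpolated channel
  ep <- quick_epochs(array(2.5, c(1, 63, 10)), channels = fixture_montage$labels)
  out <- interpolate_channels_spherical(ep, "CP1", fixture_montage)
  expect_equal(out$data[1, match("CP1", ep$channels), ],
               rep(2.5, 10), tolerance = 1e-6)
  # leave-one-out on a smooth planted topography, time-varying
  times <- seq(0, 99, 1)
  tmpl <- make_component(fixture_montage, times, "C3", 50, 20, 5, 1, 0.06) +
    make_component(fixture_montage, times, "Pz", 70, 25, 3, -1, 0.07)
  ep2 <- quick_epochs(array(tmpl, c(1, 63, 100)),
                      channels = fixture_montage$labels)
  for (bad in c("CP1", "FC2", "POz")) {
    bi <- match(bad, ep2$channels)
    out2 <- interpolate_channels_spherical(ep2, bad, fixture_montage)
    expect_gt(cor(out2$data[1, bi, ], tmpl[bi, ]), 0.95)
    good <- setdiff(seq_len(63), bi)
    expect_identical(out2$data[1, good, ], ep2$data[1, good, ])
  }
  expect_error(interpolate_channels_spherical(ep, ep$channels[1:60],
                                              fixture_montage), "4 good")
})

test_that("condition averaging and sham subtraction obey their contracts", {
  set.seed(3)
  dat <- array(rnorm(4 * 2 * 10), c(4, 2, 10))
  ep <- quick_epochs(dat)
  ep$condition <- c("active", "active", "sham", "sham")
  av <- average_evoked(ep, "active")
  expect_equal(av$data, colMeans(dat[1:2, , , drop = FALSE]))
  expect_equal(av$n_trials, 2L)
  expect_error(average_evoked(ep, "nope"), "no trials")
  # trials x and -x average to zero
  arr2 <- array(0, c(2, 2, 10))
  arr2[1, , ] <- dat[1, , ]
  arr2[2, , ] <- -dat[1, , ]
  ep2 <- quick_epochs(arr2)
  expect_equal(average_evoked(ep2, "active")$data,
               matrix(0, 2, 10), tolerance = 1e-12)
  sh <- average_evoked(ep, "sham")
  cl <- subtract_sham(av, sh)
  expect_equal(cl$data, av$data - sh$data)
  expect_equal(cl$condition, "cleaned")
  expect_true(all(subtract_sham(av, av)$data == 0))
  bad <- av; bad$channels <- rev(bad$channels)
  expect_error(subtract_sham(av, bad), "share")
})

test_that("the full chain runs in the documented order", {
  cfg <- sim_config(n_participants = 1, n_sessions = 1, n_trials_active = 3,
                    n_trials_sham = 3, montage = mini_montage(),
                    target = "Cz", seed = 4)
  d <- generate_dataset(cfg)
  pp <- run_preprocess(d$epochs$P01$S1, preprocess_config(),
                       montage = mini_montage())
  stages <- vapply(pp$log, `[[`, "", "stage")
  expect_equal(stages, c("baseline_correct", "robust_detrend", "resegment",
                         "remove_decay", "excise_pulse",
                         "rereference_average", "average_evoked",
                         "subtract_sham"))
  expect_s3_class(pp$cleaned, "eeg_evoked")
})

test_that("joint and separate condition processing agree without
           data-adaptive stages", {
  cfg <- sim_config(n_participants = 1, n_sessions = 1, n_trials_active = 3,
                    n_trials_sham = 3, montage = mini_montage(),
                    target = "Cz", seed = 6)
  ep <- generate_dataset(cfg)$epochs$P01$S1
  pc <- preprocess_config(decay_fit = FALSE)
  joint <- run_preprocess(ep, pc)
  # manually run the same deterministic chain on the active trials only
  sel <- ep$condition == "active"
  epa <- eeg_epochs(ep$data[sel, , , drop = FALSE], ep$times, ep$fs,
                    ep$channels, ep$condition[sel])
  epa <- baseline_correct(epa, pc$baseline_window)
  epa <- robust_detrend(epa, pc$detrend_order, pc$detrend_exclude)
  epa <- crop_epochs(epa, pc$resegment_window)
  epa <- excise_pulse(epa, pc$pulse_window)
  epa <- rereference_average(epa)
  expect_equal(average_evoked(epa, "active")$data, joint$active$data,
               tolerance = 1e-12)
})
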