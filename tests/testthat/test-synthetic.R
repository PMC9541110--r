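test_that("ground-truth waveforms have one peak per repetition", {
  prof <- exercise_profile("biceps_curl", n_sets = 1, n_reps = 1,
                           rep_duration = 2, rest_duration = 0,
                           amplitude_jitter = 0)
  truth <- generate_ground_truth(prof, the_model, seed = 1, rate = 100)
  x <- truth$elbow_flexion
  imax <- which.max(x)
  # single interior maximum at mid-rep
  expect_equal(sum(diff(sign(diff(x))) == -2), 1)
  expect_equal(truth$time[imax], prof$lead_in + 1, tolerance = 0.02)

  fly <- exercise_profile("lateral_fly", n_sets = 1, n_reps = 5,
                          rep_duration = 2, rest_duration = 0)
  t5 <- generate_ground_truth(fly, the_model, seed = 2, rate = 100)
  e <- t5$shoulder_elv
  peaks <- which(diff(sign(diff(e))) == -2) + 1
  expect_equal(sum(e[peaks] > 80), 5)
})

test_that("ground truth is deterministic per seed and validates amplitude", {
  prof <- small_profile("lateral_fly")
  a <- generate_ground_truth(prof, the_model, seed = 42, rate = 50)
  b <- generate_ground_truth(prof, the_model, seed = 42, rate = 50)
  expect_identical(a, b)
  c <- generate_ground_truth(prof, the_model, seed = 43, rate = 50)
  expect_false(identical(a$shoulder_elv, c$shoulder_elv))

  bad <- exercise_profile("lateral_fly", amplitude = c(shoulder_elv = 400))
  expect_error(generate_ground_truth(bad, the_model, seed = 1),
               "coordinate range")
})

test_that("marker rendering is an identity at zero noise and honors dropout", {
  prof <- small_profile("biceps_curl", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 1, rate = 50)
  mk <- render_marker_stream(truth, the_model, noise_free())
  ij <- mk[mk$label == "Incisura Jugularis", ]
  vm <- the_model$virtual_markers$marker[["Incisura Jugularis"]]$offset
  expect_equal(ij$x, rep(vm[1], nrow(ij)), tolerance = 1e-12)
  expect_equal(ij$y, rep(vm[2], nrow(ij)), tolerance = 1e-12)

  nz <- noise_model(marker_noise_sigma = 0, dropout_prob = 0, sigma_xy = 0,
                    failure_prob = 0)
  nz$dropout_prob <- 1
  mk2 <- render_marker_stream(truth, the_model, nz)
  expect_true(all(is.na(mk2$x)))
})

test_that("marker noise magnitude matches its stated sd", {
  prof <- exercise_profile("biceps_curl", n_sets = 1, n_reps = 4,
                           rep_duration = 2, rest_duration = 0)
  truth <- generate_ground_truth(prof, the_model, seed = 3, rate = 200)
  nz <- noise_model(marker_noise_sigma = 0.001, dropout_prob = 0, sigma_xy = 0,
                    failure_prob = 0, seed = 5)
  noisy <- render_marker_stream(truth, the_model, nz)
  clean <- render_marker_stream(truth, the_model, noise_free())
  resid <- noisy$x - clean$x
  expect_gt(length(resid), 1e4)
  expect_gt(stats::sd(resid), 0.0008)
  expect_lt(stats::sd(resid), 0.0012)
})

test_that("camera noise is AR(1) with the configured lag-1 autocorrelation", {
  prof <- exercise_profile("lateral_fly", n_sets = 1, n_reps = 3,
                           rep_duration = 2, rest_duration = 0, lead_in = 2)
  truth <- generate_ground_truth(prof, the_model, seed = 4, rate = 400)
  nz <- noise_model(sigma_xy = 0.02, sigma_depth_multiplier = 1,
                    temporal_corr = 0.9, failure_prob = 0, seed = 6)
  # many trials pooled to pass 1e4 noise samples
  resid <- unlist(lapply(1:7, function(k) {
    nzk <- nz; nzk$seed <- k
    noisy <- render_camera_stream(truth, the_model, nzk)
    clean <- render_camera_stream(truth, the_model, noise_free())
    split(noisy$x - clean$x, noisy$label)
  }), use.names = FALSE)
  n_per <- length(resid) / 35
  ac <- mean(vapply(split(resid, rep(1:35, each = n_per)), function(e)
    stats::cor(e[-1], e[-length(e)]), 0))
  expect_gt(ac, 0.85)
  expect_lt(ac, 0.95)
})

test_that("camera MPJPE matches the scaled chi-distribution mean", {
  # isotropic case: E||e|| = sigma * sqrt(2) * gamma(2) / gamma(3/2)
  prof <- exercise_profile("lateral_fly", n_sets = 1, n_reps = 3,
                           rep_duration = 2, rest_duration = 0, lead_in = 2)
  truth <- generate_ground_truth(prof, the_model, seed = 4, rate = 400)
  clean <- render_camera_stream(truth, the_model, noise_free())
  sig <- 0.02
  err <- unlist(lapply(1:30, function(k) {
    nz <- noise_model(sigma_xy = sig, sigma_depth_multiplier = 1,
                      temporal_corr = 0.9, failure_prob = 0, seed = 100 + k)
    noisy <- render_camera_stream(truth, the_model, nz)
    mpjpe(noisy, clean)
  }))
  expected <- sig * sqrt(2) * gamma(2) / gamma(3 / 2)
  expect_equal(mean(err), expected, tolerance = 0.05)
})

test_that("catastrophic failure collapses every inter-label distance", {
  prof <- small_profile("biceps_curl", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 1, rate = 50)
  nz <- noise_free(); nz$failure_prob <- 1
  cm <- render_camera_stream(truth, the_model, nz)
  w <- muscleval:::traj_wide(cm)
  for (a in 1:4) for (b in (a + 1):5) {
    d <- sqrt((w$x[, a] - w$x[, b])^2 + (w$y[, a] - w$y[, b])^2 +
                (w$z[, a] - w$z[, b])^2)
    expect_lt(max(d), 0.1)
  }
})

test_that("zero-noise camera stream equals marker-derived joint centres", {
  prof <- small_profile("biceps_curl", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 9, rate = 60)
  mk <- render_marker_stream(truth, the_model, noise_free())
  cm <- render_camera_stream(truth, the_model, noise_free(), rate = 30)
  centers <- estimate_joint_centers(mk, regression_coefficients(the_model))
  # compare at shared time points (camera grid is a subset of 60 Hz grid)
  j <- dplyr::inner_join(
    dplyr::filter(cm, .data$label != "Mid Spine", .data$label != "Mid Thorax"),
    centers, by = c("time", "label"), suffix = c("", "_mk"))
  expect_gt(nrow(j), 0)
  err <- sqrt((j$x - j$x_mk)^2 + (j$y - j$y_mk)^2 + (j$z - j$z_mk)^2)
  # elbow and wrist midpoints are exact; the shoulder regression stand-in
  # carries a sub-millimetre residual
  expect_lt(max(err), 2e-4)
  expect_lt(max(err[j$label != "Shoulder joint center"]), 1e-6)
})

test_that("rendering is reproducible for a fixed seed", {
  prof <- small_profile("lateral_fly", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 5, rate = 50)
  nz <- noise_model(seed = 77)
  expect_identical(render_marker_stream(truth, the_model, nz),
                   render_marker_stream(truth, the_model, nz))
  expect_identical(render_camera_stream(truth, the_model, nz),
                   render_camera_stream(truth, the_model, nz))
})
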