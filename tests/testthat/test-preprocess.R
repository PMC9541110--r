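test_that("elbow and wrist centres are exact midpoints", {
  mk <- trajectory_set(tibble::tibble(
    time = 0,
    label = c("Epicondylus Medialis", "Epicondylus Lateralis",
              "Head of Ulna", "Styloid Radius", "Acromion",
              "Incisura Jugularis", "Cervical Vertebrae 7",
              "Processus Xiphoideus", "Thoracic Vertebrae 10"),
    x = c(0, 0.06, 1, 1, 0.2, 0, 0, 0, 0),
    y = c(0, 0, 1, 1, 0.3, 0.24, 0.28, 0.02, 0.02),
    z = c(0, 0, 1, 0, 0, 0.09, -0.08, 0.11, -0.11)),
    rate = 400, stream_kind = "marker")
  cen <- estimate_joint_centers(mk, regression_coefficients(the_model))
  el <- cen[cen$label == "Elbow joint center", ]
  expect_identical(c(el$x, el$y, el$z), c(0.03, 0, 0))
  wr <- cen[cen$label == "Wrist joint center", ]
  expect_identical(c(wr$x, wr$y, wr$z), c(1, 1, 0.5))
})

test_that("zero-noise centres reproduce the chain's joint positions", {
  # constant scapula (zero rhythm) and the exact constant acromion offset:
  # the centre estimates must match forward kinematics to <= 1e-6 m
  coeffs <- flat_rhythm()
  p0 <- marker_positions(the_model, zero_coords(), kind = "marker")
  th <- lapply(c("Incisura Jugularis", "Cervical Vertebrae 7",
                 "Processus Xiphoideus", "Thoracic Vertebrae 10"),
               function(lb) unlist(p0[p0$label == lb, c("x", "y", "z")]))
  Rth <- muscleval:::thorax_frame(th[[1]], th[[2]], th[[3]], th[[4]])
  acr <- unlist(p0[p0$label == "Acromion", c("x", "y", "z")])
  gh0 <- marker_positions(the_model, zero_coords(), kind = "centers")
  gh <- unlist(gh0[gh0$label == "Shoulder joint center", c("x", "y", "z")])
  coeffs$shoulder_center_offset <- as.numeric(t(Rth) %*% (gh - acr))

  prof <- small_profile("biceps_curl", n_reps = 1)
  model0 <- the_model
  model0$regression$rhythm <- lapply(model0$regression$rhythm, function(x)
    list(slope = 0, intercept = 0))
  truth <- generate_ground_truth(prof, model0, seed = 2, rate = 50)
  mk <- render_marker_stream(truth, model0, noise_free())
  cen <- estimate_joint_centers(mk, coeffs)
  oracle <- muscleval:::truth_points(truth, model0, unique(cen$label), "centers")
  w <- muscleval:::traj_wide(cen)
  for (lb in oracle$labels) {
    err <- sqrt((w$x[, lb] - oracle$x[, lb])^2 + (w$y[, lb] - oracle$y[, lb])^2 +
                  (w$z[, lb] - oracle$z[, lb])^2)
    expect_lt(max(err), 1e-6)
  }
})

test_that("centre estimation propagates missing frames and rejects absent landmarks", {
  prof <- small_profile("biceps_curl", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 2, rate = 50)
  mk <- render_marker_stream(truth, the_model, noise_free())
  mk$x[mk$label == "Epicondylus Medialis"][3] <- NA
  cen <- estimate_joint_centers(mk, regression_coefficients(the_model))
  expect_true(is.na(cen$x[cen$label == "Elbow joint center"][3]))
  mk2 <- dplyr::filter(mk, .data$label != "Acromion")
  mk2 <- trajectory_set(mk2, rate = 50, stream_kind = "marker")
  expect_error(estimate_joint_centers(mk2, regression_coefficients(the_model)),
               "Acromion")
})

test_that("marker QC applies the three-markers-per-segment rule", {
  prof <- small_profile("lateral_fly", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 3, rate = 50)
  mk <- render_marker_stream(truth, the_model, noise_free())
  expect_true(qc_marker_trial(mk)$included)

  # both epicondyles + the lower-arm tracking marker lost throughout
  drop <- mk$label %in% c("Epicondylus Medialis", "Epicondylus Lateralis",
                          "Lower arm")
  mk_bad <- mk
  mk_bad$x[drop] <- NA; mk_bad$y[drop] <- NA; mk_bad$z[drop] <- NA
  qc <- qc_marker_trial(mk_bad)
  expect_false(qc$included)
  expect_equal(qc$reason, "too_many_missing_markers")

  # one marker missing on ~1% of frames stays included
  mk_ok <- mk
  idx <- which(mk_ok$label == "Acromion")[1:2]
  mk_ok$x[idx] <- NA
  expect_true(qc_marker_trial(mk_ok)$included)
})

test_that("camera QC flags collapsed skeletons, not boundary lengths", {
  prof <- small_profile("lateral_fly", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 3, rate = 50)
  cm <- render_camera_stream(truth, the_model, noise_free())
  expect_true(qc_camera_trial(cm)$included)

  nz <- noise_free(); nz$failure_prob <- 1
  bad <- render_camera_stream(truth, the_model, nz)
  qc <- qc_camera_trial(bad)
  expect_false(qc$included)
  expect_equal(qc$reason, "unrealistic_pose")

  # exactly at the lower length bound: included (strict inequality)
  t2 <- tibble::tibble(
    time = rep(c(0, 1 / 30), each = 5),
    label = rep(c("Mid Spine", "Mid Thorax", "Shoulder joint center",
                  "Elbow joint center", "Wrist joint center"), 2),
    x = rep(c(0, 0, 0.2, 0.2, 0.2), 2),
    y = rep(c(0.3, 0, 0.2, 0.05, -0.10), 2),
    z = 0)
  ts2 <- trajectory_set(t2, rate = 30, stream_kind = "camera")
  expect_true(qc_camera_trial(ts2)$included)
  # QC determinism
  expect_identical(qc_camera_trial(ts2), qc_camera_trial(ts2))
})

test_that("static-pose scaling recovers segment size ratios", {
  static <- generate_static_trial(the_model, duration = 0.5, rate = 50)
  mk <- render_marker_stream(static, the_model, noise_free())
  sc <- compute_scales(mk, the_model)
  expect_equal(sc$sx, rep(1, 6), tolerance = 1e-9)
  expect_equal(sc$sy, rep(1, 6), tolerance = 1e-9)

  # uniformly larger subject: every factor doubles with doubled distances
  mk2 <- mk
  mk2$x <- mk$x * 2; mk2$y <- mk$y * 2; mk2$z <- mk$z * 2
  mk2 <- trajectory_set(mk2, rate = 50, stream_kind = "marker")
  sc2 <- compute_scales(mk2, the_model)
  expect_equal(sc2$sx, rep(2, 6), tolerance = 1e-9)

  # camera stream: one thorax factor applied uniformly to all axes
  big <- scale_segments(the_model, c(thorax = 1.1, clavicle = 1.1,
                                     scapula = 1.1, humerus = 1.1,
                                     forearm = 1.1, hand = 1.1))
  static_b <- generate_static_trial(big, duration = 0.5, rate = 50)
  cmb <- render_camera_stream(static_b, big, noise_free())
  scc <- compute_scales(cmb, the_model)
  th <- scc[scc$segment == "thorax", ]
  expect_equal(th$method, "uniform")
  expect_equal(th$sx, th$sy)
  expect_equal(th$sy, th$sz)
  expect_equal(th$sx, 1.1, tolerance = 1e-6)
  hu <- scc[scc$segment == "humerus", ]
  expect_equal(hu$sx, 1.1, tolerance = 1e-6)
})

test_that("camera humerus scaling recovers a longer arm under default noise", {
  # 10 s static calibration trials: long enough for the slow AR(1) camera
  # noise to average out of the mean relative vector
  long_arm <- scale_segments(the_model, c(humerus = 1.10))
  static <- generate_static_trial(long_arm, duration = 10, rate = 60)
  facs <- vapply(1:100, function(k) {
    nz <- noise_model(failure_prob = 0, dropout_prob = 0, seed = 1000 + k)
    cm <- render_camera_stream(static, long_arm, nz)
    sc <- compute_scales(cm, the_model)
    sc$sx[sc$segment == "humerus"]
  }, 0)
  expect_gt(mean(facs), 1.09)
  expect_lt(mean(facs), 1.11)
})

test_that("rhythm prescription is affine in elevation", {
  coeffs <- regression_coefficients(the_model)
  coeffs$elevation_map <- NULL  # direct affine check
  pp0 <- prescribe_scapula_clavicle(
    tibble::tibble(time = 0:2, shoulder_elv = c(0, 45, 90)), coeffs)
  expect_equal(pp0$scap_upward_rot, c(0, 22.5, 45))
  zero <- coeffs
  zero$rhythm <- lapply(zero$rhythm, function(x) list(slope = 0, intercept = 0))
  ppz <- prescribe_scapula_clavicle(
    tibble::tibble(time = 0:1, shoulder_elv = c(30, 80)), zero)
  expect_true(all(as.matrix(ppz[, -1]) == 0))
})
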