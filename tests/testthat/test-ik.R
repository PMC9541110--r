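test_that("single-frame IK inverts forward kinematics at zero noise", {
  q <- rhythm_pose(30, shoulder_elv_plane = 10, elbow_flexion = 40)
  pts <- dplyr::bind_rows(marker_positions(the_model, q, "marker"),
                          marker_positions(the_model, q, "centers"))
  presc <- as.list(q[the_model$coords$name[the_model$coords$prescribed]])
  fit <- solve_ik_frame(pts, the_model, ik_settings(), warm_start = NULL,
                        prescribed = presc)
  expect_lt(max(abs(fit$coords - q)), 1e-3)
  expect_lt(fit$residual, 1e-6)
})

test_that("IK residual reflects a displaced marker and the solution is stable", {
  q <- rhythm_pose(40, elbow_flexion = 30)
  pts <- dplyr::bind_rows(marker_positions(the_model, q, "marker"),
                          marker_positions(the_model, q, "centers"))
  presc <- as.list(q[the_model$coords$name[the_model$coords$prescribed]])
  base <- solve_ik_frame(pts, the_model, ik_settings(), warm_start = q,
                         prescribed = presc)
  pts2 <- pts
  pts2$x[pts2$label == "Hand"] <- pts2$x[pts2$label == "Hand"] + 0.010
  fit <- solve_ik_frame(pts2, the_model, ik_settings(), warm_start = q,
                        prescribed = presc)
  expect_gt(fit$residual, 0)
  # continuity probe: random small perturbations move the solution boundedly
  set.seed(21)
  for (k in 1:40) {
    ptsk <- pts
    ptsk$x <- ptsk$x + stats::rnorm(nrow(ptsk), 0, 0.002)
    ptsk$y <- ptsk$y + stats::rnorm(nrow(ptsk), 0, 0.002)
    ptsk$z <- ptsk$z + stats::rnorm(nrow(ptsk), 0, 0.002)
    fk <- solve_ik_frame(ptsk, the_model, ik_settings(), warm_start = q,
                         prescribed = presc)
    expect_lt(max(abs(fk$coords - base$coords)), 15)
  }
})

test_that("under-determined frames are flagged and carry the warm start", {
  q <- rhythm_pose(30)
  pts <- marker_positions(the_model, q, "marker")[1:2, ]
  fit <- solve_ik_frame(pts, the_model, ik_settings(), warm_start = q,
                        prescribed = NULL)
  expect_true(fit$flagged)
  expect_equal(unname(fit$coords), unname(q))
})

test_that("trajectory IK recovers the generated motion for both streams", {
  rc <- regression_coefficients(the_model)
  prof <- small_profile("lateral_fly", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 8, rate = 50)
  mk <- render_marker_stream(truth, the_model, noise_free())
  cen <- estimate_joint_centers(mk, rc)
  pose <- solve_ik_trajectory(bind_centers(mk, cen), the_model, ik_settings(),
                              prescribe_scapula_clavicle(estimate_elevation(cen), rc))
  expect_lt(max(abs(pose$shoulder_elv - truth$shoulder_elv)), 1)

  cm <- render_camera_stream(truth, the_model, noise_free())
  pose2 <- solve_ik_trajectory(cm, the_model, ik_settings(),
                               prescribe_scapula_clavicle(estimate_elevation(cm), rc))
  te <- stats::approx(truth$time, truth$shoulder_elv, pose2$time)$y
  tf <- stats::approx(truth$time, truth$elbow_flexion, pose2$time)$y
  # stream-kind equivalence at zero noise (same machinery, sparser labels)
  expect_lt(sqrt(mean((pose2$shoulder_elv - te)^2)), 2)
  expect_lt(sqrt(mean((pose2$elbow_flexion - tf)^2)), 2)
  expect_false(any(is.na(pose2$shoulder_rot)))
})

test_that("constant-pose streams are a warm-start fixed point", {
  static <- generate_static_trial(the_model, duration = 0.2, rate = 30,
                                  pose = list(shoulder_elv = 25,
                                              elbow_flexion = 35))
  cm <- render_camera_stream(static, the_model, noise_free())
  pose <- solve_ik_trajectory(cm, the_model, ik_settings())
  for (cn in c("shoulder_elv", "elbow_flexion")) {
    expect_lt(diff(range(pose[[cn]])), 1e-3)
  }
})

test_that("a fully missing marker does not break the trajectory solve", {
  rc <- regression_coefficients(the_model)
  prof <- small_profile("biceps_curl", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 4, rate = 40)
  mk <- render_marker_stream(truth, the_model, noise_free())
  gone <- mk$label == "Upper arm"
  mk$x[gone] <- NA; mk$y[gone] <- NA; mk$z[gone] <- NA
  cen <- estimate_joint_centers(mk, rc)
  pose <- solve_ik_trajectory(bind_centers(mk, cen), the_model, ik_settings(),
                              prescribe_scapula_clavicle(estimate_elevation(cen), rc))
  expect_true(all(is.finite(pose$residual_rms)))
  expect_lt(max(abs(pose$elbow_flexion - truth$elbow_flexion)), 1)
})

test_that("the solver never degrades the objective below its warm start", {
  # monotonicity contract: solution objective <= warm-start objective
  set.seed(31)
  rc <- regression_coefficients(the_model)
  q <- rhythm_pose(50, elbow_flexion = 60)
  pts <- dplyr::bind_rows(marker_positions(the_model, q, "marker"),
                          marker_positions(the_model, q, "centers"))
  presc <- as.list(q[the_model$coords$name[the_model$coords$prescribed]])
  pn <- names(presc)
  objective <- function(coords) {
    p <- dplyr::bind_rows(marker_positions(the_model, coords, "marker"),
                          marker_positions(the_model, coords, "centers"))
    marker <- sum((p$x - pts$x)^2 + (p$y - pts$y)^2 + (p$z - pts$z)^2)
    ang <- 10 * sum((pi / 180 * (coords[pn] - unlist(presc)))^2)
    prior <- 0.01 * (pi / 180 * coords[["shoulder_rot"]])^2
    marker + ang + prior
  }
  for (k in 1:10) {
    warm <- q + stats::rnorm(length(q), 0, 5)
    warm <- pmin(pmax(warm, the_model$coords$lo), the_model$coords$hi)
    fit <- solve_ik_frame(pts, the_model, ik_settings(), warm_start = warm,
                          prescribed = presc)
    expect_lte(objective(fit$coords), objective(warm) + 1e-12)
  }
})
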