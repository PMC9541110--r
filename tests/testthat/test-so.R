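# minimal geometry/model stubs for direct frame solves
stub_geo <- function(arms, f_L = NULL) {
  n <- nrow(arms)
  list(state = tibble::tibble(muscle = rownames(arms), length = 1, fiber = 1,
                              lnorm = 1, f_L = f_L %||% rep(1, n),
                              flagged = FALSE),
       moment_arms = arms)
}
stub_model <- function(fmax, alpha = NULL) {
  list(muscles = tibble::tibble(name = names(fmax), f_max_iso = unname(fmax),
                                alpha_penn = alpha %||% rep(0, length(fmax))))
}

test_that("two equal-capacity muscles split a saturating moment equally", {
  # Fhat = (100, 200) N, arms (0.02, 0.01) m: both torque capacities are
  # 2 N m, so M = 2 N m forces a1 + a2 = 1, minimized at (0.5, 0.5)
  arms <- matrix(c(0.02, 0.01), 2, 1, dimnames = list(c("A", "B"), "q"))
  sol <- solve_frame_so(c(q = 2), stub_geo(arms), stub_model(c(A = 100, B = 200)),
                        so_settings(ideal_force = TRUE))
  expect_equal(unname(sol$activations), c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(unname(sol$muscle_forces), c(50, 100), tolerance = 0.5)
  expect_equal(sol$objective_value, 0.5, tolerance = 1e-3)
  expect_true(sol$feasible)
})

test_that("zero moment demands zero activation", {
  arms <- matrix(c(0.02, 0.01), 2, 1, dimnames = list(c("A", "B"), "q"))
  sol <- solve_frame_so(c(q = 0), stub_geo(arms), stub_model(c(A = 100, B = 200)),
                        so_settings(ideal_force = TRUE))
  expect_equal(unname(sol$activations), c(0, 0))
  expect_equal(sol$objective_value, 0)
})

test_that("an over-demanded muscle clamps at 1 and the reserve carries the rest", {
  arms <- matrix(0.01, 1, 1, dimnames = list("A", "q"))
  sol <- solve_frame_so(c(q = 2), stub_geo(arms), stub_model(c(A = 100)),
                        so_settings(ideal_force = TRUE))
  expect_equal(unname(sol$activations), 1, tolerance = 1e-6)
  expect_equal(unname(sol$reserve_moments), 1, tolerance = 1e-3)
  expect_false(sol$feasible)
})

test_that("a constrained coordinate no muscle spans is a configuration error", {
  arms <- matrix(c(0.02, 0), 1, 2, dimnames = list("A", c("q1", "q2")))
  expect_error(
    solve_frame_so(c(q1 = 1, q2 = 1), stub_geo(arms), stub_model(c(A = 100)),
                   so_settings(ideal_force = TRUE, constrained = c("q1", "q2"))),
    "no muscle spans")
})

test_that("frame solutions match exhaustive grid search on small instances", {
  # the solver must (i) reach an objective at least as low as the
  # exhaustive 0.001-step lattice and (ii) lie within 0.005 of the
  # lattice's near-optimal set (the redundancy valley makes the lattice
  # argmin itself ambiguous beyond that distance)
  set.seed(99)
  for (k in 1:15) {
    inst <- so_random_instance(nm = sample(2:3, 1), nc = sample(1:2, 1))
    sol <- solve_frame_so(inst$M, inst$geo, inst$mdl,
                          so_settings(ideal_force = TRUE))
    objf <- function(a) sum(a^2) + 1000 * sum((inst$M - inst$A %*% a)^2)
    oracle <- so_grid_oracle(inst$A, inst$M)
    expect_lte(objf(sol$activations), oracle$obj_min + 1e-9)
    expect_lt(so_grid_near_dist(oracle, sol$activations, inst$A), 0.005)
  }
})

test_that("KKT proportionality holds at unclamped two-muscle optima", {
  set.seed(7)
  for (k in 1:20) {
    fhat <- stats::runif(2, 100, 400)
    r <- stats::runif(2, 0.01, 0.05)
    arms <- matrix(r, 2, 1, dimnames = list(c("A", "B"), "q"))
    cap <- fhat * r
    M <- stats::runif(1, 0.1, 0.5 * sum(cap))  # keeps both interior
    sol <- solve_frame_so(c(q = M), stub_geo(arms),
                          stub_model(stats::setNames(fhat, c("A", "B"))),
                          so_settings(ideal_force = TRUE))
    a <- sol$activations
    if (all(a > 1e-6 & a < 1 - 1e-6)) {
      # at an interior optimum a_i is proportional to its torque capacity
      expect_equal(a[["A"]] / a[["B"]], cap[1] / cap[2], tolerance = 1e-3)
      a_closed <- M * cap / sum(cap^2)  # Lagrange closed form (w -> Inf)
      expect_equal(unname(a), unname(a_closed), tolerance = 1e-2)
    }
  }
})

test_that("moment scaling never increases the objective", {
  arms <- matrix(c(0.02, -0.01, 0.015, 0.03), 2, 2,
                 dimnames = list(c("A", "B"), c("q1", "q2")))
  mdl <- stub_model(c(A = 300, B = 200))
  M0 <- c(q1 = 3, q2 = 1.5)
  objs <- vapply(c(1, 0.75, 0.5, 0.25, 0.1), function(k)
    solve_frame_so(M0 * k, stub_geo(arms), mdl,
                   so_settings(ideal_force = TRUE))$objective_value, 0)
  expect_true(all(diff(objs) <= 1e-9))
})

test_that("musculotendon geometry: force-length curve and ideal mode", {
  q <- rhythm_pose(45, shoulder_elv_plane = 15, elbow_flexion = 60)
  geo <- musculotendon_geometry(q, the_model)
  # calibration pose: every fiber sits at optimal length -> f_L = 1
  expect_equal(geo$state$lnorm, rep(1, 33), tolerance = 1e-6)
  expect_equal(geo$state$f_L, rep(1, 33), tolerance = 1e-6)
  ideal <- musculotendon_geometry(rhythm_pose(90), the_model,
                                  so_settings(ideal_force = TRUE))
  expect_equal(ideal$state$f_L, rep(1, 33))
  gauss <- musculotendon_geometry(rhythm_pose(90), the_model)
  expect_equal(gauss$state$f_L,
               exp(-((gauss$state$lnorm - 1) / 0.45)^2), tolerance = 1e-12)
})

test_that("moment arms match the analytic chord-length derivative", {
  # two-point path spanning one hinge with both points at radius r
  # perpendicular to the axis: L(q) = 2 r sin(q/2), dL/dq = r cos(q/2)
  m2 <- the_model
  r <- 0.05
  m2$geometry <- list("Chord" = list(
    muscle = "Chord",
    path = list(list(segment = "humerus", offset = c(0, -0.30 + r, 0)),
                list(segment = "forearm", offset = c(0, r, 0))),
    spanned = "elbow_flexion"))
  m2$muscles <- m2$muscles[1, ]
  m2$muscles$name <- "Chord"
  for (q in c(20, 60, 100)) {
    geo <- musculotendon_geometry(stats::setNames(q, "elbow_flexion"), m2,
                                  so_settings(ideal_force = TRUE))
    qr <- q * pi / 180
    expect_equal(abs(geo$moment_arms["Chord", "elbow_flexion"]),
                 r * cos(qr / 2), tolerance = 0.01 * r)
    expect_equal(geo$state$length[1], 2 * r * sin(qr / 2), tolerance = 1e-9)
  }
})

test_that("trajectory solves are deterministic and track the moment peak", {
  prof <- small_profile("biceps_curl", n_reps = 1)
  truth <- generate_ground_truth(prof, the_model, seed = 12, rate = 40)
  mom <- compute_net_moments(truth, the_model, make_external_load(5))
  f1 <- solve_trajectory_so(truth, mom, the_model)
  f2 <- solve_trajectory_so(truth, mom, the_model)
  expect_identical(f1, f2)
  # moment tracking: the summed biceps force peaks where the elbow moment
  # is near its maximum (not exactly at it: the moment arm and force-length
  # scaling vary over the repetition)
  biceps <- f1[["Biceps long"]] + f1[["Biceps brevis"]]
  mom_at_force_peak <- mom$elbow_flexion[which.max(biceps)]
  expect_gt(mom_at_force_peak, 0.75 * max(mom$elbow_flexion))
})

test_that("an unloaded hanging arm produces near-zero muscle forces", {
  static <- generate_static_trial(the_model, duration = 0.2, rate = 40)
  mom <- compute_net_moments(static, the_model, NULL)
  f <- solve_trajectory_so(static, mom, the_model)
  cols <- setdiff(names(f), c("time", "feasible"))
  expect_lt(max(as.matrix(f[, cols])), 25)  # segment-gravity baseline only
})
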