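test_that("RMSD follows the square-average-root definition and is symmetric", {
  s <- trial_statistics(c(3, 4), c(0, 0), fmax_group = 100)
  expect_equal(s$rmsd_N, sqrt((9 + 16) / 2))
  expect_equal(s$rmsd_pct_fmax, 100 * sqrt(12.5) / 100)
  s2 <- trial_statistics(c(0, 0), c(3, 4), fmax_group = 100)
  expect_equal(s2$rmsd_N, s$rmsd_N)
  ident <- trial_statistics(c(1, 2, 3), c(1, 2, 3), 100)
  expect_equal(ident$rmsd_N, 0)
  expect_equal(ident$pearson_r, 1)
  # zero-variance windows leave r missing
  flat <- trial_statistics(c(5, 5, 5), c(5, 5, 5), 100)
  expect_equal(flat$rmsd_N, 0)
  expect_true(is.na(flat$pearson_r))
  expect_error(trial_statistics(1:3, 1:4, 100), "equal length")
})

test_that("r is invariant to affine transforms of one window", {
  set.seed(5)
  a <- stats::rnorm(200)
  b <- a + stats::rnorm(200, 0, 0.5)
  r0 <- trial_statistics(a, b, 100)$pearson_r
  r1 <- trial_statistics(3 * a + 10, b, 100)$pearson_r
  expect_equal(r1, r0, tolerance = 1e-12)
  r2 <- trial_statistics(-2 * a + 1, b, 100)$pearson_r
  expect_equal(abs(r2), abs(r0), tolerance = 1e-12)
})

test_that("printed-table %Fmax values are reproduced from N and the registry", {
  # single-head rows and summed-head rotator-cuff rows reproduce the printed
  # percentage at 1-decimal rounding
  cases <- list(
    list(rmsd = 6.2, muscle = "Deltoideus posterior", pct = 0.5),
    list(rmsd = 3.4, muscle = "Trapezius scapula middle", pct = 0.7),
    list(rmsd = 7.9, muscle = "Triceps", pct = 0.5),
    list(rmsd = 3.4, muscle = "Teres minor", pct = 0.5),
    list(rmsd = 11.8, muscle = "Infraspinatus", pct = 0.6),
    list(rmsd = 10.4, muscle = "Subscapularis", pct = 0.5),
    list(rmsd = 3.5, muscle = "Supraspinatus", pct = 0.4))
  for (cc in cases) {
    expect_equal(round_half_up(rmsd_pct_fmax(cc$rmsd, the_model, cc$muscle), 1),
                 cc$pct)
  }
  # the two biceps-curl rows are numerically inconsistent with their printed
  # percentages at this rounding; they are flagged, not forced
  expect_false(round_half_up(rmsd_pct_fmax(7.1, the_model, "Biceps brevis"), 1) == 0.9)
  expect_false(round_half_up(rmsd_pct_fmax(3.1, the_model, "Biceps long"), 1) == 0.7)
})

test_that("body-weight percentages convert to the quoted Newton values", {
  expect_equal(round_half_up(pct_bw_to_newton(5.45, 80)), 43)
  expect_equal(round_half_up(pct_bw_to_newton(2.88, 80)), 23)
})

test_that("cubic-spline upsampling maps a 2 s window from 61 to 801 samples", {
  t30 <- seq(0, 2, by = 1 / 30)
  expect_equal(length(t30), 61)
  t400 <- seq(0, 2, by = 1 / 400)
  expect_equal(length(t400), 801)
  y <- sin(2 * pi * 1 * t30)
  out <- resample_to_reference(t30, y, t400)
  expect_equal(length(out), 801)
  expect_equal(out[1], y[1])
  expect_equal(out[length(out)], y[length(y)])
  expect_lt(max(abs(out - sin(2 * pi * t400))), 0.01)
  const <- resample_to_reference(t30, rep(7, 61), t400)
  expect_equal(const, rep(7, 801), tolerance = 1e-12)
  expect_error(resample_to_reference(c(0, 1, 1, 2), 1:4, t400), "increasing")
})

test_that("zero-phase Butterworth filtering has unit DC gain and the analytic roll-off", {
  cfg <- analysis_config()
  rate <- 400
  tt <- seq(0, 5, by = 1 / rate)
  expect_lt(max(abs(filter_forces(rep(100, length(tt)), rate, cfg) - 100)),
            1e-9)
  # two-pass magnitude at f: (1 + (f/fc)^4)^-1 for a 2nd-order design
  mid <- function(x) x[tt > 1 & tt < 4]
  amp <- function(f) {
    y <- filter_forces(sin(2 * pi * f * tt), rate, cfg)
    max(abs(mid(y)))
  }
  expect_gt(amp(1), 0.95)
  expect_equal(amp(1), 1 / (1 + (1 / 4)^4), tolerance = 0.01)
  expect_lt(amp(50), 0.01)
  expect_error(filter_forces(1:5, rate, cfg), "warm-up")
  expect_error(filter_forces(rep(1, 100), 6, cfg), "twice the cutoff")
})

test_that("peak synchronization aligns shifted streams to a camera sample", {
  rate_ref <- 400; rate_test <- 30
  tref <- seq(0, 6, by = 1 / rate_ref)
  shift <- 0.5
  sig <- function(t) 40 + 50 * pmax(0, sin(pi * (t - 1) / 2))^2
  ref_pose <- pose_trajectory(tibble::tibble(time = tref,
                                             shoulder_elv = sig(tref)),
                              rate = rate_ref)
  ttest <- seq(0, 6, by = 1 / rate_test)
  test_pose <- pose_trajectory(tibble::tibble(time = ttest,
                                              shoulder_elv = sig(ttest - shift)),
                               rate = rate_test)
  ref_forces <- tibble::tibble(time = tref, m1 = sig(tref))
  test_forces <- tibble::tibble(time = ttest, m1 = sig(ttest - shift))
  win <- synchronize_pair(list(forces = test_forces, pose = test_pose),
                          list(forces = ref_forces, pose = ref_pose),
                          analysis_config())
  expect_equal(length(unique(win$rep)), 1)
  expect_equal(nrow(win), 801)
  # peak-aligned signals coincide to within one camera sample of lag
  lag <- which.max(win$test) - which.max(win$ref)
  expect_lte(abs(lag) / 400, 1 / 30 + 1e-9)
  expect_lt(max(abs(win$test - win$ref)), 2)
})

test_that("windows that exceed the recording are dropped with a count", {
  rate <- 400
  tt <- seq(0, 2.5, by = 1 / rate)  # peak at ~1.25, window [0.25, 2.25] fits
  sig <- 10 + 10 * sin(pi * tt / 2.5)^2
  pose <- pose_trajectory(tibble::tibble(time = tt, shoulder_elv = sig), rate)
  forces <- tibble::tibble(time = tt, m1 = sig)
  short <- analysis_config(window_halfwidth = 2)  # cannot fit
  win <- synchronize_pair(list(forces = forces, pose = pose),
                          list(forces = forces, pose = pose), short)
  expect_equal(nrow(win), 0)
  expect_equal(attr(win, "dropped_reps"), 1L)
})

test_that("aggregation averages trials within subject, then subjects", {
  trials <- tibble::tibble(
    subject = c(1, 1, 2), exercise = "lateral_fly", muscle = "Deltoid middle",
    rmsd_N = c(10, 14, 30), rmsd_pct_fmax = c(0.4, 0.6, 1.2),
    pearson_r = c(0.9, 0.8, 0.4))
  tab <- aggregate_trials(trials)
  expect_equal(tab$rmsd_N, mean(c(mean(c(10, 14)), 30)))
  expect_equal(tab$rmsd_N_sd, stats::sd(c(12, 30)))
  expect_equal(tab$pearson_r, mean(c(0.85, 0.4)))
  one <- aggregate_trials(trials[1, ])
  expect_equal(one$rmsd_N, 10)
  expect_equal(one$rmsd_N_sd, 0)
})

test_that("correlation categories follow the published bounds", {
  expect_equal(r_category(c(0.31, 0.36, 0.72, 0.92, -0.92)),
               c("weak", "moderate", "strong", "excellent", "excellent"))
  expect_equal(r_category(c(0.35, 0.67, 0.90)),
               c("weak", "moderate", "strong"))
  expect_true(is.na(r_category(NA_real_)))
})

test_that("Bland-Altman bias and limits follow the sample-SD convention", {
  ba0 <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)
  ba <- bland_altman(c(11, 19), c(10, 20))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, stats::sd(c(1, -1)))
  expect_equal(ba$loa_upper, 1.96 * sqrt(2))
  ba5 <- bland_altman(c(15, 25, 35), c(10, 20, 30))
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$sd_diff, 0)
  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 1), "at least 2")
  per <- bland_altman(c(11, 19, 33), c(10, 20, 30),
                      subjects = c("a", "a", "b"))$per_subject
  expect_equal(per$mean_diff[per$subject == "a"], 0)
  expect_equal(per$mean_diff[per$subject == "b"], 3)
})

test_that("report objects expose tidy, glance and autoplot methods", {
  ba <- bland_altman(c(11, 19, 33), c(10, 20, 30))
  expect_s3_class(tidy(ba), "tbl_df")
  expect_equal(glance(ba)$n, 3)
  expect_s3_class(autoplot(ba), "ggplot")
})
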