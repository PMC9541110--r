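#' Exercise profile for the synthetic-data generator
#'
#' Describes one dumbbell exercise trial: the lateral fly (frontal-plane
#' shoulder elevation with a near-extended elbow, 3 kg dumbbell) or the
#' biceps curl (sagittal-plane elbow flexion with a near-neutral shoulder,
#' 5 kg dumbbell). Defaults reproduce the study protocol: 3 sets of 5
#' repetitions at a self-selected (here sinusoidal) pace with 30 s rest
#' between sets.
#'
#' @param name `"lateral_fly"` or `"biceps_curl"`.
#' @param n_sets,n_reps sets per trial and repetitions per set.
#' @param rep_duration seconds per repetition.
#' @param rest_duration rest between sets, s.
#' @param lead_in quiet baseline before the first and after the last set, s.
#' @param baseline,amplitude named numeric vectors (deg) for the driven
#'   coordinates; defaults depend on `name`.
#' @param dumbbell_mass kg; defaults to 3 (fly) or 5 (curl).
#' @param amplitude_jitter per-rep multiplicative amplitude jitter half-width
#'   (uniform, seeded) emulating self-selected effort; 0 disables.
#' @return an `exercise_profile` list.
#' @export
exercise_profile <- function(name = c("lateral_fly", "biceps_curl"),
                             n_sets = 3, n_reps = 5, rep_duration = 2,
                             rest_duration = 30, lead_in = 1.5,
                             baseline = NULL, amplitude = NULL,
                             dumbbell_mass = NULL, amplitude_jitter = 0.05) {
  name <- match.arg(name)
  if (rep_duration <= 0) stop("rep_duration must be > 0")
  if (name == "lateral_fly") {
    baseline <- baseline %||% c(shoulder_elv = 15, elbow_flexion = 10,
                                shoulder_elv_plane = 0, shoulder_rot = 0, pro_sup = 0)
    amplitude <- amplitude %||% c(shoulder_elv = 75)
    dumbbell_mass <- dumbbell_mass %||% 3
  } else {
    baseline <- baseline %||% c(shoulder_elv = 10, elbow_flexion = 10,
                                shoulder_elv_plane = 30, shoulder_rot = 0, pro_sup = 0)
    amplitude <- amplitude %||% c(elbow_flexion = 120)
    dumbbell_mass <- dumbbell_mass %||% 5
  }
  if (dumbbell_mass < 0) stop("dumbbell_mass must be >= 0")
  structure(list(name = name, n_sets = n_sets, n_reps = n_reps,
                 rep_duration = rep_duration, rest_duration = rest_duration,
                 lead_in = lead_in, baseline = baseline, amplitude = amplitude,
                 dumbbell_mass = dumbbell_mass,
                 amplitude_jitter = amplitude_jitter),
            class = "exercise_profile")
}

#' Measurement noise model for the synthetic streams
#'
#' Camera joint centres receive temporally correlated AR(1) Gaussian noise
#' with marginal sd `sigma_xy` in the image plane and
#' `sigma_xy * sigma_depth_multiplier` along the depth (anterior) axis --
#' magnitudes sized to published single-camera pose errors (MPJPE roughly
#' 23-47 mm). Markers receive small isotropic Gaussian noise with independent
#' per-frame dropout. With probability `failure_prob` a camera trial is
#' replaced by a collapsed skeleton (segment lengths of a few centimetres),
#' emulating catastrophic pose-estimation failures.
#'
#' @param sigma_xy camera noise sd in-plane, m.
#' @param sigma_depth_multiplier unitless depth-axis sd multiplier.
#' @param temporal_corr AR(1) coefficient in `[0, 1)`.
#' @param marker_noise_sigma marker noise sd, m.
#' @param dropout_prob per-frame per-marker dropout probability.
#' @param failure_prob per-trial catastrophic failure probability.
#' @param seed integer seed; all rendering is deterministic given it.
#' @return a `noise_model` list.
#' @export
noise_model <- function(sigma_xy = 0.02, sigma_depth_multiplier = 2,
                        temporal_corr = 0.9, marker_noise_sigma = 0.001,
                        dropout_prob = 0.005, failure_prob = 0.02, seed = 1L) {
  stopifnot(sigma_xy >= 0, sigma_depth_multiplier >= 0,
            temporal_corr >= 0, temporal_corr < 1,
            marker_noise_sigma >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            failure_prob >= 0, failure_prob <= 1)
  structure(list(sigma_xy = sigma_xy,
                 sigma_depth_multiplier = sigma_depth_multiplier,
                 temporal_corr = temporal_corr,
                 marker_noise_sigma = marker_noise_sigma,
                 dropout_prob = dropout_prob, failure_prob = failure_prob,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Zero-noise settings (identity rendering)
#' @return a `noise_model` with every noise source off.
#' @export
noise_free <- function(seed = 1L) {
  noise_model(sigma_xy = 0, sigma_depth_multiplier = 0, temporal_corr = 0,
              marker_noise_sigma = 0, dropout_prob = 0, failure_prob = 0,
              seed = seed)
}

#' Generate ground-truth exercise kinematics
#'
#' Produces a smooth (raised-cosine per repetition, hence C^2 at interior
#' points) generalized-coordinate trajectory for an exercise profile. The
#' driven coordinate rises from baseline to baseline + amplitude and back
#' once per repetition; the scapula and clavicle follow the model's linear
#' scapulohumeral-rhythm regression of humeral elevation.
#'
#' @param profile an [exercise_profile()].
#' @param model an `msk_model`.
#' @param seed integer; drives per-rep amplitude jitter.
#' @param rate output rate Hz (marker-stream rate).
#' @return a `pose_trajectory` at `rate` Hz.
#' @export
generate_ground_truth <- function(profile, model, seed = 1L, rate = 400) {
  stopifnot(inherits(profile, "exercise_profile"), inherits(model, "msk_model"))
  rng <- model$coords
  for (cn in names(profile$amplitude)) {
    base <- profile$baseline[cn]
    if (is.na(base)) base <- 0
    peak <- base + profile$amplitude[cn] * (1 + profile$amplitude_jitter)
    i <- match(cn, rng$name)
    if (is.na(i)) stop("driven coordinate '", cn, "' not on the chain")
    if (peak > rng$hi[i] + 1e-9 || base < rng$lo[i] - 1e-9) {
      stop("amplitude for '", cn, "' leaves the coordinate range [",
           rng$lo[i], ", ", rng$hi[i], "] deg")
    }
  }
  set_dur <- profile$n_reps * profile$rep_duration
  total <- 2 * profile$lead_in + profile$n_sets * set_dur +
    (profile$n_sets - 1) * profile$rest_duration
  times <- seq(0, total, by = 1 / rate)
  n <- length(times)

  n_reps_total <- profile$n_sets * profile$n_reps
  jit <- with_seed(seed, stats::runif(n_reps_total, 1 - profile$amplitude_jitter,
                                      1 + profile$amplitude_jitter))
  # phase in [0,1) within a rep, NA outside reps; rep index per frame
  rep_start <- function(s, r) {
    profile$lead_in + (s - 1) * (set_dur + profile$rest_duration) +
      (r - 1) * profile$rep_duration
  }
  phase <- rep(NA_real_, n)
  repix <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(profile$n_sets)) for (r in seq_len(profile$n_reps)) {
    k <- k + 1L
    t0 <- rep_start(s, r)
    sel <- times >= t0 & times < t0 + profile$rep_duration
    phase[sel] <- (times[sel] - t0) / profile$rep_duration
    repix[sel] <- k
  }

  coords <- matrix(0, n, nrow(rng), dimnames = list(NULL, rng$name))
  for (cn in names(profile$baseline)) coords[, cn] <- profile$baseline[cn]
  for (cn in names(profile$amplitude)) {
    wave <- rep(0, n)
    act <- !is.na(phase)
    wave[act] <- jit[repix[act]] * 0.5 * (1 - cos(2 * pi * phase[act]))
    coords[, cn] <- coords[, cn] + profile$amplitude[cn] * wave
  }
  # scapulohumeral rhythm on the prescribed coordinates
  rhy <- model$regression$rhythm
  elv <- coords[, "shoulder_elv"]
  for (cn in names(rhy)) {
    coords[, cn] <- rhy[[cn]]$intercept + rhy[[cn]]$slope * elv
  }
  pose_trajectory(
    tibble::as_tibble(cbind(tibble::tibble(time = times),
                            tibble::as_tibble(coords))),
    rate = rate,
    meta = list(exercise = profile$name, seed = seed,
                dumbbell_mass = profile$dumbbell_mass,
                rep_duration = profile$rep_duration))
}

#' Generate a static (neutral-pose) calibration trial
#'
#' @param model an `msk_model`.
#' @param duration seconds.
#' @param rate Hz.
#' @param pose optional named coordinate map (deg) held throughout.
#' @return a `pose_trajectory`.
#' @export
generate_static_trial <- function(model, duration = 1, rate = 400, pose = NULL) {
  times <- seq(0, duration, by = 1 / rate)
  coords <- matrix(0, length(times), nrow(model$coords),
                   dimnames = list(NULL, model$coords$name))
  if (!is.null(pose)) for (cn in names(pose)) coords[, cn] <- pose[[cn]]
  pose_trajectory(
    tibble::as_tibble(cbind(tibble::tibble(time = times),
                            tibble::as_tibble(coords))),
    rate = rate, meta = list(exercise = "static"))
}

# FK of a pose trajectory -> wide point arrays for the given labels
truth_points <- function(truth, model, labels, kind) {
  qn <- model$core$qnames
  Q <- deg2rad(as.matrix(truth[, qn, drop = FALSE]))
  n <- nrow(Q)
  X <- matrix(NA_real_, n, length(labels), dimnames = list(NULL, labels))
  Y <- X; Z <- X
  for (i in seq_len(n)) {
    fk <- fk_core(model$core, Q[i, ])
    pts <- marker_points_fk(model, fk, labels, kind)
    X[i, ] <- pts[1, ]; Y[i, ] <- pts[2, ]; Z[i, ] <- pts[3, ]
  }
  list(times = truth$time, labels = labels, x = X, y = Y, z = Z)
}

#' Render the marker-based 400 Hz measurement stream
#'
#' Forward kinematics of the 12 bony-landmark virtual markers plus isotropic
#' Gaussian noise and independent per-frame dropout (missing values).
#'
#' @param truth `pose_trajectory` ground truth.
#' @param model the subject's `msk_model`.
#' @param noise a [noise_model()].
#' @return a marker-kind `trajectory_set` at the truth's rate.
#' @export
render_marker_stream <- function(truth, model, noise = noise_model()) {
  labels <- names(model$virtual_markers$marker)
  w <- truth_points(truth, model, labels, "marker")
  n <- length(w$times); m <- length(labels)
  with_seed(noise$seed + 101L, {
    if (noise$marker_noise_sigma > 0) {
      w$x <- w$x + matrix(stats::rnorm(n * m, 0, noise$marker_noise_sigma), n, m)
      w$y <- w$y + matrix(stats::rnorm(n * m, 0, noise$marker_noise_sigma), n, m)
      w$z <- w$z + matrix(stats::rnorm(n * m, 0, noise$marker_noise_sigma), n, m)
    }
    if (noise$dropout_prob > 0) {
      drop <- matrix(stats::runif(n * m) < noise$dropout_prob, n, m)
      w$x[drop] <- NA_real_; w$y[drop] <- NA_real_; w$z[drop] <- NA_real_
    }
  })
  traj_from_wide(w, rate = attr(truth, "rate"), stream_kind = "marker",
                 meta = c(traj_meta_from_pose(truth), list(noise = noise)))
}

traj_meta_from_pose <- function(truth) attr(truth, "meta") %||% list()

#' Render the camera-based 30 Hz joint-centre stream
#'
#' Downsamples the ground truth to the camera rate, runs forward kinematics
#' of the five joint-centre labels, and adds AR(1)-correlated Gaussian noise
#' (marginal sd `sigma_xy` in-plane, `sigma_xy * sigma_depth_multiplier`
#' along the anterior depth axis). With probability `failure_prob` the whole
#' trial collapses to a tiny skeleton to exercise quality control.
#'
#' @inheritParams render_marker_stream
#' @param rate camera rate, Hz.
#' @return a camera-kind `trajectory_set`.
#' @export
render_camera_stream <- function(truth, model, noise = noise_model(), rate = 30) {
  labels <- names(model$virtual_markers$camera)
  cam_times <- seq(0, max(truth$time), by = 1 / rate)
  qn <- model$core$qnames
  sub <- tibble::tibble(time = cam_times)
  for (cn in qn) {
    sub[[cn]] <- stats::approx(truth$time, truth[[cn]], xout = cam_times)$y
  }
  w <- truth_points(sub, model, labels, "camera")
  n <- length(cam_times); m <- length(labels)
  with_seed(noise$seed + 202L, {
    failed <- stats::runif(1) < noise$failure_prob
    if (noise$sigma_xy > 0) {
      rho <- noise$temporal_corr
      ar1 <- function(sd_m) {
        e <- matrix(stats::rnorm(n * m, 0, sd_m), n, m)
        if (rho > 0 && n > 1) {
          s <- sqrt(1 - rho^2)
          out <- e
          for (i in 2:n) out[i, ] <- rho * out[i - 1, ] + s * e[i, ]
          out
        } else e
      }
      w$x <- w$x + ar1(noise$sigma_xy)
      w$y <- w$y + ar1(noise$sigma_xy)
      w$z <- w$z + ar1(noise$sigma_xy * noise$sigma_depth_multiplier)
    }
    if (failed) {
      # collapsed skeleton: every label pulled to 5% of its offset from the
      # per-frame centroid => all inter-label distances shrink 20-fold
      cx <- rowMeans(w$x); cy <- rowMeans(w$y); cz <- rowMeans(w$z)
      w$x <- cx + 0.05 * (w$x - cx)
      w$y <- cy + 0.05 * (w$y - cy)
      w$z <- cz + 0.05 * (w$z - cz)
    }
  })
  traj_from_wide(w, rate = rate, stream_kind = "camera",
                 meta = c(traj_meta_from_pose(truth), list(noise = noise)))
}
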