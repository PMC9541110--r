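#' Regression coefficients for joint-centre estimation and the
#' scapulohumeral rhythm
#'
#' The shoulder joint centre is placed at the acromion marker plus a constant
#' offset expressed in the thorax frame reconstructed from the four thorax
#' landmarks; the five prescribed scapula/clavicle coordinates are affine
#' functions of humero-thoracic elevation. Both default coefficient sets are
#' configurable stand-ins (the source regressions are not published in
#' numeric form here); `shoulder_center` may also be a function
#' `f(markers_frame)` returning a 3-vector for a custom regression.
#'
#' @param model optional `msk_model` supplying defaults.
#' @param shoulder_center_offset length-3 numeric, m (thorax frame).
#' @param rhythm named list of `list(slope, intercept)` per prescribed
#'   coordinate (deg per deg of elevation).
#' @return a `regression_coefficients` list.
#' @export
regression_coefficients <- function(model = NULL, shoulder_center_offset = NULL,
                                    rhythm = NULL) {
  structure(list(
    shoulder_center_offset = shoulder_center_offset %||%
      model$regression$shoulder_center_offset %||% c(-0.01, -0.06, 0.01),
    rhythm = rhythm %||% model$regression$rhythm %||%
      list(scap_upward_rot = list(slope = 0.5, intercept = 0),
           scap_prot = list(slope = 0.2, intercept = 0),
           scap_tilt = list(slope = 0.1, intercept = 0),
           clav_elev = list(slope = 0.2, intercept = 0),
           clav_prot = list(slope = 0.1, intercept = 0)),
    elevation_map = model$regression$elevation_map,
    provenance = "configurable stand-in regression coefficients"
  ), class = "regression_coefficients")
}

#' Estimate arm joint centres from bony landmarks
#'
#' Elbow centre: midpoint of the medial and lateral epicondyle markers.
#' Wrist centre: midpoint of the ulnar head and radial styloid markers.
#' Shoulder centre: acromion marker plus a regression offset expressed in
#' the estimated thorax frame. Frames missing a required landmark yield a
#' missing centre.
#'
#' @param markers a marker-kind `trajectory_set`.
#' @param coeffs a [regression_coefficients()].
#' @return a `trajectory_set` with labels `Shoulder joint center`,
#'   `Elbow joint center`, `Wrist joint center` at the marker rate.
#' @export
estimate_joint_centers <- function(markers, coeffs = regression_coefficients()) {
  stopifnot(inherits(markers, "trajectory_set"))
  if (traj_kind(markers) != "marker") stop("joint-centre estimation needs a marker stream")
  w <- traj_wide(markers)
  need <- c("Epicondylus Medialis", "Epicondylus Lateralis", "Head of Ulna",
            "Styloid Radius", "Acromion", "Incisura Jugularis",
            "Cervical Vertebrae 7", "Processus Xiphoideus", "Thoracic Vertebrae 10")
  for (lb in need) {
    if (!lb %in% w$labels || all(is.na(w$x[, lb]))) {
      stop("required landmark '", lb, "' absent from the stream")
    }
  }
  n <- length(w$times)
  g <- function(lb, i) c(w$x[i, lb], w$y[i, lb], w$z[i, lb])
  out <- list(x = matrix(NA_real_, n, 3), y = matrix(NA_real_, n, 3),
              z = matrix(NA_real_, n, 3))
  labs <- c("Shoulder joint center", "Elbow joint center", "Wrist joint center")
  mid <- function(a, b) (a + b) / 2
  off <- coeffs$shoulder_center_offset
  for (i in seq_len(n)) {
    el <- mid(g("Epicondylus Medialis", i), g("Epicondylus Lateralis", i))
    wr <- mid(g("Head of Ulna", i), g("Styloid Radius", i))
    sh <- c(NA_real_, NA_real_, NA_real_)
    acr <- g("Acromion", i)
    th <- list(g("Incisura Jugularis", i), g("Cervical Vertebrae 7", i),
               g("Processus Xiphoideus", i), g("Thoracic Vertebrae 10", i))
    if (!anyNA(acr) && !anyNA(unlist(th))) {
      if (is.function(off)) {
        sh <- off(stats::setNames(c(list(acr), th), c("Acromion", need[6:9])))
      } else if (is.list(off) && identical(off$type, "affine_acromion")) {
        Rth <- thorax_frame(th[[1]], th[[2]], th[[3]], th[[4]])
        cen <- (th[[1]] + th[[2]] + th[[3]] + th[[4]]) / 4
        acr_l <- as.numeric(t(Rth) %*% (acr - cen))
        sh <- acr + as.numeric(Rth %*% (off$intercept + off$gain %*% acr_l))
      } else {
        Rth <- thorax_frame(th[[1]], th[[2]], th[[3]], th[[4]])
        sh <- acr + as.numeric(Rth %*% off)
      }
    }
    pts <- cbind(sh, el, wr)
    out$x[i, ] <- pts[1, ]; out$y[i, ] <- pts[2, ]; out$z[i, ] <- pts[3, ]
  }
  colnames(out$x) <- labs; colnames(out$y) <- labs; colnames(out$z) <- labs
  traj_from_wide(list(times = w$times, labels = labs,
                      x = out$x, y = out$y, z = out$z),
                 rate = traj_rate(markers), stream_kind = "marker",
                 meta = traj_meta(markers))
}

# Table-1 segment grouping used by the missing-marker rule; only segments
# carrying >= 3 markers are subject to it.
default_segment_markers <- function() {
  list(thorax = c("Incisura Jugularis", "Processus Xiphoideus",
                  "Cervical Vertebrae 7", "Thoracic Vertebrae 10"),
       upper_arm = c("Acromion", "Epicondylus Medialis",
                     "Epicondylus Lateralis", "Upper arm"),
       lower_arm = c("Head of Ulna", "Styloid Radius", "Lower arm"))
}

#' Quality control of a marker trial
#'
#' A trial is excluded when any segment has fewer than three non-missing
#' markers on more than `max_missing_frac` of frames (default 5%).
#'
#' @param markers a marker-kind `trajectory_set`.
#' @param max_missing_frac tolerated fraction of under-markered frames.
#' @param segment_markers named list `segment -> marker labels`.
#' @return a `qc_report` tibble row: `trial`, `included`, `reason`,
#'   `detail`.
#' @export
qc_marker_trial <- function(markers, max_missing_frac = 0.05,
                            segment_markers = default_segment_markers()) {
  stopifnot(traj_kind(markers) == "marker")
  w <- traj_wide(markers)
  bad_frac <- vapply(segment_markers, function(labs) {
    labs <- intersect(labs, w$labels)
    if (length(labs) < 3) return(0)
    present <- rowSums(!is.na(w$x[, labs, drop = FALSE]))
    mean(present < 3)
  }, 0)
  excluded <- any(bad_frac > max_missing_frac)
  qc_report(trial = traj_meta(markers)$trial %||% NA_character_,
            included = !excluded,
            reason = if (excluded) "too_many_missing_markers" else "ok",
            detail = if (excluded) {
              paste0(names(bad_frac)[bad_frac > max_missing_frac], ": ",
                     round(100 * bad_frac[bad_frac > max_missing_frac], 1),
                     "% frames < 3 markers", collapse = "; ")
            } else "")
}

#' Quality control of a camera trial
#'
#' Flags catastrophic pose-estimation failures: a trial is excluded when the
#' median upper-arm or forearm inter-centre length is implausible
#' (< `len_min` or > `len_max`) or any centre teleports (median
#' frame-to-frame speed above `speed_max`).
#'
#' @param centers a camera-kind `trajectory_set`.
#' @param len_min,len_max plausible segment length bounds, m.
#' @param speed_max m/s.
#' @return a `qc_report` tibble row.
#' @export
qc_camera_trial <- function(centers, len_min = 0.15, len_max = 0.6,
                            speed_max = 10) {
  stopifnot(traj_kind(centers) == "camera")
  w <- traj_wide(centers)
  dist_series <- function(a, b) {
    sqrt((w$x[, a] - w$x[, b])^2 + (w$y[, a] - w$y[, b])^2 +
           (w$z[, a] - w$z[, b])^2)
  }
  ua <- stats::median(dist_series("Shoulder joint center", "Elbow joint center"),
                      na.rm = TRUE)
  fa <- stats::median(dist_series("Elbow joint center", "Wrist joint center"),
                      na.rm = TRUE)
  dt <- 1 / traj_rate(centers)
  speeds <- vapply(w$labels, function(lb) {
    d <- sqrt(diff(w$x[, lb])^2 + diff(w$y[, lb])^2 + diff(w$z[, lb])^2)
    stats::median(d / dt, na.rm = TRUE)
  }, 0)
  bad_len <- ua < len_min || ua > len_max || fa < len_min || fa > len_max
  bad_speed <- any(speeds > speed_max, na.rm = TRUE)
  excluded <- bad_len || bad_speed
  qc_report(trial = traj_meta(centers)$trial %||% NA_character_,
            included = !excluded,
            reason = if (excluded) "unrealistic_pose" else "ok",
            detail = if (excluded) {
              sprintf("median upper arm %.3f m, forearm %.3f m, max median speed %.1f m/s",
                      ua, fa, max(speeds, na.rm = TRUE))
            } else "")
}

qc_report <- function(trial, included, reason, detail = "") {
  structure(tibble::tibble(trial = trial, included = included,
                           reason = reason, detail = detail),
            class = c("qc_report", class(tibble::tibble())))
}

#' Compute segment scale factors from a static trial
#'
#' For each configured virtual-marker pair, factor = mean measured distance /
#' generic model distance at the neutral pose. The dense marker stream
#' scales thorax axes separately; the sparse camera stream has only one
#' thorax distance and applies it uniformly to all thorax axes. Segments
#' without a pair inherit a configured neighbour's factors.
#'
#' @param static a `trajectory_set` of a static (neutral) trial.
#' @param model the generic `msk_model`.
#' @return a `scale_set` tibble: `segment`, `sx`, `sy`, `sz`, `method`.
#' @export
compute_scales <- function(static, model) {
  stopifnot(inherits(static, "trajectory_set"), inherits(model, "msk_model"))
  kind <- traj_kind(static)
  pairs <- model$scale_pairs[[kind]]
  if (is.null(pairs)) stop("no scale pairs configured for stream kind '", kind, "'")
  w <- traj_wide(static)
  generic <- marker_positions(model, NULL, kind = kind)
  gdist <- function(a, b) {
    pa <- unlist(generic[generic$label == a, c("x", "y", "z")])
    pb <- unlist(generic[generic$label == b, c("x", "y", "z")])
    vnorm(pa - pb)
  }
  # distance of the mean relative vector over the static trial: for a
  # static pose the measurement noise averages out before the norm is
  # taken, avoiding the upward bias of averaging noisy distances
  mdist <- function(a, b) {
    ok <- !(is.na(w$x[, a]) | is.na(w$x[, b]))
    vnorm(c(mean(w$x[ok, a] - w$x[ok, b]),
            mean(w$y[ok, a] - w$y[ok, b]),
            mean(w$z[ok, a] - w$z[ok, b])))
  }
  segs <- model$segments
  S <- matrix(NA_real_, length(segs), 3, dimnames = list(segs, c("sx", "sy", "sz")))
  method <- stats::setNames(rep(NA_character_, length(segs)), segs)
  for (p in pairs) {
    g <- gdist(p$a, p$b)
    if (g < 1e-6) stop("degenerate generic distance for pair ", p$a, " - ", p$b)
    f <- mdist(p$a, p$b) / g
    if (!is.finite(f)) stop("pair ", p$a, " - ", p$b, " unmeasurable in static trial")
    if (identical(p$axis, "all")) {
      S[p$segment, ] <- f
      method[p$segment] <- "uniform"
    } else {
      S[p$segment, paste0("s", p$axis)] <- f
      method[p$segment] <- "per_axis"
    }
  }
  # fill unmeasured axes with the mean of measured ones
  for (s in segs) {
    if (all(is.na(S[s, ]))) next
    S[s, is.na(S[s, ])] <- mean(S[s, ], na.rm = TRUE)
  }
  inherit <- model$scale_pairs$inherit %||% list()
  for (s in names(inherit)) {
    if (all(is.na(S[s, ])) && !all(is.na(S[inherit[[s]], ]))) {
      S[s, ] <- S[inherit[[s]], ]
      method[s] <- "inherited"
    }
  }
  S[is.na(S)] <- 1
  method[is.na(method)] <- "unity"
  if (any(S <= 0)) stop("non-positive scale factor computed")
  structure(tibble::tibble(segment = segs, sx = unname(S[, 1]),
                           sy = unname(S[, 2]), sz = unname(S[, 3]),
                           method = unname(method),
                           static_pose_source = traj_meta(static)$trial %||% NA_character_),
            class = c("scale_set", class(tibble::tibble())))
}

#' Humero-thoracic elevation estimated from joint centres
#'
#' The angle between the downward vertical and the shoulder-to-elbow vector;
#' used to drive the scapulohumeral-rhythm regression before inverse
#' kinematics.
#'
#' @param stream a `trajectory_set` containing `Shoulder joint center` and
#'   `Elbow joint center` labels.
#' @return tibble `time`, `shoulder_elv` (deg).
#' @export
estimate_elevation <- function(stream) {
  w <- traj_wide(stream)
  for (lb in c("Shoulder joint center", "Elbow joint center")) {
    if (!lb %in% w$labels) stop("stream lacks label '", lb, "'")
  }
  dx <- w$x[, "Elbow joint center"] - w$x[, "Shoulder joint center"]
  dy <- w$y[, "Elbow joint center"] - w$y[, "Shoulder joint center"]
  dz <- w$z[, "Elbow joint center"] - w$z[, "Shoulder joint center"]
  nn <- sqrt(dx^2 + dy^2 + dz^2)
  elv <- rad2deg(acos(pmin(pmax(-dy / nn, -1), 1)))
  tibble::tibble(time = w$times, shoulder_elv = elv)
}

#' Prescribe scapula and clavicle coordinates from elevation
#'
#' Fills the five prescribed coordinates as affine functions of humeral
#' elevation (linear scapulohumeral rhythm). The measured humero-thoracic
#' elevation includes the scapula's own rotation, so it is first converted
#' back to the glenohumeral elevation coordinate via the model's calibrated
#' elevation map (when available in `coeffs`).
#'
#' @param pose_partial tibble with `time` and `shoulder_elv` (deg; the
#'   measured humero-thoracic elevation, e.g. from [estimate_elevation()]).
#' @param coeffs a [regression_coefficients()].
#' @return tibble `time` plus the five prescribed coordinate columns (deg).
#' @export
prescribe_scapula_clavicle <- function(pose_partial,
                                       coeffs = regression_coefficients()) {
  stopifnot(all(c("time", "shoulder_elv") %in% names(pose_partial)))
  elv <- pose_partial$shoulder_elv
  em <- coeffs$elevation_map
  if (!is.null(em)) {
    elv <- stats::approx(em$thoracic, em$coord, xout = elv, rule = 2)$y
  }
  out <- tibble::tibble(time = pose_partial$time)
  for (cn in names(coeffs$rhythm)) {
    rc <- coeffs$rhythm[[cn]]
    out[[cn]] <- rc$intercept + rc$slope * elv
  }
  out
}
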