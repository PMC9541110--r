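#' Inverse-kinematics settings
#'
#' The per-frame pose fit minimizes a weighted least-squares objective:
#' squared distances between virtual and experimental markers, plus a
#' quadratic tracking term pulling the prescribed scapula/clavicle
#' coordinates toward their regression targets, plus a small quadratic prior
#' pulling humeral axial rotation toward neutral (that coordinate is
#' unobservable from a joint-centre-only stream).
#'
#' @param marker_weights named numeric, weight per label; unlisted labels get
#'   `default_weight`.
#' @param default_weight weight for labels not in `marker_weights`.
#' @param angle_weight weight of the prescribed-coordinate tracking term
#'   (radian residuals).
#' @param axial_rotation_prior_weight weight of the axial-rotation prior.
#' @param max_iterations damped Gauss-Newton iteration cap.
#' @param convergence_tol m; stop when the weighted marker RMS improves by
#'   less than this between iterations.
#' @param retry_residual m; during a trajectory solve, frames whose weighted
#'   RMS marker error exceeds this are re-solved from multiple starting
#'   poses (escape hatch from a wrong warm-started branch under heavy
#'   noise).
#' @param initial_pose named coordinate map (deg) used for the first frame.
#' @return an `ik_settings` list.
#' @export
ik_settings <- function(marker_weights = NULL, default_weight = 1,
                        angle_weight = 10, axial_rotation_prior_weight = 0.01,
                        max_iterations = 100, convergence_tol = 1e-6,
                        retry_residual = 0.15, initial_pose = NULL) {
  stopifnot(convergence_tol > 0, max_iterations >= 1,
            default_weight >= 0, angle_weight >= 0,
            axial_rotation_prior_weight >= 0, retry_residual > 0)
  structure(list(marker_weights = marker_weights, default_weight = default_weight,
                 angle_weight = angle_weight,
                 axial_rotation_prior_weight = axial_rotation_prior_weight,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 retry_residual = retry_residual,
                 initial_pose = initial_pose),
            class = "ik_settings")
}

# residual vector at q (radians, full coordinate vector):
# sqrt(w_l) * (marker residual components), sqrt(angle_w) * (q_presc - target),
# sqrt(prior_w) * q_axial
ik_residual <- function(core, vm, q, pts, wsqrt, presc_idx, presc_target,
                        angle_wsqrt, axial_idx, axial_wsqrt) {
  fk <- fk_core(core, q)
  nlab <- ncol(pts)
  r <- numeric(3 * nlab + length(presc_idx) + length(axial_idx))
  for (i in seq_len(nlab)) {
    m <- vm[[i]]
    k <- m$seg
    mod <- fk$p[, k] + fk$R[[k]] %*% m$offset
    r[(3 * i - 2):(3 * i)] <- wsqrt[i] * (mod - pts[, i])
  }
  o <- 3 * nlab
  if (length(presc_idx)) {
    r[o + seq_along(presc_idx)] <- angle_wsqrt * (q[presc_idx] - presc_target)
    o <- o + length(presc_idx)
  }
  if (length(axial_idx)) r[o + 1] <- axial_wsqrt * q[axial_idx]
  r
}

# One frame: damped Gauss-Newton over free + prescribed-tracked coordinates.
ik_solve_frame_core <- function(core, vm, pts, wsqrt, q0, presc_idx,
                                presc_target, angle_wsqrt, axial_idx,
                                axial_wsqrt, max_iter, tol) {
  q <- q0
  fdh <- 1e-6
  res <- function(qq) ik_residual(core, vm, qq, pts, wsqrt, presc_idx,
                                  presc_target, angle_wsqrt, axial_idx,
                                  axial_wsqrt)
  r <- res(q)
  f <- sum(r^2)
  lambda <- 1e-6
  nq <- length(q)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), nq)
    for (k in seq_len(nq)) {
      qk <- q; qk[k] <- qk[k] + fdh
      J[, k] <- (res(qk) - r) / fdh
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (tries in 1:12) {
      step <- tryCatch(
        -solve(JtJ + lambda * diag(nq), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        qn <- q + as.numeric(step)
        rn <- res(qn)
        fn <- sum(rn^2)
        if (fn < f) {
          # accepted: solver never degrades the fit
          dmr <- sqrt(f) - sqrt(fn)
          q <- qn; r <- rn; f <- fn
          lambda <- max(lambda / 3, 1e-10)
          improved <- TRUE
          if (dmr < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(q = q, objective = f, converged = converged)
}

# Build solver context shared across frames of a stream.
ik_context <- function(model, labels, settings, kind) {
  map_kind <- if (kind == "camera") "camera" else "marker"
  vm_all <- model$virtual_markers[[map_kind]]
  if (kind == "marker") {
    # the marker pathway also tracks the estimated joint centres
    vm_all <- c(vm_all, model$virtual_markers$centers)
  }
  known <- intersect(labels, names(vm_all))
  if (!length(known)) stop("no stream label matches a virtual marker")
  w <- vapply(known, function(lb) {
    settings$marker_weights[[lb]] %||% settings$default_weight
  }, 0)
  keep <- w > 0
  known <- known[keep]; w <- w[keep]
  if (!length(known)) stop("all marker weights are zero")
  si <- model$core$seg_index
  vm <- lapply(known, function(lb) {
    m <- vm_all[[lb]]
    list(seg = si[[m$segment]], offset = m$offset)
  })
  qn <- model$core$qnames
  list(vm = vm, labels = known, wsqrt = sqrt(w),
       presc_idx = which(qn %in% model$coords$name[model$coords$prescribed]),
       axial_idx = which(qn == "shoulder_rot"),
       angle_wsqrt = sqrt(settings$angle_weight),
       axial_wsqrt = sqrt(settings$axial_rotation_prior_weight))
}

#' Solve inverse kinematics for one frame
#'
#' @param points tibble `label`, `x`, `y`, `z` of one frame's experimental
#'   points (m); missing points allowed.
#' @param model a scaled `msk_model`.
#' @param settings an [ik_settings()].
#' @param warm_start named coordinate map, deg; also the fallback for an
#'   under-determined frame.
#' @param prescribed named values (deg) of the prescribed coordinates.
#' @param kind stream kind ("marker" or "camera"), selects the label map.
#' @return list with `coords` (named deg), `residual` (weighted RMS marker
#'   error, m), `converged`, `flagged`.
#' @export
solve_ik_frame <- function(points, model, settings = ik_settings(),
                           warm_start = NULL, prescribed = NULL,
                           kind = "marker") {
  ctx <- ik_context(model, points$label, settings, kind)
  frame <- points[match(ctx$labels, points$label), ]
  solve_ik_frame_internal(frame, model, settings, ctx, warm_start, prescribed)
}

solve_ik_frame_internal <- function(frame, model, settings, ctx, warm_start,
                                    prescribed) {
  qn <- model$core$qnames
  multistart <- is.null(warm_start)
  q0 <- deg2rad(coord_map_full(model, warm_start %||% settings$initial_pose))
  ok <- !(is.na(frame$x) | is.na(frame$y) | is.na(frame$z))
  pts <- rbind(frame$x[ok], frame$y[ok], frame$z[ok])
  vm <- ctx$vm[ok]
  wsqrt <- ctx$wsqrt[ok]
  flagged <- FALSE
  if (sum(ok) < 3 || rank_deficient(pts)) {
    return(list(coords = rad2deg(stats::setNames(q0, qn)), residual = NA_real_,
                converged = FALSE, flagged = TRUE, failed = TRUE))
  }
  target <- deg2rad(vapply(qn[ctx$presc_idx], function(cn)
    prescribed[[cn]] %||% 0, 0))
  solve_from <- function(qs) {
    ik_solve_frame_core(model$core, vm, pts, wsqrt, qs, ctx$presc_idx,
                        target, ctx$angle_wsqrt, ctx$axial_idx,
                        ctx$axial_wsqrt, settings$max_iterations,
                        settings$convergence_tol)
  }
  fit <- solve_from(q0)
  if (multistart && is.null(settings$initial_pose)) {
    # no warm start: the elevation-plane / axial-rotation parametrization is
    # near-degenerate at low elevation, so probe several starting poses and
    # keep the best fit
    i_plane <- match("shoulder_elv_plane", qn)
    i_elv <- match("shoulder_elv", qn)
    i_flex <- match("elbow_flexion", qn)
    for (pl in c(-60, 0, 60)) for (el in c(20, 70)) {
      qs <- q0
      if (!is.na(i_plane)) qs[i_plane] <- deg2rad(pl)
      if (!is.na(i_elv)) qs[i_elv] <- deg2rad(el)
      if (!is.na(i_flex)) qs[i_flex] <- deg2rad(30)
      alt <- solve_from(qs)
      if (alt$objective < fit$objective - 1e-12) fit <- alt
    }
  }
  qdeg <- rad2deg(stats::setNames(fit$q, qn))
  # soft range handling: clamp and flag
  lo <- model$coords$lo[match(qn, model$coords$name)]
  hi <- model$coords$hi[match(qn, model$coords$name)]
  clamped <- qdeg < lo | qdeg > hi
  if (any(clamped)) { qdeg <- pmin(pmax(qdeg, lo), hi); flagged <- TRUE }
  # weighted RMS marker error from the marker part of the residual
  r <- ik_residual(model$core, vm, deg2rad(qdeg), pts, wsqrt, integer(),
                   numeric(), 0, integer(), 0)
  resid <- sqrt(sum(r^2) / sum(rep(wsqrt^2, each = 3)))
  # range-clamped frames are flagged but still usable; only solver failures
  # (under-determined or non-converged frames) invalidate the warm start
  list(coords = qdeg, residual = resid, converged = fit$converged,
       flagged = flagged || !fit$converged, failed = !fit$converged)
}

coord_map_full <- function(model, coords) {
  q <- stats::setNames(numeric(length(model$core$qnames)), model$core$qnames)
  if (!is.null(coords)) q[names(coords)] <- as.numeric(coords)
  q
}

rank_deficient <- function(pts) {
  if (ncol(pts) < 3) return(TRUE)
  cc <- pts - rowMeans(pts)
  s <- svd(cc, nu = 0, nv = 0)$d
  s[2] < 1e-9  # collinear
}

#' Solve inverse kinematics over a trajectory
#'
#' Frame-sequential weighted least-squares fit with previous-frame warm
#' start. The identical solver path serves the dense marker stream and the
#' sparse camera stream; only the label-to-virtual-marker map differs.
#'
#' @param stream a `trajectory_set` (for the marker pathway, bind the
#'   estimated joint centres to the stream first).
#' @param model a scaled `msk_model`.
#' @param settings an [ik_settings()].
#' @param prescribed tibble `time` + prescribed-coordinate columns (deg),
#'   e.g. from [prescribe_scapula_clavicle()]; values are interpolated onto
#'   the stream's time base.
#' @return a `pose_trajectory` with coordinate columns (deg),
#'   `residual_rms` (m) and `flagged`; attribute `unusable` is set when more
#'   than half the frames are flagged.
#' @export
solve_ik_trajectory <- function(stream, model, settings = ik_settings(),
                                prescribed = NULL) {
  stopifnot(inherits(stream, "trajectory_set"))
  kind <- traj_kind(stream)
  ctx <- ik_context(model, unique(stream$label), settings, kind)
  w <- traj_wide(stream)
  sel <- match(ctx$labels, w$labels)
  n <- length(w$times)
  qn <- model$core$qnames
  presc_names <- model$coords$name[model$coords$prescribed]
  presc_mat <- NULL
  if (!is.null(prescribed)) {
    presc_mat <- sapply(presc_names, function(cn) {
      if (!cn %in% names(prescribed)) return(rep(0, n))
      if (nrow(prescribed) == 1) return(rep(prescribed[[cn]], n))
      stats::approx(prescribed$time, prescribed[[cn]], xout = w$times,
                    rule = 2)$y
    })
    if (is.null(dim(presc_mat))) presc_mat <- matrix(presc_mat, nrow = n)
  }
  out <- matrix(NA_real_, n, length(qn), dimnames = list(NULL, qn))
  resid <- numeric(n)
  flagged <- logical(n)
  failed <- logical(n)
  warm <- settings$initial_pose
  for (i in seq_len(n)) {
    frame <- tibble::tibble(label = ctx$labels,
                            x = w$x[i, sel], y = w$y[i, sel], z = w$z[i, sel])
    presc <- if (is.null(presc_mat)) NULL else
      as.list(stats::setNames(presc_mat[i, ], presc_names))
    fit <- solve_ik_frame_internal(frame, model, settings, ctx, warm, presc)
    if (!fit$failed && is.finite(fit$residual) &&
        fit$residual > (settings$retry_residual %||% 0.15)) {
      # poor fit from the warm-started branch: retry from multiple starts
      alt <- solve_ik_frame_internal(frame, model, settings, ctx, NULL, presc)
      if (is.finite(alt$residual) && alt$residual < fit$residual) fit <- alt
    }
    out[i, ] <- fit$coords
    resid[i] <- fit$residual
    flagged[i] <- fit$flagged
    failed[i] <- fit$failed
    if (!fit$failed) warm <- fit$coords
  }
  pose <- pose_trajectory(
    tibble::as_tibble(cbind(tibble::tibble(time = w$times),
                            tibble::as_tibble(out),
                            tibble::tibble(residual_rms = resid,
                                           flagged = flagged))),
    rate = traj_rate(stream),
    meta = c(traj_meta(stream), list(ik_settings = settings)))
  if (mean(failed) > 0.5) {
    attr(pose, "unusable") <- TRUE
    warning("more than half of the frames failed to solve; trial marked unusable")
  }
  pose
}

#' Bind estimated joint centres to a marker stream
#'
#' @param markers marker `trajectory_set`.
#' @param centers output of [estimate_joint_centers()].
#' @return combined `trajectory_set`.
#' @export
bind_centers <- function(markers, centers) {
  trajectory_set(dplyr::bind_rows(markers, centers),
                 rate = traj_rate(markers), stream_kind = "marker",
                 meta = traj_meta(markers))
}
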