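#' Static-optimization settings
#'
#' @param ideal_force logical; when `TRUE` the active force-length scaling is
#'   1 regardless of fiber length (the "ideal force" mode standard
#'   musculoskeletal simulation tools offer), when `FALSE` (default) a
#'   Gaussian force-length curve of width 0.45 applies.
#' @param w_reserve quadratic penalty weight on the reserve moments that
#'   guarantee feasibility.
#' @param constrained coordinate names whose net moments the muscles must
#'   reproduce; defaults to every free coordinate spanned by at least one
#'   muscle.
#' @param moment_arm_dq finite-difference step for moment arms, deg.
#' @return an `so_settings` list.
#' @export
so_settings <- function(ideal_force = FALSE, w_reserve = 1000,
                        constrained = NULL, moment_arm_dq = 0.1) {
  structure(list(ideal_force = ideal_force, w_reserve = w_reserve,
                 constrained = constrained, moment_arm_dq = moment_arm_dq),
            class = "so_settings")
}

# path length of every muscle at pose q (radians); returns numeric vector
muscle_lengths_core <- function(model, q) {
  fk <- fk_core(model$core, q)
  si <- model$core$seg_index
  vapply(model$geometry, function(g) {
    prev <- NULL
    L <- 0
    for (p in g$path) {
      k <- si[[p$segment]]
      pt <- fk$p[, k] + fk$R[[k]] %*% p$offset
      if (!is.null(prev)) L <- L + vnorm(pt - prev)
      prev <- pt
    }
    L
  }, 0)
}

#' Musculotendon geometry at a pose
#'
#' Path lengths over the straight-line path points, tendon-excursion moment
#' arms (`-dL/dq`, central finite differences, per free coordinate), and
#' rigid-tendon fiber state: fiber length `(L - l_ts)/cos(alpha)` floored at
#' `0.01 * l_opt`, normalized length, and Gaussian active force-length
#' scaling `f_L = exp(-((lnorm - 1)/0.45)^2)` (or 1 in ideal-force mode).
#'
#' @param coords named coordinate map, deg.
#' @param model a scaled `msk_model`.
#' @param settings an [so_settings()].
#' @return list with `state` (tibble per muscle: length, fiber, lnorm, f_L,
#'   flagged) and `moment_arms` (muscles x free coordinates matrix, m/rad).
#' @export
musculotendon_geometry <- function(coords, model, settings = so_settings()) {
  q <- coord_vector(model, coords)
  qn <- model$core$qnames
  free <- qn[!model$coords$prescribed[match(qn, model$coords$name)]]
  L0 <- muscle_lengths_core(model, q)
  dq <- deg2rad(settings$moment_arm_dq)
  arms <- matrix(0, length(L0), length(free),
                 dimnames = list(names(L0), free))
  spanned <- lapply(model$geometry, `[[`, "spanned")
  for (j in seq_along(free)) {
    qi <- match(free[j], qn)
    qp <- q; qp[qi] <- qp[qi] + dq
    qm <- q; qm[qi] <- qm[qi] - dq
    arm_j <- -(muscle_lengths_core(model, qp) - muscle_lengths_core(model, qm)) / (2 * dq)
    span_j <- vapply(spanned, function(s) free[j] %in% s, TRUE)
    arms[span_j, j] <- arm_j[span_j]
  }
  mp <- model$muscles[match(names(L0), model$muscles$name), ]
  cosa <- cos(deg2rad(mp$alpha_penn))
  fiber_raw <- (L0 - mp$l_ts) / cosa
  flagged <- fiber_raw < 0.01 * mp$l_opt
  fiber <- pmax(fiber_raw, 0.01 * mp$l_opt)
  lnorm <- fiber / mp$l_opt
  f_L <- if (settings$ideal_force) rep(1, length(L0)) else
    exp(-((lnorm - 1) / 0.45)^2)
  list(state = tibble::tibble(muscle = names(L0), length = unname(L0),
                              fiber = unname(fiber), lnorm = unname(lnorm),
                              f_L = unname(f_L), flagged = unname(flagged)),
       moment_arms = arms)
}

#' Solve one static-optimization frame
#'
#' Distributes the net joint moments over the muscles by minimizing
#' `sum(a_i^2) + w_reserve * sum(r_j^2)` subject to
#' `sum_i a_i Fhat_i R_ij + r_j = M_j` and `0 <= a_i <= 1`, where
#' `Fhat_i = f_L * F_max * cos(alpha)` is the available force and `R_ij` the
#' moment arm. Solved as a box-constrained quadratic program via the exact
#' penalty form with analytic gradient.
#'
#' @param moments named numeric, N m per constrained coordinate.
#' @param geometry output of [musculotendon_geometry()].
#' @param model a scaled `msk_model`.
#' @param settings an [so_settings()].
#' @param warm_start optional activation vector.
#' @return list: `activations`, `muscle_forces` (N), `reserve_moments`
#'   (N m), `objective_value` (= sum a^2), `feasible` (all reserves within
#'   `0.01 |M_j| + 0.1` N m).
#' @export
solve_frame_so <- function(moments, geometry, model, settings = so_settings(),
                           warm_start = NULL) {
  cn <- settings$constrained %||% names(moments)
  missing_mom <- setdiff(cn, names(moments))
  if (length(missing_mom)) stop("no moment supplied for coordinate ",
                                paste(missing_mom, collapse = ", "))
  arms <- geometry$moment_arms[, cn, drop = FALSE]
  spans <- colSums(abs(arms) > 1e-12) > 0
  if (!all(spans)) {
    stop("no muscle spans constrained coordinate ",
         paste(cn[!spans], collapse = ", "))
  }
  mp <- model$muscles[match(rownames(arms), model$muscles$name), ]
  Fhat <- geometry$state$f_L * mp$f_max_iso * cos(deg2rad(mp$alpha_penn))
  A <- t(arms * Fhat)            # coords x muscles: A[j, i] = Fhat_i R_ij
  M <- as.numeric(moments[cn])
  w <- settings$w_reserve
  a <- solve_box_qp(A, M, w, warm_start)
  r <- as.numeric(M - A %*% a)
  feasible <- all(abs(r) <= 0.01 * abs(M) + 0.1)
  list(activations = stats::setNames(a, rownames(arms)),
       muscle_forces = stats::setNames(a * Fhat, rownames(arms)),
       reserve_moments = stats::setNames(r, cn),
       objective_value = sum(a^2), feasible = feasible)
}

#' Default moment-constrained coordinate set
#'
#' A free coordinate is moment-constrained only when the muscle set can
#' generate moment about it in both directions (agonist and antagonist),
#' judged from the moment arms at a mid-range pose. With the simplified
#' straight-line path set this yields the three shoulder coordinates and
#' elbow flexion; forearm pronation has single-signed arms and is left
#' unconstrained (its small net moment is not distributed over muscles).
#'
#' @param model a `msk_model`.
#' @param settings an [so_settings()].
#' @return character vector of coordinate names.
#' @export
default_constrained_coords <- function(model, settings = so_settings()) {
  probe <- c(shoulder_elv = 45, shoulder_elv_plane = 15, elbow_flexion = 60)
  for (cn in names(model$regression$rhythm)) {
    rc <- model$regression$rhythm[[cn]]
    probe[cn] <- rc$intercept + rc$slope * 45
  }
  probe <- probe[names(probe) %in% model$coords$name]
  geo <- musculotendon_geometry(probe, model, settings)
  arms <- geo$moment_arms
  keep <- apply(arms, 2, function(a) any(a > 1e-4) && any(a < -1e-4))
  colnames(arms)[keep]
}

# Exact active-set solve of the strictly convex box QP
#   min  sum(a^2) + w ||M - A a||^2   s.t.  0 <= a <= 1
# i.e. min 1/2 a' Q a - b' a with Q = 2(I + w A'A), b = 2 w A'M.
solve_box_qp <- function(A, M, w, warm_start = NULL, max_iter = 200) {
  n <- ncol(A)
  Q <- 2 * (diag(n) + w * crossprod(A))
  b <- as.numeric(2 * w * crossprod(A, M))
  a <- rep(0, n)
  state <- rep(0L, n)  # 0 free, -1 at lower, +1 at upper
  if (!is.null(warm_start) && length(warm_start) == n) {
    state[warm_start <= 1e-10] <- -1L
    state[warm_start >= 1 - 1e-10] <- 1L
    a[state == 1L] <- 1
  }
  for (it in seq_len(max_iter)) {
    fr <- which(state == 0L)
    a[state == -1L] <- 0
    a[state == 1L] <- 1
    if (length(fr)) {
      rhs <- b[fr]
      up <- which(state == 1L)
      if (length(up)) rhs <- rhs - Q[fr, up, drop = FALSE] %*% rep(1, length(up))
      a_f <- tryCatch(solve(Q[fr, fr, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(a_f)) break
      a[fr] <- as.numeric(a_f)
    }
    viol_lo <- which(state == 0L & a < -1e-12)
    viol_hi <- which(state == 0L & a > 1 + 1e-12)
    if (length(viol_lo) || length(viol_hi)) {
      state[viol_lo] <- -1L
      state[viol_hi] <- 1L
      next
    }
    # KKT: at lower bound need gradient >= 0, at upper <= 0
    g <- as.numeric(Q %*% pmin(pmax(a, 0), 1) - b)
    rel_lo <- which(state == -1L & g < -1e-9)
    rel_hi <- which(state == 1L & g > 1e-9)
    if (!length(rel_lo) && !length(rel_hi)) break
    if (length(rel_lo)) state[rel_lo[which.min(g[rel_lo])]] <- 0L
    if (length(rel_hi)) state[rel_hi[which.max(g[rel_hi])]] <- 0L
  }
  pmin(pmax(a, 0), 1)
}

#' Static optimization over a trajectory
#'
#' Frame-wise activation solve with previous-frame warm start.
#'
#' @param pose a `pose_trajectory`.
#' @param moments a `joint_moments` tibble on the same time base.
#' @param model a scaled `msk_model`.
#' @param settings an [so_settings()].
#' @return a `muscle_forces` tibble: `time`, one force column per muscle
#'   (N), `feasible`; attributes `activations` (matrix), `reserves`
#'   (matrix), `settings`. More than 10% infeasible frames sets attribute
#'   `flagged_trial`.
#' @export
solve_trajectory_so <- function(pose, moments, model, settings = so_settings()) {
  stopifnot(nrow(pose) == nrow(moments),
            max(abs(pose$time - moments$time)) < 1e-9)
  qn <- model$core$qnames
  free <- qn[!model$coords$prescribed[match(qn, model$coords$name)]]
  cn <- settings$constrained %||% default_constrained_coords(model, settings)
  settings$constrained <- cn
  n <- nrow(pose)
  muscles <- model$muscles$name
  forces <- matrix(0, n, length(muscles), dimnames = list(NULL, muscles))
  acts <- forces
  reserves <- matrix(0, n, length(cn), dimnames = list(NULL, cn))
  feas <- logical(n)
  warm <- NULL
  for (i in seq_len(n)) {
    coords <- stats::setNames(as.numeric(pose[i, qn]), qn)
    geo <- musculotendon_geometry(coords, model, settings)
    mm <- stats::setNames(as.numeric(moments[i, cn]), cn)
    sol <- solve_frame_so(mm, geo, model, settings, warm_start = warm)
    forces[i, ] <- sol$muscle_forces[muscles]
    acts[i, ] <- sol$activations[muscles]
    reserves[i, ] <- sol$reserve_moments
    feas[i] <- sol$feasible
    warm <- sol$activations
  }
  out <- structure(
    tibble::as_tibble(cbind(tibble::tibble(time = pose$time),
                            tibble::as_tibble(forces),
                            tibble::tibble(feasible = feas))),
    rate = attr(pose, "rate"), activations = acts, reserves = reserves,
    settings = settings, meta = attr(pose, "meta"),
    class = c("muscle_forces", class(tibble::tibble())))
  if (mean(!feas) > 0.10) attr(out, "flagged_trial") <- TRUE
  out
}

#' Aggregate muscle-head forces into report groups
#'
#' Sums head forces into the rows a validation table reports (e.g.
#' "Infraspinatus" = superior + inferior heads).
#'
#' @param forces a `muscle_forces` tibble.
#' @param model an `msk_model` (for the group map).
#' @param exercise `"lateral_fly"` or `"biceps_curl"`.
#' @return tibble `time` plus one summed force column per report group.
#' @export
group_forces <- function(forces, model, exercise) {
  groups <- model$report_groups[[exercise]]
  if (is.null(groups)) stop("no report groups for exercise '", exercise, "'")
  out <- tibble::tibble(time = forces$time)
  for (g in names(groups)) {
    members <- unlist(groups[[g]])
    out[[g]] <- rowSums(as.matrix(forces[, members, drop = FALSE]))
  }
  structure(out, rate = attr(forces, "rate"), meta = attr(forces, "meta"),
            class = c("muscle_forces", class(tibble::tibble())))
}
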