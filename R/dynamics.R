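#' External dumbbell load
#'
#' A hand-held dumbbell is modeled as a pure downward gravitational force at
#' the hand's centre of mass (global -Y convention; dumbbell inertia is
#' ignored). A 3 kg dumbbell gives 29.4 N, a 5 kg dumbbell 49.1 N at
#' g = 9.81 m/s^2.
#'
#' @param dumbbell_mass kg, >= 0.
#' @param g gravitational acceleration, m/s^2.
#' @return an `external_load` list with `force_vector` (N, global),
#'   `applied_segment = "hand"`, `dumbbell_mass`, `g`.
#' @examples
#' make_external_load(3)$force_vector   # c(0, -29.43, 0)
#' @export
make_external_load <- function(dumbbell_mass, g = 9.81) {
  if (!is.numeric(dumbbell_mass) || dumbbell_mass < 0) {
    stop("dumbbell_mass must be a non-negative number")
  }
  structure(list(applied_segment = "hand",
                 force_vector = c(0, -dumbbell_mass * g, 0),
                 application_point = "hand_com",
                 dumbbell_mass = dumbbell_mass, g = g),
            class = "external_load")
}

# Per-frame chain kinematics for the arm segments.
# Returns, for frames 1..n: list of fk results and, per segment of interest,
# com position (3 x n), R list, plus per-coordinate global axes/joint
# positions from fk_core(want_axes).
arm_segments <- c("humerus", "forearm", "hand")

#' Net joint moments by inverse dynamics
#'
#' Computes the generalized moments at the free coordinates (shoulder
#' elevation plane / elevation / axial rotation, elbow flexion, forearm
#' pronation) that reproduce the recorded motion under segment gravity,
#' segment inertia and the external dumbbell force at the hand's centre of
#' mass. Segment velocities and accelerations come from central finite
#' differences on low-pass-filtered coordinates (2nd-order Butterworth,
#' `smooth_cutoff` Hz, zero-phase); the filter is skipped for very short
#' series.
#'
#' @param pose a `pose_trajectory` on a uniform time base.
#' @param model a scaled `msk_model`.
#' @param load an [make_external_load()]; `NULL` for no dumbbell.
#' @param gravity global gravity vector, m/s^2.
#' @param smooth_cutoff Hz for coordinate smoothing before differentiation;
#'   `NA` disables smoothing.
#' @return a `joint_moments` tibble: `time`, one column per free coordinate
#'   (N m), and `inertial_fraction` (share of the moment vector norm due to
#'   velocity/acceleration terms).
#' @export
compute_net_moments <- function(pose, model, load = NULL,
                                gravity = c(0, -9.81, 0), smooth_cutoff = 6) {
  stopifnot(inherits(pose, "pose_trajectory"), inherits(model, "msk_model"))
  times <- pose$time
  n <- length(times)
  dt <- diff(times)
  if (n > 1 && max(abs(dt - dt[1])) > 1e-6) stop("pose time base is not uniform")
  dt <- if (n > 1) dt[1] else NA_real_
  rate <- attr(pose, "rate") %||% (1 / dt)

  qn <- model$core$qnames
  Q <- as.matrix(pose[, qn, drop = FALSE])
  if (!is.na(smooth_cutoff) && n >= 24 && rate > 2 * smooth_cutoff) {
    bf <- signal::butter(2, smooth_cutoff / (rate / 2))
    for (k in seq_len(ncol(Q))) Q[, k] <- filtfilt_padded(bf, Q[, k])
  }
  Qr <- deg2rad(Q)

  free <- !model$coords$prescribed[match(qn, model$coords$name)]
  free_idx <- which(free)
  si <- model$core$seg_index
  inr <- model$inertia
  seg_ids <- si[arm_segments]
  mass <- inr$mass[match(arm_segments, inr$segment)]
  com_l <- lapply(match(arm_segments, inr$segment), function(i)
    c(inr$com_x[i], inr$com_y[i], inr$com_z[i]))
  I_l <- lapply(match(arm_segments, inr$segment), function(i)
    diag(c(inr$i_x[i], inr$i_y[i], inr$i_z[i])))
  # the joint of each free coordinate must be proximal to all arm segments;
  # segments distal to a coordinate's joint:
  distal <- lapply(free_idx, function(qi) {
    seg <- model$coords$segment[match(qn[qi], model$coords$name)]
    k <- match(seg, model$segments)
    which(match(arm_segments, model$segments) >= k)
  })
  Fext <- if (is.null(load)) c(0, 0, 0) else load$force_vector
  hand_i <- match("hand", arm_segments)

  # frame-wise FK with axes
  fks <- vector("list", n)
  for (i in seq_len(n)) fks[[i]] <- fk_core(model$core, Qr[i, ], want_axes = TRUE)
  com <- lapply(seq_along(arm_segments), function(s) {
    sapply(seq_len(n), function(i) {
      fk <- fks[[i]]
      fk$p[, seg_ids[s]] + fk$R[[seg_ids[s]]] %*% com_l[[s]]
    })
  })
  # linear accelerations (central differences; ends use nearest interior)
  acc_of <- function(P) {
    A <- matrix(0, 3, n)
    if (n >= 3) {
      A[, 2:(n - 1)] <- (P[, 3:n] - 2 * P[, 2:(n - 1)] + P[, 1:(n - 2)]) / dt^2
      A[, 1] <- A[, 2]; A[, n] <- A[, n - 1]
    }
    A
  }
  # angular velocity/acceleration per segment
  angvel <- function(s) {
    W <- matrix(0, 3, n)
    if (n >= 3) {
      for (i in 2:(n - 1)) {
        Rd <- (fks[[i + 1]]$R[[seg_ids[s]]] - fks[[i - 1]]$R[[seg_ids[s]]]) / (2 * dt)
        W[, i] <- vee(Rd %*% t(fks[[i]]$R[[seg_ids[s]]]))
      }
      W[, 1] <- W[, 2]; W[, n] <- W[, n - 1]
    }
    W
  }
  acc <- lapply(com, acc_of)
  W <- lapply(seq_along(arm_segments), angvel)
  Wd <- lapply(W, function(wm) {
    A <- matrix(0, 3, n)
    if (n >= 3) {
      A[, 2:(n - 1)] <- (wm[, 3:n] - wm[, 1:(n - 2)]) / (2 * dt)
      A[, 1] <- A[, 2]; A[, n] <- A[, n - 1]
    }
    A
  })

  M <- matrix(0, n, length(free_idx),
              dimnames = list(NULL, qn[free_idx]))
  Mstat <- M
  for (i in seq_len(n)) {
    fk <- fks[[i]]
    for (jj in seq_along(free_idx)) {
      qi <- free_idx[jj]
      aj <- fk$axes[, qi]
      oj <- fk$jpos[, qi]
      m_full <- 0; m_stat <- 0
      for (s in distal[[jj]]) {
        cs <- com[[s]][, i]
        Rseg <- fk$R[[seg_ids[s]]]
        grav_t <- sum(aj * vcross(cs - oj, -mass[s] * gravity))
        iner_t <- sum(aj * vcross(cs - oj, mass[s] * acc[[s]][, i])) +
          sum(aj * (Rseg %*% I_l[[s]] %*% (t(Rseg) %*% Wd[[s]][, i]) +
                      vcross(W[[s]][, i],
                             as.numeric(Rseg %*% I_l[[s]] %*% (t(Rseg) %*% W[[s]][, i])))))
        m_stat <- m_stat + grav_t
        m_full <- m_full + grav_t + iner_t
        if (s == hand_i && !is.null(load)) {
          ext_t <- -sum(aj * vcross(cs - oj, Fext))
          m_stat <- m_stat + ext_t
          m_full <- m_full + ext_t
        }
      }
      M[i, jj] <- m_full
      Mstat[i, jj] <- m_stat
    }
  }
  inertial_fraction <- sqrt(rowSums((M - Mstat)^2)) /
    pmax(sqrt(rowSums(M^2)), 1e-9)
  structure(
    tibble::as_tibble(cbind(tibble::tibble(time = times), tibble::as_tibble(M),
                            tibble::tibble(inertial_fraction = inertial_fraction))),
    rate = rate, load = load,
    class = c("joint_moments", class(tibble::tibble())))
}
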