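#' Trajectory set container
#'
#' A trajectory set is a tidy tibble of labeled 3D point trajectories with
#' columns `time` (s), `label`, `x`, `y`, `z` (m; `NA` marks a missing
#' sample) and attributes `rate` (Hz), `stream_kind` (`"marker"` or
#' `"camera"`) and `meta` (subject/trial/exercise identifiers).
#'
#' @param data tibble with columns `time`, `label`, `x`, `y`, `z`.
#' @param rate sample rate in Hz; must match the time spacing.
#' @param stream_kind `"marker"` or `"camera"`.
#' @param meta named list of identifiers.
#' @return a `trajectory_set` tibble.
#' @export
trajectory_set <- function(data, rate, stream_kind = c("marker", "camera"),
                           meta = list()) {
  stream_kind <- match.arg(stream_kind)
  stopifnot(all(c("time", "label", "x", "y", "z") %in% names(data)))
  times <- sort(unique(data$time))
  if (length(times) > 1) {
    dt <- diff(times)
    if (max(abs(dt - 1 / rate)) > 1e-9) {
      stop("sample rate ", rate, " Hz does not match the time spacing")
    }
  }
  structure(tibble::as_tibble(data),
            rate = rate, stream_kind = stream_kind, meta = meta,
            class = c("trajectory_set", class(tibble::tibble())))
}

traj_rate <- function(ts) attr(ts, "rate")
traj_kind <- function(ts) attr(ts, "stream_kind")
traj_meta <- function(ts) attr(ts, "meta") %||% list()

# wide layout for fast per-frame access: list(times, labels, x/y/z matrices
# [frame, label])
traj_wide <- function(ts) {
  labels <- unique(ts$label)
  times <- sort(unique(ts$time))
  idx_t <- match(ts$time, times)
  idx_l <- match(ts$label, labels)
  mk <- function(v) {
    m <- matrix(NA_real_, length(times), length(labels),
                dimnames = list(NULL, labels))
    m[cbind(idx_t, idx_l)] <- v
    m
  }
  list(times = times, labels = labels, x = mk(ts$x), y = mk(ts$y), z = mk(ts$z))
}

traj_from_wide <- function(w, rate, stream_kind, meta = list()) {
  nl <- length(w$labels)
  nt <- length(w$times)
  trajectory_set(
    tibble::tibble(time = rep(w$times, nl),
                   label = rep(w$labels, each = nt),
                   x = as.vector(w$x), y = as.vector(w$y), z = as.vector(w$z)),
    rate = rate, stream_kind = stream_kind, meta = meta)
}

#' Mean per-joint position error between two trajectory sets
#'
#' The standard 3D pose accuracy metric: Euclidean error per label per
#' frame, averaged over everything present in both sets.
#'
#' @param ts,ref trajectory sets sharing labels and times.
#' @return mean error in m.
#' @export
mpjpe <- function(ts, ref) {
  j <- dplyr::inner_join(ts, ref, by = c("time", "label"),
                         suffix = c("", "_ref"))
  e <- sqrt((j$x - j$x_ref)^2 + (j$y - j$y_ref)^2 + (j$z - j$z_ref)^2)
  mean(e, na.rm = TRUE)
}

#' Pose trajectory container
#'
#' Generalized-coordinate time series: tibble with `time` (s) plus one column
#' per coordinate (degrees), optionally `residual_rms` (m) and `flagged`
#' from the inverse-kinematics solve. Attribute `rate` holds the sample rate.
#'
#' @param data tibble with a `time` column and coordinate columns in degrees.
#' @param rate sample rate Hz.
#' @param meta named list.
#' @return a `pose_trajectory` tibble.
#' @export
pose_trajectory <- function(data, rate, meta = list()) {
  stopifnot("time" %in% names(data))
  if (is.unsorted(data$time, strictly = TRUE)) stop("times must be strictly increasing")
  structure(tibble::as_tibble(data), rate = rate, meta = meta,
            class = c("pose_trajectory", class(tibble::tibble())))
}

pose_coord_names <- function(pose) {
  setdiff(names(pose), c("time", "residual_rms", "flagged"))
}
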