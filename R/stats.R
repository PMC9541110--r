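#' Analysis configuration for the validation statistics
#'
#' @param sync_event coordinate whose per-rep peak aligns the two methods:
#'   peak shoulder elevation (lateral fly) or peak elbow flexion (biceps
#'   curl).
#' @param window_halfwidth s on each side of the peak (default 1 s).
#' @param filter_order,filter_cutoff Butterworth low-pass applied zero-phase
#'   to the force windows (default 2nd order, 4 Hz).
#' @param target_rate Hz of the reference (marker) method; camera forces are
#'   up-sampled to it.
#' @param r_bounds increasing bounds categorizing |r| as weak / moderate /
#'   strong / excellent.
#' @param ba_loa_multiplier limits-of-agreement multiplier.
#' @param min_filter_length minimum samples a series needs before filtering.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(sync_event = c("shoulder_elv", "elbow_flexion"),
                            window_halfwidth = 1.0, filter_order = 2,
                            filter_cutoff = 4.0, target_rate = 400,
                            r_bounds = c(0.35, 0.67, 0.90),
                            ba_loa_multiplier = 1.96,
                            min_filter_length = 24) {
  sync_event <- match.arg(sync_event)
  stopifnot(filter_cutoff < target_rate / 2,
            all(diff(r_bounds) > 0), all(r_bounds > 0 & r_bounds < 1))
  structure(list(sync_event = sync_event, window_halfwidth = window_halfwidth,
                 filter_order = filter_order, filter_cutoff = filter_cutoff,
                 target_rate = target_rate, r_bounds = r_bounds,
                 ba_loa_multiplier = ba_loa_multiplier,
                 min_filter_length = min_filter_length),
            class = "analysis_config")
}

config_for_exercise <- function(exercise, ...) {
  analysis_config(sync_event = if (exercise == "lateral_fly") "shoulder_elv"
                  else "elbow_flexion", ...)
}

# local maxima of a coordinate series that rise above half its range,
# separated by at least min_sep samples
find_rep_peaks <- function(times, x, min_sep_s = 0.5) {
  n <- length(x)
  if (n < 3) return(integer())
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) < 1e-6) return(integer())
  thr <- rng[1] + 0.5 * diff(rng)
  cand <- which(x[-c(1, n)] >= x[-c(n - 1, n)] & x[-c(1, n)] > x[-(1:2)]) + 1L
  cand <- cand[x[cand] > thr]
  if (!length(cand)) return(integer())
  dt <- stats::median(diff(times))
  min_sep <- max(1L, round(min_sep_s / dt))
  keep <- integer()
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Synchronize a camera/marker force pair into per-rep windows
#'
#' For each repetition, the peak instant of the synchronization coordinate
#' is located independently in each method's pose, the peaks are aligned,
#' and a window of +/- `window_halfwidth` s is extracted on the reference
#' (marker-rate) grid. The test (camera) forces are cubic-spline up-sampled
#' onto that grid and both windows are zero-phase Butterworth filtered.
#' Reps whose window exceeds either recording are dropped.
#'
#' @param test list with `forces` (`muscle_forces`) and `pose`
#'   (`pose_trajectory`) from the camera method.
#' @param ref same for the marker-based reference method.
#' @param cfg an [analysis_config()].
#' @return long tibble: `rep`, `muscle`, `sample`, `time_rel`, `ref`,
#'   `test` (N); attribute `dropped_reps` counts windows that did not fit.
#' @export
synchronize_pair <- function(test, ref, cfg = analysis_config()) {
  sc <- cfg$sync_event
  for (side in list(test, ref)) {
    if (!sc %in% names(side$pose)) stop("sync coordinate '", sc, "' missing from pose")
  }
  pk_ref <- find_rep_peaks(ref$pose$time, ref$pose[[sc]])
  pk_test <- find_rep_peaks(test$pose$time, test$pose[[sc]])
  n_rep <- min(length(pk_ref), length(pk_test))
  if (n_rep == 0) {
    out <- tibble::tibble(rep = integer(), muscle = character(),
                          sample = integer(), time_rel = numeric(),
                          ref = numeric(), test = numeric())
    attr(out, "dropped_reps") <- 0L
    return(out)
  }
  hw <- cfg$window_halfwidth
  dt <- 1 / cfg$target_rate
  grid <- seq(-hw, hw, by = dt)
  muscles <- setdiff(intersect(names(ref$forces), names(test$forces)),
                     c("time", "feasible"))
  bf <- signal::butter(cfg$filter_order, cfg$filter_cutoff / (cfg$target_rate / 2))
  dropped <- 0L
  rows <- list()
  for (k in seq_len(n_rep)) {
    t_ref <- ref$pose$time[pk_ref[k]]
    t_test <- test$pose$time[pk_test[k]]
    if (t_ref - hw < min(ref$forces$time) - 1e-9 ||
        t_ref + hw > max(ref$forces$time) + 1e-9 ||
        t_test - hw < min(test$forces$time) - 1e-9 ||
        t_test + hw > max(test$forces$time) + 1e-9) {
      dropped <- dropped + 1L
      next
    }
    for (m in muscles) {
      rw <- resample_to_reference(ref$forces$time, ref$forces[[m]],
                                  t_ref + grid)
      tw <- resample_to_reference(test$forces$time, test$forces[[m]],
                                  t_test + grid)
      if (length(grid) >= cfg$min_filter_length) {
        rw <- filtfilt_padded(bf, rw)
        tw <- filtfilt_padded(bf, tw)
      }
      rows[[length(rows) + 1]] <-
        tibble::tibble(rep = k, muscle = m, sample = seq_along(grid),
                       time_rel = grid, ref = rw, test = tw)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(rep = integer(), muscle = character(), sample = integer(),
                   time_rel = numeric(), ref = numeric(), test = numeric())
  attr(out, "dropped_reps") <- dropped
  out
}

#' Cubic-spline resampling onto a reference grid
#'
#' @param times,values input series (>= 4 samples, strictly increasing
#'   times).
#' @param target_times output grid, s.
#' @return interpolated values; endpoints shared with the input grid are
#'   reproduced exactly.
#' @export
resample_to_reference <- function(times, values, target_times) {
  if (length(times) < 4) stop("need at least 4 samples for spline resampling")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  sf <- stats::splinefun(times, values, method = "fmm")
  sf(target_times)
}

#' Zero-phase Butterworth filtering of a force series
#'
#' Forward-backward application of the configured low-pass design (default
#' 2nd order, 4 Hz): DC gain 1, no phase distortion.
#'
#' @param series numeric force series, N.
#' @param rate sample rate Hz (> 2 x cutoff).
#' @param cfg an [analysis_config()].
#' @return filtered series.
#' @export
filter_forces <- function(series, rate, cfg = analysis_config()) {
  if (rate <= 2 * cfg$filter_cutoff) stop("sample rate must exceed twice the cutoff")
  if (length(series) < cfg$min_filter_length) {
    stop("series shorter than the filter warm-up (", cfg$min_filter_length,
         " samples)")
  }
  bf <- signal::butter(cfg$filter_order, cfg$filter_cutoff / (rate / 2))
  filtfilt_padded(bf, series)
}

#' Per-trial agreement statistics between two aligned force windows
#'
#' RMSD: the per-frame deviation is squared, averaged over the window, and
#' rooted. %Fmax expresses it relative to the summed maximum isometric force
#' of the report group. Pearson r is recorded missing for zero-variance
#' windows.
#'
#' @param test_window,ref_window equal-length numeric vectors, N.
#' @param fmax_group group maximum isometric force, N.
#' @return one-row tibble: `rmsd_N`, `rmsd_pct_fmax`, `pearson_r`,
#'   `peak_ref`, `peak_test`.
#' @export
trial_statistics <- function(test_window, ref_window, fmax_group) {
  if (length(test_window) != length(ref_window)) {
    stop("windows must have equal length")
  }
  d <- test_window - ref_window
  rmsd <- sqrt(mean(d^2))
  r <- if (stats::sd(test_window) < 1e-12 || stats::sd(ref_window) < 1e-12) {
    NA_real_
  } else {
    stats::cor(test_window, ref_window)
  }
  tibble::tibble(rmsd_N = rmsd,
                 rmsd_pct_fmax = 100 * rmsd / fmax_group,
                 pearson_r = r,
                 peak_ref = max(ref_window), peak_test = max(test_window))
}

#' Categorize a correlation coefficient
#'
#' |r| <= 0.35 weak; <= 0.67 moderate; <= 0.90 strong; above excellent.
#' @param r correlation (vectorized); `NA` stays `NA`.
#' @param bounds increasing category bounds.
#' @return character vector.
#' @export
r_category <- function(r, bounds = c(0.35, 0.67, 0.90)) {
  out <- rep(NA_character_, length(r))
  a <- abs(r)
  out[!is.na(a) & a <= bounds[1]] <- "weak"
  out[!is.na(a) & a > bounds[1] & a <= bounds[2]] <- "moderate"
  out[!is.na(a) & a > bounds[2] & a <= bounds[3]] <- "strong"
  out[!is.na(a) & a > bounds[3]] <- "excellent"
  out
}

#' Aggregate trial comparisons to a validation table
#'
#' For each muscle row: trial statistics are averaged within subject, the
#' subject means averaged (unweighted) into a grand mean, and the SD across
#' subject means reported as between-subject variation. Correlations with a
#' missing value (zero-variance windows) are excluded from the r aggregation
#' but counted.
#'
#' @param trials tibble with columns `subject`, `exercise`, `muscle`,
#'   `rmsd_N`, `rmsd_pct_fmax`, `pearson_r` (one row per trial x muscle).
#' @param r_bounds category bounds for the mean r.
#' @return tibble, one row per exercise x muscle: grand means, between-
#'   subject SDs, `r_category`, `n_subjects`, `n_trials`, `n_r_missing`.
#' @export
aggregate_trials <- function(trials, r_bounds = c(0.35, 0.67, 0.90)) {
  stopifnot(all(c("subject", "exercise", "muscle", "rmsd_N", "rmsd_pct_fmax",
                  "pearson_r") %in% names(trials)))
  sd0 <- function(x) { x <- x[!is.na(x)]; if (length(x) < 2) 0 else stats::sd(x) }
  subj <- trials |>
    dplyr::group_by(.data$exercise, .data$muscle, .data$subject) |>
    dplyr::summarise(rmsd_N = mean(.data$rmsd_N),
                     rmsd_pct_fmax = mean(.data$rmsd_pct_fmax),
                     pearson_r = mean(.data$pearson_r, na.rm = TRUE),
                     n_trials = dplyr::n(),
                     n_r_missing = sum(is.na(.data$pearson_r)),
                     .groups = "drop")
  subj$pearson_r[is.nan(subj$pearson_r)] <- NA_real_
  subj |>
    dplyr::group_by(.data$exercise, .data$muscle) |>
    dplyr::summarise(rmsd_N_sd = sd0(.data$rmsd_N),
                     rmsd_N = mean(.data$rmsd_N),
                     rmsd_pct_sd = sd0(.data$rmsd_pct_fmax),
                     rmsd_pct_fmax = mean(.data$rmsd_pct_fmax),
                     r_sd = sd0(.data$pearson_r),
                     pearson_r = mean(.data$pearson_r, na.rm = TRUE),
                     n_subjects = dplyr::n(),
                     n_trials = sum(.data$n_trials),
                     n_r_missing = sum(.data$n_r_missing),
                     .groups = "drop") |>
    dplyr::mutate(pearson_r = ifelse(is.nan(.data$pearson_r), NA_real_,
                                     .data$pearson_r),
                  r_category = r_category(.data$pearson_r, r_bounds)) |>
    dplyr::select("exercise", "muscle", "rmsd_N", "rmsd_N_sd",
                  "rmsd_pct_fmax", "rmsd_pct_sd", "pearson_r", "r_sd",
                  "r_category", "n_subjects", "n_trials", "n_r_missing")
}

#' Bland-Altman agreement of peak forces
#'
#' Differences (test - ref) against pairwise means; bias is the mean
#' difference, limits of agreement bias +/- 1.96 x sample SD (n - 1
#' denominator). Per-subject mean differences support spotting
#' between-subject inconsistency.
#'
#' @param peaks_test,peaks_ref paired peak forces, N (length >= 2).
#' @param subjects optional subject id per pair.
#' @param cfg an [analysis_config()].
#' @return a `bland_altman` object: list with `data` (tibble `mean`,
#'   `diff`, `subject`), `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `per_subject` tibble.
#' @export
bland_altman <- function(peaks_test, peaks_ref, subjects = NULL,
                         cfg = analysis_config()) {
  if (length(peaks_test) != length(peaks_ref)) {
    stop("peak lists must have equal length")
  }
  if (length(peaks_test) < 2) stop("need at least 2 pairs")
  d <- peaks_test - peaks_ref
  m <- (peaks_test + peaks_ref) / 2
  subjects <- subjects %||% rep("all", length(d))
  bias <- mean(d)
  sdd <- stats::sd(d)
  per_subject <- tibble::tibble(subject = subjects, diff = d) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(mean_diff = mean(.data$diff), n = dplyr::n(),
                     .groups = "drop")
  structure(list(
    data = tibble::tibble(mean = m, diff = d, subject = subjects),
    bias = bias, sd_diff = sdd,
    loa_lower = bias - cfg$ba_loa_multiplier * sdd,
    loa_upper = bias + cfg$ba_loa_multiplier * sdd,
    per_subject = per_subject), class = "bland_altman")
}

#' Express an RMSD as a percentage of group maximum force
#'
#' @param rmsd_N RMSD in N.
#' @param model an `msk_model`.
#' @param muscle_base_name base name; multi-head groups use the summed Fmax.
#' @return percentage of Fmax.
#' @examples
#' model <- load_default_model()
#' rmsd_pct_fmax(6.2, model, "Deltoideus posterior") # ~0.47 -> prints 0.5
#' @export
rmsd_pct_fmax <- function(rmsd_N, model, muscle_base_name) {
  100 * rmsd_N / group_f_max(model, muscle_base_name)
}

#' Convert a body-weight-relative force to Newtons
#'
#' Used for cross-study comparison of forces reported in %BW.
#'
#' @param pct_bw force in percent of body weight.
#' @param body_mass kg.
#' @param g m/s^2.
#' @return force in N.
#' @examples
#' pct_bw_to_newton(5.45, 80) # ~42.8 N, prints as 43 N
#' @export
pct_bw_to_newton <- function(pct_bw, body_mass, g = 9.81) {
  pct_bw / 100 * body_mass * g
}
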