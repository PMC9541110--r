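#' Synthetic study design
#'
#' Describes the synthetic stand-in for the validation study: subjects with
#' varying anthropometry, per-exercise trials (one set of repetitions each),
#' and the camera/marker noise model. Defaults mirror the study protocol
#' (5 subjects, 3 sets of 5 reps per exercise, 3 kg lateral-fly and 5 kg
#' biceps-curl dumbbells).
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials (sets) per subject per exercise.
#' @param n_reps repetitions per trial.
#' @param rep_duration s per repetition.
#' @param exercises character vector of exercise names.
#' @param noise a [noise_model()].
#' @param marker_rate,camera_rate stream sample rates, Hz.
#' @param anthropometry_sd sd of the per-segment log-normal-ish size factors
#'   around 1 (uniform half-width).
#' @param seed master seed; per-subject/trial seeds derive from it.
#' @return a `study_design` list.
#' @export
study_design <- function(n_subjects = 5, n_trials = 3, n_reps = 5,
                         rep_duration = 2,
                         exercises = c("lateral_fly", "biceps_curl"),
                         noise = noise_model(), anthropometry_sd = 0.05,
                         marker_rate = 400, camera_rate = 30, seed = 1L) {
  stopifnot(n_subjects >= 1, n_trials >= 1, n_reps >= 1)
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 n_reps = n_reps, rep_duration = rep_duration,
                 exercises = exercises, noise = noise,
                 anthropometry_sd = anthropometry_sd,
                 marker_rate = marker_rate, camera_rate = camera_rate,
                 seed = as.integer(seed)),
            class = "study_design")
}

# deterministic per-subject/exercise/trial seed, kept well below 2^31
trial_seed <- function(master, subject, exercise_i, trial) {
  (master * 7919L + subject * 947L + exercise_i * 101L + trial * 13L) %% 2000000011L
}

# Per-segment uniform size factors for a synthetic subject.
subject_factors <- function(model, sd, seed) {
  segs <- model$segments
  with_seed(seed, stats::setNames(stats::runif(length(segs), 1 - sd, 1 + sd),
                                  segs))
}

#' Run one measurement pathway on a trial
#'
#' Applies the full processing chain of one method (marker or camera) to a
#' rendered stream: quality control, joint-centre estimation (marker
#' pathway), static-pose scaling, rhythm-prescribed inverse kinematics,
#' inverse dynamics with the dumbbell load, and static optimization.
#'
#' @param stream the trial's `trajectory_set`.
#' @param static_stream the same subject's static-trial `trajectory_set` of
#'   the same kind.
#' @param model the generic (unscaled) `msk_model`.
#' @param dumbbell_mass kg.
#' @param ik an [ik_settings()], `so` an [so_settings()], `coeffs` a
#'   [regression_coefficients()].
#' @param so,coeffs see above.
#' @return list `pose`, `moments`, `forces`, `qc`, `scales`; or the `qc`
#'   report alone (with `$excluded = TRUE`) when QC rejects the trial.
#' @export
run_pathway <- function(stream, static_stream, model, dumbbell_mass,
                        ik = ik_settings(), so = so_settings(),
                        coeffs = NULL) {
  kind <- traj_kind(stream)
  coeffs <- coeffs %||% regression_coefficients(model)
  qc <- if (kind == "marker") qc_marker_trial(stream) else qc_camera_trial(stream)
  if (!qc$included) return(list(qc = qc, excluded = TRUE))
  if (kind == "marker") {
    centers <- estimate_joint_centers(stream, coeffs)
    stream <- bind_centers(stream, centers)
    elev_src <- centers
  } else {
    elev_src <- stream
  }
  scales <- compute_scales(static_stream, model)
  scaled <- apply_scales(model, scales)
  prescribed <- prescribe_scapula_clavicle(estimate_elevation(elev_src), coeffs)
  pose <- solve_ik_trajectory(stream, scaled, ik, prescribed)
  if (isTRUE(attr(pose, "unusable"))) {
    qc$included <- FALSE
    qc$reason <- "ik_unusable"
    return(list(qc = qc, excluded = TRUE))
  }
  load <- make_external_load(dumbbell_mass)
  moments <- compute_net_moments(pose, scaled, load)
  forces <- solve_trajectory_so(pose, moments, scaled, so)
  list(pose = pose, moments = moments, forces = forces, qc = qc,
       scales = scales, excluded = FALSE)
}

#' Compare the two pathways of one trial
#'
#' Synchronizes the camera-method and marker-method force trajectories rep
#' by rep and computes per-report-row agreement statistics.
#'
#' @param camera,marker pathway results from [run_pathway()].
#' @param model an `msk_model`.
#' @param exercise exercise name (selects report rows and sync event).
#' @param cfg optional [analysis_config()].
#' @return tibble: one row per rep x report row with RMSD (N, %Fmax),
#'   Pearson r and peak forces; attribute `windows` carries the aligned
#'   windows.
#' @export
compare_trial <- function(camera, marker, model, exercise, cfg = NULL) {
  cfg <- cfg %||% config_for_exercise(exercise)
  gtest <- group_forces(camera$forces, model, exercise)
  gref <- group_forces(marker$forces, model, exercise)
  win <- synchronize_pair(list(forces = gtest, pose = camera$pose),
                          list(forces = gref, pose = marker$pose), cfg)
  groups <- model$report_groups[[exercise]]
  fmax <- vapply(groups, function(members)
    sum(model$muscles$f_max_iso[match(unlist(members), model$muscles$name)]), 0)
  if (nrow(win) == 0) {
    stats <- tibble::tibble(rep = integer(), muscle = character(),
                            rmsd_N = numeric(), rmsd_pct_fmax = numeric(),
                            pearson_r = numeric(), peak_ref = numeric(),
                            peak_test = numeric())
  } else {
    stats <- win |>
      dplyr::group_by(.data$rep, .data$muscle) |>
      dplyr::group_modify(function(d, key)
        trial_statistics(d$test, d$ref, fmax[[key$muscle]])) |>
      dplyr::ungroup()
  }
  attr(stats, "windows") <- win
  stats
}

#' Run the full synthetic validation study
#'
#' For every subject and trial: generate ground-truth kinematics, render
#' both measurement streams, run both pathways (QC, scaling, IK, ID, SO)
#' and compare them; then aggregate trial statistics to subject means and a
#' grand mean with between-subject SD, and compute Bland-Altman agreement
#' of per-rep peak forces for the prime movers.
#'
#' @param design a [study_design()].
#' @param model the generic `msk_model`.
#' @param ik,so,cfg optional settings overrides.
#' @param out_dir optional directory; when given, every trial's rendered
#'   streams (TRC), solved coordinates, net moments and muscle forces
#'   (STO) plus the aggregated report and exclusion log (TSV) are written
#'   there, so the pipeline can be restarted or inspected from any stage.
#' @param verbose print per-trial progress lines.
#' @return a `validation_report`: list with `table` (aggregated per-muscle
#'   statistics), `trials` (per-trial rows), `bland_altman` (per prime
#'   mover), `exclusions` (every generated trial with status and reason)
#'   and `design`.
#' @export
run_study <- function(design, model = load_default_model(), ik = ik_settings(),
                      so = so_settings(), cfg = NULL, out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  trial_rows <- list()
  excl <- list()
  peaks <- list()
  for (s in seq_len(design$n_subjects)) {
    fac <- subject_factors(model, design$anthropometry_sd,
                           trial_seed(design$seed, s, 0L, 0L))
    subject_model <- scale_segments(model, fac)
    static_truth <- generate_static_trial(subject_model, rate = design$marker_rate)
    nz <- design$noise
    static_marker <- render_marker_stream(static_truth, subject_model,
                                          noise_model(marker_noise_sigma = nz$marker_noise_sigma,
                                                      dropout_prob = 0, failure_prob = 0,
                                                      sigma_xy = 0, seed = nz$seed + s))
    static_camera <- render_camera_stream(static_truth, subject_model,
                                          noise_model(sigma_xy = nz$sigma_xy,
                                                      sigma_depth_multiplier = nz$sigma_depth_multiplier,
                                                      temporal_corr = nz$temporal_corr,
                                                      failure_prob = 0, dropout_prob = 0,
                                                      marker_noise_sigma = 0,
                                                      seed = nz$seed + 31L * s),
                                          rate = design$camera_rate)
    for (ei in seq_along(design$exercises)) {
      ex <- design$exercises[ei]
      for (tr in seq_len(design$n_trials)) {
        sd_tr <- trial_seed(design$seed, s, ei, tr)
        id <- sprintf("S%02d_%s_T%d", s, ex, tr)
        profile <- exercise_profile(ex, n_sets = 1, n_reps = design$n_reps,
                                    rep_duration = design$rep_duration,
                                    rest_duration = 0)
        truth <- generate_ground_truth(profile, subject_model, seed = sd_tr,
                                       rate = design$marker_rate)
        tr_noise <- nz; tr_noise$seed <- sd_tr
        markers <- render_marker_stream(truth, subject_model, tr_noise)
        centers <- render_camera_stream(truth, subject_model, tr_noise,
                                        rate = design$camera_rate)
        attr(markers, "meta")$trial <- id
        attr(centers, "meta")$trial <- id
        mk <- run_pathway(markers, static_marker, model, profile$dumbbell_mass,
                          ik, so)
        cm <- run_pathway(centers, static_camera, model, profile$dumbbell_mass,
                          ik, so)
        status <- if (mk$excluded) paste0("marker:", mk$qc$reason)
        else if (cm$excluded) paste0("camera:", cm$qc$reason) else "ok"
        excl[[id]] <- tibble::tibble(trial = id, subject = s, exercise = ex,
                                     included = status == "ok", reason = status)
        if (!is.null(out_dir)) {
          write_trc(markers, file.path(out_dir, paste0(id, "_markers.trc")))
          write_trc(centers, file.path(out_dir, paste0(id, "_camera.trc")))
          write_sto(tibble::as_tibble(truth),
                    file.path(out_dir, paste0(id, "_truth.sto")),
                    name = "ground_truth_coordinates")
          if (!mk$excluded && !cm$excluded) {
            for (side in list(list(tag = "marker", p = mk),
                              list(tag = "camera", p = cm))) {
              base <- file.path(out_dir, paste0(id, "_", side$tag))
              write_sto(tibble::as_tibble(side$p$pose),
                        paste0(base, "_ik.sto"), name = "coordinates")
              write_sto(tibble::as_tibble(side$p$moments),
                        paste0(base, "_id.sto"), name = "net_moments",
                        in_degrees = FALSE)
              forces_out <- dplyr::bind_cols(
                tibble::as_tibble(side$p$forces)[setdiff(names(side$p$forces), "feasible")],
                group_forces(side$p$forces, model, ex)[-1])
              write_sto(forces_out, paste0(base, "_so.sto"),
                        name = "muscle_forces", in_degrees = FALSE)
            }
          }
        }
        if (verbose) message(id, " -> ", status)
        if (status != "ok") next
        tr_cfg <- cfg %||% config_for_exercise(ex, target_rate = design$marker_rate)
        st <- compare_trial(cm, mk, model, ex, tr_cfg)
        if (nrow(st) == 0) {
          excl[[id]]$included <- FALSE
          excl[[id]]$reason <- "no_aligned_repetitions"
          next
        }
        st$subject <- s; st$exercise <- ex; st$trial <- id
        trial_rows[[id]] <- st
        pm <- model$report_groups$prime_movers[[ex]]
        pk <- st[st$muscle %in% unlist(pm), c("muscle", "rep", "peak_ref", "peak_test")]
        pk$subject <- s; pk$exercise <- ex
        peaks[[id]] <- pk
      }
    }
  }
  trials <- dplyr::bind_rows(trial_rows)
  exclusions <- dplyr::bind_rows(excl)
  table <- if (nrow(trials)) aggregate_trials(trials) else NULL
  ba <- list()
  if (length(peaks)) {
    pk <- dplyr::bind_rows(peaks)
    for (m in unique(pk$muscle)) {
      sub <- pk[pk$muscle == m, ]
      if (nrow(sub) >= 2) {
        ba[[m]] <- bland_altman(sub$peak_test, sub$peak_ref,
                                subjects = sub$subject)
      }
    }
  }
  if (!is.null(out_dir)) {
    utils::write.table(exclusions, file.path(out_dir, "exclusions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(table)) {
      utils::write.table(table, file.path(out_dir, "report_table.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  structure(list(table = table, trials = trials, bland_altman = ba,
                 exclusions = exclusions, design = design),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (!is.null(x$exclusions)) {
    cat(sprintf("  trials: %d generated, %d included, %d excluded\n",
                nrow(x$exclusions), sum(x$exclusions$included),
                sum(!x$exclusions$included)))
  }
  if (!is.null(x$table)) {
    tab <- x$table
    cat("  per-muscle grand means (RMSD N / %Fmax / r):\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-12s %-28s %6.1f +- %4.1f N  %4.1f%%  r=%s (%s)\n",
                  tab$exercise[i], tab$muscle[i],
                  round_half_up(tab$rmsd_N[i], 1), round_half_up(tab$rmsd_N_sd[i], 1),
                  round_half_up(tab$rmsd_pct_fmax[i], 1),
                  ifelse(is.na(tab$pearson_r[i]), "NA",
                         sprintf("%.2f", tab$pearson_r[i])),
                  ifelse(is.na(tab$r_category[i]), "-", tab$r_category[i])))
    }
  }
  invisible(x)
}
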