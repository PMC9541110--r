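#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return the per-muscle statistics table as a tibble.
#' @export
tidy.validation_report <- function(x, ...) {
  x$table %||% tibble::tibble()
}

#' One-row summary of a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return tibble with trial counts and overall mean statistics.
#' @export
glance.validation_report <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    n_trials_generated = nrow(x$exclusions),
    n_trials_included = sum(x$exclusions$included),
    n_trials_excluded = sum(!x$exclusions$included),
    mean_rmsd_N = if (is.null(tab)) NA_real_ else mean(tab$rmsd_N),
    mean_rmsd_pct_fmax = if (is.null(tab)) NA_real_ else mean(tab$rmsd_pct_fmax),
    mean_r = if (is.null(tab)) NA_real_ else mean(tab$pearson_r, na.rm = TRUE))
}

#' Tidy Bland-Altman results
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @return tibble of paired means and differences.
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' One-row Bland-Altman summary
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @return tibble with bias, SD of differences and limits of agreement.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 n = nrow(x$data))
}

#' Bland-Altman plot
#'
#' @param object a `bland_altman` object.
#' @param ... unused.
#' @return a ggplot: differences against pairwise means with bias and
#'   limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$diff,
                               colour = factor(.data$subject))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of methods (N)", y = "Camera - marker (N)",
                  colour = "Subject") +
    ggplot2::theme_minimal()
}

#' Muscle force trajectory plot
#'
#' @param object a `muscle_forces` tibble.
#' @param muscles optional subset of force columns.
#' @param ... unused.
#' @return a ggplot of force against time, one facet per muscle.
#' @export
autoplot.muscle_forces <- function(object, muscles = NULL, ...) {
  cols <- setdiff(names(object), c("time", "feasible"))
  if (!is.null(muscles)) cols <- intersect(cols, muscles)
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("time", cols)],
                              -"time", names_to = "muscle",
                              values_to = "force")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Muscle force (N)") +
    ggplot2::theme_minimal()
}

#' Validation-report summary plot
#'
#' @param object a `validation_report`.
#' @param ... unused.
#' @return a ggplot: grand-mean RMSD per report row with between-subject SD
#'   error bars, faceted by exercise.
#' @export
autoplot.validation_report <- function(object, ...) {
  tab <- object$table
  if (is.null(tab)) stop("report has no included trials")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$muscle, y = .data$rmsd_N)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rmsd_N - .data$rmsd_N_sd,
                                        ymax = .data$rmsd_N + .data$rmsd_N_sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~exercise, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RMSD (N)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
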