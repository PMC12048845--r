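## broom-style tidiers and ggplot2 methods for the result containers.

#' Tidy a decision summary into the outcome table
#'
#' @param x A `decision_summary`.
#' @param ... Unused.
#' @return A tibble with one row per outcome and columns `without_noac`,
#'   `with_noac`, `difference` (with minus without) and `per_patient`.
#' @method tidy decision_summary
#' @export
tidy.decision_summary <- function(x, ...) x$table

#' One-row summary of a decision comparison
#'
#' @param x A `decision_summary`.
#' @param ... Unused.
#' @return A one-row tibble: per-patient QALY and life-year differences,
#'   cohort size, horizon and engine mode.
#' @method glance decision_summary
#' @export
glance.decision_summary <- function(x, ...) {
  t <- x$table
  tibble::tibble(
    qaly_diff_per_patient = t$per_patient[t$outcome == "qalys"],
    life_year_diff_per_patient = t$per_patient[t$outcome == "life_years"],
    n_patients = x$n_patients,
    horizon = x$horizon,
    mode = x$mode
  )
}

#' @rdname tidy.decision_summary
#' @method tidy arm_result
#' @export
tidy.arm_result <- function(x, ...) {
  tibble::tibble(metric = names(x$totals), value = unlist(x$totals))
}

#' @rdname tidy.decision_summary
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$iterations

#' @rdname glance.decision_summary
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) summarize_psa(x)

#' Plot cumulative QALY curves for both decision arms
#'
#' Mean cumulative quality-adjusted life-years per patient by model cycle,
#' one curve per arm.
#'
#' @param object A `decision_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decision_summary
#' @export
autoplot.decision_summary <- function(object, ...) {
  n <- object$n_patients
  traj <- dplyr::bind_rows(
    dplyr::mutate(object$without$trajectories, arm = "Without NOAC"),
    dplyr::mutate(object$with_noac$trajectories, arm = "With NOAC")
  )
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$cycle / 12,
                                     y = .data$cum_qalys / n,
                                     colour = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Years", y = "Mean cumulative QALYs per patient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of PSA QALY differences
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot histogram of per-patient QALY differences across
#'   iterations, with zero marked.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$iterations, ggplot2::aes(x = .data$qaly_diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "QALY difference per patient (NOAC - no NOAC)",
                  y = "Iterations") +
    ggplot2::theme_minimal()
}

#' Bar chart of cumulative event counts by arm
#'
#' @param summary A `decision_summary`.
#' @return A ggplot.
#' @export
plot_event_incidence <- function(summary) {
  stopifnot(inherits(summary, "decision_summary"))
  t <- summary$table
  t <- t[t$outcome %in% c("ischemic_stroke", "hemorrhagic_stroke",
                          "other_intracranial_bleeding",
                          "extracranial_major_bleeding", "deaths"), ]
  long <- tidyr::pivot_longer(t[, c("outcome", "without_noac", "with_noac")],
                              cols = c("without_noac", "with_noac"),
                              names_to = "arm", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome, y = .data$count,
                                     fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = sprintf("Events per %d patients",
                                        summary$n_patients), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
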