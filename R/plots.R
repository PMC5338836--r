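#' Age-stage survival curves
#'
#' One curve of `s_xj` against age per stage (egg, larva, pupa, female
#' and male adults). Overlapping supports between consecutive stages
#' reflect between-individual variation in development time — the feature
#' the age-stage framework exists to keep visible.
#'
#' @param schedules A `schedule_set`.
#' @return A ggplot object.
#' @export
plot_survival <- function(schedules) {
  stopifnot(inherits(schedules, "schedule_set"))
  df <- schedules$survival
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$s,
                                   colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Age (days)", y = expression(s[xj]),
      colour = "Stage",
      title = paste0("Age-stage-specific survival (", schedules$label, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Age-specific survival and fecundity curves
#'
#' `l_x` (survival), `f_x` (daily eggs per female) and `m_x` (population
#' daily fecundity) against age, with fecundities on their own panel since
#' their scale is eggs/day rather than a probability.
#'
#' @param schedules A `schedule_set`.
#' @return A ggplot object.
#' @export
plot_rates <- function(schedules) {
  stopifnot(inherits(schedules, "schedule_set"))
  df <- tidyr::pivot_longer(schedules$rates, -"age",
                            names_to = "series", values_to = "value")
  df$panel <- ifelse(df$series == "lx", "survival", "fecundity (eggs/day)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "Age (days)", y = NULL, colour = NULL,
      title = paste0("Age-specific schedules (", schedules$label, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_survival
#' @param object A `schedule_set`.
#' @param which `"survival"` for the age-stage curves, `"rates"` for
#'   `l_x`/`f_x`/`m_x`.
#' @param ... Unused.
#' @export
autoplot.schedule_set <- function(object, which = c("survival", "rates"),
                                  ...) {
  which <- match.arg(which)
  if (which == "survival") plot_survival(object) else plot_rates(object)
}

#' Bootstrap distribution histogram
#'
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(
      x = object$statistic, y = "resamples",
      title = sprintf("Bootstrap distribution of %s (%s), B = %d",
                      object$statistic, object$label, object$B)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
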