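#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a bootstrap result into one row per resample
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A tibble with columns `statistic`, `resample`, `value`.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble(statistic = x$statistic, resample = seq_len(x$B), value = x$values)
}

#' One-row summary of a bootstrap result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A tibble with `label`, `statistic`, `mean`, `se`,
#'   `valid_count`, `B`.
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(label = x$label, statistic = x$statistic, mean = x$mean,
         se = x$se, valid_count = x$valid_count, B = x$B)
}

#' Tidy a group comparison into one row per group
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The `groups` tibble (`group`, `mean`, `se`, `valid_count`,
#'   `letters`) with a `statistic` column prepended.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$groups, statistic = x$statistic, .before = 1)
}

#' Tidy a paired bootstrap test
#'
#' @param x A `paired_bootstrap_test`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, CI and significance flag.
#' @export
tidy.paired_bootstrap_test <- function(x, ...) {
  tibble(statistic = x$statistic, group_a = x$groups[1],
         group_b = x$groups[2], estimate = x$estimate,
         conf_low = x$ci[1], conf_high = x$ci[2], alpha = x$alpha,
         significant = x$significant, n_pairs = x$n_pairs)
}

#' Tidy a schedule set into one long table
#'
#' @param x A `schedule_set`.
#' @param ... Unused.
#' @return A tibble with columns `label`, `age`, `series` (a stage name
#'   for `s_xj` rows, or `lx` / `fx` / `mx`) and `value`.
#' @export
tidy.schedule_set <- function(x, ...) {
  surv <- tibble(label = x$label, age = x$survival$age,
                 series = as.character(x$survival$stage),
                 value = x$survival$s)
  rates <- tidyr::pivot_longer(x$rates, -"age", names_to = "series",
                               values_to = "value")
  rates <- dplyr::mutate(rates, label = x$label, .before = 1)
  dplyr::bind_rows(surv, rates)
}
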