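ALL_STAGES <- c("egg", "larva", "pupa", "female_adult", "male_adult")

# Stage entry ages per record: an individual with durations (d_egg, d_larva,
# ...) occupies egg at ages 0..d_egg-1, larva at d_egg..d_egg+d_larva-1, etc.
# Age 0 is the day of oviposition.
stage_intervals <- function(cohort) {
  d <- cbind(cohort$egg_days, cohort$larva_days,
             cohort$pupa_days, cohort$adult_days)
  d0 <- d
  d0[is.na(d0)] <- 0L
  ends <- t(apply(d0, 1, cumsum))
  starts <- ends - d0
  list(starts = starts, ends = ends, present = !is.na(d))
}

# Number alive in a stage at each age 0..max_age, from half-open intervals
# [start, end), via a difference array.
interval_counts <- function(starts, ends, max_age) {
  nb <- max_age + 2L
  inc <- tabulate(starts + 1L, nbins = nb)
  dec <- tabulate(ends + 1L, nbins = nb)
  cumsum(inc - dec)[seq_len(max_age + 1L)]
}

#' Age-stage survival schedule
#'
#' Computes the age-stage-specific survival rate `s_xj`: the probability
#' that a newly oviposited egg is alive at age `x` (days) and in stage `j`,
#' estimated as the number of individuals alive at that age in that stage
#' divided by the initial cohort size `N`. Adult females and males are
#' distinct stages, which is what makes the life table two-sex: male
#' survival shapes `l_x` alongside female survival and fecundity.
#'
#' @param cohort A [cohort_study()].
#' @return A tibble with columns `age`, `stage`, `s`, covering ages
#'   `0..max_age` for every stage entered by at least one individual.
#' @export
age_stage_survival <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_study"))
  n <- nrow(cohort)
  iv <- stage_intervals(cohort)
  lifespans <- iv$ends[cbind(seq_len(n), apply(iv$present, 1, function(p) max(which(p))))]
  max_age <- max(lifespans) - 1L

  stage_of <- function(k) {
    if (k < 4L) return(rep(STAGES[k], n))
    ifelse(cohort$sex == "female", "female_adult", "male_adult")
  }
  pieces <- list()
  for (k in 1:4) {
    in_stage <- iv$present[, k]
    if (!any(in_stage)) next
    labels <- stage_of(k)[in_stage]
    for (lab in unique(labels)) {
      sel <- which(in_stage)[labels == lab]
      cnt <- interval_counts(iv$starts[sel, k], iv$ends[sel, k], max_age)
      pieces[[lab]] <- tibble(age = 0:max_age, stage = lab, s = cnt / n)
    }
  }
  out <- dplyr::bind_rows(pieces)
  out$stage <- factor(out$stage, levels = ALL_STAGES)
  dplyr::arrange(out, .data$age, .data$stage)
}

#' Age-stage fecundity schedule
#'
#' Computes `f_xj`, the mean daily egg output of an individual of age `x`
#' in stage `j`. Eggs are credited to the laying female, so `f` is nonzero
#' only for the `female_adult` stage: `f_x` is the total eggs laid at age
#' `x` divided by the number of females alive (as adults) at that age.
#'
#' @param cohort A [cohort_study()].
#' @return A tibble with columns `age` and `fx` (eggs/female/day), over
#'   ages `0..max_age`.
#' @export
age_stage_fecundity <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_study"))
  surv <- age_stage_survival(cohort)
  max_age <- max(surv$age)
  eggsum <- egg_totals_by_age(cohort, max_age)
  fem <- surv[surv$stage == "female_adult", ]
  fem_count <- numeric(max_age + 1L)
  if (nrow(fem) > 0) fem_count[fem$age + 1L] <- fem$s * nrow(cohort)
  fx <- ifelse(fem_count > 0, eggsum / fem_count, 0)
  tibble(age = 0:max_age, fx = fx)
}

# Total eggs laid in the cohort at each age 0..max_age.
egg_totals_by_age <- function(cohort, max_age) {
  eggsum <- numeric(max_age + 1L)
  iv <- stage_intervals(cohort)
  fem <- which(cohort$sex == "female")
  for (i in fem) {
    eggs <- cohort$daily_eggs[[i]]
    if (length(eggs) == 0 || sum(eggs) == 0) next
    ages <- iv$starts[i, 4] + seq_along(eggs) - 1L
    eggsum[ages + 1L] <- eggsum[ages + 1L] + eggs
  }
  eggsum
}

#' Full schedule set for a cohort
#'
#' Bundles the age-stage survival matrix `s_xj` with the derived
#' age-specific schedules: survival `l_x = sum_j s_xj`, female daily
#' fecundity `f_x`, and the population fecundity
#' `m_x = sum_j s_xj f_xj / sum_j s_xj` (zero where no one is alive).
#' These are the inputs to the population parameters: `R0 = sum l_x m_x`,
#' `GRR = sum m_x`, and the Euler-Lotka equation for `r`.
#'
#' @param cohort A [cohort_study()].
#' @return A `schedule_set` object: a list with `survival` (tibble `age`,
#'   `stage`, `s`), `rates` (tibble `age`, `lx`, `fx`, `mx`), `n` (initial
#'   cohort size), `max_age` and `label`.
#' @export
#' @examples
#' ch <- simulate_cohort(preset_params("27C"), seed = 1)
#' s <- life_schedules(ch)
#' head(s$rates)
life_schedules <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_study"))
  n <- nrow(cohort)
  surv <- age_stage_survival(cohort)
  max_age <- max(surv$age)
  lx <- surv |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(lx = sum(.data$s), .groups = "drop")
  fec <- age_stage_fecundity(cohort)
  eggsum <- egg_totals_by_age(cohort, max_age)
  # m_x = (s_{x,fem} * f_x) / l_x, i.e. total eggs at age x over all alive
  mx <- ifelse(lx$lx > 0, eggsum / (n * lx$lx), 0)
  rates <- tibble(age = 0:max_age, lx = lx$lx, fx = fec$fx, mx = mx)
  structure(
    list(survival = surv, rates = rates, n = n, max_age = max_age,
         label = cohort_label(cohort)),
    class = "schedule_set"
  )
}

#' @export
print.schedule_set <- function(x, ...) {
  cat("<schedule_set>", x$label, "- N:", x$n, " max age:", x$max_age, "days\n")
  cat("  R0 =", format(sum(x$rates$lx * x$rates$mx), digits = 4), "\n")
  invisible(x)
}

#' Cohort summary statistics
#'
#' Per-cohort means of the quantities reported in rearing studies, with
#' the field's conventions on who enters each mean:
#' \describe{
#'   \item{egg_days, larva_days, pupa_days}{over individuals *completing*
#'     the stage (entering the next one).}
#'   \item{preadult_days}{egg+larva+pupa duration, over individuals
#'     reaching adulthood.}
#'   \item{immature_mortality}{`1 - adults / N`.}
#'   \item{adult_longevity_*, lifespan_*}{adult days and egg-to-death
#'     lifespan, by sex.}
#'   \item{apop}{adult pre-oviposition period: the adult day (1-based) of a
#'     female's first egg, over females that laid.}
#'   \item{tpop}{total pre-oviposition period: pre-adult duration + APOP.}
#'   \item{oviposition_days}{number of adult days with at least one egg,
#'     over females that laid.}
#'   \item{fecundity}{lifetime eggs per female, over *all* adult females
#'     (zero-layers included).}
#' }
#'
#' @param cohort A [cohort_study()].
#' @return A tibble with columns `statistic`, `n` (individuals entering the
#'   mean) and `value`. Statistics over empty subsets have `n = 0` and
#'   `value = NA`.
#' @export
cohort_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_study"))
  feats <- cohort_features(cohort)
  stats <- summary_stat_names()
  vals <- vapply(stats, function(s) eval_statistic(s, feats, seq_len(feats$n)),
                 numeric(1))
  ns <- vapply(stats, function(s) stat_subset_size(s, feats, seq_len(feats$n)),
               integer(1))
  tibble(statistic = stats, n = unname(ns), value = unname(vals))
}
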