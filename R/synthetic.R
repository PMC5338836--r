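#' Generator parameters for a synthetic cohort
#'
#' The generator draws, per individual: stage durations as
#' `1 + round(Gamma)` with the given mean and SD (SD 0 gives a fixed
#' integer duration — every egg hatches on the same day); per-stage
#' completion as Bernoulli trials with the given probabilities (the death
#' day within a failed stage is uniform over that stage's drawn duration);
#' sex as Bernoulli(`p_female`) among emerging adults; adult longevity by
#' sex; lifetime fecundity as negative binomial with mean
#' `fecundity_mean` and dispersion `fecundity_size` (large size is
#' near-Poisson); a first laying day of `1 + Poisson(apop_mean - 1)` adult
#' days; and `1 + Poisson(ovi_days_mean - 1)` consecutive laying days over
#' which the eggs are spread multinomially (each laying day gets at least
#' one egg when enough eggs exist).
#'
#' @param label Cohort label.
#' @param n Initial number of eggs.
#' @param egg_mean,egg_sd,larva_mean,larva_sd,pupa_mean,pupa_sd Duration
#'   means/SDs (days) for the immature stages.
#' @param egg_surv,larva_surv,pupa_surv Per-stage completion
#'   probabilities; their product is the expected adult fraction.
#' @param p_female Probability a surviving adult is female.
#' @param adult_mean_f,adult_sd_f,adult_mean_m,adult_sd_m Adult longevity
#'   (days) by sex.
#' @param apop_mean Mean adult pre-oviposition period (days, >= 1).
#' @param ovi_days_mean Mean number of laying days (>= 1).
#' @param fecundity_mean Mean lifetime eggs per female.
#' @param fecundity_size Negative-binomial size (overdispersion) of
#'   lifetime fecundity.
#' @return A `generator_params` list.
#' @export
generator_params <- function(label = "synthetic", n = 100,
                             egg_mean = 4, egg_sd = 0.5,
                             larva_mean = 15, larva_sd = 2,
                             pupa_mean = 5, pupa_sd = 1,
                             egg_surv = 0.8, larva_surv = 0.7,
                             pupa_surv = 0.8, p_female = 0.5,
                             adult_mean_f = 4, adult_sd_f = 1,
                             adult_mean_m = 4, adult_sd_m = 1,
                             apop_mean = 2, ovi_days_mean = 2,
                             fecundity_mean = 200, fecundity_size = 3) {
  p <- list(label = label, n = n,
            egg_mean = egg_mean, egg_sd = egg_sd,
            larva_mean = larva_mean, larva_sd = larva_sd,
            pupa_mean = pupa_mean, pupa_sd = pupa_sd,
            egg_surv = egg_surv, larva_surv = larva_surv,
            pupa_surv = pupa_surv, p_female = p_female,
            adult_mean_f = adult_mean_f, adult_sd_f = adult_sd_f,
            adult_mean_m = adult_mean_m, adult_sd_m = adult_sd_m,
            apop_mean = apop_mean, ovi_days_mean = ovi_days_mean,
            fecundity_mean = fecundity_mean,
            fecundity_size = fecundity_size)
  validate_generator_params(p)
}

validate_generator_params <- function(p) {
  probs <- c(p$egg_surv, p$larva_surv, p$pupa_surv, p$p_female)
  if (any(probs < 0 | probs > 1)) {
    abort("survival probabilities and p_female must lie in [0, 1]")
  }
  means <- c(p$egg_mean, p$larva_mean, p$pupa_mean,
             p$adult_mean_f, p$adult_mean_m, p$apop_mean, p$ovi_days_mean)
  if (any(means < 1)) {
    abort("duration means (incl. apop_mean, ovi_days_mean) must be >= 1 day")
  }
  sds <- c(p$egg_sd, p$larva_sd, p$pupa_sd, p$adult_sd_f, p$adult_sd_m)
  if (any(sds < 0)) abort("duration SDs must be >= 0")
  if (p$n < 1) abort("n must be >= 1")
  if (p$fecundity_mean < 0 || p$fecundity_size <= 0) {
    abort("fecundity_mean must be >= 0 and fecundity_size > 0")
  }
  structure(p, class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params>", x$label, "- n:", x$n,
      " adult fraction:", format(x$egg_surv * x$larva_surv * x$pupa_surv,
                                 digits = 3),
      " fecundity:", x$fecundity_mean, "\n")
  invisible(x)
}

#' Preset generator parameters for the six temperature treatments
#'
#' Returns parameters calibrated to the rearing summaries of the six
#' constant temperatures (21-36 degrees C): stage-duration means and
#' stage completion fractions, sex ratio among adults, adult longevities,
#' APOP, laying-day counts and mean lifetime fecundities. Presets live in
#' an editable YAML file, `system.file("extdata", "presets.yaml",
#' package = "twosexlt")`.
#'
#' @param treatment One of `"21C"`, `"24C"`, `"27C"`, `"30C"`, `"33C"`,
#'   `"36C"`.
#' @param file Optional path to an alternative preset YAML.
#' @return A [generator_params()] object.
#' @export
#' @examples
#' preset_params("27C")
preset_params <- function(treatment, file = NULL) {
  file <- file %||% system.file("extdata", "presets.yaml",
                                package = "twosexlt")
  presets <- yaml::read_yaml(file)
  if (!treatment %in% names(presets)) {
    abort(paste0("unknown treatment '", treatment, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  }
  validate_generator_params(presets[[treatment]])
}

#' Names of the shipped treatment presets
#' @return Character vector of treatment labels.
#' @export
preset_names <- function() {
  names(yaml::read_yaml(system.file("extdata", "presets.yaml",
                                    package = "twosexlt")))
}

# 1 + round(Gamma) durations; SD 0 (or mean 1) degenerates to a constant.
r_duration <- function(n, mean, sd) {
  m1 <- mean - 1
  if (sd == 0 || m1 <= 0) return(rep(1L + as.integer(round(m1)), n))
  shape <- m1^2 / sd^2
  rate <- m1 / sd^2
  1L + as.integer(round(stats::rgamma(n, shape = shape, rate = rate)))
}

# Death day within a failed stage: uniform over 1..dur.
r_death_day <- function(dur) {
  as.integer(1L + floor(stats::runif(length(dur)) * dur))
}

#' Simulate a cohort under a daily census
#'
#' Draws a full life history per individual (see [generator_params()] for
#' the distributional families) and returns it in the same record format
#' as observed cohorts, so every downstream computation treats simulated
#' and real data identically. The same seed reproduces the same cohort
#' exactly.
#'
#' @param params A [generator_params()] (e.g. from [preset_params()]).
#' @param seed Integer seed.
#' @return A [cohort_study()].
#' @export
#' @examples
#' ch <- simulate_cohort(preset_params("27C"), seed = 7)
#' stage_transition_counts(ch)
simulate_cohort <- function(params, seed = NULL) {
  params <- validate_generator_params(unclass(params))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n

  egg_dur <- r_duration(n, params$egg_mean, params$egg_sd)
  larva_dur <- r_duration(n, params$larva_mean, params$larva_sd)
  pupa_dur <- r_duration(n, params$pupa_mean, params$pupa_sd)
  egg_ok <- stats::runif(n) < params$egg_surv
  larva_ok <- stats::runif(n) < params$larva_surv
  pupa_ok <- stats::runif(n) < params$pupa_surv
  female <- stats::runif(n) < params$p_female
  adult_dur <- ifelse(
    female,
    r_duration(n, params$adult_mean_f, params$adult_sd_f),
    r_duration(n, params$adult_mean_m, params$adult_sd_m)
  )
  death_day_egg <- r_death_day(egg_dur)
  death_day_larva <- r_death_day(larva_dur)
  death_day_pupa <- r_death_day(pupa_dur)

  fec_total <- as.integer(stats::rnbinom(n, mu = params$fecundity_mean,
                                         size = params$fecundity_size))
  apop_draw <- 1L + stats::rpois(n, params$apop_mean - 1)
  ovi_draw <- 1L + stats::rpois(n, params$ovi_days_mean - 1)

  egg_days <- larva_days <- pupa_days <- adult_days <- rep(NA_integer_, n)
  sex <- rep("undetermined", n)
  death_stage <- character(n)
  daily_eggs <- rep(list(integer()), n)

  for (i in seq_len(n)) {
    if (!egg_ok[i]) {
      egg_days[i] <- death_day_egg[i]
      death_stage[i] <- "egg"
      next
    }
    egg_days[i] <- egg_dur[i]
    if (!larva_ok[i]) {
      larva_days[i] <- death_day_larva[i]
      death_stage[i] <- "larva"
      next
    }
    larva_days[i] <- larva_dur[i]
    if (!pupa_ok[i]) {
      pupa_days[i] <- death_day_pupa[i]
      death_stage[i] <- "pupa"
      next
    }
    pupa_days[i] <- pupa_dur[i]
    adult_days[i] <- adult_dur[i]
    death_stage[i] <- "adult"
    if (female[i]) {
      sex[i] <- "female"
      daily_eggs[[i]] <- lay_eggs(fec_total[i], adult_dur[i],
                                  apop_draw[i], ovi_draw[i])
    } else {
      sex[i] <- "male"
    }
  }

  cohort_study(
    tibble(
      individual_id = sprintf("%s_%04d", params$label, seq_len(n)),
      egg_days = egg_days, larva_days = larva_days,
      pupa_days = pupa_days, sex = sex, adult_days = adult_days,
      death_stage = death_stage, daily_eggs = daily_eggs
    ),
    label = params$label
  )
}

# Spread `total` eggs over `k` consecutive adult days starting at `first`,
# clipped to the adult lifespan; each laying day gets >= 1 egg when total
# allows, the remainder multinomially.
lay_eggs <- function(total, adult_days, first, k) {
  out <- integer(adult_days)
  if (total <= 0) return(out)
  first <- min(first, adult_days)
  k <- min(k, adult_days - first + 1L)
  days <- first:(first + k - 1L)
  if (total >= k) {
    extra <- as.integer(stats::rmultinom(1, total - k, rep(1, k)))
    out[days] <- 1L + extra
  } else {
    out[days[seq_len(total)]] <- 1L
  }
  out
}

#' Monte-Carlo oracle for a generator's expected schedules and parameters
#'
#' Simulates one very large cohort from `params` and computes its
#' schedules and population parameters. By the law of large numbers these
#' approach the generator's theoretical `l_x`, `m_x`, `R0`, `r`, `lambda`
#' and `T`, giving a ground truth against which estimates from small
#' simulated cohorts can be benchmarked (parameter-recovery tests).
#'
#' @param params A [generator_params()].
#' @param n_mc Monte-Carlo cohort size (default 200000).
#' @param seed Integer seed.
#' @return A list with `schedules` (a `schedule_set`) and `params` (the
#'   one-row tibble of [population_params()]).
#' @export
theoretical_schedules <- function(params, n_mc = 200000, seed = 1) {
  params <- unclass(params)
  params$n <- as.integer(n_mc)
  big <- simulate_cohort(validate_generator_params(params), seed = seed)
  s <- life_schedules(big)
  list(schedules = s, params = population_params(s))
}
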