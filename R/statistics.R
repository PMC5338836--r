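# Per-record features cached once so that summaries and bootstrap resamples
# evaluate any statistic from an index vector without rebuilding schedules.
cohort_features <- function(cohort) {
  n <- nrow(cohort)
  iv <- stage_intervals(cohort)
  last <- apply(iv$present, 1, function(p) max(which(p)))
  lifespan <- iv$ends[cbind(seq_len(n), last)]
  is_female <- cohort$sex == "female"
  is_male <- cohort$sex == "male"
  is_adult <- iv$present[, 4]
  preadult <- ifelse(is_adult, iv$starts[, 4], NA_real_)
  total_eggs <- vapply(cohort$daily_eggs, function(x) sum(as.numeric(x)),
                       numeric(1))
  apop <- rep(NA_real_, n)
  ovi_days <- rep(NA_real_, n)
  egg_ages <- vector("list", n)
  egg_counts <- vector("list", n)
  for (i in which(is_female)) {
    eggs <- cohort$daily_eggs[[i]]
    lay <- which(eggs > 0)
    if (length(lay) > 0) {
      apop[i] <- lay[1]
      ovi_days[i] <- length(lay)
      egg_ages[[i]] <- iv$starts[i, 4] + lay - 1L
      egg_counts[[i]] <- eggs[lay]
    }
  }
  list(
    n = n,
    egg_days = as.numeric(cohort$egg_days),
    larva_days = as.numeric(cohort$larva_days),
    pupa_days = as.numeric(cohort$pupa_days),
    adult_days = as.numeric(cohort$adult_days),
    completed_egg = iv$present[, 2],
    completed_larva = iv$present[, 3],
    completed_pupa = iv$present[, 4],
    lifespan = as.numeric(lifespan),
    is_female = is_female,
    is_male = is_male,
    is_adult = is_adult,
    preadult = preadult,
    total_eggs = total_eggs,
    apop = apop,
    ovi_days = ovi_days,
    egg_ages = egg_ages,
    egg_counts = egg_counts
  )
}

summary_stat_names <- function() {
  c("egg_days", "larva_days", "pupa_days", "preadult_days",
    "immature_mortality",
    "adult_longevity_female", "adult_longevity_male",
    "lifespan_female", "lifespan_male",
    "apop", "tpop", "oviposition_days", "fecundity")
}

population_stat_names <- function() c("R0", "GRR", "r", "lambda", "T")

#' Names of the statistics the bootstrap machinery understands
#'
#' Cohort summaries (see [cohort_summaries()]) plus the five population
#' parameters `R0`, `GRR`, `r`, `lambda`, `T`.
#'
#' @return A character vector of statistic names.
#' @export
statistic_names <- function() c(summary_stat_names(), population_stat_names())

# The subset of records a summary statistic averages over, as an index into
# idx (the resample).
stat_subset <- function(name, feats, idx) {
  switch(name,
    egg_days = idx[feats$completed_egg[idx]],
    larva_days = idx[feats$completed_larva[idx]],
    pupa_days = idx[feats$completed_pupa[idx]],
    preadult_days = idx[feats$is_adult[idx]],
    adult_longevity_female = ,
    lifespan_female = idx[feats$is_female[idx]],
    adult_longevity_male = ,
    lifespan_male = idx[feats$is_male[idx]],
    apop = ,
    tpop = ,
    oviposition_days = idx[feats$is_female[idx] & !is.na(feats$apop[idx])],
    fecundity = idx[feats$is_female[idx]],
    idx
  )
}

stat_subset_size <- function(name, feats, idx) length(stat_subset(name, feats, idx))

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

# Evaluate one statistic on the resample given by idx. Undefined statistics
# (empty subset; r when nobody reproduces) come back NA_real_.
eval_statistic <- function(name, feats, idx) {
  if (name %in% population_stat_names()) {
    return(eval_population_stat(name, feats, idx))
  }
  sub <- stat_subset(name, feats, idx)
  switch(name,
    egg_days = mean_or_na(feats$egg_days[sub]),
    larva_days = mean_or_na(feats$larva_days[sub]),
    pupa_days = mean_or_na(feats$pupa_days[sub]),
    preadult_days = mean_or_na(feats$preadult[sub]),
    immature_mortality = 1 - sum(feats$is_adult[idx]) / length(idx),
    adult_longevity_female = ,
    adult_longevity_male = mean_or_na(feats$adult_days[sub]),
    lifespan_female = ,
    lifespan_male = mean_or_na(feats$lifespan[sub]),
    apop = mean_or_na(feats$apop[sub]),
    tpop = mean_or_na(feats$preadult[sub] + feats$apop[sub]),
    oviposition_days = mean_or_na(feats$ovi_days[sub]),
    fecundity = mean_or_na(feats$total_eggs[sub]),
    abort(paste0("unknown statistic: ", name))
  )
}

# l_x m_x collapses to (eggs laid at age x) / n, so the population
# parameters of a resample need only the death ages and the egg-age
# profiles of the sampled records.
resample_egg_profile <- function(feats, idx) {
  tab <- tabulate(idx, nbins = feats$n)
  active <- which(tab > 0 & !vapply(feats$egg_ages, is.null, logical(1)))
  if (length(active) == 0) {
    return(list(ages = integer(), eggs = numeric()))
  }
  max_age <- max(vapply(active, function(i) max(feats$egg_ages[[i]]),
                        integer(1)))
  eggsum <- numeric(max_age + 1L)
  for (i in active) {
    a <- feats$egg_ages[[i]]
    eggsum[a + 1L] <- eggsum[a + 1L] + tab[i] * feats$egg_counts[[i]]
  }
  keep <- which(eggsum > 0)
  list(ages = keep - 1L, eggs = eggsum[keep])
}

eval_population_stat <- function(name, feats, idx) {
  nn <- length(idx)
  r0 <- sum(feats$total_eggs[idx]) / nn
  if (name == "R0") return(r0)
  if (name == "GRR") {
    prof <- resample_egg_profile(feats, idx)
    if (length(prof$ages) == 0) return(0)
    lifespans <- feats$lifespan[idx]
    max_age <- max(prof$ages)
    deaths <- tabulate(pmin(lifespans, max_age + 1L), nbins = max_age + 1L)
    alive <- nn - cumsum(c(0, deaths))[seq_len(max_age + 1L)]
    a <- alive[prof$ages + 1L]
    return(sum(prof$eggs[a > 0] / a[a > 0]))
  }
  # r, lambda, T: undefined without reproduction
  if (r0 <= 0) return(NA_real_)
  prof <- resample_egg_profile(feats, idx)
  r <- solve_euler_lotka(prof$ages, prof$eggs / nn)
  switch(name,
    r = r,
    lambda = exp(r),
    T = if (r == 0) NA_real_ else log(r0) / r
  )
}

# Solve sum_a w_a * exp(-r (a + offset)) = 1 for r by bracketed bisection.
# The left side is strictly decreasing in r (w_a > 0), so the root is
# unique. The bracket is widened geometrically up to +/- `limit`.
solve_euler_lotka <- function(ages, weights, tol = 1e-10,
                              bracket = c(-1, 1), offset = 1, limit = 5) {
  stopifnot(length(ages) == length(weights))
  keep <- weights > 0
  ages <- ages[keep]
  weights <- weights[keep]
  if (length(ages) == 0) {
    abort("no reproduction: the intrinsic rate is undefined",
          class = "twosexlt_no_solution")
  }
  resid <- function(r) sum(weights * exp(-r * (ages + offset))) - 1
  lo <- min(bracket)
  hi <- max(bracket)
  if (lo >= 0) lo <- -1
  if (hi <= 0) hi <- 1
  while (resid(lo) < 0 && lo > -limit) lo <- max(-limit, lo * 2)
  while (resid(hi) > 0 && hi < limit) hi <- min(limit, hi * 2)
  f_lo <- resid(lo)
  f_hi <- resid(hi)
  if (f_lo < 0 || f_hi > 0) {
    abort(paste0("no sign change for the growth-rate residual in [",
                 -limit, ", ", limit, "]"),
          class = "twosexlt_no_solution")
  }
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    f_mid <- resid(mid)
    if (abs(f_mid) < tol) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
    if ((hi - lo) < .Machine$double.eps * max(1, abs(mid))) break
  }
  (lo + hi) / 2
}
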