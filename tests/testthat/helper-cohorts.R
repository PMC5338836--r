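# Record and cohort builders used across the test files.

make_record <- function(id, egg = NA, larva = NA, pupa = NA, adult = NA,
                        sex = "undetermined", eggs = integer()) {
  present <- !is.na(c(egg, larva, pupa, adult))
  death <- c("egg", "larva", "pupa", "adult")[max(which(present))]
  tibble::tibble(
    individual_id = id,
    egg_days = as.integer(egg), larva_days = as.integer(larva),
    pupa_days = as.integer(pupa), sex = sex,
    adult_days = as.integer(adult), death_stage = death,
    daily_eggs = list(as.integer(eggs))
  )
}

toy_cohort <- function() {
  cohort_study(dplyr::bind_rows(
    make_record("f1", egg = 3, larva = 10, pupa = 5, adult = 3,
                sex = "female", eggs = c(0L, 4L, 2L)),
    make_record("m1", egg = 3, larva = 11, pupa = 5, adult = 4,
                sex = "male"),
    make_record("d1", egg = 3, larva = 6)
  ), label = "toy")
}

# A cohort realising given stage-transition counts and (optionally) a
# target total egg number spread evenly over the females.
counts_cohort <- function(n_egg, n_larva, n_pupa, n_adult, n_female,
                          total_eggs = 0, label = "counts") {
  recs <- list()
  k <- 0
  add <- function(r) {
    k <<- k + 1
    r$individual_id <- sprintf("i%04d", k)
    recs[[k]] <<- r
  }
  per_f <- if (n_female > 0) {
    diff(round(seq(0, total_eggs, length.out = n_female + 1)))
  } else integer()
  for (i in seq_len(n_egg - n_larva)) add(make_record("x", egg = 2))
  for (i in seq_len(n_larva - n_pupa)) add(make_record("x", egg = 3, larva = 5))
  for (i in seq_len(n_pupa - n_adult)) {
    add(make_record("x", egg = 3, larva = 10, pupa = 2))
  }
  for (i in seq_len(n_female)) {
    add(make_record("x", egg = 3, larva = 10, pupa = 5, adult = 3,
                    sex = "female", eggs = c(0L, as.integer(per_f[i]), 0L)))
  }
  for (i in seq_len(n_adult - n_female)) {
    add(make_record("x", egg = 3, larva = 10, pupa = 5, adult = 3,
                    sex = "male"))
  }
  cohort_study(dplyr::bind_rows(recs), label = label)
}

# Random generator parameters for property-style sweeps.
random_params <- function(n = 60) {
  generator_params(
    label = "rand", n = n,
    egg_mean = stats::runif(1, 2, 7), egg_sd = stats::runif(1, 0, 1),
    larva_mean = stats::runif(1, 5, 20), larva_sd = stats::runif(1, 0.5, 3),
    pupa_mean = stats::runif(1, 3, 7), pupa_sd = stats::runif(1, 0, 1.5),
    egg_surv = stats::runif(1, 0.4, 1), larva_surv = stats::runif(1, 0.3, 1),
    pupa_surv = stats::runif(1, 0.5, 1), p_female = stats::runif(1, 0.2, 0.8),
    adult_mean_f = stats::runif(1, 2, 6), adult_sd_f = stats::runif(1, 0, 1.5),
    adult_mean_m = stats::runif(1, 2, 6), adult_sd_m = stats::runif(1, 0, 1.5),
    apop_mean = stats::runif(1, 1, 2.5),
    ovi_days_mean = stats::runif(1, 1, 2.5),
    fecundity_mean = stats::runif(1, 3, 300),
    fecundity_size = stats::runif(1, 0.5, 8)
  )
}
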