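test_that("everyone starts as an egg: s at age 0 is 1 in the egg stage", {
  for (seed in 1:3) {
    ch <- simulate_cohort(random_params(n = 40), seed = seed)
    surv <- age_stage_survival(ch)
    at0 <- surv[surv$age == 0, ]
    expect_equal(at0$s[at0$stage == "egg"], 1)
    expect_equal(sum(at0$s[at0$stage != "egg"]), 0)
  }
})

test_that("a two-record cohort gives the hand-computed survival schedule", {
  # one egg dying after 2 days; one hatching at day 1, dying as larva day 2
  ch <- cohort_study(dplyr::bind_rows(
    make_record("a", egg = 2),
    make_record("b", egg = 1, larva = 2)
  ), "tiny")
  s <- life_schedules(ch)
  surv <- s$survival
  expect_equal(surv$s[surv$age == 1 & surv$stage == "egg"], 0.5)
  expect_equal(surv$s[surv$age == 1 & surv$stage == "larva"], 0.5)
  expect_equal(s$rates$lx, c(1, 1, 0.5))
  expect_equal(s$max_age, 2)  # nobody is alive at age 3: l_3 = 0
})

test_that("synchronous hatching gives a square egg survival curve", {
  ch <- cohort_study(dplyr::bind_rows(lapply(1:6, function(i) {
    make_record(paste0("i", i), egg = 4, larva = 3)
  })), "sync")
  surv <- age_stage_survival(ch)
  egg <- surv[surv$stage == "egg", ]
  expect_equal(egg$s[egg$age < 4], rep(1, 4))
  expect_equal(egg$s[egg$age == 4], 0)
})

test_that("survival matrix matches the day-by-day brute-force tally", {
  for (seed in 4:6) {
    ch <- simulate_cohort(random_params(n = 50), seed = seed)
    surv <- age_stage_survival(ch)
    surv_pos <- surv[surv$s > 0, ]
    surv_pos$stage <- as.character(surv_pos$stage)
    oracle <- brute_schedules(ch)
    merged <- merge(surv_pos, oracle, by = c("age", "stage"),
                    all = TRUE, suffixes = c("_pkg", "_oracle"))
    expect_equal(nrow(merged), nrow(oracle))
    expect_equal(merged$s_pkg, merged$s_oracle)
  }
})

test_that("fecundity schedule follows its definition", {
  # no females anywhere: f and m identically zero
  males <- cohort_study(dplyr::bind_rows(
    make_record("m", egg = 1, larva = 1, pupa = 1, adult = 2, sex = "male"),
    make_record("d", egg = 2)
  ), "males")
  sm <- life_schedules(males)
  expect_true(all(sm$rates$fx == 0))
  expect_true(all(sm$rates$mx == 0))

  # one female laying 4 eggs on her first adult day (age 5) in a cohort
  # of two: f_5 = 4 (per female), m_5 = (0.5 * 4) / 0.5 = 4
  ch <- cohort_study(dplyr::bind_rows(
    make_record("f", egg = 2, larva = 2, pupa = 1, adult = 1,
                sex = "female", eggs = 4L),
    make_record("d", egg = 1)
  ), "pair")
  s <- life_schedules(ch)
  expect_equal(s$rates$fx[s$rates$age == 5], 4)
  expect_equal(s$rates$mx[s$rates$age == 5], 4)
  expect_equal(s$rates$lx[s$rates$age == 5], 0.5)
})

test_that("schedule invariants hold on simulated cohorts", {
  for (seed in 7:10) {
    ch <- simulate_cohort(random_params(n = 70), seed = seed)
    s <- life_schedules(ch)
    lx_from_s <- as.numeric(tapply(s$survival$s, s$survival$age, sum))
    expect_equal(lx_from_s, s$rates$lx)
    expect_true(all(diff(s$rates$lx) <= 1e-12))
    expect_true(all(s$rates$lx >= 0 & s$rates$lx <= 1))
    expect_true(all(s$rates$mx[s$rates$lx == 0] == 0))
    # sum l_x m_x is exactly total eggs laid over initial cohort size
    total_eggs <- sum(unlist(ch$daily_eggs))
    expect_equal(sum(s$rates$lx * s$rates$mx), total_eggs / nrow(ch),
                 tolerance = 1e-12)
  }
})

test_that("cohort summaries reproduce definitional examples", {
  # immature mortality from transition counts
  ch27 <- counts_cohort(167, 124, 80, 58, 29)
  sm27 <- cohort_summaries(ch27)
  expect_equal(
    round(sm27$value[sm27$statistic == "immature_mortality"], 2), 0.65
  )
  ch36 <- counts_cohort(125, 74, 4, 4, 2)
  sm36 <- cohort_summaries(ch36)
  expect_equal(
    round(sm36$value[sm36$statistic == "immature_mortality"], 2), 0.97
  )

  # APOP is the adult day of the first egg; TPOP adds the pre-adult time
  ch <- cohort_study(dplyr::bind_rows(
    make_record("f", egg = 5, larva = 17, pupa = 6, adult = 4,
                sex = "female", eggs = c(0L, 3L, 1L, 0L))
  ), "apop")
  sm <- cohort_summaries(ch)
  v <- function(s) sm$value[sm$statistic == s]
  expect_equal(v("apop"), 2)
  expect_equal(v("tpop"), 30)
  expect_equal(v("oviposition_days"), 2)
  expect_equal(v("fecundity"), 4)
})

test_that("summaries over empty subsets are absent, not zero", {
  ch <- cohort_study(make_record("a", egg = 3), "egg-only")
  sm <- cohort_summaries(ch)
  fec <- sm[sm$statistic == "fecundity", ]
  expect_true(is.na(fec$value))
  expect_equal(fec$n, 0)
  expect_equal(sm$value[sm$statistic == "immature_mortality"], 1)
})
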