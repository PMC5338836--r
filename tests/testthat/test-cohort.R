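test_that("a small mixed cohort validates and carries its metadata", {
  ch <- toy_cohort()
  expect_s3_class(ch, "cohort_study")
  expect_equal(nrow(ch), 3)
  expect_equal(cohort_label(ch), "toy")
  expect_equal(attr(ch, "census_interval"), 1L)
})

test_that("write/read round trip is the identity on records", {
  for (ch in list(toy_cohort(),
                  simulate_cohort(preset_params("27C"), seed = 11),
                  cohort_study(make_record("only", egg = 2), "single"))) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(ch, path)
    back <- read_cohort(path, label = cohort_label(ch))
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(ch))
    # and the file itself is reproduced bit-identically on a second write
    path2 <- withr::local_tempfile(fileext = ".csv")
    write_cohort(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("long-format daily-egg files parse to the same cohort", {
  ch <- toy_cohort()
  main <- withr::local_tempfile(fileext = ".csv")
  eggs <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, main)
  # strip the canonical column, move the counts to long-format rows
  flat <- readr::read_csv(main, show_col_types = FALSE)
  flat$daily_eggs <- NULL
  readr::write_csv(flat, main)
  readr::write_csv(
    tibble::tibble(individual_id = "f1", adult_day = c(2L, 3L),
                   eggs = c(4L, 2L)),
    eggs
  )
  back <- read_cohort(main, eggs_path = eggs, label = "toy")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ch))
})

test_that("invalid records are rejected with informative errors", {
  # female whose daily egg counts do not cover her adult days
  bad <- dplyr::bind_rows(
    make_record("f1", egg = 3, larva = 10, pupa = 5, adult = 3,
                sex = "female", eggs = c(1L, 2L))
  )
  expect_error(cohort_study(bad), "daily_eggs",
               class = "twosexlt_validation_error")
  # stage chain with a gap: pupa recorded without larva
  gap <- make_record("g1", egg = 3, pupa = 5)
  gap$death_stage <- "pupa"
  expect_error(cohort_study(gap), "gap",
               class = "twosexlt_validation_error")
  # non-integer duration
  noni <- make_record("n1", egg = 2)
  noni$egg_days <- 2.5
  expect_error(cohort_study(noni), "non-integer",
               class = "twosexlt_validation_error")
  # duplicated ids
  expect_error(
    cohort_study(dplyr::bind_rows(make_record("a", egg = 2),
                                  make_record("a", egg = 3))),
    "unique", class = "twosexlt_validation_error"
  )
  # unsexed adult (a censored/incomplete observation is not representable)
  unsexed <- make_record("u1", egg = 2, larva = 3, pupa = 2, adult = 1)
  expect_error(cohort_study(unsexed), "sexed",
               class = "twosexlt_validation_error")
  # missing header column on read
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("individual_id,egg_days\nx,2", path)
  expect_error(read_cohort(path), "missing column",
               class = "twosexlt_format_error")
})

test_that("stage transition counts reproduce the n(N) bookkeeping", {
  ch <- counts_cohort(167, 124, 80, 58, 29)
  tab <- stage_transition_counts(ch)
  expect_equal(tab$entered, c(167, 124, 80, 58))
  expect_equal(tab$completed[1:3], c(124, 80, 58))
  expect_true(is.na(tab$completed[4]))
  # sexes among adults add up to pupal completions
  expect_equal(sum(ch$sex == "female") + sum(ch$sex == "male"),
               tab$completed[3])

  all_eggs <- cohort_study(dplyr::bind_rows(
    make_record("a", egg = 2), make_record("b", egg = 1)
  ), "eggs")
  tab2 <- stage_transition_counts(all_eggs)
  expect_equal(tab2$stage, "egg")
  expect_equal(tab2$entered, 2)
  expect_equal(tab2$completed, 0)
})

test_that("transition counts match a brute-force per-record tally", {
  for (seed in 1:3) {
    set.seed(seed)
    ch <- simulate_cohort(random_params(n = 80), seed = seed + 100)
    tab <- stage_transition_counts(ch)
    expected_entered <- c(
      egg = sum(!is.na(ch$egg_days)), larva = sum(!is.na(ch$larva_days)),
      pupa = sum(!is.na(ch$pupa_days)), adult = sum(!is.na(ch$adult_days))
    )
    expected_entered <- expected_entered[expected_entered > 0]
    expect_equal(stats::setNames(tab$entered, tab$stage), expected_entered)
    # chaining: entries into stage k+1 equal completions of stage k
    expect_equal(tab$completed[-nrow(tab)], tab$entered[-1])
  }
})
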