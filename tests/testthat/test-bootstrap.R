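identical_cohort <- function(n, egg = 5L, label = "ident") {
  cohort_study(dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_record(paste0("i", i), egg = egg, larva = 2)
  })), label)
}

test_that("cohorts of identical individuals bootstrap to SE = 0", {
  ch <- identical_cohort(30)
  res <- bootstrap_statistic(ch, "egg_days", B = 200, seed = 1)
  expect_equal(res$se, 0)
  expect_equal(res$mean, 5)
  expect_equal(res$valid_count, 200)
  # synchronous hatching in a mixed cohort: egg duration still has SE 0
  mixed <- simulate_cohort(preset_params("24C"), seed = 2)
  res2 <- bootstrap_statistic(mixed, "egg_days", B = 200, seed = 1)
  expect_equal(res2$se, 0)
  expect_equal(res2$mean, 6)
})

test_that("a fixed seed reproduces an independent same-seed recomputation", {
  ch <- simulate_cohort(preset_params("30C"), seed = 8)
  B <- 400
  seed <- 123
  for (stat in c("fecundity", "R0", "r")) {
    res <- bootstrap_statistic(ch, stat, B = B, seed = seed)
    # brute force: rebuild each resample as a fresh cohort_study and run
    # the full pipeline on it
    set.seed(seed)
    vals <- vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(ch), nrow(ch), replace = TRUE)
      sub <- tibble::as_tibble(ch)[idx, ]
      sub$individual_id <- sprintf("r%04d", seq_along(idx))
      rch <- cohort_study(sub, label = "resample")
      if (stat %in% c("R0", "r")) {
        p <- population_params(life_schedules(rch))
        p[[stat]]
      } else {
        sm <- cohort_summaries(rch)
        sm$value[sm$statistic == stat]
      }
    }, numeric(1))
    ok <- !is.na(vals)
    expect_equal(res$values, vals)
    expect_equal(res$mean, mean(vals[ok]))
    expect_equal(res$se, stats::sd(vals[ok]))
    expect_equal(res$valid_count, sum(ok))
  }
})

test_that("undefined resamples are excluded and full failure errors", {
  # males only: fecundity is never defined
  males <- cohort_study(dplyr::bind_rows(
    make_record("m1", egg = 1, larva = 1, pupa = 1, adult = 2, sex = "male"),
    make_record("m2", egg = 1, larva = 1, pupa = 1, adult = 2, sex = "male")
  ), "males")
  expect_error(bootstrap_statistic(males, "fecundity", B = 50, seed = 1),
               "fecundity", class = "twosexlt_degenerate_bootstrap")
  # one female among many: some resamples miss her
  ch <- simulate_cohort(preset_params("36C"), seed = 4)
  res <- bootstrap_statistic(ch, "r", B = 300, seed = 2)
  expect_lt(res$valid_count, 300)
  expect_equal(res$valid_count, sum(!is.na(res$values)))
  expect_equal(res$mean, mean(res$values, na.rm = TRUE))
})

test_that("paired bootstrap test behaves on degenerate inputs", {
  ch <- identical_cohort(20)
  a <- bootstrap_statistic(ch, "egg_days", B = 100, seed = 7)
  b <- bootstrap_statistic(ch, "egg_days", B = 100, seed = 7)
  t0 <- paired_bootstrap_test(a, b)
  expect_false(t0$significant)
  expect_equal(t0$ci, c(0, 0))

  c5 <- identical_cohort(20, egg = 5L, label = "five")
  c9 <- identical_cohort(20, egg = 9L, label = "nine")
  ra <- bootstrap_statistic(c5, "egg_days", B = 100, seed = 1)
  rb <- bootstrap_statistic(c9, "egg_days", B = 100, seed = 2)
  t1 <- paired_bootstrap_test(ra, rb)
  expect_true(t1$significant)
  expect_equal(t1$ci, c(-4, -4))

  short <- bootstrap_statistic(c5, "egg_days", B = 50, seed = 1)
  expect_error(paired_bootstrap_test(ra, short), "equal")
})

test_that("high- and low-fecundity treatments separate significantly", {
  warm <- simulate_cohort(preset_params("24C"), seed = 31)
  hot <- simulate_cohort(preset_params("36C"), seed = 32)
  cmp <- compare_groups(list(`24C` = warm, `36C` = hot), "fecundity",
                        B = 1000, seed = 9)
  expect_true(cmp$significant["24C", "36C"])
  expect_false(any(strsplit(cmp$groups$letters[1], "")[[1]] %in%
                     strsplit(cmp$groups$letters[2], "")[[1]]))
})

test_that("letter displays encode the significance pattern", {
  no_sig <- matrix(FALSE, 3, 3)
  expect_equal(unname(letter_display(no_sig, 3:1)), c("a", "a", "a"))

  all_sig <- !diag(6) > 0
  expect_equal(unname(letter_display(all_sig, 6:1)),
               c("a", "b", "c", "d", "e", "f"))

  chain <- matrix(FALSE, 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  chain["A", "C"] <- chain["C", "A"] <- TRUE
  expect_equal(letter_display(chain, c(A = 3, B = 2, C = 1)),
               c(A = "a", B = "ab", C = "b"))
})

test_that("decoding any letter display recovers the input flags", {
  share_letter <- function(x, y) {
    any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])
  }
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    sig <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(sig))
    on <- pairs[stats::runif(length(pairs)) < 0.4]
    sig[on] <- TRUE
    sig <- sig | t(sig)
    means <- stats::rnorm(k)
    disp <- letter_display(sig, means)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        expect_equal(share_letter(disp[i], disp[j]), !sig[i, j])
      }
    }
  }
})

test_that("bootstrap SEs shrink with cohort size and stabilise over seeds", {
  params <- preset_params("27C")
  ses <- vapply(c(50, 200, 800), function(n) {
    p <- params
    p$n <- n
    ch <- simulate_cohort(twosexlt:::validate_generator_params(unclass(p)),
                          seed = n)
    bootstrap_statistic(ch, "preadult_days", B = 400, seed = 1)$se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))

  ch <- simulate_cohort(params, seed = 17)
  se1 <- bootstrap_statistic(ch, "R0", B = 5000, seed = 101)$se
  se2 <- bootstrap_statistic(ch, "R0", B = 5000, seed = 202)$se
  expect_lt(abs(se1 - se2) / se1, 0.1)
})
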