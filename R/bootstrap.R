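#' Bootstrap a cohort statistic
#'
#' Resamples whole individuals (life histories) with replacement, `N` per
#' resample, recomputes the statistic on each resample, and reports the
#' resample mean and standard error. The individual is the resampling unit
#' because it is the only unit that keeps the survival and fecundity
#' schedules well defined.
#'
#' A resample can leave a statistic undefined — no surviving female leaves
#' `r`, `lambda` and `T` without a solution, an empty stage leaves a
#' duration mean empty. Such resamples are excluded from the mean and SE;
#' `valid_count` says how many resamples contributed.
#'
#' @param cohort A [cohort_study()].
#' @param statistic One of [statistic_names()]: a cohort summary (e.g.
#'   `"egg_days"`, `"fecundity"`) or a population parameter (`"R0"`,
#'   `"GRR"`, `"r"`, `"lambda"`, `"T"`).
#' @param B Number of bootstrap resamples (default 10000; raise towards
#'   1e6 for publication-grade SEs if runtime allows).
#' @param seed Integer seed; fixed seed gives bit-identical resamples.
#' @return A `bootstrap_result`: list with `statistic`, `B`, `seed`,
#'   `values` (length-`B`, `NA` where undefined), `mean`, `se`,
#'   `valid_count`, `label`.
#' @export
#' @examples
#' ch <- simulate_cohort(preset_params("27C"), seed = 1)
#' bootstrap_statistic(ch, "R0", B = 200, seed = 42)
bootstrap_statistic <- function(cohort, statistic, B = 10000, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_study"), length(statistic) == 1)
  if (!statistic %in% statistic_names()) {
    abort(paste0("unknown statistic: ", statistic,
                 " (see statistic_names())"))
  }
  if (B < 2) abort("B must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  feats <- cohort_features(cohort)
  n <- feats$n
  values <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(
      eval_statistic(statistic, feats, idx),
      twosexlt_no_solution = function(e) NA_real_
    )
  }, numeric(1))
  new_bootstrap_result(statistic, values, B, seed, cohort_label(cohort))
}

new_bootstrap_result <- function(statistic, values, B, seed, label) {
  ok <- !is.na(values)
  if (!any(ok)) {
    abort(paste0("statistic '", statistic,
                 "' was undefined in every bootstrap resample"),
          class = "twosexlt_degenerate_bootstrap")
  }
  structure(
    list(statistic = statistic, B = B, seed = seed, values = values,
         mean = mean(values[ok]), se = stats::sd(values[ok]),
         valid_count = sum(ok), label = label),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s [%s]: mean %.4g, SE %.4g (B = %d, %d valid)\n",
              x$statistic, x$label, x$mean, x$se, x$B, x$valid_count))
  invisible(x)
}

#' Paired bootstrap test for a difference between two groups
#'
#' Pairs the two groups' bootstrap replicates by resample index, forms the
#' `B` differences, and takes the percentile `100 (1 - alpha)%` interval of
#' the differences. The difference is significant when that interval
#' excludes zero.
#'
#' @param res_a,res_b `bootstrap_result`s of the same statistic with equal
#'   `B`.
#' @param alpha Significance level (default 0.05).
#' @return A `paired_bootstrap_test`: list with `estimate` (mean
#'   difference), `ci` (length-2), `alpha`, `significant`, `n_pairs`.
#' @export
paired_bootstrap_test <- function(res_a, res_b, alpha = 0.05) {
  stopifnot(inherits(res_a, "bootstrap_result"),
            inherits(res_b, "bootstrap_result"))
  if (res_a$B != res_b$B) {
    abort("paired bootstrap test needs equal numbers of resamples")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  d <- res_a$values - res_b$values
  d <- d[!is.na(d)]
  if (length(d) < 2) {
    abort("fewer than 2 valid paired differences")
  }
  ci <- unname(stats::quantile(d, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(
    list(statistic = res_a$statistic, groups = c(res_a$label, res_b$label),
         estimate = mean(d), ci = ci, alpha = alpha,
         significant = ci[1] > 0 || ci[2] < 0, n_pairs = length(d)),
    class = "paired_bootstrap_test"
  )
}

#' @export
print.paired_bootstrap_test <- function(x, ...) {
  cat(sprintf(
    "<paired_bootstrap_test> %s: %s - %s = %.4g, %g%% CI [%.4g, %.4g]%s\n",
    x$statistic, x$groups[1], x$groups[2], x$estimate,
    100 * (1 - x$alpha), x$ci[1], x$ci[2],
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare a statistic across treatment groups
#'
#' Bootstraps the statistic in every group (independent streams derived
#' from one root seed), runs all pairwise paired bootstrap tests, and
#' summarises the pattern as a compact letter display: groups sharing a
#' letter are not significantly different.
#'
#' @param cohorts A named list of [cohort_study()] objects; names are the
#'   group labels.
#' @param statistic One of [statistic_names()].
#' @param B Resamples per group.
#' @param seed Root seed for the whole comparison.
#' @param alpha Significance level.
#' @return A `group_comparison`: list with `groups` (tibble `group`,
#'   `mean`, `se`, `valid_count`, `letters`), `significant` (logical
#'   matrix), `results` (the per-group `bootstrap_result`s), `statistic`,
#'   `alpha`, `B`.
#' @export
compare_groups <- function(cohorts, statistic, B = 10000, seed = NULL,
                           alpha = 0.05) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2)
  labels <- names(cohorts)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    abort("cohorts must be a named list with unique non-empty names")
  }
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(cohorts))
  results <- purrr::map2(cohorts, sub_seeds, function(ch, s) {
    bootstrap_statistic(ch, statistic, B = B, seed = s)
  })
  k <- length(results)
  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  tests <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tst <- paired_bootstrap_test(results[[i]], results[[j]], alpha = alpha)
      sig[i, j] <- sig[j, i] <- tst$significant
      tests[[paste(labels[i], labels[j], sep = " vs ")]] <- tst
    }
  }
  means <- vapply(results, function(r) r$mean, numeric(1))
  letters <- letter_display(sig, means)
  groups <- tibble(
    group = labels,
    mean = unname(means),
    se = vapply(results, function(r) r$se, numeric(1), USE.NAMES = FALSE),
    valid_count = vapply(results, function(r) r$valid_count, integer(1),
                         USE.NAMES = FALSE),
    letters = unname(letters)
  )
  structure(
    list(groups = groups, significant = sig, results = results,
         tests = tests, statistic = statistic, alpha = alpha, B = B),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (B = %d, alpha = %g)\n",
              x$statistic, x$B, x$alpha))
  df <- x$groups
  cat(paste0("  ", df$group, ": ",
             sprintf("%.2f+-%.2f", df$mean, df$se), df$letters,
             collapse = "\n"), "\n")
  invisible(x)
}

#' Compact letter display from a significance matrix
#'
#' Assigns each group a set of letters such that two groups share at least
#' one letter exactly when they are *not* significantly different
#' (insert-and-absorb construction). Letters are ordered so that `"a"`
#' goes with the largest mean.
#'
#' @param significant Symmetric logical matrix: `TRUE` where the pair
#'   differs significantly.
#' @param means Group means, used only to order the letters.
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' sig <- matrix(c(FALSE, FALSE, TRUE,
#'                 FALSE, FALSE, FALSE,
#'                 TRUE, FALSE, FALSE), 3, 3,
#'               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' letter_display(sig, c(A = 3, B = 2, C = 1))
letter_display <- function(significant, means) {
  k <- nrow(significant)
  stopifnot(ncol(significant) == k, length(means) == k)
  if (!isTRUE(all.equal(significant, t(significant)))) {
    abort("significance matrix must be symmetric")
  }
  if (any(diag(significant))) {
    abort("a group cannot differ significantly from itself")
  }
  labels <- rownames(significant) %||% as.character(seq_len(k))
  ord <- order(-means)
  # insert-and-absorb: maintain letter groups (sets of mutually
  # non-different groups); each significant pair splits every set that
  # contains both; subsets of other sets are absorbed.
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!significant[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      sets <- absorb_sets(new_sets)
    }
  }
  # letter order follows the descending-mean order of first membership
  first_pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(out, labels)
}

absorb_sets <- function(sets) {
  sets <- unique(lapply(sets, sort))
  sets <- sets[lengths(sets) > 0]
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  # drop exact duplicates kept twice and proper subsets
  sets[keep]
}
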