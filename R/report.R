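# Which statistics go in which report table (the classic four-table layout
# of temperature rearing studies).
REPORT_TABLES <- list(
  development = c("egg_days", "larva_days", "pupa_days", "preadult_days",
                  "immature_mortality"),
  longevity = c("adult_longevity_male", "adult_longevity_female",
                "lifespan_male", "lifespan_female"),
  reproduction = c("apop", "tpop", "oviposition_days", "fecundity"),
  population_params = c("R0", "GRR", "r", "lambda", "T")
)

#' Run the full multi-group life-table analysis
#'
#' For each statistic of the four standard report tables (stage
#' durations and immature mortality; adult longevity and lifespan; APOP,
#' TPOP, oviposition days and fecundity; the five population parameters),
#' bootstraps every group, runs all pairwise paired bootstrap tests, and
#' writes delimited report tables with `mean+-SE` cells annotated with
#' compact-display letters. Tidy full-precision exports (per-group
#' schedules and per-statistic group summaries) are written alongside,
#' plus a plain-text log of the seed, B, alpha and package version.
#'
#' @param cohorts A named list of [cohort_study()] objects or cohort file
#'   paths (names become group labels). A single group is analysed
#'   without comparisons, with a warning.
#' @param out_dir Output directory, created if needed.
#' @param B Bootstrap resamples per group and statistic.
#' @param seed Root seed for the whole analysis.
#' @param alpha Significance level for the paired tests.
#' @param plots If `TRUE`, also writes survival/fecundity curve figures
#'   per group (PNG).
#' @return Invisibly, a list with `tables` (formatted report tibbles),
#'   `summaries` (full-precision tidy group summaries), `schedules`
#'   (per-group `schedule_set`s) and `files` (paths written).
#' @export
run_analysis <- function(cohorts, out_dir, B = 10000, seed = 1,
                         alpha = 0.05, plots = FALSE) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  labels <- names(cohorts)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    abort("cohorts must be a named list with unique non-empty names")
  }
  cohorts <- purrr::imap(cohorts, function(ch, lab) {
    if (is.character(ch)) {
      if (!file.exists(ch)) {
        abort(paste0("cohort file for group '", lab, "' not found: ", ch))
      }
      read_cohort(ch, label = lab)
    } else {
      stopifnot(inherits(ch, "cohort_study"))
      ch
    }
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  single <- length(cohorts) == 1
  if (single) {
    warn("only one group supplied: between-group comparisons skipped")
  }

  set.seed(seed)
  stat_seeds <- stats::setNames(
    sample.int(.Machine$integer.max, length(unlist(REPORT_TABLES))),
    unlist(REPORT_TABLES)
  )

  summaries <- list()
  tables <- list()
  files <- character()
  for (tbl_name in names(REPORT_TABLES)) {
    stats_here <- REPORT_TABLES[[tbl_name]]
    rows <- list()
    for (st in stats_here) {
      if (single) {
        res <- bootstrap_statistic(cohorts[[1]], st, B = B,
                                   seed = stat_seeds[[st]])
        gsum <- dplyr::mutate(glance(res), letters = "", .after = "se")
        gsum <- dplyr::rename(gsum, group = "label")
        gsum <- dplyr::relocate(gsum, "statistic", .before = 1)
      } else {
        cmp <- compare_groups(cohorts, st, B = B, seed = stat_seeds[[st]],
                              alpha = alpha)
        gsum <- tidy(cmp)
      }
      summaries[[st]] <- gsum
      cell <- sprintf("%.2f±%.2f%s", gsum$mean, gsum$se, gsum$letters)
      rows[[st]] <- tibble(statistic = st,
                           !!!stats::setNames(as.list(cell), gsum$group))
    }
    tab <- dplyr::bind_rows(rows)
    tables[[tbl_name]] <- tab
    path <- file.path(out_dir, paste0("table_", tbl_name, ".csv"))
    readr::write_csv(tab, path, progress = FALSE)
    files <- c(files, path)
  }

  summary_path <- file.path(out_dir, "group_summaries.csv")
  readr::write_csv(dplyr::bind_rows(summaries), summary_path,
                   progress = FALSE)
  files <- c(files, summary_path)

  schedules <- purrr::map(cohorts, life_schedules)
  sched_path <- file.path(out_dir, "schedules.csv")
  readr::write_csv(dplyr::bind_rows(purrr::map(schedules, tidy)),
                   sched_path, progress = FALSE)
  files <- c(files, sched_path)

  if (plots) {
    for (lab in names(schedules)) {
      files <- c(files, render_curves(schedules[[lab]], out_dir))
    }
  }

  log_path <- file.path(out_dir, "analysis_log.txt")
  writeLines(c(
    paste0("twosexlt version: ",
           as.character(utils::packageVersion("twosexlt"))),
    paste0("groups: ", paste(names(cohorts), collapse = ", ")),
    paste0("B: ", B), paste0("seed: ", seed), paste0("alpha: ", alpha)
  ), log_path)
  files <- c(files, log_path)

  invisible(list(tables = tables, summaries = summaries,
                 schedules = schedules, files = files))
}

#' Write survival and fecundity curve figures for one group
#'
#' @param schedules A `schedule_set`.
#' @param path Output directory.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return The paths of the two PNG files written.
#' @export
render_curves <- function(schedules, path, width = 7, height = 5,
                          dpi = 150) {
  stopifnot(inherits(schedules, "schedule_set"))
  if (!dir.exists(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
  }
  safe <- gsub("[^A-Za-z0-9_-]", "_", schedules$label)
  f1 <- file.path(path, paste0("survival_", safe, ".png"))
  f2 <- file.path(path, paste0("rates_", safe, ".png"))
  ggplot2::ggsave(f1, plot_survival(schedules), width = width,
                  height = height, dpi = dpi)
  ggplot2::ggsave(f2, plot_rates(schedules), width = width,
                  height = height, dpi = dpi)
  c(f1, f2)
}
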