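#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Immature stages are observed for every individual that enters them; the
# adult stage is split by sex downstream (female_adult / male_adult).
PREADULT_STAGES <- c("egg", "larva", "pupa")
STAGES <- c(PREADULT_STAGES, "adult")
DURATION_COLS <- c("egg_days", "larva_days", "pupa_days", "adult_days")

#' Assemble a treatment cohort from individual life-history records
#'
#' A cohort is a tibble with one row per individual followed from
#' oviposition to death under a daily census. Stage durations are whole
#' days; a duration is present exactly when the individual entered that
#' stage, and the duration of the stage it died in counts the days it was
#' alive there. Sex is recorded only for individuals that reached
#' adulthood. Daily egg counts are kept as an integer vector per female,
#' one entry per adult day.
#'
#' Censored individuals (alive at the end of observation, escaped, lost)
#' are not representable: rearing is assumed to continue until every
#' individual has died, and validation rejects inconsistent records.
#'
#' @param records A data frame with columns `individual_id`, `egg_days`,
#'   `larva_days`, `pupa_days`, `sex` (`"female"`, `"male"` or
#'   `"undetermined"`), `adult_days`, `death_stage` (`"egg"`, `"larva"`,
#'   `"pupa"` or `"adult"`) and `daily_eggs` (a list column of integer
#'   vectors). Missing stages are `NA`.
#' @param label Cohort label, e.g. the rearing temperature (`"27C"`).
#'
#' @return A `cohort_study` tibble (one row per individual) with
#'   attributes `label` and `census_interval` (fixed at 1 day).
#' @export
#' @examples
#' cohort_study(
#'   tibble::tibble(
#'     individual_id = c("a", "b"),
#'     egg_days = c(3L, 3L), larva_days = c(10L, NA),
#'     pupa_days = c(5L, NA), sex = c("female", "undetermined"),
#'     adult_days = c(2L, NA), death_stage = c("adult", "egg"),
#'     daily_eggs = list(c(4L, 0L), integer())
#'   ),
#'   label = "toy"
#' )
cohort_study <- function(records, label = "cohort") {
  records <- as_tibble(records)
  required <- c("individual_id", DURATION_COLS, "sex", "death_stage", "daily_eggs")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort records are missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "twosexlt_format_error")
  }
  records <- records[, required]
  for (col in DURATION_COLS) {
    v <- records[[col]]
    if (is.double(v) && !all(is.na(v) | v == round(v))) {
      abort(paste0("non-integer value in ", col),
            class = "twosexlt_validation_error")
    }
    records[[col]] <- as.integer(records[[col]])
  }
  records$individual_id <- as.character(records$individual_id)
  records$sex <- as.character(records$sex)
  records$death_stage <- as.character(records$death_stage)
  records$daily_eggs <- lapply(records$daily_eggs, function(x) {
    x <- as.integer(x)
    if (length(x) == 0) integer() else x
  })
  out <- validate_cohort(records)
  attr(out, "label") <- label
  attr(out, "census_interval") <- 1L
  class(out) <- c("cohort_study", class(out))
  out
}

validate_cohort <- function(records) {
  n <- nrow(records)
  if (n < 1) abort("a cohort needs at least one record",
                   class = "twosexlt_validation_error")
  if (anyDuplicated(records$individual_id)) {
    abort("individual_id values must be unique",
          class = "twosexlt_validation_error")
  }
  bad_sex <- !records$sex %in% c("female", "male", "undetermined")
  if (any(bad_sex)) {
    abort(paste0("invalid sex for individual ",
                 records$individual_id[which(bad_sex)[1]]),
          class = "twosexlt_validation_error")
  }
  bad_death <- !records$death_stage %in% STAGES
  if (any(bad_death)) {
    abort(paste0("invalid death_stage for individual ",
                 records$individual_id[which(bad_death)[1]]),
          class = "twosexlt_validation_error")
  }
  for (i in seq_len(n)) {
    rec <- records[i, ]
    id <- rec$individual_id
    durs <- c(rec$egg_days, rec$larva_days, rec$pupa_days, rec$adult_days)
    present <- !is.na(durs)
    if (!present[1]) {
      abort(paste0("individual ", id, ": egg_days is required ",
                   "(every individual starts as an egg)"),
            class = "twosexlt_validation_error")
    }
    # entered stages must form an unbroken chain egg -> larva -> pupa -> adult
    last_present <- max(which(present))
    if (!all(present[seq_len(last_present)])) {
      abort(paste0("individual ", id, ": stage chain has a gap ",
                   "(a later stage is recorded without an earlier one)"),
            class = "twosexlt_validation_error")
    }
    if (any(durs[present] < 1)) {
      abort(paste0("individual ", id, ": stage durations must be >= 1 day"),
            class = "twosexlt_validation_error")
    }
    if (rec$death_stage != STAGES[last_present]) {
      abort(paste0("individual ", id, ": death_stage '", rec$death_stage,
                   "' does not match the last recorded stage '",
                   STAGES[last_present], "'"),
            class = "twosexlt_validation_error")
    }
    is_adult <- present[4]
    if (is_adult && !rec$sex %in% c("female", "male")) {
      abort(paste0("individual ", id, ": adults must be sexed"),
            class = "twosexlt_validation_error")
    }
    if (!is_adult && rec$sex != "undetermined") {
      abort(paste0("individual ", id,
                   ": sex must be 'undetermined' before adulthood"),
            class = "twosexlt_validation_error")
    }
    eggs <- rec$daily_eggs[[1]]
    if (length(eggs) > 0 && any(is.na(eggs) | eggs < 0)) {
      abort(paste0("individual ", id, ": daily_eggs must be non-negative"),
            class = "twosexlt_validation_error")
    }
    if (is_adult && rec$sex == "female") {
      if (length(eggs) != rec$adult_days) {
        abort(paste0("individual ", id, ": daily_eggs has length ",
                     length(eggs), " but adult_days is ", rec$adult_days),
              class = "twosexlt_validation_error")
      }
    } else if (length(eggs) != 0) {
      abort(paste0("individual ", id,
                   ": daily_eggs must be empty for non-females"),
            class = "twosexlt_validation_error")
    }
  }
  records
}

#' @export
print.cohort_study <- function(x, ...) {
  cat("<cohort_study> label:", cohort_label(x),
      " N:", nrow(x),
      " adults:", sum(!is.na(x$adult_days)), "\n")
  NextMethod()
}

#' Cohort label
#' @param cohort A `cohort_study`.
#' @return The label string.
#' @export
cohort_label <- function(cohort) attr(cohort, "label") %||% "cohort"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort file
#'
#' The canonical dialect is a comma-delimited file with a header row and a
#' `daily_eggs` column holding each female's egg counts joined with
#' semicolons (`"4;0;2"`). Alternatively (`eggs_path`), daily counts may be
#' supplied as long-format rows in a companion file with columns
#' `individual_id`, `adult_day`, `eggs`; days not listed are zero.
#'
#' @param path Path to the cohort CSV.
#' @param eggs_path Optional path to a long-format daily-egg file.
#' @param label Cohort label; defaults to the file name without extension.
#' @return A validated [cohort_study()].
#' @export
read_cohort <- function(path, eggs_path = NULL, label = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path),
          class = "twosexlt_format_error")
  }
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  needed <- c("individual_id", DURATION_COLS, "sex", "death_stage")
  if (!all(needed %in% header)) {
    abort(paste0("cohort file ", path, " is missing column(s): ",
                 paste(setdiff(needed, header), collapse = ", ")),
          class = "twosexlt_format_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      individual_id = readr::col_character(),
      egg_days = readr::col_double(),
      larva_days = readr::col_double(),
      pupa_days = readr::col_double(),
      sex = readr::col_character(),
      adult_days = readr::col_double(),
      death_stage = readr::col_character(),
      .default = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  if ("daily_eggs" %in% names(raw)) {
    eggs <- lapply(raw$daily_eggs, function(s) {
      if (is.na(s) || !nzchar(s)) integer()
      else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  } else if (!is.null(eggs_path)) {
    long <- readr::read_csv(
      eggs_path,
      col_types = readr::cols(
        individual_id = readr::col_character(),
        adult_day = readr::col_integer(),
        eggs = readr::col_integer()
      ),
      progress = FALSE
    )
    eggs <- lapply(seq_len(nrow(raw)), function(i) {
      nd <- raw$adult_days[i]
      if (is.na(nd) || raw$sex[i] != "female") return(integer())
      v <- integer(nd)
      rows <- long[long$individual_id == raw$individual_id[i], ]
      if (any(rows$adult_day < 1 | rows$adult_day > nd)) {
        abort(paste0("individual ", raw$individual_id[i],
                     ": adult_day outside 1..adult_days in ", eggs_path),
              class = "twosexlt_validation_error")
      }
      v[rows$adult_day] <- rows$eggs
      v
    })
  } else {
    eggs <- rep(list(integer()), nrow(raw))
  }
  raw$daily_eggs <- eggs
  cohort_study(raw, label = label)
}

#' Write a cohort file in the canonical dialect
#'
#' Emits a comma-delimited file that [read_cohort()] parses back to an
#' identical cohort (round trip is the identity on records).
#'
#' @param cohort A `cohort_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_study"))
  flat <- as_tibble(cohort)
  flat$daily_eggs <- vapply(
    cohort$daily_eggs,
    function(x) paste(x, collapse = ";"),
    character(1)
  )
  readr::write_csv(flat, path, na = "", progress = FALSE)
  invisible(path)
}

#' Stage transition counts (the n(N) bookkeeping of rearing tables)
#'
#' For each stage that at least one individual entered, counts how many
#' individuals entered it and how many completed it, i.e. entered the next
#' stage. The adult stage has no successor, so its `completed` is `NA`.
#'
#' @param cohort A `cohort_study`.
#' @return A tibble with columns `stage`, `entered`, `completed`.
#' @export
stage_transition_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_study"))
  entered <- vapply(DURATION_COLS, function(col) sum(!is.na(cohort[[col]])),
                    integer(1))
  completed <- c(entered[-1], NA_integer_)
  out <- tibble(stage = STAGES, entered = unname(entered),
                completed = unname(completed))
  out[out$entered > 0, ]
}
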