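# Independent oracles: deliberately naive implementations used only to
# check the package's vectorised code paths.

# Day-by-day tally of who is alive where, looping over individuals.
brute_schedules <- function(cohort) {
  n <- nrow(cohort)
  rows <- list()
  for (i in seq_len(n)) {
    durs <- c(cohort$egg_days[i], cohort$larva_days[i],
              cohort$pupa_days[i], cohort$adult_days[i])
    stages <- c("egg", "larva", "pupa",
                if (identical(cohort$sex[i], "female")) "female_adult"
                else "male_adult")
    age <- 0L
    for (k in 1:4) {
      if (is.na(durs[k])) break
      for (d in seq_len(durs[k])) {
        rows[[length(rows) + 1]] <- data.frame(age = age, stage = stages[k])
        age <- age + 1L
      }
    }
  }
  all_days <- do.call(rbind, rows)
  counts <- stats::aggregate(list(count = rep(1, nrow(all_days))),
                             all_days[, c("age", "stage")], sum)
  counts$s <- counts$count / n
  counts[order(counts$age, counts$stage), c("age", "stage", "s")]
}

# Locate the Euler-Lotka root by scanning a fine grid for the sign change.
grid_scan_r <- function(ages, w, lo = -1, hi = 1, grid = 1e-4) {
  resid <- function(r) sum(w * exp(-r * (ages + 1))) - 1
  while (resid(lo) < 0) lo <- lo * 2
  while (resid(hi) > 0) hi <- hi * 2
  rs <- seq(lo, hi, by = grid)
  vals <- vapply(rs, resid, numeric(1))
  i <- which(vals[-length(vals)] >= 0 & vals[-1] < 0)[1]
  c(rs[i], rs[i + 1])
}

lxmx_of <- function(schedules) {
  list(ages = schedules$rates$age,
       w = schedules$rates$lx * schedules$rates$mx)
}
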