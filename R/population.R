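#' Net reproductive rate
#'
#' `R0 = sum_x l_x m_x`: the expected number of offspring a newly
#' oviposited egg contributes over its lifetime. Because
#' `l_x m_x` equals (eggs laid at age x) / N, `R0` also equals the total
#' eggs laid by the cohort divided by its initial size.
#'
#' @param schedules A [life_schedules()] result.
#' @return `R0` (offspring/individual), a non-negative number.
#' @export
net_reproductive_rate <- function(schedules) {
  stopifnot(inherits(schedules, "schedule_set"))
  sum(schedules$rates$lx * schedules$rates$mx)
}

#' Gross reproductive rate
#'
#' `GRR = sum_x m_x`: lifetime reproduction if mortality were absent.
#' Always at least `R0`, since `l_x <= 1`.
#'
#' @inheritParams net_reproductive_rate
#' @return `GRR` (offspring/individual).
#' @export
gross_reproductive_rate <- function(schedules) {
  stopifnot(inherits(schedules, "schedule_set"))
  sum(schedules$rates$mx)
}

#' Intrinsic rate of increase
#'
#' Solves the Euler-Lotka equation
#' `sum_x exp(-r (x + 1)) l_x m_x = 1` for `r` by bracketed bisection.
#' The left side is strictly decreasing in `r`, so the root is unique
#' whenever any reproduction occurred. The `x + 1` exponent is the
#' age-indexed-from-zero convention of the two-sex life table literature;
#' set `convention = "x"` for the `exp(-r x)` form.
#'
#' @inheritParams net_reproductive_rate
#' @param tol Residual tolerance for the root (default `1e-10`).
#' @param bracket Initial bracket for `r` (per day); widened automatically
#'   up to +/- 5 if it does not straddle the root.
#' @param convention `"x_plus_1"` (default) or `"x"`.
#' @return `r` in per-day units. Errors if no reproduction occurred
#'   (`R0 = 0` leaves `r` undefined).
#' @export
intrinsic_rate <- function(schedules, tol = 1e-10, bracket = c(-1, 1),
                           convention = c("x_plus_1", "x")) {
  stopifnot(inherits(schedules, "schedule_set"))
  convention <- match.arg(convention)
  w <- schedules$rates$lx * schedules$rates$mx
  solve_euler_lotka(schedules$rates$age, w, tol = tol, bracket = bracket,
                    offset = if (convention == "x_plus_1") 1 else 0)
}

#' Finite rate of increase
#'
#' `lambda = exp(r)`: the factor by which a stably growing population
#' multiplies per day.
#'
#' @param r Intrinsic rate of increase (per day).
#' @return `lambda` (per day).
#' @export
finite_rate <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)))
  exp(r)
}

#' Mean generation time
#'
#' `T = log(R0) / r`: the time a stably growing population needs to
#' multiply `R0`-fold.
#'
#' @param R0 Net reproductive rate.
#' @param r Intrinsic rate of increase (per day).
#' @return `T` in days.
#' @export
mean_generation_time <- function(R0, r) {
  if (any(R0 <= 0)) abort("mean generation time needs R0 > 0")
  if (any(r == 0)) abort("mean generation time is undefined at r = 0")
  log(R0) / r
}

#' All five population parameters of a cohort
#'
#' Convenience wrapper computing `R0`, `GRR`, `r`, `lambda` and `T` from a
#' schedule set. When the cohort produced no eggs, `R0` and `GRR` are zero
#' and `r`, `lambda`, `T` are `NA` (undefined).
#'
#' @inheritParams intrinsic_rate
#' @return A one-row tibble with columns `label`, `R0`, `GRR`, `r`,
#'   `lambda`, `T`.
#' @export
#' @examples
#' ch <- simulate_cohort(preset_params("24C"), seed = 1)
#' population_params(life_schedules(ch))
population_params <- function(schedules, tol = 1e-10,
                              convention = c("x_plus_1", "x")) {
  stopifnot(inherits(schedules, "schedule_set"))
  convention <- match.arg(convention)
  r0 <- net_reproductive_rate(schedules)
  grr <- gross_reproductive_rate(schedules)
  if (r0 > 0) {
    r <- intrinsic_rate(schedules, tol = tol, convention = convention)
    lam <- finite_rate(r)
    gen_t <- if (r == 0) NA_real_ else mean_generation_time(r0, r)
  } else {
    r <- NA_real_
    lam <- NA_real_
    gen_t <- NA_real_
  }
  tibble(label = schedules$label, R0 = r0, GRR = grr, r = r,
         lambda = lam, T = gen_t)
}
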