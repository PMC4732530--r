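#' @keywords internal
"_PACKAGE"

## Fixed nuclide order used throughout: the deposition-ratio vector, the
## calibration and the closed-form integrals all index into this order.
NUCLIDE_ORDER <- c("Te-129m", "Te-129", "I-131", "Te-132", "I-132",
                   "Cs-134", "Cs-137")

#' Hours in one year as used by the dose integral
#'
#' One year is taken as 365.25 d = 8766 h. The choice versus 365 d changes
#' the caesium term of the one-year dose by less than 0.1\%; every function
#' that integrates over time accepts an explicit `horizon_hours` so the
#' convention is overridable.
#'
#' @return Number of hours (8766).
#' @export
hours_per_year <- function() 8766

#' Seven-nuclide table for surface beta-dose calculations
#'
#' Builds the ordered table of the seven radionuclides that dominate the
#' surface beta-ray dose after a reactor release: Te-129m, Te-129, I-131,
#' Te-132, I-132, Cs-134 and Cs-137 (in this fixed order). Each nuclide
#' carries a half-life, an initial surface dose-rate coefficient `d0`
#' (70 um dose equivalent, uSv/h produced when that nuclide's own deposition
#' is 1000 kBq/m2), and optionally a `decay_parent`: the short-lived
#' daughters Te-129 (70 min) and I-132 (2.3 h) are sustained in activity
#' equilibrium by their parents, so their time behaviour follows the
#' parent's half-life.
#'
#' @param half_life_days Named numeric vector of half-lives in days for all
#'   seven nuclides. Daughters in equilibrium may carry their own (unused)
#'   half-life; decay always uses the parent-resolved value.
#' @param d0 Named numeric vector of initial dose-rate coefficients in
#'   uSv/h per 1000 kBq/m2 of the nuclide's own deposition; defaults to 0
#'   (uncalibrated). See [calibrate_coefficients()].
#' @param decay_parent Named character vector mapping daughter name to
#'   parent name; `NA` for independent nuclides.
#' @param reference_date Calendar date of the main deposition. Defaults to
#'   2011-03-15, the main fallout date of the event the model targets.
#' @return A `data.frame` of class `"nuclide_set"` with columns `name`,
#'   `half_life_hours`, `d0`, `decay_parent` and attribute `reference_date`.
#' @examples
#' ns <- default_nuclides()
#' effective_half_life(ns) / 24   # parent-resolved half-lives in days
#' @export
nuclide_set <- function(half_life_days,
                        d0 = stats::setNames(numeric(7), NUCLIDE_ORDER),
                        decay_parent = c("Te-129" = "Te-129m",
                                         "I-132" = "Te-132"),
                        reference_date = as.Date("2011-03-15")) {
  if (!all(NUCLIDE_ORDER %in% names(half_life_days)))
    stop("half_life_days must name all seven nuclides: ",
         paste(NUCLIDE_ORDER, collapse = ", "))
  hl <- half_life_days[NUCLIDE_ORDER]
  if (any(!is.finite(hl)) || any(hl <= 0))
    stop("half-lives must be positive and finite")
  d0v <- stats::setNames(numeric(7), NUCLIDE_ORDER)
  d0v[names(d0)] <- d0
  if (any(d0v < 0)) stop("d0 coefficients must be non-negative")
  parent <- stats::setNames(rep(NA_character_, 7), NUCLIDE_ORDER)
  parent[names(decay_parent)] <- decay_parent
  if (any(!is.na(parent) & !(parent %in% NUCLIDE_ORDER)))
    stop("decay_parent refers to an unknown nuclide")
  out <- data.frame(name = NUCLIDE_ORDER,
                    half_life_hours = unname(hl) * 24,
                    d0 = unname(d0v),
                    decay_parent = unname(parent),
                    stringsAsFactors = FALSE)
  attr(out, "reference_date") <- as.Date(reference_date)
  class(out) <- c("nuclide_set", "data.frame")
  out
}

#' Default nuclide set
#'
#' Half-lives: Te-129m 33.6 d, I-131 8.021 d, Te-132 3.204 d; Cs-134
#' 2.0652 y and Cs-137 30.07 y from standard nuclear data. Te-129 and
#' I-132 are flagged as equilibrium daughters of Te-129m and Te-132.
#' Dose-rate coefficients `d0` start at zero; use
#' [calibrate_coefficients()] or [beta_dose_model()] to fill them.
#'
#' @inheritParams nuclide_set
#' @param cs134_half_life_days,cs137_half_life_days Overridable caesium
#'   half-lives in days.
#' @return A `"nuclide_set"`.
#' @export
default_nuclides <- function(reference_date = as.Date("2011-03-15"),
                             cs134_half_life_days = 2.0652 * 365.25,
                             cs137_half_life_days = 30.07 * 365.25) {
  nuclide_set(
    half_life_days = c("Te-129m" = 33.6,
                       "Te-129"  = 70 / 60 / 24,   # 70 min, unused (parent-driven)
                       "I-131"   = 8.021,
                       "Te-132"  = 3.204,
                       "I-132"   = 2.3 / 24,       # 2.3 h, unused (parent-driven)
                       "Cs-134"  = cs134_half_life_days,
                       "Cs-137"  = cs137_half_life_days),
    reference_date = reference_date)
}

#' Parent-resolved half-lives
#'
#' Returns the effective half-life (hours) governing each nuclide's decay:
#' its own, or its `decay_parent`'s where one is set.
#'
#' @param nuclides A `"nuclide_set"`.
#' @return Named numeric vector of hours, in nuclide order.
#' @export
effective_half_life <- function(nuclides) {
  stopifnot(inherits(nuclides, "nuclide_set"))
  hl <- stats::setNames(nuclides$half_life_hours, nuclides$name)
  out <- hl
  has_parent <- !is.na(nuclides$decay_parent)
  out[has_parent] <- hl[nuclides$decay_parent[has_parent]]
  out
}

#' Deposition-ratio vector from the two free ratio parameters
#'
#' The seven-component vector of nuclide-to-Cs-137 activity ratios at the
#' time of deposition, parameterized by `r_i` (I-131/Cs-137) and `r_t`
#' (Te-129m/Cs-137). Te-129 and I-132 are tied to Te-129m by the fixed
#' factors 0.7 and 8.3; Te-132 shares I-132's ratio (equilibrium);
#' Cs-134/Cs-137 and Cs-137/Cs-137 are 1. With `r_i = 9.2`, `r_t = 1`
#' this reproduces the reference vector 1 : 0.7 : 9.2 : 8.3 : 8.3 : 1 : 1.
#'
#' @param r_i I-131/Cs-137 activity ratio at deposition (dimensionless, >= 0).
#' @param r_t Te-129m/Cs-137 activity ratio at deposition (>= 0).
#' @return Named numeric vector of length 7 in nuclide order.
#' @examples
#' deposition_ratios(9.2, 1)
#' @export
deposition_ratios <- function(r_i, r_t) {
  if (length(r_i) != 1L || length(r_t) != 1L)
    stop("r_i and r_t must be scalars")
  if (!is.finite(r_i) || !is.finite(r_t) || r_i < 0 || r_t < 0)
    stop("ratio parameters must be finite and non-negative")
  stats::setNames(c(r_t, 0.7 * r_t, r_i, 8.3 * r_t, 8.3 * r_t, 1, 1),
                  NUCLIDE_ORDER)
}

#' Surface beta dose rate at a time after deposition
#'
#' Sum over nuclides of `f_i * d0_i * 2^(-t / T_i)`, where `f_i` is the
#' deposition-ratio vector, `d0_i` the initial dose-rate coefficient and
#' `T_i` the parent-resolved half-life. Units: uSv/h per 1000 kBq/m2 of
#' Cs-137 deposition.
#'
#' @inheritParams deposition_ratios
#' @param nuclides A calibrated `"nuclide_set"`.
#' @param t_hours Time(s) since deposition in hours (vectorized, >= 0).
#' @return Dose rate(s), uSv/h per 1000 kBq/m2 Cs-137.
#' @export
dose_rate <- function(nuclides, r_i, r_t, t_hours) {
  stopifnot(inherits(nuclides, "nuclide_set"))
  if (any(!is.finite(t_hours)) || any(t_hours < 0))
    stop("t_hours must be finite and non-negative")
  f <- deposition_ratios(r_i, r_t)
  T_eff <- effective_half_life(nuclides)
  w <- f * nuclides$d0
  vapply(t_hours, function(t) sum(w * 2^(-t / T_eff)), numeric(1))
}

#' Dose-rate curve over a time grid
#'
#' Convenience wrapper evaluating [dose_rate()] on a time grid, for plots of
#' the decaying surface dose rate (the fast I-131 roll-off against the slow
#' caesium floor).
#'
#' @inheritParams dose_rate
#' @param times_hours Strictly increasing time grid in hours.
#' @return `data.frame` with `t_hours`, `t_days`, `rate` columns, class
#'   `"dose_rate_curve"`.
#' @export
dose_rate_curve <- function(nuclides, r_i, r_t,
                            times_hours = 10^seq(0, log10(hours_per_year()),
                                                 length.out = 200)) {
  if (any(diff(times_hours) <= 0)) stop("times_hours must be strictly increasing")
  out <- data.frame(t_hours = times_hours,
                    t_days = times_hours / 24,
                    rate = dose_rate(nuclides, r_i, r_t, times_hours))
  class(out) <- c("dose_rate_curve", "data.frame")
  out
}

## Integral of 2^(-t/T) from 0 to H: (T/ln 2) (1 - 2^(-H/T)), hours.
decay_integral <- function(T_half, horizon) {
  T_half / log(2) * (1 - 2^(-horizon / T_half))
}

#' Cumulative surface beta dose over a horizon
#'
#' Closed-form time integral of [dose_rate()] from deposition to
#' `horizon_hours`:
#' `(1/1000) * sum_i f_i * d0_i * (T_i/ln 2) * (1 - 2^(-H/T_i))`,
#' the 1/1000 converting uSv to mSv. Defaults to the one-year horizon.
#'
#' @inheritParams dose_rate
#' @param horizon_hours Positive integration horizon in hours.
#' @return Dose in mSv per 1000 kBq/m2 of Cs-137 deposition.
#' @examples
#' m <- beta_dose_model()
#' cumulative_dose(m$nuclides, r_i = 9.2, r_t = 1)   # ~91.3 mSv
#' @export
cumulative_dose <- function(nuclides, r_i, r_t,
                            horizon_hours = hours_per_year()) {
  stopifnot(inherits(nuclides, "nuclide_set"))
  if (!is.finite(horizon_hours) || horizon_hours <= 0)
    stop("horizon_hours must be positive")
  f <- deposition_ratios(r_i, r_t)
  T_eff <- effective_half_life(nuclides)
  sum(f * nuclides$d0 * decay_integral(T_eff, horizon_hours)) / 1000
}

#' Decay-correct an activity ratio to a reference date
#'
#' Rescales a measured activity ratio back to the deposition date using the
#' exponential decay law with parent-resolved half-lives:
#' `(a_num/a_den) * 2^(dt/T_num) / 2^(dt/T_den)` with `dt` the whole-day
#' interval from `reference_date` to `sample_date`, converted to hours.
#'
#' @param a_num,a_den Measured activities (same units); `a_den > 0`.
#' @param num,den Nuclide names (e.g. `"I-131"`, `"Cs-137"`).
#' @param sample_date,reference_date Calendar dates; `sample_date` must not
#'   precede `reference_date`.
#' @param nuclides `"nuclide_set"` supplying half-lives; defaults to
#'   [default_nuclides()].
#' @return Dimensionless ratio at `reference_date`.
#' @examples
#' # raw 17/7900 measured 91 d after deposition -> ~5.6 at deposition
#' decay_correct_ratio(17, 7900, "I-131", "Cs-137",
#'                     as.Date("2011-06-14"), as.Date("2011-03-15"))
#' @export
decay_correct_ratio <- function(a_num, a_den, num, den,
                                sample_date,
                                reference_date = attr(nuclides, "reference_date"),
                                nuclides = default_nuclides()) {
  if (any(!is.finite(a_den)) || any(a_den <= 0))
    stop("denominator activity must be positive")
  T_eff <- effective_half_life(nuclides)
  if (!num %in% names(T_eff) || !den %in% names(T_eff))
    stop("unknown nuclide name")
  dt_days <- as.numeric(as.Date(sample_date) - as.Date(reference_date),
                        units = "days")
  if (any(dt_days < 0)) stop("sample_date precedes reference_date")
  dt <- floor(dt_days) * 24
  (a_num / a_den) * 2^(dt / T_eff[[num]]) / 2^(dt / T_eff[[den]])
}

#' Calibrate dose-rate coefficients from a linear dose surface
#'
#' Inverts the one-year linear dose surface
#' `D(r_i, r_t) = a * r_i + slope_b * r_t + intercept_b` back to per-nuclide
#' initial dose-rate coefficients `d0`. With
#' `I(T) = (T/ln 2)(1 - 2^(-H/T))` at horizon `H`:
#' the I-131 coefficient is `1000 a / I(T_I131)`; the 33.6-d tellurium group
#' composite `d0_Te129m + 0.7 d0_Te129` and the 3.204-d group composite
#' `8.3 (d0_Te132 + d0_I132)` partition `1000 slope_b` across `I(T_Te129m)`
#' and `I(T_Te132)` by `te_split`; the caesium coefficients partition
#' `1000 intercept_b` across `I(T_Cs134)` and `I(T_Cs137)` by `cs_split`.
#' Only the group composites are identifiable from the surface; within each
#' tellurium group the coefficient is shared equally between the two members.
#' Whatever the splits, [cumulative_dose()] with the returned set reproduces
#' the linear surface exactly (round-trip guarantee).
#'
#' @param targets A [parameterization()] (or numeric `c(a, slope_b,
#'   intercept_b)`).
#' @param nuclides `"nuclide_set"` supplying half-lives.
#' @param te_split Fraction of the `r_t` slope carried by the 33.6-d
#'   tellurium group (remainder to the 3.204-d group); in `[0, 1]`.
#' @param cs_split Fraction of the intercept carried by Cs-134; in `[0, 1]`.
#' @param horizon_hours Horizon the targets refer to.
#' @return The `"nuclide_set"` with `d0` filled.
#' @export
calibrate_coefficients <- function(targets,
                                   nuclides = default_nuclides(),
                                   te_split = 0.5, cs_split = 0.5,
                                   horizon_hours = hours_per_year()) {
  p <- as_parameterization(targets)
  if (!is.finite(te_split) || te_split < 0 || te_split > 1 ||
      !is.finite(cs_split) || cs_split < 0 || cs_split > 1)
    stop("splits must lie in [0, 1]")
  T_eff <- effective_half_life(nuclides)
  I <- decay_integral(T_eff, horizon_hours)
  d0 <- stats::setNames(numeric(7), NUCLIDE_ORDER)
  d0["I-131"] <- 1000 * p$a / I[["I-131"]]
  # 33.6-d group: (d0_Te129m + 0.7 d0_Te129) * I_129m = te_split * 1000 slope_b
  g1 <- te_split * 1000 * p$slope_b / I[["Te-129m"]]
  d0["Te-129m"] <- g1 / 2
  d0["Te-129"]  <- g1 / 2 / 0.7
  # 3.204-d group: 8.3 (d0_Te132 + d0_I132) * I_132 = (1-te_split) * 1000 slope_b
  g2 <- (1 - te_split) * 1000 * p$slope_b / I[["Te-132"]] / 8.3
  d0["Te-132"] <- g2 / 2
  d0["I-132"]  <- g2 / 2
  d0["Cs-134"] <- cs_split * 1000 * p$intercept_b / I[["Cs-134"]]
  d0["Cs-137"] <- (1 - cs_split) * 1000 * p$intercept_b / I[["Cs-137"]]
  if (any(d0 < 0)) stop("calibration targets imply negative coefficients")
  nuclides$d0 <- unname(d0[nuclides$name])
  nuclides
}
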