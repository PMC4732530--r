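#' Linear dose-surface parameterization
#'
#' The one-year cumulative surface beta dose per 1000 kBq/m2 of Cs-137,
#' as a linear function of the two deposition-ratio parameters:
#' `D(r_i, r_t) = a * r_i + slope_b * r_t + intercept_b` (mSv per
#' 1000 kBq/m2). The published calibration is
#' `D = 1.1165 r_i + 31.032 r_t + 50.009`.
#'
#' @param a Slope in `r_i` (mSv per unit ratio per 1000 kBq/m2).
#' @param slope_b Slope in `r_t`.
#' @param intercept_b Intercept (caesium-only dose); must be positive for
#'   any physical calibration.
#' @return An object of class `"parameterization"`.
#' @examples
#' p <- parameterization()
#' evaluate_dose(p, r_i = 9.2, r_t = 1)
#' @export
parameterization <- function(a = 1.1165, slope_b = 31.032,
                             intercept_b = 50.009) {
  vals <- c(a = a, slope_b = slope_b, intercept_b = intercept_b)
  if (any(!is.finite(vals))) stop("coefficients must be finite")
  if (intercept_b <= 0) stop("intercept_b must be positive")
  structure(list(a = a, slope_b = slope_b, intercept_b = intercept_b),
            class = "parameterization")
}

as_parameterization <- function(x) {
  if (inherits(x, "parameterization")) return(x)
  if (is.numeric(x) && length(x) == 3)
    return(parameterization(x[[1]], x[[2]], x[[3]]))
  stop("cannot interpret 'targets' as a parameterization")
}

#' @export
print.parameterization <- function(x, ...) {
  cat(sprintf("Linear dose surface: D(r_I, r_T) = %.4f r_I + %.3f r_T + %.3f  [mSv per 1000 kBq/m2 Cs-137]\n",
              x$a, x$slope_b, x$intercept_b))
  invisible(x)
}

#' Evaluate the linear dose surface
#'
#' @param param A [parameterization()].
#' @param r_i,r_t Deposition-ratio parameters (vectorized, >= 0).
#' @return Dose(s) in mSv per 1000 kBq/m2 of Cs-137.
#' @export
evaluate_dose <- function(param, r_i, r_t) {
  param <- as_parameterization(param)
  if (any(!is.finite(r_i)) || any(!is.finite(r_t)) ||
      any(r_i < 0) || any(r_t < 0))
    stop("ratio parameters must be finite and non-negative")
  param$a * r_i + param$slope_b * r_t + param$intercept_b
}

#' Scale a per-unit-deposition dose by the local Cs-137 deposition
#'
#' `d_a = d_unit * a_cs137 / 1000`: the absolute cumulative dose (mSv) at a
#' location with Cs-137 deposition density `a_cs137` (kBq/m2), given the
#' dose `d_unit` per 1000 kBq/m2.
#'
#' @param d_unit Dose per 1000 kBq/m2 Cs-137 (mSv), vectorized.
#' @param a_cs137 Cs-137 deposition density (kBq/m2, >= 0), vectorized.
#' @return Absolute dose(s) in mSv.
#' @examples
#' apply_deposition(89.9, 7900)   # 710.2 mSv
#' @export
apply_deposition <- function(d_unit, a_cs137) {
  if (any(!is.finite(a_cs137)) || any(a_cs137 < 0))
    stop("deposition density must be finite and non-negative")
  d_unit * a_cs137 / 1000
}

#' Fit the dose surface slope in r_I at a series of r_T values
#'
#' For each value of `r_t`, evaluates the forward model [cumulative_dose()]
#' over the `r_i` grid and fits an ordinary least-squares line
#' `D = slope * r_i + b`. Because the forward model is exactly linear in
#' both ratio parameters, the slope is identical across `r_t` values and
#' residuals vanish to rounding; the table of intercepts `b(r_t)` is the
#' input to [fit_b_line()].
#'
#' @param model A [beta_dose_model()] (or calibrated `"nuclide_set"`).
#' @param r_i_grid Numeric grid of `r_i` values (>= 2 distinct).
#' @param r_t_values Values of `r_t` at which to fit.
#' @param horizon_hours Integration horizon.
#' @return `data.frame` of class `"fit_table"` with columns `r_t`, `slope`,
#'   `intercept`, `max_resid`.
#' @export
scan_fit <- function(model,
                     r_i_grid = c(5, 9.2, 20, 40, 100, 200),
                     r_t_values = c(0.1, 0.5, 1, 5, 10, 50),
                     horizon_hours = hours_per_year()) {
  nuclides <- if (inherits(model, "beta_dose_model")) model$nuclides else model
  stopifnot(inherits(nuclides, "nuclide_set"))
  if (length(unique(r_i_grid)) < 2)
    stop("degenerate r_i grid: need at least 2 distinct values")
  rows <- lapply(r_t_values, function(rt) {
    d <- vapply(r_i_grid, function(ri)
      cumulative_dose(nuclides, ri, rt, horizon_hours), numeric(1))
    fit <- stats::lm(d ~ r_i_grid)
    data.frame(r_t = rt,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               max_resid = max(abs(stats::residuals(fit))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fit_table", "data.frame")
  out
}

#' Re-fit the intercept series against r_T
#'
#' Ordinary least squares of the per-`r_t` intercepts `b` on `r_t`,
#' collapsing the [scan_fit()] table to the final two coefficients of the
#' linear dose surface.
#'
#' @param table A `"fit_table"` from [scan_fit()], or any data.frame with
#'   columns `r_t` and `intercept` (or `b`).
#' @return List with `slope_b` and `intercept_b`.
#' @examples
#' tab <- data.frame(r_t = c(0.1, 0.5, 1, 5),
#'                   intercept = c(53.064, 65.478, 81.1425, 205.1310))
#' fit_b_line(tab)   # ~31.03 and ~50.01
#' @export
fit_b_line <- function(table) {
  b <- if ("intercept" %in% names(table)) table$intercept else table$b
  r_t <- table$r_t
  if (is.null(b) || is.null(r_t)) stop("need columns r_t and intercept (or b)")
  if (length(r_t) < 2 || length(unique(r_t)) < 2)
    stop("singular fit: need >= 2 distinct r_t values")
  fit <- stats::lm(b ~ r_t)
  list(slope_b = unname(stats::coef(fit)[2]),
       intercept_b = unname(stats::coef(fit)[1]))
}

#' Recover the full linear parameterization from the forward model
#'
#' Runs [scan_fit()] then [fit_b_line()] and returns the implied
#' [parameterization()] (`a` is the mean of the per-`r_t` slopes, which are
#' identical up to rounding).
#'
#' @inheritParams scan_fit
#' @return A `"parameterization"`.
#' @export
refit_parameterization <- function(model,
                                   r_i_grid = c(5, 9.2, 20, 40, 100, 200),
                                   r_t_values = c(0.1, 0.5, 1, 5, 10, 50),
                                   horizon_hours = hours_per_year()) {
  tab <- scan_fit(model, r_i_grid, r_t_values, horizon_hours)
  bl <- fit_b_line(tab)
  parameterization(mean(tab$slope), bl$slope_b, bl$intercept_b)
}
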