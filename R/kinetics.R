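#' Fractional carbohydrate solubilization
#'
#' `FCS = (mass_initial - mass_final) / mass_initial`: the fraction of fed
#' monomer-equivalent carbohydrate no longer present as solids. Residual mass
#' exceeding the fed mass is a measurement inconsistency and is rejected, not
#' clipped to zero — silent clipping hides assay problems.
#'
#' @param mass_initial Fed carbohydrate, g monomer equivalent (or g/L).
#' @param mass_final Residual carbohydrate on the same basis.
#'
#' @return FCS as a fraction in `[0, 1]`. Vectorised over both arguments.
#' @examples
#' compute_fcs(17.3, 5.0)
#' @export
compute_fcs <- function(mass_initial, mass_final) {
  if (any(!is.finite(mass_initial)) || any(mass_initial <= 0)) {
    stop_domain("mass_initial must be > 0", "thermodigest_domain_error")
  }
  if (any(!is.finite(mass_final)) || any(mass_final < 0)) {
    stop_domain("mass_final must be >= 0", "thermodigest_domain_error")
  }
  bad <- mass_final > mass_initial
  if (any(bad)) {
    i <- which(bad)[1]
    stop_domain(
      sprintf(
        "residual carbohydrate (%.4g) exceeds fed carbohydrate (%.4g); negative solubilization rejected",
        mass_final[i], mass_initial[i]
      ),
      "thermodigest_measurement_inconsistency",
      mass_initial = mass_initial[bad], mass_final = mass_final[bad]
    )
  }
  (mass_initial - mass_final) / mass_initial
}

#' Convert steady-state observations to kinetic points
#'
#' At steady state with residence time RT the unutilized carbohydrate
#' concentration is `C = C0 * (1 - FCS)` and the volumetric solubilization
#' rate is `r = C0 * FCS / RT`. One row per observation; typically the
#' per-RT means of replicate reactors are used.
#'
#' @param obs Data frame with columns `rt_days` and `fcs_total` (extra
#'   columns are carried through).
#' @param c0 Feed carbohydrate concentration, g monomer equivalent / L
#'   (see [feed_carbohydrate_concentration()]).
#'
#' @return The input tibble with `c_unutilized` (g/L) and `rate` (g/L/day)
#'   columns appended.
#' @export
steady_state_points <- function(obs, c0) {
  obs <- as_tibble(obs)
  stopifnot(all(c("rt_days", "fcs_total") %in% names(obs)))
  if (!is.numeric(c0) || length(c0) != 1 || !is.finite(c0) || c0 <= 0) {
    stop_domain("c0 must be a single positive number", "thermodigest_domain_error")
  }
  if (any(!is.finite(obs$rt_days)) || any(obs$rt_days <= 0)) {
    stop_domain("rt_days must be > 0", "thermodigest_domain_error")
  }
  if (any(obs$fcs_total < 0) || any(obs$fcs_total > 1)) {
    stop_domain("fcs_total must lie in [0, 1]", "thermodigest_domain_error")
  }
  dplyr::mutate(obs,
    c_unutilized = c0 * (1 - .data$fcs_total),
    rate = c0 * .data$fcs_total / .data$rt_days
  )
}

#' Fit the recalcitrant-fraction first-order rate law
#'
#' Fits `r = k (C - C0 * fr)` by unweighted ordinary least squares of the
#' solubilization rate `r` on the unutilized carbohydrate concentration `C`.
#' The slope is the first-order rate constant `k` (1/day); the recalcitrant
#' fraction is recovered from the intercept `b` as `fr = -b / (k * C0)`:
#' the extrapolated share of entering carbohydrate unconverted at infinite
#' residence time. The standard error of `fr` is propagated from the OLS
#' coefficient covariance by the delta method.
#'
#' @param points Data frame with columns `c_unutilized` and `rate`, e.g.
#'   from [steady_state_points()]. At least 3 points with distinct
#'   `c_unutilized` values are required.
#' @param c0 Feed carbohydrate concentration, g/L.
#'
#' @return An object of class `recalcitrance_fit`; see [tidy()], [glance()]
#'   and [autoplot()] methods, and [predict_steady_state_fcs()].
#' @examples
#' obs <- tibble::tibble(
#'   rt_days = c(20, 10, 5, 3.3),
#'   fcs_total = c(0.711, 0.654, 0.581, 0.538)
#' )
#' fit <- obs |>
#'   steady_state_points(c0 = 17.3) |>
#'   fit_recalcitrant_first_order(c0 = 17.3)
#' tidy(fit)
#' @export
fit_recalcitrant_first_order <- function(points, c0) {
  points <- as_tibble(points)
  stopifnot(all(c("c_unutilized", "rate") %in% names(points)))
  if (!is.numeric(c0) || length(c0) != 1 || !is.finite(c0) || c0 <= 0) {
    stop_domain("c0 must be a single positive number", "thermodigest_domain_error")
  }
  if (nrow(points) < 3 || dplyr::n_distinct(points$c_unutilized) < 2) {
    stop_domain(
      "need at least 3 kinetic points with distinct unutilized-carbohydrate values",
      "thermodigest_fit_error")
  }
  if (any(points$c_unutilized < 0) || any(points$rate < 0)) {
    stop_domain("kinetic points must have non-negative C and r",
      "thermodigest_domain_error")
  }
  mod <- lm(rate ~ c_unutilized, data = points)
  b <- unname(coef(mod)[1])
  a <- unname(coef(mod)[2])
  if (!is.finite(a) || a <= 0) {
    stop_domain(
      sprintf("fitted slope k = %.4g is not positive; rate law r = k(C - C0 fr) does not describe these points", a),
      "thermodigest_nonphysical_fit")
  }
  f_r <- -b / (a * c0)
  # delta method: f = -b/(a c0); grad = (d f / d b, d f / d a)
  V <- suppressWarnings(vcov(mod)) # perfect-fit warning on noiseless input
  grad <- c(-1 / (a * c0), b / (a^2 * c0))
  f_r_var <- drop(t(grad) %*% V %*% grad)
  smry <- suppressWarnings(summary(mod)) # noiseless inputs trip lm's perfect-fit warning
  out <- structure(
    list(
      k = a,
      f_r = f_r,
      k_se = unname(smry$coefficients["c_unutilized", "Std. Error"]),
      f_r_se = sqrt(f_r_var),
      c0 = c0,
      r_squared = smry$r.squared,
      points = dplyr::mutate(points, fitted = unname(predict(mod)),
        residual = .data$rate - .data$fitted),
      model = mod
    ),
    class = "recalcitrance_fit"
  )
  out
}

#' @export
print.recalcitrance_fit <- function(x, ...) {
  cat("Recalcitrant-fraction first-order solubilization fit\n")
  cat(sprintf("  r = k (C - C0 fr),  C0 = %.3g g/L,  n = %d points\n",
    x$c0, nrow(x$points)))
  cat(sprintf("  k   = %.3f +/- %.3f 1/day\n", x$k, x$k_se))
  cat(sprintf("  fr  = %.1f +/- %.1f %%\n", 100 * x$f_r, 100 * x$f_r_se))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Tidy a recalcitrance fit
#'
#' @param x A `recalcitrance_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`k`, `f_r`).
#' @method tidy recalcitrance_fit
#' @export
tidy.recalcitrance_fit <- function(x, ...) {
  tibble(
    term = c("k", "f_r"),
    estimate = c(x$k, x$f_r),
    std.error = c(x$k_se, x$f_r_se),
    unit = c("1/day", "fraction")
  )
}

#' One-row fit summary
#'
#' @param x A `recalcitrance_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `k_se`, `f_r`, `f_r_se`, `c0`,
#'   `r.squared`, `nobs`.
#' @method glance recalcitrance_fit
#' @export
glance.recalcitrance_fit <- function(x, ...) {
  tibble(
    k = x$k, k_se = x$k_se, f_r = x$f_r, f_r_se = x$f_r_se,
    c0 = x$c0, r.squared = x$r_squared, nobs = nrow(x$points)
  )
}

#' Predict steady-state solubilization at a given residence time
#'
#' Closed-form steady state of the rate law under continuous washout: solving
#' `k (C - C0 fr) = (C0 - C) / RT` gives
#' `FCS = 1 - fr - (1 - fr) / (1 + k RT)`. Strictly increasing in RT,
#' approaching `1 - fr` as RT grows.
#'
#' @param fit A `recalcitrance_fit`, or a list with elements `k` and `f_r`.
#' @param rt_days Residence time(s), days.
#' @return Predicted FCS, same length as `rt_days`.
#' @export
predict_steady_state_fcs <- function(fit, rt_days) {
  k <- fit$k
  f_r <- fit$f_r
  stopifnot(is.numeric(k), k > 0, is.numeric(f_r), f_r >= 0, f_r < 1)
  if (any(!is.finite(rt_days)) || any(rt_days <= 0)) {
    stop_domain("rt_days must be > 0", "thermodigest_domain_error")
  }
  (1 - f_r) - (1 - f_r) / (1 + k * rt_days)
}

#' Glucan-xylan co-solubilization regression
#'
#' OLS of fractional xylan solubilization on fractional glucan
#' solubilization across samples. A slope near 1 with a small intercept
#' indicates the two polysaccharides are attacked together rather than
#' sequentially.
#'
#' @param pairs Data frame with columns `fcs_glucan` and `fcs_xylan`.
#' @return A one-row tibble: `slope`, `intercept`, their standard errors,
#'   `r_squared`, `n`.
#' @export
glucan_xylan_regression <- function(pairs) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("fcs_glucan", "fcs_xylan") %in% names(pairs)))
  if (nrow(pairs) < 3 || dplyr::n_distinct(pairs$fcs_glucan) < 2) {
    stop_domain("need at least 3 pairs with non-degenerate fcs_glucan",
      "thermodigest_fit_error")
  }
  mod <- lm(fcs_xylan ~ fcs_glucan, data = pairs)
  s <- suppressWarnings(summary(mod))
  tibble(
    slope = unname(coef(mod)[2]),
    intercept = unname(coef(mod)[1]),
    slope_se = s$coefficients["fcs_glucan", "Std. Error"],
    intercept_se = s$coefficients["(Intercept)", "Std. Error"],
    r_squared = s$r.squared,
    n = nrow(pairs)
  )
}
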