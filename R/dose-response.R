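#' Fit the median-effect model to a single-agent dose series
#'
#' The median-effect model relates the fraction affected `fa` and fraction
#' unaffected `fu = 1 - fa` to dose `D` through `fa/fu = (D/Dm)^m`, where `Dm`
#' is the median-effect dose (the dose giving `fa = 0.5`, i.e. the IC50) and
#' `m` the sigmoidicity slope. The default fit is the classical linearization:
#' least squares of `log(fa/fu)` on `log(D)`, whose slope is `m` and intercept
#' `-m log(Dm)`. `method = "nonlinear"` refines the linearized estimate by
#' nonlinear least squares on the `fa` scale.
#'
#' Wells with `fa` at (or clamped to) 0 or 1 carry no information on the log
#' scale; `fa` is clamped to `[epsilon, 1 - epsilon]` and dose levels sitting
#' at the clamp boundary are excluded from the fit (their indices are recorded
#' in `censored_levels`). Doses above `dose_ceiling` (default 10 uM, where
#' off-target effects dominate) and the vehicle level are excluded likewise.
#'
#' Saturation at the drug's own maximal effect is censored the same way:
#' once the response has plateaued, doses beyond the first level reaching
#' within `plateau_tol` of the maximal observed `fa` repeat the ceiling
#' without adding dose-response information, and fitting them flattens the
#' slope and corrupts the effect-dose interpolation the combination index
#' relies on (partial-efficacy drugs would otherwise read as spuriously
#' synergistic). Only the first plateau level is kept. Set `plateau_tol = 0`
#' to disable.
#'
#' @param doses Vector of doses (molar); a vehicle level (0) is allowed and
#'   ignored.
#' @param fa Fraction affected at each dose (from [normalize_block()]).
#' @param epsilon Clamp half-width defining unusable saturated levels.
#' @param dose_ceiling Doses strictly above this are excluded (molar).
#' @param plateau_tol Effect tolerance defining the saturation plateau
#'   (absolute, on the `fa` scale; default 0.05).
#' @param method `"linearized"` (default) or `"nonlinear"` (minpack.lm
#'   Levenberg-Marquardt on the `fa` scale, started from the linearized fit).
#' @return A `medfit` object: list with `Dm`, `m`, `n_points_used`,
#'   `r_squared` (of the linearized fit), `censored_levels`, `method`, `ok`.
#'   An unfittable series (< 2 usable points, or a non-positive slope) raises
#'   a fit error flagging the compound as inactive/unfittable.
#' @export
#' @examples
#' fit <- fit_median_effect(c(100, 400, 1600) * 1e-9, c(0.2, 0.5, 0.8))
#' tidy(fit)
#' dose_for_effect(fit, 0.8)
fit_median_effect <- function(doses, fa, epsilon = 1e-4, dose_ceiling = 10e-6,
                              plateau_tol = 0.05,
                              method = c("linearized", "nonlinear")) {
  method <- match.arg(method)
  if (length(doses) != length(fa)) cs_abort("doses and fa differ in length", "value")
  if (any(doses < 0, na.rm = TRUE)) cs_abort("doses must be nonnegative", "value")

  fa_cl <- pmin(pmax(fa, epsilon), 1 - epsilon)
  usable <- is.finite(doses) & is.finite(fa_cl) &
    doses > 0 & doses <= dose_ceiling &
    fa_cl > epsilon & fa_cl < 1 - epsilon

  if (plateau_tol > 0 && sum(usable) > 2) {
    # Censor the saturated plateau: keep the first dose level whose effect
    # reaches (max fa - plateau_tol); everything above it repeats the
    # drug's own ceiling.
    ord <- order(doses)
    uord <- ord[usable[ord]]
    fa_u <- fa_cl[uord]
    first_plateau <- which(fa_u >= max(fa_u) - plateau_tol)[1]
    if (first_plateau < length(uord)) {
      usable[uord[(first_plateau + 1):length(uord)]] <- FALSE
    }
  }
  censored <- which(!usable)
  if (sum(usable) < 2) {
    cs_abort("fewer than 2 usable dose levels: compound inactive/unfittable",
             "fit", n_usable = sum(usable))
  }

  x <- log(doses[usable])
  y <- log(fa_cl[usable] / (1 - fa_cl[usable]))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  if (!is.finite(m) || m <= 0) {
    cs_abort("median-effect slope is not positive: compound inactive/unfittable", "fit")
  }
  Dm <- exp(-unname(coef(fit)[1]) / m)
  r2 <- if (sum(usable) > 2) suppressWarnings(summary(fit)$r.squared) else 1

  if (method == "nonlinear") {
    d_use <- doses[usable]
    fa_use <- fa_cl[usable]
    nl <- tryCatch(
      minpack.lm::nlsLM(
        fa_use ~ (d_use / Dm)^m / (1 + (d_use / Dm)^m),
        start = list(Dm = Dm, m = m),
        lower = c(Dm = .Machine$double.xmin, m = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(nl)) {
      cf <- coef(nl)
      Dm <- unname(cf["Dm"])
      m <- unname(cf["m"])
    }
  }

  structure(
    list(Dm = Dm, m = m, n_points_used = sum(usable), r_squared = r2,
         censored_levels = censored, method = method, ok = TRUE),
    class = "medfit"
  )
}

#' @export
print.medfit <- function(x, ...) {
  cat(sprintf("<medfit> Dm = %.4g M (%.3g nM), m = %.3f, n = %d, R^2 = %.4f [%s]\n",
              x$Dm, x$Dm * 1e9, x$m, x$n_points_used, x$r_squared, x$method))
  invisible(x)
}

#' @export
tidy.medfit <- function(x, ...) {
  tibble::tibble(term = c("Dm", "m"), estimate = c(x$Dm, x$m))
}

#' @export
glance.medfit <- function(x, ...) {
  tibble::tibble(Dm = x$Dm, m = x$m, r.squared = x$r_squared,
                 n_points_used = x$n_points_used,
                 n_censored = length(x$censored_levels), method = x$method)
}

#' Dose producing a target effect level
#'
#' Inverts the median-effect model: `Dx = Dm * (fa / (1 - fa))^(1/m)`, the dose
#' of the single agent producing fraction affected `fa_target`. This is the
#' `Dx` entering the combination index.
#'
#' @param fit A `medfit` from [fit_median_effect()].
#' @param fa_target Effect level(s), strictly inside (0, 1).
#' @return Dose(s) in the units of `fit$Dm` (molar).
#' @export
dose_for_effect <- function(fit, fa_target) {
  if (!inherits(fit, "medfit")) cs_abort("fit must be a medfit object", "value")
  if (any(fa_target <= 0 | fa_target >= 1)) {
    cs_abort("fa_target must lie strictly inside (0, 1)", "domain")
  }
  fit$Dm * (fa_target / (1 - fa_target))^(1 / fit$m)
}

#' Fit a four-parameter logistic (Hill) viability curve
#'
#' Nonlinear least squares of
#' `v(D) = emax + (e0 - emax) / (1 + (D/ec50)^hill_slope)` on
#' fraction-of-control viability, used for curve QC alongside the
#' median-effect fit (which supplies the IC50s used by the combination-index
#' machinery). Initialization is deterministic: `e0 = 1`, `emax = min(v)`,
#' `ec50` = geometric middle of the nonzero doses, slope 1.
#'
#' @param doses Dose vector (molar), including the vehicle level.
#' @param v Fraction-of-control viability at each dose.
#' @return A `hillfit`: list with `ec50`, `hill_slope`, `e0`, `emax`, `rss`,
#'   `converged`. On non-convergence the fit is returned flagged
#'   (`converged = FALSE`) with the median-effect-derived `ec50` as fallback
#'   (or `NA` if that also fails).
#' @export
fit_hill <- function(doses, v) {
  if (length(doses) != length(v)) cs_abort("doses and v differ in length", "value")
  if (length(doses) < 4) cs_abort("fit_hill needs at least 4 points including vehicle", "value")
  pos <- doses[doses > 0]
  start <- list(e0 = 1, emax = min(v),
                ec50 = exp(mean(log(range(pos)))), hill_slope = 1)
  nl <- tryCatch(
    minpack.lm::nlsLM(
      v ~ emax + (e0 - emax) / (1 + (doses / ec50)^hill_slope),
      start = start,
      lower = c(e0 = 0, emax = 0, ec50 = .Machine$double.xmin, hill_slope = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  flat <- sd(v) < 1e-12
  if (is.null(nl) || flat) {
    fallback <- tryCatch(fit_median_effect(doses, clamp01(1 - v))$Dm,
                         error = function(e) NA_real_)
    return(structure(list(ec50 = fallback, hill_slope = NA_real_, e0 = NA_real_,
                          emax = NA_real_, rss = NA_real_, converged = FALSE),
                     class = "hillfit"))
  }
  cf <- coef(nl)
  structure(
    list(ec50 = unname(cf["ec50"]), hill_slope = unname(cf["hill_slope"]),
         e0 = unname(cf["e0"]), emax = unname(cf["emax"]),
         rss = sum(stats::resid(nl)^2), converged = TRUE),
    class = "hillfit"
  )
}

#' @export
print.hillfit <- function(x, ...) {
  cat(sprintf("<hillfit> ec50 = %.4g M, slope = %.3f, e0 = %.3f, emax = %.3f%s\n",
              x$ec50, x$hill_slope, x$e0, x$emax,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
tidy.hillfit <- function(x, ...) {
  tibble::tibble(term = c("ec50", "hill_slope", "e0", "emax"),
                 estimate = c(x$ec50, x$hill_slope, x$e0, x$emax))
}

#' @export
glance.hillfit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, hill_slope = x$hill_slope, e0 = x$e0,
                 emax = x$emax, rss = x$rss, converged = x$converged)
}

#' IC50 of one drug alone and combined with a fixed dose of its partner
#'
#' Takes the row-slice of a normalized dose matrix at one fixed dose of the
#' partner drug, fits the median-effect model along the varying drug's doses,
#' and reports the resulting IC50 beside the single-agent IC50 (the slice at
#' partner dose 0) as a potency fold-shift. A fold-shift above 1 means the
#' partner sensitizes the cells to the varying drug.
#'
#' @param norm_block Normalized block tibble from [normalize_block()].
#' @param partner_dose Fixed dose of the partner drug (must match a grid
#'   level exactly).
#' @param vary `"A"` (default) to titrate drug A at a fixed drug B dose, or
#'   `"B"` for the transpose.
#' @param ... Passed to [fit_median_effect()] (e.g. `dose_ceiling`).
#' @return One-row tibble: `ic50_alone`, `ic50_combo`, `fold_shift`, `flag`
#'   (`NA` flag when both slices fit; otherwise which slice failed).
#' @export
ic50_in_combination <- function(norm_block, partner_dose, vary = c("A", "B"), ...) {
  vary <- match.arg(vary)
  fixed_col <- if (vary == "A") "doseB" else "doseA"
  vary_col <- if (vary == "A") "doseA" else "doseB"
  if (!any(norm_block[[fixed_col]] == partner_dose)) {
    cs_abort("partner_dose does not match any grid level", "value")
  }
  fit_slice <- function(at) {
    sl <- dplyr::filter(norm_block, .data[[fixed_col]] == at)
    tryCatch(fit_median_effect(sl[[vary_col]], sl$fa, ...)$Dm,
             comboscreen_error = function(e) NA_real_)
  }
  alone <- fit_slice(0)
  combo <- fit_slice(partner_dose)
  flag <- dplyr::case_when(
    is.na(alone) & is.na(combo) ~ "both-slices-unfittable",
    is.na(alone) ~ "single-agent-unfittable",
    is.na(combo) ~ "combination-slice-unfittable",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    ic50_alone = alone, ic50_combo = combo,
    fold_shift = alone / combo, flag = flag
  )
}
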