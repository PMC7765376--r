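new_synergy_surface <- function(grid, metric, sum_neg) {
  structure(tibble::as_tibble(grid), metric = metric, sum_neg = sum_neg,
            class = c("synergy_surface", class(tibble::tibble())))
}

#' Sum of negative (synergistic) deviations of a synergy surface
#'
#' @param surface A surface tibble from [excess_hsa()] or [delta_bliss()].
#' @return The sum over wells of `min(deviation, 0)`; 0 or negative, more
#'   negative meaning stronger overall synergy.
#' @export
sum_neg <- function(surface) attr(surface, "sum_neg")

#' Excess over the highest single agent (HSA)
#'
#' For every interior well (both doses nonzero) the observed combination
#' viability is compared with the better (lower-viability) of the two single
#' agents at the matched doses:
#' `excess(i,j) = v(i,j) - min(v(i,0), v(0,j))`.
#' Negative values mean the combination kills more than the best single agent
#' alone, i.e. synergy on the HSA reference model. The scalar summary is the
#' sum of negative excesses over the grid (see [sum_neg()]).
#'
#' @param norm_block Normalized block tibble from [normalize_block()].
#' @return A `synergy_surface` tibble (`doseA, doseB, v, reference, excess`)
#'   over interior wells, with the negative-sum summary as attribute.
#' @export
#' @examples
#' blk <- simulate_combination_block(
#'   sim_compound("a"), sim_compound("b"), interaction = "hsa_equal", seed = 1
#' )
#' s <- excess_hsa(normalize_block(blk))
#' sum_neg(s)
excess_hsa <- function(norm_block) {
  m <- surface_matrix(norm_block, "v")
  grid <- interior_grid(m)
  grid$reference <- pmin(grid$vA_alone, grid$vB_alone)
  grid$excess <- grid$v - grid$reference
  out <- grid[, c("doseA", "doseB", "v", "reference", "excess")]
  new_synergy_surface(out, "excess_hsa", sum(pmin(out$excess, 0)))
}

#' Deviation from Bliss independence
#'
#' Under Bliss independence two non-interacting drugs combine multiplicatively
#' on the viability scale: `v_exp(i,j) = v(i,0) * v(0,j)` (equivalently
#' `fa_exp = fa_A + fa_B - fa_A fa_B`). The per-well deviation
#' `delta(i,j) = v(i,j) - v_exp(i,j)` is negative where the combination kills
#' more than independence predicts (synergy) and positive where it kills less
#' (antagonism). The scalar summary is the sum of negative deltas.
#'
#' @inheritParams excess_hsa
#' @return A `synergy_surface` tibble (`doseA, doseB, v, reference, delta`)
#'   over interior wells.
#' @export
delta_bliss <- function(norm_block) {
  m <- surface_matrix(norm_block, "v")
  grid <- interior_grid(m)
  grid$reference <- grid$vA_alone * grid$vB_alone
  grid$delta <- grid$v - grid$reference
  out <- grid[, c("doseA", "doseB", "v", "reference", "delta")]
  new_synergy_surface(out, "delta_bliss", sum(pmin(out$delta, 0)))
}

# Interior wells of a viability matrix with the matched single-agent
# viabilities attached.
interior_grid <- function(m) {
  dA <- attr(m, "dosesA")
  dB <- attr(m, "dosesB")
  ii <- seq_along(dA)[-1]
  jj <- seq_along(dB)[-1]
  tibble::tibble(
    doseA = rep(dA[ii], times = length(jj)),
    doseB = rep(dB[jj], each = length(ii)),
    v = as.vector(m[ii, jj, drop = FALSE]),
    vA_alone = rep(unname(m[ii, 1]), times = length(jj)),
    vB_alone = rep(unname(m[1, jj]), each = length(ii))
  )
}

#' Chou-Talalay combination index of a dose matrix
#'
#' For an interior well at doses `(dA, dB)` with observed fraction affected
#' `fa`, the combination index is
#' `CI = dA / DxA(fa) + dB / DxB(fa)`,
#' where `DxA(fa)` and `DxB(fa)` are the single-agent doses that would produce
#' the same effect alone, obtained from each drug's median-effect fit
#' ([dose_for_effect()]). `CI < 1` indicates synergy, `CI = 1` additivity,
#' `CI > 1` antagonism. The two-term (mutually exclusive) form is used.
#'
#' A full dose matrix yields one CI per well; the reported scalar follows
#' `policy`:
#' The matrix diagonal (equal dose ranks) is a constant-ratio ray whenever
#' both axes share one dilution factor, so diagonal wells are the matched-
#' ratio combinations classical fixed-ratio synergy analysis evaluates; for
#' potency-shift (Loewe-type) synergy the per-well CI is constant along that
#' ray, making any robust location estimate over its in-band wells an
#' estimator of the same quantity.
#' \describe{
#'   \item{`"diag_band_median"` (default)}{the median per-well CI over
#'     diagonal wells whose observed `fa` lies in `fa_band`. Pooling the
#'     matched-ratio wells suppresses replicate noise; the median resists the
#'     occasional band-edge well where the fits interpolate poorly.}
#'   \item{`"nearest_half"`}{the per-well CI at the in-band diagonal well
#'     whose observed `fa` is nearest 0.5 (one representative well).}
#'   \item{`"ray_fit"`}{the classical fixed-ratio fit: the diagonal mixture
#'     is treated as a single agent, its own median-effect model is fitted
#'     to (total dose, observed fa), and CI is evaluated at fa = 0.5 as
#'     `CI = fA Dmix / DmA + fB Dmix / DmB` (`Dmix` the ray's fitted
#'     median-effect dose, `fA`, `fB` the mixture dose fractions). Exact for
#'     matched single-agent slopes; the global line fit biases it when the
#'     two slopes differ strongly.}
#'   \item{`"fa_band_min"`}{the minimum per-well CI over all interior wells
#'     with observed `fa` in `fa_band`. Reports the strongest synergy signal
#'     anywhere on the surface, but as a minimum over many noisy wells it is
#'     biased low under replicate noise and inflates false-positive calls;
#'     prefer it for noise-free or heavily replicated data.}
#' }
#'
#' @param norm_block Normalized block tibble from [normalize_block()].
#' @param fitA,fitB `medfit` objects for drug A and drug B single agents.
#' @param policy CI collapse policy, see Details.
#' @param fa_band Numeric length-2: the fa evaluation band for
#'   `"fa_band_min"`.
#' @param dose_ceiling Diagonal wells with either component dose above this
#'   are excluded from the ray fit (molar).
#' @return One-row tibble: `ci`, `fa_at`, `doseA_at`, `doseB_at`, `ci_policy`,
#'   `flag` (`"no-effect-band"` / `"ray-unfittable"` with `ci = NA` when no
#'   well or ray qualifies). The full per-well CI grid is attached as
#'   attribute `"ci_grid"`.
#' @export
combination_index <- function(norm_block, fitA, fitB,
                              policy = c("diag_band_median", "nearest_half",
                                         "ray_fit", "fa_band_min"),
                              fa_band = c(0.25, 0.75), dose_ceiling = 10e-6) {
  policy <- match.arg(policy)
  m <- surface_matrix(norm_block, "fa")
  dA <- attr(m, "dosesA")
  dB <- attr(m, "dosesB")
  grid <- tidyr::expand_grid(i = seq_along(dA)[-1], j = seq_along(dB)[-1])
  grid$doseA <- dA[grid$i]
  grid$doseB <- dB[grid$j]
  grid$fa <- m[cbind(grid$i, grid$j)]
  inside <- grid$fa > 0 & grid$fa < 1
  grid$ci <- NA_real_
  grid$ci[inside] <- grid$doseA[inside] / dose_for_effect(fitA, grid$fa[inside]) +
    grid$doseB[inside] / dose_for_effect(fitB, grid$fa[inside])

  out <- if (policy == "ray_fit") {
    ray_fit_ci(grid, fitA, fitB, dose_ceiling)
  } else if (policy == "diag_band_median") {
    diag_band <- which(inside & grid$i == grid$j &
                         grid$fa >= fa_band[1] & grid$fa <= fa_band[2])
    if (length(diag_band) == 0) {
      tibble::tibble(ci = NA_real_, fa_at = NA_real_, doseA_at = NA_real_,
                     doseB_at = NA_real_, ci_policy = policy, flag = "no-effect-band")
    } else {
      rep_well <- diag_band[which.min(abs(grid$fa[diag_band] - 0.5))]
      tibble::tibble(ci = median(grid$ci[diag_band]), fa_at = grid$fa[rep_well],
                     doseA_at = grid$doseA[rep_well], doseB_at = grid$doseB[rep_well],
                     ci_policy = policy, flag = NA_character_)
    }
  } else {
    pick <- switch(policy,
      fa_band_min = {
        band <- which(inside & grid$fa >= fa_band[1] & grid$fa <= fa_band[2])
        if (length(band) > 0) band[which.min(grid$ci[band])] else NA_integer_
      },
      nearest_half = {
        diag_wells <- which(inside & grid$i == grid$j &
                              grid$fa >= fa_band[1] & grid$fa <= fa_band[2])
        if (length(diag_wells) > 0) {
          diag_wells[which.min(abs(grid$fa[diag_wells] - 0.5))]
        } else NA_integer_
      }
    )
    if (is.na(pick)) {
      tibble::tibble(ci = NA_real_, fa_at = NA_real_, doseA_at = NA_real_,
                     doseB_at = NA_real_, ci_policy = policy, flag = "no-effect-band")
    } else {
      tibble::tibble(ci = grid$ci[pick], fa_at = grid$fa[pick],
                     doseA_at = grid$doseA[pick], doseB_at = grid$doseB[pick],
                     ci_policy = policy, flag = NA_character_)
    }
  }
  attr(out, "ci_grid") <- grid[, c("doseA", "doseB", "fa", "ci")]
  out
}

# Classical fixed-ratio evaluation: median-effect fit to the diagonal mixture
# series, CI read at fa = 0.5 where Dx = Dm for all three fits (slope error
# cancels).
ray_fit_ci <- function(grid, fitA, fitB, dose_ceiling) {
  ray <- grid[grid$i == grid$j & grid$doseA <= dose_ceiling &
                grid$doseB <= dose_ceiling, ]
  undefined <- tibble::tibble(ci = NA_real_, fa_at = NA_real_,
                              doseA_at = NA_real_, doseB_at = NA_real_,
                              ci_policy = "ray_fit", flag = "ray-unfittable")
  if (nrow(ray) < 2) return(undefined)
  frac_a <- ray$doseA[1] / (ray$doseA[1] + ray$doseB[1])
  mix_fit <- tryCatch(
    fit_median_effect(ray$doseA + ray$doseB, ray$fa, dose_ceiling = Inf),
    comboscreen_error = function(e) NULL
  )
  if (is.null(mix_fit)) return(undefined)
  d_mix <- mix_fit$Dm
  ci <- frac_a * d_mix / fitA$Dm + (1 - frac_a) * d_mix / fitB$Dm
  tibble::tibble(ci = ci, fa_at = 0.5, doseA_at = frac_a * d_mix,
                 doseB_at = (1 - frac_a) * d_mix, ci_policy = "ray_fit",
                 flag = NA_character_)
}

#' Maximal-efficacy beta ratio
#'
#' A co-filter alongside the combination index that asks whether the
#' combination, at the top dose of both drugs, kills beyond what the better
#' single agent achieves at its own top dose:
#' `beta = v(top, top) / min(v(top, 0), v(0, top))`.
#' `beta < 1` means the combination exceeds the best single agent's maximal
#' effect. When the best single agent already drives viability below `floor`
#' the ratio divides two near-zero numbers and is reported undefined
#' (`"singles-saturating"`).
#'
#' @inheritParams excess_hsa
#' @param floor Best-single-agent viability below which beta is undefined.
#' @return One-row tibble: `beta`, `flag`.
#' @export
beta_parameter <- function(norm_block, floor = 0.01) {
  m <- surface_matrix(norm_block, "v")
  ni <- nrow(m)
  nj <- ncol(m)
  best_single <- min(m[ni, 1], m[1, nj])
  if (best_single < floor) {
    return(tibble::tibble(beta = NA_real_, flag = "singles-saturating"))
  }
  tibble::tibble(beta = m[ni, nj] / best_single, flag = NA_character_)
}

#' Score one drug pair: surfaces, CI, beta, hit call
#'
#' Assembles the full synergy report for one normalized dose-matrix block:
#' the excess-HSA and delta-Bliss negative sums, the combination index under
#' the configured policy, the beta ratio, and the hit flag
#' (`CI < ci_max` and `beta < beta_max`, both strict, both defined).
#'
#' @param norm_block Normalized block tibble from [normalize_block()].
#' @param fitA,fitB Optional `medfit` objects; fitted from the block's own
#'   single-agent rows when omitted. An unfittable single agent leaves the CI
#'   undefined and flags the pair.
#' @param config A [screen_config()] carrying thresholds, CI policy, fa band,
#'   beta floor and dose ceiling.
#' @return One-row tibble (the pair's synergy report): ids, `sum_neg_bliss`,
#'   `sum_neg_hsa`, `ci`, `ci_fa`, `ci_policy`, `beta`, `hit`, `flags`
#'   (semicolon-joined QC flags, `NA` when clean).
#' @export
summarize_pair <- function(norm_block, fitA = NULL, fitB = NULL,
                           config = screen_config()) {
  flags <- character()
  single_fit <- function(dose_col, other_col) {
    sl <- dplyr::filter(norm_block, .data[[other_col]] == 0, .data[[dose_col]] > 0)
    tryCatch(
      fit_median_effect(sl[[dose_col]], sl$fa, dose_ceiling = config$dose_ceiling),
      comboscreen_error = function(e) NULL
    )
  }
  if (is.null(fitA)) fitA <- single_fit("doseA", "doseB")
  if (is.null(fitB)) fitB <- single_fit("doseB", "doseA")

  hsa <- excess_hsa(norm_block)
  bliss <- delta_bliss(norm_block)
  beta <- beta_parameter(norm_block, floor = config$beta_floor)
  if (!is.na(beta$flag)) flags <- c(flags, beta$flag)

  if (is.null(fitA) || is.null(fitB)) {
    flags <- c(flags, "single-agent-unfittable")
    ci_row <- tibble::tibble(ci = NA_real_, fa_at = NA_real_, ci_policy = config$ci_policy)
  } else {
    ci_row <- combination_index(norm_block, fitA, fitB,
                                policy = config$ci_policy, fa_band = config$fa_band,
                                dose_ceiling = config$dose_ceiling)
    if (!is.na(ci_row$flag)) flags <- c(flags, ci_row$flag)
  }

  hit <- !is.na(ci_row$ci) && !is.na(beta$beta) &&
    ci_row$ci < config$ci_max && beta$beta < config$beta_max

  tibble::tibble(
    block_id = norm_block$block_id[1],
    assay = norm_block$assay[1],
    drugA_id = norm_block$drugA_id[1],
    drugB_id = norm_block$drugB_id[1],
    sum_neg_bliss = sum_neg(bliss),
    sum_neg_hsa = sum_neg(hsa),
    ci = ci_row$ci,
    ci_fa = ci_row$fa_at,
    ci_policy = ci_row$ci_policy,
    beta = beta$beta,
    hit = hit,
    flags = if (length(flags) > 0) paste(unique(flags), collapse = ";") else NA_character_
  )
}
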