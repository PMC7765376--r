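#' Describe a simulated compound's ground-truth dose response
#'
#' Single agents follow a four-parameter logistic on viability,
#' `v(D) = emax + (1 - emax) / (1 + (D/ec50)^slope)`: full viability at
#' vehicle, dropping to the floor `emax` at saturating dose. With `emax = 0`
#' this is exactly the median-effect model with `Dm = ec50`, `m = slope`.
#'
#' @param compound_id Compound identifier.
#' @param ec50 Midpoint dose (molar).
#' @param slope Hill sigmoidicity (dimensionless, > 0).
#' @param emax Viability floor at saturating dose (0 = full kill).
#' @param top_dose Highest dose plated for this compound (molar).
#' @param name,moa_class Annotation fields.
#' @return A `sim_compound` list.
#' @export
sim_compound <- function(compound_id, ec50 = 400e-9, slope = 1, emax = 0,
                         top_dose = 10e-6, name = compound_id,
                         moa_class = "unannotated") {
  if (ec50 <= 0 || slope <= 0 || emax < 0 || emax >= 1 || top_dose <= 0) {
    cs_abort("invalid sim_compound parameters", "config")
  }
  structure(list(compound_id = compound_id, name = name, moa_class = moa_class,
                 ec50 = ec50, slope = slope, emax = emax, top_dose = top_dose),
            class = "sim_compound")
}

#' Dose-matrix plate design
#'
#' The primary screen plates 6x6 blocks: 5 serial 5-fold dilutions plus a
#' vehicle level on each axis, in triplicate. The confirmatory stage uses
#' 10x10 blocks: 9 serial dilution steps plus vehicle, by default in
#' sqrt(10)-fold steps so nine steps span the same 4-log range, also in
#' triplicate.
#'
#' @param n_levels Dose levels per axis including vehicle (>= 2).
#' @param dilution Serial dilution factor between consecutive nonzero doses
#'   (> 1).
#' @param replicates Replicates per well (>= 1).
#' @return A `matrix_design` list.
#' @export
matrix_design <- function(n_levels = 6, dilution = 5, replicates = 3) {
  if (n_levels < 2 || dilution <= 1 || replicates < 1) {
    cs_abort("invalid matrix design (need n_levels >= 2, dilution > 1, replicates >= 1)",
             "config")
  }
  structure(list(n_levels = as.integer(n_levels), dilution = dilution,
                 replicates = as.integer(replicates)),
            class = "matrix_design")
}

#' Confirmatory 10x10 design
#' @param replicates Replicates per well.
#' @param dilution Dilution factor (default `sqrt(10)`).
#' @return A `matrix_design`.
#' @export
confirmation_design <- function(replicates = 3, dilution = sqrt(10)) {
  matrix_design(n_levels = 10, dilution = dilution, replicates = replicates)
}

# Dose series for one compound under a design: vehicle then n-1 ascending doses
# ending at top_dose.
design_doses <- function(compound, design) {
  k <- design$n_levels - 1
  c(0, compound$top_dose / design$dilution^((k - 1):0))
}

#' Ground-truth single-agent viability
#'
#' @param dose Dose vector (molar).
#' @param compound A [sim_compound()].
#' @return Viability fraction in `[emax, 1]`.
#' @export
hill_viability <- function(dose, compound) {
  compound$emax + (1 - compound$emax) / (1 + (dose / compound$ec50)^compound$slope)
}

# Exact inverse of the single-agent curve: dose producing fraction affected fa.
# Infinite beyond the achievable ceiling 1 - emax.
inverse_dose <- function(fa, compound) {
  fa_max <- 1 - compound$emax
  out <- rep(Inf, length(fa))
  ok <- fa < fa_max
  out[ok] <- compound$ec50 * (fa[ok] / (fa_max - fa[ok]))^(1 / compound$slope)
  out[fa <= 0] <- 0
  out
}

# Loewe-additive combination effect under a symmetric potency shift psi:
# the fa at (dA, dB) solves psi*dA/DxA(fa) + psi*dB/DxB(fa) = 1. psi = 1 is
# plain Loewe additivity (the sham surface); psi > 1 plants synergy in which
# the dose requirement of both agents drops psi-fold at fixed ratio.
loewe_fa <- function(dA, dB, compA, compB, psi = 1) {
  if (dA == 0 && dB == 0) return(0)
  g <- function(fa) {
    psi * dA / inverse_dose(fa, compA) + psi * dB / inverse_dose(fa, compB) - 1
  }
  lo <- 1e-12
  hi <- 1 - 1e-12
  if (g(lo) <= 0) return(0)        # doses too low to register any effect
  if (g(hi) >= 0) return(hi)       # beyond both agents' ceilings
  uniroot(g, c(lo, hi), tol = 1e-13, maxiter = 1000)$root
}

# Restore the RNG state on exit so seeded simulators do not disturb the
# caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one drug-pair dose-matrix block
#'
#' Builds the noise-free combination viability surface from the two agents'
#' ground-truth curves under the chosen interaction model, then applies
#' multiplicative lognormal replicate noise and scales to raw signal
#' (viability x 1000 arbitrary luminescence units; vehicle wells are noisy
#' around 1000).
#'
#' Interaction models (interior wells; edges are always the plain single-agent
#' response):
#' \describe{
#'   \item{`bliss_independent`}{`v = vA(dA) * vB(dB)` — no interaction under
#'     the Bliss null.}
#'   \item{`hsa_equal`}{`v = min(vA(dA), vB(dB))` — combination exactly equals
#'     the highest single agent.}
#'   \item{`potency_shift`}{Loewe-additive surface on `psi`-scaled doses: the
#'     well's fa solves `psi dA / DxA(fa) + psi dB / DxB(fa) = 1`, so both
#'     agents' dose requirements drop `psi`-fold at fixed ratio. `psi = 1` is
#'     exact Loewe additivity (combination index 1, the sham surface);
#'     `psi > 1` plants synergy with closed-form combination index `1/psi`.}
#' }
#'
#' @param truthA,truthB [sim_compound()] ground truths (A varies along rows,
#'   B is the anchor).
#' @param interaction Interaction model, see Details.
#' @param psi Potency-shift strength (>= 1; only used by `potency_shift`).
#' @param design A [matrix_design()].
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise (0 = noise-free).
#' @param seed Optional seed (local to this call).
#' @param block_id Block identifier (default derived from the compound ids).
#' @param assay Readout label for the block.
#' @return Long-format wells tibble (one row per replicate), ready for
#'   [normalize_block()] or [as_screen_dataset()].
#' @export
#' @examples
#' blk <- simulate_combination_block(
#'   sim_compound("a", ec50 = 2e-7), sim_compound("b", ec50 = 5e-7),
#'   interaction = "potency_shift", psi = 4, seed = 42
#' )
simulate_combination_block <- function(truthA, truthB,
                                       interaction = c("bliss_independent",
                                                       "hsa_equal",
                                                       "potency_shift"),
                                       psi = 1, design = matrix_design(),
                                       noise_cv = 0, seed = NULL,
                                       block_id = NULL, assay = "viability") {
  interaction <- match.arg(interaction)
  if (psi < 1) cs_abort("psi must be >= 1", "config")
  if (noise_cv < 0) cs_abort("noise_cv must be nonnegative", "config")
  dosesA <- design_doses(truthA, design)
  dosesB <- design_doses(truthB, design)
  grid <- tidyr::expand_grid(doseA = dosesA, doseB = dosesB)

  vA <- hill_viability(grid$doseA, truthA)
  vB <- hill_viability(grid$doseB, truthB)
  edge <- grid$doseA == 0 | grid$doseB == 0
  v <- switch(interaction,
    bliss_independent = vA * vB,
    hsa_equal = pmin(vA, vB),
    potency_shift = {
      out <- pmin(vA, vB)  # placeholder, overwritten well by well
      for (k in seq_len(nrow(grid))) {
        out[k] <- if (edge[k]) {
          min(vA[k], vB[k])  # single-agent response on the axes
        } else {
          1 - loewe_fa(grid$doseA[k], grid$doseB[k], truthA, truthB, psi = psi)
        }
      }
      out
    }
  )
  grid$v_true <- v

  with_local_seed(seed, {
    wells <- tidyr::expand_grid(grid, replicate = seq_len(design$replicates))
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log1p(noise_cv^2))
      rlnorm(nrow(wells), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    tibble::tibble(
      block_id = block_id %||% paste0("blk_", truthA$compound_id, "_", truthB$compound_id),
      drugA_id = truthA$compound_id, doseA = wells$doseA,
      drugB_id = truthB$compound_id, doseB = wells$doseB,
      replicate = as.integer(wells$replicate),
      signal = wells$v_true * 1000 * noise,
      assay = assay
    )
  })
}

#' Simulate a combination-screen library with known ground truth
#'
#' Generates one dose-matrix block per library compound against a fixed
#' anchor drug, with a known fraction of planted synergists, so the whole
#' triage pipeline can be exercised and scored against truth labels.
#'
#' Compound parameters are sampled per compound: `ec50` log-uniform across
#' the nonzero dose range, Hill slope uniform on `[0.5, 3]`, viability floor
#' `emax` uniform on `[0, 0.4]`. Synergists interact with the anchor through
#' a [simulate_combination_block()] potency shift with `psi` uniform on
#' `[2, 8]`; all other pairs are Bliss-independent. Mechanism-of-action
#' labels are drawn from a synergy-enriched class pool for synergists (and
#' occasionally for nulls), so class-level aggregation shows the enrichment
#' structure real screens report.
#'
#' @param n_compounds Library size (>= 1).
#' @param fraction_synergists Fraction of compounds planted as synergists;
#'   `round(n * fraction)` labels are assigned.
#' @param design A [matrix_design()] shared by all blocks.
#' @param noise_cv Replicate noise CV (default 0.10).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param anchor Anchor-drug ground truth ([sim_compound()]).
#' @param top_dose Shared top dose for library compounds (molar).
#' @return List with `dataset` (a `screen_dataset`) and `truth` (list with
#'   per-compound tibble `compounds` incl. `synergist` labels and `psi`, the
#'   `anchor`, `design`, `noise_cv`, `seed`).
#' @export
simulate_library <- function(n_compounds, fraction_synergists = 0.1,
                             design = matrix_design(), noise_cv = 0.1,
                             seed = 1,
                             anchor = sim_compound("anchor", ec50 = 400e-9,
                                                   slope = 1.5, emax = 0,
                                                   top_dose = 2.5e-6,
                                                   name = "anchor",
                                                   moa_class = "SMAC mimetic"),
                             top_dose = 10e-6) {
  if (n_compounds < 1) cs_abort("n_compounds must be >= 1", "config")
  if (fraction_synergists < 0 || fraction_synergists > 1) {
    cs_abort("fraction_synergists must lie in [0, 1]", "config")
  }
  synergy_classes <- c("taxane", "proteasome inhibitor", "PLK1 inhibitor",
                       "HDAC inhibitor", "topoisomerase inhibitor")
  null_classes <- c("kinase inhibitor", "antimetabolite", "alkylating agent",
                    "antibiotic", "GPCR modulator", "nucleoside analog")

  with_local_seed(seed, {
    n_syn <- round(n_compounds * fraction_synergists)
    syn <- rep(FALSE, n_compounds)
    if (n_syn > 0) syn[sample.int(n_compounds, n_syn)] <- TRUE

    dose_min <- top_dose / design$dilution^(design$n_levels - 2)
    compounds <- tibble::tibble(
      compound_id = sprintf("cmpd%03d", seq_len(n_compounds)),
      ec50 = exp(runif(n_compounds, log(dose_min), log(top_dose))),
      slope = runif(n_compounds, 0.5, 3),
      emax = runif(n_compounds, 0, 0.4),
      synergist = syn,
      psi = ifelse(syn, runif(n_compounds, 2, 8), 1),
      interaction = ifelse(syn, "potency_shift", "bliss_independent"),
      moa_class = ifelse(
        runif(n_compounds) < ifelse(syn, 0.8, 0.1),
        sample(synergy_classes, n_compounds, replace = TRUE),
        sample(null_classes, n_compounds, replace = TRUE)
      )
    )
    compounds$name <- compounds$compound_id

    wells <- purrr::pmap(compounds, function(compound_id, ec50, slope, emax,
                                             synergist, psi, interaction,
                                             moa_class, name) {
      truth <- sim_compound(compound_id, ec50 = ec50, slope = slope,
                            emax = emax, top_dose = top_dose,
                            name = name, moa_class = moa_class)
      simulate_combination_block(truth, anchor, interaction = interaction,
                                 psi = psi, design = design,
                                 noise_cv = noise_cv, seed = NULL,
                                 block_id = paste0("blk_", compound_id))
    }) |> purrr::list_rbind()

    annotations <- dplyr::bind_rows(
      dplyr::select(compounds, dplyr::all_of(c("compound_id", "name", "moa_class"))),
      tibble::tibble(compound_id = anchor$compound_id, name = anchor$name,
                     moa_class = anchor$moa_class)
    )
    list(
      dataset = as_screen_dataset(wells, annotations),
      truth = structure(
        list(compounds = compounds, anchor = anchor, design = design,
             noise_cv = noise_cv, seed = seed),
        class = "ground_truth"
      )
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d compounds (%d synergists), noise CV = %g, seed = %s\n",
              nrow(x$compounds), sum(x$compounds$synergist), x$noise_cv,
              format(x$seed)))
  invisible(x)
}

#' Score a screen result against simulator ground truth
#'
#' @param result A `screen_result` from [run_stage()].
#' @param truth The `truth` element of [simulate_library()].
#' @return One-row tibble: `n_synergists`, `n_nulls_scoreable`, `tp`, `fp`,
#'   `sensitivity`, `false_positive_rate`. Pairs with undefined scores are
#'   excluded from the denominators (only scoreable pairs are triaged).
#' @export
score_against_truth <- function(result, truth) {
  labels <- dplyr::select(truth$compounds,
                          dplyr::all_of(c("compound_id", "synergist")))
  scored <- result$reports |>
    dplyr::filter(!is.na(.data$ci), !is.na(.data$beta)) |>
    dplyr::left_join(labels, by = c("drugA_id" = "compound_id"))
  tp <- sum(scored$hit & scored$synergist)
  fp <- sum(scored$hit & !scored$synergist)
  n_syn <- sum(scored$synergist)
  n_null <- sum(!scored$synergist)
  tibble::tibble(
    n_synergists = n_syn, n_nulls_scoreable = n_null, tp = tp, fp = fp,
    sensitivity = if (n_syn > 0) tp / n_syn else NA_real_,
    false_positive_rate = if (n_null > 0) fp / n_null else NA_real_
  )
}
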