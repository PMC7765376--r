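#' Screen analysis configuration
#'
#' Bundles the tunable parameters of the triage pipeline. Defaults follow the
#' screening workflow this package implements: hits require a combination
#' index strictly below 0.5 and a beta ratio strictly below 1, the CI is
#' the median per-well CI over in-band matched-ratio (diagonal) wells
#' (`ci_policy = "diag_band_median"`; see [combination_index()] for the
#' alternatives and their noise behaviour), doses above 10 uM are excluded
#' from fits, and the viability readout drives triage.
#'
#' @param readout Assay used for scoring: `"viability"` or `"caspase"`.
#' @param ci_max,beta_max Strict hit thresholds for CI and beta.
#' @param ci_policy CI collapse policy, `"diag_band_median"` by default (see
#'   [combination_index()]).
#' @param fa_band CI evaluation band on observed fraction affected.
#' @param beta_floor Best-single viability below which beta is undefined.
#' @param dose_ceiling Dose ceiling for median-effect fits (molar).
#' @param seed Optional integer seed echoed into exports for provenance.
#' @return A `screen_config` list.
#' @export
screen_config <- function(readout = c("viability", "caspase"),
                          ci_max = 0.5, beta_max = 1.0,
                          ci_policy = c("diag_band_median", "nearest_half", "ray_fit", "fa_band_min"),
                          fa_band = c(0.25, 0.75), beta_floor = 0.01,
                          dose_ceiling = 10e-6, seed = NULL) {
  readout <- match.arg(readout)
  ci_policy <- match.arg(ci_policy)
  if (ci_max <= 0 || beta_max <= 0) cs_abort("thresholds must be positive", "config")
  structure(
    list(readout = readout, ci_max = ci_max, beta_max = beta_max,
         ci_policy = ci_policy, fa_band = fa_band, beta_floor = beta_floor,
         dose_ceiling = dose_ceiling, seed = seed),
    class = "screen_config"
  )
}

#' Select screen hits from per-pair synergy reports
#'
#' Applies the triage rule: a pair is a hit when its combination index and
#' beta ratio are both defined and strictly below their thresholds
#' (`CI < ci_max` and `beta < beta_max`). Hits are ranked by CI ascending,
#' ties broken by `sum_neg_bliss` ascending (more negative first) then pair
#' id. Pairs with undefined CI or beta are never hits; they are listed
#' separately in the `"excluded"` attribute so flagged chemistry is reported
#' rather than silently dropped.
#'
#' @param reports Tibble of per-pair reports from [summarize_pair()].
#' @param ci_max,beta_max Strict thresholds (defaults 0.5 and 1).
#' @return The ranked hits tibble (with a `rank` column); excluded
#'   (undefined-score) pairs as attribute `"excluded"`.
#' @export
select_hits <- function(reports, ci_max = 0.5, beta_max = 1.0) {
  if (nrow(reports) == 0) {
    out <- dplyr::mutate(reports, rank = integer())
    attr(out, "excluded") <- reports
    return(out)
  }
  excluded <- dplyr::filter(reports, is.na(.data$ci) | is.na(.data$beta))
  hits <- reports |>
    dplyr::filter(!is.na(.data$ci), !is.na(.data$beta),
                  .data$ci < ci_max, .data$beta < beta_max) |>
    dplyr::arrange(.data$ci, .data$sum_neg_bliss, .data$drugA_id, .data$drugB_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(hits, "excluded") <- excluded
  hits
}

#' Run one screen stage end to end
#'
#' Orchestrates one stage of the matrix screen (primary 6x6 or confirmatory
#' 10x10): normalize every block of the configured readout, fit both single
#' agents, score every pair ([summarize_pair()]), apply the hit rule
#' ([select_hits()]), and aggregate hits by mechanism-of-action class. All
#' blocks must share one anchor drug (the fixed partner, drug B of every
#' block).
#'
#' The anchor appears in every block, so its single-agent median-effect fit
#' is pooled across all blocks of the stage by default (every block's anchor
#' row contributes); per-compound fits remain per block. Set
#' `pool_anchor_fit = FALSE` to refit the anchor per block instead.
#'
#' @param dataset A `screen_dataset` (from [read_screen_table()],
#'   [as_screen_dataset()] or [simulate_library()]).
#' @param config A [screen_config()].
#' @param stage Label stored in the result: `"primary"` or `"confirmation"`.
#' @param pool_anchor_fit Pool the anchor's single-agent fit across blocks
#'   (default `TRUE`).
#' @return A `screen_result`: list with `stage`, `reports` (per-pair tibble),
#'   `hits` (ranked tibble), `excluded` (undefined-score pairs),
#'   `class_summary`, and the `config`.
#' @export
#' @examples
#' sim <- simulate_library(n_compounds = 8, fraction_synergists = 0.25, seed = 7)
#' res <- run_stage(sim$dataset, screen_config())
#' res$hits
run_stage <- function(dataset, config = screen_config(),
                      stage = c("primary", "confirmation"),
                      pool_anchor_fit = TRUE) {
  stage <- match.arg(stage)
  if (!inherits(dataset, "screen_dataset")) dataset <- as_screen_dataset(dataset)
  wells <- dplyr::filter(dataset$wells, .data$assay == config$readout)
  if (nrow(wells) == 0) {
    cs_abort(paste0("dataset has no wells for readout '", config$readout, "'"), "config")
  }
  anchors <- unique(wells$drugB_id)
  if (length(anchors) != 1) {
    cs_abort(paste0("blocks mix anchor drugs (drugB_id): ",
                    paste(anchors, collapse = ", ")), "config")
  }
  norm_blocks <- wells |>
    dplyr::group_by(.data$block_id, .data$assay) |>
    dplyr::group_split() |>
    purrr::map(normalize_block)

  fitB <- NULL
  if (pool_anchor_fit) {
    anchor_rows <- purrr::list_rbind(norm_blocks) |>
      dplyr::filter(.data$doseA == 0, .data$doseB > 0) |>
      dplyr::group_by(.data$doseB) |>
      dplyr::summarise(fa = mean(.data$fa), .groups = "drop")
    fitB <- tryCatch(
      fit_median_effect(anchor_rows$doseB, anchor_rows$fa,
                        dose_ceiling = config$dose_ceiling),
      comboscreen_error = function(e) NULL
    )
  }

  reports <- norm_blocks |>
    purrr::map(function(nb) summarize_pair(nb, fitB = fitB, config = config)) |>
    purrr::list_rbind()
  hits <- select_hits(reports, ci_max = config$ci_max, beta_max = config$beta_max)
  result <- structure(
    list(stage = stage, reports = reports, hits = hits,
         excluded = attr(hits, "excluded"), config = config,
         class_summary = NULL),
    class = "screen_result"
  )
  result$class_summary <- aggregate_by_class(result, dataset$compounds)
  result
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> stage = %s: %d pair(s) scored, %d hit(s), %d excluded\n",
              x$stage, nrow(x$reports), nrow(x$hits), nrow(x$excluded)))
  if (nrow(x$hits) > 0) print(utils::head(x$hits[, c("drugA_id", "ci", "beta", "sum_neg_bliss")], 10))
  invisible(x)
}

#' @export
tidy.screen_result <- function(x, ...) x$reports

#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    n_pairs = nrow(x$reports),
    n_scoreable = nrow(x$reports) - nrow(x$excluded),
    n_hits = nrow(x$hits),
    n_excluded = nrow(x$excluded),
    ci_max = x$config$ci_max,
    beta_max = x$config$beta_max
  )
}

#' Aggregate hit calls by mechanism-of-action class
#'
#' Counts tested and hit pairs per MoA class of the library (drug A) compound,
#' sorted by hit fraction descending. Compounds missing from the annotation
#' are grouped as `"unannotated"`.
#'
#' @param result A `screen_result` (or a bare reports tibble with a `hit`
#'   column).
#' @param annotations Compound annotation tibble
#'   (`compound_id, name, moa_class`).
#' @return Tibble: `moa_class, n_tested, n_hits, hit_fraction`.
#' @export
aggregate_by_class <- function(result, annotations) {
  reports <- if (inherits(result, "screen_result")) result$reports else tibble::as_tibble(result)
  if (nrow(reports) == 0) {
    return(tibble::tibble(moa_class = character(), n_tested = integer(),
                          n_hits = integer(), hit_fraction = double()))
  }
  ann <- dplyr::select(annotations, dplyr::all_of(c("compound_id", "moa_class")))
  reports |>
    dplyr::left_join(ann, by = c("drugA_id" = "compound_id")) |>
    dplyr::mutate(moa_class = dplyr::coalesce(.data$moa_class, "unannotated")) |>
    dplyr::group_by(.data$moa_class) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_hits = sum(.data$hit, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(hit_fraction = .data$n_hits / .data$n_tested) |>
    dplyr::arrange(dplyr::desc(.data$hit_fraction), .data$moa_class)
}
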