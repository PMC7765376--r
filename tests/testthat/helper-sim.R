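# Shared fixtures: everything is generated in code at test time.

# Random full-kill median-effect compound whose ec50 sits inside the plated
# dose range (top 10 uM, 5-fold series).
rand_compound <- function(id, top_dose = 1e-5) {
  sim_compound(id,
               ec50 = exp(stats::runif(1, log(top_dose / 300), log(top_dose / 3))),
               slope = stats::runif(1, 0.6, 2.5),
               emax = 0, top_dose = top_dose)
}

# Fit both single agents of a normalized block.
fit_singles <- function(nb, ...) {
  slA <- nb[nb$doseB == 0 & nb$doseA > 0, ]
  slB <- nb[nb$doseA == 0 & nb$doseB > 0, ]
  list(A = fit_median_effect(slA$doseA, slA$fa, ...),
       B = fit_median_effect(slB$doseB, slB$fa, ...))
}

# Hand-built normalized block from a viability matrix (rows = doses of A,
# cols = doses of B, [1,1] the vehicle well).
norm_block_from_matrix <- function(v, dosesA, dosesB) {
  grid <- tidyr::expand_grid(i = seq_along(dosesA), j = seq_along(dosesB))
  tibble::tibble(
    block_id = "blk", assay = "viability", drugA_id = "A", drugB_id = "B",
    doseA = dosesA[grid$i], doseB = dosesB[grid$j],
    n_rep = 1L, v = v[cbind(grid$i, grid$j)], sem = NA_real_
  ) |>
    dplyr::mutate(fa = pmin(pmax(1 - v, 0), 1))
}
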