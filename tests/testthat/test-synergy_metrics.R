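test_that("excess HSA is zero when the combination equals the best single agent", {
  withr::local_seed(20)
  for (k in 1:5) {
    nb <- normalize_block(simulate_combination_block(
      rand_compound("a"), rand_compound("b"), interaction = "hsa_equal"))
    s <- excess_hsa(nb)
    expect_true(all(s$excess == 0))
    expect_equal(sum_neg(s), 0)
  }
})

test_that("excess HSA arithmetic matches hand-computed wells", {
  doses <- c(0, 1e-8)
  # singles at 0.6 and 0.8 viability; combo 0.4 -> excess -0.2
  v <- matrix(c(1, 0.8, 0.6, 0.4), 2, 2, byrow = TRUE)
  s <- excess_hsa(norm_block_from_matrix(v, doses, doses))
  expect_equal(s$excess, -0.2)
  expect_equal(sum_neg(s), -0.2)

  # combo strictly worse than both singles: positive excess, no synergy sum
  v2 <- matrix(c(1, 0.6, 0.6, 0.9), 2, 2, byrow = TRUE)
  s2 <- excess_hsa(norm_block_from_matrix(v2, doses, doses))
  expect_equal(s2$excess, 0.3)
  expect_equal(sum_neg(s2), 0)
})

test_that("delta Bliss arithmetic matches the independence expectation", {
  doses <- c(0, 1e-8)
  # both singles at fa 0.5 -> expected combo viability 0.25
  v <- matrix(c(1, 0.5, 0.5, 0.25), 2, 2, byrow = TRUE)
  s <- delta_bliss(norm_block_from_matrix(v, doses, doses))
  expect_equal(s$delta, 0)

  v2 <- v
  v2[2, 2] <- 0.10
  s2 <- delta_bliss(norm_block_from_matrix(v2, doses, doses))
  expect_equal(s2$delta, -0.15)
  expect_equal(sum_neg(s2), -0.15)
})

test_that("delta Bliss vanishes identically on simulated independent surfaces", {
  withr::local_seed(21)
  for (k in 1:20) {
    a <- sim_compound("a", ec50 = 10^stats::runif(1, -8, -6),
                      slope = stats::runif(1, 0.5, 3),
                      emax = stats::runif(1, 0, 0.4), top_dose = 1e-5)
    b <- sim_compound("b", ec50 = 10^stats::runif(1, -8, -6),
                      slope = stats::runif(1, 0.5, 3),
                      emax = stats::runif(1, 0, 0.4), top_dose = 1e-5)
    nb <- normalize_block(simulate_combination_block(a, b, "bliss_independent"))
    expect_lt(max(abs(delta_bliss(nb)$delta)), 1e-12)
  }
})

test_that("delta Bliss on viability equals the negated fa-scale deviation where v <= 1", {
  withr::local_seed(22)
  nb <- normalize_block(simulate_combination_block(
    rand_compound("a"), rand_compound("b"), interaction = "potency_shift",
    psi = 3, noise_cv = 0.05))
  s <- delta_bliss(nb)
  singles_A <- dplyr::filter(nb, doseB == 0)
  singles_B <- dplyr::filter(nb, doseA == 0)
  vA <- singles_A$v[match(s$doseA, singles_A$doseA)]
  vB <- singles_B$v[match(s$doseB, singles_B$doseB)]
  ok <- s$v <= 1 & vA <= 1 & vB <= 1
  expect_gt(sum(ok), 0)
  fa_obs <- 1 - s$v[ok]
  fa_exp <- (1 - vA[ok]) + (1 - vB[ok]) - (1 - vA[ok]) * (1 - vB[ok])
  expect_equal(s$delta[ok], -(fa_obs - fa_exp), tolerance = 1e-12)
})

test_that("per-well CI follows the defining formula on a constructed block", {
  fit1 <- fit_median_effect(c(100, 400, 1600) * 1e-9, c(0.2, 0.5, 0.8))
  doses <- c(0, 2e-7, 4e-7)
  # choose a well whose observed fa makes DxA = its own dose: contribution 1
  v <- matrix(1, 3, 3)
  v[2, ] <- c(0.7, 0.6, 0.5)
  v[3, ] <- c(0.5, 0.45, 0.4)
  nb <- norm_block_from_matrix(v, doses, doses)
  ci <- combination_index(nb, fit1, fit1, policy = "nearest_half")
  g <- attr(ci, "ci_grid")
  for (r in seq_len(nrow(g))) {
    expect_equal(
      g$ci[r],
      g$doseA[r] / dose_for_effect(fit1, g$fa[r]) +
        g$doseB[r] / dose_for_effect(fit1, g$fa[r])
    )
  }
})

test_that("self-combination sham surfaces score CI = 1 under every policy", {
  withr::local_seed(23)
  for (k in 1:10) {
    cmp <- rand_compound("a")
    twin <- cmp
    twin$compound_id <- "a2"
    nb <- normalize_block(simulate_combination_block(cmp, twin, "potency_shift",
                                                     psi = 1))
    fits <- fit_singles(nb)
    for (pol in c("diag_band_median", "nearest_half", "fa_band_min", "ray_fit")) {
      ci <- combination_index(nb, fits$A, fits$B, policy = pol)
      if (is.na(ci$ci)) {
        # a steep curve can step the 5-well diagonal clean over the band
        expect_equal(ci$flag, "no-effect-band")
      } else {
        expect_equal(ci$ci, 1, tolerance = 1e-3)
      }
    }
  }
})

test_that("CI tracks the planted potency shift and decreases strictly in psi", {
  withr::local_seed(24)
  a <- rand_compound("a")
  b <- rand_compound("b")
  cis <- sapply(c(1, 2, 4, 8), function(psi) {
    nb <- normalize_block(simulate_combination_block(a, b, "potency_shift",
                                                     psi = psi))
    fits <- fit_singles(nb)
    combination_index(nb, fits$A, fits$B)$ci
  })
  expect_equal(cis, 1 / c(1, 2, 4, 8), tolerance = 1e-3)
  expect_true(all(diff(cis) < 0))
})

test_that("CI is undefined with an explanatory flag when no well is in the band", {
  doses <- c(0, 1e-8)
  v <- matrix(c(1, 0.99, 0.99, 0.98), 2, 2, byrow = TRUE)  # nothing reaches fa 0.25
  nb <- norm_block_from_matrix(v, doses, doses)
  fit <- fit_median_effect(c(100, 400, 1600) * 1e-9, c(0.2, 0.5, 0.8))
  ci <- combination_index(nb, fit, fit, policy = "nearest_half")
  expect_true(is.na(ci$ci))
  expect_equal(ci$flag, "no-effect-band")
})

test_that("beta compares top-dose combination against the best single agent", {
  doses <- c(0, 1e-8, 1e-7)
  base <- matrix(1, 3, 3)
  base[3, 1] <- 0.4   # drug A alone at top
  base[1, 3] <- 0.6   # drug B alone at top

  eq <- base; eq[3, 3] <- 0.4
  expect_equal(beta_parameter(norm_block_from_matrix(eq, doses, doses))$beta, 1)

  deeper <- base; deeper[3, 3] <- 0.2
  expect_equal(beta_parameter(norm_block_from_matrix(deeper, doses, doses))$beta, 0.5)

  worse <- base; worse[3, 3] <- 0.5
  expect_equal(beta_parameter(norm_block_from_matrix(worse, doses, doses))$beta, 1.25)

  saturated <- base; saturated[3, 1] <- 0.005; saturated[3, 3] <- 0.001
  out <- beta_parameter(norm_block_from_matrix(saturated, doses, doses))
  expect_true(is.na(out$beta))
  expect_equal(out$flag, "singles-saturating")
})

test_that("summarize_pair assembles scores and applies the hit rule", {
  a <- sim_compound("a", ec50 = 1e-6, slope = 1.2, emax = 0, top_dose = 1e-5)
  anchor <- sim_compound("anchor", ec50 = 4e-7, slope = 1.5, emax = 0,
                         top_dose = 2.5e-6)

  null_rep <- summarize_pair(normalize_block(
    simulate_combination_block(a, anchor, "bliss_independent")))
  expect_false(null_rep$hit)
  expect_equal(null_rep$sum_neg_bliss, 0, tolerance = 1e-12)

  syn_rep <- summarize_pair(normalize_block(
    simulate_combination_block(a, anchor, "potency_shift", psi = 6)))
  expect_true(syn_rep$hit)
  expect_lt(syn_rep$ci, 0.5)
  expect_lt(syn_rep$beta, 1)

  dead <- sim_compound("inert", ec50 = 1, slope = 1, emax = 0, top_dose = 1e-5)
  flat_rep <- summarize_pair(normalize_block(
    simulate_combination_block(dead, dead, "bliss_independent")))
  expect_true(is.na(flat_rep$ci))
  expect_false(flat_rep$hit)
  expect_match(flat_rep$flags, "unfittable|no-effect-band")
})

test_that("synergy surfaces and fits render as ggplot objects", {
  withr::local_seed(26)
  nb <- normalize_block(simulate_combination_block(
    rand_compound("a"), rand_compound("b"), interaction = "potency_shift", psi = 4))
  expect_s3_class(ggplot2::autoplot(delta_bliss(nb)), "ggplot")
  expect_s3_class(ggplot2::autoplot(excess_hsa(nb)), "ggplot")
  sl <- nb[nb$doseB == 0, ]
  fit <- fit_median_effect(sl$doseA, sl$fa)
  expect_s3_class(ggplot2::autoplot(fit, doses = sl$doseA, fa = sl$fa), "ggplot")
})
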