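test_that("long CSV round-trips through write/read with doses and signals intact", {
  withr::local_seed(1)
  blk <- simulate_combination_block(rand_compound("a"), rand_compound("b"),
                                    noise_cv = 0.1)
  ds <- as_screen_dataset(blk)
  f <- withr::local_tempfile(fileext = ".csv")
  fa <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(ds, f, annotation_path = fa)
  back <- read_screen_table(f, annotation_path = fa)

  expect_s3_class(back, "screen_dataset")
  key <- function(w) dplyr::arrange(w, doseA, doseB, replicate)
  expect_identical(key(back$wells)$doseA, key(ds$wells)$doseA)
  expect_identical(key(back$wells)$doseB, key(ds$wells)$doseB)
  expect_identical(key(back$wells)$signal, key(ds$wells)$signal)
  expect_identical(key(back$wells)$replicate, key(ds$wells)$replicate)
})

test_that("reader reshapes 6x6 blocks for one and three replicates", {
  for (reps in c(1L, 3L)) {
    blk <- simulate_combination_block(
      sim_compound("a"), sim_compound("b"),
      design = matrix_design(replicates = reps)
    )
    expect_equal(nrow(blk), 36 * reps)
    f <- withr::local_tempfile(fileext = ".csv")
    write_screen_table(as_screen_dataset(blk), f)
    ds <- read_screen_table(f)
    expect_equal(nrow(dplyr::distinct(ds$wells, block_id, assay)), 1)
    expect_equal(sort(unique(ds$wells$replicate)), seq_len(reps))
    expect_equal(length(unique(ds$wells$doseA)), 6)
  }
})

test_that("a 10x10 triplicate block writes 100 * R rows", {
  blk <- simulate_combination_block(sim_compound("a"), sim_compound("b"),
                                    design = confirmation_design())
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(as_screen_dataset(blk), f)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), 100 * 3)
})

test_that("format, structure and value errors are specific", {
  f <- withr::local_tempfile(fileext = ".csv")
  blk <- simulate_combination_block(sim_compound("a"), sim_compound("b"))

  readr::write_csv(dplyr::select(blk, -doseB), f)
  expect_error(read_screen_table(f), "doseB", class = "comboscreen_error_format")

  ragged <- dplyr::filter(blk, !(doseA == max(doseA) & doseB == max(doseB)))
  readr::write_csv(ragged, f)  # the top-top well is absent from the grid
  expect_error(read_screen_table(f), "missing well",
               class = "comboscreen_error_structural")

  blk2 <- blk
  blk2$signal[5] <- -1
  readr::write_csv(blk2, f)
  expect_error(read_screen_table(f), "negative", class = "comboscreen_error_value")
})

test_that("unknown compounds are carried as unannotated", {
  blk <- simulate_combination_block(sim_compound("mystery"), sim_compound("b"))
  f <- withr::local_tempfile(fileext = ".csv")
  fa <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(blk, f)
  readr::write_csv(tibble::tibble(compound_id = "b", name = "anchor drug",
                                  moa_class = "SMAC mimetic"), fa)
  ds <- read_screen_table(f, annotation_path = fa)
  expect_equal(ds$compounds$moa_class[ds$compounds$compound_id == "mystery"],
               "unannotated")
})

test_that("wide dialect reads a matrix-shaped block", {
  doses <- c(0, 1e-8, 1e-7)
  wide <- tibble::tibble(doseA = doses, `0` = c(1000, 900, 500),
                         `1e-08` = c(950, 850, 400), `1e-07` = c(600, 500, 200))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(wide, f)
  ds <- read_screen_table(f, dialect = "wide")
  expect_equal(nrow(ds$wells), 9)
  expect_equal(sort(unique(ds$wells$doseB)), doses)
})

test_that("normalization divides by the vehicle-well replicate mean", {
  blk <- tibble::tibble(
    block_id = "b", drugA_id = "A", drugB_id = "B", assay = "viability",
    doseA = rep(c(0, 1e-7), each = 2), doseB = 0,
    replicate = rep(1:2, 2),
    signal = c(900, 1100, 500, 500)  # vehicle mean 1000, test well 500
  )
  nb <- normalize_block(blk)
  test_row <- nb[nb$doseA > 0, ]
  expect_equal(test_row$v, 0.5)
  expect_equal(test_row$fa, 0.5)
  expect_equal(nb$v[nb$doseA == 0], 1)
})

test_that("viability above control is retained in v but clamped in fa", {
  blk <- tibble::tibble(
    block_id = "b", drugA_id = "A", drugB_id = "B", assay = "viability",
    doseA = c(0, 1e-7), doseB = 0, replicate = 1L, signal = c(1000, 1200)
  )
  nb <- normalize_block(blk)
  expect_equal(nb$v[nb$doseA > 0], 1.2)
  expect_equal(nb$fa[nb$doseA > 0], 0)
})

test_that("all-equal wells normalize to v = 1, fa = 0 and the step is idempotent", {
  doses <- c(0, 1e-8, 1e-7)
  blk <- tidyr::expand_grid(doseA = doses, doseB = doses, replicate = 1:2) |>
    dplyr::mutate(block_id = "b", drugA_id = "A", drugB_id = "B",
                  assay = "viability", signal = 840)
  nb <- normalize_block(blk)
  expect_true(all(abs(nb$v - 1) < 1e-12))
  expect_true(all(nb$fa == 0))

  # idempotence: feed normalized viability back as signal
  withr::local_seed(2)
  blk2 <- simulate_combination_block(rand_compound("a"), rand_compound("b"))
  n1 <- normalize_block(blk2)
  renorm <- dplyr::mutate(
    dplyr::select(n1, -dplyr::any_of(c("n_rep", "sem", "fa"))),
    replicate = 1L, signal = v
  )
  n2 <- normalize_block(dplyr::select(renorm, -v))
  expect_equal(n2$v, n1$v, tolerance = 1e-12)
})

test_that("vehicle signal of zero is a normalization error", {
  blk <- tibble::tibble(
    block_id = "b", drugA_id = "A", drugB_id = "B", assay = "viability",
    doseA = c(0, 1e-7), doseB = 0, replicate = 1L, signal = c(0, 500)
  )
  expect_error(normalize_block(blk), class = "comboscreen_error_normalization")
})

test_that("fa stays in [0,1] and decreases as v increases across random blocks", {
  withr::local_seed(3)
  for (k in 1:5) {
    nb <- normalize_block(simulate_combination_block(
      rand_compound("a"), rand_compound("b"), noise_cv = 0.3))
    expect_true(all(nb$fa >= 0 & nb$fa <= 1))
    o <- order(nb$v)
    expect_true(all(diff(nb$fa[o]) <= 1e-12))
  }
})

test_that("activity normalizes to viability elementwise, masking dead wells", {
  doses <- c(0, 1e-8, 1e-7)
  v_act <- matrix(2, 3, 3)
  v_via <- matrix(0.5, 3, 3)
  act <- norm_block_from_matrix(v_act, doses, doses)
  via <- norm_block_from_matrix(v_via, doses, doses)
  out <- normalize_activity_to_viability(act, via)
  expect_true(all(out$v == 4))

  out2 <- normalize_activity_to_viability(act, act)
  expect_true(all(out2$v == 1))

  v_dead <- v_via
  v_dead[3, 3] <- 0.001
  expect_warning(
    out3 <- normalize_activity_to_viability(act, norm_block_from_matrix(v_dead, doses, doses)),
    "masked"
  )
  expect_true(is.na(out3$v[out3$doseA == 1e-7 & out3$doseB == 1e-7]))
  expect_equal(sum(is.na(out3$v)), 1)

  bad <- norm_block_from_matrix(v_via[1:2, 1:2], doses[1:2], doses[1:2])
  expect_error(normalize_activity_to_viability(act, bad),
               class = "comboscreen_error_structural")
})
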