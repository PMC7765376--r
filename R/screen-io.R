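#' Read a long-format combination screen table
#'
#' Reads plate data for drug-pair dose matrices from a long-format CSV with
#' columns `block_id, drugA_id, doseA, drugB_id, doseB, replicate, signal,
#' assay`, plus an optional compound annotation CSV with columns
#' `compound_id, name, moa_class`. Each `(block_id, assay)` combination is one
#' dose-matrix block: a full factorial grid of the two drugs' dose series,
#' including the vehicle-only row and column (dose 0).
#'
#' Lines starting with `#` are treated as comments (the package's own writers
#' prepend a provenance comment). A wide, matrix-shaped dialect is accepted via
#' `dialect = "wide"`: first column `doseA`, remaining column names the doses
#' of drug B, one block per file.
#'
#' @param path Path to the wells CSV.
#' @param annotation_path Optional path to the compound annotation CSV.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param drugA_id,drugB_id,assay Used only by the wide dialect, which carries
#'   no identifier columns.
#' @return A `screen_dataset`: a list with `wells` (tibble, one row per well
#'   replicate) and `compounds` (annotation tibble; compounds present in the
#'   wells but absent from the annotation get `moa_class = "unannotated"`).
#' @export
#' @examples
#' blk <- simulate_combination_block(
#'   sim_compound("cmpdA"), sim_compound("anchor"),
#'   interaction = "bliss_independent", seed = 1
#' )
#' f <- tempfile(fileext = ".csv")
#' write_screen_table(as_screen_dataset(blk), f)
#' ds <- read_screen_table(f)
#' ds$wells
read_screen_table <- function(path, annotation_path = NULL, dialect = c("long", "wide"),
                              drugA_id = "drugA", drugB_id = "drugB",
                              assay = "viability") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) cs_abort(paste0("no such file: ", path), "io")
  wells <- if (dialect == "long") read_long_wells(path) else {
    read_wide_wells(path, drugA_id, drugB_id, assay)
  }
  validate_wells(wells)

  compounds <- if (!is.null(annotation_path)) {
    ann <- readr::read_csv(annotation_path, comment = "#", show_col_types = FALSE)
    need <- c("compound_id", "name", "moa_class")
    missing <- setdiff(need, names(ann))
    if (length(missing) > 0) {
      cs_abort(paste0("annotation file lacks column(s): ",
                      paste(missing, collapse = ", ")), "format")
    }
    dplyr::select(ann, dplyr::all_of(need))
  } else {
    tibble::tibble(compound_id = character(), name = character(), moa_class = character())
  }
  seen <- unique(c(wells$drugA_id, wells$drugB_id))
  unknown <- setdiff(seen, compounds$compound_id)
  if (length(unknown) > 0) {
    compounds <- dplyr::bind_rows(
      compounds,
      tibble::tibble(compound_id = unknown, name = unknown, moa_class = "unannotated")
    )
  }
  new_screen_dataset(wells, compounds)
}

read_long_wells <- function(path) {
  need <- c("block_id", "drugA_id", "doseA", "drugB_id", "doseB",
            "replicate", "signal", "assay")
  # base read.csv: its correctly-rounded double parser lets 17-digit doses
  # and signals round-trip bit-identically
  wells <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                             stringsAsFactors = FALSE))
  missing <- setdiff(need, names(wells))
  if (length(missing) > 0) {
    cs_abort(paste0("screen table lacks column(s): ",
                    paste(missing, collapse = ", ")), "format")
  }
  wells <- dplyr::select(wells, dplyr::all_of(need))
  for (col in c("block_id", "drugA_id", "drugB_id", "assay")) {
    wells[[col]] <- as.character(wells[[col]])
  }
  for (col in c("doseA", "doseB", "signal")) {
    wells[[col]] <- as.numeric(wells[[col]])
  }
  wells$replicate <- as.integer(wells$replicate)
  wells
}

read_wide_wells <- function(path, drugA_id, drugB_id, assay) {
  m <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (names(m)[1] != "doseA") {
    cs_abort("wide dialect requires first column 'doseA'", "format")
  }
  long <- tidyr::pivot_longer(m, -"doseA", names_to = "doseB", values_to = "signal")
  tibble::tibble(
    block_id = "block1", drugA_id = drugA_id, doseA = long$doseA,
    drugB_id = drugB_id, doseB = as.numeric(long$doseB),
    replicate = 1L, signal = long$signal, assay = assay
  )
}

# Structural checks shared by the reader and the simulator output:
# nonnegative signal, complete factorial grid per block, vehicle level present.
validate_wells <- function(wells) {
  if (any(wells$signal < 0, na.rm = TRUE)) {
    cs_abort("negative raw signal values are not allowed", "value")
  }
  by_block <- dplyr::group_split(dplyr::group_by(wells, .data$block_id, .data$assay))
  for (blk in by_block) {
    dA <- sort(unique(blk$doseA))
    dB <- sort(unique(blk$doseB))
    if (dA[1] != 0 || dB[1] != 0) {
      cs_abort(paste0("block ", blk$block_id[1],
                      ": dose series must include a vehicle level (dose 0)"),
               "structural")
    }
    have <- dplyr::distinct(blk, .data$doseA, .data$doseB)
    grid <- tidyr::expand_grid(doseA = dA, doseB = dB)
    miss <- dplyr::anti_join(grid, have, by = c("doseA", "doseB"))
    if (nrow(miss) > 0) {
      cs_abort(paste0(
        "block ", blk$block_id[1], ": ragged grid, missing well(s): ",
        paste(sprintf("(%.3g, %.3g)", miss$doseA, miss$doseB), collapse = ", ")
      ), "structural")
    }
  }
  invisible(wells)
}

new_screen_dataset <- function(wells, compounds) {
  structure(list(wells = tibble::as_tibble(wells),
                 compounds = tibble::as_tibble(compounds)),
            class = "screen_dataset")
}

#' Assemble a screen dataset from a wells tibble
#'
#' @param wells Long-format wells tibble (columns as in [read_screen_table()]).
#' @param compounds Optional annotation tibble (`compound_id, name, moa_class`);
#'   compounds appearing only in `wells` are added as `"unannotated"`.
#' @return A `screen_dataset`.
#' @export
as_screen_dataset <- function(wells, compounds = NULL) {
  validate_wells(wells)
  ids <- unique(c(wells$drugA_id, wells$drugB_id))
  if (is.null(compounds)) {
    compounds <- tibble::tibble(compound_id = ids, name = ids, moa_class = "unannotated")
  } else {
    extra <- setdiff(ids, compounds$compound_id)
    if (length(extra) > 0) {
      compounds <- dplyr::bind_rows(
        compounds,
        tibble::tibble(compound_id = extra, name = extra, moa_class = "unannotated")
      )
    }
  }
  new_screen_dataset(wells, compounds)
}

#' @export
print.screen_dataset <- function(x, ...) {
  nb <- nrow(dplyr::distinct(x$wells, .data$block_id, .data$assay))
  cat("<screen_dataset> ", nb, " block(s), ", nrow(x$wells), " wells, ",
      nrow(x$compounds), " annotated compounds\n", sep = "")
  invisible(x)
}

#' Write a screen dataset to CSV
#'
#' Writes the long-format wells table (and, when `annotation_path` is given,
#' the compound table). Round-trips bit-identically through
#' [read_screen_table()] for doses, signals and replicate labels.
#'
#' @param dataset A `screen_dataset` (or bare wells tibble).
#' @param path Output CSV path for the wells.
#' @param annotation_path Optional output path for the compound table.
#' @param header_comment Optional `#`-prefixed provenance line(s) to prepend.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(dataset, path, annotation_path = NULL,
                               header_comment = NULL) {
  wells <- if (inherits(dataset, "screen_dataset")) dataset$wells else tibble::as_tibble(dataset)
  write_csv_commented(wells, path, header_comment)
  if (!is.null(annotation_path) && inherits(dataset, "screen_dataset")) {
    write_csv_commented(dataset$compounds, annotation_path, header_comment)
  }
  invisible(path)
}

write_csv_commented <- function(df, path, header_comment = NULL) {
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    cs_abort(paste0("cannot open for writing: ", path), "io")
  })
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", sub("^#\\s*", "", header_comment)), con)
  }
  # doubles rendered with 17 significant digits so doses and signals
  # round-trip bit-identically through the reader
  dbl <- vapply(df, is.double, logical(1))
  df[dbl] <- lapply(df[dbl], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  readr::write_csv(df, con)
  invisible(path)
}

#' Normalize one dose-matrix block to fraction-of-control viability
#'
#' Each well replicate is divided by the replicate mean of the vehicle-vehicle
#' well (dose 0 of both drugs), so the block is expressed as a fraction of
#' control: `v(i,j,r) = signal(i,j,r) / mean_r signal(0,0,r)`. Values above 1
#' (wells outgrowing the control) are retained in `v` but the derived fraction
#' affected `fa = 1 - v` is clamped to `[0, 1]`, since downstream median-effect
#' arithmetic works on `log(fa/fu)` which is only defined inside the unit
#' interval.
#'
#' @param block Wells tibble for exactly one `(block_id, assay)` block.
#' @param keep_replicates If `TRUE`, return one row per replicate with the
#'   per-replicate `v_rep` alongside the well-level mean (for QC); default
#'   returns one row per well.
#' @return A tibble with one row per well: `block_id, assay, drugA_id,
#'   drugB_id, doseA, doseB, n_rep, v, sem, fa`. `v` is the replicate mean,
#'   `sem` its standard error.
#' @export
#' @examples
#' blk <- simulate_combination_block(
#'   sim_compound("cmpdA"), sim_compound("anchor"), seed = 1
#' )
#' normalize_block(blk)
normalize_block <- function(block, keep_replicates = FALSE) {
  block <- tibble::as_tibble(block)
  nb <- dplyr::n_distinct(block$block_id, block$assay)
  if (nb != 1) cs_abort("normalize_block() expects exactly one (block_id, assay) block", "structural")
  validate_wells(block)

  veh <- block$signal[block$doseA == 0 & block$doseB == 0]
  veh_mean <- mean(veh)
  if (!is.finite(veh_mean) || veh_mean <= 0) {
    cs_abort("vehicle-well mean signal must be positive to normalize", "normalization")
  }

  per_rep <- dplyr::mutate(block, v_rep = .data$signal / veh_mean)
  out <- per_rep |>
    dplyr::group_by(.data$block_id, .data$assay, .data$drugA_id, .data$drugB_id,
                    .data$doseA, .data$doseB) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      v = mean(.data$v_rep),
      sem = if (dplyr::n() > 1) sd(.data$v_rep) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(fa = clamp01(1 - .data$v)) |>
    dplyr::arrange(.data$doseA, .data$doseB)

  if (keep_replicates) {
    out <- dplyr::left_join(
      dplyr::select(per_rep, dplyr::all_of(c(
        "block_id", "assay", "drugA_id", "drugB_id",
        "doseA", "doseB", "replicate", "v_rep"
      ))),
      out,
      by = c("block_id", "assay", "drugA_id", "drugB_id", "doseA", "doseB")
    )
  }
  out
}

#' Normalize every block of a screen
#'
#' Applies [normalize_block()] per `(block_id, assay)` group.
#'
#' @param wells A `screen_dataset` or long wells tibble.
#' @param assay Optional assay readout to keep (`"viability"` or `"caspase"`);
#'   default keeps all.
#' @return One normalized tibble (see [normalize_block()]) over all blocks.
#' @export
normalize_screen <- function(wells, assay = NULL) {
  if (inherits(wells, "screen_dataset")) wells <- wells$wells
  if (!is.null(assay)) wells <- dplyr::filter(wells, .data$assay == !!assay)
  if (nrow(wells) == 0) cs_abort("no wells to normalize (check the assay filter)", "structural")
  wells |>
    dplyr::group_by(.data$block_id, .data$assay) |>
    dplyr::group_split() |>
    purrr::map(normalize_block) |>
    purrr::list_rbind()
}

#' Normalize an activity readout to cell viability
#'
#' Expresses a luminescence activity matrix (for example caspase activation)
#' per viable cell by dividing, well by well, the activity fraction-of-control
#' by the viability fraction-of-control measured on a congruent design. Wells
#' whose viability falls below `floor` are masked (`NA`) with a warning: the
#' ratio there divides by an essentially dead well and is not interpretable.
#'
#' @param activity,viability Normalized block tibbles from [normalize_block()]
#'   with identical dose vectors.
#' @param floor Viability below which the ratio is masked (default 0.01).
#' @return The `activity` tibble with `v` replaced by the viability-normalized
#'   ratio (`sem` dropped, `fa` recomputed from the ratio is meaningless and
#'   removed).
#' @export
normalize_activity_to_viability <- function(activity, viability, floor = 0.01) {
  a <- dplyr::arrange(tibble::as_tibble(activity), .data$doseA, .data$doseB)
  w <- dplyr::arrange(tibble::as_tibble(viability), .data$doseA, .data$doseB)
  if (nrow(a) != nrow(w) ||
      !isTRUE(all.equal(a$doseA, w$doseA)) || !isTRUE(all.equal(a$doseB, w$doseB))) {
    cs_abort("activity and viability blocks have different dose grids", "structural")
  }
  ratio <- a$v / w$v
  masked <- w$v < floor
  if (any(masked)) {
    warn(paste0(sum(masked), " well(s) masked: viability below floor of ", floor))
    ratio[masked] <- NA_real_
  }
  dplyr::mutate(
    dplyr::select(a, -dplyr::any_of(c("sem", "fa"))),
    v = ratio, masked = masked
  )
}

# Pivot one normalized block to a dose-by-dose matrix of `value`
# (rows = doseA ascending, cols = doseB ascending).
surface_matrix <- function(norm_block, value = "v") {
  dA <- sort(unique(norm_block$doseA))
  dB <- sort(unique(norm_block$doseB))
  m <- matrix(NA_real_, length(dA), length(dB),
              dimnames = list(format(dA, trim = TRUE), format(dB, trim = TRUE)))
  i <- match(norm_block$doseA, dA)
  j <- match(norm_block$doseB, dB)
  m[cbind(i, j)] <- norm_block[[value]]
  attr(m, "dosesA") <- dA
  attr(m, "dosesB") <- dB
  m
}
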