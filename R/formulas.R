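#' Ellipsoid tumor volume from caliper measurements
#'
#' Standard xenograft convention: `V = 1/2 * length * width^2`, with length
#' the longer of the two caliper axes. If a width larger than its length is
#' supplied the two are swapped with a warning rather than silently producing
#' the wrong volume.
#'
#' @param length_mm,width_mm Caliper measurements in mm (vectorized).
#' @return Tumor volume(s) in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 6)  # 180
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0 | width_mm < 0, na.rm = TRUE)) {
    cs_abort("caliper measurements must be nonnegative", "value")
  }
  swap <- which(width_mm > length_mm)
  if (length(swap) > 0) {
    warn(paste0("width > length for ", length(swap),
                " measurement(s); axes swapped"))
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  0.5 * length_mm * width_mm^2
}

#' Log2 fold change over control
#'
#' @param treated,control Positive measurements (vectorized).
#' @return `log2(treated / control)`.
#' @export
#' @examples
#' log2_fold_change(4, 1)  # 2
log2_fold_change <- function(treated, control) {
  if (any(treated <= 0 | control <= 0, na.rm = TRUE)) {
    cs_abort("treated and control must be strictly positive", "value")
  }
  log2(treated / control)
}
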