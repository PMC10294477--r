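#' Build a clone mixture with known ground-truth fractions
#'
#' Emulates the calibration experiments in which monoclonal barcoded cell
#' lines are mixed at known ratios (for example ten clones at
#' 1:10:10:50:100:100:200:200:200:250, where the smallest clone contributes
#' 1/1121 = 0.089% of the mix). Fractions are the ratios renormalized to
#' sum to one.
#'
#' @param library A [generate_barcode_library()] result.
#' @param ratios Positive mixing ratios, one per clone.
#' @param barcode_ids Barcode identifiers drawn from `library`; defaults to
#'   the first `length(ratios)` informative barcodes.
#'
#' @return A `bc_mixture` tibble with columns `barcode_id`, `sequence`,
#'   `ratio`, `fraction`; the attribute `smallest_fraction` records the
#'   detection-limit clone of the design.
#' @examples
#' lib <- generate_barcode_library(10, length = 16, seed = 1)
#' mix <- simulate_mixture(lib, c(1, 10, 10, 50, 100, 100, 200, 200, 200, 250))
#' round(100 * min(mix$fraction), 3)  # 0.089 (percent)
#' @export
simulate_mixture <- function(library, ratios, barcode_ids = NULL) {
  if (any(ratios <= 0)) stop("all mixing ratios must be positive", call. = FALSE)
  if (is.null(barcode_ids)) {
    barcode_ids <- library$barcode_id[!library$noninformative][seq_along(ratios)]
  }
  if (length(ratios) != length(barcode_ids)) {
    stop("`ratios` and `barcode_ids` must have equal length", call. = FALSE)
  }
  idx <- match(barcode_ids, library$barcode_id)
  if (anyNA(idx)) {
    stop("barcode_ids absent from the library: ",
         paste(barcode_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  fractions <- ratios / sum(ratios)
  out <- tibble(
    barcode_id = barcode_ids,
    sequence = library$sequence[idx],
    ratio = as.numeric(ratios),
    fraction = fractions
  )
  structure(out, smallest_fraction = min(fractions),
            class = c("bc_mixture", class(out)))
}
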