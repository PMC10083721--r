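#' ER area and volume fraction from segmented cross-section areas
#'
#' From pre-measured cell and ER cross-section areas (one optical section
#' per cell), computes the ER area fraction `er_area / cell_area` and the
#' stereological volume-fraction estimate `(area fraction)^(3/2)`.
#'
#' @param cell_area cell cross-section area (um^2), > 0 (vectorised).
#' @param er_area ER cross-section area (um^2), `0 < er_area <= cell_area`.
#' @param nucleus_area optional nucleus area (um^2), carried through.
#' @return A data.frame with the input areas plus `area_fraction` and
#'   `volume_fraction` columns (both in (0, 1\]).
#' @examples
#' er_volume_fraction(618.4, 376.0)  # ~0.61 area, ~0.48 volume fraction
#' @export
er_volume_fraction <- function(cell_area, er_area, nucleus_area = NA_real_) {
  cell_area <- as.numeric(cell_area)
  er_area <- as.numeric(er_area)
  if (any(!is.finite(cell_area)) || any(cell_area <= 0)) {
    stop("cell_area must be > 0")
  }
  if (any(!is.finite(er_area)) || any(er_area <= 0)) {
    stop("er_area must be > 0")
  }
  if (any(er_area > cell_area)) {
    stop("er_area must not exceed cell_area")
  }
  af <- er_area / cell_area
  data.frame(cell_area = cell_area, er_area = er_area,
             nucleus_area = nucleus_area,
             area_fraction = af, volume_fraction = af^1.5)
}

#' Apply the ER volume-fraction arithmetic to a measurement table
#'
#' Reads a delimited table with columns `cell_id, cell_area_um2,
#' er_area_um2` (optionally `nucleus_area_um2`) and appends the fraction
#' columns.
#'
#' @param path input table path (comma-separated, header).
#' @param out optional output path; when given, the augmented table is
#'   written there.
#' @return The augmented data.frame, invisibly when `out` is given.
#' @export
er_morphometry_table <- function(path, out = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_area_um2", "er_area_um2")
  if (!all(need %in% names(df))) {
    stop(sprintf("morphometry table needs columns %s",
                 paste(need, collapse = ", ")))
  }
  nuc <- if ("nucleus_area_um2" %in% names(df)) df$nucleus_area_um2 else
    NA_real_
  fr <- er_volume_fraction(df$cell_area_um2, df$er_area_um2, nuc)
  df$area_fraction <- fr$area_fraction
  df$volume_fraction <- fr$volume_fraction
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
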