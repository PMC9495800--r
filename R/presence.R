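#' Host-presence mask
#'
#' The parasitoid is evaluated only where its host can occur: pixels whose
#' habitat-suitability probability strictly exceeds `threshold` (default
#' 0.2, the resilience level assumed for *T. absoluta*) AND whose land
#' cover is cropland (tomato and other solanaceous host crops).  Nodata in
#' either input propagates to nodata in the mask.
#'
#' @param suitability [land_grid()] of probabilities in `[0, 1]`.
#' @param lulc [land_grid()] of integer land-cover class codes.
#' @param threshold suitability cut, in `[0, 1]`; strict `>` is applied.
#' @param cropland_codes integer vector of codes counted as cropland.
#' @return [land_grid()] with values 1 (presence), 0 (absence) or `NA`.
#' @export
presence_mask <- function(suitability, lulc, threshold = 0.2,
                          cropland_codes = 2L) {
  stopifnot(inherits(suitability, "land_grid"), inherits(lulc, "land_grid"))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a probability in [0, 1]")
  stop_if_geometry_mismatch(suitability, lulc, "presence_mask")
  s <- suitability$values
  if (any(s[!is.na(s)] < 0 | s[!is.na(s)] > 1))
    stop("suitability values must lie in [0, 1]")
  l <- lulc$values
  m <- (s > threshold) & (matrix(l %in% cropland_codes, nrow(l), ncol(l)) &
                            !is.na(l))
  m[is.na(s) | is.na(l)] <- NA
  land_grid(m + 0, suitability$xll, suitability$yll,
            suitability$cellsize, suitability$crs)
}

#' Count presence pixels in a mask
#' @param mask a mask from [presence_mask()].
#' @return integer number of presence (value 1) pixels.
#' @export
mask_cardinality <- function(mask) {
  stopifnot(inherits(mask, "land_grid"))
  sum(mask$values == 1, na.rm = TRUE)
}
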