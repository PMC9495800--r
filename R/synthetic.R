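#' Regional monthly temperature climatology
#'
#' Long-term (1991-2021) monthly mean temperatures (deg C) for the six
#' Kenyan tomato-cropping regions, January to December.
#'
#' @return 6 x 12 numeric matrix, rownames = regions, colnames = months.
#' @export
regional_climatology <- function() {
  m <- rbind(
    "Western"     = c(21.0, 21.9, 21.6, 20.5, 19.5, 18.6, 18.2, 18.3, 19.0, 19.7, 19.8, 20.2),
    "Nyanza"      = c(23.6, 24.6, 23.9, 22.8, 22.5, 22.4, 22.5, 22.7, 23.2, 23.2, 22.7, 22.9),
    "Rift Valley" = c(18.9, 19.5, 19.3, 18.1, 17.2, 16.4, 16.1, 16.5, 17.5, 18.3, 17.7, 18.1),
    "Central"     = c(19.3, 20.0, 19.8, 18.6, 17.7, 16.8, 16.3, 16.7, 17.9, 18.6, 17.8, 18.2),
    "Eastern"     = c(19.6, 20.5, 20.4, 19.5, 18.7, 17.8, 17.2, 17.6, 18.8, 19.6, 18.7, 18.7),
    "Coast"       = c(27.9, 28.1, 28.7, 28.1, 26.6, 25.9, 25.4, 25.5, 26.2, 26.8, 27.2, 27.7))
  colnames(m) <- sprintf("%02d", 1:12)
  m
}

#' Land-cover legend used by the synthetic landscape
#'
#' Nine classes; code 2 is cropland (tomato and other solanaceous host
#' crops), the only code relevant to presence masking.
#' @return named integer vector code -> class name.
#' @export
lulc_legend <- function() {
  stats::setNames(1:9,
    c("grassland", "cropland", "forest", "shrubland", "water",
      "built-up", "barren", "wetland", "woodland"))
}

#' Synthetic landscape specification
#'
#' Describes the simulated study area: regions laid out as contiguous
#' vertical bands (west to east) by areal fraction, each carrying its
#' monthly climatology; per-pixel temperature = regional mean + Gaussian
#' noise; host suitability = logistic of annual mean temperature + noise,
#' clipped to `[0, 1]`; land cover drawn per pixel with a per-region
#' cropland fraction, remaining mass spread over the other legend classes.
#'
#' @param nrow,ncol grid dimensions in pixels (default 200 x 200).
#' @param region_temps numeric matrix regions x 12 months (deg C); default
#'   [regional_climatology()].
#' @param fractions areal fraction per region, summing to 1.
#' @param temp_noise_sd spatial temperature noise sd (deg C).
#' @param suit_midpoint,suit_slope logistic parameters mapping annual mean
#'   temperature (deg C) to suitability.
#' @param suit_noise_sd suitability noise sd (probability units).
#' @param cropland_fraction per-region probability a pixel is cropland
#'   (recycled to the number of regions).
#' @param cellsize,xll,yll,crs grid geometry.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(nrow = 200L, ncol = 200L,
                           region_temps = regional_climatology(),
                           fractions = rep(1 / base::nrow(region_temps),
                                           base::nrow(region_temps)),
                           temp_noise_sd = 0.5,
                           suit_midpoint = 15, suit_slope = 0.5,
                           suit_noise_sd = 0.1,
                           cropland_fraction = 0.4,
                           cellsize = 1, xll = 0, yll = 0, crs = "synthetic") {
  stopifnot(is.matrix(region_temps), ncol(region_temps) == 12L,
            base::nrow(region_temps) >= 1L,
            length(fractions) == base::nrow(region_temps))
  if (abs(sum(fractions) - 1) > 1e-9) stop("areal fractions must sum to 1")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (temp_noise_sd < 0 || suit_noise_sd < 0) stop("noise sd must be >= 0")
  cf <- rep_len(cropland_fraction, base::nrow(region_temps))
  if (any(cf < 0 | cf > 1)) stop("cropland fractions must lie in [0, 1]")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 region_temps = region_temps, fractions = fractions,
                 temp_noise_sd = temp_noise_sd,
                 suit_midpoint = suit_midpoint, suit_slope = suit_slope,
                 suit_noise_sd = suit_noise_sd,
                 cropland_fraction = cf,
                 cellsize = cellsize, xll = xll, yll = yll, crs = crs),
            class = "landscape_spec")
}

#' Default synthetic landscape
#'
#' Six equal-width regional bands carrying the published monthly
#' climatology, 200 x 200 pixels, 0.5 deg C spatial temperature noise,
#' suitability rising logistically with annual mean temperature (midpoint
#' 15 deg C, slope 0.5 — the host is resilient across the tropical range,
#' so most cropped land clears the 0.2 presence threshold), and 40%
#' cropland per region.
#' @export
default_landscape_spec <- function() landscape_spec()

#' Generate the synthetic input bundle
#'
#' Fully reproducible from `seed`; the caller's RNG state is untouched.
#' With `temp_noise_sd = 0`, every pixel of a region equals the region's
#' monthly mean exactly.
#'
#' @param spec a [landscape_spec()].
#' @param seed integer seed.
#' @return list with `temperature` ([temperature_stack()]), `suitability`,
#'   `lulc`, `regions` (all [land_grid()]), `region_names` (named by code),
#'   `legend`, `spec`, `seed`.
#' @export
generate_landscape <- function(spec = default_landscape_spec(), seed = 1L) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$nrow; nc <- spec$ncol
  n_reg <- nrow(spec$region_temps)
  # vertical bands: region of a pixel depends only on its column
  cum <- cumsum(spec$fractions)
  col_region <- findInterval((seq_len(nc) - 0.5) / nc, c(0, cum),
                             rightmost.closed = TRUE)
  col_region <- pmin(pmax(col_region, 1L), n_reg)
  region_m <- matrix(rep(col_region, each = nr), nr, nc)
  mk <- function(v) land_grid(v, spec$xll, spec$yll, spec$cellsize, spec$crs)

  with_seed(seed, {
    temps <- vector("list", 12L)
    for (m in 1:12) {
      mu <- spec$region_temps[region_m, m]
      noise <- if (spec$temp_noise_sd > 0)
        stats::rnorm(nr * nc, 0, spec$temp_noise_sd) else 0
      temps[[m]] <- mk(matrix(mu + noise, nr, nc))
    }
    annual <- Reduce(`+`, lapply(temps, function(g) g$values)) / 12
    suit <- stats::plogis(spec$suit_slope * (annual - spec$suit_midpoint))
    if (spec$suit_noise_sd > 0)
      suit <- suit + stats::rnorm(nr * nc, 0, spec$suit_noise_sd)
    suit <- pmin(pmax(suit, 0), 1)
    legend <- lulc_legend()
    other <- setdiff(unname(legend), legend[["cropland"]])
    p_crop <- spec$cropland_fraction[region_m]
    is_crop <- stats::runif(nr * nc) < p_crop
    lulc <- matrix(NA_real_, nr, nc)
    lulc[is_crop] <- legend[["cropland"]]
    lulc[!is_crop] <- sample(other, sum(!is_crop), replace = TRUE)
    list(temperature = suppressWarnings(temperature_stack(temps)),
         suitability = mk(matrix(suit, nr, nc)),
         lulc = mk(lulc),
         regions = mk(region_m + 0),
         region_names = stats::setNames(rownames(spec$region_temps),
                                        seq_len(n_reg)),
         legend = legend, spec = spec, seed = as.integer(seed))
  })
}

#' Write a landscape bundle to disk
#'
#' Emits the same plain-text formats the pipeline reads: ASCII grids
#' `temp_01.asc` .. `temp_12.asc`, `suitability.asc`, `lulc.asc`,
#' `regions.asc`, plus `region_names.csv` and a YAML echo of the spec.
#'
#' @param ls a bundle from [generate_landscape()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in 1:12)
    write_ascii_grid(ls$temperature[[m]],
                     file.path(dir, sprintf("temp_%02d.asc", m)))
  write_ascii_grid(ls$suitability, file.path(dir, "suitability.asc"))
  write_ascii_grid(ls$lulc, file.path(dir, "lulc.asc"))
  write_ascii_grid(ls$regions, file.path(dir, "regions.asc"))
  utils::write.csv(data.frame(code = names(ls$region_names),
                              region = unname(ls$region_names)),
                   file.path(dir, "region_names.csv"), row.names = FALSE)
  spec <- ls$spec
  yaml::write_yaml(list(nrow = spec$nrow, ncol = spec$ncol,
                        temp_noise_sd = spec$temp_noise_sd,
                        suit_midpoint = spec$suit_midpoint,
                        suit_slope = spec$suit_slope,
                        suit_noise_sd = spec$suit_noise_sd,
                        cropland_fraction = spec$cropland_fraction,
                        fractions = spec$fractions,
                        regions = rownames(spec$region_temps),
                        seed = ls$seed),
                   file.path(dir, "landscape_spec.yaml"))
  invisible(dir)
}

#' Read a landscape bundle written by [write_landscape()]
#'
#' @param dir directory containing the ASCII grids.
#' @return list with `temperature`, `suitability`, `lulc`, `regions`,
#'   `region_names`.
#' @export
read_landscape <- function(dir) {
  paths <- file.path(dir, sprintf("temp_%02d.asc", 1:12))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing temperature layers: %s",
                 paste(basename(missing), collapse = ", ")))
  temps <- lapply(paths, read_ascii_grid)
  rn_path <- file.path(dir, "region_names.csv")
  region_names <- if (file.exists(rn_path)) {
    rn <- utils::read.csv(rn_path)
    stats::setNames(as.character(rn$region), rn$code)
  } else NULL
  list(temperature = suppressWarnings(temperature_stack(temps)),
       suitability = read_ascii_grid(file.path(dir, "suitability.asc")),
       lulc = read_ascii_grid(file.path(dir, "lulc.asc")),
       regions = read_ascii_grid(file.path(dir, "regions.asc")),
       region_names = region_names)
}
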