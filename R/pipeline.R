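#' Monthly temperature stack
#'
#' Validates a January-to-December list of 12 mean-temperature grids
#' sharing one geometry.  Values outside a plausible range (-20..60 deg C)
#' are flagged with a warning, not an error.
#'
#' @param grids list of 12 [land_grid()]s, ordered January to December.
#' @return the list, classed `temperature_stack`, named `"01".."12"`.
#' @export
temperature_stack <- function(grids) {
  if (!is.list(grids) || length(grids) != 12L)
    stop("a temperature stack must contain exactly 12 monthly grids")
  ok <- vapply(grids, inherits, logical(1), what = "land_grid")
  if (!all(ok)) stop("all stack layers must be land_grid objects")
  for (m in 2:12) stop_if_geometry_mismatch(grids[[1]], grids[[m]],
                                            "temperature_stack")
  rng <- range(unlist(lapply(grids, function(g) range(g$values, na.rm = TRUE))))
  if (rng[1] < -20 || rng[2] > 60)
    warning(sprintf("temperatures outside plausible -20..60 degC range: [%g, %g]",
                    rng[1], rng[2]))
  names(grids) <- sprintf("%02d", 1:12)
  structure(grids, class = "temperature_stack")
}

#' Climate scenario configuration
#'
#' The future scenario applies a uniform temperature shift to every defined
#' pixel of the stack; the headline projection is +2 deg C by 2050
#' (SSP2-4.5 class warming).  `current` is the identity.
#'
#' @param scenario `"current"` or `"future"`.
#' @param delta_t uniform shift in deg C applied under `"future"`
#'   (default `2`).
#' @export
scenario_config <- function(scenario = c("current", "future"), delta_t = 2) {
  scenario <- match.arg(scenario)
  if (!is.finite(delta_t)) stop("delta_t must be finite")
  structure(list(scenario = scenario,
                 delta_t = if (scenario == "current") 0 else as.numeric(delta_t),
                 label = if (scenario == "current") "current"
                         else sprintf("future+%g", delta_t)),
            class = "scenario_config")
}

#' Apply a scenario shift to a temperature stack
#'
#' @param ts a [temperature_stack()].
#' @param sc a [scenario_config()].
#' @return shifted [temperature_stack()] (identity for `current` or
#'   `delta_t = 0`); nodata pixels untouched.
#' @export
apply_scenario <- function(ts, sc) {
  stopifnot(inherits(ts, "temperature_stack"), inherits(sc, "scenario_config"))
  if (sc$delta_t == 0) return(ts)
  out <- lapply(unclass(ts), function(g) {
    g$values <- g$values + sc$delta_t
    g
  })
  suppressWarnings(temperature_stack(out))
}

#' Per-pixel R0 prediction for one month
#'
#' Runs [predict_r0()] on every presence pixel of a temperature grid;
#' pixels where the mask is 0 or either input is nodata become nodata.
#'
#' @param rb calibrated [rule_base()].
#' @param cfg [inference_config()].
#' @param temp_grid [land_grid()] of mean temperature (deg C).
#' @param mask [presence_mask()] output on the same geometry.
#' @return [land_grid()] of crisp R0.
#' @export
predict_month <- function(rb, cfg, temp_grid, mask) {
  stopifnot(inherits(temp_grid, "land_grid"))
  stop_if_geometry_mismatch(temp_grid, mask, "predict_month")
  use <- which(mask$values == 1 & !is.na(temp_grid$values))
  out <- matrix(NA_real_, nrow(temp_grid$values), ncol(temp_grid$values))
  if (length(use)) {
    # chunked so the n x output_grid aggregation matrix stays small
    chunk <- 20000L
    for (b in split(use, ceiling(seq_along(use) / chunk)))
      out[b] <- as.numeric(predict_r0(rb, cfg, temp_grid$values[b]))
  }
  land_grid(out, temp_grid$xll, temp_grid$yll, temp_grid$cellsize,
            temp_grid$crs)
}

#' Performance class scheme
#'
#' Ordered labels with lower-inclusive R0 boundaries; the last class is
#' open-ended.  The default maps R0 below replacement (< 1) to
#' `very-poor`, `[1, 5)` to `poor`, `[5, 10)` to `good` and `>= 10`
#' (covering the laboratory optimum of 14-15) to `optimal`.
#'
#' @param labels character vector of class names, lowest first.
#' @param lower_bounds numeric vector, same length, strictly increasing;
#'   first element 0 so classes exhaust `[0, Inf)`.
#' @export
class_scheme <- function(labels = c("very-poor", "poor", "good", "optimal"),
                         lower_bounds = c(0, 1, 5, 10)) {
  stopifnot(length(labels) == length(lower_bounds), length(labels) >= 1L,
            !anyDuplicated(labels))
  if (any(diff(lower_bounds) <= 0) || lower_bounds[1] != 0)
    stop("lower bounds must start at 0 and be strictly increasing")
  structure(list(labels = labels, lower_bounds = as.numeric(lower_bounds)),
            class = "class_scheme")
}

#' Classify an R0 grid into performance classes
#'
#' Lower-inclusive binning: a pixel with R0 exactly on a boundary takes the
#' upper class.  Nodata propagates.
#'
#' @param r0_grid [land_grid()] of R0 values (>= 0 where defined).
#' @param scheme a [class_scheme()].
#' @return [land_grid()] of integer class codes (1 = first label), with the
#'   scheme attached as attribute `scheme`.
#' @export
classify_r0 <- function(r0_grid, scheme = class_scheme()) {
  stopifnot(inherits(r0_grid, "land_grid"), inherits(scheme, "class_scheme"))
  v <- r0_grid$values
  if (any(v[!is.na(v)] < 0)) stop("R0 values must be non-negative")
  code <- matrix(NA_real_, nrow(v), ncol(v))
  def <- !is.na(v)
  code[def] <- findInterval(v[def], scheme$lower_bounds)
  g <- land_grid(code, r0_grid$xll, r0_grid$yll, r0_grid$cellsize,
                 r0_grid$crs)
  attr(g, "scheme") <- scheme
  g
}

#' Pixel counts per region, month and performance class
#'
#' @param class_maps named list (by month `"01".."12"`, or any labels) of
#'   class-code grids from [classify_r0()].
#' @param regions [land_grid()] of integer region codes on the same
#'   geometry.
#' @param region_names optional named character vector mapping code to
#'   region name.
#' @param scheme the [class_scheme()] used for classification.
#' @return data.frame `region, month, class, pixel_count` including
#'   zero-count rows, ordered by region, month, class.
#' @export
pixel_counts <- function(class_maps, regions, region_names = NULL,
                         scheme = class_scheme()) {
  stopifnot(is.list(class_maps), length(class_maps) >= 1L,
            inherits(regions, "land_grid"))
  months <- names(class_maps)
  if (is.null(months)) months <- sprintf("%02d", seq_along(class_maps))
  codes <- sort(unique(regions$values[!is.na(regions$values)]))
  if (is.null(region_names))
    region_names <- stats::setNames(paste0("region_", codes), codes)
  out <- list()
  for (m in seq_along(class_maps)) {
    cm <- class_maps[[m]]
    stop_if_geometry_mismatch(cm, regions, "pixel_counts")
    for (rc in codes) {
      in_region <- regions$values == rc & !is.na(regions$values)
      cls <- cm$values[in_region]
      tab <- tabulate(cls[!is.na(cls)], nbins = length(scheme$labels))
      out[[length(out) + 1L]] <- data.frame(
        region = unname(region_names[as.character(rc)]),
        month = months[m],
        class = scheme$labels,
        pixel_count = as.integer(tab))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$region, res$month, match(res$class, scheme$labels)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
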