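#' Georeferenced raster grid
#'
#' A minimal single-band raster container: a numeric matrix (row 1 =
#' northernmost row, following the ESRI ASCII grid convention) plus an
#' affine geometry (lower-left corner, square cell size) and a CRS tag.
#' Missing cells are `NA` in memory and a declared nodata value on disk.
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize square cell edge length in CRS units.
#' @param crs free-text CRS tag (e.g. `"EPSG:3857"`); compared verbatim.
#' @return object of class `land_grid`.
#' @export
land_grid <- function(values, xll = 0, yll = 0, cellsize = 1, crs = "") {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  storage.mode(values) <- "double"
  structure(list(values = values, xll = as.numeric(xll),
                 yll = as.numeric(yll), cellsize = as.numeric(cellsize),
                 crs = as.character(crs)),
            class = "land_grid")
}

#' @export
print.land_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<land_grid> %d x %d, cell %g, origin (%g, %g)%s; range [%g, %g], %d nodata\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll,
              if (nzchar(x$crs)) paste0(", ", x$crs) else "",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

#' Do two grids share geometry?
#'
#' Same dimensions, origin, cell size (to a relative 1e-9) and CRS tag.
#' @param a,b `land_grid` objects.
#' @export
same_geometry <- function(a, b) {
  stopifnot(inherits(a, "land_grid"), inherits(b, "land_grid"))
  isTRUE(all(dim(a$values) == dim(b$values))) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                     c(b$xll, b$yll, b$cellsize), tolerance = 1e-9)) &&
    identical(a$crs, b$crs)
}

stop_if_geometry_mismatch <- function(a, b, what) {
  if (!same_geometry(a, b))
    stop(sprintf("%s: grids do not share geometry (use resample_to() first)",
                 what))
}

# cell-center coordinates (row 1 = north)
grid_x_centers <- function(g) g$xll + (seq_len(ncol(g$values)) - 0.5) * g$cellsize
grid_y_centers <- function(g) g$yll + (nrow(g$values) - seq_len(nrow(g$values)) + 0.5) * g$cellsize

#' Read / write ESRI ASCII grids
#'
#' Plain-text georeferenced raster exchange format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, northernmost row first.
#' The CRS tag travels in a sidecar comment-free `.prj`-style companion
#' only if supplied; by default it is carried in-memory only.
#'
#' @param path file path.
#' @param crs CRS tag attached to the grid on read.
#' @return `read_ascii_grid`: a [land_grid()].
#' @export
read_ascii_grid <- function(path, crs = "") {
  lines <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop(sprintf("not an ESRI ASCII grid: %s", path))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- hdr[["nrows"]]; nc <- hdr[["ncols"]]
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr[["nodata_value"]]] <- NA_real_
  land_grid(m, xll = hdr[["xllcorner"]], yll = hdr[["yllcorner"]],
            cellsize = hdr[["cellsize"]], crs = crs)
}

#' @rdname read_ascii_grid
#' @param g a [land_grid()].
#' @param nodata nodata sentinel written to the file header.
#' @param digits significant digits for cell values.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999, digits = 10L) {
  stopifnot(inherits(g, "land_grid"))
  v <- g$values
  if (any(v[!is.na(v)] == nodata))
    stop("nodata sentinel collides with a data value")
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", g$xll),
           sprintf("yllcorner %.10g", g$yll),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a grid onto a reference geometry
#'
#' `"nearest"` (mandatory for categorical grids: class codes are never
#' interpolated) assigns each target cell the value of the source cell
#' containing its center.  `"bilinear"` interpolates continuous values
#' between the four surrounding source cell centers, clamping at the
#' source edges.  Errors if any target cell center falls outside the
#' source extent.
#'
#' @param g source [land_grid()].
#' @param ref reference [land_grid()] supplying the target geometry.
#' @param method `"nearest"` or `"bilinear"`.
#' @return a [land_grid()] on `ref`'s geometry.
#' @export
resample_to <- function(g, ref, method = c("nearest", "bilinear")) {
  stopifnot(inherits(g, "land_grid"), inherits(ref, "land_grid"))
  method <- match.arg(method)
  if (same_geometry(g, ref)) return(land_grid(g$values, ref$xll, ref$yll,
                                              ref$cellsize, ref$crs))
  xt <- grid_x_centers(ref); yt <- grid_y_centers(ref)
  nrs <- nrow(g$values); ncs <- ncol(g$values)
  x0 <- g$xll; y0 <- g$yll; cs <- g$cellsize
  if (min(xt) < x0 || max(xt) > x0 + ncs * cs ||
      min(yt) < y0 || max(yt) > y0 + nrs * cs)
    stop("resample_to: reference extent is not covered by the source grid")
  if (method == "nearest") {
    cj <- pmin(pmax(floor((xt - x0) / cs) + 1L, 1L), ncs)
    ri <- pmin(pmax(nrs - floor((yt - y0) / cs), 1L), nrs)
    out <- g$values[ri, cj, drop = FALSE]
  } else {
    # positions in 0-based source cell-center coordinates, south-up rows
    fx <- (xt - x0) / cs - 0.5
    fy <- (yt - y0) / cs - 0.5
    j0 <- pmin(pmax(floor(fx) + 1L, 1L), max(ncs - 1L, 1L))
    i0 <- pmin(pmax(floor(fy) + 1L, 1L), max(nrs - 1L, 1L))
    wx <- pmin(pmax(fx - (j0 - 1L), 0), 1)
    wy <- pmin(pmax(fy - (i0 - 1L), 0), 1)
    j1 <- pmin(j0 + 1L, ncs)
    i1 <- pmin(i0 + 1L, nrs)
    vs <- g$values[nrs:1, , drop = FALSE]             # south-up view
    out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
    for (ii in seq_along(yt)) {                       # target row (north first)
      r0 <- i0[ii]; r1 <- i1[ii]; w2 <- wy[ii]
      out[ii, ] <- (1 - w2) * ((1 - wx) * vs[r0, j0] + wx * vs[r0, j1]) +
                   w2 * ((1 - wx) * vs[r1, j0] + wx * vs[r1, j1])
    }
  }
  land_grid(out, ref$xll, ref$yll, ref$cellsize, ref$crs)
}
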