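#' Laboratory temperature-R0 calibration table
#'
#' The six laboratory endpoints of the parasitoid's net reproductive rate:
#' the suboptimal-low band 10-15 deg C spans R0 0.13-1.55, the optimal band
#' 20-25 deg C spans 15-14, and the suboptimal-high band 30-35 deg C spans
#' 2.18-0.06 daughters/female.
#'
#' @return data.frame with columns `temperature_C` and `r0`, six rows.
#' @export
default_calibration_table <- function() {
  data.frame(temperature_C = c(10, 15, 20, 25, 30, 35),
             r0            = c(0.13, 1.55, 15, 14, 2.18, 0.06))
}

#' Read / write a calibration table as CSV
#'
#' CSV contract: columns `temperature_C` (deg C) and `r0`
#' (daughters/female, non-negative).
#'
#' @param path CSV file path.
#' @return `read_calibration_csv`: validated data.frame.
#' @export
read_calibration_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("temperature_C", "r0") %in% names(tab)))
    stop("calibration CSV must have columns temperature_C and r0")
  tab <- tab[, c("temperature_C", "r0")]
  if (any(!is.finite(tab$temperature_C)) || any(!is.finite(tab$r0)))
    stop("calibration table contains non-finite values")
  if (any(tab$r0 < 0)) stop("observed R0 must be non-negative")
  tab
}

#' @rdname read_calibration_csv
#' @param tab calibration data.frame.
#' @export
write_calibration_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Root mean square error
#' @param pred,obs numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("rmse: length mismatch")
  if (length(pred) < 1L) stop("rmse: need at least one point")
  sqrt(mean((pred - obs)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observations.  Can be negative for fits worse than the mean.
#'
#' @param pred,obs numeric vectors of equal length (>= 2); `obs` must vary.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("r_squared: length mismatch")
  if (length(obs) < 2L) stop("r_squared: need at least two points")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot <= 0) stop("r_squared: observations have zero variance")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Default free-breakpoint specification for calibration
#'
#' Declares which trapezoid breakpoints [fit_rule_base()] may move.
#' Temperature plateaus stay anchored at the laboratory bands; only the
#' connecting shoulders are free, and only where the shoulder lies inside
#' the temperature universe (an edge shoulder outside the universe cannot
#' influence any prediction under the zero out-of-range policy, so freeing
#' it would add unidentifiable parameters).  All four breakpoints of every
#' R0 consequent set are free.
#'
#' @param rb template [rule_base()].
#' @return data.frame with columns `partition` (`"temperature"`/`"r0"`),
#'   `set`, `breakpoint` (`"a"`,`"b"`,`"c"`,`"d"`).
#' @export
default_free_spec <- function(rb) {
  eps <- 1e-9
  rows <- list()
  lo <- rb$temp_partition$universe[1]; hi <- rb$temp_partition$universe[2]
  for (s in rb$temp_partition$sets) {
    if (s$b > lo + eps)
      rows[[length(rows) + 1L]] <- c("temperature", s$name, "a")
    if (s$c < hi - eps)
      rows[[length(rows) + 1L]] <- c("temperature", s$name, "d")
  }
  for (s in rb$r0_partition$sets)
    for (bp in c("a", "b", "c", "d"))
      rows[[length(rows) + 1L]] <- c("r0", s$name, bp)
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("partition", "set", "breakpoint")
  out
}

# -- parameter packing -------------------------------------------------------

free_param_names <- function(free)
  paste(free$partition, free$set, free$breakpoint, sep = ".")

extract_params <- function(rb, free) {
  v <- numeric(nrow(free))
  for (i in seq_len(nrow(free))) {
    p <- if (free$partition[i] == "temperature") rb$temp_partition else rb$r0_partition
    v[i] <- p$sets[[free$set[i]]][[free$breakpoint[i]]]
  }
  stats::setNames(v, free_param_names(free))
}

# Rebuild a rule base with the free breakpoints replaced by `par`.  Returns
# NULL (instead of erroring) when the ordering a <= b <= c <= d is violated,
# so the optimizer can penalize infeasible proposals smoothly.
apply_params <- function(rb, free, par) {
  tp <- rb$temp_partition; rp <- rb$r0_partition
  for (i in seq_len(nrow(free))) {
    if (free$partition[i] == "temperature")
      tp$sets[[free$set[i]]][[free$breakpoint[i]]] <- unname(par[i])
    else
      rp$sets[[free$set[i]]][[free$breakpoint[i]]] <- unname(par[i])
  }
  viol <- 0
  for (p in list(tp, rp)) for (s in p$sets) {
    bp <- c(s$a, s$b, s$c, s$d)
    viol <- viol + sum(pmax(0, -diff(bp)))
  }
  if (viol > 0) return(structure(list(), violation = viol))
  rb$temp_partition <- tp
  rb$r0_partition <- rp
  rb
}

# -- fitting -----------------------------------------------------------------

#' Fit membership breakpoints to laboratory data
#'
#' Constrained least squares over the free breakpoints of a template rule
#' base: minimizes the RMSE between [predict_r0()] at the calibration
#' temperatures and the observed R0 values, subject to `a <= b <= c <= d`
#' ordering within every set and coverage of both universes.  The search is
#' a seeded multi-start Nelder-Mead followed by a deterministic
#' coordinate-descent polish with geometrically shrinking steps (terminal
#' step `1e-7`, the search resolution).  The best objective value is
#' monotone non-increasing over accepted iterates, and the whole procedure
#' is deterministic for a fixed seed.
#'
#' @param points data.frame with `temperature_C`, `r0` (>= 2 rows).
#' @param template [rule_base()] giving shapes and starting breakpoints.
#' @param cfg [inference_config()].
#' @param seed integer seed controlling the multi-start jitter.
#' @param free free-breakpoint spec, see [default_free_spec()].
#' @param n_starts number of Nelder-Mead starts (first = template values).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return object of class `calibration_result`: `rule_base` (fitted),
#'   `rmse`, `r_squared`, `residuals` (pred - obs), `predicted`, `points`,
#'   `par` (fitted free breakpoints), `objective_trace` (best objective
#'   after each accepted stage, monotone non-increasing).
#' @export
fit_rule_base <- function(points, template, cfg = inference_config(),
                          seed = 1L, free = default_free_spec(template),
                          n_starts = 8L, maxit = 2000L) {
  stopifnot(inherits(template, "rule_base"), nrow(points) >= 2L,
            nrow(free) >= 1L)
  if (!all(c("temperature_C", "r0") %in% names(points)))
    stop("points must have columns temperature_C and r0")

  x <- points$temperature_C; obs <- points$r0
  objective <- function(par) {
    rb2 <- apply_params(template, free, par)
    v <- attr(rb2, "violation")
    if (!is.null(v)) return(1e6 + 1e3 * v)
    pen <- 0
    for (p in list(rb2$temp_partition, rb2$r0_partition)) {
      g <- partition_coverage_gap(p, n = 201L, floor = 1e-3)
      pen <- pen + 1e3 * as.numeric(g)
    }
    rmse(as.numeric(predict_r0(rb2, cfg, x)), obs) + pen
  }

  par0 <- extract_params(template, free)
  span <- ifelse(free$partition == "temperature",
                 diff(template$temp_partition$universe),
                 diff(template$r0_partition$universe))
  starts <- with_seed(seed, {
    s <- list(par0)
    for (k in seq_len(max(0L, n_starts - 1L)))
      s[[k + 1L]] <- par0 + stats::runif(length(par0), -0.1, 0.1) * span
    s
  })

  best_par <- par0
  best_val <- objective(par0)
  trace <- best_val
  for (st in starts) {
    # (suppressed warning: optim cautions against 1-D Nelder-Mead, but the
    # coordinate polish below refines any 1-D case to the same resolution)
    fit <- suppressWarnings(
      stats::optim(st, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12)))
    if (fit$value < best_val) {
      best_val <- fit$value
      best_par <- fit$par
    }
    trace <- c(trace, best_val)
  }

  # coordinate polish: deterministic, monotone, terminal step = resolution.
  # Sweeps per step level are capped so total search effort is bounded; a
  # slow crawl along a shallow valley resumes at the next (finer) level.
  step <- 0.25
  while (step >= 1e-7) {
    for (sweep in 1:25) {
      improved <- FALSE
      for (j in seq_along(best_par)) {
        for (d in c(step, -step)) {
          cand <- best_par
          cand[j] <- cand[j] + d
          v <- objective(cand)
          if (v < best_val) {
            best_val <- v
            best_par <- cand
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    trace <- c(trace, best_val)
    step <- step / 2
  }

  fitted_rb <- apply_params(template, free, best_par)
  if (!inherits(fitted_rb, "rule_base"))
    stop("calibration ended on an infeasible breakpoint ordering")
  pred <- as.numeric(predict_r0(fitted_rb, cfg, x))
  structure(list(rule_base = fitted_rb,
                 rmse = rmse(pred, obs),
                 r_squared = r_squared(pred, obs),
                 residuals = pred - obs,
                 predicted = pred,
                 points = points,
                 par = best_par,
                 objective_trace = trace,
                 seed = as.integer(seed)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d points, RMSE = %.4f, R^2 = %.4f\n",
              nrow(x$points), x$rmse, x$r_squared))
  invisible(x)
}

#' Write calibration metrics as JSON
#'
#' @param result a `calibration_result`.
#' @param path output file (conventionally `metrics.json`).
#' @export
write_metrics_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(rmse = result$rmse, r_squared = result$r_squared,
         n_points = nrow(result$points),
         residuals = result$residuals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
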