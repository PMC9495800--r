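#' Single-antecedent fuzzy rule
#'
#' `IF temperature is <antecedent> THEN R0 is <consequent>`, by set name.
#'
#' @param antecedent name of a set in the temperature partition.
#' @param consequent name of a set in the R0 partition.
#' @export
fuzzy_rule <- function(antecedent, consequent) {
  stopifnot(is.character(antecedent), length(antecedent) == 1L,
            is.character(consequent), length(consequent) == 1L)
  structure(list(antecedent = antecedent, consequent = consequent),
            class = "fuzzy_rule")
}

#' Mamdani rule base
#'
#' Binds a temperature partition, an R0 partition and a list of
#' single-antecedent rules whose set names must resolve in their
#' respective partitions.
#'
#' @param temp_partition [fuzzy_partition()] over temperature (deg C).
#' @param r0_partition [fuzzy_partition()] over R0 (daughters/female).
#' @param rules list of [fuzzy_rule()] objects, at least one.
#' @return an object of class `rule_base`.
#' @export
rule_base <- function(temp_partition, r0_partition, rules) {
  stopifnot(inherits(temp_partition, "fuzzy_partition"),
            inherits(r0_partition, "fuzzy_partition"),
            is.list(rules))
  if (length(rules) < 1L) stop("rule base must contain at least one rule")
  ok <- vapply(rules, inherits, logical(1), what = "fuzzy_rule")
  if (!all(ok)) stop("all rules must be fuzzy_rule objects")
  for (r in rules) {
    if (!r$antecedent %in% names(temp_partition$sets))
      stop(sprintf("rule antecedent '%s' not found in temperature partition",
                   r$antecedent))
    if (!r$consequent %in% names(r0_partition$sets))
      stop(sprintf("rule consequent '%s' not found in R0 partition",
                   r$consequent))
  }
  structure(list(temp_partition = temp_partition,
                 r0_partition = r0_partition, rules = rules),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("<rule_base> %d rules\n", length(x$rules)))
  for (r in x$rules)
    cat(sprintf("  IF temperature is %s THEN R0 is %s\n",
                r$antecedent, r$consequent))
  invisible(x)
}

#' Inference configuration
#'
#' @param output_grid number of uniform discretization points over the R0
#'   universe used by aggregation and defuzzification (default 501, min 3).
#' @param defuzz_method `"centroid"` (default) or `"mean_of_maxima"`.
#' @param out_of_range_policy temperature outside the universe: `"zero"`
#'   (no rule fires, default) or `"clamp"` (evaluate at the nearest bound).
#' @export
inference_config <- function(output_grid = 501L,
                             defuzz_method = c("centroid", "mean_of_maxima"),
                             out_of_range_policy = c("zero", "clamp")) {
  output_grid <- as.integer(output_grid)
  if (is.na(output_grid) || output_grid < 3L)
    stop("output_grid must be an integer >= 3")
  structure(list(output_grid = output_grid,
                 defuzz_method = match.arg(defuzz_method),
                 out_of_range_policy = match.arg(out_of_range_policy)),
            class = "inference_config")
}

#' Discretized R0 universe for a rule base
#' @keywords internal
r0_grid_points <- function(rb, cfg) {
  seq(rb$r0_partition$universe[1], rb$r0_partition$universe[2],
      length.out = cfg$output_grid)
}

#' Mamdani max-min inference for one crisp temperature
#'
#' Singleton fuzzification: each rule i fires with strength
#' `w_i = degree of x in its antecedent set`; its output is the consequent
#' set clipped at `w_i` (pointwise min), and the rule outputs are aggregated
#' by pointwise max over the discretized R0 universe.
#'
#' @param rb a [rule_base()].
#' @param cfg an [inference_config()].
#' @param x a single finite temperature in deg C.
#' @return an object of class `fuzzy_aggregate`: list with `y` (grid points),
#'   `mu` (aggregated membership, in `[0,1]`), and `firing` (named strengths
#'   per rule antecedent).
#' @export
infer <- function(rb, cfg = inference_config(), x) {
  stopifnot(inherits(rb, "rule_base"), inherits(cfg, "inference_config"))
  if (length(x) != 1L || !is.finite(x)) stop("infer: x must be a single finite number")
  y <- r0_grid_points(rb, cfg)
  deg <- fuzzify(rb$temp_partition, x, policy = cfg$out_of_range_policy)
  mu <- numeric(length(y))
  w <- numeric(length(rb$rules))
  for (i in seq_along(rb$rules)) {
    r <- rb$rules[[i]]
    w[i] <- deg[[r$antecedent]]
    if (w[i] > 0) {
      cons <- membership_degree(rb$r0_partition$sets[[r$consequent]], y)
      mu <- pmax(mu, pmin(w[i], cons))
    }
  }
  structure(list(y = y, mu = mu,
                 firing = stats::setNames(
                   w, vapply(rb$rules, `[[`, character(1), "antecedent"))),
            class = "fuzzy_aggregate")
}

#' Defuzzify an aggregated output membership
#'
#' Centroid: `sum(y * mu) / sum(mu)` over the discretized universe.
#' Mean-of-maxima: mean of the grid points attaining the maximum membership.
#' An all-zero aggregate (no rule fired) returns 0 with attribute
#' `no_fire = TRUE` rather than an error, so raster application never aborts
#' on extreme pixels.
#'
#' @param agg a `fuzzy_aggregate` from [infer()].
#' @param cfg an [inference_config()] (selects the method).
#' @return crisp R0 (numeric scalar) with logical attribute `no_fire`.
#' @export
defuzzify <- function(agg, cfg = inference_config()) {
  stopifnot(inherits(agg, "fuzzy_aggregate"))
  total <- sum(agg$mu)
  if (total <= 0)
    return(structure(0, no_fire = TRUE))
  v <- if (cfg$defuzz_method == "centroid") {
    sum(agg$y * agg$mu) / total
  } else {
    mx <- max(agg$mu)
    mean(agg$y[agg$mu >= mx - 1e-15])
  }
  structure(v, no_fire = FALSE)
}

#' Predict crisp R0 for crisp temperatures
#'
#' The full inference chain (fuzzify, fire rules by min, aggregate by max,
#' defuzzify), vectorized over temperature.  Deterministic.
#'
#' @param rb a [rule_base()].
#' @param cfg an [inference_config()].
#' @param x numeric vector of temperatures (deg C); must be finite.
#' @return numeric vector of crisp R0 values (daughters/female) with a
#'   logical attribute `no_fire` marking inputs for which no rule fired
#'   (those return 0).
#' @export
predict_r0 <- function(rb, cfg = inference_config(), x) {
  stopifnot(inherits(rb, "rule_base"), inherits(cfg, "inference_config"))
  if (any(!is.finite(x))) stop("predict_r0: temperatures must be finite")
  n <- length(x)
  y <- r0_grid_points(rb, cfg)
  g <- length(y)
  lo <- rb$temp_partition$universe[1]; hi <- rb$temp_partition$universe[2]
  xe <- x
  if (cfg$out_of_range_policy == "clamp") {
    xe <- pmin(pmax(x, lo), hi)
    in_univ <- rep(TRUE, n)
  } else {
    in_univ <- x >= lo & x <= hi
  }
  # consequent curves sampled once; firing strengths per pixel per rule
  num <- numeric(n); den <- numeric(n)
  mu_max <- NULL
  for (i in seq_along(rb$rules)) {
    r <- rb$rules[[i]]
    w <- membership_degree(rb$temp_partition$sets[[r$antecedent]], xe)
    w[!in_univ] <- 0
    cons <- membership_degree(rb$r0_partition$sets[[r$consequent]], y)
    clip <- outer(w, cons, pmin)              # n x g, rule output
    mu_max <- if (is.null(mu_max)) clip else pmax(mu_max, clip)
  }
  den <- rowSums(mu_max)
  no_fire <- den <= 0
  out <- numeric(n)
  if (cfg$defuzz_method == "centroid") {
    num <- as.vector(mu_max %*% y)
    out[!no_fire] <- num[!no_fire] / den[!no_fire]
  } else {
    for (p in which(!no_fire)) {
      mx <- max(mu_max[p, ])
      out[p] <- mean(y[mu_max[p, ] >= mx - 1e-15])
    }
  }
  structure(out, no_fire = no_fire)
}

#' Default three-rule template for the parasitoid R0 response
#'
#' Encodes the laboratory-derived linguistic rules: a suboptimal-low
#' temperature band (plateau 10-15 deg C) mapping to low R0, an optimal band
#' (plateau 20-25 deg C) mapping to high R0 (the lab optimum of 14-15
#' daughters/female), and a suboptimal-high band (plateau 30-35 deg C)
#' mapping to very low R0.  Temperature universe `[10, 35]` deg C (the range
#' of the laboratory trials), R0 universe `[0, 20]`.  Shoulder breakpoints
#' are starting values intended to be refined by [fit_rule_base()].
#'
#' @return a [rule_base()].
#' @export
default_rule_base <- function() {
  temp <- fuzzy_partition(
    universe = c(10, 35), units = "degC",
    sets = list(
      trapezoid_mf("suboptimal_low",  5,   10, 15, 19),
      trapezoid_mf("optimal",         16,  20, 25, 29),
      trapezoid_mf("suboptimal_high", 26,  30, 35, 40)))
  r0 <- fuzzy_partition(
    universe = c(0, 20), units = "R0",
    sets = list(
      trapezoid_mf("very_low", -1,  0,   1.2, 9),
      trapezoid_mf("low",      -0.5, 0.6, 2.2, 10),
      trapezoid_mf("high",      7,  13.5, 15.5, 21)))
  rule_base(temp, r0, list(
    fuzzy_rule("suboptimal_low",  "low"),
    fuzzy_rule("optimal",         "high"),
    fuzzy_rule("suboptimal_high", "very_low")))
}
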