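# Shared fixtures and independent oracles, built in code.

# literal double-loop brute force of max-min inference over the output grid:
# independent of the vectorized implementation in the package
brute_force_infer <- function(rb, cfg, x) {
  y <- seq(rb$r0_partition$universe[1], rb$r0_partition$universe[2],
           length.out = cfg$output_grid)
  deg <- fuzzify(rb$temp_partition, x, policy = cfg$out_of_range_policy)
  mu <- numeric(length(y))
  for (j in seq_along(y)) {
    best <- 0
    for (r in rb$rules) {
      w <- deg[[r$antecedent]]
      nj <- membership_degree(rb$r0_partition$sets[[r$consequent]], y[j])
      v <- min(w, nj)
      if (v > best) best <- v
    }
    mu[j] <- best
  }
  list(y = y, mu = mu)
}

# random rule base over arbitrary universes (coverage not enforced: these
# exercise the inference arithmetic, not the modelling defaults)
random_rule_base <- function(n_rules = sample(1:4, 1)) {
  rand_partition <- function(lo, hi, n, prefix) {
    sets <- lapply(seq_len(n), function(i) {
      bp <- sort(stats::runif(4, lo - 2, hi + 2))
      trapezoid_mf(paste0(prefix, i), bp[1], bp[2], bp[3], bp[4])
    })
    fuzzy_partition(c(lo, hi), sets, check_coverage = FALSE)
  }
  tp <- rand_partition(0, 40, n_rules, "t")
  rp <- rand_partition(0, 20, n_rules, "r")
  rules <- lapply(seq_len(n_rules), function(i)
    fuzzy_rule(paste0("t", i), paste0("r", i)))
  rule_base(tp, rp, rules)
}

# small grid helper
mk_grid <- function(values, ...) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  land_grid(values, ...)
}

# a tiny single-region cold landscape (all temperatures below the optimal
# plateau's lower shoulder) for scenario monotonicity checks
cold_landscape <- function(nrow = 20, ncol = 20, seed = 11) {
  temps <- matrix(seq(12, 15.5, length.out = 12), nrow = 1,
                  dimnames = list("Cold", sprintf("%02d", 1:12)))
  spec <- landscape_spec(nrow = nrow, ncol = ncol, region_temps = temps,
                         fractions = 1, temp_noise_sd = 0.2,
                         cropland_fraction = 1, suit_midpoint = 5,
                         suit_noise_sd = 0)
  generate_landscape(spec, seed = seed)
}

# one calibrated rule base shared across test files (fitting is the costly
# step; cache it for the session)
calibrated_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fit_rule_base(default_calibration_table(),
                              default_rule_base(), inference_config(),
                              seed = 1)
    cache
  }
})
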