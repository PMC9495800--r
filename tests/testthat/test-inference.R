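cfg <- inference_config()

test_that("a fully fired rule passes its consequent curve through unclipped", {
  rb <- default_rule_base()
  agg <- infer(rb, cfg, 22)                  # optimal plateau, w = 1
  cons <- membership_degree(rb$r0_partition$sets$high, agg$y)
  expect_equal(agg$mu, cons)
  expect_equal(unname(agg$firing["optimal"]), 1)
})

test_that("no rule firing yields a zero aggregate and a flagged zero R0", {
  rb <- default_rule_base()
  agg <- infer(rb, cfg, 5)                   # outside universe, zero policy
  expect_true(all(agg$mu == 0))
  out <- defuzzify(agg, cfg)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "no_fire"))
  v <- predict_r0(rb, cfg, c(5, 22))
  expect_equal(attr(v, "no_fire"), c(TRUE, FALSE))
  expect_equal(as.numeric(v[1]), 0)
})

test_that("infer matches a brute-force double loop on random rule bases", {
  set.seed(1)
  worst <- 0
  for (i in 1:1000) {
    rb <- random_rule_base()
    g <- sample(3:51, 1)
    ccfg <- inference_config(output_grid = g)
    x <- runif(1, -5, 45)
    got <- infer(rb, ccfg, x)
    want <- brute_force_infer(rb, ccfg, x)
    expect_equal(got$y, want$y)
    worst <- max(worst, max(abs(got$mu - want$mu)))
    expect_true(all(got$mu >= 0 & got$mu <= 1))
  }
  expect_lt(worst, 1e-12)
})

test_that("centroid of a symmetric clipped trapezoid sits on its axis", {
  tp <- fuzzy_partition(c(0, 30), list(trapezoid_mf("t", -1, 0, 30, 31)),
                        check_coverage = FALSE)
  rp <- fuzzy_partition(c(0, 20), list(trapezoid_mf("sym", 4, 8, 12, 16)),
                        check_coverage = FALSE)
  rb <- rule_base(tp, rp, list(fuzzy_rule("t", "sym")))
  # grid symmetric about y = 10 so the discretized centroid is exact
  v <- predict_r0(rb, inference_config(output_grid = 501), 15)
  expect_equal(as.numeric(v), 10)
})

test_that("a two-rule aggregate on a coarse grid matches the hand-computed mean", {
  tp <- fuzzy_partition(c(0, 10), list(trapezoid_mf("a", -1, 0, 4, 6),
                                       trapezoid_mf("b", 4, 6, 10, 11)))
  rp <- fuzzy_partition(c(0, 4), list(trapezoid_mf("lo", -1, 0, 1, 3),
                                      trapezoid_mf("hi", 1, 3, 4, 5)))
  rb <- rule_base(tp, rp, list(fuzzy_rule("a", "lo"), fuzzy_rule("b", "hi")))
  ccfg <- inference_config(output_grid = 5)    # y = 0, 1, 2, 3, 4
  x <- 5                                       # w_a = 0.5, w_b = 0.5
  # mu(y) = max(min(.5, lo(y)), min(.5, hi(y)))
  #  lo: 1, 1, .5, 0, 0 -> clipped .5, .5, .5, 0, 0
  #  hi: 0, 0, .5, 1, 1 -> clipped 0, 0, .5, .5, .5
  mu <- c(.5, .5, .5, .5, .5)
  expect_equal(infer(rb, ccfg, x)$mu, mu)
  expect_equal(as.numeric(predict_r0(rb, ccfg, x)),
               sum(c(0, 1, 2, 3, 4) * mu) / sum(mu))
})

test_that("defuzzified output lies within the support of fired consequents", {
  set.seed(7)
  for (i in 1:200) {
    rb <- random_rule_base()
    x <- runif(1, 0, 40)
    agg <- infer(rb, cfg, x)
    v <- defuzzify(agg, cfg)
    if (attr(v, "no_fire")) next
    fired <- agg$firing > 0
    supports <- vapply(rb$rules[fired], function(r) {
      s <- rb$r0_partition$sets[[r$consequent]]
      c(s$a, s$d)
    }, numeric(2))
    expect_gte(as.numeric(v), min(supports[1, ]))
    expect_lte(as.numeric(v), max(supports[2, ]))
  }
})

test_that("prediction is invariant to rule order", {
  set.seed(9)
  for (i in 1:50) {
    rb <- random_rule_base(n_rules = 3)
    perm <- rb
    perm$rules <- rev(rb$rules)
    x <- runif(5, 0, 40)
    expect_equal(as.numeric(predict_r0(rb, cfg, x)),
                 as.numeric(predict_r0(perm, cfg, x)))
  }
})

test_that("R0 is constant where the optimal plateau fires alone", {
  # template shoulders stop short of the optimal plateau: sole-rule firing
  rb <- default_rule_base()
  plateau <- rb$temp_partition$sets$optimal
  xs <- seq(plateau$b, plateau$c, length.out = 21)
  v <- as.numeric(predict_r0(rb, cfg, xs))
  expect_equal(v, rep(v[1], length(v)))
  # calibrated system: constant over the sub-interval where the other
  # antecedents have zero degree (calibration may overlap shoulders into
  # the plateau to separate the two optimal-band observations)
  fitted <- calibrated_result()$rule_base
  xs <- seq(fitted$temp_partition$sets$optimal$b,
            fitted$temp_partition$sets$optimal$c, length.out = 41)
  sole <- vapply(xs, function(x) {
    d <- fuzzify(fitted$temp_partition, x)
    d[["optimal"]] == 1 && sum(d > 0) == 1
  }, logical(1))
  v <- as.numeric(predict_r0(fitted, cfg, xs[sole]))
  expect_gt(length(v), 1)
  expect_equal(v, rep(v[1], length(v)))
})

test_that("the temperature sweep is unimodal: rising then falling", {
  rb <- calibrated_result()$rule_base
  xs <- seq(10, 35, by = 0.25)
  v <- as.numeric(predict_r0(rb, cfg, xs))
  peak <- which.max(v)
  expect_true(all(diff(v[1:peak]) >= -1e-9))
  expect_true(all(diff(v[peak:length(v)]) <= 1e-9))
  expect_gt(max(v), 10)                      # optimum reaches the high band
  expect_lt(v[1], 3)                         # cold end near the lab values
})

test_that("mean-of-maxima defuzzification picks the plateau of the maximum", {
  tp <- fuzzy_partition(c(0, 10), list(trapezoid_mf("t", -1, 0, 10, 11)))
  rp <- fuzzy_partition(c(0, 20), list(trapezoid_mf("s", -1, 8, 12, 21)))
  rb <- rule_base(tp, rp, list(fuzzy_rule("t", "s")))
  mcfg <- inference_config(output_grid = 501,
                           defuzz_method = "mean_of_maxima")
  expect_equal(as.numeric(predict_r0(rb, mcfg, 5)), 10)
})

test_that("rule-base YAML serialization round-trips losslessly", {
  rb <- calibrated_result()$rule_base
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_base(rb, path)
  rb2 <- read_rule_base(path)
  expect_equal(rb2, rb)
  xs <- seq(10, 35, by = 0.5)
  expect_identical(as.numeric(predict_r0(rb2, cfg, xs)),
                   as.numeric(predict_r0(rb, cfg, xs)))
})

test_that("invalid rule bases and configs are rejected", {
  rb <- default_rule_base()
  expect_error(rule_base(rb$temp_partition, rb$r0_partition, list()),
               "at least one rule")
  expect_error(rule_base(rb$temp_partition, rb$r0_partition,
                         list(fuzzy_rule("nope", "high"))),
               "not found")
  expect_error(inference_config(output_grid = 2), ">= 3")
})
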