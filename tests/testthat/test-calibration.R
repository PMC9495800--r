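cfg <- inference_config()

test_that("the laboratory calibration table carries the six published pairs", {
  tab <- default_calibration_table()
  expect_equal(nrow(tab), 6)
  expect_equal(tab$temperature_C, c(10, 15, 20, 25, 30, 35))
  expect_equal(tab$r0, c(0.13, 1.55, 15, 14, 2.18, 0.06))
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(tab, path)
  expect_equal(read_calibration_csv(path), tab)
})

test_that("rmse follows its closed form", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, -4), c(0, 0)), sqrt(12.5))   # mean(9 + 16) = 12.5
  obs <- runif(10)
  expect_equal(rmse(obs + 0.3, obs), 0.3)             # constant offset
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("r_squared follows 1 - SS_res/SS_tot about the observed mean", {
  obs <- c(1, 2, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 3), obs), 0)
  # hand computation: SS_res = .25 + 0 + .25, SS_tot = 42/9
  expect_equal(r_squared(c(1.5, 2, 3.5), obs), 1 - 0.5 / (42 / 9))
  expect_error(r_squared(c(1, 2), c(3, 3)), "variance")
  expect_error(r_squared(1:3, 1:2), "length")
})

test_that("a single free breakpoint matches a 1-D grid-search oracle", {
  template <- default_rule_base()
  free <- data.frame(partition = "temperature", set = "optimal",
                     breakpoint = "a")
  # two observations on the optimal rising shoulder pin the shoulder start
  truth <- template
  truth$temp_partition$sets$optimal$a <- 17.3
  pts <- data.frame(temperature_C = c(18, 19),
                    r0 = as.numeric(predict_r0(truth, cfg, c(18, 19))))
  obj <- function(a) {
    rb <- template
    rb$temp_partition$sets$optimal$a <- a
    rmse(as.numeric(predict_r0(rb, cfg, pts$temperature_C)), pts$r0)
  }
  grid_a <- seq(15.2, 19.8, by = 0.001)
  grid_rmse <- vapply(grid_a, obj, numeric(1))
  oracle_a <- grid_a[which.min(grid_rmse)]
  fit <- fit_rule_base(pts, template, cfg, seed = 3, free = free,
                       n_starts = 3, maxit = 500)
  expect_lte(fit$rmse, min(grid_rmse) + 1e-9)
  expect_lt(abs(fit$par[[1]] - oracle_a), 0.001)      # grid resolution
})

test_that("data from a known rule base is recovered to numerical precision", {
  truth <- default_rule_base()
  truth$temp_partition$sets$suboptimal_low$d <- 18.5
  truth$temp_partition$sets$optimal$a <- 16.8
  truth$temp_partition$sets$optimal$d <- 28.2
  truth$temp_partition$sets$suboptimal_high$a <- 27.1
  x <- seq(10, 35, by = 0.5)
  pts <- data.frame(temperature_C = x,
                    r0 = as.numeric(predict_r0(truth, cfg, x)))
  free <- default_free_spec(truth)
  free <- free[free$partition == "temperature", ]
  template <- default_rule_base()               # perturbed start
  fit <- fit_rule_base(pts, template, cfg, seed = 7, free = free,
                       n_starts = 4, maxit = 1500)
  expect_lt(fit$rmse, 1e-6)
  true_par <- c(18.5, 16.8, 28.2, 27.1)
  expect_lt(max(abs(fit$par - true_par)), 1e-6)
})

test_that("the fit is seed-deterministic with a monotone objective trace", {
  pts <- default_calibration_table()
  free <- data.frame(partition = c("temperature", "temperature"),
                     set = c("optimal", "optimal"),
                     breakpoint = c("a", "d"))
  f1 <- fit_rule_base(pts, default_rule_base(), cfg, seed = 5, free = free,
                      n_starts = 3, maxit = 300)
  f2 <- fit_rule_base(pts, default_rule_base(), cfg, seed = 5, free = free,
                      n_starts = 3, maxit = 300)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$rmse, f2$rmse)
  expect_true(all(diff(f1$objective_trace) <= 1e-12))
})

test_that("fitted breakpoints honour ordering and universe coverage", {
  res <- calibrated_result()
  rb <- res$rule_base
  for (p in list(rb$temp_partition, rb$r0_partition)) {
    for (s in p$sets)
      expect_false(is.unsorted(c(s$a, s$b, s$c, s$d)))
    expect_identical(
      attr(parafuzz:::partition_coverage_gap(p), "n_uncovered"), 0L)
  }
})

test_that("calibration on the laboratory table reaches the reported accuracy", {
  res <- calibrated_result()
  expect_lte(res$rmse, 0.90)
  expect_gte(res$r_squared, 0.98)
  # metrics report round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(res, path)
  m <- jsonlite::read_json(path)
  expect_equal(m$rmse, res$rmse)
  expect_equal(m$n_points, 6L)
})
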