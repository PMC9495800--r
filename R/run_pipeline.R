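pipeline_config_defaults <- function() {
  list(input_dir = NULL,         # read inputs here; NULL = simulate them
       rules = NULL,             # rules.yaml; NULL = calibrate from table
       calibration_csv = NULL,   # NULL = built-in laboratory table
       threshold = 0.2,
       cropland_codes = 2L,
       delta_t = 2,
       class_labels = c("very-poor", "poor", "good", "optimal"),
       class_bounds = c(0, 1, 5, 10),
       output_grid = 501L,
       defuzz_method = "centroid",
       out_of_range_policy = "zero",
       seed = 1L,
       nrow = 200L, ncol = 200L,  # synthetic landscape size when simulating
       write_maps = TRUE,
       out_dir = NULL)
}

#' Validate a pipeline run configuration
#'
#' Fills defaults and rejects unknown keys before any stage runs.
#'
#' @param config named list of overrides, or a path to a YAML file of them.
#' @return validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (length(cfg$class_labels) != length(cfg$class_bounds))
    stop("class_labels and class_bounds must have equal length")
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the full performance-mapping pipeline
#'
#' Calibrates (or loads) the fuzzy rule base, builds the host-presence
#' mask, predicts per-pixel monthly R0 under the current climate and a
#' uniformly shifted future climate, classifies the maps, and tallies
#' per-region per-month class pixel counts.  Deterministic end to end for
#' fixed inputs and seed.  Writes, under `out_dir`: the (possibly
#' simulated) inputs, fitted `rules.yaml` and `metrics.json`, monthly R0
#' and class ASCII grids per scenario (`write_maps = TRUE`), summary CSVs
#' `summary_current.csv` / `summary_future.csv`, and `provenance.json`
#' (config echo, input hashes, seed, package version).
#'
#' @param config see [pipeline_config()].
#' @return invisible list with `calibration`, `mask`, `maps` (per scenario:
#'   `r0` and `class` grids per month), `summaries` (per scenario
#'   data.frame), `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_stage("config", pipeline_config(config))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- run_stage("inputs", {
    if (is.null(cfg$input_dir)) {
      ls <- generate_landscape(
        landscape_spec(nrow = cfg$nrow, ncol = cfg$ncol), seed = cfg$seed)
      input_dir <- file.path(cfg$out_dir, "inputs")
      write_landscape(ls, input_dir)
      ls$input_dir <- input_dir
      ls
    } else {
      ls <- read_landscape(cfg$input_dir)
      ls$input_dir <- cfg$input_dir
      ls
    }
  })

  icfg <- run_stage("config", inference_config(
    output_grid = cfg$output_grid, defuzz_method = cfg$defuzz_method,
    out_of_range_policy = cfg$out_of_range_policy))

  calib <- run_stage("calibrate", {
    if (!is.null(cfg$rules)) {
      list(rule_base = read_rule_base(cfg$rules), result = NULL)
    } else {
      tab <- if (is.null(cfg$calibration_csv)) default_calibration_table()
             else read_calibration_csv(cfg$calibration_csv)
      res <- fit_rule_base(tab, default_rule_base(), icfg, seed = cfg$seed)
      write_rule_base(res$rule_base, file.path(cfg$out_dir, "rules.yaml"))
      write_metrics_json(res, file.path(cfg$out_dir, "metrics.json"))
      list(rule_base = res$rule_base, result = res)
    }
  })
  rb <- calib$rule_base

  mask <- run_stage("mask", presence_mask(
    inputs$suitability, inputs$lulc, threshold = cfg$threshold,
    cropland_codes = cfg$cropland_codes))

  scheme <- run_stage("config", class_scheme(cfg$class_labels,
                                             cfg$class_bounds))
  scenarios <- list(current = scenario_config("current"),
                    future = scenario_config("future", cfg$delta_t))

  maps <- list(); summaries <- list()
  for (sn in names(scenarios)) {
    stack <- run_stage("scenario",
                       apply_scenario(inputs$temperature, scenarios[[sn]]))
    r0_maps <- list(); class_maps <- list()
    for (m in names(stack)) {
      r0_maps[[m]] <- run_stage("predict",
                                predict_month(rb, icfg, stack[[m]], mask))
      class_maps[[m]] <- run_stage("classify",
                                   classify_r0(r0_maps[[m]], scheme))
    }
    summaries[[sn]] <- run_stage("summarize", pixel_counts(
      class_maps, inputs$regions, region_names = inputs$region_names,
      scheme = scheme))
    utils::write.csv(summaries[[sn]],
                     file.path(cfg$out_dir, sprintf("summary_%s.csv", sn)),
                     row.names = FALSE)
    if (isTRUE(cfg$write_maps)) {
      sdir <- file.path(cfg$out_dir, sn)
      dir.create(sdir, showWarnings = FALSE)
      for (m in names(stack)) {
        write_ascii_grid(r0_maps[[m]],
                         file.path(sdir, sprintf("r0_%s.asc", m)))
        write_ascii_grid(class_maps[[m]],
                         file.path(sdir, sprintf("class_%s.asc", m)))
      }
    }
    maps[[sn]] <- list(r0 = r0_maps, class = class_maps)
  }

  provenance <- run_stage("provenance", {
    in_files <- list.files(inputs$input_dir, full.names = TRUE)
    prov <- list(
      package = "parafuzz",
      version = as.character(utils::packageVersion("parafuzz")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "out_dir")],
      input_hashes = as.list(file_hashes(in_files)))
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    prov
  })

  invisible(list(calibration = calib$result, rule_base = rb, mask = mask,
                 maps = maps, summaries = summaries, provenance = provenance,
                 out_dir = cfg$out_dir))
}
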