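#' Run manifest for a report directory
#'
#' Records the scenario, seed, package version, timestamp, active engine
#' toggles, and an md5 digest of every emitted file, so identical config +
#' seed reruns can be certified byte-identical for deterministic outputs.
#'
#' @param scenario Scenario identifier.
#' @param seed Seed used (NA for deterministic runs).
#' @param files Paths of the emitted artifacts.
#' @param toggles Active toggle values (the auditable assumption trail).
#' @return List ready for JSON serialisation.
#' @export
run_manifest <- function(scenario, seed, files, toggles) {
  digests <- as.list(tools::md5sum(files))
  names(digests) <- basename(files)
  list(scenario = scenario, seed = seed,
       package_version = as.character(utils::packageVersion("tirocea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       toggles = toggles, artifacts = digests)
}

#' Write the base-case report
#'
#' Runs the base case for a scenario and writes the two-arm summary (CSV and
#' JSON), the full cohort trace per arm (CSV), and a manifest.
#'
#' @param scenario Scenario name or config-file path (see [load_scenario()]).
#' @param output_dir Destination directory (created if absent).
#' @return The [run_manifest()] list, invisibly.
#' @export
write_basecase_report <- function(scenario, output_dir) {
  cfg <- if (inherits(scenario, "scenario_config")) scenario else load_scenario(scenario)
  label <- if (is.character(scenario)) basename(scenario) else cfg$country
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_scenario(cfg)
  files <- character(0)

  f <- file.path(output_dir, "basecase_summary.csv")
  utils::write.csv(cea_table(res), f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(output_dir, "basecase_summary.json")
  jsonlite::write_json(
    list(country = cfg$country, currency = cfg$currency, wtp = cfg$wtp,
         arms = res$arms, incr_cost = res$incr_cost, incr_qaly = res$incr_qaly,
         icer = res$icer$ratio, icer_flag = res$icer$flag,
         quadrant = res$icer$quadrant, cost_effective = res$cost_effective),
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)

  for (arm in c("tirofiban", "aspirin")) {
    ac <- acute_phase(cfg, arm)
    trace <- run_cohort(ac$mrs_month3, cfg)
    f <- file.path(output_dir, sprintf("trace_%s.csv", arm))
    write_trace_csv(trace, f)
    files <- c(files, f)
  }

  manifest <- run_manifest(label, NA, files, cfg$toggles)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a sensitivity-analysis report
#'
#' Emits, per mode: `oneway` the full tornado table; `psa` the draws table
#' plus a JSON summary (quadrant fractions, acceptability at WTP 0 and at the
#' national threshold, top-5 tornado parameters omitted here); `ceac` the
#' acceptability curve over a WTP grid; `subgroup` a base-case rerun under a
#' substituted life table.
#'
#' @param scenario Scenario name or config-file path.
#' @param mode One of `"oneway"`, `"psa"`, `"ceac"`, `"subgroup"`.
#' @param output_dir Destination directory.
#' @param n_iterations,seed PSA settings.
#' @param wtp_grid WTP grid for the CEAC.
#' @param life_table_override,start_age_override Subgroup settings.
#' @return The [run_manifest()] list, invisibly.
#' @export
write_sensitivity_report <- function(scenario, mode = c("oneway", "psa", "ceac", "subgroup"),
                                     output_dir, n_iterations = 10000, seed = 1,
                                     wtp_grid = seq(0, 2e5, by = 5000),
                                     life_table_override = NULL,
                                     start_age_override = NULL) {
  mode <- match.arg(mode)
  cfg <- if (inherits(scenario, "scenario_config")) scenario else load_scenario(scenario)
  label <- if (is.character(scenario)) basename(scenario) else cfg$country
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  if (mode == "oneway") {
    f <- file.path(output_dir, "oneway_tornado.csv")
    utils::write.csv(tornado(cfg), f, row.names = FALSE)
    files <- c(files, f)
  } else if (mode %in% c("psa", "ceac")) {
    psa <- run_psa(cfg, n_iterations = n_iterations, seed = seed)
    if (mode == "psa") {
      f <- file.path(output_dir, "psa_draws.csv")
      utils::write.csv(psa$samples, f, row.names = FALSE)
      files <- c(files, f)
      quad <- psa_quadrants(psa)
      f <- file.path(output_dir, "psa_summary.json")
      jsonlite::write_json(
        list(country = cfg$country, n = psa$n, seed = seed,
             quadrant_fractions = as.list(quad),
             acceptability_wtp0 = mean(psa$samples$incr_cost < 0),
             acceptability_national_wtp =
               mean(psa$samples$incr_qaly * cfg$wtp - psa$samples$incr_cost > 0)),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, f)
    } else {
      f <- file.path(output_dir, "ceac.csv")
      utils::write.csv(ceac(psa, wtp_grid), f, row.names = FALSE)
      files <- c(files, f)
    }
  } else {
    res <- subgroup_run(cfg, life_table_override, start_age_override)
    f <- file.path(output_dir, "subgroup_summary.csv")
    utils::write.csv(cea_table(res), f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- run_manifest(label, seed, files, cfg$toggles)
  jsonlite::write_json(manifest, file.path(output_dir, sprintf("manifest_%s.json", mode)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
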