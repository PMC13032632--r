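# Single entry point: run the base case, the sensitivity suites and the
# scenario analyses from a configuration, write tabular outputs, and log
# provenance (config digest, seed, package version).

usd <- function(tzs, cfg) tzs / cfg$econ$exchange_rate

#' Run the full analysis suite and write all outputs
#'
#' Runs the base-case comparison, per-arm cost-category and DALY
#' decompositions, the one-way (tornado) analysis, the probabilistic
#' sensitivity analysis with cost-effectiveness plane and acceptability
#' curve, the stage-shift sweep, and the number-needed-to-test and
#' availability scenario tables. Writes one CSV per table plus a JSON
#' summary, a JSON export of the resolved configuration, and a run
#' manifest with the config digest and seed.
#'
#' @param config a `bl_config`, or a path to a YAML config file, or `NULL`
#'   for the packaged base case.
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed for the probabilistic analysis.
#' @param psa_iterations number of PSA iterations.
#' @return Invisibly, the run manifest (list with `config_digest`, `seed`,
#'   `timestamp`, `package_version`, `outputs`); also written as
#'   `manifest.json`.
#' @export
run_all <- function(config = NULL, out_dir, seed = NULL,
                    psa_iterations = NULL) {
  cfg <- if (is.null(config)) bl_default_config()
         else if (is.character(config)) read_bl_config(config)
         else config
  stop_if_invalid(cfg)
  if (!is.null(seed)) cfg$econ$psa_seed <- seed
  if (!is.null(psa_iterations)) cfg$econ$psa_iterations <- psa_iterations
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)

  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # resolved configuration (provenance)
  cfg_json <- file.path(out_dir, "config_resolved.json")
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  outputs <- c(outputs, cfg_json)

  # base case
  base <- evaluate_cea(cfg)
  arm_tbl <- data.frame(
    arm = c("liquid", "pathology"),
    cost_tzs = c(base$comparator$cost_tzs, base$reference$cost_tzs),
    cost_usd = usd(c(base$comparator$cost_tzs, base$reference$cost_tzs), cfg),
    dalys = c(base$comparator$dalys, base$reference$dalys)
  )
  emit(arm_tbl, "arm_results.csv")

  comp <- rbind(liquid = base$comparator$cost_components,
                pathology = base$reference$cost_components)
  cost_tbl <- data.frame(category = colnames(comp),
                         liquid_tzs = comp["liquid", ],
                         pathology_tzs = comp["pathology", ],
                         liquid_usd = usd(comp["liquid", ], cfg),
                         pathology_usd = usd(comp["pathology", ], cfg))
  emit(cost_tbl, "cost_breakdown.csv")

  dcomp <- rbind(liquid = base$comparator$daly_components,
                 pathology = base$reference$daly_components)
  emit(data.frame(component = colnames(dcomp),
                  liquid = dcomp["liquid", ], pathology = dcomp["pathology", ]),
       "daly_breakdown.csv")

  # one-way sensitivity
  tor <- one_way_sa(cfg)
  emit(as.data.frame(tor), "tornado.csv")

  # probabilistic sensitivity
  psa <- run_psa(cfg)
  emit(psa$draws, "ce_plane.csv")
  cc <- ceac(psa)
  emit(as.data.frame(cc), "ceac.csv")

  # scenario suites
  emit(stage_shift_sweep(cfg), "stage_shift.csv")
  nnt_tbl <- do.call(rbind, lapply(2:6, function(k) {
    r <- run_scenario(cfg, "nnt", k)
    data.frame(nnt = k, cost_liquid_tzs = r$comparator$cost_tzs,
               dalys_liquid = r$comparator$dalys,
               icer_tzs = r$icer_tzs, icer_usd = r$icer_usd)
  }))
  emit(nnt_tbl, "scenario_nnt.csv")
  av_tbl <- do.call(rbind, lapply(seq(0.2, 1.0, by = 0.2), function(a) {
    r <- run_scenario(cfg, "availability", a)
    data.frame(availability = a, cost_combined_tzs = r$comparator$cost_tzs,
               dalys_combined = r$comparator$dalys,
               icer_tzs = r$icer_tzs, icer_usd = r$icer_usd)
  }))
  emit(av_tbl, "scenario_availability.csv")

  summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    base_case = list(
      cost_liquid_tzs = base$comparator$cost_tzs,
      cost_pathology_tzs = base$reference$cost_tzs,
      dalys_liquid = base$comparator$dalys,
      dalys_pathology = base$reference$dalys,
      delta_cost_usd = base$delta_cost_usd,
      delta_dalys_averted = base$delta_dalys_averted,
      icer_usd = base$icer_usd
    ),
    psa = list(iterations = psa$iterations, seed = psa$seed,
               ci_delta_cost_usd = psa$ci$delta_cost_usd,
               ci_delta_dalys = psa$ci$delta_dalys_averted,
               ceac_crossing_usd = ceac_crossing(cc))
  ), summary_json, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, summary_json)

  manifest <- list(
    config_digest = unname(tools::md5sum(cfg_json)),
    seed = cfg$econ$psa_seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("blcea")),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stopifnot(all(file.exists(outputs)))
  invisible(manifest)
}
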