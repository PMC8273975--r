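#' Render a simulation summary as a compact table
#'
#' One row per parameter, one column per design/method, each cell
#' formatted `"mean (SE) coverage%"` with two decimals for mean and SE
#' and one for the coverage percentage. Rounding is round-half-to-even.
#' Missing cells render as an em dash.
#'
#' @param summary A `sim_summary`.
#' @return A character matrix (parameters x design/method columns).
#' @export
render_summary_table <- function(summary) {
  stopifnot(inherits(summary, "sim_summary") || is.data.frame(summary))
  cols <- unique(paste(summary$design, summary$method, sep = "/"))
  pars <- unique(summary$parameter)
  out <- matrix("—", length(pars), length(cols),
                dimnames = list(pars, cols))
  for (i in seq_len(nrow(summary))) {
    row <- summary[i, ]
    out[row$parameter, paste(row$design, row$method, sep = "/")] <-
      format_cell(row$mean_estimate, row$empirical_se, row$coverage)
  }
  out
}

#' Format one summary cell
#'
#' `"mean (SE) coverage%"` using round-half-to-even at 2 decimals for
#' mean and SE and 1 decimal for coverage in percent; any missing piece
#' makes the cell an em dash.
#'
#' @param mean_estimate,empirical_se,coverage Cell values (coverage as a
#'   fraction in `[0, 1]`).
#' @return A single string.
#' @examples
#' format_cell(-0.75, 0.01, 0.947)  # "-0.75 (0.01)94.7"
#' @export
format_cell <- function(mean_estimate, empirical_se, coverage) {
  if (anyNA(c(mean_estimate, empirical_se, coverage))) return("—")
  paste0(formatC(round(mean_estimate, 2), format = "f", digits = 2),
         " (", formatC(round(empirical_se, 2), format = "f", digits = 2), ")",
         formatC(round(100 * coverage, 1), format = "f", digits = 1))
}

# floats at 6 significant digits in every CSV the harness writes
sig6 <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Write / read harness CSV outputs
#'
#' Long per-replicate estimates, summaries, and sweep tables are written
#' as plain CSV with floats at 6 significant digits; the readers restore
#' the classes so outputs round-trip.
#'
#' @param x The table to write.
#' @param path CSV path.
#' @return The path (writers, invisibly) or the table (readers).
#' @export
write_estimates_csv <- function(x, path) {
  utils::write.csv(sig6(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
write_summary_csv <- function(x, path) {
  utils::write.csv(sig6(as.data.frame(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("sim_summary", "data.frame")
  df
}

#' @rdname write_estimates_csv
#' @export
write_sweep_csv <- function(x, path) {
  utils::write.csv(sig6(as.data.frame(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("sweep_result", "data.frame")
  df
}

config_error <- function(...) stop("config error: ", ..., call. = FALSE)

# build a scenario from one validated config entry
scenario_from_config <- function(sc, idx = 1L) {
  if (is.null(sc$name)) config_error("scenarios[", idx, "]: missing `name`")
  pc <- sc$population
  if (is.null(pc)) pc <- list()
  if (any(names(pc) %in% c("TRUE", "FALSE")))
    config_error(sc$name, ": a population key parsed as a YAML boolean — ",
                 "use `size:` for the population size")
  for (f in names(pc))
    if (!f %in% c("size", "race_probs", "trust_coefs", "income_coefs"))
      config_error(sc$name, ": unknown population field `", f, "`")
  names(pc)[names(pc) == "size"] <- "N"
  pop <- tryCatch(
    do.call(pop_config, lapply(pc, unlist)),
    error = function(e) config_error(sc$name, ": population: ",
                                     conditionMessage(e)))
  mech <- sc$misclassification
  if (is.null(mech)) mech <- "none"
  if (is.list(mech)) {
    if (!identical(mech$type, "degree") || is.null(mech$d))
      config_error(sc$name, ": list-valued misclassification must be ",
                   "{type: degree, d: <value>[, pattern: <pattern>]}")
    mech <- list(type = "degree", d = as.numeric(mech$d),
                 pattern = if (is.null(mech$pattern)) "uniform"
                           else mech$pattern)
  }
  dz <- sc$designs
  if (is.null(dz)) config_error(sc$name, ": missing `designs`")
  designs <- list(
    full_cohort = isTRUE(dz$full_cohort),
    srs = if (!is.null(dz$srs)) as.integer(dz$srs),
    dss = if (!is.null(dz$dss)) as.integer(unlist(dz$dss)))
  methods <- if (is.null(sc$methods))
    c("design_agnostic", "model_based", "design_based") else unlist(sc$methods)
  if (is.null(sc$reps)) config_error(sc$name, ": missing `reps`")
  if (is.null(sc$seed)) config_error(sc$name, ": missing `seed`")
  tryCatch(
    scenario(population = pop, misclassification = mech,
             matrix_interpretation = if (is.null(sc$matrix_interpretation))
               "bayes_inverted" else sc$matrix_interpretation,
             designs = designs, methods = methods,
             reps = sc$reps, seed = sc$seed,
             variance = if (is.null(sc$variance)) "unstratified" else sc$variance,
             ci_level = if (is.null(sc$ci_level)) 0.95 else sc$ci_level,
             name = sc$name),
    error = function(e) config_error(sc$name, ": ", conditionMessage(e)))
}

#' Read and validate a scenario configuration file
#'
#' YAML schema: a top-level `scenarios:` list whose entries carry `name`,
#' `reps`, `seed`, `designs` (any of `full_cohort`, `srs`, `dss`) and
#' optionally `population` (`size`, `race_probs`, `trust_coefs`,
#' `income_coefs`), `misclassification`, `matrix_interpretation`,
#' `methods`, `variance`, `ci_level`; plus an optional top-level `sweep:`
#' block (`degrees`, `pattern`, `base` naming one scenario). Field-level
#' problems raise errors naming the scenario and field.
#'
#' @param path YAML file.
#' @return List with `scenarios` (list of [scenario()] objects) and
#'   `sweep` (the sweep block or `NULL`).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) config_error("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    config_error("top-level `scenarios:` list is required")
  scns <- lapply(seq_along(cfg$scenarios), function(i)
    scenario_from_config(cfg$scenarios[[i]], i))
  names(scns) <- vapply(scns, `[[`, "", "name")
  sweep <- cfg$sweep
  if (!is.null(sweep)) {
    if (is.null(sweep$degrees) || !length(sweep$degrees))
      config_error("sweep: non-empty `degrees` is required")
    sweep$degrees <- as.numeric(unlist(sweep$degrees))
    if (any(sweep$degrees < 0 | sweep$degrees > 1))
      config_error("sweep: degrees must lie in [0, 1]")
    if (is.null(sweep$pattern)) sweep$pattern <- "uniform"
    if (is.null(sweep$base)) sweep$base <- names(scns)[1]
    if (!sweep$base %in% names(scns))
      config_error("sweep: base scenario `", sweep$base, "` not defined")
  }
  list(scenarios = scns, sweep = sweep)
}

#' Run every scenario in a configuration and write its outputs
#'
#' For each scenario writes `<name>_estimates.csv` (per replicate) and
#' `<name>_summary.csv`, then a `manifest.json` recording the config
#' hash, seeds, package version, timestamp, output paths, and
#' convergence counts.
#'
#' @param config_path YAML configuration file.
#' @param out_dir Output directory (created if needed).
#' @param reps,seed Optional overrides applied to every scenario.
#' @param verbose Progress to stderr.
#' @return The manifest, invisibly.
#' @export
run_config <- function(config_path, out_dir, reps = NULL, seed = NULL,
                       verbose = FALSE) {
  cfg <- read_scenario_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  convergence <- list()
  for (scn in cfg$scenarios) {
    if (verbose) message("running scenario: ", scn$name)
    res <- run_scenario(scn, reps = reps, seed = seed, verbose = verbose)
    ep <- file.path(out_dir, paste0(scn$name, "_estimates.csv"))
    sp <- file.path(out_dir, paste0(scn$name, "_summary.csv"))
    write_estimates_csv(res$estimates, ep)
    write_summary_csv(res$summary, sp)
    outputs[[scn$name]] <- c(ep, sp)
    convergence[[scn$name]] <-
      stats::aggregate(converged ~ design + method, res$estimates, mean)
  }
  manifest <- list(
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed_override = seed, reps_override = reps,
    package_version = as.character(utils::packageVersion("misclassdss")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs,
    convergence_rates = lapply(convergence, function(d)
      stats::setNames(as.list(d$converged), paste(d$design, d$method, sep = "/"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the sweep block of a configuration
#'
#' @param config_path YAML configuration with a `sweep:` block.
#' @param out_dir Output directory.
#' @param verbose Progress to stderr.
#' @return The sweep table, invisibly.
#' @export
run_sweep_config <- function(config_path, out_dir, verbose = FALSE) {
  cfg <- read_scenario_config(config_path)
  if (is.null(cfg$sweep))
    config_error("this configuration has no `sweep:` block")
  base <- cfg$scenarios[[cfg$sweep$base]]
  if (verbose) message("sweep over degrees: ",
                       paste(cfg$sweep$degrees, collapse = ", "))
  sw <- sweep_degree(base, cfg$sweep$degrees, pattern = cfg$sweep$pattern)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(out_dir, "sweep.csv")
  write_sweep_csv(sw, sp)
  jsonlite::write_json(
    list(config = config_path,
         config_md5 = unname(tools::md5sum(config_path)),
         package_version = as.character(utils::packageVersion("misclassdss")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = sp),
    file.path(out_dir, "sweep_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sw)
}
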