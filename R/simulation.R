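#' Define a Monte-Carlo scenario
#'
#' A scenario bundles the population model, the misclassification
#' mechanism, the sampling designs, the analysis strategies, and the
#' replication settings for one simulation cell.
#'
#' Misclassification mechanisms:
#' \describe{
#'   \item{`"none"`}{recorded category equals the true category.}
#'   \item{`"ehr_nondifferential"`}{the overall empirical EHR matrix
#'     ([ehr_misclass_matrices()]), interpreted per
#'     `matrix_interpretation`.}
#'   \item{`"ehr_differential"`}{the outcome-stratified empirical EHR
#'     matrices, ditto.}
#'   \item{`list(type = "degree", d = , pattern = )`}{a
#'     [degree_matrix()] family member (already generator-direction).}
#' }
#'
#' Designs: `full_cohort = TRUE` fits the design-agnostic model to the
#' whole population (a bias/coverage benchmark); `srs = n` draws a simple
#' random sample analyzed design-agnostically; `dss = quotas` draws a
#' disproportionate stratified sample on the recorded category, analyzed
#' with every strategy in `methods`.
#'
#' @param population A [pop_config()].
#' @param misclassification Mechanism, see above.
#' @param matrix_interpretation How inverse-direction empirical matrices
#'   become generators: `"bayes_inverted"` (uniform prior over recorded
#'   categories; the default, which reproduces the published simulation
#'   results) or `"direct"`.
#' @param designs List with any of `full_cohort`, `srs`, `dss`.
#' @param methods Analysis strategies for the DSS design.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Parent seed; per-replicate seeds are drawn from it so any
#'   replicate is reproducible in isolation.
#' @param variance Sandwich form for the design-based strategy.
#' @param ci_level Wald confidence level used everywhere.
#' @param name Scenario name used in output files.
#' @return An object of class `scenario`.
#' @examples
#' scn <- scenario(pop_config(N = 5000), "ehr_nondifferential",
#'                 designs = list(dss = 50), reps = 3, seed = 1)
#' @export
scenario <- function(population = pop_config(),
                     misclassification = "none",
                     matrix_interpretation = c("bayes_inverted", "direct"),
                     designs = list(full_cohort = FALSE, srs = NULL, dss = NULL),
                     methods = c("design_agnostic", "model_based", "design_based"),
                     reps = 100L, seed = 1L,
                     variance = c("unstratified", "stratified"),
                     ci_level = 0.95, name = "scenario") {
  stopifnot(inherits(population, "pop_config"))
  matrix_interpretation <- match.arg(matrix_interpretation)
  variance <- match.arg(variance)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(reps) != 1 || reps < 1 || reps != floor(reps))
    stop("`reps` must be a positive integer", call. = FALSE)
  ok_mech <- (is.character(misclassification) && length(misclassification) == 1 &&
                misclassification %in% c("none", "ehr_nondifferential",
                                         "ehr_differential")) ||
    (is.list(misclassification) && identical(misclassification$type, "degree"))
  if (!ok_mech)
    stop("unknown misclassification mechanism; use \"none\", ",
         "\"ehr_nondifferential\", \"ehr_differential\", or ",
         "list(type = \"degree\", d = , pattern = )", call. = FALSE)
  bad <- setdiff(names(designs), c("full_cohort", "srs", "dss"))
  if (length(bad))
    stop("unknown design(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!isTRUE(designs$full_cohort) && is.null(designs$srs) && is.null(designs$dss))
    stop("at least one design (full_cohort, srs, dss) is required", call. = FALSE)
  structure(list(population = population,
                 misclassification = misclassification,
                 matrix_interpretation = matrix_interpretation,
                 designs = designs, methods = methods,
                 reps = as.integer(reps), seed = as.integer(seed),
                 variance = variance, ci_level = ci_level, name = name),
            class = "scenario")
}

# resolve the scenario's mechanism to a generator-direction matrix (or NULL)
scenario_generator <- function(scn) {
  mech <- scn$misclassification
  if (identical(mech, "none")) return(NULL)
  if (is.list(mech)) {
    return(degree_matrix(mech$d, H = scn$population$H,
                         pattern = if (is.null(mech$pattern)) "uniform"
                                   else mech$pattern))
  }
  emp <- ehr_misclass_matrices()
  m <- if (mech == "ehr_nondifferential") emp$overall else emp$stratified
  as_generator(m, interpretation = scn$matrix_interpretation)
}

# truth vector on the parameter naming used by fit_method()
scenario_truth <- function(scn) {
  cfg <- scn$population
  b <- cfg$trust_coefs
  stats::setNames(c(b[1], b[2:cfg$H], b[cfg$H + 1]),
                  c("(Intercept)", cfg$labels[-1], "low_income"))
}

#' Run a Monte-Carlo scenario
#'
#' For each replicate: generate a population, apply the misclassification
#' mechanism, draw each requested design's sample, fit each analysis
#' strategy, and record estimates and standard errors. Replicates use
#' independent seeds drawn from the scenario seed, so results are
#' reproducible and order-independent. Fits that fail to converge are
#' kept in the per-replicate table (flagged) but excluded from the
#' summary; separation-flagged fits that did converge by the deviance
#' criterion are retained, matching standard practice of reporting
#' whatever the fitter returns.
#'
#' @param scn A [scenario()].
#' @param reps,seed Optional overrides of the scenario settings.
#' @param verbose If `TRUE`, progress messages to stderr every 200
#'   replicates.
#' @return A `sim_result` list: `scenario`, `estimates` (long
#'   per-replicate data.frame), `summary` (a `sim_summary`, see
#'   [summarize_estimates()]).
#' @export
run_scenario <- function(scn, reps = NULL, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(scn, "scenario"))
  if (!is.null(reps)) scn$reps <- as.integer(reps)
  if (!is.null(seed)) scn$seed <- as.integer(seed)
  G <- scenario_generator(scn)
  truth <- scenario_truth(scn)
  set.seed(scn$seed)
  rep_seeds <- sample.int(2147483646L, scn$reps)

  cells <- new.env(parent = emptyenv())
  record <- function(key, r, fit) {
    cell <- cells[[key]]
    if (is.null(cell)) {
      k <- length(fit$coefficients)
      cell <- list(par = names(fit$coefficients),
                   est = matrix(NA_real_, scn$reps, k),
                   se = matrix(NA_real_, scn$reps, k),
                   conv = logical(scn$reps), sep = logical(scn$reps))
    }
    pars <- names(fit$coefficients)
    miss <- setdiff(pars, cell$par)
    if (length(miss)) {   # widen for parameters first seen later
      add <- matrix(NA_real_, scn$reps, length(miss))
      cell$est <- cbind(cell$est, add); cell$se <- cbind(cell$se, add)
      cell$par <- c(cell$par, miss)
    }
    j <- match(pars, cell$par)
    cell$est[r, j] <- fit$coefficients
    cell$se[r, j] <- fit$se
    cell$conv[r] <- fit$converged
    cell$sep[r] <- fit$separated
    cells[[key]] <- cell
    invisible(NULL)
  }

  for (r in seq_len(scn$reps)) {
    set.seed(rep_seeds[r])
    pop <- generate_population(scn$population)
    if (!is.null(G)) pop <- apply_misclassification(pop, G)
    if (isTRUE(scn$designs$full_cohort)) {
      record("full_cohort.design_agnostic", r,
             fit_method(pop, model_spec("design_agnostic",
                                        ci_level = scn$ci_level)))
    }
    if (!is.null(scn$designs$srs)) {
      smp <- draw_srs(pop, scn$designs$srs)
      record("srs.design_agnostic", r,
             fit_method(smp, model_spec("design_agnostic",
                                        ci_level = scn$ci_level)))
    }
    if (!is.null(scn$designs$dss)) {
      smp <- withCallingHandlers(
        draw_dss(pop, scn$designs$dss),
        warning = function(w) invokeRestart("muffleWarning"))
      for (m in scn$methods) {
        record(paste("dss", m, sep = "."), r,
               fit_method(smp, model_spec(m, ci_level = scn$ci_level,
                                          variance = scn$variance)))
      }
    }
    if (verbose && r %% 200 == 0)
      message("[", scn$name, "] replicate ", r, "/", scn$reps)
  }

  est_list <- lapply(ls(cells), function(key) {
    cell <- cells[[key]]
    dm <- strsplit(key, ".", fixed = TRUE)[[1]]
    k <- length(cell$par)
    data.frame(replicate = rep(seq_len(scn$reps), each = k),
               design = dm[1], method = dm[2],
               parameter = rep(cell$par, scn$reps),
               estimate = as.vector(t(cell$est)),
               se = as.vector(t(cell$se)),
               converged = rep(cell$conv, each = k),
               separated = rep(cell$sep, each = k))
  })
  estimates <- do.call(rbind, est_list)
  summary <- summarize_estimates(estimates, truth, ci_level = scn$ci_level)
  structure(list(scenario = scn, estimates = estimates, summary = summary),
            class = "sim_result")
}

#' Summarize per-replicate estimates
#'
#' Per (design, method, parameter): the Monte-Carlo mean estimate, the
#' empirical SE (standard deviation of the estimates across converged
#' replicates; `NA` with fewer than two), and the coverage — the fraction
#' of converged replicates whose Wald interval contains the generating
#' value. Parameters without a generating value (the recorded-category
#' dummies of the model-based strategy) are summarized against a truth of
#' zero, their generating value under any outcome model that excludes
#' them.
#'
#' @param estimates Long per-replicate data.frame as produced by
#'   [run_scenario()].
#' @param truth Named vector of generating coefficient values.
#' @param ci_level Confidence level the coverage refers to.
#' @return A `sim_summary` data.frame: `design`, `method`, `parameter`,
#'   `truth`, `mean_estimate`, `empirical_se`, `coverage`, `n_converged`,
#'   `n_total`.
#' @export
summarize_estimates <- function(estimates, truth, ci_level = 0.95) {
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- list()
  for (key in unique(paste(estimates$design, estimates$method, sep = "\r"))) {
    dm <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- estimates[estimates$design == dm[1] & estimates$method == dm[2], ]
    for (p in unique(sub$parameter)) {
      sp <- sub[sub$parameter == p & sub$converged & !is.na(sub$estimate), ]
      tv <- if (p %in% names(truth)) truth[[p]] else 0
      n_conv <- nrow(sp)
      out[[length(out) + 1L]] <- data.frame(
        design = dm[1], method = dm[2], parameter = p, truth = tv,
        mean_estimate = if (n_conv) mean(sp$estimate) else NA_real_,
        empirical_se = if (n_conv >= 2) stats::sd(sp$estimate) else NA_real_,
        coverage = if (n_conv) mean(abs(sp$estimate - tv) <= zq * sp$se)
                   else NA_real_,
        n_converged = n_conv,
        n_total = length(unique(sub[sub$parameter == p, "replicate"])))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ci_level") <- ci_level
  class(res) <- c("sim_summary", "data.frame")
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation result:", x$scenario$name, "(", x$scenario$reps, "replicates )\n")
  print(render_summary_table(x$summary))
  invisible(x)
}

#' Relative uncertainty of DSS estimates versus SRS
#'
#' For every (method, parameter) cell of the DSS summary, the ratio of
#' its empirical SE to the SRS empirical SE for the same parameter,
#' together with its log2. Values below one mean the stratified design
#' is more precise than simple random sampling for that parameter.
#'
#' @param dss_summary A `sim_summary` containing `design == "dss"` rows.
#' @param srs_summary A `sim_summary` containing `design == "srs"` rows
#'   (may be the same object).
#' @return Data.frame: `method`, `parameter`, `se_dss`, `se_srs`,
#'   `ratio`, `log2_ratio`; ratio is `NA` where the SRS SE is zero or
#'   missing.
#' @export
relative_uncertainty <- function(dss_summary, srs_summary) {
  d <- dss_summary[dss_summary$design == "dss", ]
  s <- srs_summary[srs_summary$design == "srs", ]
  if (!nrow(d) || !nrow(s))
    stop("need a summary with dss rows and one with srs rows", call. = FALSE)
  i <- match(d$parameter, s$parameter)
  se_srs <- s$empirical_se[i]
  ratio <- ifelse(!is.na(se_srs) & se_srs > 0, d$empirical_se / se_srs, NA_real_)
  data.frame(method = d$method, parameter = d$parameter,
             se_dss = d$empirical_se, se_srs = se_srs,
             ratio = ratio, log2_ratio = log2(ratio))
}

#' Sweep the degree of misclassification
#'
#' Reruns a base scenario at each degree `d` of a [degree_matrix()]
#' family (both DSS and SRS designs are forced on), and assembles the
#' per-degree relative uncertainty of every method and parameter.
#'
#' @param base A [scenario()]; its `misclassification` is replaced by the
#'   degree mechanism at each sweep point.
#' @param degrees Vector of degrees in `[0, 1]`.
#' @param pattern Off-diagonal pattern, see [degree_matrix()].
#' @return A `sweep_result` data.frame: `degree`, `method`, `parameter`,
#'   `se_dss`, `se_srs`, `ratio`, `log2_ratio`.
#' @export
sweep_degree <- function(base, degrees, pattern = c("uniform", "table_proportional")) {
  stopifnot(inherits(base, "scenario"))
  pattern <- match.arg(pattern)
  if (!length(degrees)) stop("`degrees` must be non-empty", call. = FALSE)
  if (any(degrees < 0 | degrees > 1))
    stop("`degrees` must lie in [0, 1]", call. = FALSE)
  if (is.null(base$designs$dss) || is.null(base$designs$srs))
    stop("the sweep needs both `dss` and `srs` designs in the base scenario",
         call. = FALSE)
  set.seed(base$seed)
  degree_seeds <- sample.int(2147483646L, length(degrees))
  out <- vector("list", length(degrees))
  for (i in seq_along(degrees)) {
    scn <- base
    scn$misclassification <- list(type = "degree", d = degrees[i],
                                  pattern = pattern)
    scn$seed <- degree_seeds[i]
    scn$name <- paste0(base$name, "_d", degrees[i])
    res <- run_scenario(scn)
    ru <- relative_uncertainty(res$summary, res$summary)
    ru <- cbind(degree = degrees[i], ru)
    out[[i]] <- ru
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sweep_result", "data.frame")
  res
}
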