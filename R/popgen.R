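#' Default race/ethnicity category labels
#'
#' Fixed category order used throughout the package. Category 1 (White) is
#' the reference level of every dummy encoding.
#' @keywords internal
default_labels <- function() c("White", "Black", "Asian", "Other", "Hispanic")

#' Population configuration
#'
#' Bundles everything needed to generate a finite cohort: the population
#' size, the marginal distribution of the true categorical exposure
#' (race/ethnicity), and the log-odds coefficients of the two generative
#' logistic models — one for the binary non-sampling covariate (low income,
#' depending on race only) and one for the binary outcome (trust in the
#' healthcare system, depending on race and low income).
#'
#' The defaults are the study conditions used throughout the package's
#' simulations: a cohort of 100,000 with race/ethnicity proportions
#' (0.82, 0.10, 0.01, 0.05, 0.02) over (White, Black, Asian, Other,
#' Hispanic), trust coefficients (-0.75, -0.25, -0.50, 1.25, -1.50, 1.00)
#' for (intercept, Black, Asian, Other, Hispanic, low income), and
#' low-income coefficients (-2.00, 1.25, 0.25, 1.75, 0.50).
#'
#' @param N Positive integer, number of units in the cohort.
#' @param race_probs Probability vector over the `H` categories (must sum
#'   to 1; `H >= 2`).
#' @param trust_coefs Numeric vector of length `H + 1`: intercept, one
#'   log-odds coefficient per non-reference category, and the low-income
#'   coefficient.
#' @param income_coefs Numeric vector of length `H`: intercept plus one
#'   log-odds coefficient per non-reference category.
#' @param labels Character vector of category labels, length `H`.
#' @return An object of class `pop_config`.
#' @examples
#' cfg <- pop_config(N = 1000)
#' cfg$race_probs
#' @export
pop_config <- function(N = 100000,
                       race_probs = c(0.82, 0.10, 0.01, 0.05, 0.02),
                       trust_coefs = c(-0.75, -0.25, -0.50, 1.25, -1.50, 1.00),
                       income_coefs = c(-2.00, 1.25, 0.25, 1.75, 0.50),
                       labels = NULL) {
  if (length(N) != 1L || is.na(N) || N < 1 || N != floor(N))
    stop("`N` must be a positive integer", call. = FALSE)
  H <- length(race_probs)
  if (H < 2)
    stop("`race_probs` must have at least two categories", call. = FALSE)
  if (any(!is.finite(race_probs)) || any(race_probs < 0))
    stop("`race_probs` entries must be nonnegative and finite", call. = FALSE)
  if (abs(sum(race_probs) - 1) > 1e-12)
    stop("`race_probs` must sum to 1 (within 1e-12), got ",
         format(sum(race_probs), digits = 15), call. = FALSE)
  if (length(trust_coefs) != H + 1)
    stop("`trust_coefs` must have length H + 1 = ", H + 1,
         " (intercept, non-reference categories, low income)", call. = FALSE)
  if (length(income_coefs) != H)
    stop("`income_coefs` must have length H = ", H,
         " (intercept, non-reference categories)", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (H == 5L) default_labels() else paste0("cat", seq_len(H))
  }
  if (length(labels) != H)
    stop("`labels` must have length H = ", H, call. = FALSE)
  structure(
    list(N = as.integer(N), race_probs = as.numeric(race_probs),
         trust_coefs = as.numeric(trust_coefs),
         income_coefs = as.numeric(income_coefs),
         H = H, labels = labels),
    class = "pop_config")
}

#' @export
print.pop_config <- function(x, ...) {
  cat("Population configuration\n")
  cat("  N:", x$N, " categories:", paste(x$labels, collapse = ", "), "\n")
  cat("  race probs:  ", paste(format(x$race_probs), collapse = " "), "\n")
  cat("  trust coefs: ", paste(format(x$trust_coefs), collapse = " "), "\n")
  cat("  income coefs:", paste(format(x$income_coefs), collapse = " "), "\n")
  invisible(x)
}

#' Generate a finite population
#'
#' Draws a cohort of `config$N` units. True category `X` is i.i.d.
#' categorical with probabilities `race_probs`; `low_income | X` is
#' Bernoulli on the inverse-logit scale of the income model; the outcome
#' `Y | X, low_income` is Bernoulli on the inverse-logit scale of the
#' trust model. Generation order is X, then low income, then Y. The
#' recorded category `X_star` is initialized equal to `X`; apply a
#' misclassification matrix with [apply_misclassification()] to perturb
#' it.
#'
#' @param config A [pop_config()] object.
#' @param seed Optional integer seed; if supplied, the draw is a pure
#'   function of `(config, seed)`. If `NULL`, the current RNG stream is
#'   used.
#' @return A `population`: a data.frame with columns `id`, `X`, `X_star`,
#'   `low_income`, `Y` (categories as integer codes `1..H`), carrying the
#'   configuration and label map as attributes.
#' @examples
#' pop <- generate_population(pop_config(N = 500), seed = 1)
#' table(pop$X)
#' @export
generate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pop_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  H <- config$H
  X <- sample.int(H, N, replace = TRUE, prob = config$race_probs)
  g <- config$income_coefs
  p_low <- stats::plogis(g[1] + c(0, g[-1]))[X]       # per-category lookup
  low_income <- as.integer(stats::runif(N) < p_low)
  b <- config$trust_coefs
  bl <- b[H + 1]
  eta <- (b[1] + c(0, b[2:H]))[X] + bl * low_income
  Y <- as.integer(stats::runif(N) < stats::plogis(eta))
  pop <- data.frame(id = seq_len(N), X = X, X_star = X,
                    low_income = low_income, Y = Y)
  attr(pop, "config") <- config
  attr(pop, "labels") <- config$labels
  class(pop) <- c("population", "data.frame")
  pop
}

#' @export
print.population <- function(x, ...) {
  lab <- attr(x, "labels")
  cat("Finite population of", nrow(x), "units,", length(lab), "categories\n")
  tab <- tabulate(x$X, length(lab))
  names(tab) <- lab
  print(tab)
  cat("misclassified units (X_star != X):", sum(x$X_star != x$X), "\n")
  invisible(x)
}

#' Write / read a population as CSV with a JSON label map
#'
#' The CSV holds integer category codes; the sidecar JSON (same path with
#' extension `.labels.json`) records the code-to-label mapping so the file
#' is self-describing.
#'
#' @param pop A `population`.
#' @param path CSV file path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns a `population`.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  utils::write.csv(as.data.frame(pop)[, c("id", "X", "X_star", "low_income", "Y")],
                   path, row.names = FALSE)
  lab <- attr(pop, "labels")
  jsonlite::write_json(
    list(columns = c("id", "X", "X_star", "low_income", "Y"),
         labels = as.list(stats::setNames(seq_along(lab), lab))),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_population
#' @param path CSV file path previously written by `write_population()`.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "X", "X_star", "low_income", "Y")
  if (!all(need %in% names(df)))
    stop("population CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path))
  labels <- names(meta$labels)
  attr(df, "labels") <- labels
  class(df) <- c("population", "data.frame")
  df
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |> paste0(".labels.json")
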