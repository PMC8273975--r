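#' Survey samples
#'
#' A `survey_sample` is a data.frame of sampled units carrying the unit
#' id, true and recorded categories, covariate and outcome, the sampling
#' stratum (for stratified designs), and the sampling weight
#' `w_i = 1 / Pr(selected)`. Attributes record the design
#' (`srs` or `dss`), the per-stratum population sizes `N*_h` and realized
#' sample sizes `n*_h`, and any strata that could not meet their quota.
#' @name survey_sample
NULL

new_survey_sample <- function(df, design, pop_size,
                              stratum_pop_sizes = NULL,
                              stratum_sample_sizes = NULL,
                              short_strata = integer(0), labels = NULL) {
  attr(df, "design") <- design
  attr(df, "pop_size") <- pop_size
  attr(df, "stratum_pop_sizes") <- stratum_pop_sizes
  attr(df, "stratum_sample_sizes") <- stratum_sample_sizes
  attr(df, "short_strata") <- short_strata
  attr(df, "labels") <- labels
  class(df) <- c("survey_sample", "data.frame")
  df
}

#' @export
print.survey_sample <- function(x, ...) {
  cat("Survey sample (", attr(x, "design"), "): ", nrow(x), " of ",
      attr(x, "pop_size"), " units\n", sep = "")
  if (!is.null(attr(x, "stratum_sample_sizes"))) {
    cat("  per-stratum n*_h:", paste(attr(x, "stratum_sample_sizes"),
                                     collapse = " "), "\n")
    cat("  per-stratum N*_h:", paste(attr(x, "stratum_pop_sizes"),
                                     collapse = " "), "\n")
  }
  cat("  weight range: [", format(min(x$weight)), ", ",
      format(max(x$weight)), "], sum = ", format(sum(x$weight)), "\n", sep = "")
  invisible(x)
}

#' Simple random sample
#'
#' Uniform without-replacement draw of `n` units; every sampled unit gets
#' weight `N / n`, so the weights sum to the population size exactly.
#'
#' @param pop A `population`.
#' @param n Sample size, `1 <= n <= N`.
#' @param seed Optional integer seed.
#' @return A [survey_sample].
#' @examples
#' pop <- generate_population(pop_config(N = 1000), seed = 1)
#' s <- draw_srs(pop, 100, seed = 2)
#' sum(s$weight)  # 1000
#' @export
draw_srs <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  N <- nrow(pop)
  if (length(n) != 1 || n < 1 || n > N || n != floor(n))
    stop("`n` must be an integer in [1, N = ", N, "]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(N, n)
  df <- as.data.frame(pop)[idx, c("id", "X", "X_star", "low_income", "Y")]
  df$stratum <- NA_integer_
  df$weight <- N / n
  rownames(df) <- NULL
  new_survey_sample(df, "srs", N, labels = attr(pop, "labels"))
}

#' Disproportionate stratified sample
#'
#' Strata are the recorded categories `X_star`. Each stratum `h` yields an
#' independent without-replacement draw of `min(quota_h, N*_h)` units, and
#' every unit sampled from stratum `h` gets the inverse selection
#' probability `w_i = N*_h / n*_h` as its weight, where `n*_h` is the
#' realized stratum sample size. The Horvitz-Thompson stratum totals
#' `sum(w_i)` therefore reproduce each `N*_h` exactly. A stratum smaller
#' than its quota is taken whole (weight 1) with a warning; an empty
#' stratum with a positive quota contributes nothing and is recorded in
#' the `short_strata` attribute.
#'
#' @param pop A `population`.
#' @param quotas Per-stratum sample sizes: a vector of length `H`, or a
#'   single value recycled to all strata.
#' @param seed Optional integer seed.
#' @return A [survey_sample] with `stratum`, `weight`, and per-stratum
#'   size attributes.
#' @examples
#' pop <- generate_population(pop_config(N = 5000), seed = 1)
#' s <- draw_dss(pop, quotas = 100)
#' tapply(s$weight, s$stratum, sum)  # the stratum population sizes
#' @export
draw_dss <- function(pop, quotas, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  H <- length(attr(pop, "labels"))
  if (length(quotas) == 1L) quotas <- rep(quotas, H)
  if (length(quotas) != H || any(quotas < 1) || any(quotas != floor(quotas)))
    stop("`quotas` must be positive integers, one per stratum (H = ", H, ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Npop <- nrow(pop)
  Nh <- tabulate(pop$X_star, H)
  take <- integer(0)
  wt <- numeric(0)
  strat <- integer(0)
  nh <- integer(H)
  short <- integer(0)
  for (h in seq_len(H)) {
    idx <- which(pop$X_star == h)
    nh[h] <- min(quotas[h], Nh[h])
    if (Nh[h] == 0L) {
      warning("stratum ", h, " is empty; quota ", quotas[h], " unmet",
              call. = FALSE)
      short <- c(short, h)
      next
    }
    if (nh[h] < quotas[h]) {
      warning("stratum ", h, " has only ", Nh[h], " units for quota ",
              quotas[h], "; taking the whole stratum", call. = FALSE)
      short <- c(short, h)
    }
    s <- if (length(idx) == 1L) idx else sample(idx, nh[h])
    take <- c(take, s)
    wt <- c(wt, rep(Nh[h] / nh[h], nh[h]))
    strat <- c(strat, rep(h, nh[h]))
  }
  df <- as.data.frame(pop)[take, c("id", "X", "X_star", "low_income", "Y")]
  df$stratum <- strat
  df$weight <- wt
  rownames(df) <- NULL
  new_survey_sample(df, "dss", Npop, stratum_pop_sizes = Nh,
                    stratum_sample_sizes = nh, short_strata = short,
                    labels = attr(pop, "labels"))
}

#' Truncate sampling weights at a percentile
#'
#' Weights above the given percentile of the weight distribution are set
#' equal to that percentile value; all others are unchanged. The
#' percentile is computed by linear interpolation between order
#' statistics (the default quantile definition in this package's host
#' environment, `type = 7`).
#'
#' @param weights Positive weight vector.
#' @param percentile Percentile in `(0, 100]`; `100` leaves the weights
#'   unchanged.
#' @return Weight vector of the same length.
#' @examples
#' truncate_weights(1:10, 90)  # cap at 9.1
#' @export
truncate_weights <- function(weights, percentile = 90) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all weights must be positive and finite", call. = FALSE)
  if (length(percentile) != 1 || !is.finite(percentile) ||
      percentile <= 0 || percentile > 100)
    stop("`percentile` must lie in (0, 100]", call. = FALSE)
  cap <- stats::quantile(weights, percentile / 100, names = FALSE, type = 7)
  pmin(weights, cap)
}

#' Write / read a survey sample as CSV plus JSON design descriptor
#'
#' @param smp A [survey_sample].
#' @param path CSV file path.
#' @return `write_survey_sample()` returns `path` invisibly;
#'   `read_survey_sample()` returns a [survey_sample].
#' @export
write_survey_sample <- function(smp, path) {
  stopifnot(inherits(smp, "survey_sample"))
  utils::write.csv(as.data.frame(smp), path, row.names = FALSE)
  jsonlite::write_json(
    list(design = attr(smp, "design"), pop_size = attr(smp, "pop_size"),
         stratum_pop_sizes = attr(smp, "stratum_pop_sizes"),
         stratum_sample_sizes = attr(smp, "stratum_sample_sizes"),
         short_strata = attr(smp, "short_strata"),
         labels = attr(smp, "labels")),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_survey_sample
#' @export
read_survey_sample <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  new_survey_sample(df, meta$design, meta$pop_size,
                    stratum_pop_sizes = unlist(meta$stratum_pop_sizes),
                    stratum_sample_sizes = unlist(meta$stratum_sample_sizes),
                    short_strata = as.integer(unlist(meta$short_strata)),
                    labels = unlist(meta$labels))
}
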