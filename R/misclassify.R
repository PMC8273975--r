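#' Misclassification matrix
#'
#' A row-stochastic conditional distribution of one category label given
#' another, in one of two directions:
#' \describe{
#'   \item{`generator`}{row `i` gives `Pr(recorded = j | true = i)` — the
#'     direction needed to simulate recorded labels from true ones.}
#'   \item{`inverse`}{row `i` gives `Pr(true = j | recorded = i)` — the
#'     direction in which validation tables are usually published, with
#'     rows indexed by the recorded (e.g. EHR) category.}
#' }
#' A non-differential matrix is a single `H x H` matrix `P`; a
#' differential one carries a pair `P_by_y` (one matrix per outcome level
#' 0/1), so the label error may depend on the outcome.
#'
#' @param P `H x H` row-stochastic matrix (non-differential mode).
#' @param P_by_y List of two `H x H` row-stochastic matrices named `"0"`
#'   and `"1"` (differential mode). Exactly one of `P`, `P_by_y` must be
#'   given.
#' @param direction `"generator"` or `"inverse"` (see above).
#' @param labels Optional category labels.
#' @return An object of class `misclass_matrix`.
#' @examples
#' m <- misclass_matrix(diag(5), direction = "generator")
#' m$mode
#' @export
misclass_matrix <- function(P = NULL, P_by_y = NULL,
                            direction = c("generator", "inverse"),
                            labels = NULL) {
  direction <- match.arg(direction)
  if (is.null(P) == is.null(P_by_y))
    stop("give exactly one of `P` (non-differential) or `P_by_y` (differential)",
         call. = FALSE)
  check_rows <- function(M, what) {
    if (!is.matrix(M) || nrow(M) != ncol(M))
      stop(what, " must be a square matrix", call. = FALSE)
    if (any(!is.finite(M)) || any(M < -1e-12) || any(M > 1 + 1e-12))
      stop(what, " entries must lie in [0, 1]", call. = FALSE)
    bad <- abs(rowSums(M) - 1) > 1e-9
    if (any(bad))
      stop(what, " rows must sum to 1 (within 1e-9); offending rows: ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    unname(pmin(pmax(M, 0), 1))
  }
  if (!is.null(P)) {
    P <- check_rows(P, "`P`")
    H <- nrow(P)
    mode <- "non_differential"
  } else {
    if (length(P_by_y) != 2)
      stop("differential mode carries exactly two matrices (outcome 0 and 1)",
           call. = FALSE)
    P_by_y <- lapply(P_by_y, check_rows, what = "`P_by_y` matrices")
    if (nrow(P_by_y[[1]]) != nrow(P_by_y[[2]]))
      stop("the two differential matrices must have the same dimension",
           call. = FALSE)
    names(P_by_y) <- c("0", "1")
    H <- nrow(P_by_y[[1]])
    mode <- "differential"
  }
  if (is.null(labels)) labels <- if (H == 5L) default_labels() else paste0("cat", seq_len(H))
  structure(list(mode = mode, direction = direction, H = H,
                 P = P, P_by_y = P_by_y, labels = labels),
            class = "misclass_matrix")
}

#' @export
print.misclass_matrix <- function(x, digits = 3, ...) {
  cat("Misclassification matrix (", x$mode, ", direction = ", x$direction,
      ", H = ", x$H, ")\n", sep = "")
  fmt <- function(M) {
    dimnames(M) <- list(x$labels, x$labels)
    print(round(M, digits))
  }
  if (x$mode == "non_differential") fmt(x$P)
  else for (y in c("0", "1")) { cat("outcome =", y, "\n"); fmt(x$P_by_y[[y]]) }
  invisible(x)
}

# Observed EHR-vs-self-report race/ethnicity counts among the VUMC biobank
# survey respondents, overall and stratified by the trust outcome. Rows are
# the EHR-recorded category, columns the self-reported one; counts are
# embedded verbatim so row normalization is reproducible.
ehr_counts <- function() {
  lab <- default_labels()
  mk <- function(v) matrix(v, 5, 5, byrow = TRUE, dimnames = list(lab, lab))
  list(
    overall = mk(c(134, 1, 0, 6, 1,
                   0, 74, 0, 4, 1,
                   1, 1, 62, 14, 3,
                   59, 5, 16, 34, 9,
                   43, 29, 3, 9, 95)),
    trust0 = mk(c(35, 0, 0, 0, 1,
                  0, 20, 0, 2, 1,
                  0, 0, 25, 6, 1,
                  28, 1, 3, 14, 4,
                  11, 9, 1, 3, 37)),
    trust1 = mk(c(99, 1, 0, 6, 0,
                  0, 54, 0, 2, 0,
                  1, 1, 37, 8, 2,
                  31, 4, 13, 20, 5,
                  32, 20, 2, 6, 58)))
}

#' Empirical EHR race/ethnicity misclassification matrices
#'
#' Row-normalizes the observed cross-tabulation of EHR-recorded versus
#' self-reported race/ethnicity among the Vanderbilt University Medical
#' Center biobank-survey respondents, overall and stratified by the trust
#' outcome. Rows condition on the EHR-recorded category, so both returned
#' matrices are in `inverse` direction (`Pr(self-reported | EHR[, Y])`);
#' convert with [invert_direction()] or let the simulation pipeline do so
#' via its `matrix_interpretation` setting before generating recorded
#' labels.
#'
#' @return A list with elements `overall` (non-differential) and
#'   `stratified` (differential, matrices for outcome 0 and 1), each a
#'   [misclass_matrix()], plus `counts`, the embedded count tables.
#' @examples
#' m <- ehr_misclass_matrices()
#' round(m$overall$P["White", ], 3)
#' @export
ehr_misclass_matrices <- function() {
  cnt <- ehr_counts()
  rn <- function(M) M / rowSums(M)
  list(
    overall = misclass_matrix(P = rn(cnt$overall), direction = "inverse"),
    stratified = misclass_matrix(
      P_by_y = list("0" = rn(cnt$trust0), "1" = rn(cnt$trust1)),
      direction = "inverse"),
    counts = cnt)
}

#' Degree-parameterized misclassification matrix
#'
#' Builds a non-differential generator matrix whose diagonal is `1 - d`:
#' a unit keeps its label with probability `1 - d` and is misclassified
#' with probability `d`. Off-diagonal mass is split evenly over the
#' `H - 1` other categories (`pattern = "uniform"`) or proportionally to
#' the off-diagonal profile of the empirical EHR matrix's corresponding
#' row (`pattern = "table_proportional"`); empirical rows with zero
#' off-diagonal mass fall back to the uniform split.
#'
#' @param d Degree of misclassification in `[0, 1]`.
#' @param H Number of categories (`>= 2`); `table_proportional` requires
#'   `H = 5`.
#' @param pattern Off-diagonal allocation rule.
#' @return A generator-direction [misclass_matrix()].
#' @examples
#' degree_matrix(0.5, H = 5)$P[1, ]
#' @export
degree_matrix <- function(d, H = 5L, pattern = c("uniform", "table_proportional")) {
  pattern <- match.arg(pattern)
  if (length(d) != 1 || !is.finite(d) || d < 0 || d > 1)
    stop("`d` must be a single value in [0, 1]", call. = FALSE)
  if (H < 2) stop("`H` must be at least 2", call. = FALSE)
  P <- matrix(0, H, H)
  if (pattern == "uniform") {
    P[] <- d / (H - 1)
  } else {
    if (H != 5L)
      stop("pattern 'table_proportional' is defined for the 5-category empirical table",
           call. = FALSE)
    E <- ehr_misclass_matrices()$overall$P
    for (i in seq_len(H)) {
      off <- E[i, -i]
      P[i, -i] <- if (sum(off) > 0) d * off / sum(off) else d / (H - 1)
    }
  }
  diag(P) <- 1 - d
  misclass_matrix(P = P, direction = "generator")
}

#' Reverse the conditioning direction of a misclassification matrix
#'
#' Given rows `Pr(A = j | B = i)` and the marginal distribution of the
#' row-conditioning variable `B`, constructs the joint table and
#' re-conditions it the other way, returning rows `Pr(B = j | A = i)`.
#' Applying the function twice with consistent marginals recovers the
#' input. With a uniform `prior` this amounts to column-normalizing the
#' input matrix.
#'
#' For differential matrices the same prior is applied within each
#' outcome level (pass a list of two priors to differ by outcome).
#'
#' @param m A [misclass_matrix()].
#' @param prior Marginal probability vector of the row-conditioning
#'   variable (length `H`, strictly positive entries where the matrix has
#'   support), `"uniform"`, or for differential matrices optionally a
#'   list of two such vectors named `"0"` and `"1"`.
#' @return A [misclass_matrix()] with the opposite `direction`.
#' @examples
#' m <- ehr_misclass_matrices()$overall
#' g <- invert_direction(m)          # uniform prior over recorded categories
#' rowSums(g$P)
#' @export
invert_direction <- function(m, prior = "uniform") {
  stopifnot(inherits(m, "misclass_matrix"))
  H <- m$H
  norm_prior <- function(p) {
    if (identical(p, "uniform")) p <- rep(1 / H, H)
    if (length(p) != H || any(!is.finite(p)) || any(p < 0))
      stop("`prior` must be a nonnegative probability vector of length ", H,
           call. = FALSE)
    p / sum(p)
  }
  flip <- function(M, p) {
    joint <- M * p                       # joint[i, j] = Pr(B = i, A = j)
    colmass <- colSums(joint)            # marginal of A
    if (any(colmass <= 0))
      stop("degenerate inversion: target category with zero probability (",
           paste(which(colmass <= 0), collapse = ", "), ")", call. = FALSE)
    t(joint) / colmass                   # row i: Pr(B = j | A = i)
  }
  newdir <- if (m$direction == "generator") "inverse" else "generator"
  if (m$mode == "non_differential") {
    misclass_matrix(P = flip(m$P, norm_prior(prior)), direction = newdir,
                    labels = m$labels)
  } else {
    priors <- if (is.list(prior)) lapply(prior, norm_prior)
              else list("0" = norm_prior(prior), "1" = norm_prior(prior))
    misclass_matrix(
      P_by_y = list("0" = flip(m$P_by_y[["0"]], priors[["0"]]),
                    "1" = flip(m$P_by_y[["1"]], priors[["1"]])),
      direction = newdir, labels = m$labels)
  }
}

#' Turn a matrix into generator direction under an interpretation rule
#'
#' Published misclassification tables usually condition on the recorded
#' category (`inverse` direction), while simulating recorded labels needs
#' `Pr(recorded | true)`. Two readings are supported:
#' \describe{
#'   \item{`bayes_inverted`}{(default) Bayes inversion via
#'     [invert_direction()] with a prior over recorded categories
#'     (uniform unless given). This reading reproduces the published
#'     simulation results for the empirical EHR matrices.}
#'   \item{`direct`}{reuse the numbers as-is, re-reading row `i` as the
#'     true category; only the `direction` tag changes.}
#' }
#' Generator-direction input is returned unchanged.
#'
#' @param m A [misclass_matrix()].
#' @param interpretation `"bayes_inverted"` or `"direct"`.
#' @param prior Prior for `bayes_inverted`, see [invert_direction()].
#' @return A generator-direction [misclass_matrix()].
#' @export
as_generator <- function(m, interpretation = c("bayes_inverted", "direct"),
                         prior = "uniform") {
  stopifnot(inherits(m, "misclass_matrix"))
  interpretation <- match.arg(interpretation)
  if (m$direction == "generator") return(m)
  if (interpretation == "bayes_inverted") {
    invert_direction(m, prior)
  } else {
    if (m$mode == "non_differential")
      misclass_matrix(P = m$P, direction = "generator", labels = m$labels)
    else
      misclass_matrix(P_by_y = m$P_by_y, direction = "generator",
                      labels = m$labels)
  }
}

#' Apply a misclassification matrix to a population
#'
#' Draws the recorded category `X_star` independently for every unit from
#' the generator row of its true category `X` (non-differential) or from
#' the outcome-specific matrix's row (differential). The true labels,
#' covariate, and outcome are untouched — only the recorded label changes.
#'
#' @param pop A `population` (see [generate_population()]).
#' @param m A generator-direction [misclass_matrix()] with `H` matching
#'   the population. Inverse-direction matrices are refused: convert
#'   first with [as_generator()] or [invert_direction()].
#' @param seed Optional integer seed.
#' @return The population with `X_star` replaced.
#' @export
apply_misclassification <- function(pop, m, seed = NULL) {
  stopifnot(inherits(pop, "population"), inherits(m, "misclass_matrix"))
  if (m$direction != "generator")
    stop("matrix is in `inverse` direction (rows condition on the recorded ",
         "category); convert it with as_generator() or invert_direction() ",
         "before applying", call. = FALSE)
  H <- m$H
  if (any(pop$X < 1L | pop$X > H))
    stop("population contains categories absent from the matrix", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Xs <- integer(nrow(pop))
  if (m$mode == "non_differential") {
    for (h in seq_len(H)) {
      idx <- which(pop$X == h)
      if (length(idx))
        Xs[idx] <- sample.int(H, length(idx), replace = TRUE, prob = m$P[h, ])
    }
  } else {
    for (h in seq_len(H)) for (y in 0:1) {
      idx <- which(pop$X == h & pop$Y == y)
      if (length(idx))
        Xs[idx] <- sample.int(H, length(idx), replace = TRUE,
                              prob = m$P_by_y[[as.character(y)]][h, ])
    }
  }
  pop$X_star <- Xs
  pop
}

#' Write / read a misclassification matrix as CSV plus JSON descriptor
#'
#' Non-differential matrices go to a single `H x H` CSV (header = labels);
#' differential ones to two CSVs suffixed `_y0` / `_y1`. A one-line JSON
#' descriptor (same path, `.json`) records mode and direction.
#'
#' @param m A [misclass_matrix()].
#' @param path CSV file path (used as stem in differential mode).
#' @return `write_misclass_matrix()` returns `path` invisibly;
#'   `read_misclass_matrix()` returns a [misclass_matrix()].
#' @export
write_misclass_matrix <- function(m, path) {
  stopifnot(inherits(m, "misclass_matrix"))
  put <- function(M, p) {
    dimnames(M) <- list(NULL, m$labels)
    utils::write.csv(M, p, row.names = FALSE)
  }
  if (m$mode == "non_differential") {
    put(m$P, path)
  } else {
    put(m$P_by_y[["0"]], stem_path(path, "_y0"))
    put(m$P_by_y[["1"]], stem_path(path, "_y1"))
  }
  jsonlite::write_json(
    list(mode = m$mode, direction = m$direction, labels = m$labels),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_misclass_matrix
#' @export
read_misclass_matrix <- function(path) {
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  get <- function(p) as.matrix(utils::read.csv(p, check.names = FALSE))
  labels <- unlist(meta$labels)
  if (meta$mode == "non_differential") {
    misclass_matrix(P = get(path), direction = meta$direction, labels = labels)
  } else {
    misclass_matrix(
      P_by_y = list("0" = get(stem_path(path, "_y0")),
                    "1" = get(stem_path(path, "_y1"))),
      direction = meta$direction, labels = labels)
  }
}

stem_path <- function(path, suffix) sub("\\.csv$", paste0(suffix, ".csv"), path)
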