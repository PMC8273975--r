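#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximizes the (optionally weighted) Bernoulli log-likelihood
#' `sum_i w_i { y_i log p_i + (1 - y_i) log(1 - p_i) }` by IRLS. With all
#' weights equal this is ordinary maximum likelihood; with sampling
#' weights it is the design-based pseudo-likelihood, in which case the
#' reported model-based variance is not design-consistent — use
#' [variance_sandwich()].
#'
#' The iteration starts from the standard shrunken-mean values
#' `mu = (w y + 0.5) / (w + 1)` and stops when the relative deviance
#' change falls below `tol` or after `maxit` iterations, with
#' step-halving if a step fails to decrease the deviance. These choices
#' deliberately match the conventional GLM fitter, so that fits near
#' perfect separation stop at the same finite coefficient values a
#' standard analysis would report. Fits whose largest coefficient
#' magnitude exceeds 15 on the log-odds scale are flagged `separated`
#' (a diagnostic, not an error); fits that fail the deviance criterion
#' within `maxit` iterations are flagged `converged = FALSE`.
#'
#' @param y Binary response vector (0/1).
#' @param X Design matrix including the intercept column.
#' @param weights Optional positive sampling weights (default: all 1).
#' @param ci_level Wald confidence level (normal quantiles).
#' @param maxit Maximum IRLS iterations.
#' @param tol Relative deviance-change convergence tolerance.
#' @return An object of class `logit_fit`: `coefficients`, `vcov`
#'   (inverse observed information of the weighted log-likelihood),
#'   `se`, `ci_lower`, `ci_upper`, `fitted`, `log_likelihood`,
#'   `deviance`, `deviance_trace`, `converged`, `separated`, `n_iter`,
#'   `variance_method`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rbinom(200, 1, plogis(-0.5 + x))
#' f <- fit_logistic(y, cbind(1, x))
#' coef(f)
#' @export
fit_logistic <- function(y, X, weights = NULL, ci_level = 0.95,
                         maxit = 25L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) stop("`X` must have one row per observation", call. = FALSE)
  if (any(!(y %in% c(0, 1)))) stop("`y` must be coded 0/1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
    stop("`weights` must be positive and finite, one per observation",
         call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1L)))

  w <- weights
  mu <- (w * y + 0.5) / (w + 1)
  eta <- log(mu / (1 - mu))
  beta <- rep(0, k)
  dev <- bern_deviance(y, mu, w)
  trace <- dev
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    varmu <- mu * (1 - mu)
    good <- varmu > 1e-10
    if (!any(good)) break
    z <- eta[good] + (y[good] - mu[good]) / varmu[good]
    sw <- sqrt(w[good] * varmu[good])
    qrx <- qr(X[good, , drop = FALSE] * sw)
    if (qrx$rank < k) {
      co <- qr.coef(qrx, z * sw)
      stop("singular design matrix; offending column(s): ",
           paste(colnames(X)[is.na(co)], collapse = ", "), call. = FALSE)
    }
    beta_new <- qr.coef(qrx, z * sw)
    # step-halving keeps the deviance non-increasing across iterates; the
    # first step is taken unconditionally (the starting values are fitted
    # means, not a coefficient vector, so their deviance is not comparable)
    half <- 0L
    repeat {
      eta_new <- drop(X %*% beta_new)
      mu_new <- stats::plogis(eta_new)
      dev_new <- bern_deviance(y, mu_new, w)
      if (iter == 1L && is.finite(dev_new)) break
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      half <- half + 1L
      if (half > 30L) break
      beta_new <- (beta + beta_new) / 2
    }
    beta <- beta_new
    eta <- eta_new
    mu <- mu_new
    devold <- dev
    dev <- dev_new
    trace <- c(trace, dev)
    if (abs(dev - devold) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
  }
  names(beta) <- colnames(X)

  info <- crossprod(X, X * (w * mu * (1 - mu)))
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, k, k)
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(
    coefficients = beta,
    vcov = vc,
    se = se,
    ci_lower = beta - zq * se,
    ci_upper = beta + zq * se,
    ci_level = ci_level,
    fitted = mu,
    y = y,
    weights = w,
    log_likelihood = -dev / 2,
    deviance = dev,
    deviance_trace = trace,
    converged = converged,
    separated = max(abs(beta)) > 15,
    n_iter = iter,
    variance_method = "model_based_information"),
    class = "logit_fit")
}

# -2 * weighted Bernoulli log-likelihood, safe at fitted values of 0/1
bern_deviance <- function(y, mu, w) {
  mu <- pmin(pmax(mu, .Machine$double.xmin), 1 - .Machine$double.eps)
  -2 * sum(w * (y * log(mu) + (1 - y) * log1p(-mu)))
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic fit (", x$variance_method, ")\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se,
               ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(round(tab, 4))
  cat("log-likelihood:", format(x$log_likelihood), " iterations:", x$n_iter,
      " converged:", x$converged,
      if (x$separated) " [flagged: separation]" else "", "\n")
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' Model-based variance: inverse observed information
#'
#' Variance of the coefficient estimates as the inverse of the negative
#' Hessian of the (weighted) log-likelihood at the optimum,
#' `solve(t(X) W X)` with `W = w p (1 - p)`. Appropriate for maximum
#' likelihood under a correctly specified model with exchangeable units;
#' not design-consistent under informative weighting.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param X The design matrix used in the fit.
#' @param weights Weights used in the fit (default: those stored in
#'   `fit`).
#' @return Variance matrix.
#' @export
variance_model_based <- function(fit, X, weights = NULL) {
  stopifnot(inherits(fit, "logit_fit"))
  if (is.null(weights)) weights <- fit$weights
  p <- fit$fitted
  info <- crossprod(X, X * (weights * p * (1 - p)))
  vc <- tryCatch(chol2inv(chol(info)),
                 error = function(e) stop("singular information matrix",
                                          call. = FALSE))
  dimnames(vc) <- list(names(fit$coefficients), names(fit$coefficients))
  vc
}

#' Linearization (sandwich) variance for weighted pseudo-likelihood fits
#'
#' `A^{-1} B A^{-1}` with `A` the negative Hessian of the weighted
#' log-likelihood and `B` the variability of the weighted score
#' contributions `u_i = w_i (y_i - p_i) x_i`. The default unstratified
#' form takes `B = sum_i u_i u_i'` (independent weighted units,
#' with-replacement approximation, no finite-population correction).
#' With `strata`, scores are centered within stratum and the
#' with-replacement factor `n_h / (n_h - 1)` applied.
#'
#' The result is invariant to rescaling all weights by a constant.
#'
#' @param fit A converged weighted [fit_logistic()] result.
#' @param X The design matrix used in the fit.
#' @param weights Sampling weights (default: those stored in `fit`).
#' @param strata Optional stratum labels for the stratified form.
#' @return Variance matrix.
#' @export
variance_sandwich <- function(fit, X, weights = NULL, strata = NULL) {
  stopifnot(inherits(fit, "logit_fit"))
  if (is.null(weights)) weights <- fit$weights
  p <- fit$fitted
  A <- crossprod(X, X * (weights * p * (1 - p)))
  u <- X * (weights * (fit$y - p))
  if (is.null(strata)) {
    B <- crossprod(u)
  } else {
    B <- matrix(0, ncol(X), ncol(X))
    for (h in unique(strata)) {
      uh <- u[strata == h, , drop = FALSE]
      nh <- nrow(uh)
      if (nh < 2)
        stop("stratum ", h, " has a single sampled unit; the stratified ",
             "variance is undefined — use the unstratified form", call. = FALSE)
      uc <- sweep(uh, 2, colMeans(uh))
      B <- B + crossprod(uc) * nh / (nh - 1)
    }
  }
  Ainv <- tryCatch(chol2inv(chol(A)),
                   error = function(e) stop("singular information matrix",
                                            call. = FALSE))
  vc <- Ainv %*% B %*% Ainv
  dimnames(vc) <- list(names(fit$coefficients), names(fit$coefficients))
  vc
}

#' Analysis-strategy specification
#'
#' The three strategies for regressing the outcome on the true category
#' dummies (reference = category 1) plus the non-sampling covariate:
#' \describe{
#'   \item{`design_agnostic`}{plain unweighted logistic regression,
#'     ignoring the design.}
#'   \item{`model_based`}{unweighted, adding the recorded-category
#'     dummies as covariates to absorb the design.}
#'   \item{`design_based`}{weighted pseudo-likelihood with the sampling
#'     weights and linearization (sandwich) variance.}
#' }
#'
#' @param method One of the three strategies.
#' @param ci_level Wald confidence level.
#' @param variance Sandwich form for `design_based`: `"unstratified"`
#'   (default) or `"stratified"` (within-stratum centering).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method = c("design_agnostic", "model_based", "design_based"),
                       ci_level = 0.95,
                       variance = c("unstratified", "stratified")) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  structure(list(method = method, ci_level = ci_level,
                 use_weights = method == "design_based",
                 strata_covariate = method == "model_based",
                 variance = variance),
            class = "model_spec")
}

# 0/1 dummy columns for categories 2..H, named after the labels
dummy_cols <- function(v, H, labels, suffix = "") {
  n <- length(v)
  M <- matrix(0, n, H - 1L)
  hit <- v > 1L
  M[cbind(which(hit), v[hit] - 1L)] <- 1
  colnames(M) <- paste0(labels[-1L], suffix)
  M
}

#' Fit one analysis strategy to a sample or a full population
#'
#' Assembles the design matrix for the given [model_spec()] — intercept,
#' true-category dummies, the low-income covariate, and for the
#' model-based strategy the recorded-category dummies — and fits it with
#' [fit_logistic()]. The design-based strategy requires a weighted
#' [survey_sample] and replaces the model-based variance with
#' [variance_sandwich()]. Recorded-category dummies for categories absent
#' from the sample are dropped (with a message) to preserve rank.
#'
#' @param data A [survey_sample] or `population`.
#' @param spec A [model_spec()].
#' @return A `logit_fit` with attribute `method`.
#' @export
fit_method <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!inherits(data, "survey_sample") && !inherits(data, "population"))
    stop("`data` must be a survey_sample or a population", call. = FALSE)
  labels <- attr(data, "labels")
  H <- length(labels)
  n <- nrow(data)
  Xd <- cbind("(Intercept)" = rep(1, n),
              dummy_cols(data$X, H, labels),
              low_income = data$low_income)
  if (spec$strata_covariate) {
    S <- dummy_cols(data$X_star, H, labels, suffix = "_recorded")
    absent <- colSums(S) == 0
    if (any(absent)) {
      message("dropping recorded-category dummies absent from the sample: ",
              paste(colnames(S)[absent], collapse = ", "))
      S <- S[, !absent, drop = FALSE]
    }
    Xd <- cbind(Xd, S)
  }
  w <- NULL
  if (spec$use_weights) {
    if (is.null(data$weight))
      stop("design_based analysis requires sampling weights", call. = FALSE)
    w <- data$weight
  }
  fit <- fit_logistic(data$Y, Xd, weights = w, ci_level = spec$ci_level)
  if (spec$method == "design_based") {
    strata <- if (spec$variance == "stratified") data$stratum else NULL
    vc <- variance_sandwich(fit, Xd, w, strata = strata)
    fit$vcov <- vc
    fit$se <- sqrt(diag(vc))
    zq <- stats::qnorm(1 - (1 - spec$ci_level) / 2)
    fit$ci_lower <- fit$coefficients - zq * fit$se
    fit$ci_upper <- fit$coefficients + zq * fit$se
    fit$variance_method <- "sandwich"
  }
  attr(fit, "method") <- spec$method
  fit
}

#' Serialize a fit to JSON or a long CSV-ready data.frame
#'
#' @param fit A `logit_fit`.
#' @param scenario,method Optional identifiers carried into the rows.
#' @return `fit_to_frame()` returns a data.frame with one row per
#'   parameter; `write_fit_json()` writes the whole fit to `path`.
#' @export
fit_to_frame <- function(fit, scenario = NA_character_, method = NA_character_) {
  stopifnot(inherits(fit, "logit_fit"))
  data.frame(scenario = scenario, method = method,
             parameter = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(fit$se),
             ci_lower = unname(fit$ci_lower), ci_upper = unname(fit$ci_upper),
             converged = fit$converged)
}

#' @rdname fit_to_frame
#' @param path JSON file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "logit_fit"))
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         se = as.list(stats::setNames(fit$se, names(fit$coefficients))),
         ci_level = fit$ci_level,
         ci_lower = as.list(stats::setNames(fit$ci_lower, names(fit$coefficients))),
         ci_upper = as.list(stats::setNames(fit$ci_upper, names(fit$coefficients))),
         log_likelihood = fit$log_likelihood,
         converged = fit$converged, separated = fit$separated,
         n_iter = fit$n_iter, variance_method = fit$variance_method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
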