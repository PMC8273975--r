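# Shared fixtures for the suite. Everything is generated in code.

small_config <- function(N = 5000) pop_config(N = N)

# less extreme category prevalences for tiny-sample tests, so no category
# vanishes from a small draw
balanced_config <- function(N = 5000)
  pop_config(N = N, race_probs = c(0.40, 0.20, 0.15, 0.15, 0.10))

# a deterministic 2x2-cell dataset: y ~ binary x with cell counts
# (y1x1, y0x1, y1x0, y0x0)
cells_2x2 <- function(a, b, c, d) {
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  x <- c(rep(1, a + b), rep(0, c + d))
  list(y = y, X = cbind("(Intercept)" = 1, x = x))
}

# brute-force weighted Bernoulli log-likelihood maximizer (independent of
# the IRLS path): BFGS on the negative log-likelihood with tight tolerance
brute_force_logit <- function(y, X, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(weights * (y * eta - log1p(exp(eta))))
  }
  gr <- function(b) {
    p <- plogis(drop(X %*% b))
    -drop(crossprod(X, weights * (y - p)))
  }
  o <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-15))
  o$par
}

# one small weighted survey-like dataset reused by estimator tests
weighted_fixture <- function() {
  set.seed(77)
  n <- 40
  x1 <- round(rnorm(n), 6)
  x2 <- rep(0:1, each = 20)
  w <- round(runif(n, 1, 5), 6)
  y <- rbinom(n, 1, plogis(-0.2 + 0.7 * x1 - 0.4 * x2))
  list(y = y, X = cbind("(Intercept)" = 1, x1 = x1, x2 = x2), w = w)
}

# Independent survey-GLM reference for the unstratified sandwich variance
# of the weighted_fixture() fit, computed once with sandwich::sandwich()
# on a quasibinomial glm and frozen. (The reference derives its bread from
# the GLM's internal penultimate-iteration weights, hence the comparison
# tolerance of a few 1e-5 relative.)
frozen_sandwich_reference <- function() {
  matrix(c(0.271483864527, -0.0397329860176, -0.256379673354,
           -0.0397329860176, 0.185379139445, -0.0126698380929,
           -0.256379673354, -0.0126698380929, 0.510071757563),
         3, 3, byrow = TRUE)
}
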