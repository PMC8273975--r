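test_that("saturated 2x2 fits match the closed-form log odds", {
  d <- cells_2x2(30, 10, 20, 40)
  f <- fit_logistic(d$y, d$X)
  expect_true(f$converged)
  expect_equal(unname(coef(f)["x"]), log(6), tolerance = 1e-7)
  expect_equal(unname(coef(f)["(Intercept)"]), log(20 / 40), tolerance = 1e-7)
  # and agree with the brute-force likelihood maximizer
  bf <- brute_force_logit(d$y, d$X)
  expect_equal(unname(coef(f)), bf, tolerance = 1e-6)
})

test_that("a covariate independent of a balanced outcome gets coefficient zero", {
  # equal 2x2 cell counts: perfect balance
  d <- cells_2x2(25, 25, 25, 25)
  f <- fit_logistic(d$y, d$X)
  expect_equal(unname(coef(f)["x"]), 0, tolerance = 1e-10)
})

test_that("IRLS equals a brute-force optimizer on small instances", {
  for (s in 1:4) {
    set.seed(400 + s)
    n <- sample(40:200, 1)
    X <- cbind("(Intercept)" = 1, a = rnorm(n), b = rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, plogis(drop(X %*% c(-0.4, 0.9, -0.7))))
    w <- if (s %% 2) NULL else runif(n, 0.5, 4)
    f <- fit_logistic(y, X, weights = w)
    bf <- brute_force_logit(y, X, weights = w)
    expect_equal(unname(coef(f)), bf, tolerance = 1e-6)
  }
})

test_that("constant weights leave the fit unchanged and rescaling leaves the sandwich unchanged", {
  fx <- weighted_fixture()
  f0 <- fit_logistic(fx$y, fx$X, tol = 1e-13)
  fc <- fit_logistic(fx$y, fx$X, weights = rep(3.7, length(fx$y)), tol = 1e-13)
  expect_equal(coef(fc), coef(f0), tolerance = 1e-10)
  fw <- fit_logistic(fx$y, fx$X, weights = fx$w)
  V1 <- variance_sandwich(fw, fx$X, fx$w)
  V2 <- variance_sandwich(fw, fx$X, fx$w * 11)   # A scales by c, B by c^2
  expect_equal(V1, V2, tolerance = 1e-12)
  # and a full refit at the rescaled weights reaches the same answer
  fw2 <- fit_logistic(fx$y, fx$X, weights = fx$w * 11, tol = 1e-13)
  expect_equal(coef(fw2), coef(fw), tolerance = 1e-7)
})

test_that("the sandwich variance matches the frozen survey-GLM reference", {
  fx <- weighted_fixture()
  fw <- fit_logistic(fx$y, fx$X, weights = fx$w)
  V <- variance_sandwich(fw, fx$X, fx$w)
  expect_equal(unname(V), unname(frozen_sandwich_reference()),
               tolerance = 5e-4)
})

test_that("model-based variance is the inverse information", {
  # intercept-only: Var = 1 / (n p (1 - p))
  y <- c(rep(1, 30), rep(0, 70))
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_logistic(y, X)
  expect_equal(unname(f$vcov[1, 1]), 1 / (100 * 0.3 * 0.7), tolerance = 1e-7)
  # stacking the data twice halves every variance
  f2 <- fit_logistic(c(y, y), rbind(X, X))
  expect_equal(unname(f2$vcov[1, 1]), unname(f$vcov[1, 1]) / 2,
               tolerance = 1e-7)
  # and matches a finite-difference Hessian of the log-likelihood
  fx <- weighted_fixture()
  fw <- fit_logistic(fx$y, fx$X, weights = fx$w)
  V <- variance_model_based(fw, fx$X, fx$w)
  ll <- function(b) {
    eta <- drop(fx$X %*% b)
    sum(fx$w * (fx$y * eta - log1p(exp(eta))))
  }
  k <- ncol(fx$X); eps <- 1e-4; b0 <- coef(fw)
  Hn <- matrix(NA_real_, k, k)
  for (i in 1:k) for (j in 1:k) {
    ei <- ej <- rep(0, k); ei[i] <- eps; ej[j] <- eps
    Hn[i, j] <- (ll(b0 + ei + ej) - ll(b0 + ei - ej) -
                   ll(b0 - ei + ej) + ll(b0 - ei - ej)) / (4 * eps^2)
  }
  expect_equal(unname(V), unname(solve(-Hn)), tolerance = 1e-6)
})

test_that("Wald interval width is exactly twice the normal quantile times the SE", {
  fx <- weighted_fixture()
  f <- fit_logistic(fx$y, fx$X, ci_level = 0.95)
  expect_equal(unname(f$ci_upper - f$ci_lower),
               unname(2 * qnorm(0.975) * f$se), tolerance = 1e-12)
  f90 <- fit_logistic(fx$y, fx$X, ci_level = 0.90)
  expect_equal(unname(f90$ci_upper - f90$ci_lower),
               unname(2 * qnorm(0.95) * f90$se), tolerance = 1e-12)
})

test_that("the deviance is non-increasing across IRLS iterations", {
  for (s in 1:3) {
    set.seed(500 + s)
    n <- 150
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rbinom(n, 1, plogis(drop(X %*% c(0.2, -1.5, 2))))
    f <- fit_logistic(y, X)
    tr <- f$deviance_trace[-1]  # drop the starting-value deviance
    expect_true(all(diff(tr) <= 1e-10))
  }
})

test_that("rank deficiency raises an error naming the offending column", {
  set.seed(600)
  n <- 80
  x <- rnorm(n)
  X <- cbind("(Intercept)" = 1, good = x, copy = x)
  y <- rbinom(n, 1, plogis(x))
  expect_error(fit_logistic(y, X), "copy")
})

test_that("separation is flagged but reported like a standard fitter", {
  # a rare category with only zero outcomes: the coefficient diverges and
  # the fit must stop where the conventional GLM fitter stops
  set.seed(601)
  n <- 400
  g <- c(rep(0, 360), rep(1, 40))
  y <- ifelse(g == 1, 0, rbinom(n, 1, 0.4))
  X <- cbind("(Intercept)" = 1, g = g)
  f <- fit_logistic(y, X)
  gl <- suppressWarnings(glm(y ~ g, binomial))
  expect_equal(unname(coef(f)), unname(coef(gl)), tolerance = 1e-6)
  expect_true(f$separated)
  expect_lt(coef(f)["g"], -10)
})

test_that("IRLS agrees with glm on ordinary and weighted fits", {
  fx <- weighted_fixture()
  f <- fit_logistic(fx$y, fx$X, weights = fx$w)
  gl <- suppressWarnings(glm(fx$y ~ fx$X[, -1], quasibinomial, weights = fx$w))
  expect_equal(unname(coef(f)), unname(coef(gl)), tolerance = 1e-9)
})

test_that("strategy fits assemble the documented design matrices", {
  pop <- generate_population(small_config(N = 20000), seed = 40)
  G <- as_generator(ehr_misclass_matrices()$overall)
  pop <- apply_misclassification(pop, G, seed = 41)
  s <- draw_dss(pop, 200, seed = 42)
  f1 <- fit_method(s, model_spec("design_agnostic"))
  f2 <- fit_method(s, model_spec("model_based"))
  f3 <- fit_method(s, model_spec("design_based"))
  expect_named(coef(f1), c("(Intercept)", "Black", "Asian", "Other",
                           "Hispanic", "low_income"))
  expect_true(all(c("Black_recorded", "Hispanic_recorded") %in% names(coef(f2))))
  expect_identical(f3$variance_method, "sandwich")
  expect_identical(f1$variance_method, "model_based_information")
  # a self-weighting sample: design-based point estimates equal design-agnostic
  srs <- draw_srs(pop, 1500, seed = 43)
  fa <- fit_method(srs, model_spec("design_agnostic"))
  fb <- fit_method(srs, model_spec("design_based"))
  expect_equal(coef(fa), coef(fb), tolerance = 1e-9)
})

test_that("recorded-category dummies absent from the sample are dropped", {
  pop <- generate_population(small_config(N = 5000), seed = 44)
  # force every recorded label to White
  pop$X_star <- rep(1L, nrow(pop))
  pop$X_star[1:10] <- 2L
  s <- suppressWarnings(draw_dss(pop, c(200, 10, 1, 1, 1), seed = 45))
  expect_message(f <- fit_method(s, model_spec("model_based")), "dropping")
  expect_false("Asian_recorded" %in% names(coef(f)))
})

test_that("stratified sandwich centers scores within strata", {
  pop <- generate_population(small_config(N = 20000), seed = 46)
  G <- as_generator(ehr_misclass_matrices()$overall)
  pop <- apply_misclassification(pop, G, seed = 47)
  s <- draw_dss(pop, 200, seed = 48)
  f <- fit_method(s, model_spec("design_based"))
  Xd <- cbind("(Intercept)" = 1, misclassdss:::dummy_cols(s$X, 5, attr(s, "labels")),
              low_income = s$low_income)
  V_unstrat <- variance_sandwich(f, Xd, s$weight)
  V_strat <- variance_sandwich(f, Xd, s$weight, strata = s$stratum)
  expect_false(isTRUE(all.equal(V_unstrat, V_strat)))
  expect_true(all(diag(V_strat) > 0))
  # a single-unit stratum is refused
  expect_error(variance_sandwich(f, Xd, s$weight,
                                 strata = c(99, s$stratum[-1])),
               "single sampled unit")
})

test_that("fits serialize to frame and JSON", {
  fx <- weighted_fixture()
  f <- fit_logistic(fx$y, fx$X)
  fr <- fit_to_frame(f, scenario = "s", method = "design_agnostic")
  expect_equal(nrow(fr), 3)
  expect_named(fr, c("scenario", "method", "parameter", "estimate", "se",
                     "ci_lower", "ci_upper", "converged"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$coefficients$x1, unname(coef(f)["x1"]), tolerance = 1e-12)
})
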