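test_that("linear predictor reduces to closed forms", {
  des <- toy_design(matrix(1, 5, 1), 1)
  f <- list(beta0 = 0, beta = 3, weights = 2, covariate_coefs = numeric(0),
            family = "gaussian", lambda_g = 0, lambda_p = 0)
  expect_equal(predict(structure(c(f, list(design = des)),
                                 class = "hiscom")),
               rep(6, 5))

  # all weights zero: eta = intercept + covariates
  desX <- toy_design(matrix(rnorm(20), 10, 2), c(1, 2),
                     covariates = matrix(1:10, 10, 1))
  f0 <- structure(list(beta0 = 1.5, beta = c(2, 3), weights = c(0, 0),
                       covariate_coefs = 0.5, family = "gaussian",
                       design = desX), class = "hiscom")
  expect_equal(predict(f0), 1.5 + 0.5 * (1:10))

  # bilinear invariance: (cw, beta/c) leaves eta unchanged
  set.seed(2)
  des2 <- random_design(30, 2, 3, seed = 2)
  f1 <- hiscom(des2, rnorm(30), "gaussian", 1, 1)
  f2 <- f1
  f2$weights <- f1$weights * 4
  f2$beta <- f1$beta / 4
  expect_equal(predict(f1), predict(f2), tolerance = 1e-12)
})

test_that("penalized log-likelihood matches closed-form anchors", {
  set.seed(7)
  n <- 40
  des <- random_design(n, 2, 2, seed = 7)
  y <- rbinom(n, 1, 0.4)
  ybar <- mean(y)
  fit0 <- list(beta0 = qlogis(ybar), beta = c(0, 0), weights = rep(0, 4),
               covariate_coefs = numeric(0), family = "binomial",
               lambda_g = 0, lambda_p = 0, y = y)
  expect_equal(penalized_loglik(des, fit0),
               n * (ybar * log(ybar) + (1 - ybar) * log(1 - ybar)))

  # unit increase in lambda_p with ||beta||^2 = 4 lowers phi by exactly 2
  fitb <- within(fit0, {beta <- c(2, 0); lambda_p <- 1})
  expect_equal(penalized_loglik(des, within(fitb, lambda_p <- 2)) -
                 penalized_loglik(des, fitb), -2)

  # gaussian perfect fit at unit dispersion
  yg <- rnorm(n)
  desg <- toy_design(matrix(yg, ncol = 1), 1)
  fitg <- list(beta0 = 0, beta = 1, weights = 1,
               covariate_coefs = numeric(0), family = "gaussian",
               lambda_g = 0, lambda_p = 0, y = yg)
  expect_equal(penalized_loglik(desg, fitg), -(n / 2) * log(2 * pi))
})

test_that("single-component fits match unpenalized GLM slopes", {
  set.seed(14)
  z <- rnorm(90)
  des <- toy_design(matrix(z, ncol = 1), 1)
  y <- 0.8 * z + rnorm(90)
  f <- hiscom(des, y, "gaussian", lambda_g = 0, lambda_p = 0)
  ols <- lm(y ~ z)
  expect_equal(unname(f$weights * f$beta), unname(coef(ols)[2]),
               tolerance = 1e-6)
  # phi equals the OLS log-likelihood at the residual-mean-square scale
  expect_equal(penalized_loglik(des, f, dispersion = f$dispersion),
               as.numeric(logLik(ols)), tolerance = 1e-4)

  yb <- rbinom(90, 1, plogis(z))
  fb <- hiscom(des, yb, "binomial", lambda_g = 0, lambda_p = 0, tol = 1e-8)
  ref <- glm(yb ~ z, family = binomial)
  expect_equal(unname(fb$weights * fb$beta), unname(coef(ref)[2]),
               tolerance = 1e-4)
})

test_that("the ALS objective is monotone over half-steps", {
  for (s in 1:8) {
    des <- random_design(n = 100, K = 3, genes_per_pathway = 3, seed = s)
    set.seed(s + 100)
    y <- drop(des$Z %*% rnorm(9, 0, 0.3)) + rnorm(100)
    f <- suppressWarnings(hiscom(des, y, "gaussian", 0.5, 0.5))
    expect_gt(min(diff(f$objective_trace)), -1e-8)
    fb <- suppressWarnings(
      hiscom(des, as.integer(y > 0), "binomial", 0.5, 0.5))
    expect_gt(min(diff(fb$objective_trace)), -1e-6)
    expect_gte(tail(fb$objective_trace, 1), fb$objective_trace[1])
  }
})

test_that("heavy pathway penalty drives beta to zero", {
  des <- random_design(60, 2, 3, seed = 3)
  set.seed(42)
  y <- rnorm(60) + des$Z[, 1]
  f <- hiscom(des, y, "gaussian", lambda_g = 1, lambda_p = 1e8)
  expect_lt(sqrt(sum(f$beta^2)), 1e-3)
  expect_lt(max(abs(predict(f) - mean(y))), 0.05)
})

test_that("pathway-effect shrinkage is monotone in lambda_p at fixed weights", {
  des <- random_design(120, 3, 3, seed = 8)
  set.seed(8)
  y <- drop(des$Z %*% rnorm(9, 0, 0.4)) + rnorm(120)
  base <- suppressWarnings(hiscom(des, y, "gaussian", 1, 1))
  S <- pathway_scores(base)
  M <- cbind(1, S)
  norms <- vapply(c(0.1, 1, 10, 100), function(lp) {
    A <- crossprod(M) + diag(c(0, rep(lp, ncol(S))))
    sum(solve(A, crossprod(M, y))[-1]^2)
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("initialization follows the stated conventions", {
  des <- toy_design(matrix(rnorm(40), 10, 4), rep(1, 4))
  ini <- hiscom_init(des, rnorm(10), "gaussian")
  expect_equal(ini$w, rep(0.5, 4))          # block of 4 PCs
  expect_equal(ini$beta, 0)

  y <- c(rep(1, 5), rep(0, 15))
  ini2 <- hiscom_init(des, y, "binomial")
  expect_equal(ini2$beta0, log(1 / 3))      # mean 0.25

  set.seed(1)
  y2 <- rnorm(10)
  fa <- hiscom(des, y2, "gaussian", 1, 1, init = "random", seed = 77)
  fb <- hiscom(des, y2, "gaussian", 1, 1, init = "random", seed = 77)
  expect_identical(coef(fa, "all"), coef(fb, "all"))
})

test_that("sign convention and pure-function contract hold", {
  des <- random_design(80, 3, 4, seed = 12)
  set.seed(12)
  y <- rnorm(80) + drop(des$Z %*% rnorm(12, 0, 0.3))
  f <- hiscom(des, y, "gaussian", 1, 1)
  for (k in 1:3) {
    wk <- f$weights[f$design$index$k == k]
    expect_gt(wk[which.max(abs(wk))], 0)
  }
  # refitting with permuted y must not alter the design object
  des_before <- unserialize(serialize(des, NULL))
  invisible(hiscom(des, sample(y), "gaussian", 1, 1))
  expect_identical(des, des_before)
})

test_that("model methods are mutually consistent", {
  des <- random_design(70, 2, 3, seed = 19, covariates = 2)
  set.seed(19)
  y <- rnorm(70) + drop(des$Z %*% rnorm(6, 0, 0.5))
  f <- hiscom(des, y, "gaussian", 1, 1)
  expect_equal(residuals(f), y - fitted(f))
  expect_s3_class(summary(f), "summary.hiscom")
  expect_equal(nrow(summary(f)$pathways), 2)
  expect_length(coef(f, "covariates"), 2)
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(70L, 3L))
  ll <- logLik(f)
  expect_true(is.finite(as.numeric(ll)))

  yb <- as.integer(y > median(y))
  fbin <- hiscom(des, yb, "binomial", 1, 1)
  mu <- predict(fbin, type = "response")
  expect_true(all(mu > 0 & mu < 1))
  expect_equal(predict(fbin, type = "link"), qlogis(mu))
})
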