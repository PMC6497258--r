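test_that("imputation fills missing spread with a 20% CV and n = 1", {
  d <- summary_dataset(c(1, 2, 3), c(10, 5, -4),
                       sd = c(NA, 1, NA), n = c(NA, 12L, 3L))
  out <- impute_summary(d)
  expect_equal(out$sd, c(2.0, 1, 0.8))
  expect_equal(out$n, c(1L, 12L, 3L))
  expect_equal(out$imputed_sd, c(TRUE, FALSE, TRUE))
  expect_equal(out$imputed_n, c(TRUE, FALSE, FALSE))

  zero <- summary_dataset(1, 0)
  expect_error(impute_summary(zero), "degenerate")
})

test_that("summary log-likelihood matches a raw-observation Gaussian likelihood", {
  # single on-curve point with unit SD: only the normalizing constant
  d1 <- summary_dataset(5, 10, sd = 1, n = 1L)
  spec <- model_spec("linear", c(0, 2))      # y(5) = 10, zero residual
  expect_equal(summary_loglik(spec, d1), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  # sufficiency: records with n > 1 reproduce the likelihood of raw
  # observations with exactly that sample mean and SD
  set.seed(7)
  cov <- c(4, 9, 16)
  mns <- c(8.3, 17.5, 33.0); sds <- c(1.2, 2.5, 3.1); ns <- c(4L, 6L, 9L)
  d <- summary_dataset(cov, mns, sd = sds, n = ns)
  spec2 <- model_spec("linear", c(0.5, 2))
  ll_raw <- 0
  for (i in 1:3) {
    obs <- raw_obs(mns[i], sds[i], ns[i])
    expect_equal(mean(obs), mns[i], tolerance = 1e-12)
    expect_equal(sd(obs), sds[i], tolerance = 1e-12)
    ll_raw <- ll_raw + sum(dnorm(obs, evaluate_model(spec2, cov[i]),
                                 sds[i], log = TRUE))
  }
  expect_equal(summary_loglik(spec2, d), ll_raw, tolerance = 1e-10)

  # for n = 1 everywhere, exp(loglik) is the product of Gaussian densities
  d3 <- impute_summary(summary_dataset(c(1, 2), c(3, 5)))
  spec3 <- model_spec("linear", c(1, 1.8))
  expect_equal(exp(summary_loglik(spec3, d3)),
               prod(dnorm(d3$mean, evaluate_model(spec3, d3$covariate),
                          d3$sd)), tolerance = 1e-12)
})

test_that("log-likelihood decreases monotonically with the residual", {
  d <- summary_dataset(1, 10, sd = 2, n = 5L)
  lls <- sapply(c(0, 0.5, 1, 2, 4), function(shift)
    summary_loglik(model_spec("linear", c(10 + shift, 0)), d))
  expect_true(all(diff(lls) < 0))
})

test_that("the AIC identity is exact for fits and for reported scores", {
  # reference (k, loglik) pairs from published model-comparison tables
  mk_fit <- function(k, ll) structure(
    list(spec = model_spec("logistic", c(1, 1, 1)), loglik = ll,
         k = k, aic = 2 * k - 2 * ll, converged = TRUE,
         n_starts = 1L, seed = 1L), class = "fit_result")
  expect_equal(aic_score(mk_fit(3L, -739.00)), 1484.00)
  expect_equal(aic_score(mk_fit(3L, -1059.02)), 2124.04)
  expect_equal(aic_score(mk_fit(2L, 0)), 4)

  d <- impute_summary(summary_dataset(1:6, 2 * (1:6) + 1, sd = 0.5, n = 3L))
  f <- fit_mle("linear", d, seed = 1)
  expect_identical(f$aic, 2 * f$k - 2 * f$loglik)
  expect_equal(AIC(f), f$aic)                 # through the logLik method
})

test_that("noiseless data are recovered exactly", {
  t <- 1:10
  d <- summary_dataset(t, 2 * t, sd = 0.2 * 2 * t, n = 1L)
  f <- fit_mle("linear_growth", d, seed = 1)
  expect_equal(f$spec$theta, 2, tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("the optimizer agrees with an exhaustive grid search", {
  # 2-parameter family on 5 points; brute-force 201 x 201 grid around truth
  truth <- c(1.5, 0.08)
  t <- c(5, 12, 20, 30, 40)
  y <- truth[1] * t + truth[2] * t^2
  d <- summary_dataset(t, y * c(1.03, 0.97, 1.02, 0.99, 1.01),
                       sd = 0.05 * y, n = 1L)
  f <- fit_mle("quadratic_growth", d, seed = 1)
  g0 <- seq(truth[1] - 0.5, truth[1] + 0.5, length.out = 201)
  g1 <- seq(truth[2] - 0.05, truth[2] + 0.05, length.out = 201)
  di <- impute_summary(d)
  ll <- outer(g0, g1, Vectorize(function(a, b)
    summary_loglik(model_spec("quadratic_growth", c(a, b)), di)))
  best <- arrayInd(which.max(ll), dim(ll))
  cell <- c(diff(g0)[1], diff(g1)[1])
  expect_lt(abs(f$spec$theta[1] - g0[best[1]]), cell[1])
  expect_lt(abs(f$spec$theta[2] - g1[best[2]]), cell[2])
  expect_gte(f$loglik, max(ll))               # MLE at least as good as grid
})

test_that("likelihood terms free of theta do not move the optimum", {
  spec <- model_spec("gompertz", ref_gompertz)
  d <- impute_summary(generate_summary_dataset(spec, sampling_design(seed = 9)))
  f <- fit_mle("gompertz", d, seed = 9, n_starts = 5)
  # minimizing the pure weighted sum of squares from the MLE does not move it
  wss <- function(th) {
    y <- evaluate_model(model_spec("gompertz", th), d$covariate)
    sum(d$n * (d$mean - y)^2 / d$sd^2)
  }
  o <- optim(f$spec$theta, wss, method = "BFGS")
  expect_lt((wss(f$spec$theta) - o$value) / wss(f$spec$theta), 1e-5)
  expect_equal(o$par, f$spec$theta, tolerance = 1e-3)
})

test_that("shifting covariates shifts a linear fit without changing its likelihood", {
  t <- 1:8
  m <- 3 + 0.7 * t + c(0.1, -0.2, 0.05, 0, -0.1, 0.2, -0.05, 0.1)
  d1 <- summary_dataset(t, m, sd = 0.3, n = 2L)
  d2 <- summary_dataset(t + 5, m, sd = 0.3, n = 2L)
  f1 <- fit_mle("linear", d1, seed = 1)
  f2 <- fit_mle("linear", d2, seed = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_equal(f2$spec$theta[1], f1$spec$theta[1] - 5 * f1$spec$theta[2],
               tolerance = 1e-8)
  expect_equal(f2$spec$theta[2], f1$spec$theta[2], tolerance = 1e-9)
})

test_that("selection screens out low-AIC models that go negative", {
  mk_fit <- function(family, theta, aic, covariate = "age_weeks")
    structure(list(spec = model_spec(family, theta, covariate = covariate),
                   loglik = (2 * family_k(family) - aic) / 2,
                   k = family_k(family), aic = aic, converged = TRUE,
                   n_starts = 1L, seed = 1L), class = "fit_result")
  # fetal-brain-like scenario: the cubic growth curve has the lowest AIC
  # but dips negative early; the Gompertz curve is next and feasible
  cubic <- mk_fit("cubic_growth", c(-2.1208, 0.15645, 0.0034746), 21861.4)
  gomp <- mk_fit("gompertz", c(0.01574, 0.70707, 0.064827), 21893.5)
  sel <- select_model(list(cubic, gomp))
  expect_identical(sel$preferred, "gompertz")
  expect_identical(sel$rationale, "lowest_nonneg_aic")
  expect_identical(sel$screened_out$family, "cubic_growth")

  # all candidates nonnegative: plain argmin of AIC
  lin <- mk_fit("linear", c(1, 0.1), 100)
  quad <- mk_fit("quadratic", c(1, 0.1, 0.01), 90)
  sel2 <- select_model(list(lin, quad))
  expect_identical(sel2$preferred, "quadratic")
  expect_identical(sel2$rationale, "lowest_aic")

  # near-tied AICs: the age-based covariate wins over the mass-based one
  mlp <- mk_fit("modified_luecke_power_law", c(1.165, 0.14125, -0.083058,
                                               2.5002), 365.07, "body_mass")
  mlog <- mk_fit("modified_logistic", c(1.2406, 0.31338, 17.813, 2.4958),
                 365.13)
  sel3 <- select_model(list(mlp, mlog))
  expect_identical(sel3$preferred, "modified_logistic")
  expect_identical(sel3$rationale, "tiebreak")

  # every candidate infeasible is an explicit error
  neg <- mk_fit("linear", c(-5, 0.01), 50)
  expect_error(select_model(list(neg)), "no feasible model")
})
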