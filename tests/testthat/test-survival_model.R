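params_t1 <- population_params(
  mu = c("4-1BB" = 2.83, "CD28" = 2.23),
  sigma = c("4-1BB" = 1.52, "CD28" = 1.42),
  theta = c(morph_relapse_frac = 1.22),
  cov_ref = c(morph_relapse_frac = 0.85),
  omega_sigma = 0.329, omega_mu = 0.240, epsilon = 0.623)

test_that("log-normal survival has the right values, limits and monotonicity", {
  # median of a log-normal sits at exp(mu) for any sigma
  for (sg in c(0.5, 1.52, 3))
    expect_equal(lognormal_survival(exp(2.83), 2.83, sg), 0.5)
  # left limit
  expect_lt(abs(lognormal_survival(1e-9, 2.83, 1.52) - 1), 1e-12)
  # frozen high-precision value of Phi((log 12 - 2.83)/1.52) upper tail
  expect_equal(lognormal_survival(12, 2.83, 1.52), 0.5898018, tolerance = 1e-6)
  tt <- seq(0.5, 120, by = 0.5)
  s <- lognormal_survival(tt, 2.83, 1.52)
  expect_true(all(diff(s) < 0))
  expect_lt(lognormal_survival(1e6, 2.83, 1.52), 1e-8)
  expect_error(lognormal_survival(-1, 2.83, 1.52), "positive")
  expect_error(lognormal_survival(5, 2.83, -1), "sigma")
})

test_that("hazard matches -d log S/dt and integrates back to survival", {
  grid <- expand.grid(mu = c(1.5, 2.83), sigma = c(0.8, 1.52))
  for (k in seq_len(nrow(grid))) {
    mu <- grid$mu[k]; sg <- grid$sigma[k]
    for (t0 in c(2, 8, 20)) {
      d <- 1e-5 * t0
      fd <- -(log(lognormal_survival(t0 + d, mu, sg)) -
                log(lognormal_survival(t0 - d, mu, sg))) / (2 * d)
      expect_equal(lognormal_hazard(t0, mu, sg), fd, tolerance = 1e-6)
    }
    ch <- integrate(function(u) lognormal_hazard(u, mu, sg), 0, 15,
                    rel.tol = 1e-10)$value
    expect_equal(exp(-ch), lognormal_survival(15, mu, sg), tolerance = 1e-6)
  }
  # hazard vanishes at the origin
  expect_lt(lognormal_hazard(1e-8, 2.83, 1.52), 1e-10)
})

test_that("covariate multiplier reproduces the published hazard increases", {
  expect_identical(covariate_hazard_multiplier(0.85, 1.22, 0.85), 1)
  # +0.10 in morphological relapse: 13% on the death hazard, 19.5% on
  # the progression hazard
  expect_equal(covariate_hazard_multiplier(0.95, 1.22, 0.85), 1.13,
               tolerance = 0.005)
  expect_equal(covariate_hazard_multiplier(0.95, 1.78, 0.85), 1.195,
               tolerance = 0.005)
})

test_that("trial curve obeys the proportional-hazards identity", {
  tt <- seq(0.5, 48, length.out = 50)
  # identity multiplier at reference covariates, zero etas
  s <- trial_survival_curve(tt, params_t1, "4-1BB",
                            covariates = list(morph_relapse_frac = 0.85))
  expect_identical(s, lognormal_survival(tt, 2.83, 1.52))
  # multiplier 2 squares baseline survival: engineered via theta
  p2 <- population_params(mu = c("4-1BB" = 2.83), sigma = c("4-1BB" = 1.52),
                          theta = c(x = log(2)), cov_ref = c(x = 0),
                          epsilon = 0.5)
  s2 <- trial_survival_curve(tt, p2, "4-1BB", covariates = list(x = 1))
  expect_equal(s2, lognormal_survival(tt, 2.83, 1.52)^2, tolerance = 1e-12)
  # arbitrary multiplier against quadrature of m * h0
  m <- covariate_hazard_multiplier(0.95, 1.22, 0.85)
  sq <- vapply(tt, function(u)
    exp(-m * integrate(function(v) lognormal_hazard(v, 2.83, 1.52), 0, u,
                       rel.tol = 1e-10)$value), numeric(1))
  s3 <- trial_survival_curve(tt, params_t1, "4-1BB",
                             covariates = list(morph_relapse_frac = 0.95))
  expect_equal(s3, sq, tolerance = 1e-6)
  # random effects scale mu and sigma multiplicatively
  eta <- c(sigma = 0.3, mu = -0.2)
  s4 <- trial_survival_curve(tt, params_t1, "4-1BB", eta = eta,
                             covariates = list(morph_relapse_frac = 0.85))
  expect_equal(s4, lognormal_survival(tt, 2.83 * exp(-0.2), 1.52 * exp(0.3)))
  expect_error(trial_survival_curve(tt, params_t1, "4-1BB"),
               "morph_relapse_frac")
})

test_that("survival quantiles invert the curve", {
  covs <- list(morph_relapse_frac = 0.85)
  expect_equal(predict_survival_quantile(params_t1, "4-1BB", 0.5,
                                         covariates = covs), exp(2.83))
  # closed form vs bisection on S for a multiplier of 2
  p2 <- population_params(mu = c("4-1BB" = 2.83), sigma = c("4-1BB" = 1.52),
                          theta = c(x = log(2)), cov_ref = c(x = 0),
                          epsilon = 0.5)
  tq <- predict_survival_quantile(p2, "4-1BB", 0.5, covariates = list(x = 1))
  root <- uniroot(function(u)
    trial_survival_curve(u, p2, "4-1BB", covariates = list(x = 1)) - 0.5,
    c(0.01, 200), tol = 1e-12)$root
  expect_equal(tq, root, tolerance = 1e-8)
  expect_equal(tq, exp(2.83 + 1.52 * qnorm(1 - sqrt(0.5))), tolerance = 1e-12)
  # S(quantile) = q round trip and monotonicity in the multiplier
  for (q in c(0.1, 0.5, 0.9)) {
    t_q <- predict_survival_quantile(params_t1, "4-1BB", q, covariates = covs)
    expect_equal(trial_survival_curve(t_q, params_t1, "4-1BB",
                                      covariates = covs), q,
                 tolerance = 1e-9)
  }
  m_small <- predict_survival_quantile(params_t1, "4-1BB", 0.5,
                                       covariates = list(morph_relapse_frac = 0.5))
  m_large <- predict_survival_quantile(params_t1, "4-1BB", 0.5,
                                       covariates = list(morph_relapse_frac = 1.0))
  expect_gt(m_small, m_large)
  expect_error(predict_survival_quantile(params_t1, "4-1BB", 1.2,
                                         covariates = covs), "q")
})

test_that("logit residual transform round-trips and maps known values", {
  expect_identical(residual_transform(0.5), 0)
  expect_equal(residual_transform(0.7311), 1.0, tolerance = 1e-3)
  for (s in c(0.01, 0.5, 0.99))
    expect_equal(inv_residual_transform(residual_transform(s)), s,
                 tolerance = 1e-12)
  expect_error(residual_transform(0), "inside")
  expect_error(residual_transform(1), "inside")
})

test_that("parameter container validates its inputs", {
  expect_error(population_params(mu = c(2.8), sigma = c(1.5)), "named")
  expect_error(population_params(mu = c("4-1BB" = 2.8),
                                 sigma = c("4-1BB" = -1)), "positive")
  expect_error(population_params(mu = c("4-1BB" = 2.8),
                                 sigma = c("4-1BB" = 1.5),
                                 theta = c(x = 1), cov_ref = numeric()),
               "centering")
  expect_error(population_params(mu = c("4-1BB" = 2.8),
                                 sigma = c("4-1BB" = 1.5), epsilon = 0),
               "epsilon")
})
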