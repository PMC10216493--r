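test_that("OFV reduces to the closed-form fixed-effects -2LL when omega = 0", {
  trials <- toy_trials(2)
  fr <- toy_frames(trials)
  eps <- 0.45
  p <- population_params(mu = c("4-1BB" = 2.8), sigma = c("4-1BB" = 1.5),
                         omega_sigma = 0, omega_mu = 0, epsilon = eps)
  ofv <- objective_function(fr$arms, fr$curves, p, "OS")
  # hand closed form from the model definition
  closed <- 0
  for (tr in trials) {
    s <- pnorm((log(tr$t) - 2.8) / 1.5, lower.tail = FALSE)
    r <- tr$y - qlogis(s)
    closed <- closed + sum(r^2 / eps^2 + log(2 * pi * eps^2))
  }
  expect_equal(ofv, closed, tolerance = 1e-10)
})

test_that("OFV is invariant to trial ordering, bitwise", {
  gen <- generate_survival_dataset(generator_config(), seed = 21)
  p <- gen$truth$params
  o1 <- objective_function(gen$arms, gen$curves, p, "OS")
  perm <- sample(nrow(gen$curves))
  curves2 <- gen$curves[perm, ]
  arms2 <- gen$arms[rev(seq_len(nrow(gen$arms))), ]
  class(curves2) <- class(gen$curves); class(arms2) <- class(gen$arms)
  o2 <- objective_function(arms2, curves2, p, "OS")
  expect_identical(o1, o2)
})

test_that("Laplace OFV agrees with adaptive Gauss-Hermite quadrature", {
  # single random effect on mu, 2 trials
  trials <- toy_trials(2)
  fr <- toy_frames(trials)
  p1 <- population_params(mu = c("4-1BB" = 2.8), sigma = c("4-1BB" = 1.5),
                          omega_sigma = 0, omega_mu = 0.3, epsilon = 0.45)
  ofv <- objective_function(fr$arms, fr$curves, p1, "OS")
  oracle <- agq_ofv(trials, om_s = 0, om_m = 0.3, eps = 0.45)
  expect_lt(abs(ofv - oracle), 0.1)
  # both random effects active, several toy sizes and omegas
  for (cfg in list(list(n = 2, om = c(0.2, 0.3)),
                   list(n = 3, om = c(0.5, 0.25)),
                   list(n = 4, om = c(0.35, 0.5)))) {
    jit <- round(sin(seq_len(cfg$n * 3)) * 0.15, 3)  # deterministic jitter
    trials <- toy_trials(cfg$n, eps_jit = jit)
    fr <- toy_frames(trials)
    p <- population_params(mu = c("4-1BB" = 2.8), sigma = c("4-1BB" = 1.5),
                           omega_sigma = cfg$om[1], omega_mu = cfg$om[2],
                           epsilon = 0.5)
    ofv <- objective_function(fr$arms, fr$curves, p, "OS")
    oracle <- agq_ofv(trials, cfg$om[1], cfg$om[2], 0.5)
    expect_lt(abs(ofv - oracle), 0.5)
  }
})

test_that("fixed-effects fit recovers generating values on a clean corpus", {
  cfg <- generator_config(
    n_trials_per_group = c("4-1BB" = 10L),
    patients_range = list("4-1BB" = c(3000L, 3000L)),
    truth = population_params(mu = c("4-1BB" = 2.83),
                              sigma = c("4-1BB" = 1.52),
                              omega_sigma = 0, omega_mu = 0,
                              epsilon = 0.05),
    dropout_rate = 0, grid_step = 3, cutoff_range = c(30, 36))
  gen <- generate_survival_dataset(cfg, seed = 11)
  fit <- suppressWarnings(fit_model(
    gen$arms, gen$curves, "OS",
    config = fit_config(estimate_omega = FALSE, n_starts = 1,
                        compute_rse = FALSE)))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$mu[["4-1BB"]] - 2.83) / 2.83, 0.02)
  expect_lt(abs(fit$estimates$sigma[["4-1BB"]] - 1.52) / 1.52, 0.02)
})

test_that("estimates are stable to jittered starting values", {
  gen <- generate_survival_dataset(generator_config(), seed = 31)
  f1 <- suppressWarnings(fit_model(gen$arms, gen$curves, "OS",
                                   "morph_relapse_frac",
                                   config = fit_config(n_starts = 1,
                                                       compute_rse = FALSE)))
  init <- gen$truth$params
  init$mu <- init$mu * 1.4          # +40% start displacement
  init$sigma <- init$sigma * 0.7
  f2 <- suppressWarnings(fit_model(gen$arms, gen$curves, "OS",
                                   "morph_relapse_frac", init = init,
                                   config = fit_config(n_starts = 1,
                                                       compute_rse = FALSE)))
  expect_lt(abs(f1$ofv - f2$ofv), 0.05)
  expect_equal(unname(f1$estimates$mu), unname(f2$estimates$mu),
               tolerance = 0.02)
})

test_that("degenerate designs are flagged rather than silently fitted", {
  gen <- generate_survival_dataset(
    generator_config(n_trials_per_group = c("4-1BB" = 1L)), seed = 2)
  expect_warning(fit_model(gen$arms, gen$curves, "OS",
                           config = fit_config(n_starts = 1,
                                               compute_rse = FALSE)),
                 "fewer than 2 trials|boundary")
})

test_that("shrinkage follows its definition", {
  expect_equal(compute_shrinkage(c(0, 0, 0), 0.329), 100)
  eb <- c(-0.3, 0.1, 0.2)           # sd happens to be what we divide by
  expect_equal(compute_shrinkage(eb, sd(eb)), 0)
  expect_equal(compute_shrinkage(c(-0.2, 0.2), 0.329), 14.0295,
               tolerance = 1e-4)
  expect_error(compute_shrinkage(c(-0.2, 0.2), 0), "positive")
  expect_error(compute_shrinkage(0.1, 0.3), "at least 2")
})

test_that("an empty candidate list returns the base model", {
  gen <- generate_survival_dataset(
    generator_config(n_trials_per_group = c("4-1BB" = 6L, "CD28" = 3L)),
    seed = 13)
  cs <- suppressWarnings(covariate_search(
    gen$arms, gen$curves, "OS", candidates = character(),
    config = fit_config(n_starts = 1, compute_rse = FALSE)))
  expect_identical(cs$selected, character())
  expect_equal(cs$base_ofv, cs$final_fit$ofv)
  expect_equal(nrow(cs$trace), 0)
})

test_that("sparsely observed candidates are excluded from the search", {
  gen <- generate_survival_dataset(
    generator_config(n_trials_per_group = c("4-1BB" = 6L, "CD28" = 3L)),
    seed = 13)
  gen$arms$primary_refractory_frac[1:5] <- NA  # > 30% missing
  expect_warning(
    covariate_search(gen$arms, gen$curves, "OS",
                     candidates = "primary_refractory_frac",
                     config = fit_config(n_starts = 1, compute_rse = FALSE)),
    "excluded")
})

test_that("fit JSON export carries the estimation results", {
  gen <- generate_survival_dataset(
    generator_config(n_trials_per_group = c("4-1BB" = 6L, "CD28" = 3L)),
    seed = 17)
  fit <- suppressWarnings(fit_model(gen$arms, gen$curves, "OS",
                                    config = fit_config(n_starts = 1)))
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$ofv, fit$ofv)
  expect_equal(back$estimates$epsilon, fit$estimates$epsilon)
  expect_equal(length(back$eb_effects), nrow(fit$eb_effects))
})
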