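params_nore <- population_params(
  mu = c("4-1BB" = 2.83, "CD28" = 2.23),
  sigma = c("4-1BB" = 1.52, "CD28" = 1.42),
  theta = c(morph_relapse_frac = 1.22),
  cov_ref = c(morph_relapse_frac = 0.85),
  omega_sigma = 0, omega_mu = 0, epsilon = 0.623)

test_that("with omega = 0 the simulation collapses to the closed form", {
  s <- simulate_typical_curves(params_nore, "4-1BB", n_sim = 50, seed = 1)
  closed <- lognormal_survival(s$grid, 2.83, 1.52)
  expect_equal(s$median_curve, closed, tolerance = 1e-12)
  expect_lt(abs(unname(s$median_survival["est"]) - exp(2.83)), 0.05)
  # 12 months lies on the grid, so the landmark equals 100 * S(12) exactly
  expect_equal(unname(s$landmarks$m12["rate"]),
               100 * lognormal_survival(12, 2.83, 1.52), tolerance = 1e-9)
})

test_that("simulation output is bit-identical under the same seed", {
  p <- population_params(mu = c("4-1BB" = 2.83), sigma = c("4-1BB" = 1.52),
                         omega_sigma = 0.329, omega_mu = 0.240,
                         epsilon = 0.623)
  s1 <- simulate_typical_curves(p, "4-1BB", n_sim = 200, seed = 42)
  s2 <- simulate_typical_curves(p, "4-1BB", n_sim = 200, seed = 42)
  expect_identical(s1$median_curve, s2$median_curve)
  expect_identical(s1$landmarks, s2$landmarks)
  s3 <- simulate_typical_curves(p, "4-1BB", n_sim = 200, seed = 43)
  expect_false(identical(s1$median_curve, s3$median_curve))
})

test_that("percentile curves bracket the median pointwise for every seed", {
  p <- population_params(mu = c("4-1BB" = 2.83), sigma = c("4-1BB" = 1.52),
                         omega_sigma = 0.329, omega_mu = 0.240,
                         epsilon = 0.623)
  for (sd in 1:5) {
    s <- simulate_typical_curves(p, "4-1BB", n_sim = 100, seed = sd)
    expect_true(all(s$lower_curve <= s$median_curve + 1e-12))
    expect_true(all(s$median_curve <= s$upper_curve + 1e-12))
  }
})

test_that("covariate levels shift median survival monotonically", {
  ss <- summarize_at_covariate_levels(params_nore, "4-1BB",
                                      "morph_relapse_frac",
                                      levels = c(0.25, 0.85, 1.0),
                                      n_sim = 50, seed = 2)
  med <- vapply(ss, function(x) unname(x$median_survival["est"]), numeric(1))
  expect_true(med["0.25"] > med["0.85"])
  expect_true(med["0.85"] > med["1"])
  # reference level reproduces the plain typical simulation exactly
  ref <- simulate_typical_curves(params_nore, "4-1BB", n_sim = 50, seed = 2)
  expect_identical(ss[["0.85"]]$median_curve, ref$median_curve)
  # theta = 0 makes all levels identical
  p0 <- params_nore
  p0$theta[] <- 0
  ss0 <- summarize_at_covariate_levels(p0, "4-1BB", "morph_relapse_frac",
                                       levels = c(0.25, 1.0), n_sim = 50,
                                       seed = 2)
  expect_identical(ss0[["0.25"]]$median_curve, ss0[["1"]]$median_curve)
})

small_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      gen <- generate_survival_dataset(
        generator_config(n_trials_per_group = c("4-1BB" = 10L, "CD28" = 4L)),
        seed = 19)
      memo <<- list(
        gen = gen,
        fit = suppressWarnings(fit_model(gen$arms, gen$curves, "OS",
                                         "morph_relapse_frac",
                                         config = fit_config(n_starts = 1))))
    }
    memo
  }
})

test_that("subgroup pooling inverts the covariate model and matches DL by hand", {
  sf <- small_fit()
  sp <- subgroup_pool(sf$fit, sf$gen$arms, "age_group")
  pt <- sp$per_trial
  # inverse covariate adjustment round-trips to the original hazard scale
  expect_equal(pt$hazard_scale_unadjusted * (1 / pt$adjustment),
               pt$hazard_scale, tolerance = 1e-14)
  expect_true(all(abs(pt$hazard_scale_unadjusted - 1) < 1e-12))
  # pooled level mean reproduces the closed-form DerSimonian-Laird value
  lv <- names(sp$pooled)[[1]]
  sub <- pt[!is.na(pt$level) & pt$level == lv, ]
  keep <- is.finite(sub$log_mu) & is.finite(sub$se_log_mu) & sub$se_log_mu > 0
  o <- dl_pool(sub$log_mu[keep], sub$se_log_mu[keep]^2)
  expect_equal(unname(sp$pooled[[lv]]$log_mu["mean"]), o$est,
               tolerance = 1e-8)
  expect_equal(unname(sp$pooled[[lv]]$log_mu["tau2"]), o$tau2,
               tolerance = 1e-8)
  # CI contains the mean
  for (lv in names(sp$pooled)) {
    pm <- sp$pooled[[lv]]$log_mu
    expect_true(pm["lower"] <= pm["mean"] && pm["mean"] <= pm["upper"])
  }
})

test_that("subgroup simulation respects dispersion and the seed", {
  sf <- small_fit()
  sp <- subgroup_pool(sf$fit, sf$gen$arms, "age_group")
  s1 <- simulate_subgroup(sp, n_sim = 100, seed = 5)
  s2 <- simulate_subgroup(sp, n_sim = 100, seed = 5)
  lv <- names(s1)[[1]]
  expect_identical(s1[[lv]]$median_curve, s2[[lv]]$median_curve)
  # zero dispersion -> deterministic curve
  sp0 <- sp
  for (l in names(sp0$pooled)) {
    sp0$pooled[[l]]$log_mu["tau2"] <- 0
    sp0$pooled[[l]]$log_sigma["tau2"] <- 0
  }
  s0 <- simulate_subgroup(sp0, n_sim = 50, seed = 5)
  expect_equal(s0[[lv]]$lower_curve, s0[[lv]]$upper_curve, tolerance = 1e-12)
  # wider pooled dispersion widens the 95% band at every grid point
  wins <- 0L
  for (sd in 1:20) {
    spw <- sp
    for (l in names(spw$pooled)) spw$pooled[[l]]$log_mu["tau2"] <-
        4 * max(spw$pooled[[l]]$log_mu["tau2"], 0.01)
    wn <- simulate_subgroup(spw, n_sim = 60, seed = sd)[[lv]]
    nr <- simulate_subgroup(sp0, n_sim = 60, seed = sd)[[lv]]
    wide <- wn$upper_curve - wn$lower_curve
    narrow <- nr$upper_curve - nr$lower_curve
    if (mean(wide >= narrow - 1e-9) > 0.99) wins <- wins + 1L
  }
  expect_gte(wins, 18)
})

test_that("simulation summaries serialize to CSV + JSON", {
  s <- simulate_typical_curves(params_nore, "4-1BB", n_sim = 20, seed = 1)
  stem <- tempfile()
  write_simulation_summary(s, stem)
  expect_true(file.exists(paste0(stem, "_curves.csv")))
  back <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(back$median_survival_months$est,
               unname(s$median_survival["est"]), tolerance = 1e-12)
})
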