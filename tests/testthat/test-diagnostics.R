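# one small corpus + fit shared across diagnostics tests
diag_fix <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      gen <- generate_survival_dataset(
        generator_config(n_trials_per_group = c("4-1BB" = 8L, "CD28" = 3L)),
        seed = 29)
      fit <- suppressWarnings(fit_model(gen$arms, gen$curves, "OS",
                                        config = fit_config(n_starts = 1)))
      memo <<- list(gen = gen, fit = fit)
    }
    memo
  }
})

test_that("bootstrap is seed-reproducible and counts failures honestly", {
  fx <- diag_fix()
  b1 <- bootstrap_model(fx$fit, fx$gen$arms, fx$gen$curves, n_boot = 12,
                        seed = 4)
  b2 <- bootstrap_model(fx$fit, fx$gen$arms, fx$gen$curves, n_boot = 12,
                        seed = 4)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$replicates, b2$replicates)
  expect_lte(b1$n_converged, b1$n_requested)
  expect_equal(b1$success_rate_percent,
               100 * b1$n_converged / b1$n_requested)
  expect_true(all(b1$summary$lower <= b1$summary$median &
                    b1$summary$median <= b1$summary$upper))
})

test_that("cloning trials shrinks the bootstrap interval", {
  base <- generate_survival_dataset(
    generator_config(n_trials_per_group = c("4-1BB" = 4L, "CD28" = 2L)),
    seed = 41)
  clone <- function(k) {
    a <- do.call(rbind, lapply(seq_len(k), function(i) {
      ai <- base$arms
      ai$trial_id <- paste0(ai$trial_id, "_", i)
      ai
    }))
    cv <- do.call(rbind, lapply(seq_len(k), function(i) {
      ci <- base$curves
      ci$trial_id <- paste0(ci$trial_id, "_", i)
      ci
    }))
    class(a) <- c("mbma_trials", "data.frame")
    class(cv) <- c("mbma_curves", "data.frame")
    list(arms = a, curves = cv)
  }
  widths <- vapply(c(1, 4), function(k) {
    d <- clone(k)
    f <- suppressWarnings(fit_model(d$arms, d$curves, "OS",
                                    config = fit_config(n_starts = 1,
                                                        compute_rse = FALSE)))
    b <- bootstrap_model(f, d$arms, d$curves, n_boot = 25, seed = 8)
    w <- b$summary$upper - b$summary$lower
    w[b$summary$parameter == "mu(4-1BB)"]
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("VPC on self-simulated data covers the observed percentiles", {
  fx <- diag_fix()
  v <- vpc(fx$fit, n_replicates = 150, seed = 6)
  tab <- v$table
  med <- tab[tab$percentile == 50, ]
  expect_gte(mean(med$covered), 0.85)
  # bands are ordered and bins partition the observed times
  expect_true(all(tab$sim_lower <= tab$sim_median + 1e-12))
  expect_true(all(tab$sim_median <= tab$sim_upper + 1e-12))
  tt <- exp(fx$fit$data$logt)
  expect_true(all(tt > v$breaks[1] & tt < v$breaks[length(v$breaks)]))
  # a single replicate collapses the band onto that replicate
  v1 <- vpc(fx$fit, n_replicates = 1, seed = 6)
  expect_equal(v1$table$sim_lower, v1$table$sim_upper, tolerance = 1e-12)
})

test_that("leave-one-out flags nothing on a redundant corpus", {
  base <- generate_survival_dataset(
    generator_config(n_trials_per_group = c("4-1BB" = 4L, "CD28" = 2L)),
    seed = 43)
  a2 <- base$arms; a2$trial_id <- paste0(a2$trial_id, "_b")
  c2 <- base$curves; c2$trial_id <- paste0(c2$trial_id, "_b")
  arms <- rbind(base$arms, a2); curves <- rbind(base$curves, c2)
  class(arms) <- c("mbma_trials", "data.frame")
  class(curves) <- c("mbma_curves", "data.frame")
  fit <- suppressWarnings(fit_model(arms, curves, "OS",
                                    config = fit_config(n_starts = 1,
                                                        compute_rse = FALSE)))
  loo <- leave_one_out(fit, arms, curves)
  # every trial still has a duplicate in the data, so the fixed effects
  # barely move (variance components are free to wobble at this size)
  fx <- loo$table[grepl("^mu|^sigma", loo$table$parameter), ]
  expect_lt(max(abs(fx$rel_change), na.rm = TRUE), 0.1)
  expect_equal(length(unique(loo$table$left_out)), nrow(arms))
  # too-small datasets are rejected
  two <- generate_survival_dataset(
    generator_config(n_trials_per_group = c("4-1BB" = 2L)), seed = 1)
  f2 <- suppressWarnings(fit_model(two$arms, two$curves, "OS",
                                   config = fit_config(n_starts = 1,
                                                       compute_rse = FALSE)))
  expect_error(leave_one_out(f2, two$arms, two$curves), "at least 3")
})

test_that("GOF residuals are calibrated on self-consistent data", {
  fx <- diag_fix()
  g <- gof_residuals(fx$fit)
  expect_equal(nrow(g), length(fx$fit$data$y))
  expect_equal(g$residual, g$observed - g$individual_predicted)
  expect_equal(g$standardized_residual * fx$fit$estimates$epsilon,
               g$residual, tolerance = 1e-12)
  expect_lt(abs(mean(g$standardized_residual)), 0.25)
  # population prediction ignores the random effects: differs from the
  # individual one whenever the EB etas are non-zero
  expect_gt(sd(g$individual_predicted - g$population_predicted), 0)
})
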