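.fit_param_vector <- function(est, groups, covs) {
  c(setNames(unname(est$mu[groups]), paste0("mu(", groups, ")")),
    setNames(unname(est$sigma[groups]), paste0("sigma(", groups, ")")),
    if (length(covs)) setNames(unname(est$theta[covs]), covs),
    omega_sigma = est$omega_sigma, omega_mu = est$omega_mu,
    epsilon = est$epsilon)
}

#' Nonparametric bootstrap of the model fit
#'
#' Resamples whole trials with replacement, stratified by domain group so
#' that both groups stay represented and the group-specific fixed effects
#' remain estimable; refits every replicate (warm-started at the full-fit
#' estimates, single start).  Replicates that fail to converge are counted
#' in the success rate and excluded from the percentile summaries.
#'
#' @param fit converged `mbma_fit` (provides data, settings and the warm
#'   start).
#' @param arms trial table used for the fit.
#' @param curves survival observations used for the fit.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed; the resampling plan is bit-reproducible.
#' @return An object of class `mbma_bootstrap`: `n_requested`,
#'   `n_converged`, `success_rate_percent` and per-parameter
#'   median / 2.5% / 97.5% columns in `summary`.
#' @export
bootstrap_model <- function(fit, arms, curves, n_boot = 200L, seed = 1L) {
  stopifnot(n_boot >= 1)
  dat <- fit$data
  groups <- fit$groups
  ids_by_group <- split(dat$ids, dat$group)
  cfg <- fit$config
  cfg$n_starts <- 1L
  cfg$compute_rse <- FALSE
  cfg$rel_tol <- max(cfg$rel_tol, 1e-3)  # replicate refits need less polish
  curves_ep <- curves[curves$endpoint == fit$endpoint, , drop = FALSE]
  reps <- list()
  n_conv <- 0L
  plans <- .with_rng(.substream(seed, "bootstrap"), {
    lapply(seq_len(n_boot), function(b)
      unlist(lapply(ids_by_group, function(ids)
        sample(ids, length(ids), replace = TRUE)), use.names = FALSE))
  })
  for (b in seq_len(n_boot)) {
    picked <- plans[[b]]
    new_ids <- sprintf("B%03d", seq_along(picked))
    a2 <- arms[match(picked, arms$trial_id), , drop = FALSE]
    a2$trial_id <- new_ids
    c2 <- do.call(rbind, lapply(seq_along(picked), function(i) {
      cc <- curves_ep[curves_ep$trial_id == picked[i], , drop = FALSE]
      cc$trial_id <- new_ids[i]
      cc
    }))
    class(a2) <- c("mbma_trials", "data.frame")
    class(c2) <- c("mbma_curves", "data.frame")
    f <- try(suppressWarnings(
      fit_model(a2, c2, fit$endpoint, fit$included_covariates,
                init = fit$estimates, config = cfg)), silent = TRUE)
    if (!inherits(f, "try-error") && f$converged) {
      n_conv <- n_conv + 1L
      reps[[length(reps) + 1L]] <-
        .fit_param_vector(f$estimates, groups, fit$included_covariates)
    }
  }
  if (!n_conv) stop("no bootstrap replicate converged")
  mat <- do.call(rbind, reps)
  summary <- data.frame(
    parameter = colnames(mat),
    median = apply(mat, 2, median),
    lower = apply(mat, 2, quantile, probs = 0.025, names = FALSE),
    upper = apply(mat, 2, quantile, probs = 0.975, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(n_requested = n_boot, n_converged = n_conv,
                 success_rate_percent = 100 * n_conv / n_boot,
                 summary = summary, replicates = mat),
            class = "mbma_bootstrap")
}

#' @export
print.mbma_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d replicates converged (%.1f%%)\n",
              x$n_converged, x$n_requested, x$success_rate_percent))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

.equal_count_bins <- function(times, n_bins) {
  qs <- unique(quantile(times, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE))
  if (length(qs) < 3) qs <- range(times) + c(-1e-9, 1e-9)
  qs[1] <- qs[1] - 1e-9
  qs[length(qs)] <- qs[length(qs)] + 1e-9
  qs
}

#' Visual predictive check
#'
#' Simulates `n_replicates` full datasets at the observed design (new
#' random effects per trial, new logit-scale residuals per observation),
#' then compares the observed 10/50/90th percentiles of the survival
#' fraction per time bin against the 95% band of the same percentile
#' across replicates.  Bins are equal-count over observed times; empty bins
#' cannot arise by construction.
#'
#' @param fit converged `mbma_fit`.
#' @param n_replicates simulated datasets.
#' @param seed integer seed.
#' @param n_bins number of time bins.
#' @return An object of class `mbma_vpc` with a `table` (per bin and
#'   percentile: observed value, simulated band) and `n_replicates`.
#' @export
vpc <- function(fit, n_replicates = 500L, seed = 1L, n_bins = 8L) {
  if (!fit$converged) stop("VPC requires a converged fit")
  dat <- fit$data
  if (any(!is.finite(exp(dat$logt)))) stop("non-finite observation times")
  est <- fit$estimates
  brk <- .equal_count_bins(exp(dat$logt), n_bins)
  bin <- cut(exp(dat$logt), brk, labels = FALSE)
  probs <- c(0.1, 0.5, 0.9)
  obs_s <- inv_residual_transform(dat$y)
  obs_pct <- vapply(sort(unique(bin)), function(b)
    quantile(obs_s[bin == b], probs = probs, names = FALSE), numeric(3))
  mu_g <- unname(est$mu[dat$group]); sig_g <- unname(est$sigma[dat$group])
  mscale <- .mscale_from(dat, est$theta)
  nob <- length(dat$y)
  ntr <- length(dat$ids)
  sim_pct <- .with_rng(.substream(seed, "vpc"), {
    arr <- array(NA_real_, c(n_replicates, 3, max(bin)))
    for (r in seq_len(n_replicates)) {
      es <- rnorm(ntr, 0, est$omega_sigma)
      em <- rnorm(ntr, 0, est$omega_mu)
      yh <- predict_logit_surv_cpp(dat$logt, dat$trial,
                                   mu_g * exp(em), sig_g * exp(es), mscale)
      ysim <- yh + rnorm(nob, 0, est$epsilon)
      ssim <- inv_residual_transform(ysim)
      for (b in sort(unique(bin)))
        arr[r, , b] <- quantile(ssim[bin == b], probs = probs, names = FALSE)
    }
    arr
  })
  rows <- list()
  for (b in sort(unique(bin))) {
    for (pi in 1:3) {
      band <- quantile(sim_pct[, pi, b], probs = c(0.025, 0.5, 0.975),
                       names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, bin_mid = mean(exp(dat$logt)[bin == b]),
        percentile = 100 * probs[pi],
        observed = obs_pct[pi, b],
        sim_lower = band[1], sim_median = band[2], sim_upper = band[3],
        covered = obs_pct[pi, b] >= band[1] && obs_pct[pi, b] <= band[3])
    }
  }
  structure(list(table = do.call(rbind, rows), n_replicates = n_replicates,
                 breaks = brk), class = "mbma_vpc")
}

#' @export
print.mbma_vpc <- function(x, ...) {
  tab <- x$table
  cat(sprintf("VPC (%d replicates): %d/%d bin-percentiles inside the 95%% band\n",
              x$n_replicates, sum(tab$covered), nrow(tab)))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the model once per left-out trial (warm-started, single start)
#' and reports each parameter's relative change against the full fit.  A
#' replicate that fails is recorded as non-converged; the others proceed.
#'
#' @param fit converged `mbma_fit`.
#' @param arms,curves the data used for the fit.
#' @return An object of class `mbma_loo`: `table` with one row per
#'   left-out trial per parameter (estimate, relative change), and
#'   `max_abs_rel_change`.
#' @export
leave_one_out <- function(fit, arms, curves) {
  dat <- fit$data
  if (length(dat$ids) < 3) stop("leave-one-out needs at least 3 trials")
  cfg <- fit$config
  cfg$n_starts <- 1L
  cfg$compute_rse <- FALSE
  full <- .fit_param_vector(fit$estimates, fit$groups, fit$included_covariates)
  rows <- list()
  for (id in dat$ids) {
    a2 <- arms[arms$trial_id != id, , drop = FALSE]
    c2 <- curves[curves$trial_id != id, , drop = FALSE]
    f <- try(suppressWarnings(
      fit_model(a2, c2, fit$endpoint, fit$included_covariates,
                init = fit$estimates, config = cfg)), silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) {
      rows[[length(rows) + 1L]] <- data.frame(
        left_out = id, parameter = names(full), estimate = NA_real_,
        rel_change = NA_real_, converged = FALSE, stringsAsFactors = FALSE)
      next
    }
    est <- .fit_param_vector(f$estimates, fit$groups, fit$included_covariates)
    rows[[length(rows) + 1L]] <- data.frame(
      left_out = id, parameter = names(full), estimate = unname(est),
      rel_change = unname((est - full) / full), converged = TRUE,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 max_abs_rel_change = max(abs(tab$rel_change), na.rm = TRUE)),
            class = "mbma_loo")
}

#' @export
print.mbma_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d trials: max |relative change| = %.1f%%\n",
              length(unique(x$table$left_out)), 100 * x$max_abs_rel_change))
  invisible(x)
}

#' Goodness-of-fit residual table
#'
#' One row per observation with the population prediction (random effects
#' at zero), the individual prediction (empirical-Bayes random effects),
#' and raw / standardized residuals on the logit scale (standardized by
#' \eqn{\epsilon}).
#'
#' @param fit converged `mbma_fit`.
#' @return data frame of class `mbma_gof`.
#' @export
gof_residuals <- function(fit) {
  if (!fit$converged) stop("GOF residuals require a converged fit")
  dat <- fit$data
  est <- fit$estimates
  mu_g <- unname(est$mu[dat$group]); sig_g <- unname(est$sigma[dat$group])
  mscale <- .mscale_from(dat, est$theta)
  pred <- predict_logit_surv_cpp(dat$logt, dat$trial, mu_g, sig_g, mscale)
  eb <- fit$eb_effects
  ipred <- predict_logit_surv_cpp(dat$logt, dat$trial,
                                  mu_g * exp(eb$eta_mu),
                                  sig_g * exp(eb$eta_sigma), mscale)
  out <- data.frame(
    trial_id = dat$ids[dat$trial],
    time_months = exp(dat$logt),
    observed = dat$y,
    population_predicted = pred,
    individual_predicted = ipred,
    residual = dat$y - ipred,
    standardized_residual = (dat$y - ipred) / est$epsilon,
    stringsAsFactors = FALSE)
  class(out) <- c("mbma_gof", "data.frame")
  out
}
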