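.default_grid <- function() seq(0.25, 72, by = 0.25)

# First downward crossing of level `q` on a summary curve, by linear
# interpolation between grid points; NA (reported as "> max") if not reached.
.crossing_time <- function(grid, s, q = 0.5) {
  below <- which(s <= q)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(grid[1])
  grid[i - 1] + (grid[i] - grid[i - 1]) * (s[i - 1] - q) / (s[i - 1] - s[i])
}

.landmark <- function(grid, s, at) {
  if (at > max(grid)) return(NA_real_)
  100 * approx(grid, s, xout = at, rule = 2)$y
}

.summarize_curves <- function(sims, grid, landmark_times) {
  med <- apply(sims, 2, median)
  lo <- apply(sims, 2, quantile, probs = 0.025, names = FALSE)
  hi <- apply(sims, 2, quantile, probs = 0.975, names = FALSE)
  lmk <- lapply(landmark_times, function(at) c(
    rate = .landmark(grid, med, at),
    lower = .landmark(grid, lo, at),
    upper = .landmark(grid, hi, at)))
  names(lmk) <- paste0("m", landmark_times)
  list(grid = grid, median_curve = med, lower_curve = lo, upper_curve = hi,
       median_survival = c(est = .crossing_time(grid, med),
                           lower = .crossing_time(grid, lo),
                           upper = .crossing_time(grid, hi)),
       landmarks = lmk)
}

#' Monte-Carlo simulation of the typical survival curve
#'
#' Draws `n_sim` pairs of trial-level random effects from
#' \eqn{N(0, \omega^2)}, forms each trial-level curve with the covariate
#' setting applied, and summarizes pointwise by the median and the
#' 2.5/97.5 percentiles.  Median survival is the interpolated 0.5-crossing
#' of each summary curve; landmark rates are read off at 12, 24 and 60
#' months.  With both \eqn{\omega = 0} the simulation degenerates to the
#' closed-form typical curve.
#'
#' @param params [population_params()].
#' @param group `"4-1BB"` or `"CD28"`.
#' @param covariates named list of covariate values (defaults to the
#'   reference values, i.e. multiplier 1).
#' @param n_sim number of Monte-Carlo draws.
#' @param seed integer seed (bit-reproducible output).
#' @param grid ascending positive time grid, months.
#' @param landmark_times landmark months to report.
#' @return An object of class `mbma_simsummary`: summary curves, median
#'   survival with 95% CI and landmark rates (percent) with 95% CIs.
#' @export
simulate_typical_curves <- function(params, group, covariates = NULL,
                                    n_sim = 1000L, seed = 1L,
                                    grid = .default_grid(),
                                    landmark_times = c(12, 24, 60)) {
  stopifnot(n_sim >= 1, all(grid > 0), !is.unsorted(grid))
  if (is.null(covariates))
    covariates <- as.list(params$cov_ref)
  .with_rng(.substream(seed, "typical"), {
    etas <- cbind(sigma = rnorm(n_sim, 0, params$omega_sigma),
                  mu = rnorm(n_sim, 0, params$omega_mu))
    sims <- t(vapply(seq_len(n_sim), function(k)
      trial_survival_curve(grid, params, group, etas[k, ], covariates),
      numeric(length(grid))))
    out <- .summarize_curves(sims, grid, landmark_times)
    out$endpoint_group <- group
    out$covariates <- covariates
    out$n_sim <- n_sim
    class(out) <- "mbma_simsummary"
    out
  })
}

#' @export
print.mbma_simsummary <- function(x, ...) {
  ms <- x$median_survival
  fmt <- function(v) if (is.na(v)) paste0("> ", max(x$grid)) else sprintf("%.1f", v)
  cat(sprintf("Typical curve (%s, %d simulations)\n",
              x$endpoint_group, x$n_sim))
  cat(sprintf("  median survival: %s months (95%% CI %s-%s)\n",
              fmt(ms["est"]), fmt(ms["lower"]), fmt(ms["upper"])))
  for (nm in names(x$landmarks)) {
    l <- x$landmarks[[nm]]
    cat(sprintf("  %s-month rate: %.1f%% (%.1f-%.1f)\n",
                sub("^m", "", nm), l["rate"], l["lower"], l["upper"]))
  }
  invisible(x)
}

#' Typical curves across covariate levels
#'
#' Repeats [simulate_typical_curves()] at each level of one covariate,
#' holding everything else at reference.  For a hazard-increasing
#' coefficient (\eqn{\theta > 0}) the median survival decreases as the
#' level rises.
#'
#' @inheritParams simulate_typical_curves
#' @param covariate covariate name (must appear in `params$theta`).
#' @param levels numeric levels to evaluate.
#' @return Named list of `mbma_simsummary`, one per level.
#' @export
summarize_at_covariate_levels <- function(params, group, covariate, levels,
                                          n_sim = 1000L, seed = 1L,
                                          grid = .default_grid()) {
  stopifnot(covariate %in% names(params$theta))
  out <- lapply(levels, function(lv) {
    covs <- as.list(params$cov_ref)
    covs[[covariate]] <- lv
    simulate_typical_curves(params, group, covs, n_sim = n_sim, seed = seed,
                            grid = grid)
  })
  names(out) <- as.character(levels)
  out
}

#' Two-step subgroup pooling of trial-level parameter estimates
#'
#' Step 1 removes the covariate model from each trial's estimates: the
#' trial's hazard-scale multiplier is divided by
#' \eqn{\exp\{\theta(x_i - r)\}} (an exact inverse of the forward model).
#' Step 2 pools each trial-level parameter (log \eqn{\mu_i},
#' log \eqn{\sigma_i}) per subgroup level with a DerSimonian-Laird
#' random-effects meta-analysis of single means, with per-trial SEs from
#' the conditional (empirical-Bayes) curvature.
#'
#' @param fit `mbma_fit` object.
#' @param arms trial table used for the fit.
#' @param subgroup name of the trial-table column defining the subgroup; a
#'   numeric column is split at its median into low/high levels.
#' @return A list of class `mbma_subgroup_pooled`: per-level pooled
#'   log-parameter means with 95% CIs and per-trial adjusted estimates.
#' @export
subgroup_pool <- function(fit, arms, subgroup) {
  if (!subgroup %in% names(arms)) stop("unknown subgroup column: ", subgroup)
  dat <- fit$data
  a <- arms[match(dat$ids, arms$trial_id), , drop = FALSE]
  est <- fit$estimates
  eb <- fit$eb_effects
  # per-trial parameters and approximate SEs of the etas from the
  # conditional Hessian (inverse curvature at the EB mode)
  H <- fit$cond_hessian
  se_eta <- function(i) {
    h <- H[i, ]
    det <- h[1] * h[3] - h[2]^2
    if (det <= 0) return(c(NA_real_, NA_real_))
    sqrt(c(h[3], h[1]) / det)  # sd(eta_sigma), sd(eta_mu)
  }
  ses <- t(vapply(seq_len(nrow(eb)), se_eta, numeric(2)))
  mu_i <- unname(est$mu[dat$group]) * exp(eb$eta_mu)
  sig_i <- unname(est$sigma[dat$group]) * exp(eb$eta_sigma)
  m_i <- .mscale_from(dat, est$theta)
  per_trial <- data.frame(
    trial_id = dat$ids, group = dat$group,
    mu_i = mu_i, sigma_i = sig_i, hazard_scale = m_i,
    hazard_scale_unadjusted = m_i * exp(-log(m_i)),  # = 1 after inverse adjustment
    adjustment = exp(-log(m_i)),
    log_mu = log(mu_i), log_sigma = log(sig_i),
    se_log_mu = ses[, 2], se_log_sigma = ses[, 1],
    stringsAsFactors = FALSE)
  # subgroup levels
  v <- a[[subgroup]]
  lev <- if (is.numeric(v)) {
    med <- median(v, na.rm = TRUE)
    ifelse(is.na(v), NA, ifelse(v < med, paste0("<", signif(med, 3)),
                                paste0(">=", signif(med, 3))))
  } else as.character(v)
  per_trial$level <- lev
  pooled <- list()
  for (lv in sort(unique(lev[!is.na(lev)]))) {
    sub <- per_trial[!is.na(lev) & lev == lv, , drop = FALSE]
    pool_one <- function(y, se) {
      keep <- is.finite(y) & is.finite(se) & se > 0
      y <- y[keep]; se <- se[keep]
      if (length(y) == 0) return(c(mean = NA, lower = NA, upper = NA, tau2 = NA, k = 0))
      if (length(y) == 1) {
        warning("subgroup level '", lv, "' has a single trial; ",
                "its CI comes from that trial's SE alone")
        return(c(mean = y, lower = y - 1.96 * se, upper = y + 1.96 * se,
                 tau2 = 0, k = 1))
      }
      r <- metafor::rma.uni(yi = y, sei = se, method = "DL")
      c(mean = as.numeric(r$beta), lower = r$ci.lb, upper = r$ci.ub,
        tau2 = r$tau2, k = r$k)
    }
    pooled[[lv]] <- list(
      level = lv, n_trials = nrow(sub),
      log_mu = pool_one(sub$log_mu, sub$se_log_mu),
      log_sigma = pool_one(sub$log_sigma, sub$se_log_sigma))
  }
  structure(list(subgroup = subgroup, pooled = pooled, per_trial = per_trial,
                 groups_present = unique(dat$group)),
            class = "mbma_subgroup_pooled")
}

#' Simulate survival distributions for pooled subgroups
#'
#' Samples log-scale parameters from each level's pooled random-effects
#' distribution (mean and between-trial SD \eqn{\sqrt{\tau^2}}) and
#' summarizes the implied log-normal curves as in
#' [simulate_typical_curves()].  Zero pooled dispersion gives a
#' deterministic curve.
#'
#' @param pooled `mbma_subgroup_pooled` from [subgroup_pool()].
#' @param n_sim number of draws per level.
#' @param seed integer seed.
#' @param grid time grid, months.
#' @return Named list of `mbma_simsummary`, one per subgroup level.
#' @export
simulate_subgroup <- function(pooled, n_sim = 1000L, seed = 1L,
                              grid = .default_grid()) {
  out <- list()
  for (lv in names(pooled$pooled)) {
    p <- pooled$pooled[[lv]]
    out[[lv]] <- .with_rng(.substream(seed, paste0("subgroup:", lv)), {
      mu_draw <- exp(rnorm(n_sim, p$log_mu["mean"], sqrt(max(p$log_mu["tau2"], 0))))
      sig_draw <- exp(rnorm(n_sim, p$log_sigma["mean"], sqrt(max(p$log_sigma["tau2"], 0))))
      sims <- t(vapply(seq_len(n_sim), function(k)
        lognormal_survival(grid, mu_draw[k], sig_draw[k]),
        numeric(length(grid))))
      s <- .summarize_curves(sims, grid, c(12, 24, 60))
      s$endpoint_group <- paste0(pooled$subgroup, "=", lv)
      s$covariates <- list()
      s$n_sim <- n_sim
      class(s) <- "mbma_simsummary"
      s
    })
  }
  out
}

#' Write a simulation summary to CSV + JSON
#'
#' The grid curves go to `<stem>_curves.csv`; medians, landmarks and CIs to
#' `<stem>.json`.
#'
#' @param summary `mbma_simsummary`.
#' @param stem output path stem (no extension).
#' @export
write_simulation_summary <- function(summary, stem) {
  curves <- data.frame(time_months = summary$grid,
                       median = summary$median_curve,
                       lower95 = summary$lower_curve,
                       upper95 = summary$upper_curve)
  utils::write.csv(curves, paste0(stem, "_curves.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(group = summary$endpoint_group,
         n_sim = summary$n_sim,
         median_survival_months = as.list(summary$median_survival),
         landmark_rates_percent = lapply(summary$landmarks, as.list)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(stem)
}
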