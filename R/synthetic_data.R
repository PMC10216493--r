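#' Configuration for the synthetic-trial generator
#'
#' Describes a corpus of single-arm CAR-T trials with the statistical
#' structure the MBMA pipeline assumes.  The defaults mirror the design of
#' the published corpus the package emulates: 26 trials with the 4-1BB
#' co-stimulatory domain (around 27 patients each, about 700 in total) and
#' 5 trials with CD28 (around 46 each, about 228 in total), a
#' morphological-relapse fraction spanning 0.286-1.0 with median near 0.85,
#' administrative follow-up cutoffs of 12-36 months with 5% random dropout,
#' and survival curves digitized every 1.5 months.
#'
#' @param n_trials_per_group named integer vector, trials per group.
#' @param patients_range named list of `c(min, max)` patient counts per
#'   trial, per group.
#' @param truth [population_params()] generating parameters.
#' @param morph_beta shape parameters of the Beta distribution for the
#'   morphological-relapse fraction, rescaled to `morph_range`.
#' @param morph_range support of the morphological-relapse fraction.
#' @param cutoff_range administrative censoring window, months.
#' @param dropout_rate probability a patient drops out (uniformly over the
#'   follow-up window) before the cutoff.
#' @param grid_step spacing of the digitization grid, months.
#' @param resid_noise logical; add logit-scale residual noise of SD
#'   `truth$epsilon` to the sampled KM values (emulating digitization and
#'   reporting error).
#' @param prop_truth data frame with columns `endpoint, group, logit_mean,
#'   logit_sd`: the latent logit-normal law of each proportion endpoint.
#'   `NULL` installs defaults consistent with reported CAR-T response and
#'   toxicity rates.
#' @param surrogate_correlation latent trial-level correlation used by
#'   [generate_surrogate_endpoints()].
#' @param endpoints survival endpoints to generate curves for.
#' @return A list of class `mbma_genconfig`.
#' @export
generator_config <- function(
    n_trials_per_group = c("4-1BB" = 26L, "CD28" = 5L),
    patients_range = list("4-1BB" = c(18L, 36L), "CD28" = c(35L, 57L)),
    truth = population_params(
      mu = c("4-1BB" = 2.83, "CD28" = 2.23),
      sigma = c("4-1BB" = 1.52, "CD28" = 1.42),
      theta = c(morph_relapse_frac = 1.22),
      cov_ref = c(morph_relapse_frac = 0.85),
      omega_sigma = 0.329, omega_mu = 0.240, epsilon = 0.623),
    morph_beta = c(3, 1), morph_range = c(0.286, 1),
    cutoff_range = c(12, 36), dropout_rate = 0.05,
    grid_step = 1.5, resid_noise = TRUE,
    prop_truth = NULL, surrogate_correlation = 0.95,
    endpoints = "OS") {
  n_trials_per_group <- unlist(n_trials_per_group)   # YAML configs give lists
  patients_range <- lapply(patients_range, unlist)
  if (is.null(names(n_trials_per_group)) ||
      !all(names(n_trials_per_group) %in% .groups))
    stop("'n_trials_per_group' must be named with groups among: ",
         paste(.groups, collapse = ", "))
  stopifnot(all(n_trials_per_group >= 1),
            grid_step > 0, dropout_rate >= 0, dropout_rate < 1,
            abs(surrogate_correlation) <= 1)
  if (is.null(prop_truth)) prop_truth <- .default_prop_truth()
  structure(list(n_trials_per_group = n_trials_per_group,
                 patients_range = patients_range, truth = truth,
                 morph_beta = morph_beta, morph_range = morph_range,
                 cutoff_range = cutoff_range, dropout_rate = dropout_rate,
                 grid_step = grid_step, resid_noise = isTRUE(resid_noise),
                 prop_truth = prop_truth,
                 surrogate_correlation = surrogate_correlation,
                 endpoints = endpoints),
            class = "mbma_genconfig")
}

# Latent logit-normal proportion laws, centred on reported pooled rates for
# second-generation anti-CD19 CAR-T in B-ALL.
.default_prop_truth <- function() {
  p <- c(ORR = 0.857, MRD_NEG_CR = 0.738, CRS = 0.891, CRS_G34 = 0.295,
         NEUROTOX = 0.311, NEUROTOX_G34 = 0.078)
  p2 <- c(ORR = 0.718, MRD_NEG_CR = 0.630, CRS = 0.887, CRS_G34 = 0.235,
          NEUROTOX = 0.603, NEUROTOX_G34 = 0.283)
  rbind(
    data.frame(endpoint = names(p), group = "4-1BB", logit_mean = qlogis(p),
               logit_sd = 0.5, stringsAsFactors = FALSE),
    data.frame(endpoint = names(p2), group = "CD28", logit_mean = qlogis(p2),
               logit_sd = 0.5, stringsAsFactors = FALSE))
}

.draw_arms <- function(config) {
  groups <- rep(names(config$n_trials_per_group), config$n_trials_per_group)
  n <- length(groups)
  ids <- sprintf("T%02d", seq_len(n))
  npat <- vapply(groups, function(g) {
    r <- config$patients_range[[g]]
    as.integer(round(runif(1, r[1], r[2])))
  }, integer(1))
  morph <- config$morph_range[1] +
    diff(config$morph_range) * rbeta(n, config$morph_beta[1], config$morph_beta[2])
  data.frame(
    trial_id = ids, domain_group = groups, n_patients = npat,
    morph_relapse_frac = round(morph, 4),
    age_group = sample(.age_groups, n, replace = TRUE, prob = c(0.35, 0.5, 0.15)),
    primary_refractory_frac = round(pmin(1, pmax(0, rbeta(n, 1.2, 9))), 4),
    bridge_hsct_frac = round(pmin(1, pmax(0, rbeta(n, 1.5, 5))), 4),
    scfv_clone = sample(.scfv_clones, n, replace = TRUE, prob = c(0.8, 0.2)),
    t_cell_origin = sample(.t_origins, n, replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic corpus of digitized survival curves
#'
#' Inverts the structural model: per trial it draws covariates and random
#' effects, simulates patient-level event times from
#' \eqn{S(t) = S_0(t;\mu_i,\sigma_i)^{m_i}} by inverse-CDF, applies
#' administrative and random censoring, computes the Kaplan-Meier estimator
#' (via [survival::survfit()]) and samples it on the digitization grid,
#' optionally perturbing the logit of each sampled value with residual
#' noise of SD \eqn{\epsilon}.  KM values of exactly 1 are moved to
#' \eqn{1 - 1/(2n)} before the logit-noise step.
#'
#' @param config [generator_config()].
#' @param seed integer seed; the corpus is bit-reproducible given the seed.
#' @return A list with `arms` (`mbma_trials`), `curves` (`mbma_curves`) and
#'   `truth` (generating parameters, per-trial random effects and
#'   covariates).
#' @export
generate_survival_dataset <- function(config = generator_config(), seed = 1L) {
  .with_rng(.substream(seed, "survival"), {
    arms <- .draw_arms(config)
    tr <- config$truth
    n <- nrow(arms)
    eta <- data.frame(
      trial_id = arms$trial_id,
      eta_sigma = rnorm(n, 0, tr$omega_sigma),
      eta_mu = rnorm(n, 0, tr$omega_mu), stringsAsFactors = FALSE)
    cut <- runif(n, config$cutoff_range[1], config$cutoff_range[2])
    rows <- list()
    dropped <- 0L
    for (ep in config$endpoints) {
      for (i in seq_len(n)) {
        g <- arms$domain_group[i]
        mu_i <- tr$mu[[g]] * exp(eta$eta_mu[i])
        sig_i <- tr$sigma[[g]] * exp(eta$eta_sigma[i])
        m_i <- .hazard_multiplier(tr, arms[i, , drop = FALSE])
        npat <- arms$n_patients[i]
        # S(t) = S0^m = u  =>  S0 = u^(1/m)
        u <- runif(npat)
        tev <- qlnorm(1 - u^(1 / m_i), meanlog = mu_i, sdlog = sig_i)
        cens <- rep(cut[i], npat)
        drop_idx <- runif(npat) < config$dropout_rate
        cens[drop_idx] <- runif(sum(drop_idx), 0, cut[i])
        time <- pmin(tev, cens)
        status <- as.integer(tev <= cens)
        km <- survival::survfit(survival::Surv(time, status) ~ 1)
        grid <- seq(config$grid_step, cut[i], by = config$grid_step)
        if (!length(grid)) grid <- config$grid_step
        sm <- summary(km, times = grid, extend = FALSE)
        if (length(sm$time) < length(grid)) dropped <- dropped + length(grid) - length(sm$time)
        s <- sm$surv
        keep <- s > 0
        s <- s[keep]; gt <- sm$time[keep]
        if (!length(s)) next
        if (config$resid_noise) {
          s <- pmin(s, 1 - 1 / (2 * npat))
          ylog <- residual_transform(s) + rnorm(length(s), 0, tr$epsilon)
          # digitized published curves are monotone by construction, so the
          # noisy curve is projected back onto the non-increasing cone by
          # least-squares isotonic regression (unbiased, unlike a cummax)
          if (length(ylog) > 1) ylog <- -stats::isoreg(seq_along(ylog), -ylog)$yf
          s <- inv_residual_transform(ylog)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = arms$trial_id[i], endpoint = ep, time_months = gt,
          surv_fraction = s, stringsAsFactors = FALSE)
      }
    }
    if (dropped > 0)
      warning(dropped, " grid points beyond the last follow-up time were dropped")
    curves <- do.call(rbind, rows)
    curves <- curves[order(curves$trial_id, curves$endpoint, curves$time_months), ]
    rownames(curves) <- NULL
    class(arms) <- c("mbma_trials", "data.frame")
    class(curves) <- c("mbma_curves", "data.frame")
    list(arms = arms, curves = curves,
         truth = list(params = tr, eta = eta,
                      covariates = arms[c("trial_id", "morph_relapse_frac")],
                      cutoff = cut, seed = seed))
  })
}

#' Generate synthetic proportion outcomes
#'
#' Per trial and endpoint, a latent logit is drawn from
#' \eqn{N(m_{\mathrm{group}}, s^2)} and events from
#' \eqn{\mathrm{Binomial}(n, \mathrm{logit}^{-1}(\cdot))}.
#'
#' @param config [generator_config()].
#' @param arms trial table to attach outcomes to; `NULL` draws a fresh one.
#' @param seed integer seed.
#' @return list with `props` (`mbma_props`) and `truth` (per-trial latent
#'   proportions).
#' @export
generate_proportion_dataset <- function(config = generator_config(),
                                        arms = NULL, seed = 1L) {
  .with_rng(.substream(seed, "proportions"), {
    if (is.null(arms)) arms <- .draw_arms(config)
    rows <- list(); latents <- list()
    for (r in seq_len(nrow(config$prop_truth))) {
      law <- config$prop_truth[r, ]
      sel <- which(arms$domain_group == law$group)
      if (!length(sel)) next
      lat <- rnorm(length(sel), law$logit_mean, law$logit_sd)
      pr <- plogis(lat)
      ev <- rbinom(length(sel), arms$n_patients[sel], pr)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = arms$trial_id[sel], endpoint = law$endpoint,
        events = ev, total = arms$n_patients[sel], stringsAsFactors = FALSE)
      latents[[length(latents) + 1L]] <- data.frame(
        trial_id = arms$trial_id[sel], endpoint = law$endpoint,
        latent_prop = pr, stringsAsFactors = FALSE)
    }
    props <- do.call(rbind, rows)
    rownames(props) <- NULL
    class(props) <- c("mbma_props", "data.frame")
    list(props = props, truth = do.call(rbind, latents), arms = arms)
  })
}

#' Generate a trial-level surrogate-endpoint table
#'
#' One latent standard-normal trait per trial; each endpoint's logit-scale
#' value loads on the trait with loading \eqn{\sqrt{\rho}} plus independent
#' noise \eqn{\sqrt{1-\rho}}, so every endpoint pair has latent correlation
#' \eqn{\rho}.  Values are mapped to percents; out-of-range values cannot
#' occur (inverse-logit mapping), but a `clipped` attribute is kept for the
#' contract.
#'
#' @param config [generator_config()] (uses `surrogate_correlation`).
#' @param arms trial table; `NULL` draws a fresh one.
#' @param seed integer seed.
#' @return data.frame of class `mbma_endpoints` with columns `trial_id`,
#'   `n_patients` and percent columns `ORR`, `MRD_NEG_CR`, `PFS_6m`,
#'   `PFS_12m`, `OS_12m`, `OS_24m`; attribute `latent` holds the latent
#'   traits.
#' @export
generate_surrogate_endpoints <- function(config = generator_config(),
                                         arms = NULL, seed = 1L) {
  .with_rng(.substream(seed, "surrogate"), {
    if (is.null(arms)) arms <- .draw_arms(config)
    rho <- config$surrogate_correlation
    sgn <- if (rho < 0) -1 else 1
    rho <- abs(rho)
    n <- nrow(arms)
    lat <- rnorm(n)
    centers <- c(ORR = 0.85, MRD_NEG_CR = 0.74, PFS_6m = 0.45, PFS_12m = 0.34,
                 OS_12m = 0.57, OS_24m = 0.35)
    out <- data.frame(trial_id = arms$trial_id, n_patients = arms$n_patients,
                      stringsAsFactors = FALSE)
    for (k in seq_along(centers)) {
      ep <- names(centers)[k]
      load_sign <- if (k == 1) 1 else sgn  # negative rho flips all but the first
      val <- qlogis(centers[[ep]]) +
        (load_sign * sqrt(rho) * lat + sqrt(1 - rho) * rnorm(n))
      out[[ep]] <- round(100 * plogis(val), 3)
    }
    attr(out, "latent") <- lat
    attr(out, "clipped") <- integer(0)
    class(out) <- c("mbma_endpoints", "data.frame")
    out
  })
}
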