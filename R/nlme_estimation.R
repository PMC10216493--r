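#' Estimation settings for [fit_model()]
#'
#' @param n_starts number of deterministic multi-starts; the first uses the
#'   data-driven initial values, the rest jitter them (fixed `start_seed`),
#'   and the best-OFV solution wins.
#' @param start_seed seed controlling the jittered starts.
#' @param rel_tol relative convergence tolerance on the OFV.
#' @param max_iter optimizer iteration cap.
#' @param estimate_omega logical; `FALSE` fits a fixed-effects model
#'   (both inter-trial SDs pinned at zero).
#' @param compute_rse logical; turn off to skip the finite-difference
#'   Hessian (used by bootstrap/leave-one-out refits).
#' @param omega_boundary threshold below which an estimated inter-trial SD
#'   is flagged as on the boundary.
#' @return A list of class `mbma_fit_config`.
#' @export
fit_config <- function(n_starts = 3L, start_seed = 1234L, rel_tol = 1e-6,
                       max_iter = 500L, estimate_omega = TRUE,
                       compute_rse = TRUE, omega_boundary = 1e-3) {
  structure(list(n_starts = as.integer(n_starts), start_seed = as.integer(start_seed),
                 rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 estimate_omega = isTRUE(estimate_omega),
                 compute_rse = isTRUE(compute_rse),
                 omega_boundary = omega_boundary),
            class = "mbma_fit_config")
}

# Assemble flattened per-endpoint fitting data.  Observed fractions of
# exactly 1 (a digitized point before the first event) get the standard
# 1 - 1/(2n) boundary adjustment so the logit is finite.
.prep_data <- function(arms, curves, endpoint, covariate_names = character(),
                       cov_ref = NULL, impute = TRUE) {
  obs <- curves[curves$endpoint == endpoint, , drop = FALSE]
  if (!nrow(obs)) stop("no survival observations for endpoint ", endpoint)
  unknown <- setdiff(unique(obs$trial_id), arms$trial_id)
  if (length(unknown))
    stop("survival observations reference unknown trials: ",
         paste(unknown, collapse = ", "))
  ids <- sort(unique(obs$trial_id))
  obs <- obs[order(obs$trial_id, obs$time_months), , drop = FALSE]
  a <- arms[match(ids, arms$trial_id), , drop = FALSE]
  s <- obs$surv_fraction
  n_at <- a$n_patients[match(obs$trial_id, ids)]
  s <- ifelse(s >= 1, 1 - 1 / (2 * n_at), s)
  covm <- NULL
  refs <- numeric()
  if (length(covariate_names)) {
    covm <- matrix(NA_real_, nrow(a), length(covariate_names),
                   dimnames = list(ids, covariate_names))
    for (cv in covariate_names) {
      if (!cv %in% names(a)) stop("unknown covariate column: ", cv)
      v <- a[[cv]]
      if (!is.numeric(v)) {  # categorical -> indicator for the first level
        lev <- sort(unique(v[!is.na(v)]))
        v <- as.numeric(v == lev[1])
      }
      if (anyNA(v)) {
        if (!impute) stop("covariate ", cv, " is missing for trials: ",
                          paste(ids[is.na(v)], collapse = ", "))
        v[is.na(v)] <- median(v, na.rm = TRUE)
      }
      covm[, cv] <- v
      refs[cv] <- if (!is.null(cov_ref) && cv %in% names(cov_ref))
        cov_ref[[cv]] else if (cv == "morph_relapse_frac") 0.85 else median(v)
    }
  }
  cnt <- as.integer(table(factor(obs$trial_id, levels = ids)))
  list(ids = ids, group = a$domain_group, n_patients = a$n_patients,
       y = residual_transform(s), logt = log(obs$time_months),
       trial = match(obs$trial_id, ids),
       start = c(0L, cumsum(cnt))[seq_along(ids)], len = cnt,
       covm = covm, refs = refs, obs = obs)
}

.mscale_from <- function(dat, theta) {
  if (!length(theta)) return(rep(1, length(dat$ids)))
  exp(as.vector(dat$covm[, names(theta), drop = FALSE] %*% theta -
                  sum(theta * dat$refs[names(theta)])))
}

.ofv_from_params <- function(dat, params, want_eb = FALSE) {
  mu_t <- unname(params$mu[dat$group])
  sig_t <- unname(params$sigma[dat$group])
  mscale <- .mscale_from(dat, params$theta)
  res <- laplace_ofv_cpp(dat$y, dat$logt, dat$start, dat$len, mu_t, sig_t,
                         mscale, params$omega_sigma, params$omega_mu,
                         params$epsilon, want_eb)
  if (!res$ok) {
    i <- res$bad_trial
    stop(sprintf("non-finite likelihood for trial %s (first time %.3g months)",
                 dat$ids[i], exp(dat$logt[dat$start[i] + 1])))
  }
  res
}

#' Marginal objective function (OFV)
#'
#' \eqn{-2 \log} of the Laplace-approximated marginal likelihood of the
#' logit-scale survival residuals, integrating the two trial-level random
#' effects per trial around their conditional modes.  With both inter-trial
#' SDs at zero this reduces exactly to the fixed-effects Gaussian
#' \eqn{-2\log L = \sum_j \{r_j^2/\epsilon^2 + \ln(2\pi\epsilon^2)\}}.
#'
#' @param arms trial table.
#' @param curves survival observations (one endpoint is selected).
#' @param params [population_params()] with the covariate coefficients to
#'   apply (the covariates named in `params$theta` must exist in `arms`).
#' @param endpoint `"OS"` or `"PFS"`.
#' @return The OFV (numeric scalar).
#' @export
objective_function <- function(arms, curves, params, endpoint = "OS") {
  dat <- .prep_data(arms, curves, endpoint, names(params$theta),
                    cov_ref = params$cov_ref)
  .ofv_from_params(dat, params)$ofv
}

# parameter packing: mu_g identity, log sigma_g, theta identity,
# log omega_sigma, log omega_mu, log epsilon
.pack_names <- function(groups, covs, est_om) {
  c(paste0("mu(", groups, ")"), paste0("log_sigma(", groups, ")"), covs,
    if (est_om) c("log_omega_sigma", "log_omega_mu"), "log_epsilon")
}

.unpack <- function(par, groups, covs, est_om) {
  ng <- length(groups); nc <- length(covs)
  mu <- setNames(par[seq_len(ng)], groups)
  sigma <- setNames(exp(par[ng + seq_len(ng)]), groups)
  theta <- if (nc) setNames(par[2 * ng + seq_len(nc)], covs) else numeric()
  i <- 2 * ng + nc
  if (est_om) {
    om_s <- exp(unname(par[i + 1])); om_m <- exp(unname(par[i + 2]))
    eps <- exp(unname(par[i + 3]))
  } else {
    om_s <- 0; om_m <- 0; eps <- exp(unname(par[i + 1]))
  }
  list(mu = mu, sigma = sigma, theta = theta,
       omega_sigma = om_s, omega_mu = om_m, epsilon = eps)
}

.init_par <- function(dat, groups, covs, est_om, init = NULL) {
  # data-driven start for mu: log median crossing time of S = 0.5 per group
  mu0 <- sapply(groups, function(g) {
    tt <- c()
    for (i in which(dat$group == g)) {
      idx <- dat$start[i] + seq_len(dat$len[i])
      s <- inv_residual_transform(dat$y[idx]); t <- exp(dat$logt[idx])
      cross <- .crossing_time(t, s, 0.5)
      if (!is.na(cross) && min(s) <= 0.5) tt <- c(tt, cross)
    }
    if (length(tt)) log(median(tt)) else mean(dat$logt[dat$trial %in% which(dat$group == g)])
  })
  par <- c(mu0, rep(0, length(groups)),              # sigma = 1
           rep(0, length(covs)),                     # theta = 0
           if (est_om) c(log(0.2), log(0.2)), log(0.5))
  if (!is.null(init)) {
    if (!is.null(init$mu)) par[seq_along(groups)] <- init$mu[groups]
    if (!is.null(init$sigma)) par[length(groups) + seq_along(groups)] <- log(init$sigma[groups])
    if (!is.null(init$theta) && length(covs)) {
      th <- rep(0, length(covs)); names(th) <- covs
      th[intersect(covs, names(init$theta))] <- init$theta[intersect(covs, names(init$theta))]
      par[2 * length(groups) + seq_along(covs)] <- th
    }
    i <- 2 * length(groups) + length(covs)
    if (est_om) {
      if (!is.null(init$omega_sigma)) par[i + 1] <- log(max(init$omega_sigma, 1e-3))
      if (!is.null(init$omega_mu)) par[i + 2] <- log(max(init$omega_mu, 1e-3))
      if (!is.null(init$epsilon)) par[i + 3] <- log(init$epsilon)
    } else if (!is.null(init$epsilon)) par[i + 1] <- log(init$epsilon)
  }
  par
}

#' Fit the MBMA survival model
#'
#' Maximises the Laplace-approximated marginal likelihood over the fixed
#' effects (group-specific \eqn{\mu}, \eqn{\sigma}, covariate coefficients
#' \eqn{\theta}), the inter-trial SDs \eqn{\omega_\sigma, \omega_\mu} and
#' the residual SD \eqn{\epsilon}.  Optimization runs in transformed space
#' (log for the positive parameters) with a deterministic multi-start;
#' relative standard errors come from the central-difference Hessian of the
#' OFV, empirical-Bayes effects are the per-trial conditional modes, and
#' shrinkage is \eqn{100\,(1 - \mathrm{SD}(\hat\eta)/\omega)} (for
#' \eqn{\epsilon}: \eqn{100\,(1 - \mathrm{SD}(\mathrm{IWRES}))}).
#'
#' @param arms trial table ([read_trial_table()]).
#' @param curves survival observations ([read_survival_curves()]).
#' @param endpoint `"OS"` or `"PFS"`.
#' @param included_covariates character vector of trial-table columns used
#'   as proportional-hazards covariates (centered at 0.85 for
#'   `morph_relapse_frac`, at the observed median otherwise).  Trials with
#'   a missing value are median-imputed.
#' @param init optional list of starting values (`mu`, `sigma`, `theta`,
#'   `omega_sigma`, `omega_mu`, `epsilon`), e.g. a previous fit's estimates.
#' @param config [fit_config()] settings.
#' @return An object of class `mbma_fit` with elements `estimates`
#'   ([population_params()]), `rse_percent`, `ci95`, `ofv`, `eb_effects`,
#'   `shrinkage_percent`, `converged`, `n_function_evals`.
#' @export
fit_model <- function(arms, curves, endpoint = "OS",
                      included_covariates = character(), init = NULL,
                      config = fit_config()) {
  dat <- .prep_data(arms, curves, endpoint, included_covariates)
  groups <- sort(unique(dat$group))
  for (g in groups)
    if (sum(dat$group == g) < 2 && config$estimate_omega)
      warning("fewer than 2 trials in group ", g,
              "; inter-trial variability is weakly identified")
  if (any(dat$len < 3))
    warning("trials with fewer than 3 digitized points: ",
            paste(dat$ids[dat$len < 3], collapse = ", "))
  est_om <- config$estimate_omega && length(dat$ids) >= 2
  covs <- included_covariates

  nev <- 0L
  obj <- function(par) {
    nev <<- nev + 1L
    p <- .unpack(par, groups, covs, est_om)
    mu_t <- unname(p$mu[dat$group]); sig_t <- unname(p$sigma[dat$group])
    mscale <- .mscale_from(dat, p$theta)
    res <- laplace_ofv_cpp(dat$y, dat$logt, dat$start, dat$len, mu_t, sig_t,
                           mscale, p$omega_sigma, p$omega_mu, p$epsilon, FALSE)
    if (!res$ok || !is.finite(res$ofv)) return(1e10)
    res$ofv
  }

  base_par <- .init_par(dat, groups, covs, est_om, init)
  starts <- list(base_par)
  if (config$n_starts > 1) {
    jrng <- .substream(config$start_seed, "multistart")
    for (k in seq_len(config$n_starts - 1))
      starts[[k + 1]] <- base_par + .with_rng(jrng + k, runif(length(base_par), -0.3, 0.3))
  }
  best <- NULL
  for (st in starts) {
    opt <- nlminb(st, obj, control = list(rel.tol = config$rel_tol * 1e-2,
                                          iter.max = config$max_iter,
                                          eval.max = 4L * config$max_iter))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  opt <- best
  converged <- opt$convergence == 0 && opt$objective < 1e9

  p <- .unpack(opt$par, groups, covs, est_om)
  estimates <- population_params(
    mu = p$mu, sigma = p$sigma, theta = p$theta,
    cov_ref = if (length(covs)) dat$refs[covs] else numeric(),
    omega_sigma = p$omega_sigma, omega_mu = p$omega_mu, epsilon = p$epsilon)

  boundary <- est_om && (p$omega_sigma < config$omega_boundary ||
                           p$omega_mu < config$omega_boundary)
  if (boundary)
    warning("an inter-trial SD was estimated at its lower boundary; ",
            "the random-effects structure may not be identifiable here")

  pn <- .pack_names(groups, covs, est_om)
  rse <- setNames(rep(NA_real_, length(pn)), pn)
  ci95 <- NULL
  vcov_t <- NULL
  if (config$compute_rse && converged) {
    H <- .fd_hessian(obj, opt$par)
    vc <- try(2 * solve(H), silent = TRUE)   # OFV = -2 logL
    if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
        all(diag(vc) > 0)) {
      vcov_t <- vc
      se_t <- sqrt(diag(vc))
      nat <- .natural_values(opt$par, groups, covs, est_om)
      is_log <- grepl("^log_", pn)
      se_nat <- ifelse(is_log, se_t * nat, se_t)
      rse <- setNames(100 * se_nat / abs(nat), pn)
      lo <- ifelse(is_log, exp(opt$par - 1.96 * se_t), opt$par - 1.96 * se_t)
      hi <- ifelse(is_log, exp(opt$par + 1.96 * se_t), opt$par + 1.96 * se_t)
      ci95 <- data.frame(parameter = .natural_names(pn), estimate = nat,
                         lower = lo, upper = hi, rse_percent = unname(rse))
    }
  }
  names(rse) <- .natural_names(pn)

  eb_res <- .ofv_from_params(dat, estimates, want_eb = TRUE)
  eb <- data.frame(trial_id = dat$ids,
                   eta_sigma = eb_res$eta[, 1], eta_mu = eb_res$eta[, 2],
                   stringsAsFactors = FALSE)
  shr <- c(eta_sigma = NA_real_, eta_mu = NA_real_, epsilon = NA_real_)
  if (est_om && p$omega_sigma > 0)
    shr["eta_sigma"] <- compute_shrinkage(eb$eta_sigma, p$omega_sigma)
  if (est_om && p$omega_mu > 0)
    shr["eta_mu"] <- compute_shrinkage(eb$eta_mu, p$omega_mu)
  mu_i <- unname(estimates$mu[dat$group]) * exp(eb$eta_mu)
  sig_i <- unname(estimates$sigma[dat$group]) * exp(eb$eta_sigma)
  ipred <- predict_logit_surv_cpp(dat$logt, dat$trial, mu_i, sig_i,
                                  .mscale_from(dat, estimates$theta))
  shr["epsilon"] <- 100 * (1 - sd((dat$y - ipred) / p$epsilon))

  structure(list(estimates = estimates, rse_percent = rse, ci95 = ci95,
                 ofv = opt$objective, eb_effects = eb,
                 cond_hessian = eb_res$cond_hessian,
                 shrinkage_percent = shr,
                 converged = converged, boundary = boundary,
                 n_function_evals = nev,
                 endpoint = endpoint, included_covariates = covs,
                 groups = groups, data = dat, config = config,
                 vcov_trans = vcov_t, par_trans = opt$par,
                 message = opt$message),
            class = "mbma_fit")
}

.natural_names <- function(pn) {
  out <- sub("^log_", "", pn)
  sub("^sigma\\(", "sigma(", out)
}

.natural_values <- function(par, groups, covs, est_om) {
  p <- .unpack(par, groups, covs, est_om)
  c(unname(p$mu), unname(p$sigma), unname(p$theta),
    if (est_om) c(p$omega_sigma, p$omega_mu), p$epsilon)
}

.fd_hessian <- function(f, x, rel_step = 1e-4) {
  n <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' @export
print.mbma_fit <- function(x, ...) {
  cat(sprintf("MBMA survival model fit (%s), OFV = %.3f, %s\n", x$endpoint,
              x$ofv, if (x$converged) "converged" else "NOT converged"))
  print(x$estimates)
  if (!all(is.na(x$rse_percent))) {
    cat("RSE%:\n")
    print(round(x$rse_percent, 1))
  }
  cat("Shrinkage %:", paste(sprintf("%s %.1f", names(x$shrinkage_percent),
                                    x$shrinkage_percent), collapse = ", "), "\n")
  invisible(x)
}

#' Empirical-Bayes shrinkage
#'
#' \eqn{100\,(1 - \mathrm{SD}(\hat\eta)/\omega)}, the standard measure of
#' how much the conditional-mode estimates are pulled toward zero relative
#' to the population SD.  Values near 100% mean the data carry almost no
#' trial-level information.
#'
#' @param eb_effects numeric vector of empirical-Bayes estimates (>= 2).
#' @param omega positive population SD of the random effect.
#' @return Shrinkage percent (can be negative; at most 100).
#' @export
compute_shrinkage <- function(eb_effects, omega) {
  if (!is.numeric(omega) || length(omega) != 1 || omega <= 0)
    stop("'omega' must be a positive scalar")
  if (length(eb_effects) < 2) stop("need at least 2 empirical-Bayes estimates")
  100 * (1 - sd(eb_effects) / omega)
}

#' Stepwise covariate selection on the OFV
#'
#' Forward inclusion (largest OFV drop first, requiring at least the
#' forward threshold) followed by backward elimination (a retained covariate
#' must worsen the OFV by at least the backward threshold when removed).
#' Default thresholds 3.84 / 6.63 are the 1-df chi-square critical values
#' at p = 0.05 and p = 0.01.  Candidates missing for more than 30% of
#' trials are excluded up front with a warning; remaining missing values
#' are median-imputed by the fitter.
#'
#' @inheritParams fit_model
#' @param candidates character vector of trial-table columns to screen.
#' @param forward,backward OFV-change thresholds.
#' @return An object of class `mbma_covsearch`: `selected`, `trace`
#'   (candidate, delta_ofv, decision per step), `base_ofv`, `final_fit`.
#' @export
covariate_search <- function(arms, curves, endpoint = "OS",
                             candidates = character(),
                             forward = 3.84, backward = 6.63,
                             config = fit_config()) {
  keep <- character()
  for (cv in candidates) {
    if (!cv %in% names(arms)) stop("unknown candidate covariate: ", cv)
    frac_ok <- mean(!is.na(arms[[cv]]))
    if (frac_ok < 0.7)
      warning("candidate ", cv, " available for only ",
              round(100 * frac_ok), "% of trials; excluded from the search")
    else keep <- c(keep, cv)
  }
  candidates <- keep
  trace <- list()
  note <- function(candidate, delta, decision)
    trace[[length(trace) + 1L]] <<- data.frame(
      candidate = candidate, delta_ofv = delta, decision = decision,
      stringsAsFactors = FALSE)

  base_fit <- fit_model(arms, curves, endpoint, character(), config = config)
  base_ofv <- base_fit$ofv
  selected <- character()
  current_fit <- base_fit
  fits <- list()
  remaining <- candidates
  while (length(remaining)) {
    deltas <- sapply(remaining, function(cv) {
      f <- fit_model(arms, curves, endpoint, c(selected, cv),
                     init = current_fit$estimates, config = config)
      fits[[cv]] <<- f
      current_fit$ofv - f$ofv
    })
    bestc <- remaining[which.max(deltas)]
    if (max(deltas) >= forward) {
      note(bestc, max(deltas), "forward: included")
      selected <- c(selected, bestc)
      current_fit <- fits[[bestc]]
      remaining <- setdiff(remaining, bestc)
    } else {
      for (cv in remaining) note(cv, deltas[[cv]], "forward: below threshold")
      break
    }
  }
  # backward elimination
  drop_any <- TRUE
  while (drop_any && length(selected)) {
    drop_any <- FALSE
    for (cv in selected) {
      f <- fit_model(arms, curves, endpoint, setdiff(selected, cv),
                     init = current_fit$estimates, config = config)
      inc <- f$ofv - current_fit$ofv
      if (inc < backward) {
        note(cv, inc, "backward: removed")
        selected <- setdiff(selected, cv)
        current_fit <- f
        drop_any <- TRUE
        break
      } else {
        note(cv, inc, "backward: retained")
      }
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(candidate = character(), delta_ofv = numeric(),
               decision = character(), stringsAsFactors = FALSE)
  structure(list(selected = selected, trace = trace, base_ofv = base_ofv,
                 final_fit = current_fit),
            class = "mbma_covsearch")
}

#' @export
print.mbma_covsearch <- function(x, ...) {
  cat("Stepwise covariate search: base OFV", round(x$base_ofv, 3), "\n")
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  if (nrow(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Export a fit as JSON
#'
#' Writes estimates, RSE%, OFV, per-trial empirical-Bayes effects,
#' shrinkage and convergence metadata to a JSON file.
#'
#' @param fit `mbma_fit` object.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(
    endpoint = fit$endpoint,
    estimates = list(mu = as.list(fit$estimates$mu),
                     sigma = as.list(fit$estimates$sigma),
                     theta = as.list(fit$estimates$theta),
                     cov_ref = as.list(fit$estimates$cov_ref),
                     omega_sigma = fit$estimates$omega_sigma,
                     omega_mu = fit$estimates$omega_mu,
                     epsilon = fit$estimates$epsilon),
    rse_percent = as.list(fit$rse_percent),
    ofv = fit$ofv,
    shrinkage_percent = as.list(fit$shrinkage_percent),
    eb_effects = fit$eb_effects,
    converged = fit$converged,
    n_function_evals = fit$n_function_evals)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
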