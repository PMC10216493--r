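#' @useDynLib mbmasurv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm dnorm rnorm runif rbinom median sd quantile
#'   lm coef vcov setNames approx qlnorm integrate optimize var weighted.mean
#'   cov.wt complete.cases plogis qlogis aggregate nlminb rbeta
NULL

.groups <- c("4-1BB", "CD28")

#' Population-level parameters of the MBMA survival model
#'
#' Container for the fixed effects, covariate coefficients, inter-trial
#' random-effect standard deviations and residual error of the log-normal
#' mixed-effects survival model.  The baseline model for a trial in group
#' \eqn{g} is a log-normal survival function with location
#' \eqn{\mu_i = \mu_g e^{\eta_\mu}} (log-months) and scale
#' \eqn{\sigma_i = \sigma_g e^{\eta_\sigma}}; trial-level covariates act as
#' proportional-hazards multipliers \eqn{m_i = \exp\{\sum_c \theta_c
#' (x_{ic} - r_c)\}} so that \eqn{S_i(t) = S_0(t;\mu_i,\sigma_i)^{m_i}}.
#'
#' @param mu named numeric vector of \eqn{\mu} per co-stimulatory group
#'   (names among `"4-1BB"`, `"CD28"`), log-months scale.
#' @param sigma named numeric vector of \eqn{\sigma > 0} per group.
#' @param theta named numeric vector of covariate coefficients (may be
#'   empty); names are covariate column names in the trial table.
#' @param cov_ref named numeric vector of centering constants, one per
#'   entry of `theta` (e.g. 0.85 for the morphological-relapse fraction).
#' @param omega_sigma,omega_mu non-negative SDs of the trial-level random
#'   effects on \eqn{\sigma} and \eqn{\mu}.
#' @param epsilon positive residual SD on the logit-survival scale.
#' @return An object of class `mbma_params`.
#' @examples
#' population_params(mu = c("4-1BB" = 2.83, "CD28" = 2.23),
#'                   sigma = c("4-1BB" = 1.52, "CD28" = 1.42),
#'                   theta = c(morph_relapse_frac = 1.22),
#'                   cov_ref = c(morph_relapse_frac = 0.85),
#'                   omega_sigma = 0.329, omega_mu = 0.240, epsilon = 0.623)
#' @export
population_params <- function(mu, sigma, theta = numeric(), cov_ref = numeric(),
                              omega_sigma = 0, omega_mu = 0, epsilon = 0.5) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(mu) == length(sigma))
  if (is.null(names(mu)) || !all(names(mu) %in% .groups))
    stop("'mu' must be named with groups among: ", paste(.groups, collapse = ", "))
  if (!identical(sort(names(mu)), sort(names(sigma))))
    stop("'mu' and 'sigma' must cover the same groups")
  if (any(sigma <= 0)) stop("'sigma' values must be positive")
  theta <- unlist(theta); cov_ref <- unlist(cov_ref)
  if (length(theta)) {
    if (is.null(names(theta)) || !all(nzchar(names(theta))))
      stop("'theta' must be a named vector of covariate coefficients")
    if (!all(names(theta) %in% names(cov_ref)))
      stop("every covariate in 'theta' needs a centering value in 'cov_ref'")
  }
  if (omega_sigma < 0 || omega_mu < 0) stop("omega values must be non-negative")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("'epsilon' must be positive")
  structure(list(mu = mu, sigma = sigma[names(mu)],
                 theta = theta, cov_ref = cov_ref[names(theta)],
                 omega_sigma = omega_sigma, omega_mu = omega_mu,
                 epsilon = epsilon),
            class = "mbma_params")
}

#' @export
print.mbma_params <- function(x, ...) {
  cat("MBMA log-normal survival model parameters\n")
  for (g in names(x$mu))
    cat(sprintf("  %-6s mu = %.4g  sigma = %.4g\n", g, x$mu[[g]], x$sigma[[g]]))
  if (length(x$theta))
    for (cv in names(x$theta))
      cat(sprintf("  theta[%s] = %.4g (ref %.4g)\n", cv, x$theta[[cv]], x$cov_ref[[cv]]))
  cat(sprintf("  omega_sigma = %.4g  omega_mu = %.4g  epsilon = %.4g\n",
              x$omega_sigma, x$omega_mu, x$epsilon))
  invisible(x)
}

#' Log-normal survival function
#'
#' \eqn{S(t) = 1 - \Phi\{(\ln t - \mu)/\sigma\}}: the probability that a
#' log-normally distributed event time exceeds `t` months.
#'
#' @param t positive event time(s), months.
#' @param mu location on the log-months scale; `exp(mu)` is the median
#'   survival time.
#' @param sigma positive scale.
#' @return Survival fraction(s) in (0, 1).
#' @export
lognormal_survival <- function(t, mu, sigma) {
  if (any(!is.finite(t)) || any(t <= 0)) stop("'t' must be positive and finite")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  pnorm((log(t) - mu) / sigma, lower.tail = FALSE)
}

#' Log-normal hazard function
#'
#' Instantaneous event rate \eqn{h(t) = \phi(z) / \{t \sigma (1 - \Phi(z))\}}
#' with \eqn{z = (\ln t - \mu)/\sigma}.  Vanishes as \eqn{t \to 0^+} and is
#' non-monotone (rises then falls), which is what makes the log-normal a
#' natural basis for relapse/refractory leukemia survival.
#'
#' @inheritParams lognormal_survival
#' @return Hazard rate(s) per month.
#' @export
lognormal_hazard <- function(t, mu, sigma) {
  if (any(!is.finite(t)) || any(t <= 0)) stop("'t' must be positive and finite")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  z <- (log(t) - mu) / sigma
  # density/survival computed on the log scale to stay stable far in the tail
  exp(dnorm(z, log = TRUE) - pnorm(z, lower.tail = FALSE, log.p = TRUE)) / (t * sigma)
}

#' Proportional-hazards covariate multiplier
#'
#' Exponential covariate model \eqn{m = \exp\{\theta (x - r)\}} applied to
#' the baseline hazard; equals 1 when the covariate sits at its reference
#' (centering) value.
#'
#' @param cov_value covariate value(s) \eqn{x}.
#' @param theta log-linear coefficient.
#' @param reference centering constant \eqn{r}.
#' @return Positive hazard multiplier(s).
#' @export
covariate_hazard_multiplier <- function(cov_value, theta, reference) {
  exp(theta * (cov_value - reference))
}

.hazard_multiplier <- function(params, covariates) {
  if (!length(params$theta)) return(1)
  m <- 0
  for (cv in names(params$theta)) {
    val <- covariates[[cv]]
    if (is.null(val) || is.na(val))
      stop("missing required covariate: ", cv)
    m <- m + params$theta[[cv]] * (val - params$cov_ref[[cv]])
  }
  exp(unname(m))
}

.trial_musig <- function(params, group, eta) {
  group <- match.arg(group, names(params$mu))
  list(mu = params$mu[[group]] * exp(eta[["mu"]]),
       sigma = params$sigma[[group]] * exp(eta[["sigma"]]))
}

#' Trial-level survival curve
#'
#' Survival fractions for one trial: group-specific log-normal baseline with
#' trial random effects folded in multiplicatively
#' (\eqn{\mu_i = \mu_g e^{\eta_\mu}}, \eqn{\sigma_i = \sigma_g
#' e^{\eta_\sigma}}) and the covariate hazard multiplier applied through the
#' proportional-hazards identity \eqn{S = S_0^m}.
#'
#' @param times positive times, months.
#' @param params [population_params()] object.
#' @param group co-stimulatory group, `"4-1BB"` or `"CD28"`.
#' @param eta named numeric vector `c(sigma=, mu=)` of trial random effects.
#' @param covariates named list/vector of covariate values for every
#'   covariate carried in `params$theta`.
#' @return Survival fractions, same length as `times`.
#' @export
trial_survival_curve <- function(times, params, group,
                                 eta = c(sigma = 0, mu = 0),
                                 covariates = list()) {
  p <- .trial_musig(params, group, eta)
  m <- .hazard_multiplier(params, covariates)
  s0 <- lognormal_survival(times, p$mu, p$sigma)
  s0 ^ m
}

#' Survival-time quantile of a trial-level curve
#'
#' Closed-form inverse of [trial_survival_curve()]: the time at which the
#' trial's survival fraction equals `q`, i.e.
#' \eqn{t = \exp\{\mu_i + \sigma_i \Phi^{-1}(1 - q^{1/m})\}}.
#' With `q = 0.5` and no covariate effect this is the median survival
#' `exp(mu_i)`.
#'
#' @inheritParams trial_survival_curve
#' @param q target survival fraction in (0, 1).
#' @return Time in months.
#' @export
predict_survival_quantile <- function(params, group, q,
                                      eta = c(sigma = 0, mu = 0),
                                      covariates = list()) {
  if (any(q <= 0 | q >= 1)) stop("'q' must lie strictly inside (0, 1)")
  p <- .trial_musig(params, group, eta)
  m <- .hazard_multiplier(params, covariates)
  exp(p$mu + p$sigma * qnorm(1 - q ^ (1 / m)))
}

#' Logit transform of a survival fraction
#'
#' The residual-error scale of the model: observed and predicted survival
#' fractions are compared on \eqn{\mathrm{logit}(s) = \ln\{s/(1-s)\}}, which
#' keeps perturbed predictions inside (0, 1).
#'
#' @param s survival fraction(s) strictly inside (0, 1).
#' @return Unbounded real value(s).
#' @seealso [inv_residual_transform()]
#' @export
residual_transform <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0 | s >= 1))
    stop("survival fractions must lie strictly inside (0, 1)")
  qlogis(s)
}

#' Inverse logit transform
#'
#' @param x unbounded real value(s).
#' @return Survival fraction(s) in (0, 1).
#' @export
inv_residual_transform <- function(x) plogis(x)
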