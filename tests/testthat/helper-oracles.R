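# Independent oracles, written from the model formulas in plain R.  They
# deliberately avoid the package's C++ path and its clamping tricks.

# Gauss-Hermite nodes/weights by Golub-Welsch (weight function exp(-x^2))
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# penalized conditional -log-likelihood of one trial, plain R
h_plain <- function(eta_s, eta_m, tt, yobs, mu0, sig0, m, om_s, om_m, eps) {
  mu <- mu0 * exp(eta_m)
  sig <- sig0 * exp(eta_s)
  S0 <- pnorm((log(tt) - mu) / sig, lower.tail = FALSE)
  yh <- qlogis(S0^m)
  h <- -sum(dnorm(yobs, yh, eps, log = TRUE))
  if (om_s > 0) h <- h - dnorm(eta_s, 0, om_s, log = TRUE)
  if (om_m > 0) h <- h - dnorm(eta_m, 0, om_m, log = TRUE)
  h
}

# adaptive Gauss-Hermite marginal -2 log-likelihood for a list of trials.
# Each trial: list(t, y, mu0, sig0, m).  Centering/scaling at the
# conditional mode found by optim with a numerically differenced Hessian.
agq_ofv <- function(trials, om_s, om_m, eps, nodes = 32) {
  rule <- gh_rule(nodes)
  total <- 0
  for (tr in trials) {
    act <- c(om_s > 0, om_m > 0)
    d <- sum(act)
    fn <- function(e) {
      eta <- c(0, 0)
      eta[act] <- e
      h_plain(eta[1], eta[2], tr$t, tr$y, tr$mu0, tr$sig0, tr$m, om_s, om_m, eps)
    }
    if (d == 0) {
      total <- total + 2 * fn(numeric(0))
      next
    }
    opt <- optim(rep(0, d), fn, method = "BFGS", hessian = TRUE)
    mode <- opt$par
    H <- opt$hessian
    A <- t(chol(solve(H)))          # H^{-1} = A %*% t(A)
    if (d == 1) {
      z <- matrix(rule$x, ncol = 1)
      w <- rule$w
    } else {
      gr <- expand.grid(i = seq_len(nodes), j = seq_len(nodes))
      z <- cbind(rule$x[gr$i], rule$x[gr$j])
      w <- rule$w[gr$i] * rule$w[gr$j]
    }
    vals <- vapply(seq_len(nrow(z)), function(k) {
      e <- mode + sqrt(2) * as.vector(A %*% z[k, ])
      exp(-fn(e) + sum(z[k, ]^2))
    }, numeric(1))
    Li <- 2^(d / 2) * abs(det(A)) * sum(w * vals)
    total <- total - 2 * log(Li)
  }
  total
}

# DerSimonian-Laird random-effects pooling, closed form
dl_pool <- function(yi, vi) {
  w <- 1 / vi
  ybar <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - ybar)^2)
  k <- length(yi)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (vi + tau2)
  est <- sum(ws * yi) / sum(ws)
  list(est = est, se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# tiny deterministic toy corpus for likelihood tests: observations generated
# from the closed-form survival function plus fixed perturbations
toy_trials <- function(n_trials = 2, mu0 = 2.8, sig0 = 1.5, m = 1,
                       eps_jit = c(0.1, -0.15, 0.05, 0.12, -0.08, 0.02)) {
  tt <- c(3, 6, 12)
  lapply(seq_len(n_trials), function(i) {
    s <- pnorm((log(tt) - mu0) / sig0, lower.tail = FALSE)^m
    y <- qlogis(s) + eps_jit[((i - 1) * 3 + 1):((i - 1) * 3 + 3)]
    list(t = tt, y = y, mu0 = mu0, sig0 = sig0, m = m)
  })
}

# package-facing data frames for the same toy
toy_frames <- function(trials, group = "4-1BB", endpoint = "OS") {
  arms <- data.frame(
    trial_id = sprintf("T%02d", seq_along(trials)),
    domain_group = group, n_patients = 30L,
    morph_relapse_frac = 0.85, age_group = "mixed",
    primary_refractory_frac = NA_real_, bridge_hsct_frac = NA_real_,
    scfv_clone = NA_character_, t_cell_origin = NA_character_,
    stringsAsFactors = FALSE)
  curves <- do.call(rbind, lapply(seq_along(trials), function(i)
    data.frame(trial_id = sprintf("T%02d", i), endpoint = endpoint,
               time_months = trials[[i]]$t,
               surv_fraction = plogis(trials[[i]]$y),
               stringsAsFactors = FALSE)))
  class(arms) <- c("mbma_trials", "data.frame")
  class(curves) <- c("mbma_curves", "data.frame")
  list(arms = arms, curves = curves)
}
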