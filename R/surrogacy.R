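.surrogate_endpoints <- c("ORR", "MRD_NEG_CR", "PFS_6m", "PFS_12m",
                          "OS_12m", "OS_24m")

#' Weighted linear regression between two trial-level endpoints
#'
#' Weighted least squares of `y` on `x` (weights default to trial sample
#' size, matching forest-plot convention where point size tracks patients),
#' with \eqn{R^2} defined as the weighted squared Pearson correlation --
#' identical to the regression \eqn{R^2} for simple WLS.  Pairs with a
#' missing value are dropped listwise.
#'
#' @param x,y percent-scale endpoint values per trial.
#' @param weights positive weights (e.g. `n_patients`).
#' @param x_name,y_name endpoint labels carried into the result.
#' @return An object of class `mbma_regression`: `slope`, `intercept`,
#'   `r2`, `k`, `classification` per [classify_correlation()].
#' @export
weighted_linear_regression <- function(x, y, weights = NULL,
                                       x_name = "x", y_name = "y") {
  if (is.null(weights)) weights <- rep(1, length(x))
  keep <- complete.cases(x, y, weights)
  x <- x[keep]; y <- y[keep]; w <- weights[keep]
  if (length(x) < 3) stop("need at least 3 complete (x, y) pairs, have ", length(x))
  if (any(w <= 0)) stop("weights must be positive")
  if (var(x) == 0) stop("zero variance in x; regression is undefined")
  fit <- lm(y ~ x, weights = w)
  r <- cov.wt(cbind(x, y), wt = w, cor = TRUE)$cor[1, 2]
  structure(list(x_endpoint = x_name, y_endpoint = y_name,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = r^2, k = length(x),
                 classification = classify_correlation(r^2)),
            class = "mbma_regression")
}

#' @export
print.mbma_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s: slope %.3f, intercept %.3f, R2 = %.3f (%s), k = %d\n",
              x$y_endpoint, x$x_endpoint, x$slope, x$intercept, x$r2,
              x$classification, x$k))
  invisible(x)
}

#' Classify an R-squared value
#'
#' Prespecified strength bands for trial-level surrogacy:
#' \eqn{R^2 \ge 0.8} high, \eqn{0.6 \le R^2 < 0.8} moderate,
#' \eqn{R^2 < 0.6} low.
#'
#' @param r2 value in `[0, 1]`.
#' @return `"high"`, `"moderate"` or `"low"`.
#' @export
classify_correlation <- function(r2) {
  if (!is.numeric(r2) || length(r2) != 1 || is.na(r2) || r2 < 0 || r2 > 1)
    stop("'r2' must be a single value in [0, 1]")
  if (r2 >= 0.8) "high" else if (r2 >= 0.6) "moderate" else "low"
}

#' Surrogacy matrix over the standard endpoint pairs
#'
#' Fits [weighted_linear_regression()] independently for every ordered
#' predictor-outcome pair among: ORR and MRD-negative CR against 0.5/1-year
#' PFS and 1/2-year OS, and 0.5/1-year PFS against 1/2-year OS.  Pairs with
#' fewer than 3 complete cases are recorded as not estimable.
#'
#' @param table `mbma_endpoints` data frame (columns `trial_id`,
#'   `n_patients` and percent columns among `ORR`, `MRD_NEG_CR`, `PFS_6m`,
#'   `PFS_12m`, `OS_12m`, `OS_24m`).
#' @return data frame of class `mbma_surrogacy`: one row per pair with
#'   slope, intercept, `r2`, `k`, `classification` (`"not estimable"` when
#'   the fit was impossible).
#' @export
surrogacy_matrix <- function(table) {
  if (!nrow(table)) stop("empty endpoint table")
  pairs <- rbind(
    expand.grid(x = c("ORR", "MRD_NEG_CR"),
                y = c("PFS_6m", "PFS_12m", "OS_12m", "OS_24m"),
                stringsAsFactors = FALSE),
    expand.grid(x = c("PFS_6m", "PFS_12m"), y = c("OS_12m", "OS_24m"),
                stringsAsFactors = FALSE))
  w <- if ("n_patients" %in% names(table)) table$n_patients else NULL
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xn <- pairs$x[i]; yn <- pairs$y[i]
    base <- data.frame(x_endpoint = xn, y_endpoint = yn, slope = NA_real_,
                       intercept = NA_real_, r2 = NA_real_, k = 0L,
                       classification = "not estimable",
                       stringsAsFactors = FALSE)
    if (!xn %in% names(table) || !yn %in% names(table)) return(base)
    res <- try(weighted_linear_regression(table[[xn]], table[[yn]], w,
                                          x_name = xn, y_name = yn),
               silent = TRUE)
    if (inherits(res, "try-error")) return(base)
    data.frame(x_endpoint = xn, y_endpoint = yn, slope = res$slope,
               intercept = res$intercept, r2 = res$r2, k = res$k,
               classification = res$classification, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mbma_surrogacy", "data.frame")
  out
}
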