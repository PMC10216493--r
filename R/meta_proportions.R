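#' Random-effects meta-analysis of a single-arm proportion
#'
#' Logit-transforms each study proportion (continuity correction of 0.5 on
#' events and non-events only for boundary studies with 0 or all events),
#' estimates the between-study variance \eqn{\tau^2} by DerSimonian-Laird,
#' pools by inverse variance on the logit scale and back-transforms the
#' pooled estimate and its Wald 95% CI to percent.  Implemented on top of
#' [metafor::rma.uni()].
#'
#' @param props `mbma_props` rows for one endpoint (and typically one
#'   domain group).
#' @param label optional label stored in the result.
#' @return An object of class `mbma_pooled_prop` with `endpoint`, `label`,
#'   `k_studies`, `pooled_percent`, `ci95_percent`, `tau2`, `i2_percent`
#'   and the logit-scale `pooled_logit`/`se_logit` used for comparisons.
#' @export
logit_re_meta <- function(props, label = "") {
  if (!nrow(props)) stop("no studies to pool")
  ep <- unique(props$endpoint)
  if (length(ep) != 1) stop("pool one endpoint at a time, got: ",
                            paste(ep, collapse = ", "))
  es <- metafor::escalc(measure = "PLO", xi = props$events, ni = props$total,
                        add = 0.5, to = "only0")
  if (nrow(props) == 1) {
    yi <- as.numeric(es$yi); se <- sqrt(es$vi)
    out <- list(pooled_logit = yi, se_logit = se, tau2 = 0, i2 = 0,
                ci_lo = yi - 1.96 * se, ci_hi = yi + 1.96 * se)
  } else {
    r <- metafor::rma.uni(yi = es$yi, vi = es$vi, method = "DL")
    out <- list(pooled_logit = as.numeric(r$beta), se_logit = r$se,
                tau2 = r$tau2, i2 = r$I2, ci_lo = r$ci.lb, ci_hi = r$ci.ub)
  }
  structure(list(endpoint = ep, label = label, k_studies = nrow(props),
                 pooled_percent = 100 * plogis(out$pooled_logit),
                 ci95_percent = c(lower = 100 * plogis(out$ci_lo),
                                  upper = 100 * plogis(out$ci_hi)),
                 tau2 = out$tau2, i2_percent = out$i2,
                 pooled_logit = out$pooled_logit, se_logit = out$se_logit),
            class = "mbma_pooled_prop")
}

#' @export
print.mbma_pooled_prop <- function(x, ...) {
  cat(sprintf("%s%s: %.2f%% (95%% CI %.2f-%.2f), k = %d, tau2 = %.3f, I2 = %.1f%%\n",
              x$endpoint, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$pooled_percent, x$ci95_percent["lower"], x$ci95_percent["upper"],
              x$k_studies, x$tau2, x$i2_percent))
  invisible(x)
}

#' Subgroup meta-analysis of proportions
#'
#' Pools one endpoint separately within each level of a trial-level
#' grouping factor (e.g. domain group, scFv clone, age group, or a numeric
#' covariate split at its median).  Trials whose grouping value is missing
#' are excluded with a warning.  Levels whose 95% CIs overlap are flagged
#' `not significantly different`, mirroring the CI-overlap reporting
#' convention of single-arm meta-analyses.
#'
#' @param props `mbma_props` rows for one endpoint.
#' @param arms trial table.
#' @param grouping trial-table column name.
#' @return list of class `mbma_subgroup_meta`: per-level
#'   `mbma_pooled_prop` plus a pairwise `comparisons` data frame.
#' @export
subgroup_meta <- function(props, arms, grouping) {
  if (!grouping %in% names(arms)) stop("unknown grouping column: ", grouping)
  v <- arms[[grouping]][match(props$trial_id, arms$trial_id)]
  if (is.numeric(v)) {
    med <- median(arms[[grouping]], na.rm = TRUE)
    v <- ifelse(v < med, paste0("<", signif(med, 3)), paste0(">=", signif(med, 3)))
  }
  if (anyNA(v)) {
    warning(sum(is.na(v)), " trials excluded: missing '", grouping, "'")
    props <- props[!is.na(v), , drop = FALSE]
    v <- v[!is.na(v)]
  }
  levels <- sort(unique(v))
  per_level <- lapply(levels, function(lv)
    logit_re_meta(props[v == lv, , drop = FALSE], label = lv))
  names(per_level) <- levels
  comparisons <- NULL
  if (length(levels) >= 2) {
    cmb <- utils::combn(levels, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      cg <- compare_groups(per_level[[cmb[1, j]]], per_level[[cmb[2, j]]])
      data.frame(level_a = cmb[1, j], level_b = cmb[2, j],
                 diff_percent = cg$diff_percent, ci_overlap = cg$ci_overlap,
                 z = cg$z, p_value = cg$p_value,
                 flag = cg$flag, stringsAsFactors = FALSE)
    }))
  }
  structure(list(grouping = grouping, per_level = per_level,
                 comparisons = comparisons),
            class = "mbma_subgroup_meta")
}

#' Compare two pooled proportions
#'
#' Headline comparison is by 95% CI overlap (the reporting convention for
#' single-arm pooled rates); a normal-approximation z-test on the logit
#' difference is reported as supplementary output.
#'
#' @param a,b `mbma_pooled_prop` objects for the same endpoint.
#' @return list with `diff_percent` (a minus b), `ci_overlap`, `z`,
#'   `p_value` and a text `flag`.
#' @export
compare_groups <- function(a, b) {
  if (!identical(a$endpoint, b$endpoint))
    stop("cannot compare different endpoints: ", a$endpoint, " vs ", b$endpoint)
  overlap <- a$ci95_percent["lower"] <= b$ci95_percent["upper"] &&
    b$ci95_percent["lower"] <= a$ci95_percent["upper"]
  z <- (a$pooled_logit - b$pooled_logit) / sqrt(a$se_logit^2 + b$se_logit^2)
  list(endpoint = a$endpoint,
       diff_percent = a$pooled_percent - b$pooled_percent,
       ci_overlap = unname(overlap),
       z = unname(z), p_value = unname(2 * pnorm(-abs(z))),
       flag = if (overlap) "not significantly different (CIs overlap)"
       else "significantly different (CIs disjoint)")
}
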