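.age_groups <- c("pediatric", "adult", "mixed")
.scfv_clones <- c("FMC63", "other")
.t_origins <- c("autologous", "allogeneic")
.surv_endpoints <- c("OS", "PFS")
.prop_endpoints <- c("ORR", "MRD_NEG_CR", "CRS", "CRS_G34", "NEUROTOX", "NEUROTOX_G34")

.trial_cols <- c("trial_id", "domain_group", "n_patients", "morph_relapse_frac",
                 "age_group", "primary_refractory_frac", "bridge_hsct_frac",
                 "scfv_clone", "t_cell_origin")

.stop_row <- function(row, col, msg)
  stop(sprintf("row %d, column '%s': %s", row, col, msg), call. = FALSE)

.check_frac <- function(x, rows, col) {
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad)) .stop_row(rows[bad[1]], col, sprintf(
    "value %g outside [0, 1]", x[bad[1]]))
  x
}

.check_level <- function(x, rows, col, levels) {
  x[!is.na(x) & x == ""] <- NA
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) .stop_row(rows[bad[1]], col, sprintf(
    "'%s' is not one of: %s", x[bad[1]], paste(levels, collapse = ", ")))
  x
}

#' Read a trial-arm metadata table
#'
#' Reads the per-arm design table of the meta-analytic corpus: one row per
#' trial arm with sample size, co-stimulatory domain group and aggregate
#' patient covariates (fractions and categorical descriptors).  Optional
#' covariates may be empty; they are carried as `NA`, never silently zero.
#'
#' @param path path to a comma-separated UTF-8 file with header columns
#'   `trial_id, domain_group, n_patients, morph_relapse_frac, age_group,
#'   primary_refractory_frac, bridge_hsct_frac, scfv_clone, t_cell_origin`.
#' @return A `data.frame` of class `mbma_trials`.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         strip.white = TRUE)
  missing_cols <- setdiff(.trial_cols, names(raw))
  if (length(missing_cols))
    stop("trial table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[.trial_cols]
  rows <- seq_len(nrow(raw)) + 1L  # file line numbers (header is line 1)
  num <- function(col, required = FALSE) {
    x <- raw[[col]]
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) .stop_row(rows[bad[1]], col, sprintf("'%s' is not numeric", x[bad[1]]))
    if (required && anyNA(out)) .stop_row(rows[which(is.na(out))[1]], col, "value is required")
    out
  }
  arms <- data.frame(
    trial_id = raw$trial_id,
    domain_group = .check_level(raw$domain_group, rows, "domain_group", .groups),
    n_patients = num("n_patients", required = TRUE),
    morph_relapse_frac = .check_frac(num("morph_relapse_frac"), rows, "morph_relapse_frac"),
    age_group = .check_level(raw$age_group, rows, "age_group", .age_groups),
    primary_refractory_frac = .check_frac(num("primary_refractory_frac"), rows,
                                          "primary_refractory_frac"),
    bridge_hsct_frac = .check_frac(num("bridge_hsct_frac"), rows, "bridge_hsct_frac"),
    scfv_clone = .check_level(raw$scfv_clone, rows, "scfv_clone", .scfv_clones),
    t_cell_origin = .check_level(raw$t_cell_origin, rows, "t_cell_origin", .t_origins),
    stringsAsFactors = FALSE)
  if (any(arms$trial_id == "" | is.na(arms$trial_id)))
    .stop_row(rows[which(arms$trial_id == "" | is.na(arms$trial_id))[1]],
              "trial_id", "value is required")
  if (anyNA(arms$domain_group))
    .stop_row(rows[which(is.na(arms$domain_group))[1]], "domain_group", "value is required")
  dup <- duplicated(arms$trial_id)
  if (any(dup)) stop("duplicate trial_id: ", arms$trial_id[which(dup)[1]])
  bad_n <- which(arms$n_patients < 1 | arms$n_patients != round(arms$n_patients))
  if (length(bad_n)) .stop_row(rows[bad_n[1]], "n_patients", "must be a positive integer")
  arms$n_patients <- as.integer(arms$n_patients)
  class(arms) <- c("mbma_trials", "data.frame")
  arms
}

#' Write a trial-arm table
#'
#' Inverse of [read_trial_table()]; round-trips all fields exactly.
#'
#' @param arms `mbma_trials` data frame.
#' @param path output CSV path.
#' @export
write_trial_table <- function(arms, path) {
  utils::write.csv(as.data.frame(arms)[.trial_cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read digitized survival observations
#'
#' Reads (time, survival-fraction) points digitized from published
#' Kaplan-Meier curves, one row per point.  Rows are sorted by
#' (trial, endpoint, time); within a curve, times must be strictly
#' increasing (after sorting) and survival fractions non-increasing up to a
#' tolerance of 1e-9.  The implied point S(0) = 1 is never stored.
#'
#' @param path CSV with header columns
#'   `trial_id, endpoint, time_months, surv_fraction`.
#' @return A `data.frame` of class `mbma_curves`.
#' @export
read_survival_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("trial_id", "endpoint", "time_months", "surv_fraction")
  if (length(setdiff(need, names(raw))))
    stop("survival file is missing required columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  rows <- seq_len(nrow(raw)) + 1L
  x <- raw[need]
  x$endpoint <- .check_level(as.character(x$endpoint), rows, "endpoint", .surv_endpoints)
  if (!is.numeric(x$time_months) || !is.numeric(x$surv_fraction))
    stop("time_months and surv_fraction must be numeric")
  bad <- which(!is.finite(x$time_months) | x$time_months <= 0)
  if (length(bad)) .stop_row(rows[bad[1]], "time_months", "must be positive")
  bad <- which(!is.finite(x$surv_fraction) | x$surv_fraction <= 0 | x$surv_fraction > 1)
  if (length(bad)) .stop_row(rows[bad[1]], "surv_fraction", "must lie in (0, 1]")
  x <- x[order(x$trial_id, x$endpoint, x$time_months), , drop = FALSE]
  rownames(x) <- NULL
  for (key in split(seq_len(nrow(x)), list(x$trial_id, x$endpoint), drop = TRUE)) {
    if (anyDuplicated(x$time_months[key]))
      stop(sprintf("curve (%s, %s): duplicated time %g",
                   x$trial_id[key[1]], x$endpoint[key[1]],
                   x$time_months[key][anyDuplicated(x$time_months[key])]))
    if (any(diff(x$surv_fraction[key]) > 1e-9))
      stop(sprintf("curve (%s, %s): survival fraction increases over time",
                   x$trial_id[key[1]], x$endpoint[key[1]]))
  }
  class(x) <- c("mbma_curves", "data.frame")
  x
}

#' Write survival observations
#'
#' @param curves `mbma_curves` data frame.
#' @param path output CSV path.
#' @export
write_survival_curves <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read proportion outcomes
#'
#' Event counts for the response and safety endpoints (overall remission,
#' MRD-negative complete remission, cytokine release syndrome and
#' neurotoxicity, with their grade 3-4 variants).
#'
#' @param path CSV with header columns `trial_id, endpoint, events, total`.
#' @return A `data.frame` of class `mbma_props`.
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("trial_id", "endpoint", "events", "total")
  if (length(setdiff(need, names(raw))))
    stop("proportions file is missing required columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  rows <- seq_len(nrow(raw)) + 1L
  x <- raw[need]
  x$endpoint <- .check_level(as.character(x$endpoint), rows, "endpoint", .prop_endpoints)
  bad <- which(!is.finite(x$total) | x$total < 1 | x$total != round(x$total))
  if (length(bad)) .stop_row(rows[bad[1]], "total", "must be a positive integer")
  bad <- which(!is.finite(x$events) | x$events < 0 | x$events > x$total |
                 x$events != round(x$events))
  if (length(bad)) .stop_row(rows[bad[1]], "events", "must be an integer in [0, total]")
  x$events <- as.integer(x$events); x$total <- as.integer(x$total)
  class(x) <- c("mbma_props", "data.frame")
  x
}

#' Write proportion outcomes
#'
#' @param props `mbma_props` data frame.
#' @param path output CSV path.
#' @export
write_proportions <- function(props, path) {
  utils::write.csv(as.data.frame(props), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a trial dataset
#'
#' Cross-references survival curves and proportion outcomes against the
#' trial-arm table and reports issues without throwing: unknown trial ids
#' are errors (downstream fitting refuses such a dataset), arms without
#' observations are warnings.  The report also tabulates observation counts
#' per endpoint and domain group.
#'
#' @param arms trial table ([read_trial_table()]).
#' @param curves survival observations ([read_survival_curves()]), or `NULL`.
#' @param props proportion outcomes ([read_proportions()]), or `NULL`.
#' @return An object of class `mbma_validation` with elements `n_arms`,
#'   `n_observations`, `issues` (data frame: severity, trial_id, message)
#'   and `counts`.
#' @export
validate_dataset <- function(arms, curves = NULL, props = NULL) {
  issues <- list()
  note <- function(severity, trial_id, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, trial_id = trial_id, message = message,
      stringsAsFactors = FALSE)
  ids <- sort(unique(arms$trial_id))
  for (src in list(curves = curves, props = props)) {
    if (is.null(src)) next
    for (id in sort(setdiff(unique(src$trial_id), ids)))
      note("error", id, "observations reference a trial absent from the arm table")
  }
  seen <- if (!is.null(curves)) unique(curves$trial_id) else character()
  for (id in sort(setdiff(ids, seen)))
    note("warning", id, "arm has no survival observations")
  counts <- NULL
  if (!is.null(curves)) {
    keep <- curves$trial_id %in% ids
    if (any(keep)) {
      grp <- arms$domain_group[match(curves$trial_id[keep], arms$trial_id)]
      counts <- as.data.frame(table(endpoint = curves$endpoint[keep], group = grp),
                              stringsAsFactors = FALSE)
      names(counts)[3] <- "n_points"
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), trial_id = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(n_arms = nrow(arms),
                 n_observations = if (is.null(curves)) 0L else nrow(curves),
                 issues = issues, counts = counts,
                 ok = !any(issues$severity == "error")),
            class = "mbma_validation")
}

#' @export
print.mbma_validation <- function(x, ...) {
  cat(sprintf("MBMA dataset: %d arms, %d survival observations\n",
              x$n_arms, x$n_observations))
  if (!nrow(x$issues)) {
    cat("  no issues\n")
  } else {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s: %s\n", x$issues$severity[i],
                  x$issues$trial_id[i], x$issues$message[i]))
  }
  invisible(x)
}
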