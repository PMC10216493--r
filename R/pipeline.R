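#' Default pipeline configuration
#'
#' Returns the config list [run_pipeline()] consumes; any subset can be
#' overridden via a YAML file or an R list.  All randomness flows from the
#' single root `seed` through named substreams, so a rerun with the same
#' config reproduces every output bit-exactly.
#'
#' @param seed root seed.
#' @param endpoints survival endpoints to model (`"OS"`, `"PFS"` or both).
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, endpoints = "OS") {
  list(seed = as.integer(seed),
       endpoints = endpoints,
       generator = list(),                 # overrides for generator_config()
       fit = list(included_covariates = "morph_relapse_frac"),
       diagnostics = list(vpc_replicates = 200L, n_bins = 8L,
                          run_bootstrap = FALSE, n_boot = 100L,
                          run_loo = FALSE),
       simulate = list(n_sim = 1000L, covariate_levels = c(0.25, 0.85, 1.0)),
       meta = list(endpoints = c("ORR", "MRD_NEG_CR", "CRS", "CRS_G34",
                                 "NEUROTOX", "NEUROTOX_G34")),
       surrogacy = list())
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full MBMA pipeline on a synthetic corpus
#'
#' Sequences generate, validate, fit, diagnose, simulate, meta-analyse and
#' surrogacy stages in dependency order, writing tidy CSV/JSON outputs and
#' a reproducibility manifest (config hash, seeds, per-stage wall clock,
#' and an MD5 checksum for every file written).  Any stage failure halts
#' the run with an error naming the stage.
#'
#' @param config a [pipeline_config()] list, a YAML file path, or `NULL`
#'   for the defaults.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config's root seed.
#' @return The manifest (list of class `mbma_manifest`), invisibly;
#'   written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("mbma_run_"),
                         seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- .merge_config(pipeline_config(), yaml::read_yaml(config))
  } else if (is.null(config)) {
    config <- pipeline_config()
  } else config <- .merge_config(pipeline_config(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_times <- c()
  outputs <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(path) outputs <<- c(outputs, path)

  gcfg <- do.call(generator_config,
                  c(config$generator, list(endpoints = config$endpoints)))
  gen <- stage("generate", {
    g <- generate_survival_dataset(gcfg, seed = config$seed)
    pr <- generate_proportion_dataset(gcfg, arms = g$arms, seed = config$seed)
    epts <- generate_surrogate_endpoints(gcfg, arms = g$arms, seed = config$seed)
    emit(write_trial_table(g$arms, file.path(out_dir, "trials.csv")))
    emit(write_survival_curves(g$curves, file.path(out_dir, "survival.csv")))
    emit(write_proportions(pr$props, file.path(out_dir, "proportions.csv")))
    ep_path <- file.path(out_dir, "endpoints.csv")
    utils::write.csv(as.data.frame(epts), ep_path, row.names = FALSE)
    emit(ep_path)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(params = list(mu = as.list(g$truth$params$mu),
                         sigma = as.list(g$truth$params$sigma),
                         theta = as.list(g$truth$params$theta),
                         omega_sigma = g$truth$params$omega_sigma,
                         omega_mu = g$truth$params$omega_mu,
                         epsilon = g$truth$params$epsilon),
           eta = g$truth$eta, seed = config$seed),
      truth_path, auto_unbox = TRUE, digits = NA)
    emit(truth_path)
    list(arms = g$arms, curves = g$curves, props = pr$props, endpoints = epts)
  })

  stage("validate", {
    rep <- validate_dataset(gen$arms, gen$curves, gen$props)
    if (!rep$ok) stop("generated dataset failed validation")
    rep
  })

  fits <- list()
  for (ep in config$endpoints) {
    fits[[ep]] <- stage(paste0("fit_", ep), {
      f <- suppressWarnings(fit_model(gen$arms, gen$curves, ep,
                                      config$fit$included_covariates))
      emit(write_fit_json(f, file.path(out_dir, paste0("fit_", ep, ".json"))))
      f
    })
    stage(paste0("diagnostics_", ep), {
      f <- fits[[ep]]
      v <- vpc(f, n_replicates = config$diagnostics$vpc_replicates,
               seed = config$seed, n_bins = config$diagnostics$n_bins)
      p <- file.path(out_dir, paste0("vpc_", ep, ".csv"))
      utils::write.csv(v$table, p, row.names = FALSE); emit(p)
      g <- gof_residuals(f)
      p <- file.path(out_dir, paste0("gof_", ep, ".csv"))
      utils::write.csv(as.data.frame(g), p, row.names = FALSE); emit(p)
      if (isTRUE(config$diagnostics$run_bootstrap)) {
        b <- bootstrap_model(f, gen$arms, gen$curves,
                             n_boot = config$diagnostics$n_boot,
                             seed = config$seed)
        p <- file.path(out_dir, paste0("bootstrap_", ep, ".csv"))
        utils::write.csv(b$summary, p, row.names = FALSE); emit(p)
      }
      if (isTRUE(config$diagnostics$run_loo)) {
        l <- leave_one_out(f, gen$arms, gen$curves)
        p <- file.path(out_dir, paste0("loo_", ep, ".csv"))
        utils::write.csv(l$table, p, row.names = FALSE); emit(p)
      }
      NULL
    })
    stage(paste0("simulate_", ep), {
      f <- fits[[ep]]
      for (g in f$groups) {
        s <- simulate_typical_curves(f$estimates, g,
                                     n_sim = config$simulate$n_sim,
                                     seed = config$seed)
        write_simulation_summary(
          s, file.path(out_dir, paste0("typical_", ep, "_", gsub("-", "", g))))
        emit(file.path(out_dir, paste0("typical_", ep, "_", gsub("-", "", g), ".json")))
        emit(file.path(out_dir, paste0("typical_", ep, "_", gsub("-", "", g), "_curves.csv")))
      }
      if (length(f$estimates$theta)) {
        lv <- config$simulate$covariate_levels
        ss <- summarize_at_covariate_levels(
          f$estimates, f$groups[1], names(f$estimates$theta)[1], lv,
          n_sim = config$simulate$n_sim, seed = config$seed)
        med <- data.frame(level = lv, median_months = vapply(
          ss, function(x) unname(x$median_survival["est"]), numeric(1)))
        p <- file.path(out_dir, paste0("covariate_levels_", ep, ".csv"))
        utils::write.csv(med, p, row.names = FALSE); emit(p)
      }
      NULL
    })
  }

  stage("meta", {
    rows <- list()
    for (ep in config$meta$endpoints) {
      sub <- gen$props[gen$props$endpoint == ep, , drop = FALSE]
      if (!nrow(sub)) next
      sm <- subgroup_meta(sub, gen$arms, "domain_group")
      for (lv in names(sm$per_level)) {
        r <- sm$per_level[[lv]]
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep, group = lv, k_studies = r$k_studies,
          pooled_percent = r$pooled_percent,
          ci_lower = r$ci95_percent["lower"], ci_upper = r$ci95_percent["upper"],
          tau2 = r$tau2, i2_percent = r$i2_percent, stringsAsFactors = FALSE)
      }
    }
    p <- file.path(out_dir, "meta_proportions.csv")
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE); emit(p)
    NULL
  })

  stage("surrogacy", {
    sm <- surrogacy_matrix(gen$endpoints)
    p <- file.path(out_dir, "surrogacy.csv")
    utils::write.csv(as.data.frame(sm), p, row.names = FALSE); emit(p)
    NULL
  })

  outputs <- unique(normalizePath(outputs))
  manifest <- list(
    config_hash = .config_hash(config),
    seed = config$seed,
    endpoints = config$endpoints,
    stage_seconds = as.list(stage_times),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  class(manifest) <- "mbma_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.config_hash <- function(config) {
  # stable content hash of the (sorted) config serialization
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(s), tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
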