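#' Run the full crop-diversification / pesticide-use analysis
#'
#' Orchestrates the pipeline end to end: (optional) simulation or reading
#' of inputs, diversity indicators, TFI scoring, inclusion filters, the
#' space-for-time composition-stability analysis, the dilution model
#' (crop-level pesticide use by crop, marginalized over climatic regions)
#' and the regulation models (pesticide use against diversity indicators,
#' with AIC candidate selection). Each stage's outputs are written before
#' the next stage starts.
#'
#' The configuration is a named list (or path to a YAML file) with
#' elements:
#' \itemize{
#'   \item `simulate`: list of [simulation_config()] overrides; mutually
#'     exclusive with `inputs`.
#'   \item `inputs`: list of paths `fields`, `sprays`, `ref_doses`,
#'     optional `catalog`.
#'   \item `out_dir`: output directory.
#'   \item `seed` (default 1), `n_permutations` (default 1000),
#'     `td_weighting` (`"arithmetic"` or `"geometric"`),
#'     `index_power` (number in (1,2), or `"profile"` to profile the
#'     Tweedie index on the baseline model of each response and fix it
#'     across that response's candidates),
#'     `responses` (subset of `c("total", "herbicide", "fungicide",
#'     "insecticide")`), `min_fields` (default 8).
#' }
#'
#' @param config named list or path to a YAML config file.
#' @return A run report (list) with the filter report, stability results,
#'   dilution means, regulation AIC tables and effects, and the seeds
#'   used; also written as `run_summary.json` with CSV side tables.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% "rotapest_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- as.integer(config$n_permutations %||% 1000L)
  td_weighting <- config$td_weighting %||% "arithmetic"
  index_power <- config$index_power %||% "profile"
  responses <- config$responses %||% c("total", "herbicide", "fungicide",
                                       "insecticide")
  min_fields <- config$min_fields %||% 8
  warn <- character(0)

  # -- stage 0: data ---------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       c(config$simulate, list(seed = seed)))
    gen <- generate_network(sim_cfg)
    dataset <- gen$dataset
    truth <- gen$truth
    write_dataset(dataset, file.path(out_dir, "inputs"))
    jsonlite::write_json(
      truth[c("intercepts", "region_effects", "beta_fd", "beta_td",
              "beta_cover", "sigma_system", "phi", "p", "seed")],
      file.path(out_dir, "inputs", "truth.json"), auto_unbox = TRUE,
      digits = NA)
  } else if (!is.null(config$inputs)) {
    dataset <- read_dataset(config$inputs$fields, config$inputs$sprays,
                            config$inputs$ref_doses, config$inputs$catalog)
  } else {
    stop("config must provide either 'simulate' or 'inputs'")
  }

  # -- stage 1: indicators ---------------------------------------------
  indicators <- diversity_profiles(dataset$fields, dataset$catalog)
  utils::write.csv(indicators, file.path(out_dir, "indicators.csv"),
                   row.names = FALSE)

  # -- stage 2: TFI ----------------------------------------------------
  tfi <- compute_tfi(dataset)
  utils::write.csv(tfi, file.path(out_dir, "tfi.csv"), row.names = FALSE)

  # -- stage 3: inclusion filters --------------------------------------
  flt <- apply_inclusion_filters(dataset, tfi = tfi, min_fields = min_fields)
  dataset <- flt$dataset
  tfi <- tfi[paste(tfi$system_id, tfi$time_point) %in%
               unique(paste(dataset$fields$system_id,
                            dataset$fields$time_point)), , drop = FALSE]
  indicators <- indicators[paste(indicators$system_id, indicators$time_point) %in%
                             unique(paste(dataset$fields$system_id,
                                          dataset$fields$time_point)), ,
                           drop = FALSE]

  # -- stage 4: composition stability ----------------------------------
  ct <- composition_table(dataset$fields)
  multi <- ct$system_id %in% names(which(table(ct$system_id) > 1))
  stability <- NULL
  if (sum(multi) > 0 && length(unique(ct$system_id[multi])) >= 2) {
    d <- bray_curtis_matrix(ct$comp[multi, , drop = FALSE])
    set.seed(seed)
    perm <- permanova(d, ct$system_id[multi], strata = ct$region[multi],
                      n_perm = n_perm)
    disp <- tryCatch(
      withCallingHandlers(
        dispersion_test(d, ct$system_id[multi]),
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) { warn <<- c(warn, conditionMessage(e)); NULL })
    perk <- tryCatch(
      suppressWarnings(
        balanced_subset_analysis(ct$comp[multi, , drop = FALSE],
                                 ct$system_id[multi], ct$region[multi],
                                 n_perm = n_perm)),
      error = function(e) { warn <<- c(warn, conditionMessage(e)); NULL })
    stability <- list(
      permanova = unclass(perm),
      dispersion = if (is.null(disp)) NULL else
        list(anova_f = disp$anova_f, df = disp$df, p_value = disp$p_value,
             n_excluded = length(disp$excluded)),
      by_observation_count = perk
    )
    jsonlite::write_json(stability, file.path(out_dir, "stability.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    warn <- c(warn, "fewer than 2 systems with repeated time points; stability stage skipped")
  }

  # -- model data: join TFI with indicators and context ----------------
  td_col <- if (identical(td_weighting, "geometric")) "td_geom" else "td_arith"
  mi <- match(paste(tfi$system_id, tfi$time_point),
              paste(indicators$system_id, indicators$time_point))
  mdata <- data.frame(
    system_id = tfi$system_id, time_point = tfi$time_point,
    crop = tfi$crop,
    climatic_region = dataset$contexts$climatic_region[
      match(tfi$system_id, dataset$contexts$system_id)],
    tfi_total = tfi$tfi_total, tfi_herbicide = tfi$tfi_h,
    tfi_fungicide = tfi$tfi_f, tfi_insecticide = tfi$tfi_i,
    fd = indicators$fd[mi], td = indicators[[td_col]][mi],
    sowing_div = indicators$sowing_div[mi],
    cover_crop_freq = indicators$cover_crop_freq[mi],
    stringsAsFactors = FALSE
  )
  main_crops <- dataset$catalog$crop[dataset$catalog$is_main_crop]
  mdata <- mdata[mdata$crop %in% main_crops, , drop = FALSE]

  # -- stage 5: dilution model -----------------------------------------
  set.seed(seed + 1L)
  dil_fit <- fit_tweedie_glm(tfi_total ~ climatic_region + crop, mdata,
                             p = index_power)
  dil_means <- marginal_means(dil_fit, "crop")
  dil_ct <- pairwise_contrasts_fdr(dil_means)
  dil_tab <- merge(as.data.frame(dil_means)[, c("label", "estimate",
                                                "ci_low", "ci_high")],
                   dil_ct$letters, by = "label")
  names(dil_tab)[1] <- "crop"
  utils::write.csv(dil_tab, file.path(out_dir, "dilution_means.csv"),
                   row.names = FALSE)

  # -- stage 6: regulation models --------------------------------------
  resp_cols <- c(total = "tfi_total", herbicide = "tfi_herbicide",
                 fungicide = "tfi_fungicide", insecticide = "tfi_insecticide")
  reg <- list()
  model_tab <- list()
  effects_tab <- list()
  for (r in responses) {
    crops_r <- flt$crop_lists[[r]]
    dr <- mdata[mdata$crop %in% crops_r, , drop = FALSE]
    if (length(unique(dr$crop)) < 2L) {
      warn <- c(warn, paste0("regulation model '", r,
                             "' skipped: fewer than 2 crops retained"))
      next
    }
    scl <- scale_predictors(dr, c("fd", "td", "cover_crop_freq"))
    cand <- regulation_candidates(resp_cols[[r]])
    p_r <- index_power
    if (identical(index_power, "profile")) {
      base_fit <- fit_tweedie_glm(cand$baseline, scl$data, p = "profile",
                                  scaling = scl$scaling)
      p_r <- base_fit$p
    }
    sel <- withCallingHandlers(
      select_model_aic(cand, scl$data, p = p_r, scaling = scl$scaling),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    wald <- type3_wald(sel$best)
    slopes_fd <- if ("fd" %in% names(sel$best$model_frame))
      slope_tests(sel$best, "fd") else NULL
    slopes_td <- slope_tests(sel$best, "td")
    pc_fd <- if (!is.null(slopes_fd))
      do.call(rbind, lapply(unique(dr$crop), function(cr)
        percent_change_effect(sel$best, "fd", 1, 4, crop = cr))) else NULL
    reg[[r]] <- list(best_name = sel$best_name, p = sel$best$p,
                     phi = sel$best$phi, aic_table = sel$table,
                     type3 = wald)
    model_tab[[r]] <- cbind(response = r, sel$table)
    eff <- rbind(
      if (!is.null(slopes_fd)) cbind(response = r, indicator = "fd",
                                     slopes_fd),
      cbind(response = r, indicator = "td", slopes_td)
    )
    effects_tab[[r]] <- eff
  }
  if (length(model_tab) > 0)
    utils::write.csv(do.call(rbind, model_tab),
                     file.path(out_dir, "model_table.csv"), row.names = FALSE)
  if (length(effects_tab) > 0)
    utils::write.csv(do.call(rbind, effects_tab),
                     file.path(out_dir, "regulation_effects.csv"),
                     row.names = FALSE)

  report <- list(
    config = list(seed = seed, n_permutations = n_perm,
                  td_weighting = td_weighting,
                  index_power = if (is.numeric(index_power)) index_power
                                else "profile",
                  min_fields = min_fields, responses = responses),
    filter_report = flt$report[c("min_fields", "n_field_rows_removed",
                                 "n_system_time_points_removed",
                                 "n_systems_kept", "n_crops_retained")],
    crop_lists = flt$crop_lists,
    stability = stability,
    dilution = list(p = dil_fit$p, phi = dil_fit$phi,
                    means = dil_tab),
    regulation = reg,
    warnings = warn
  )
  jsonlite::write_json(report, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
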