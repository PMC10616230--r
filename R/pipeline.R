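## End-to-end orchestration: synthetic generation (or reading supplied
## files), climate summarisation, BAI conversion and filtering, site-species
## model fitting and classification, driver attribution, species trends, and
## a run manifest with the attrition accounting at every filter.

#' Default pipeline configuration
#'
#' All module defaults are overridable here and nowhere else. The synthetic
#' block is a [sim_config()]; per-site climate parameters are drawn around
#' a south-north gradient by [default_site_grid()].
#'
#' @param out_dir Run directory.
#' @param seed Master seed; per-stage child seeds are derived
#'   deterministically from it.
#' @param synthetic A [sim_config()] (synthetic mode) or `NULL` to read
#'   `weather_paths` / `rings_path` instead.
#' @param smi_critical,smi_capacity Water-balance parameters, mm.
#' @param n_exclude_juvenile,min_years_per_tree Ring filters.
#' @param model Arguments for [growth_model_spec()].
#' @param alpha_level Significance threshold.
#' @param rf_n_trees Forest size (default 500).
#' @param n_boot Bootstrap replicates for correlation CIs.
#' @param weather_paths,rings_path,site_meta_path Input files for
#'   non-synthetic mode.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("vpdgrowth_run_"), seed = 1L,
                            synthetic = sim_config(), smi_critical = 300,
                            smi_capacity = 400, n_exclude_juvenile = 10,
                            min_years_per_tree = 25, model = list(),
                            alpha_level = 0.05, rf_n_trees = 500,
                            n_boot = 1000, weather_paths = NULL,
                            rings_path = NULL, site_meta_path = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Per-site climate parameter grid for synthetic runs
#'
#' Lays `n_sites` out on a south-west to north-east transect across the
#' boreal zone with a realistic MAT/MAP gradient.
#'
#' @param n_sites Number of sites.
#' @param seed RNG seed.
#' @param rh_trend RH trend passed to every site (percentage points / yr).
#' @return List of [site_params()], named by site id `S001`, ...
#' @export
default_site_grid <- function(n_sites, seed = 1L, rh_trend = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lats <- seq(48, 58, length.out = max(n_sites, 2))[seq_len(n_sites)]
  lons <- seq(-110, -70, length.out = max(n_sites, 2))[seq_len(n_sites)]
  out <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    out[[i]] <- site_params(
      mat = 4 - 0.5 * (lats[i] - 48) + stats::rnorm(1, 0, 0.5),
      map = stats::runif(1, 600, 1000),
      elev = stats::runif(1, 200, 600),
      rh_mean = stats::runif(1, 62, 75),
      rh_trend = rh_trend,
      lat = lats[i], lon = lons[i])
  }
  names(out) <- sprintf("S%03d", seq_len(n_sites))
  out
}

write_stage <- function(obj, run_dir, name) {
  p <- file.path(run_dir, name)
  if (is.data.frame(obj)) utils::write.csv(obj, p, row.names = FALSE)
  else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                            force = TRUE)
  p
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> climate -> rings -> fit -> drivers ->
#' trends, persisting every intermediate table under the run directory and
#' writing `manifest.json` with the configuration hash, per-stage timings,
#' and the convergence/significance accounting.
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(run_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "synthetic")], cfg_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   config_hash = unname(tools::md5sum(cfg_path)))
  tic <- function() proc.time()[["elapsed"]]
  stage_t0 <- tic()
  mark <- function(stage) {
    manifest$stages[[stage]] <<- list(seconds = round(tic() - stage_t0, 2))
    stage_t0 <<- tic()
  }
  fail <- function(stage, msg) {
    manifest$halted_at <- stage
    manifest$error <- msg
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop_config("pipeline halted at stage '%s': %s", stage, msg)
  }

  ## --- simulate / read -----------------------------------------------------
  site_climates <- list(); site_meta_rows <- list()
  series_all <- list(); truths <- list()
  if (!is.null(config$synthetic)) {
    sim <- config$synthetic
    grid <- default_site_grid(sim$n_sites, child_seed(config$seed, "grid"),
                              rh_trend = sim$climate_params$rh_trend %||% 0)
    weather_list <- list()
    for (i in seq_along(grid)) {
      sid <- names(grid)[i]
      sp <- sim$species_labels[((i - 1) %% length(sim$species_labels)) + 1]
      wx <- simulate_daily_weather(grid[[i]], sim$years,
                                   child_seed(config$seed, paste0("wx", sid)))
      daily <- derive_daily_climate(wx, list(lat = grid[[i]]$lat,
                                             elev = grid[[i]]$elev),
                                    config$smi_critical, config$smi_capacity)
      sc <- summarize_site_climate(daily, sim$years, sid,
                                   lat = grid[[i]]$lat, lon = grid[[i]]$lon)
      rs <- simulate_ring_series(sim, sc, site_id = sid, species = sp,
                                 seed = child_seed(config$seed,
                                                   paste0("rings", sid)))
      site_climates[[sid]] <- sc
      weather_list[[sid]] <- wx
      series_all <- c(series_all, rs$series)
      truths[[sid]] <- rs$truth
      site_meta_rows[[sid]] <- data.frame(
        site_id = sid, species = sp, lat = grid[[i]]$lat, lon = grid[[i]]$lon,
        elev = grid[[i]]$elev)
    }
    site_meta <- do.call(rbind, site_meta_rows)
    fx_dir <- file.path(run_dir, "fixtures")
    write_fixture_bundle(series_all, weather_list, site_meta,
                         truths, fx_dir)
    # exercise the reader path on the bundle we just wrote
    series_all <- read_rwl(file.path(fx_dir, "rings.rwl"))
    meta_idx <- match(substr(vapply(series_all, `[[`, "", "tree_id"), 1, 4),
                      site_meta$site_id)
    for (j in seq_along(series_all)) {
      series_all[[j]]$site_id <- site_meta$site_id[meta_idx[j]]
      series_all[[j]]$species <- site_meta$species[meta_idx[j]]
    }
  } else {
    if (is.null(config$rings_path) || is.null(config$weather_paths))
      fail("read", "non-synthetic mode needs rings_path and weather_paths")
    site_meta <- utils::read.csv(config$site_meta_path)
    series_all <- if (grepl("\\.csv$", config$rings_path))
      read_rings_csv(config$rings_path) else read_rwl(config$rings_path)
    for (sid in names(config$weather_paths)) {
      sm <- site_meta[site_meta$site_id == sid, ][1, ]
      wx <- utils::read.csv(config$weather_paths[[sid]])
      wx$date <- as.Date(wx$date)
      daily <- derive_daily_climate(wx, sm, config$smi_critical,
                                    config$smi_capacity)
      yrs <- sort(unique(as.integer(format(wx$date, "%Y"))))
      site_climates[[sid]] <- summarize_site_climate(daily, yrs, sid,
                                                     lat = sm$lat,
                                                     lon = sm$lon)
    }
  }
  mark("simulate")
  climate_tab <- do.call(rbind, site_climates)
  write_stage(climate_tab, run_dir, "site_climate.csv")
  mark("climate")

  ## --- rings ---------------------------------------------------------------
  n_read <- length(series_all)
  bai_all <- lapply(series_all, widths_to_bai)
  bai_flt <- lapply(bai_all, apply_juvenile_filter,
                    n_exclude = config$n_exclude_juvenile,
                    min_years = config$min_years_per_tree)
  excluded <- vapply(bai_flt, function(b) isTRUE(attr(b, "excluded")), TRUE)
  bai_keep <- bai_flt[!excluded]
  if (length(bai_keep) == 0) fail("rings", "no trees retained after filters")
  struct <- site_summary(bai_keep)
  write_stage(struct, run_dir, "site_structure.csv")
  mark("rings")

  ## --- fit -----------------------------------------------------------------
  spec <- do.call(growth_model_spec,
                  utils::modifyList(list(alpha_level = config$alpha_level),
                                    config$model))
  groups <- split(bai_keep, vapply(bai_keep, function(b)
    paste(b$site_id[1], b$species[1], sep = "|"), ""))
  fits <- list(); classes <- list()
  for (g in names(groups)) {
    sid <- strsplit(g, "|", fixed = TRUE)[[1]][1]
    mf <- tryCatch(prepare_model_frame(groups[[g]], site_climates[[sid]]),
                   error = function(e) NULL)
    fit <- if (is.null(mf)) {
      nonconvergent_fit(do.call(rbind, groups[[g]]), spec, "no model frame")
    } else fit_growth_gamm(mf, spec = spec)
    fits[[g]] <- fit
    classes[[g]] <- classify_response(fit, config$alpha_level)
  }
  class_tab <- do.call(rbind, classes)
  write_stage(class_tab, run_dir, "vpd_response.csv")
  fit_tab <- do.call(rbind, lapply(fits, function(f) {
    if (!isTRUE(f$converged))
      return(data.frame(site_id = f$data$site_id[1], species = f$data$species[1],
                        converged = FALSE, alpha_hat = NA, beta1_hat = NA,
                        beta2_hat = NA, t_beta1 = NA, t_beta2 = NA,
                        p_beta1 = NA, p_beta2 = NA, phi_hat = NA,
                        sigma_tree_hat = NA, sigma_eps_hat = NA, r2 = NA))
    data.frame(site_id = f$site_id, species = f$species, converged = TRUE,
               alpha_hat = f$alpha_hat, beta1_hat = f$beta1_hat,
               beta2_hat = f$beta2_hat, t_beta1 = unname(f$t["beta1"]),
               t_beta2 = unname(f$t["beta2"]), p_beta1 = unname(f$p["beta1"]),
               p_beta2 = unname(f$p["beta2"]), phi_hat = f$phi_hat,
               sigma_tree_hat = f$sigma_tree_hat,
               sigma_eps_hat = f$sigma_eps_hat, r2 = f$r2_fluctuations)
  }))
  write_stage(fit_tab, run_dir, "growth_model_fits.csv")
  mark("fit")

  ## --- drivers -------------------------------------------------------------
  climatol <- unique(data.frame(site_id = climate_tab$site_id,
                                mat = climate_tab$mat, map = climate_tab$map,
                                summer_smi = climate_tab$mean_summer_smi))
  climatol <- merge(climatol, site_meta[, c("site_id", "lat", "lon", "elev")],
                    by = "site_id")
  names(climatol)[names(climatol) == "elev"] <- "elevation"
  sens <- assemble_sensitivity_table(fits, struct, climatol,
                                     config$alpha_level)
  write_stage(sens, run_dir, "sensitivity_table.csv")
  driver_report <- NULL
  if (nrow(sens) >= 10) {
    forest <- fit_forest(sens, n_trees = config$rf_n_trees,
                         seed = child_seed(config$seed, "forest"))
    driver_report <- importance_report(forest)
    write_stage(driver_report, run_dir, "driver_importance.csv")
  }
  mark("drivers")

  ## --- trends --------------------------------------------------------------
  trend_results <- list()
  sp_all <- unique(vapply(bai_keep, function(b) b$species[1], ""))
  for (sp in sp_all) {
    sp_trees <- Filter(function(b) b$species[1] == sp, bai_keep)
    mf <- do.call(rbind, lapply(sp_trees, function(b) {
      tryCatch(prepare_model_frame(list(b), site_climates[[b$site_id[1]]]),
               error = function(e) NULL)
    }))
    if (is.null(mf) || nrow(mf) < 50) next
    dt <- fit_species_detrend(mf, spec)
    if (!isTRUE(dt$converged)) next
    gc <- growth_change(dt)
    vpd_by_year <- tapply(mf$vpd_t1, mf$year, mean)
    common <- intersect(gc$year, as.integer(names(vpd_by_year)))
    gcm <- gc$gc_mean[match(common, gc$year)]
    vy <- as.numeric(vpd_by_year[as.character(common)])
    tr_gc <- tryCatch(trend_test(gcm, common), error = function(e) NULL)
    tr_vpd <- tryCatch(trend_test(vy, common), error = function(e) NULL)
    bc <- tryCatch(boot_correlation(vy, gcm, n_boot = config$n_boot,
                                    seed = child_seed(config$seed,
                                                      paste0("boot", sp))),
                   error = function(e) NULL)
    trend_results[[sp]] <- list(species = sp, growth_change = gc,
                                trend_gc = tr_gc, trend_vpd = tr_vpd,
                                correlation = bc)
    write_stage(gc, run_dir, sprintf("growth_change_%s.csv", sp))
  }
  trj <- lapply(trend_results, function(x)
    x[c("species", "trend_gc", "trend_vpd", "correlation")])
  write_stage(trj, run_dir, "trend_results.json")
  # IDW map of prior-summer-VPD t-values
  conv_tab <- fit_tab[fit_tab$converged & is.finite(fit_tab$t_beta2), ]
  if (nrow(conv_tab) >= 3) {
    pts <- merge(conv_tab[, c("site_id", "t_beta2")],
                 site_meta[, c("site_id", "lat", "lon")], by = "site_id")
    field <- idw_interpolate(pts, pts$t_beta2, k = min(12, nrow(pts)))
    write_stage(field, run_dir, "tvalue_idw.csv")
  }
  mark("trends")

  ## --- manifest ------------------------------------------------------------
  sig <- function(cls) sum(class_tab[[cls]] %in% c("negative", "positive"))
  neg <- function(cls) sum(class_tab[[cls]] == "negative")
  manifest$counts <- list(
    trees_read = n_read,
    trees_excluded_filters = sum(excluded),
    models_attempted = length(fits),
    models_converged = sum(vapply(fits, function(f) isTRUE(f$converged), TRUE)),
    significant_vpd_t = sig("class_vpd_t"),
    significant_vpd_t1 = sig("class_vpd_t1"),
    negative_vpd_t = neg("class_vpd_t"),
    negative_vpd_t1 = neg("class_vpd_t1"),
    sensitivity_rows = nrow(sens))
  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out <- run_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}

#' Summarise a completed pipeline run
#'
#' @param run_dir Run directory produced by [run_pipeline()].
#' @return A list (also printed as text) with convergence rates, sign
#'   proportions per VPD covariate, the driver report and trend results;
#'   flagged partial if the run is incomplete.
#' @export
summarize_run <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop_config("no manifest in %s", run_dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  report <- list(complete = isTRUE(manifest$complete), counts = manifest$counts)
  cls_path <- file.path(run_dir, "vpd_response.csv")
  if (file.exists(cls_path)) {
    cls <- utils::read.csv(cls_path)
    prop <- function(col) {
      x <- factor(cls[[col]], levels = c("negative", "positive",
                                         "nonsignificant", "nonconvergent"))
      as.list(prop.table(table(x)))
    }
    report$proportions <- list(vpd_t = prop("class_vpd_t"),
                               vpd_t1 = prop("class_vpd_t1"))
  }
  di_path <- file.path(run_dir, "driver_importance.csv")
  if (file.exists(di_path)) report$drivers <- utils::read.csv(di_path)
  tr_path <- file.path(run_dir, "trend_results.json")
  if (file.exists(tr_path))
    report$trends <- jsonlite::read_json(tr_path, simplifyVector = TRUE)
  if (!report$complete) report$note <- "partial run"
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (full pipeline), `simulate` (fixtures only),
#' `report` (summarise an existing run). Typical use:
#' `Rscript -e 'vpdgrowth::pipeline_cli()' run-all --out runs/demo --seed 1`.
#'
#' @param args Character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return Exit status, invisibly (0 ok, 1 config error, 2 data error,
#'   3 numerical error).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: <run-all|simulate|report> [--out DIR] [--seed N] [--sites N] [--run DIR]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(out = "vpdgrowth_run", seed = 1L, sites = 10L, run = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message(usage); return(invisible(1L))
    }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed); opt$sites <- as.integer(opt$sites)
  status <- tryCatch({
    if (cmd == "run-all") {
      cfg <- pipeline_config(out_dir = opt$out, seed = opt$seed,
                             synthetic = sim_config(n_sites = opt$sites,
                                                    seed = opt$seed))
      run_pipeline(cfg)
      message("run complete: ", opt$out)
      0L
    } else if (cmd == "simulate") {
      cfg <- sim_config(n_sites = opt$sites, seed = opt$seed)
      grid <- default_site_grid(cfg$n_sites, opt$seed)
      sid <- names(grid)[1]
      wx <- simulate_daily_weather(grid[[1]], cfg$years, opt$seed)
      daily <- derive_daily_climate(wx, list(lat = grid[[1]]$lat))
      sc <- summarize_site_climate(daily, cfg$years, sid)
      rs <- simulate_ring_series(cfg, sc, site_id = sid, seed = opt$seed)
      write_fixture_bundle(rs$series, stats::setNames(list(wx), sid),
                           data.frame(site_id = sid, species = cfg$species_labels[1],
                                      lat = grid[[1]]$lat, lon = grid[[1]]$lon,
                                      elev = grid[[1]]$elev),
                           rs$truth, opt$out)
      message("fixtures written: ", opt$out)
      0L
    } else if (cmd == "report") {
      rep <- summarize_run(opt$run %||% opt$out)
      utils::str(rep, max.level = 2)
      0L
    } else {
      message(usage); 1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config|usage", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}
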