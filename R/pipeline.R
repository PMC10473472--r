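#' Default configuration for the end-to-end demonstration run
#'
#' One synthetic "cultivar" per entry of `frequencies_per_mm2` /
#' `core_area_means_mm2` (defaults span the density and core-area range
#' seen across mango cultivars: sparse large-cored skins to dense
#' small-cored ones), a logistic growth experiment, a two-group strain
#' experiment, and per-cultivar russet populations.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A named list of configuration values (class `run_config`).
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("mangolenticel_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cultivars = c("sparse_large", "intermediate", "dense_small"),
    frequencies_per_mm2 = c(0.05, 0.15, 0.33),
    core_area_means_mm2 = c(0.50, 0.16, 0.05),
    russet_mean_fractions_pct = c(30, 5, 0.5),
    russet_sd_pct = c(10, 4, 1),
    n_fruit_russet = 200L,
    field_mm = 12, scale_um_per_px = 20,
    halo_fraction = 0.5, halo_area_multiple = 3,
    growth = list(a_max = 370, k = 0.04, t_mid = 100,
                  times = seq(20, 180, by = 10), noise_sd = 5),
    sigmoid_family = "logistic",
    strain = list(with = c(12.6, 28.1), without = c(8.5, 15.8),
                  cv = 0.05, n = 30, punch_diameter_mm = 8),
    alpha = 0.05
  ), class = "run_config")
}

write_csv_units <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Chains every stage on generated data: simulate surface scenes per
#' "cultivar" -> segment and summarise lenticel morphometry (plus
#' fluorescent infiltration) -> fit the growth model and derive the rate
#' curve -> compute and compare strain groups -> score russet populations
#' -> ANOVA/letters report across cultivars. All outputs are CSVs with a
#' units comment line; the configuration and package version are echoed to
#' the run directory, so a run is reproducible from its own record.
#' Identical config + seed give byte-identical outputs.
#'
#' @param config A `run_config`, see [default_config()].
#' @param quiet Suppress progress messages.
#' @return The run directory, invisibly; its `summary.rds`-free contents
#'   are plain text (CSV/YAML/log).
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop("stage setup: cannot create output directory ", config$out_dir)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    say("stage ", name, " start")
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  cfg_echo <- config
  cfg_echo$package_version <- as.character(utils::packageVersion("mangolenticel"))
  yaml::write_yaml(unclass(cfg_echo), file.path(config$out_dir, "config.yaml"))

  nc <- length(config$cultivars)

  ## simulate + segment + summarize: per-cultivar morphometry
  core_pool <- vector("list", nc)  # interior core areas, reused by the report
  morpho <- stage("simulate/segment", {
    rows <- lapply(seq_len(nc), function(i) {
      spec <- scene_spec(
        field_width_mm = config$field_mm, field_height_mm = config$field_mm,
        scale_um_per_px = config$scale_um_per_px,
        lenticel_frequency_per_mm2 = config$frequencies_per_mm2[i],
        core_area_mean_mm2 = config$core_area_means_mm2[i],
        halo_fraction = config$halo_fraction,
        halo_area_multiple = config$halo_area_multiple,
        seed = config$seed + i)
      scene <- generate_surface_scene(spec)
      regions <- segment_lenticels(scene$brightfield)
      core_pool[[i]] <<- regions$core_area_mm2[!regions$border]
      sm <- summarize_window(regions, config$field_mm^2)
      infl <- infiltrated_area(scene$fluorescence, regions)
      cbind(cultivar = config$cultivars[i],
            planted_frequency_per_mm2 = attr(scene$truth, "frequency_per_mm2"),
            planted_mean_core_area_mm2 = mean(scene$truth$core_area_mm2),
            sm,
            mean_infiltrated_area_mm2 = if (length(infl)) mean(infl) else NA)
    })
    do.call(rbind, rows)
  })
  write_csv_units(morpho, file.path(config$out_dir, "morphometry_by_cultivar.csv"),
                  "areas mm2, frequency mm-2")

  ## growth
  g <- config$growth
  growth_fit <- stage("growth", {
    series <- generate_growth_series(g$a_max, g$k, g$t_mid, g$times,
                                     g$noise_sd, seed = config$seed + 100L)
    fit <- fit_growth(series, family = config$sigmoid_family)
    write_csv_units(series, file.path(config$out_dir, "growth_series.csv"),
                    "dafb d, area cm2")
    write_csv_units(growth_rate_curve(fit, g$times),
                    file.path(config$out_dir, "growth_rate_curve.csv"),
                    "dafb d, rate cm2 d-1")
    fitdf <- data.frame(family = fit$family, a_max_cm2 = fit$a_max,
                        k_per_d = fit$k, t_mid_dafb = fit$t_mid,
                        peak_rate_cm2_per_d = fit$peak_rate_cm2_per_d,
                        t_peak_dafb = fit$t_peak_dafb,
                        residual_sd_cm2 = fit$residual_sd)
    write_csv_units(fitdf, file.path(config$out_dir, "growth_fit.csv"),
                    "areas cm2, k d-1, times DAFB")
    fit
  })

  ## strain
  strain_cmp <- stage("strain", {
    s <- config$strain
    samples <- rbind(
      generate_strain_samples(s$with[1], s$with[2], s$punch_diameter_mm,
                              cv = s$cv, n = s$n, seed = config$seed + 200L,
                              has_lenticels = TRUE),
      generate_strain_samples(s$without[1], s$without[2], s$punch_diameter_mm,
                              cv = s$cv, n = s$n, seed = config$seed + 201L,
                              has_lenticels = FALSE))
    per_sample <- compute_strains(samples)
    write_csv_units(per_sample, file.path(config$out_dir, "strain_samples.csv"),
                    "areas mm2, strains %")
    cmp <- compare_groups(samples)
    tbl <- cmp$by_group
    tbl$ratio_vs_without <- c(cmp$ratio_with_over_without["tot"], 1)
    write_csv_units(tbl, file.path(config$out_dir, "strain_group_summary.csv"),
                    "strains %")
    cmp
  })

  ## russet
  russet <- stage("russet", {
    rows <- lapply(seq_len(nc), function(i) {
      pop <- generate_russet_population(config$russet_mean_fractions_pct[i],
                                        config$russet_sd_pct[i],
                                        config$n_fruit_russet,
                                        seed = config$seed + 300L + i)
      sv <- severity_summary(pop)
      data.frame(cultivar = config$cultivars[i], n = sv$n,
                 mean_score = sv$mean_score, se_score = sv$se_score,
                 t(as.integer(sv$histogram)))
    })
    out <- do.call(rbind, rows)
    names(out)[grep("^X", names(out))] <- paste0("n_score_", 0:4)
    write_csv_units(out, file.path(config$out_dir, "russet_by_cultivar.csv"),
                    "score 0-4")
    out
  })

  ## statistics report: do segmented core areas separate by cultivar?
  stage("stats report", {
    core_by_cv <- do.call(rbind, lapply(seq_len(nc), function(i)
      data.frame(cultivar = config$cultivars[i],
                 core_area_mm2 = core_pool[[i]])))
    lettered <- anova_tukey_letters(core_by_cv$core_area_mm2,
                                    core_by_cv$cultivar, alpha = config$alpha)
    write_csv_units(lettered,
                    file.path(config$out_dir, "core_area_tukey_letters.csv"),
                    "mean/se mm2")
  })

  say("run complete: ", config$out_dir)
  invisible(config$out_dir)
}
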