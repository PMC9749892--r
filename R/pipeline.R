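# Run configuration and end-to-end orchestration: validate a YAML config,
# run the requested assay stages over the built-in genotype presets, write
# TSV outputs plus a JSON manifest.  Identical config + seed gives
# byte-identical outputs; no stage consults wall-clock or global RNG state.

#' Default run configuration
#'
#' Stage parameters all default to the assay-standard values: rhythmicity
#' criteria 20 / 2 h / alpha 0.05, FDR threshold q = 0.1, sweep protocol
#' 50 s / 5 s / 95 s x 5 sweeps at 200 uW/cm2, 1-min bins, period grid
#' 16-32 h in 0.1-h steps.  Cohort sizes are sized for a demo run that
#' completes in minutes on one CPU.
#'
#' @return nested list understood by [validate_config()] and [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "results/demo",
    genotypes = c("DmCRY", "AeCRY1", "AgCRY1", "cry_null"),
    assays = c("locomotor", "ephys", "choice", "icc", "stats"),
    locomotor = list(
      n_flies = 8L, days_ld = 4L, days_dd = 5L, lux = 400,
      grid_min_h = 16, grid_max_h = 32, grid_step_h = 0.1,
      min_power = 20, min_width_h = 2, alpha = 0.05,
      anticipation_days = 3L),
    ephys = list(
      n_cells = 2L, sampling_hz = 2000,
      pre_dark_s = 50, stim_s = 5, post_s = 95, n_sweeps = 5L,
      wavelength_nm = 450, intensity_uw_cm2 = 200,
      baseline_window_s = 10, gaussian_sigma_ms = 50,
      butter_order = 3L, butter_cutoff_hz = 2,
      evoked_output_hz = 10),
    choice = list(
      n_flies = 20L, minutes = 30L, wavelength_nm = 450,
      intensity_uw_cm2 = 10, window_min = 30L),
    icc = list(
      n_brains = 3L, neurons_per_brain = 4L, zts = c(5, 11, 17, 23),
      channel = "TIM"),
    stats = list(q = 0.1, tail = "greater")
  )
}

config_schema <- function() {
  # field path -> c(type, min, max); type: number, count, character, vector
  list(
    "seed" = c("count", 0),
    "output_dir" = c("character"),
    "locomotor$n_flies" = c("count", 1),
    "locomotor$days_ld" = c("count", 0),
    "locomotor$days_dd" = c("count", 0),
    "locomotor$lux" = c("number", 0),
    "locomotor$grid_min_h" = c("number", 1),
    "locomotor$grid_max_h" = c("number", 1),
    "locomotor$grid_step_h" = c("number", 1e-6),
    "locomotor$min_power" = c("number", 0),
    "locomotor$min_width_h" = c("number", 0),
    "locomotor$alpha" = c("number", 1e-12, 0.999999),
    "locomotor$anticipation_days" = c("count", 1),
    "ephys$n_cells" = c("count", 1),
    "ephys$sampling_hz" = c("number", 2000),
    "ephys$pre_dark_s" = c("number", 1e-9),
    "ephys$stim_s" = c("number", 1e-9),
    "ephys$post_s" = c("number", 1e-9),
    "ephys$n_sweeps" = c("count", 1),
    "ephys$baseline_window_s" = c("number", 1e-9),
    "ephys$gaussian_sigma_ms" = c("number", 0),
    "ephys$butter_order" = c("count", 1),
    "ephys$butter_cutoff_hz" = c("number", 1e-9),
    "ephys$evoked_output_hz" = c("number", 1e-9),
    "choice$n_flies" = c("count", 1),
    "choice$minutes" = c("count", 1),
    "choice$window_min" = c("count", 1),
    "icc$n_brains" = c("count", 1),
    "icc$neurons_per_brain" = c("count", 1),
    "stats$q" = c("number", 1e-12, 0.999999)
  )
}

#' Validate a run configuration
#'
#' Merges the supplied configuration over [default_config()] and checks
#' every scalar against its schema entry before any computation; an invalid
#' field is reported by name and nothing is written.
#'
#' @param config nested list (e.g. from [read_config()]).
#' @return the merged, validated configuration.
#' @export
validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  schema <- config_schema()
  for (field in names(schema)) {
    spec <- schema[[field]]
    path <- strsplit(field, "$", fixed = TRUE)[[1]]
    val <- cfg
    for (p in path) val <- val[[p]]
    if (is.null(val)) stop_field(field, "is missing")
    type <- spec[1]
    if (type == "character") {
      if (!is.character(val) || length(val) != 1)
        stop_field(field, "must be a single string")
    } else {
      lo <- if (length(spec) >= 2) as.numeric(spec[2]) else -Inf
      hi <- if (length(spec) >= 3) as.numeric(spec[3]) else Inf
      if (type == "count") check_count(val, field, min = lo)
      else check_number(val, field, min = lo, max = hi)
    }
  }
  known <- names(default_presets())
  bad <- setdiff(cfg$genotypes, known)
  if (length(bad))
    stop_field("genotypes", paste("contains unknown presets:",
                                  paste(bad, collapse = ", ")))
  bad <- setdiff(cfg$assays, c("locomotor", "ephys", "choice", "icc", "stats"))
  if (length(bad))
    stop_field("assays", paste("contains unknown stages:",
                               paste(bad, collapse = ", ")))
  if (cfg$locomotor$days_ld + cfg$locomotor$days_dd < 1)
    stop_field("locomotor$days_ld + locomotor$days_dd", "must be at least 1")
  if (!all(cfg$icc$zts %in% ROI_ZTS))
    stop_field("icc$zts", "must be a subset of {5, 11, 17, 23}")
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return validated configuration (see [validate_config()]).
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# deterministic per-stage, per-genotype seed derivation
stage_seed <- function(seed, stage, index) {
  (as.integer(seed) + 7919L * stage + 101L * index) %% .Machine$integer.max
}

stage_locomotor <- function(cfg, presets, seed, out) {
  lc <- cfg$locomotor
  grid <- seq(lc$grid_min_h, lc$grid_max_h, by = lc$grid_step_h)
  criteria <- rhythmicity_criteria(lc$min_power, lc$min_width_h, lc$alpha)
  fly_rows <- list(); cohort_rows <- list(); ai_rows <- list()
  for (gi in seq_along(presets)) {
    preset <- presets[[gi]]
    cohort <- simulate_locomotor(preset, n_flies = lc$n_flies,
                                 days_ld = lc$days_ld, days_dd = lc$days_dd,
                                 lux = lc$lux,
                                 seed = stage_seed(seed, 1L, gi))
    pg <- lapply(cohort, chi_square_periodogram, dd_only = TRUE,
                 period_grid_h = grid, alpha = lc$alpha)
    calls <- lapply(pg, classify_rhythmic, criteria = criteria)
    fly_rows[[gi]] <- data.frame(
      fly_id = vapply(cohort, `[[`, character(1), "fly_id"),
      genotype = preset$name, lux = lc$lux,
      tau_h = vapply(pg, `[[`, numeric(1), "tau_h"),
      power = vapply(pg, `[[`, numeric(1), "power"),
      width_h = vapply(pg, `[[`, numeric(1), "width_h"),
      rhythmic = vapply(calls, `[[`, logical(1), "rhythmic"))
    cs <- cohort_summary(pg, criteria)
    cohort_rows[[gi]] <- data.frame(
      genotype = preset$name, lux = lc$lux, n = cs$n,
      percent_rhythmic = cs$percent_rhythmic,
      tau_mean = cs$tau_mean, tau_sem = cs$tau_sem,
      power_mean = cs$power_mean, power_sem = cs$power_sem,
      width_mean = cs$width_mean, width_sem = cs$width_sem)
    ai_rows[[gi]] <- do.call(rbind, lapply(cohort, function(fly) {
      do.call(rbind, lapply(c("morning", "evening"), function(tr) {
        ai <- anticipation_index(fly, tr, n_days = lc$anticipation_days)
        data.frame(fly_id = fly$fly_id, genotype = preset$name,
                   transition = tr, ai = ai$ai, days_used = ai$days_used)
      }))
    }))
  }
  files <- c(write_tsv(do.call(rbind, fly_rows), file.path(out, "locomotor_flies.tsv")),
             write_tsv(do.call(rbind, cohort_rows), file.path(out, "locomotor_cohort.tsv")),
             write_tsv(do.call(rbind, ai_rows), file.path(out, "anticipation.tsv")))
  list(files = files, flies = do.call(rbind, fly_rows),
       anticipation = do.call(rbind, ai_rows))
}

stage_ephys <- function(cfg, presets, seed, out) {
  ec <- cfg$ephys
  protocol <- sweep_protocol(ec$pre_dark_s, ec$stim_s, ec$post_s, ec$n_sweeps,
                             ec$wavelength_nm, ec$intensity_uw_cm2)
  cell_rows <- list(); evoked_files <- character(0)
  excluded <- 0L
  for (gi in seq_along(presets)) {
    preset <- presets[[gi]]
    evoked_sum <- NULL
    for (ci in seq_len(ec$n_cells)) {
      rec <- simulate_voltage(preset, protocol, sampling_hz = ec$sampling_hz,
                              seed = stage_seed(seed, 2L, 100L * gi + ci),
                              cell_id = sprintf("%s_cell%02d", preset$name, ci))
      spikes <- detect_spikes(rec)
      ff <- firing_frequency_ratio(spikes, protocol)
      if (!ff$defined) excluded <- excluded + 1L
      basal <- basal_metrics(rec, spikes)
      ep <- evoked_potential(rec, ec$baseline_window_s, ec$gaussian_sigma_ms,
                             ec$butter_order, ec$butter_cutoff_hz)
      keep <- seq(1, length(ep$delta_mv),
                  by = max(1, round(ec$sampling_hz / ec$evoked_output_hz)))
      evoked_sum <- if (is.null(evoked_sum)) ep$delta_mv[keep] else
        evoked_sum + ep$delta_mv[keep]
      if (ci == 1) evoked_t <- ep$time_s[keep]
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        cell_id = rec$cell_id, genotype = preset$name,
        rmp_mv = basal$rmp_mv, basal_rate_hz = basal$basal_rate_hz,
        firing_mode = basal$firing_mode, ff_defined = ff$defined,
        ff_ratio = ff$ff_ratio,
        post_ratio_10s = ff$post_ratios[1], post_ratio_20s = ff$post_ratios[2],
        post_ratio_30s = ff$post_ratios[3], post_ratio_40s = ff$post_ratios[4])
    }
    f <- write_tsv(data.frame(time_s = evoked_t,
                              mean_delta_mv = evoked_sum / ec$n_cells),
                   file.path(out, sprintf("evoked_%s.tsv", preset$name)))
    evoked_files <- c(evoked_files, f)
  }
  cells <- do.call(rbind, cell_rows)
  files <- c(write_tsv(cells, file.path(out, "ephys_cells.tsv")), evoked_files)
  message(sprintf("ephys: %d cells, %d excluded for zero baseline",
                  nrow(cells), excluded))
  list(files = files, cells = cells)
}

stage_choice <- function(cfg, presets, seed, out) {
  cc <- cfg$choice
  bin_rows <- list(); fly_tabs <- list()
  for (gi in seq_along(presets)) {
    preset <- presets[[gi]]
    cohort <- simulate_choice(preset, n_flies = cc$n_flies,
                              minutes = cc$minutes,
                              seed = stage_seed(seed, 3L, gi),
                              wavelength_nm = cc$wavelength_nm,
                              intensity_uw_cm2 = cc$intensity_uw_cm2)
    prefs <- lapply(cohort, preference_timeseries)
    per_bin <- do.call(rbind, lapply(seq_len(cc$minutes), function(b) {
      vals <- vapply(prefs, function(p) p$percent_lit[b], numeric(1))
      vals <- vals[!is.na(vals)]
      data.frame(genotype = preset$name, minute = b - 1,
                 mean_percent_lit = if (length(vals)) mean(vals) else NA_real_,
                 sem_percent_lit = sem(vals), n = length(vals))
    }))
    bin_rows[[gi]] <- per_bin
    mpa <- mean_percent_activity(cohort, window_min = cc$window_min)
    fly_tabs[[gi]] <- mpa$per_fly
  }
  flies <- do.call(rbind, fly_tabs)
  files <- c(write_tsv(do.call(rbind, bin_rows), file.path(out, "choice_bins.tsv")),
             write_tsv(flies, file.path(out, "choice_flies.tsv")))
  list(files = files, flies = flies)
}

stage_icc <- function(cfg, presets, seed, out) {
  ic <- cfg$icc
  tabs <- list(); prof_rows <- list()
  for (gi in seq_along(presets)) {
    preset <- presets[[gi]]
    tab <- do.call(rbind, lapply(seq_along(ic$zts), function(zi) {
      simulate_roi(preset, n_brains = ic$n_brains,
                   neurons_per_brain = ic$neurons_per_brain,
                   zt = ic$zts[zi], seed = stage_seed(seed, 4L, 10L * gi + zi),
                   channel = ic$channel)
    }))
    tab <- normalize_roi(tab)
    tabs[[gi]] <- tab
    prof <- zt_profile(tab, genotype = preset$name, channel = ic$channel)
    prof_rows[[gi]] <- cbind(genotype = preset$name, channel = ic$channel,
                             as.data.frame(prof))
  }
  neurons <- do.call(rbind, tabs)
  files <- c(write_tsv(neurons, file.path(out, "icc_neurons.tsv")),
             write_tsv(do.call(rbind, prof_rows), file.path(out, "icc_profile.tsv")))
  list(files = files, neurons = neurons)
}

stage_stats <- function(cfg, results, out) {
  q <- cfg$stats$q
  tail <- cfg$stats$tail
  fams <- list()
  if (!is.null(results$choice))
    fams$choice_percent_lit <- list(data = results$choice$flies,
                                    value = "mean_percent_lit",
                                    group = "genotype")
  if (!is.null(results$ephys)) {
    cells <- results$ephys$cells
    cells <- cells[cells$ff_defined, ]
    if (nrow(cells) > 0 && min(table(cells$genotype)) >= 3)
      fams$ephys_ff_ratio <- list(data = cells, value = "ff_ratio",
                                  group = "genotype")
  }
  if (!is.null(results$locomotor)) {
    flies <- results$locomotor$flies
    flies <- flies[flies$rhythmic, ]
    if (nrow(flies) > 0 && length(unique(flies$genotype)) >= 2 &&
        min(table(flies$genotype)) >= 3)
      fams$locomotor_tau <- list(data = flies, value = "tau_h",
                                 group = "genotype")
  }
  if (length(fams) == 0) return(NULL)
  comp <- do.call(rbind, lapply(names(fams), function(fam) {
    f <- fams[[fam]]
    compare_groups(f$data, f$value, f$group, tail = tail, q = q, family = fam)
  }))
  list(files = write_tsv(comp, file.path(out, "comparisons.tsv")),
       comparisons = comp)
}

#' Run the pipeline end-to-end
#'
#' Validates the configuration, simulates each requested assay for each
#' configured genotype preset, runs the corresponding analysis stage, and
#' writes per-fly/per-cell and cohort TSV tables plus a JSON manifest
#' recording the package version, seed, configuration hash and output
#' files.  Identical configuration + seed produce byte-identical outputs.
#'
#' @param config nested list (see [default_config()]); validated first.
#' @param output_dir overrides `config$output_dir` when given.
#' @param seed overrides `config$seed` when given.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (!is.null(seed)) cfg$seed <- check_count(seed, "seed", min = 0)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  presets <- default_presets()[cfg$genotypes]
  results <- list()
  if ("locomotor" %in% cfg$assays)
    results$locomotor <- stage_locomotor(cfg, presets, cfg$seed, out)
  if ("ephys" %in% cfg$assays)
    results$ephys <- stage_ephys(cfg, presets, cfg$seed, out)
  if ("choice" %in% cfg$assays)
    results$choice <- stage_choice(cfg, presets, cfg$seed, out)
  if ("icc" %in% cfg$assays)
    results$icc <- stage_icc(cfg, presets, cfg$seed, out)
  if ("stats" %in% cfg$assays)
    results$stats <- stage_stats(cfg, results, out)
  files <- unlist(lapply(results, `[[`, "files"), use.names = FALSE)
  cfg_hashed <- cfg
  cfg_hashed$output_dir <- NULL      # hash the scientific config, not the path
  manifest <- list(
    package = "crylight",
    version = as.character(utils::packageVersion("crylight")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg_hashed),
    outputs = sort(basename(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(results = results)))
}
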