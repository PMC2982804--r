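# Pipeline entry points: config in, CSV/JSON artefacts plus a run manifest
# out. These back the thin command-line wrapper shipped in inst/cli.

write_manifest <- function(outdir, command, params, seed, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    params = params,
    master_seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("mtlength")),
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  path
}

log_msg <- function(...) message(sprintf(...))

#' Run a single simulation from a config file
#'
#' Reads a YAML config mirroring \code{\link{mt_params}} field names,
#' simulates, and writes the trajectory CSV (+ JSON parameter sidecar), a
#' steady-state summary JSON, and a manifest listing every output with its
#' checksum. Identical config and seed reproduce byte-identical outputs.
#'
#' @param config_path YAML config file; NULL uses the defaults.
#' @param outdir output directory (created if needed).
#' @param duration simulated time, min.
#' @param burn_in transient for the summary, min.
#' @param record_interval recording cadence, min.
#' @return invisibly, the manifest path.
#' @export
run_simulate <- function(config_path = NULL, outdir, duration = 2000,
                         burn_in = 500, record_interval = 1) {
  params <- if (is.null(config_path)) mt_params() else {
    read_mt_config(config_path)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (burn_in >= duration) {
    burn_in <- duration / 4
    log_msg("burn-in exceeds the run; shortened to %g min", burn_in)
  }
  log_msg("simulate: seed %d, %g min, N_m = %d, alpha = %g",
          params$seed, duration, params$N_m, params$alpha)
  tr <- simulate_cell(params, duration, record_interval)
  traj_csv <- file.path(outdir, "trajectory.csv")
  write_trajectory(tr, traj_csv)
  ss <- summarize_steady_state(tr, burn_in)
  mf <- tryCatch(predicted_steady_length(params), error = function(e) NULL)
  summ <- unclass(ss)
  if (!is.null(mf)) summ$mean_field <- unclass(mf)
  summary_json <- file.path(outdir, "summary.json")
  jsonlite::write_json(summ, summary_json, auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(outdir, "simulate", unclass(params),
                             params$seed,
                             c(traj_csv, paste0(traj_csv, ".json"),
                               summary_json))
  invisible(manifest)
}

#' Run a homeostasis parameter sweep
#'
#' @param N_m_values,alpha_values grid axes.
#' @param config_path optional YAML config for the baseline parameters.
#' @param outdir output directory.
#' @param duration simulated time per grid cell, min.
#' @param burn_in transient, min.
#' @return invisibly, the manifest path.
#' @export
run_sweep <- function(N_m_values, alpha_values, config_path = NULL, outdir,
                      duration = 5000, burn_in = 500) {
  params <- if (is.null(config_path)) mt_params() else {
    read_mt_config(config_path)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_msg("sweep: %d x %d grid, %g min per cell",
          length(N_m_values), length(alpha_values), duration)
  hm <- homeostasis_map(N_m_values, alpha_values, params, duration, burn_in)
  sd_csv <- file.path(outdir, "sd_length.csv")
  utils::write.csv(hm$sd_length, sd_csv)
  mean_csv <- file.path(outdir, "mean_length.csv")
  utils::write.csv(hm$mean_length, mean_csv)
  long <- expand.grid(N_m = hm$N_m_values, alpha = hm$alpha_values)
  long$sd_length_um <- as.vector(hm$sd_length)
  long$mean_length_um <- as.vector(hm$mean_length)
  summaries_csv <- file.path(outdir, "summaries.csv")
  utils::write.csv(long, summaries_csv, row.names = FALSE)
  manifest <- write_manifest(outdir, "sweep", unclass(params), params$seed,
                             c(sd_csv, mean_csv, summaries_csv))
  invisible(manifest)
}

#' Run a mid-course parameter perturbation
#'
#' @param factors named list of positive multipliers (e.g.
#'   \code{list(v_g = 0.5)}).
#' @param t_switch switch time, min.
#' @param config_path optional YAML config.
#' @param outdir output directory.
#' @param duration total simulated time, min.
#' @return invisibly, the manifest path.
#' @export
run_perturb <- function(factors, t_switch, config_path = NULL, outdir,
                        duration = 2000) {
  params <- if (is.null(config_path)) mt_params() else {
    read_mt_config(config_path)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_msg("perturb: switch at %g min, factors %s", t_switch,
          paste(names(factors), unlist(factors), sep = " x ", collapse = ", "))
  tr <- perturb_parameter(params, t_switch, factors, duration)
  traj_csv <- file.path(outdir, "trajectory.csv")
  write_trajectory(tr, traj_csv)
  info <- list(switch_time_min = t_switch, factors = as.list(factors),
               params_after = unclass(attr(tr, "params_after")))
  info_json <- file.path(outdir, "perturbation.json")
  jsonlite::write_json(info, info_json, auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(outdir, "perturb", unclass(params),
                             params$seed,
                             c(traj_csv, paste0(traj_csv, ".json"),
                               info_json))
  invisible(manifest)
}

#' Generate a synthetic patterned-cell image on disk
#'
#' @param outdir output directory.
#' @param length_um,width_um,pixel_size,n_filaments,angle_model,noise_sd,seed
#'   forwarded to \code{\link{render_patterned_cell}}.
#' @return invisibly, the manifest path.
#' @export
run_synthimg <- function(outdir, length_um = 44, width_um = 13,
                         pixel_size = 1, n_filaments = 30,
                         angle_model = list(name = "vonmises", mu = 0,
                                            kappa = 4),
                         noise_sd = 5, seed = 1) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_msg("synthimg: %g x %g um cell, %d filaments, seed %d",
          length_um, width_um, n_filaments, seed)
  img <- render_patterned_cell(length_um, width_um, pixel_size, n_filaments,
                               angle_model, noise_sd, seed)
  write_synthetic_image(img, outdir, "cell")
  files <- file.path(outdir, c("cell_channel.tif", "cell_cell_mask.png",
                               "cell_line_mask.png", "cell_nucleus_mask.png",
                               "cell_truth.json"))
  manifest <- write_manifest(outdir, "synthimg",
                             list(length_um = length_um, width_um = width_um,
                                  pixel_size = pixel_size,
                                  n_filaments = n_filaments,
                                  angle_model = angle_model,
                                  noise_sd = noise_sd),
                             seed, files)
  invisible(manifest)
}

#' Measure a (synthetic) patterned-cell image on disk
#'
#' Reads the rasters written by \code{\link{run_synthimg}} (or equivalently
#' formatted real data), applies the measurement procedures, and writes a
#' per-cell CSV plus the orientation distribution CSV.
#'
#' @param imgdir directory holding the image set.
#' @param outdir output directory.
#' @param basename image basename.
#' @param bin_width orientation bin width, degrees.
#' @return invisibly, the manifest path.
#' @export
run_measure <- function(imgdir, outdir, basename = "cell", bin_width = 5) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  img <- read_synthetic_image(imgdir, basename)
  width <- measure_pattern_width(img$line_mask, img$pixel_size)
  lenm <- measure_cell_length(img$cell_mask, img$nucleus_mask, "patterned",
                              img$pixel_size)
  od <- orientation_distribution(img$channel, img$cell_mask, bin_width)
  fil <- img$ground_truth$filaments
  n_est <- NA_integer_
  if (!is.null(fil) && length(fil$length_um)) {
    cnt <- estimate_mt_count(
      img$channel, img$cell_mask,
      img$ground_truth$intensity_unit,
      mean(fil$length_um) / img$pixel_size)
    n_est <- cnt$count
  }
  cells_csv <- file.path(outdir, "cells.csv")
  utils::write.csv(data.frame(
    basename = basename,
    length_um = lenm$length_um,
    width_um = width,
    n_filaments_est = n_est,
    rejected_reason = ifelse(lenm$rejected, lenm$reason, "")),
    cells_csv, row.names = FALSE)
  orient_csv <- file.path(outdir, "orientation.csv")
  utils::write.csv(data.frame(angle_deg = od$bin_centres, mass = od$mass),
                   orient_csv, row.names = FALSE)
  manifest <- write_manifest(outdir, "measure", list(imgdir = imgdir),
                             NA_integer_, c(cells_csv, orient_csv))
  invisible(manifest)
}
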