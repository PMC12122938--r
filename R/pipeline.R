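#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Run configuration for the full pipeline
#'
#' Flat key-value configuration covering geometry, protocol, phantom run,
#' reconstruction and classification settings, with the vessel defaults of
#' the 84 mm eight-electrode ring (0.1 mA at 10 kHz, adjacent protocol).
#' `frequency_khz`, `rotation_rpm` and `temperature_C` are experiment
#' metadata carried verbatim to the manifest; no computation depends on them.
#'
#' @param radius_mm,n_electrodes,electrode_arc_deg Vessel geometry.
#' @param sim_edge_mm,recon_edge_mm Target element edges of the simulation and
#'   reconstruction meshes (keep the simulation mesh finer).
#' @param current_mA,frequency_khz Protocol settings.
#' @param n_frames,peak_frame,max_fraction,frame_dt_s,noise_rel,seed Synthetic
#'   agitation-run settings.
#' @param sampling_diameter_mm Diameter of the two sampling areas.
#' @param rotation_rpm,temperature_C Metadata.
#' @param recon,fcm Optional [recon_config()] / [fcm_config()] overrides.
#' @return A list of class `feit_config`.
#' @export
feit_config <- function(radius_mm = 42, n_electrodes = 8, electrode_arc_deg = 10,
                        sim_edge_mm = 4.5, recon_edge_mm = 6.5,
                        current_mA = 0.1, frequency_khz = 10,
                        n_frames = 10, peak_frame = 6, max_fraction = 0.45,
                        frame_dt_s = 60, noise_rel = 0.01, seed = 1L,
                        sampling_diameter_mm = 20,
                        rotation_rpm = 660, temperature_C = 5,
                        recon = recon_config(), fcm = fcm_config()) {
  structure(
    list(radius_mm = radius_mm, n_electrodes = n_electrodes,
         electrode_arc_deg = electrode_arc_deg,
         sim_edge_mm = sim_edge_mm, recon_edge_mm = recon_edge_mm,
         current_mA = current_mA, frequency_khz = frequency_khz,
         n_frames = n_frames, peak_frame = peak_frame,
         max_fraction = max_fraction, frame_dt_s = frame_dt_s,
         noise_rel = noise_rel, seed = as.integer(seed),
         sampling_diameter_mm = sampling_diameter_mm,
         rotation_rpm = rotation_rpm, temperature_C = temperature_C,
         recon = recon, fcm = fcm),
    class = "feit_config"
  )
}

#' Read a run configuration from a flat YAML file
#'
#' Unknown keys are rejected with a message naming them; nested `recon:` and
#' `fcm:` blocks override the corresponding [recon_config()] / [fcm_config()]
#' arguments.
#'
#' @param path YAML file path.
#' @return A `feit_config`.
#' @export
read_feit_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top <- setdiff(names(raw), c(names(formals(feit_config))))
  if (length(top) > 0) {
    stop("Unknown configuration keys: ", paste(top, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$recon)) raw$recon <- do.call(recon_config, raw$recon)
  if (!is.null(raw$fcm)) raw$fcm <- do.call(fcm_config, raw$fcm)
  do.call(feit_config, raw)
}

config_meshes <- function(config) {
  list(
    sim = build_disk_mesh(config$radius_mm, config$n_electrodes,
                          config$electrode_arc_deg, config$sim_edge_mm),
    recon = build_disk_mesh(config$radius_mm, config$n_electrodes,
                            config$electrode_arc_deg, config$recon_edge_mm)
  )
}

#' Simulate a synthetic agitation run bundle to disk
#'
#' Generates the synthetic run defined by the configuration and writes
#' `protocol.csv`, `frames.csv`, `truth_masks.csv`, the simulation mesh
#' tables, and `manifest.yml` (configuration echo, hash and seed) into
#' `out_dir`.
#'
#' @param config A [feit_config()].
#' @param out_dir Output directory (created).
#' @return The `feit_run`, invisibly; side effect: files in `out_dir`.
#' @export
feit_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "feit_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meshes <- config_meshes(config)
  protocol <- adjacent_protocol(config$n_electrodes, config$current_mA,
                                config$frequency_khz)
  profile <- make_agitation_profile(config$n_frames, config$peak_frame,
                                    config$max_fraction)
  times <- config$frame_dt_s * (seq_len(config$n_frames) - 1L)
  run <- simulate_agitation_run(meshes$sim, protocol, profile, times,
                                noise_rel = config$noise_rel, seed = config$seed)
  write_protocol(protocol, file.path(out_dir, "protocol.csv"))
  write_frames(run$frames, file.path(out_dir, "frames.csv"))
  readr::write_csv(dplyr::rename(run$truth, element_index = "element"),
                   file.path(out_dir, "truth_masks.csv"))
  write_mesh(meshes$sim, file.path(out_dir, "sim_mesh"))
  write_manifest(config, out_dir, stage = "simulate")
  invisible(run)
}

#' Reconstruct every frame of a run
#'
#' Applies the non-linear Gauss-Newton reconstruction independently to each
#' time frame on the (coarser) reconstruction mesh.
#'
#' @param frames Long tibble `time_s`, `pattern`, `voltage_V`.
#' @param mesh Reconstruction `eit_mesh`.
#' @param protocol An `eit_protocol`; each frame must contain one voltage per
#'   protocol pattern.
#' @param config A [recon_config()].
#' @param lambda_scope `"per_frame"` (default): every frame keeps the L-curve
#'   selection of its own first linearized step, as in per-frame absolute
#'   reconstruction; `"run_median"`: reconstruct all frames with the run
#'   median of those selections (comparable contrast between frames at the
#'   cost of per-frame adaptivity). Ignored when the config fixes lambda
#'   explicitly.
#' @return List of class `feit_recon_series`: `sigma_series` (tibble `time_s`,
#'   `element`, `sigma_S_per_m`) and `fits` (per-frame [glance()] rows).
#' @export
feit_reconstruct <- function(frames, mesh, protocol, config = recon_config(),
                             lambda_scope = c("per_frame", "run_median")) {
  lambda_scope <- match.arg(lambda_scope)
  stopifnot(all(c("time_s", "pattern", "voltage_V") %in% names(frames)))
  times <- sort(unique(frames$time_s))
  if (lambda_scope == "run_median" && config$lambda_mode == "l_curve" &&
      is.null(config$lambda_abs)) {
    lams <- purrr::map_dbl(times, function(tm) {
      fv <- dplyr::filter(frames, .data$time_s == tm)
      first_iteration_lambda(fv, mesh, protocol, config)
    })
    config$lambda_abs <- stats::median(lams)
  }
  out <- purrr::map(times, function(tm) {
    fv <- dplyr::filter(frames, .data$time_s == tm)
    rec <- gauss_newton_reconstruct(fv, mesh, protocol, config)
    list(sigma = dplyr::mutate(tidy(rec), time_s = tm, .before = 1),
         fit = dplyr::mutate(glance(rec), time_s = tm, .before = 1))
  })
  structure(
    list(
      sigma_series = dplyr::bind_rows(purrr::map(out, "sigma")),
      fits = dplyr::bind_rows(purrr::map(out, "fit"))
    ),
    class = "feit_recon_series"
  )
}

#' Classify and summarize a reconstructed run
#'
#' Pools the conductivity images of all time points into one fuzzy two-phase
#' classification, then reduces the per-frame membership images to the
#' aeration series (`u2_all`, `u2_area1`, `u2_area2`), their min-max
#' normalizations, and the saturation time `t_s`.
#'
#' @param sigma_series Tibble `time_s`, `element`, `sigma_S_per_m`.
#' @param mesh Reconstruction `eit_mesh`.
#' @param fcm A [fcm_config()].
#' @param regions Named list of `region_mask`s (default: the two standard
#'   sampling areas).
#' @return List of class `feit_analysis`: `classification`, `metrics` (long
#'   tibble `quantity`, `time_s`, `value`), `t_s` (per-quantity peak times).
#' @export
feit_analyze <- function(sigma_series, mesh, fcm = fcm_config(),
                         regions = sampling_areas(mesh)) {
  cls <- classify_run(sigma_series, fcm)
  series <- membership_series(cls, mesh, regions)
  norm <- series |>
    dplyr::group_by(.data$quantity) |>
    dplyr::mutate(value = minmax_normalize(.data$value),
                  quantity = paste0(.data$quantity, "_norm")) |>
    dplyr::ungroup()
  metrics <- dplyr::bind_rows(series, norm)[, c("quantity", "time_s", "value")]
  t_s <- series |>
    dplyr::group_by(.data$quantity) |>
    dplyr::reframe(peak_time(.data$time_s, .data$value))
  structure(list(classification = cls, metrics = metrics, t_s = t_s),
            class = "feit_analysis")
}

#' Run the whole synthetic pipeline in one call
#'
#' simulate -> reconstruct (on the coarser mesh) -> classify -> analyze.
#'
#' @param config A [feit_config()].
#' @param out_dir Optional directory; when given, all stage outputs and a
#'   manifest are written there.
#' @return List with `run`, `recon` (`feit_recon_series`), `analysis`
#'   (`feit_analysis`), and the meshes used.
#' @export
feit_run_all <- function(config = feit_config(), out_dir = NULL) {
  meshes <- config_meshes(config)
  protocol <- adjacent_protocol(config$n_electrodes, config$current_mA,
                                config$frequency_khz)
  profile <- make_agitation_profile(config$n_frames, config$peak_frame,
                                    config$max_fraction)
  times <- config$frame_dt_s * (seq_len(config$n_frames) - 1L)
  run <- simulate_agitation_run(meshes$sim, protocol, profile, times,
                                noise_rel = config$noise_rel, seed = config$seed)
  recon <- feit_reconstruct(run$frames, meshes$recon, protocol, config$recon)
  regions <- sampling_areas(meshes$recon, config$sampling_diameter_mm)
  analysis <- feit_analyze(recon$sigma_series, meshes$recon, config$fcm, regions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_protocol(protocol, file.path(out_dir, "protocol.csv"))
    write_frames(run$frames, file.path(out_dir, "frames.csv"))
    readr::write_csv(dplyr::rename(run$truth, element_index = "element"),
                     file.path(out_dir, "truth_masks.csv"))
    write_sigma_series(recon$sigma_series, file.path(out_dir, "conductivity.csv"))
    readr::write_csv(recon$fits, file.path(out_dir, "residual_log.csv"))
    write_membership(analysis$classification, file.path(out_dir, "membership.csv"))
    readr::write_csv(analysis$metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(analysis$t_s, file.path(out_dir, "saturation_times.csv"))
    write_manifest(config, out_dir, stage = "run-all")
  }
  list(run = run, recon = recon, analysis = analysis, meshes = meshes,
       protocol = protocol)
}

#' Conductivity / membership series CSV writers and readers
#'
#' `conductivity.csv`: `time_s, element_index, sigma_S_per_m`;
#' `membership.csv`: `frame_time_s, element_index, u2`.
#'
#' @param sigma_series Tibble `time_s`, `element`, `sigma_S_per_m`.
#' @param path CSV path.
#' @return `path` invisibly; readers return tibbles with the internal column
#'   names.
#' @export
write_sigma_series <- function(sigma_series, path) {
  readr::write_csv(dplyr::rename(sigma_series, element_index = "element"), path)
  invisible(path)
}

#' @rdname write_sigma_series
#' @export
read_sigma_series <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::rename(x, element = "element_index")
}

#' @rdname write_sigma_series
#' @param classification A `feit_classification`.
#' @export
write_membership <- function(classification, path) {
  out <- dplyr::rename(tidy(classification),
                       frame_time_s = "time_s", element_index = "element")
  readr::write_csv(out, path)
  invisible(path)
}

write_manifest <- function(config, out_dir, stage) {
  cfg <- unclass(config)
  cfg$recon <- unclass(cfg$recon)
  cfg$fcm <- unclass(cfg$fcm)
  manifest <- list(
    stage = stage,
    config = cfg,
    config_hash = rlang::hash(cfg),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("feit"))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}

#' Plot aeration series
#'
#' @param metrics Long tibble `quantity`, `time_s`, `value` (e.g. from
#'   [feit_analyze()]).
#' @param quantities Which quantities to draw.
#' @return A `ggplot` object.
#' @export
plot_aeration_series <- function(metrics,
                                 quantities = c("u2_all", "u2_area1", "u2_area2")) {
  df <- dplyr::filter(metrics, .data$quantity %in% quantities)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time [s]", y = "<u2> [-]", colour = NULL) +
    ggplot2::theme_minimal()
}
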