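#' Rasterize a two-phase phantom onto a mesh
#'
#' Builds a per-element conductivity image from a background value and a set
#' of circular inclusions (air bubbles): an element takes the inclusion
#' conductivity when its centroid falls inside any inclusion circle
#' (overlaps form a union), otherwise the background. Bubble conductivity
#' defaults to the solver floor of 1e-6 S/m rather than the physical ~1e-15
#' S/m of air: the 1e-1 vs 1e-6 contrast is already far beyond reconstruction
#' resolution and keeps the forward system well conditioned.
#'
#' @param mesh An `eit_mesh`.
#' @param inclusions Tibble/data.frame with columns `x_mm`, `y_mm`,
#'   `radius_mm` and optionally `sigma_S_per_m`; may have zero rows.
#' @param background_sigma Background (O/W phase) conductivity, S/m.
#' @param inclusion_sigma Default inclusion conductivity, S/m, used where the
#'   `sigma_S_per_m` column is absent.
#' @return List with `sigma` (per-element, S/m) and `mask` (logical,
#'   TRUE for bubble elements).
#' @export
rasterize_phantom <- function(mesh, inclusions,
                              background_sigma = 0.1,
                              inclusion_sigma = 1e-6) {
  if (is.null(inclusions) || nrow(inclusions) == 0) {
    return(list(sigma = rep(background_sigma, n_elements(mesh)),
                mask = rep(FALSE, n_elements(mesh))))
  }
  stopifnot(all(c("x_mm", "y_mm", "radius_mm") %in% names(inclusions)))
  dist_c <- sqrt(inclusions$x_mm^2 + inclusions$y_mm^2)
  if (any(dist_c + inclusions$radius_mm > mesh$radius_mm + 1e-9)) {
    stop("Inclusion extends outside the vessel disk.", call. = FALSE)
  }
  inc_sigma <- if ("sigma_S_per_m" %in% names(inclusions)) {
    inclusions$sigma_S_per_m
  } else {
    rep(inclusion_sigma, nrow(inclusions))
  }
  sigma <- rep(background_sigma, n_elements(mesh))
  mask <- rep(FALSE, n_elements(mesh))
  cx <- mesh$elements$cx_mm; cy <- mesh$elements$cy_mm
  for (r in seq_len(nrow(inclusions))) {
    inside <- (cx - inclusions$x_mm[r])^2 + (cy - inclusions$y_mm[r])^2 <=
      inclusions$radius_mm[r]^2
    sigma[inside] <- inc_sigma[r]
    mask <- mask | inside
  }
  list(sigma = sigma, mask = mask)
}

#' Programmed bubble-fraction profile of an agitation run
#'
#' Emulates the three-stage aeration narrative of whipping: no air before
#' agitation, a monotone rise of air holdup to the critical saturation point,
#' then a monotone fall as bubbles are expelled. The rise is linear: 0 at the
#' first frame and exactly `max_fraction` at `peak_frame`. By default the
#' descent steps through the midpoints of the rise grid (`max - (k - 1/2) *
#' rise_step`, clamped at 0), so every frame of the run carries a distinct,
#' equally spaced air fraction — which keeps rank-based comparisons between
#' recovered and programmed aeration well-defined. Passing `end_fraction`
#' replaces the descent by a straight line down to that value at the last
#' frame.
#'
#' @param n_frames Number of frames (>= 2).
#' @param peak_frame 1-based frame index of the programmed saturation point.
#' @param max_fraction Peak bubble area fraction in `(0, 0.9]`.
#' @param end_fraction Optional fraction at the final frame; `NULL` (default)
#'   selects the midpoint-interleaved descent.
#' @return Numeric vector of per-frame target area fractions.
#' @examples
#' make_agitation_profile(10, peak_frame = 6, max_fraction = 0.45)
#' @export
make_agitation_profile <- function(n_frames, peak_frame, max_fraction = 0.45,
                                   end_fraction = NULL) {
  stopifnot(n_frames >= 2)
  if (max_fraction <= 0 || max_fraction > 0.9) {
    stop("`max_fraction` must lie in (0, 0.9].", call. = FALSE)
  }
  if (peak_frame < 1 || peak_frame > n_frames) {
    stop("`peak_frame` must lie within 1..n_frames.", call. = FALSE)
  }
  up <- seq(0, max_fraction, length.out = peak_frame)
  n_down <- n_frames - peak_frame
  down <- if (n_down == 0) {
    numeric(0)
  } else if (is.null(end_fraction)) {
    step <- if (peak_frame > 1) max_fraction / (peak_frame - 1) else max_fraction / 2
    pmax(max_fraction - (seq_len(n_down) - 0.5) * step, 0)
  } else {
    stopifnot(end_fraction >= 0, end_fraction <= max_fraction)
    seq(max_fraction, end_fraction, length.out = n_down + 1L)[-1L]
  }
  c(up, down)
}

## Deterministic per-frame sub-seed from the run seed (kept below 2^31).
frame_subseed <- function(seed, frame) {
  (as.numeric(seed) %% 1e6) * 1000 + 7919 * frame %% 2147483647
}

#' Sample non-overlapping circular bubbles to a target area fraction
#'
#' Rejection-samples circles fully inside the disk, mutually non-overlapping,
#' with radii uniform in `radius_range_mm`, until their total area reaches the
#' requested fraction of the disk area; the final bubble is shrunk to land on
#' the target. Deterministic for a fixed seed.
#'
#' @param radius_mm Disk radius, mm.
#' @param fraction Target bubble area fraction in `[0, 0.9]`.
#' @param radius_range_mm Bubble radius band, mm (default 3-8: the phantom
#'   mimics mesoscale bulk dispersion, not microscopic bubbles).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling attempt bound.
#' @return Tibble `x_mm`, `y_mm`, `radius_mm` (possibly zero rows).
#' @export
sample_bubbles <- function(radius_mm, fraction, radius_range_mm = c(3, 8),
                           seed = 1L, max_attempts = 10000L) {
  stopifnot(fraction >= 0, fraction <= 0.9)
  set.seed(seed)
  disk_area <- pi * radius_mm^2
  target <- fraction * disk_area
  placed <- tibble::tibble(x_mm = numeric(0), y_mm = numeric(0), radius_mm = numeric(0))
  total <- 0
  attempts <- 0L
  min_keep <- 0.5 # mm: below this remaining radius the target is met
  while (target - total > pi * min_keep^2) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("Could not reach bubble fraction ", fraction,
           " within ", max_attempts, " placement attempts.", call. = FALSE)
    }
    r <- stats::runif(1, radius_range_mm[1], radius_range_mm[2])
    r <- min(r, sqrt((target - total) / pi)) # shrink last bubble onto the target
    if (r < min_keep) r <- sqrt((target - total) / pi)
    rc <- (radius_mm - r) * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    x <- rc * cos(th); y <- rc * sin(th)
    if (nrow(placed) > 0) {
      d <- sqrt((placed$x_mm - x)^2 + (placed$y_mm - y)^2)
      if (any(d < placed$radius_mm + r)) next
    }
    placed <- dplyr::bind_rows(placed, tibble::tibble(x_mm = x, y_mm = y, radius_mm = r))
    total <- total + pi * r^2
  }
  placed
}

#' Simulate a full synthetic agitation run
#'
#' Generates the virtual counterpart of an agitation experiment: for each
#' frame, bubbles are sampled to the programmed area fraction, rasterized on
#' the (fine) simulation mesh, the forward problem is solved for every
#' protocol pattern, and zero-mean Gaussian noise with standard deviation
#' `noise_rel * |V|` per pattern is added. One run seed deterministically
#' derives per-frame sub-seeds, so the whole series is reproducible.
#'
#' @param mesh Simulation `eit_mesh` (use a finer mesh than the one you
#'   reconstruct on, to avoid the inverse crime).
#' @param protocol An `eit_protocol`.
#' @param profile Per-frame bubble area fractions (e.g.
#'   [make_agitation_profile()]).
#' @param frame_times_s Time stamps, strictly increasing, same length.
#' @param noise_rel Relative noise amplitude (0 disables noise).
#' @param seed Run seed (integer).
#' @param background_sigma,bubble_sigma Phase conductivities, S/m.
#' @param radius_range_mm Bubble radius band, mm.
#' @param max_attempts Placement attempt bound per frame.
#' @return List of class `feit_run`: `frames` (tibble `time_s`, `pattern`,
#'   `voltage_V`), `truth` (tibble `time_s`, `element`, `is_bubble`),
#'   `true_fraction` (tibble `time_s`, `fraction_target`,
#'   `fraction_realized`), `bubbles` (per-frame circle specs), and the
#'   generating parameters.
#' @export
simulate_agitation_run <- function(mesh, protocol, profile, frame_times_s,
                                   noise_rel = 0.01, seed = 1L,
                                   background_sigma = 0.1, bubble_sigma = 1e-6,
                                   radius_range_mm = c(3, 8),
                                   max_attempts = 10000L) {
  stopifnot(length(profile) == length(frame_times_s), all(diff(frame_times_s) > 0),
            all(profile >= 0), all(profile <= 0.9))
  areas <- mesh$elements$area_mm2
  frames <- vector("list", length(profile))
  truth <- vector("list", length(profile))
  bubbles <- vector("list", length(profile))
  realized <- numeric(length(profile))
  for (fr in seq_along(profile)) {
    ss <- frame_subseed(seed, fr)
    bub <- sample_bubbles(mesh$radius_mm, profile[fr], radius_range_mm,
                          seed = ss, max_attempts = max_attempts)
    ph <- rasterize_phantom(mesh, bub, background_sigma, bubble_sigma)
    v <- simulate_frame(mesh, ph$sigma, protocol)$voltage_V
    if (noise_rel > 0) {
      set.seed(ss + 1)
      v <- v + stats::rnorm(length(v), 0, noise_rel * abs(v))
    }
    frames[[fr]] <- tibble::tibble(time_s = frame_times_s[fr],
                                   pattern = protocol$pattern, voltage_V = v)
    truth[[fr]] <- tibble::tibble(time_s = frame_times_s[fr],
                                  element = mesh$elements$element,
                                  is_bubble = ph$mask)
    bubbles[[fr]] <- dplyr::mutate(bub, time_s = frame_times_s[fr], .before = 1)
    realized[fr] <- sum(areas[ph$mask]) / sum(areas)
  }
  structure(
    list(
      frames = dplyr::bind_rows(frames),
      truth = dplyr::bind_rows(truth),
      true_fraction = tibble::tibble(time_s = frame_times_s,
                                     fraction_target = profile,
                                     fraction_realized = realized),
      bubbles = dplyr::bind_rows(bubbles),
      seed = seed, noise_rel = noise_rel,
      background_sigma = background_sigma, bubble_sigma = bubble_sigma,
      radius_range_mm = radius_range_mm
    ),
    class = "feit_run"
  )
}

#' @export
print.feit_run <- function(x, ...) {
  cat(sprintf(
    "<feit_run> %d frames, %d patterns/frame, noise %.2g%%, seed %d\n",
    nrow(x$true_fraction), length(unique(x$frames$pattern)),
    100 * x$noise_rel, x$seed
  ))
  invisible(x)
}
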