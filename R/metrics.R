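#' Area-weighted spatial mean membership
#'
#' Computes the spatial mean of a per-element membership (or any per-element
#' field) weighted by element area,
#' `<u2> = sum_i u2_i A_i / sum_i A_i`, over all elements or over a circular
#' sampling region.
#'
#' @param u2 Per-element values (memberships in `[0,1]` for aeration use).
#' @param element_areas Per-element areas, mm^2.
#' @param mask Optional `region_mask` (or integer element indices) restricting
#'   the mean to a sampling area.
#' @return Scalar weighted mean.
#' @examples
#' spatial_mean_membership(c(0, 1), c(1, 3)) # 0.75
#' @export
spatial_mean_membership <- function(u2, element_areas, mask = NULL) {
  stopifnot(length(u2) == length(element_areas))
  if (!is.null(mask)) {
    idx <- if (inherits(mask, "region_mask")) mask$element_indices else as.integer(mask)
    if (length(idx) == 0) stop("Empty region mask.", call. = FALSE)
    u2 <- u2[idx]; element_areas <- element_areas[idx]
  }
  tot <- sum(element_areas)
  if (tot <= 0) stop("Total element area is zero.", call. = FALSE)
  sum(u2 * element_areas) / tot
}

#' Aeration time series from a classification
#'
#' Reduces per-frame membership images to the three aeration series: the
#' area-weighted mean air-bubble membership over the whole sensor area
#' (`u2_all`) and over the two circular sampling areas (`u2_area1` at the
#' center, `u2_area2` near the wall at electrode 1).
#'
#' @param classification A `feit_classification`.
#' @param mesh The reconstruction `eit_mesh` the memberships live on.
#' @param regions Optional named list of `region_mask` objects; defaults to
#'   [sampling_areas()] of the mesh.
#' @return Long tibble: `time_s`, `quantity` (`u2_all`, `u2_area1`, ...),
#'   `value`.
#' @export
membership_series <- function(classification, mesh, regions = sampling_areas(mesh)) {
  areas <- mesh$elements$area_mm2
  per_frame <- function(u2_frame) {
    vals <- c(
      u2_all = spatial_mean_membership(u2_frame, areas),
      purrr::map_dbl(regions, ~ spatial_mean_membership(u2_frame, areas, .x))
    )
    names(vals) <- c("u2_all", paste0("u2_", names(regions)))
    tibble::enframe(vals, name = "quantity")
  }
  tidy(classification) |>
    dplyr::arrange(.data$time_s, .data$element) |>
    dplyr::group_by(.data$time_s) |>
    dplyr::group_modify(~ per_frame(.x$u2)) |>
    dplyr::ungroup()
}

#' Saturation (peak) time of a series
#'
#' Returns the time at which a series attains its maximum — for the mean
#' air-bubble membership this is the critical saturation point of air-bubble
#' incorporation during agitation. Ties break toward the earliest time
#' (first attainment of saturation).
#'
#' @param times Strictly increasing time stamps.
#' @param values Series values, same length, finite.
#' @return Tibble with one row: `t_s`, `peak`.
#' @examples
#' peak_time(0:3, c(0, 1, 3, 2)) # t_s = 2, peak = 3
#' @export
peak_time <- function(times, values) {
  if (length(times) < 2) stop("Need at least two time points.", call. = FALSE)
  stopifnot(length(times) == length(values), all(is.finite(values)),
            all(diff(times) > 0))
  i <- which.max(values) # which.max already takes the first maximum
  tibble::tibble(t_s = times[i], peak = values[i])
}

#' Overrun from masses at fixed volume
#'
#' `OR = (m0 - m_nt) / m_nt * 100` [%], where `m0` is the sample mass before
#' agitation and `m_nt` the mass of the same volume after agitation; air
#' incorporation lowers the density, so larger overrun means more air holdup.
#'
#' @param m0_g Mass before agitation, g.
#' @param mnt_g Mass after agitation (fixed volume), g.
#' @return Overrun in percent (vectorized).
#' @examples
#' overrun(20, 10) # 100
#' @export
overrun <- function(m0_g, mnt_g) {
  if (any(mnt_g <= 0) || any(m0_g <= 0)) {
    stop("Masses must be positive.", call. = FALSE)
  }
  (m0_g - mnt_g) / mnt_g * 100
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min(x)) / (max(x) - min(x))`: the series minimum maps to 0 and the
#' maximum to 1. Being a monotone affine map, it preserves the argmax, so the
#' saturation time of a normalized series equals that of the raw series.
#'
#' @param x Numeric vector with at least two points and `max > min`.
#' @return Normalized vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6)) # 0, 0.5, 1
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2) stop("Need at least two points.", call. = FALSE)
  r <- range(x)
  if (r[1] == r[2]) stop("Constant series: zero range, cannot normalize.", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Air-bubble area ratio of a microscopy field
#'
#' `S_ratio = S_air / S_all`, the fraction of the imaged field occupied by air
#' bubbles (both areas in the same units, e.g. um^2; a 1777.6 um square field
#' has `S_all = 1777.6^2 = 3159861.76 um^2`).
#'
#' @param s_air_um2 Segmented bubble area.
#' @param s_all_um2 Total field area, > 0.
#' @return Dimensionless ratio in `[0, 1]`.
#' @export
area_ratio <- function(s_air_um2, s_all_um2) {
  if (any(s_all_um2 <= 0)) stop("`s_all_um2` must be positive.", call. = FALSE)
  if (any(s_air_um2 < 0) || any(s_air_um2 > s_all_um2)) {
    stop("`s_air_um2` must lie in [0, s_all_um2].", call. = FALSE)
  }
  s_air_um2 / s_all_um2
}

#' Absolute deviation across replicates
#'
#' Mean absolute deviation from the replicate mean, the spread statistic used
#' for the error bars of replicated aeration series.
#'
#' @param x Numeric replicate values.
#' @return Scalar `mean(|x - mean(x)|)`.
#' @export
abs_deviation <- function(x) mean(abs(x - mean(x)))
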