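#' Fuzzy c-means configuration (two clusters)
#'
#' @param h Fuzziness exponent, must be > 1 (2 is the canonical choice; the
#'   membership update uses the exponent `2/(h-1)` and is undefined at 1).
#' @param tolerance Relative change of the loss below which iteration stops.
#' @param max_iterations Iteration cap.
#' @param centroid_init `"extremes"` (deterministic: pooled minimum and
#'   maximum) or `"provided"`.
#' @param centroids Optional length-2 start centroids for `"provided"`.
#' @return A list of class `fcm_config`.
#' @export
fcm_config <- function(h = 2, tolerance = 1e-8, max_iterations = 500L,
                       centroid_init = c("extremes", "provided"),
                       centroids = NULL) {
  centroid_init <- match.arg(centroid_init)
  if (h <= 1) stop("`h` must be > 1 (the membership exponent 2/(h-1) is undefined at 1).",
                   call. = FALSE)
  stopifnot(tolerance > 0, max_iterations >= 1)
  if (centroid_init == "provided" && (is.null(centroids) || length(centroids) != 2)) {
    stop("centroid_init = 'provided' needs two `centroids`.", call. = FALSE)
  }
  structure(list(h = h, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 centroid_init = centroid_init, centroids = centroids),
            class = "fcm_config")
}

#' Membership update for fixed centroids
#'
#' Evaluates the fuzzy membership of each value in each of the two clusters
#' from the distance-ratio rule
#' `u_j = 1 / sum_l (|x - mu_j| / |x - mu_l|)^(2/(h-1))`.
#' A value exactly equal to a centroid takes membership 1 in that cluster
#' (0.5 each if both centroids coincide with it).
#'
#' @param values Numeric vector (conductivities, S/m).
#' @param centroids Length-2 numeric centroids.
#' @param h Fuzziness exponent > 1.
#' @return A length(values) x 2 matrix of memberships; rows sum to 1.
#' @examples
#' fcm_memberships(0.4, c(0.1, 0.5), h = 2) # 0.1, 0.9
#' @export
fcm_memberships <- function(values, centroids, h = 2) {
  stopifnot(length(centroids) == 2, h > 1)
  d1 <- abs(values - centroids[1])
  d2 <- abs(values - centroids[2])
  e <- 2 / (h - 1)
  u1 <- 1 / (1 + (d1 / d2)^e)
  u2 <- 1 / (1 + (d2 / d1)^e)
  # singularity rule: exact coincidence with a centroid
  both <- d1 == 0 & d2 == 0
  u1[d1 == 0] <- 1; u2[d1 == 0] <- 0
  u2[d2 == 0] <- 1; u1[d2 == 0] <- 0
  u1[both] <- 0.5; u2[both] <- 0.5
  cbind(u1, u2, deparse.level = 0)
}

#' Two-cluster fuzzy c-means on scalar values
#'
#' Alternates the membership-weighted centroid update
#' `mu_j = sum_i u_ji^h x_i / sum_i u_ji^h` with the distance-ratio
#' membership update until the loss
#' `zeta = sum_j sum_i u_ji^h |x_i - mu_j|^2` changes by less than
#' `tolerance` (relative) or `max_iterations` is reached. With the default
#' deterministic extremes initialization (centroid 1 at the pooled maximum,
#' centroid 2 at the pooled minimum) the whole procedure is seed-free.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param config An [fcm_config()].
#' @return List of class `fcm_fit`: `centroids` (length 2), `memberships`
#'   (n x 2 matrix), `loss_history`, `iterations`, `h`.
#' @export
fcm_two_cluster <- function(values, config = fcm_config()) {
  stopifnot(inherits(config, "fcm_config"))
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("`values` must be finite.", call. = FALSE)
  if (length(unique(values)) < 2) {
    stop("All values identical: the two clusters are indistinguishable.", call. = FALSE)
  }
  mu <- switch(config$centroid_init,
    extremes = c(max(values), min(values)),
    provided = as.numeric(config$centroids)
  )
  h <- config$h
  loss_hist <- numeric(0)
  u <- fcm_memberships(values, mu, h)
  for (k in seq_len(config$max_iterations)) {
    uh <- u^h
    mu <- c(sum(uh[, 1] * values) / sum(uh[, 1]),
            sum(uh[, 2] * values) / sum(uh[, 2]))
    u <- fcm_memberships(values, mu, h)
    uh <- u^h
    loss <- sum(uh[, 1] * (values - mu[1])^2) + sum(uh[, 2] * (values - mu[2])^2)
    loss_hist <- c(loss_hist, loss)
    if (k > 1) {
      prev <- loss_hist[k - 1]
      if (abs(prev - loss) / max(prev, .Machine$double.eps) < config$tolerance) break
    }
  }
  structure(list(centroids = mu, memberships = u,
                 loss_history = loss_hist, iterations = length(loss_hist), h = h),
            class = "fcm_fit")
}

#' Classify a conductivity run into O/W and air-bubble memberships
#'
#' Pools the conductivity values of all frames of a run into a single
#' two-cluster fuzzy c-means problem (preserving the temporal dimension of the
#' resulting mean membership), then maps the *lower* centroid to the
#' air-bubble cluster — the O/W emulsion phase conducts at roughly 1e-1 S/m
#' while air is practically non-conducting — and reshapes the memberships back
#' into per-frame element images.
#'
#' @param sigma_series Long tibble with columns `time_s`, `element`,
#'   `sigma_S_per_m` (one row per element per frame).
#' @param config An [fcm_config()].
#' @return Object of class `feit_classification`: list with `memberships`
#'   (tibble `time_s`, `element`, `u2`), `centroids` (named: `ow`, `air`),
#'   `loss_history`, `iterations`, `h`.
#' @export
classify_run <- function(sigma_series, config = fcm_config()) {
  need <- c("time_s", "element", "sigma_S_per_m")
  stopifnot(is.data.frame(sigma_series), all(need %in% names(sigma_series)))
  df <- dplyr::arrange(sigma_series, .data$time_s, .data$element)
  fit <- fcm_two_cluster(df$sigma_S_per_m, config)
  air_col <- which.min(fit$centroids) # air bubble = low-conductivity cluster
  out <- tibble::tibble(
    time_s = df$time_s,
    element = df$element,
    u2 = fit$memberships[, air_col]
  )
  structure(
    list(memberships = out,
         centroids = c(ow = max(fit$centroids), air = min(fit$centroids)),
         loss_history = fit$loss_history, iterations = fit$iterations, h = fit$h),
    class = "feit_classification"
  )
}

#' @export
print.feit_classification <- function(x, ...) {
  cat(sprintf(
    "<feit_classification> %d frames, centroids ow = %.4g, air = %.4g S/m, %d iterations\n",
    length(unique(x$memberships$time_s)), x$centroids["ow"], x$centroids["air"],
    x$iterations
  ))
  invisible(x)
}

#' Tidy per-frame air-bubble memberships
#' @param x A `feit_classification`.
#' @param ... Unused.
#' @return Tibble `time_s`, `element`, `u2`.
#' @method tidy feit_classification
#' @export
tidy.feit_classification <- function(x, ...) x$memberships

#' One-row classification summary
#' @param x A `feit_classification`.
#' @param ... Unused.
#' @return Tibble with centroids, iteration count and final loss.
#' @method glance feit_classification
#' @export
glance.feit_classification <- function(x, ...) {
  tibble::tibble(
    centroid_ow_S_per_m = unname(x$centroids["ow"]),
    centroid_air_S_per_m = unname(x$centroids["air"]),
    iterations = x$iterations,
    loss_final = x$loss_history[length(x$loss_history)],
    h = x$h
  )
}

#' Plot an air-bubble membership image
#'
#' Renders `u2` with the two-phase display convention: O/W phase black
#' (`u2 = 0`), air bubbles white (`u2 = 1`).
#'
#' @param mesh The `eit_mesh`.
#' @param u2 Per-element membership values in `[0, 1]`.
#' @return A `ggplot` object.
#' @export
plot_membership <- function(mesh, u2) {
  plot_element_image(mesh, u2, name = "u2 [-]") +
    ggplot2::scale_fill_gradient(name = "u2 [-]", low = "black", high = "white",
                                 limits = c(0, 1))
}
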