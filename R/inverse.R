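#' Reconstruction configuration
#'
#' Bundles the Gauss-Newton solver settings. The defaults are the package's
#' working defaults for absolute conductivity reconstruction: up to
#' `max_iterations` updates, stopping when the voltage-residual norm changes
#' by less than `tolerance` (relative), Tikhonov regularization with the
#' identity matrix, and a positivity floor applied after each step.
#'
#' @param max_iterations Maximum Gauss-Newton iterations (default 20).
#' @param tolerance Relative change of the residual norm below which the
#'   iteration stops (default 1e-3).
#' @param lambda_grid Candidate regularization weights, interpreted relative
#'   to `mean(diag(J'J))` so the grid is resolution-independent; ascending.
#' @param lambda_mode `"l_curve"` (select by maximum L-curve curvature, once
#'   at the first iteration) or `"fixed"` (use `lambda_fixed`).
#' @param lambda_fixed Relative lambda used when `lambda_mode = "fixed"`.
#' @param reselect_lambda Re-run the L-curve selection at every iteration
#'   instead of holding the first choice (default FALSE).
#' @param sigma_floor Lower clamp for conductivity, S/m (default 1e-6).
#' @param lambda_abs Optional absolute regularization weight; when set it
#'   bypasses both the grid and the scaling (used e.g. to share one lambda
#'   across the frames of a run).
#' @param initial_mode `"homogeneous_fit"` (scalar best-fit start) or
#'   `"provided"` (use `initial_sigma`).
#' @param initial_sigma Optional starting image for `initial_mode = "provided"`.
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(max_iterations = 20L,
                         tolerance = 1e-3,
                         lambda_grid = 10^seq(-6, 2, by = 0.5),
                         lambda_mode = c("l_curve", "fixed"),
                         lambda_fixed = 1e-2,
                         reselect_lambda = FALSE,
                         sigma_floor = 1e-6,
                         lambda_abs = NULL,
                         initial_mode = c("homogeneous_fit", "provided"),
                         initial_sigma = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  initial_mode <- match.arg(initial_mode)
  stopifnot(tolerance > 0, sigma_floor > 0, max_iterations >= 1,
            all(lambda_grid > 0), lambda_fixed > 0)
  structure(
    list(max_iterations = as.integer(max_iterations), tolerance = tolerance,
         lambda_grid = sort(lambda_grid), lambda_mode = lambda_mode,
         lambda_fixed = lambda_fixed, reselect_lambda = reselect_lambda,
         sigma_floor = sigma_floor, lambda_abs = lambda_abs,
         initial_mode = initial_mode,
         initial_sigma = initial_sigma),
    class = "recon_config"
  )
}

#' Best-fit homogeneous conductivity
#'
#' Scale-matches a measured frame to the forward model: because the forward
#' voltages of a homogeneous image scale as `1/sigma`, a single reference
#' solve gives the closed form
#' `sigma0 = sigma_ref * (V_ref . V_exp) / (V_exp . V_exp)`.
#' Used as the absolute-scale initial condition of the reconstruction, which
#' keeps the reconstructed image in physical units of S/m.
#'
#' @param voltages Measured N-vector of four-terminal voltages (volts), or a
#'   frame tibble with a `voltage_V` column ordered by pattern.
#' @param mesh An `eit_mesh` (reconstruction mesh).
#' @param protocol An `eit_protocol`.
#' @param sigma_ref Reference conductivity for the single solve, S/m.
#' @return Scalar conductivity, S/m.
#' @export
fit_homogeneous <- function(voltages, mesh, protocol, sigma_ref = 0.1) {
  v_exp <- frame_voltages(voltages, protocol)
  if (all(v_exp == 0)) stop("Measured frame is identically zero.", call. = FALSE)
  v_ref <- simulate_frame(mesh, rep(sigma_ref, n_elements(mesh)), protocol)$voltage_V
  sigma_ref * sum(v_ref * v_exp) / sum(v_exp * v_exp)
}

#' L-curve selection of the regularization weight
#'
#' For each candidate `lambda` solves the Tikhonov-regularized linear step
#' `(J'J + lambda I) d = J' dV`, records the point
#' `(log ||J d - dV||, log ||d||)`, and returns the candidate at the point of
#' maximum discrete (Menger) curvature of that curve — the L-curve corner.
#' Ties break toward the smaller `lambda`; a singleton grid is returned as-is
#' with a warning.
#'
#' @param jacobian N x M sensitivity matrix.
#' @param delta_v Residual voltage N-vector.
#' @param lambda_grid Ascending positive candidates (absolute values here).
#' @param fallback Weight (same absolute units) used when the curve shows no
#'   convex corner (all discrete curvatures non-positive), which happens when
#'   the data can be fitted to numerical precision; defaults to the geometric
#'   middle of the grid.
#' @return Selected `lambda` with attribute `lcurve` (tibble of the curve).
#' @export
select_lambda_lcurve <- function(jacobian, delta_v, lambda_grid,
                                 fallback = exp(mean(log(range(lambda_grid))))) {
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid > 0))
  lambda_grid <- sort(lambda_grid)
  if (length(lambda_grid) == 1L) {
    warning("Single-candidate lambda grid; returning it without selection.")
    return(lambda_grid)
  }
  sv <- svd(jacobian)
  pts <- purrr::map_dfr(lambda_grid, function(l) {
    d <- tikhonov_step(sv, delta_v, l)
    tibble::tibble(lambda = l,
                   log_rho = log(sqrt(sum((jacobian %*% d - delta_v)^2))),
                   log_eta = log(sqrt(sum(d^2))))
  })
  ## Below the smallest resolvable singular value the curve degenerates into a
  ## cluster of coincident points whose Menger curvature is spurious; keep only
  ## points separated by >= 2% of the curve's bounding-box diagonal.
  span <- sqrt(diff(range(pts$log_rho))^2 + diff(range(pts$log_eta))^2)
  keep <- rep(FALSE, nrow(pts))
  last <- c(Inf, Inf)
  for (i in rev(seq_len(nrow(pts)))) { # walk from large lambda down
    d <- sqrt((pts$log_rho[i] - last[1])^2 + (pts$log_eta[i] - last[2])^2)
    if (!is.finite(last[1]) || d >= 0.02 * span) {
      keep[i] <- TRUE
      last <- c(pts$log_rho[i], pts$log_eta[i])
    }
  }
  sub <- which(keep)
  kappa_sub <- menger_curvature(pts$log_rho[sub], pts$log_eta[sub])
  kappa <- rep(-Inf, nrow(pts))
  kappa[sub] <- kappa_sub
  if (any(kappa > 0)) {
    # interior points only; ties -> smaller lambda
    best <- which.max(round(kappa, 12))
    out <- lambda_grid[best]
  } else {
    ## No convex corner: the data is fittable to numerical precision and the
    ## L-curve carries no noise-floor information. Fall back to the candidate
    ## nearest the `fallback` weight rather than an arbitrary curve point.
    best <- which.min(abs(log(lambda_grid) - log(fallback)))
    out <- lambda_grid[best]
  }
  attr(out, "lcurve") <- dplyr::mutate(pts, curvature = kappa, kept = keep)
  out
}

## Tikhonov-regularized normal-equation step (J'J + lambda I)^(-1) J' dv,
## evaluated through the SVD of J: d = V diag(s / (s^2 + lambda)) U' dv.
## Algebraically identical to the dense solve but stable for any lambda >= 0.
tikhonov_step <- function(sv, delta_v, lambda) {
  f <- sv$d / (sv$d^2 + lambda)
  as.numeric(sv$v %*% (f * crossprod(sv$u, delta_v)))
}

## Signed Menger curvature at each interior point of a planar polyline;
## endpoints get -Inf so they are never selected.
menger_curvature <- function(x, y) {
  n <- length(x)
  k <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    x1 <- x[i - 1]; x2 <- x[i]; x3 <- x[i + 1]
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    num <- 2 * ((x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1))
    den <- sqrt(((x2 - x1)^2 + (y2 - y1)^2) *
                ((x3 - x2)^2 + (y3 - y2)^2) *
                ((x3 - x1)^2 + (y3 - y1)^2))
    k_i <- if (den == 0) -Inf else num / den
    k[i] <- if (is.finite(k_i)) k_i else -Inf
  }
  k
}

#' Non-linear absolute conductivity reconstruction
#'
#' Gauss-Newton iteration for the absolute conductivity image: starting from
#' the homogeneous best-fit (or a provided image), each step recomputes the
#' sensitivity matrix `J` at the current image and applies the regularized
#' update `sigma <- sigma + (J'J + lambda I)^(-1) J' (V_exp - V_sim)`,
#' clamping at `sigma_floor`. Iteration stops when the residual norm changes
#' by less than `tolerance` (relative) or after `max_iterations`. If the
#' residual grows for three consecutive iterations the run is flagged
#' divergent and the best iterate is returned.
#'
#' @inheritParams fit_homogeneous
#' @param config A [recon_config()].
#' @return An object of class `eit_recon`: list with `sigma` (element-wise
#'   conductivity, S/m), `residual_history`, `lambda_used` (absolute value),
#'   `iterations_run`, `diverged`, `sigma0`, `mesh_ref`.
#' @examples
#' mesh <- build_disk_mesh(42, 8, target_edge_mm = 10)
#' prot <- adjacent_protocol(8)
#' v <- simulate_frame(mesh, rep(0.1, n_elements(mesh)), prot)$voltage_V
#' rec <- gauss_newton_reconstruct(v, mesh, prot,
#'                                 config = recon_config(max_iterations = 3))
#' @export
gauss_newton_reconstruct <- function(voltages, mesh, protocol,
                                     config = recon_config()) {
  stopifnot(inherits(config, "recon_config"))
  v_exp <- frame_voltages(voltages, protocol)
  M <- n_elements(mesh)

  sigma <- switch(config$initial_mode,
    homogeneous_fit = rep(max(fit_homogeneous(v_exp, mesh, protocol), config$sigma_floor), M),
    provided = {
      if (is.null(config$initial_sigma)) {
        stop("initial_mode = 'provided' needs `initial_sigma`.", call. = FALSE)
      }
      pmax(rep_len(config$initial_sigma, M), config$sigma_floor)
    }
  )
  sigma0 <- sigma[1]

  lambda_abs <- NA_real_
  res_hist <- numeric(0)
  best <- list(sigma = sigma, res = Inf)
  n_grow <- 0L
  diverged <- FALSE
  iterations <- 0L

  for (k in seq_len(config$max_iterations)) {
    v_sim <- simulate_frame(mesh, sigma, protocol)$voltage_V
    dv <- v_exp - v_sim
    res <- sqrt(sum(dv^2))
    res_hist <- c(res_hist, res)
    if (res < best$res) best <- list(sigma = sigma, res = res)
    if (res <= 1e-12 * sqrt(sum(v_exp^2))) break # data already fit to roundoff
    if (k > 1) {
      prev <- res_hist[k - 1]
      if (abs(prev - res) / max(prev, .Machine$double.eps) < config$tolerance) break
      if (res > prev) n_grow <- n_grow + 1L else n_grow <- 0L
      if (n_grow >= 3L) { diverged <- TRUE; break }
    }
    J <- compute_jacobian(mesh, sigma, protocol)
    scale <- mean(colSums(J^2)) # mean(diag(J'J)); resolution-independent lambda unit
    if (!is.null(config$lambda_abs)) {
      lambda_abs <- config$lambda_abs
    } else if (config$lambda_mode == "fixed") {
      lambda_abs <- config$lambda_fixed * scale
    } else if (is.na(lambda_abs) || config$reselect_lambda) {
      lambda_abs <- as.numeric(select_lambda_lcurve(
        J, dv, config$lambda_grid * scale, fallback = config$lambda_fixed * scale))
    }
    step <- tikhonov_step(svd(J), dv, lambda_abs)
    sigma <- pmax(sigma + step, config$sigma_floor)
    iterations <- k
  }
  ## final residual (after the last accepted update)
  if (iterations == length(res_hist)) {
    v_sim <- simulate_frame(mesh, sigma, protocol)$voltage_V
    res <- sqrt(sum((v_exp - v_sim)^2))
    res_hist <- c(res_hist, res)
    if (res < best$res) best <- list(sigma = sigma, res = res)
  }
  if (diverged || res_hist[length(res_hist)] > res_hist[1]) {
    diverged <- diverged || res_hist[length(res_hist)] > res_hist[1]
    sigma <- best$sigma
  }

  structure(
    list(sigma = sigma, residual_history = res_hist,
         lambda_used = lambda_abs, iterations_run = iterations,
         diverged = diverged, sigma0 = sigma0,
         mesh_ref = paste0("eit_mesh_M", M)),
    class = "eit_recon"
  )
}

#' Regularization weight a frame would select at its first iteration
#'
#' Runs the start of the Gauss-Newton procedure (homogeneous fit, one Jacobian)
#' and returns the absolute L-curve lambda for the first linearized step.
#' Used to share a single run-level lambda across frames (e.g. the median over
#' frames), which keeps the reconstructed contrast comparable between frames.
#'
#' @inheritParams gauss_newton_reconstruct
#' @return Absolute lambda (scalar).
#' @export
first_iteration_lambda <- function(voltages, mesh, protocol,
                                   config = recon_config()) {
  v_exp <- frame_voltages(voltages, protocol)
  M <- n_elements(mesh)
  sigma <- rep(max(fit_homogeneous(v_exp, mesh, protocol), config$sigma_floor), M)
  dv <- v_exp - simulate_frame(mesh, sigma, protocol)$voltage_V
  J <- compute_jacobian(mesh, sigma, protocol)
  scale <- mean(colSums(J^2))
  as.numeric(select_lambda_lcurve(J, dv, config$lambda_grid * scale,
                                  fallback = config$lambda_fixed * scale))
}

frame_voltages <- function(voltages, protocol) {
  if (is.data.frame(voltages)) {
    stopifnot("voltage_V" %in% names(voltages))
    voltages <- if ("pattern" %in% names(voltages)) {
      voltages$voltage_V[order(voltages$pattern)]
    } else {
      voltages$voltage_V
    }
  }
  if (length(voltages) != nrow(protocol)) {
    stop("Frame has ", length(voltages), " voltages but the protocol defines ",
         nrow(protocol), " patterns.", call. = FALSE)
  }
  if (any(!is.finite(voltages))) stop("Frame contains non-finite voltages.", call. = FALSE)
  as.numeric(voltages)
}

#' @export
print.eit_recon <- function(x, ...) {
  cat(sprintf(
    "<eit_recon> %d elements, %d iterations, lambda %.3g, residual %.3g -> %.3g%s\n",
    length(x$sigma), x$iterations_run, x$lambda_used,
    x$residual_history[1], x$residual_history[length(x$residual_history)],
    if (x$diverged) " [DIVERGED]" else ""
  ))
  invisible(x)
}

#' Tidy a reconstruction into a per-element tibble
#' @param x An `eit_recon`.
#' @param ... Unused.
#' @return Tibble with `element`, `sigma_S_per_m`.
#' @method tidy eit_recon
#' @export
tidy.eit_recon <- function(x, ...) {
  tibble::tibble(element = seq_along(x$sigma), sigma_S_per_m = x$sigma)
}

#' One-row summary of a reconstruction
#' @param x An `eit_recon`.
#' @param ... Unused.
#' @return Tibble with lambda, iteration count, residuals and divergence flag.
#' @method glance eit_recon
#' @export
glance.eit_recon <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda_used,
    iterations = x$iterations_run,
    residual_initial = x$residual_history[1],
    residual_final = x$residual_history[length(x$residual_history)],
    diverged = x$diverged,
    sigma0_S_per_m = x$sigma0
  )
}

#' Plot a conductivity image on its mesh
#'
#' @param mesh The `eit_mesh` the values live on.
#' @param values Per-element values (e.g. `sigma` in S/m or membership u2).
#' @param name Legend title.
#' @param limits Optional colour limits.
#' @return A `ggplot` object (equal-coordinate filled triangles, electrode 1
#'   at the reference angle marked).
#' @export
plot_element_image <- function(mesh, values, name = "sigma [S/m]", limits = NULL) {
  poly <- mesh_polygons(mesh, values)
  th <- mesh$reference_angle_deg * pi / 180
  mark <- tibble::tibble(x_mm = 1.05 * mesh$radius_mm * cos(th),
                         y_mm = 1.05 * mesh$radius_mm * sin(th))
  ggplot2::ggplot(poly, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                     group = .data$element, fill = .data$value)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::geom_point(data = mark, ggplot2::aes(group = NULL, fill = NULL),
                        shape = 17, size = 2) +
    ggplot2::scale_fill_viridis_c(name = name, limits = limits) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]") +
    ggplot2::theme_minimal()
}

#' @method autoplot eit_recon
#' @export
autoplot.eit_recon <- function(object, mesh, ...) {
  plot_element_image(mesh, object$sigma, name = "sigma [S/m]")
}
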