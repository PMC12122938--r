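#' Build a triangulated disk mesh with boundary electrodes
#'
#' Constructs a structured polar triangulation of a circular vessel
#' cross-section, places `n_electrodes` equally spaced electrode arcs on the
#' boundary, and precomputes the element geometry (areas, centroids, linear
#' shape-function gradients) needed by the forward solver.
#'
#' The vessel is modelled as a 2-D cross-section at electrode height; element
#' conductivities are per-unit-depth equivalents in S/m. Electrode 1 is
#' centered at `reference_angle_deg` (default 90, the +y "top" of the plot)
#' and electrodes are numbered counter-clockwise at a pitch of
#' `360 / n_electrodes` degrees. The angular node count is rounded to a
#' multiple of `n_electrodes` so the mesh is exactly symmetric under rotation
#' by one electrode pitch.
#'
#' @param radius_mm Disk radius in mm (e.g. 42 for an 84 mm vessel).
#' @param n_electrodes Number of boundary electrodes (>= 4).
#' @param electrode_arc_deg Angular coverage of each electrode arc in degrees;
#'   must be positive and smaller than the electrode pitch.
#' @param target_edge_mm Target element edge length in mm; controls resolution.
#' @param reference_angle_deg Angle (degrees, counter-clockwise from +x) of the
#'   center of electrode 1.
#'
#' @return An object of class `eit_mesh`: a list with tibbles `nodes`
#'   (`node`, `x_mm`, `y_mm`), `elements` (`element`, `n1`, `n2`, `n3`,
#'   `area_mm2`, `cx_mm`, `cy_mm`), `boundary_edges` and `electrodes`
#'   (electrode index, edge node pairs, arc lengths), plus scalar metadata.
#' @examples
#' mesh <- build_disk_mesh(radius_mm = 42, n_electrodes = 8)
#' sum(mesh$elements$area_mm2) / (pi * 42^2)
#' @export
build_disk_mesh <- function(radius_mm,
                            n_electrodes = 8L,
                            electrode_arc_deg = 10,
                            target_edge_mm = 6,
                            reference_angle_deg = 90) {
  if (!is.numeric(radius_mm) || radius_mm <= 0) {
    stop("`radius_mm` must be a positive number.", call. = FALSE)
  }
  if (n_electrodes < 4) {
    stop("`n_electrodes` must be at least 4.", call. = FALSE)
  }
  pitch <- 360 / n_electrodes
  if (electrode_arc_deg <= 0 || electrode_arc_deg >= pitch) {
    stop("`electrode_arc_deg` must lie in (0, 360/n_electrodes).", call. = FALSE)
  }
  if (target_edge_mm <= 0) {
    stop("`target_edge_mm` must be positive.", call. = FALSE)
  }

  ## Angular resolution: near-target boundary spacing, rounded up to a multiple
  ## of n_electrodes (exact discrete rotational symmetry), and fine enough that
  ## every electrode arc holds at least one full boundary edge.
  n_theta <- ceiling(2 * pi * radius_mm / target_edge_mm / n_electrodes) * n_electrodes
  n_theta <- max(n_theta, 5L * n_electrodes)
  while (360 / n_theta >= electrode_arc_deg) n_theta <- n_theta + n_electrodes
  n_rings <- max(2L, round(radius_mm / target_edge_mm))

  theta0 <- reference_angle_deg * pi / 180
  ang <- theta0 + 2 * pi * (seq_len(n_theta) - 1L) / n_theta

  ## Nodes: center + concentric rings, all rings share the angular grid.
  ring_r <- radius_mm * seq_len(n_rings) / n_rings
  x <- c(0, as.vector(outer(cos(ang), ring_r)))
  y <- c(0, as.vector(outer(sin(ang), ring_r)))
  ring_start <- function(i) 1L + (i - 1L) * n_theta # first node index of ring i, minus 1
  idx <- function(i, k) ring_start(i) + ((k - 1L) %% n_theta) + 1L

  ## Center fan + quad strips between consecutive rings, each quad split
  ## along a consistent diagonal.
  k <- seq_len(n_theta)
  tri <- matrix(0L, nrow = n_theta + 2L * n_theta * (n_rings - 1L), ncol = 3L)
  tri[k, ] <- cbind(1L, idx(1L, k), idx(1L, k + 1L))
  row <- n_theta
  if (n_rings >= 2L) {
    for (i in seq_len(n_rings - 1L)) {
      a <- idx(i, k); b <- idx(i, k + 1L)
      c_ <- idx(i + 1L, k); d <- idx(i + 1L, k + 1L)
      tri[row + k, ] <- cbind(a, c_, d)
      tri[row + n_theta + k, ] <- cbind(a, d, b)
      row <- row + 2L * n_theta
    }
  }

  x1 <- x[tri[, 1]]; y1 <- y[tri[, 1]]
  x2 <- x[tri[, 2]]; y2 <- y[tri[, 2]]
  x3 <- x[tri[, 3]]; y3 <- y[tri[, 3]]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  stopifnot(all(area > 0))

  nodes <- tibble::tibble(node = seq_along(x), x_mm = x, y_mm = y)
  elements <- tibble::tibble(
    element = seq_len(nrow(tri)),
    n1 = tri[, 1], n2 = tri[, 2], n3 = tri[, 3],
    area_mm2 = area,
    cx_mm = (x1 + x2 + x3) / 3,
    cy_mm = (y1 + y2 + y3) / 3
  )

  ## Boundary edges: consecutive outer-ring nodes, ordered counter-clockwise.
  bn <- idx(n_rings, k)
  bn_next <- idx(n_rings, k + 1L)
  mid_ang <- (ang + pi / n_theta) * 180 / pi
  edge_len <- sqrt((x[bn_next] - x[bn])^2 + (y[bn_next] - y[bn])^2)
  boundary_edges <- tibble::tibble(
    edge = k, n1 = bn, n2 = bn_next,
    mid_angle_deg = mid_ang %% 360,
    length_mm = edge_len
  )

  ## Electrode arcs: an edge belongs to electrode e when its midpoint angle is
  ## within arc/2 of the electrode center (shortest angular distance).
  centers <- (reference_angle_deg + pitch * (seq_len(n_electrodes) - 1L)) %% 360
  ang_dist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  electrodes <- purrr::map_dfr(seq_len(n_electrodes), function(e) {
    on_arc <- ang_dist(boundary_edges$mid_angle_deg, centers[e]) < electrode_arc_deg / 2
    dplyr::mutate(boundary_edges[on_arc, ], electrode = e, .before = 1)
  })
  stopifnot(all(table(factor(electrodes$electrode, levels = seq_len(n_electrodes))) >= 1),
            !anyDuplicated(electrodes$edge))

  structure(
    list(
      nodes = nodes,
      elements = elements,
      boundary_edges = boundary_edges,
      electrodes = electrodes[, c("electrode", "edge", "n1", "n2", "length_mm")],
      radius_mm = radius_mm,
      n_electrodes = as.integer(n_electrodes),
      electrode_arc_deg = electrode_arc_deg,
      reference_angle_deg = reference_angle_deg,
      n_theta = as.integer(n_theta),
      n_rings = as.integer(n_rings)
    ),
    class = "eit_mesh"
  )
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf(
    "<eit_mesh> radius %g mm, %d nodes, %d elements, %d electrodes (arc %g deg)\n",
    x$radius_mm, nrow(x$nodes), nrow(x$elements), x$n_electrodes, x$electrode_arc_deg
  ))
  invisible(x)
}

#' Number of elements in a mesh
#' @param mesh An `eit_mesh`.
#' @return Integer element count.
#' @export
n_elements <- function(mesh) nrow(mesh$elements)

#' Select mesh elements inside a circular sampling region
#'
#' Returns the elements whose centroid lies inside the given circle, the
#' geometry used for the regional mean memberships of the two sampling areas
#' (center of the vessel, and near the wall at electrode 1).
#'
#' @param mesh An `eit_mesh`.
#' @param center_mm Numeric length-2, circle center (x, y) in mm.
#' @param diameter_mm Circle diameter in mm.
#' @return A list of class `region_mask` with `element_indices`, `center_mm`,
#'   `diameter_mm` and the summed element area `area_mm2`.
#' @examples
#' mesh <- build_disk_mesh(42, 8)
#' area1 <- circular_region_mask(mesh, c(0, 0), 20)
#' @export
circular_region_mask <- function(mesh, center_mm, diameter_mm) {
  stopifnot(inherits(mesh, "eit_mesh"), length(center_mm) == 2)
  if (diameter_mm <= 0) stop("`diameter_mm` must be positive.", call. = FALSE)
  d2 <- (mesh$elements$cx_mm - center_mm[1])^2 + (mesh$elements$cy_mm - center_mm[2])^2
  inside <- which(d2 <= (diameter_mm / 2)^2)
  if (length(inside) == 0) {
    stop("Sampling circle contains no element centroids (empty mask).", call. = FALSE)
  }
  structure(
    list(
      element_indices = inside,
      center_mm = as.numeric(center_mm),
      diameter_mm = diameter_mm,
      area_mm2 = sum(mesh$elements$area_mm2[inside])
    ),
    class = "region_mask"
  )
}

#' Standard sampling areas on the vessel cross-section
#'
#' Builds the two circular sampling regions used for regional aeration
#' summaries: area 1 at the vessel center, and area 2 near the wall on the
#' electrode-1 radius, tangent to the wall
#' (center at `radius - diameter/2` from the origin).
#'
#' @param mesh An `eit_mesh`.
#' @param diameter_mm Sampling-circle diameter in mm (default 20).
#' @return Named list of two `region_mask` objects (`area1`, `area2`).
#' @export
sampling_areas <- function(mesh, diameter_mm = 20) {
  th <- mesh$reference_angle_deg * pi / 180
  r2 <- mesh$radius_mm - diameter_mm / 2
  list(
    area1 = circular_region_mask(mesh, c(0, 0), diameter_mm),
    area2 = circular_region_mask(mesh, r2 * c(cos(th), sin(th)), diameter_mm)
  )
}

#' Export / import a mesh as plain tabular files
#'
#' Writes three CSV files into `dir`: `nodes.csv` (`node,x_mm,y_mm`),
#' `elements.csv` (`element,n1,n2,n3`) and `electrodes.csv`
#' (`electrode,n1,n2`, one row per electrode boundary edge).
#'
#' @param mesh An `eit_mesh`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mesh <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(mesh$nodes, file.path(dir, "nodes.csv"))
  readr::write_csv(mesh$elements[, c("element", "n1", "n2", "n3")],
                   file.path(dir, "elements.csv"))
  readr::write_csv(mesh$electrodes[, c("electrode", "n1", "n2")],
                   file.path(dir, "electrodes.csv"))
  invisible(dir)
}

#' @rdname write_mesh
#' @param radius_mm Disk radius of the stored mesh, mm.
#' @export
read_mesh <- function(dir, radius_mm) {
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"), show_col_types = FALSE)
  tri <- as.matrix(readr::read_csv(file.path(dir, "elements.csv"),
                                   show_col_types = FALSE)[, c("n1", "n2", "n3")])
  elec <- readr::read_csv(file.path(dir, "electrodes.csv"), show_col_types = FALSE)
  x <- nodes$x_mm; y <- nodes$y_mm
  x1 <- x[tri[, 1]]; y1 <- y[tri[, 1]]
  x2 <- x[tri[, 2]]; y2 <- y[tri[, 2]]
  x3 <- x[tri[, 3]]; y3 <- y[tri[, 3]]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  elec$length_mm <- sqrt((x[elec$n2] - x[elec$n1])^2 + (y[elec$n2] - y[elec$n1])^2)
  elec$edge <- seq_len(nrow(elec))
  structure(
    list(
      nodes = nodes,
      elements = tibble::tibble(
        element = seq_len(nrow(tri)),
        n1 = tri[, 1], n2 = tri[, 2], n3 = tri[, 3],
        area_mm2 = area,
        cx_mm = (x1 + x2 + x3) / 3, cy_mm = (y1 + y2 + y3) / 3
      ),
      boundary_edges = NULL,
      electrodes = elec[, c("electrode", "edge", "n1", "n2", "length_mm")],
      radius_mm = radius_mm,
      n_electrodes = length(unique(elec$electrode)),
      electrode_arc_deg = NA_real_,
      reference_angle_deg = NA_real_
    ),
    class = "eit_mesh"
  )
}

#' Plot a mesh (elements, electrodes)
#'
#' @param object An `eit_mesh`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot eit_mesh
#' @export
autoplot.eit_mesh <- function(object, ...) {
  poly <- mesh_polygons(object)
  elec_nodes <- unique(c(object$electrodes$n1, object$electrodes$n2))
  en <- object$nodes[elec_nodes, ]
  ggplot2::ggplot(poly, ggplot2::aes(x = .data$x_mm, y = .data$y_mm, group = .data$element)) +
    ggplot2::geom_polygon(fill = "grey95", colour = "grey60", linewidth = 0.2) +
    ggplot2::geom_point(data = en, ggplot2::aes(group = NULL), colour = "red3", size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]") +
    ggplot2::theme_minimal()
}

## Long table of element corner coordinates for ggplot polygons.
mesh_polygons <- function(mesh, values = NULL) {
  el <- mesh$elements
  long <- tibble::tibble(
    element = rep(el$element, each = 3L),
    node = as.vector(t(as.matrix(el[, c("n1", "n2", "n3")])))
  )
  long$x_mm <- mesh$nodes$x_mm[long$node]
  long$y_mm <- mesh$nodes$y_mm[long$node]
  if (!is.null(values)) long$value <- rep(values, each = 3L)
  long
}
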