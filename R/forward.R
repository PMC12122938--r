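#' @importFrom Matrix sparseMatrix solve t
NULL

## ---- internal FEM machinery -------------------------------------------------
## Piecewise-linear potentials on triangles, piecewise-constant conductivity.
## All geometry is in mm; the 2-D stiffness integral is scale-free in length,
## so no unit conversion is needed. Currents are converted mA -> A.

## Per-element shape-function gradient coefficients:
## grad(phi) = (1/(2A)) * [b; c] %*% u_nodes, with b,c the usual P1 coefficients.
mesh_gradients <- function(mesh) {
  el <- mesh$elements
  x <- mesh$nodes$x_mm; y <- mesh$nodes$y_mm
  x1 <- x[el$n1]; x2 <- x[el$n2]; x3 <- x[el$n3]
  y1 <- y[el$n1]; y2 <- y[el$n2]; y3 <- y[el$n3]
  twoA <- 2 * el$area_mm2
  list(
    bx = cbind(y2 - y3, y3 - y1, y1 - y2) / twoA,  # d(shape)/dx, M x 3
    by = cbind(x3 - x2, x1 - x3, x2 - x1) / twoA,  # d(shape)/dy, M x 3
    nidx = cbind(el$n1, el$n2, el$n3),
    area = el$area_mm2
  )
}

## Sparse stiffness matrix K(sigma) with one extra row/col enforcing the
## zero-mean potential gauge (Lagrange multiplier).
assemble_system <- function(mesh, sigma, grads = mesh_gradients(mesh)) {
  M <- nrow(grads$nidx)
  nn <- nrow(mesh$nodes)
  ii <- jj <- vector("list", 9L)
  vv <- vector("list", 9L)
  p <- 0L
  for (a in 1:3) {
    for (b in 1:3) {
      p <- p + 1L
      ii[[p]] <- grads$nidx[, a]
      jj[[p]] <- grads$nidx[, b]
      vv[[p]] <- sigma * grads$area *
        (grads$bx[, a] * grads$bx[, b] + grads$by[, a] * grads$by[, b])
    }
  }
  i <- unlist(ii); j <- unlist(jj); v <- unlist(vv)
  # gauge row/column: mean potential = 0
  i <- c(i, rep(nn + 1L, nn), seq_len(nn))
  j <- c(j, seq_len(nn), rep(nn + 1L, nn))
  v <- c(v, rep(1, 2L * nn))
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(nn + 1L, nn + 1L))
}

## Nodal current-injection weights for one electrode under the gap model:
## uniform current density I/S over the electrode arc, integrated against the
## linear boundary shape functions (each edge of length l contributes l/2 to
## both end nodes). Weights sum to 1; multiply by the signed current in A.
electrode_weights <- function(mesh, electrode) {
  ed <- mesh$electrodes[mesh$electrodes$electrode == electrode, ]
  if (nrow(ed) == 0) stop("Electrode ", electrode, " has no boundary edges.", call. = FALSE)
  w <- numeric(nrow(mesh$nodes))
  half <- ed$length_mm / 2
  for (r in seq_len(nrow(ed))) {
    w[ed$n1[r]] <- w[ed$n1[r]] + half[r]
    w[ed$n2[r]] <- w[ed$n2[r]] + half[r]
  }
  w / sum(ed$length_mm)
}

## All n_e electrode weight vectors as a dense (n_nodes x n_e) matrix.
electrode_weight_matrix <- function(mesh) {
  vapply(seq_len(mesh$n_electrodes), function(e) electrode_weights(mesh, e),
         numeric(nrow(mesh$nodes)))
}

## Solve for the potentials of all adjacent drive pairs (e, e+1) at current
## `current_A`; returns an (n_nodes x n_e) matrix, one column per pair.
solve_adjacent_pairs <- function(mesh, sigma, current_A,
                                 grads = mesh_gradients(mesh),
                                 W = electrode_weight_matrix(mesh)) {
  ne <- mesh$n_electrodes
  nn <- nrow(mesh$nodes)
  A <- assemble_system(mesh, sigma, grads)
  B <- matrix(0, nn + 1L, ne)
  nxt <- c(seq_len(ne)[-1L], 1L)
  B[seq_len(nn), ] <- current_A * (W - W[, nxt])
  phi <- as.matrix(Matrix::solve(A, B))
  phi[seq_len(nn), , drop = FALSE]
}

## ---- exported operations ----------------------------------------------------

#' Solve the conduction forward problem for one drive pair
#'
#' Solves the quasi-static equation `div(sigma grad phi) = 0` on the mesh with
#' Neumann boundary conditions: uniform injected current density `I/S` over
#' the positive drive electrode arc, `-I/S` over the negative one, and zero
#' flux on the wall (gap electrode model, no contact impedance). The potential
#' gauge is fixed by a zero-mean constraint.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element conductivity vector, S/m (all > 0).
#' @param drive_pair Integer length-2: (positive, negative) electrode indices.
#' @param current_mA Injected current in mA.
#' @return Numeric vector of nodal potentials (volts), zero mean.
#' @export
solve_potential <- function(mesh, sigma, drive_pair, current_mA = 0.1) {
  check_sigma(mesh, sigma)
  nn <- nrow(mesh$nodes)
  A <- assemble_system(mesh, sigma)
  b <- numeric(nn + 1L)
  b[seq_len(nn)] <- (current_mA * 1e-3) *
    (electrode_weights(mesh, drive_pair[1]) - electrode_weights(mesh, drive_pair[2]))
  phi <- as.numeric(Matrix::solve(A, b))
  phi[seq_len(nn)]
}

#' Simulate a four-terminal voltage frame
#'
#' Runs the forward solver for every drive pattern of the protocol and
#' extracts the four-terminal voltage of each measurement pair. The electrode
#' voltage is the current-weighted mean of its nodal potentials (the same
#' boundary weights as the gap-model current injection), which makes the
#' discrete model exactly reciprocal.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element conductivity, S/m.
#' @param protocol An `eit_protocol` (adjacent pairs).
#' @param time_s Optional acquisition time stamp to attach (seconds).
#' @return A tibble with columns `pattern`, `voltage_V` (and `time_s` when
#'   given), one row per protocol pattern.
#' @examples
#' mesh <- build_disk_mesh(42, 8, target_edge_mm = 9)
#' prot <- adjacent_protocol(8)
#' frame <- simulate_frame(mesh, rep(0.1, n_elements(mesh)), prot)
#' @export
simulate_frame <- function(mesh, sigma, protocol, time_s = NULL) {
  check_sigma(mesh, sigma)
  current_A <- protocol_current_mA(protocol) * 1e-3
  W <- electrode_weight_matrix(mesh)
  phi <- solve_adjacent_pairs(mesh, sigma, current_A, W = W)
  v <- extract_voltages(mesh, phi, protocol, W)
  out <- tibble::tibble(pattern = protocol$pattern, voltage_V = v)
  if (!is.null(time_s)) out <- dplyr::mutate(out, time_s = time_s, .before = 1)
  out
}

## Four-terminal voltages for all patterns given the adjacent-pair potential
## columns. Assumes adjacent drive and measurement pairs (pair index = its
## first electrode).
extract_voltages <- function(mesh, phi, protocol, W = electrode_weight_matrix(mesh)) {
  elec_phi <- crossprod(W, phi) # (n_e x n_e): electrode voltage per pair solve
  vapply(seq_len(nrow(protocol)), function(r) {
    d <- protocol$drive_pos[r]
    elec_phi[protocol$meas_pos[r], d] - elec_phi[protocol$meas_neg[r], d]
  }, numeric(1))
}

#' Adjoint sensitivity (Jacobian) matrix
#'
#' Computes the N x M sensitivity matrix `dV_n / d sigma_i` at the given
#' conductivity by the adjoint formula
#' `-(1/I) * integral over element i of grad(V_drive) . grad(V_meas)`,
#' where both potentials are the forward solutions of the corresponding
#' adjacent electrode pairs carrying the protocol current. With piecewise
#' linear potentials and piecewise constant conductivity the element integral
#' is exact, and the result equals the exact derivative of the discrete
#' forward map.
#'
#' @inheritParams simulate_frame
#' @return Dense numeric matrix, `n_patterns x n_elements`, with attribute
#'   `sigma` recording the linearization point.
#' @export
compute_jacobian <- function(mesh, sigma, protocol) {
  check_sigma(mesh, sigma)
  current_A <- protocol_current_mA(protocol) * 1e-3
  grads <- mesh_gradients(mesh)
  W <- electrode_weight_matrix(mesh)
  phi <- solve_adjacent_pairs(mesh, sigma, current_A, grads, W)
  ## per-element constant gradients of each pair solve: (M x n_e)
  gx <- grads$bx[, 1] * phi[grads$nidx[, 1], ] +
        grads$bx[, 2] * phi[grads$nidx[, 2], ] +
        grads$bx[, 3] * phi[grads$nidx[, 3], ]
  gy <- grads$by[, 1] * phi[grads$nidx[, 1], ] +
        grads$by[, 2] * phi[grads$nidx[, 2], ] +
        grads$by[, 3] * phi[grads$nidx[, 3], ]
  J <- matrix(0, nrow(protocol), length(sigma))
  for (r in seq_len(nrow(protocol))) {
    d <- protocol$drive_pos[r]
    m <- protocol$meas_pos[r]
    J[r, ] <- -(1 / current_A) * grads$area *
      (gx[, d] * gx[, m] + gy[, d] * gy[, m])
  }
  attr(J, "sigma") <- sigma
  J
}

check_sigma <- function(mesh, sigma) {
  if (length(sigma) != n_elements(mesh)) {
    stop("`sigma` must have one value per mesh element (", n_elements(mesh), ").",
         call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("All conductivities must be finite and > 0 (use a sigma floor for voids).",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read voltage frames as long-format CSV
#'
#' Columns: `time_s, pattern_index, voltage_V`.
#'
#' @param frames Tibble with columns `time_s`, `pattern`, `voltage_V`.
#' @param path CSV path.
#' @return `path` invisibly; `read_frames()` returns the tibble.
#' @export
write_frames <- function(frames, path) {
  out <- dplyr::select(frames, time_s = "time_s", pattern_index = "pattern",
                       voltage_V = "voltage_V")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "pattern_index", "voltage_V")
  if (!all(need %in% names(x))) {
    stop("Frames CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$voltage_V))) {
    bad <- which(!is.finite(x$voltage_V))[1]
    stop("Non-finite voltage in frames CSV at row ", bad, ".", call. = FALSE)
  }
  dplyr::rename(x, pattern = "pattern_index")
}
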