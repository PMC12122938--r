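test_that("homogeneous fit recovers the exact scalar and obeys the scaling law", {
  m <- coarse_mesh
  v <- simulate_frame(m, homog_sigma(m, 0.1), std_protocol)$voltage_V
  expect_equal(fit_homogeneous(v, m, std_protocol), 0.1, tolerance = 1e-6)
  expect_equal(fit_homogeneous(2 * v, m, std_protocol), 0.05, tolerance = 1e-6)
  expect_error(fit_homogeneous(rep(0, 40), m, std_protocol), "zero")
})

test_that("homogeneous fit stays within 2% under 1% measurement noise", {
  m <- coarse_mesh
  v <- simulate_frame(m, homog_sigma(m, 0.1), std_protocol)$voltage_V
  set.seed(101)
  errs <- replicate(50, {
    vn <- v + stats::rnorm(length(v), 0, 0.01 * abs(v))
    abs(fit_homogeneous(vn, m, std_protocol) - 0.1) / 0.1
  })
  expect_lt(max(errs), 0.02)
})

test_that("Tikhonov step equals the dense ridge normal-equation solution", {
  set.seed(3)
  J <- matrix(rnorm(40 * 120), 40, 120) * 1e-3
  dv <- rnorm(40) * 1e-4
  for (lam in c(1e-8, 1e-5, 1e-2)) {
    brute <- solve(crossprod(J) + diag(lam, 120), crossprod(J, dv))
    fast <- feit:::tikhonov_step(svd(J), dv, lam)
    expect_equal(fast, as.numeric(brute), tolerance = 1e-8)
  }
})

test_that("L-curve diagnostics are monotone and the corner is selected", {
  m <- coarse_mesh
  sig <- homog_sigma(m)
  v <- simulate_frame(m, sig, std_protocol)$voltage_V
  set.seed(11)
  vn <- v + stats::rnorm(length(v), 0, 0.01 * abs(v))
  J <- compute_jacobian(m, sig, std_protocol)
  grid <- mean(colSums(J^2)) * 10^seq(-6, 2, 0.5)
  lam <- select_lambda_lcurve(J, vn - v, grid)
  lc <- attr(lam, "lcurve")
  # Tikhonov monotonicity: residual non-decreasing, solution norm non-increasing
  expect_true(all(diff(lc$log_rho) >= -1e-12))
  expect_true(all(diff(lc$log_eta) <= 1e-12))
  # noisy data: selected lambda is an interior grid point, not an endpoint
  expect_gt(as.numeric(lam), min(grid))
  expect_lt(as.numeric(lam), max(grid))
  expect_warning(got <- select_lambda_lcurve(J, vn - v, 1e-3), "Single")
  expect_equal(as.numeric(got), 1e-3)
})

test_that("Gauss-Newton recovers noiseless homogeneous data within 1% per element", {
  m <- coarse_mesh
  v <- simulate_frame(m, homog_sigma(m, 0.1), std_protocol)$voltage_V
  rec <- gauss_newton_reconstruct(v, m, std_protocol, recon_config())
  expect_lt(max(abs(rec$sigma - 0.1) / 0.1), 0.01)
  expect_false(rec$diverged)
  hist <- rec$residual_history
  expect_lte(hist[length(hist)], hist[1])
})

test_that("reconstruction is absolute: 10x conductivity gives a 10x image", {
  m <- coarse_mesh
  v1 <- simulate_frame(fine_mesh, homog_sigma(fine_mesh, 0.1), std_protocol)$voltage_V
  v2 <- simulate_frame(fine_mesh, homog_sigma(fine_mesh, 1.0), std_protocol)$voltage_V
  r1 <- gauss_newton_reconstruct(v1, m, std_protocol, recon_config())
  r2 <- gauss_newton_reconstruct(v2, m, std_protocol, recon_config())
  expect_equal(r2$sigma / r1$sigma, rep(10, n_elements(m)), tolerance = 0.05)
})

test_that("a low-conductivity inclusion reconstructs below background (2x margin)", {
  # simulate on the finer mesh, reconstruct on the coarse one (no inverse crime)
  ph <- rasterize_phantom(fine_mesh,
                          data.frame(x_mm = 0, y_mm = 20, radius_mm = 10),
                          background_sigma = 0.1, inclusion_sigma = 1e-4)
  v <- simulate_frame(fine_mesh, ph$sigma, std_protocol)$voltage_V
  rec <- gauss_newton_reconstruct(v, coarse_mesh, std_protocol, recon_config())
  inside <- (coarse_mesh$elements$cx_mm - 0)^2 +
            (coarse_mesh$elements$cy_mm - 20)^2 <= 10^2
  expect_gt(mean(rec$sigma[!inside]) / mean(rec$sigma[inside]), 2)
  hist <- rec$residual_history
  expect_lte(hist[length(hist)], hist[1])
})

test_that("reconstruction is deterministic and tidy/glance expose the fit", {
  ph <- rasterize_phantom(fine_mesh,
                          data.frame(x_mm = -15, y_mm = 5, radius_mm = 8),
                          inclusion_sigma = 1e-3)
  v <- simulate_frame(fine_mesh, ph$sigma, std_protocol)$voltage_V
  r1 <- gauss_newton_reconstruct(v, coarse_mesh, std_protocol, recon_config())
  r2 <- gauss_newton_reconstruct(v, coarse_mesh, std_protocol, recon_config())
  expect_identical(r1$residual_history, r2$residual_history)
  expect_identical(r1$sigma, r2$sigma)
  td <- tidy(r1)
  expect_named(td, c("element", "sigma_S_per_m"))
  expect_equal(nrow(td), n_elements(coarse_mesh))
  gl <- glance(r1)
  expect_equal(gl$lambda, r1$lambda_used)
  expect_false(gl$diverged)
})

test_that("four-terminal voltages are gauge-independent", {
  # grounded-node gauge: replace the zero-mean row by pinning node 1
  m <- coarse_mesh
  sig <- homog_sigma(m)
  nn <- nrow(m$nodes)
  A <- feit:::assemble_system(m, sig)
  K <- A[seq_len(nn), seq_len(nn)]
  W <- feit:::electrode_weight_matrix(m)
  I_A <- 1e-4
  v_ref <- simulate_frame(m, sig, std_protocol)$voltage_V
  Kg <- K
  Kg[1, ] <- 0; Kg[, 1] <- 0; Kg[1, 1] <- 1
  v_ground <- vapply(seq_len(nrow(std_protocol)), function(r) {
    b <- I_A * (W[, std_protocol$drive_pos[r]] - W[, std_protocol$drive_neg[r]])
    b[1] <- 0
    phi <- as.numeric(Matrix::solve(Kg, b))
    sum(W[, std_protocol$meas_pos[r]] * phi) - sum(W[, std_protocol$meas_neg[r]] * phi)
  }, numeric(1))
  expect_equal(v_ground, v_ref, tolerance = 1e-10)
})
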