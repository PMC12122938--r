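test_that("membership update reproduces the hand-worked distance-ratio case", {
  # sigma = 0.4 between centroids {0.1, 0.5} at h = 2:
  # u1 = 1 / (1 + (0.3/0.1)^2) = 0.1, u2 = 0.9
  u <- fcm_memberships(0.4, c(0.1, 0.5), h = 2)
  expect_equal(u[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(u[1, 2], 0.9, tolerance = 1e-12)
  # midway between centroids -> 0.5/0.5
  u_mid <- fcm_memberships(0.3, c(0.1, 0.5), h = 2)
  expect_equal(as.numeric(u_mid), c(0.5, 0.5), tolerance = 1e-12)
  # exact coincidence with a centroid -> hard assignment (singularity rule)
  u_hit <- fcm_memberships(c(0.1, 0.5), c(0.1, 0.5), h = 2)
  expect_equal(u_hit, cbind(c(1, 0), c(0, 1)), tolerance = 0)
})

test_that("two-cluster FCM separates well-split values and converges", {
  fit <- fcm_two_cluster(c(0.1, 0.1, 1e-5, 1e-5), fcm_config(h = 2))
  expect_equal(sort(fit$centroids), c(1e-5, 0.1), tolerance = 1e-6)
  own <- pmax(fit$memberships[, 1], fit$memberships[, 2])
  expect_true(all(own >= 0.999))
  # loss non-increasing, memberships normalized
  expect_true(all(diff(fit$loss_history) <= 1e-15))
  expect_equal(rowSums(fit$memberships), rep(1, 4), tolerance = 1e-12)
  expect_error(fcm_two_cluster(rep(0.1, 5)), "identical")
})

test_that("FCM matches an independent hand-coded oracle on random data", {
  # brute-force alternating iteration written out from scratch
  fcm_oracle <- function(x, h, iters = 200) {
    mu <- c(max(x), min(x))
    u <- NULL
    for (k in seq_len(iters)) {
      d1 <- abs(x - mu[1]); d2 <- abs(x - mu[2])
      e <- 2 / (h - 1)
      u1 <- ifelse(d1 == 0, 1, ifelse(d2 == 0, 0, 1 / (1 + (d1 / d2)^e)))
      u <- cbind(u1, 1 - u1)
      mu <- c(sum(u[, 1]^h * x) / sum(u[, 1]^h),
              sum(u[, 2]^h * x) / sum(u[, 2]^h))
    }
    list(mu = mu, u = u)
  }
  set.seed(5)
  x <- c(rnorm(30, 0.1, 0.01), rnorm(20, 0.01, 0.003))
  for (h in c(1.5, 2, 3)) {
    fit <- fcm_two_cluster(x, fcm_config(h = h, tolerance = 1e-14,
                                         max_iterations = 400))
    ora <- fcm_oracle(x, h)
    expect_equal(fit$centroids, ora$mu, tolerance = 1e-6)
    expect_equal(unname(fit$memberships), unname(ora$u), tolerance = 1e-5)
  }
})

test_that("h near 1 approaches the nearest-centroid hard assignment", {
  set.seed(8)
  x <- c(runif(40, 0.05, 0.12), runif(40, 0.001, 0.02))
  fit <- fcm_two_cluster(x, fcm_config(h = 1.05))
  nearest <- as.integer(abs(x - fit$centroids[1]) > abs(x - fit$centroids[2])) + 1L
  hard <- apply(fit$memberships, 1, which.max)
  expect_equal(hard, nearest)
  # values clearly nearer one centroid are assigned almost hard; points close
  # to equidistance legitimately keep graded memberships
  own <- pmax(fit$memberships[, 1], fit$memberships[, 2])
  expect_gt(mean(own > 0.99), 0.9)
})

test_that("fuzziness must exceed 1 (the update exponent is undefined at h = 1)", {
  expect_error(fcm_config(h = 1), "h")
  expect_error(fcm_config(h = 0.5), "h")
})

test_that("classify_run pools frames and maps the low centroid to air", {
  m <- coarse_mesh
  M <- n_elements(m)
  series <- dplyr::bind_rows(
    tibble::tibble(time_s = 0, element = 1:M, sigma_S_per_m = 0.1),
    tibble::tibble(time_s = 60, element = 1:M, sigma_S_per_m = 0.01)
  )
  # tiny jitter so the pooled values are not two exact points
  set.seed(2)
  series$sigma_S_per_m <- series$sigma_S_per_m * exp(rnorm(2 * M, 0, 0.01))
  cls <- classify_run(series)
  td <- tidy(cls)
  u_frame1 <- td$u2[td$time_s == 0]
  u_frame2 <- td$u2[td$time_s == 60]
  expect_lt(mean(u_frame1), 0.01)
  expect_gt(mean(u_frame2), 0.99)
  expect_lt(cls$centroids["air"], cls$centroids["ow"])
})

test_that("air membership is invariant to internal cluster relabeling", {
  m <- coarse_mesh
  M <- n_elements(m)
  set.seed(4)
  series <- tibble::tibble(
    time_s = rep(c(0, 60), each = M), element = rep(1:M, 2),
    sigma_S_per_m = c(runif(M, 0.08, 0.12), runif(M, 0.005, 0.02))
  )
  cls1 <- classify_run(series, fcm_config())
  # force the opposite initial centroid order via provided initialization
  cls2 <- classify_run(series, fcm_config(centroid_init = "provided",
                                          centroids = c(min(series$sigma_S_per_m),
                                                        max(series$sigma_S_per_m))))
  expect_equal(tidy(cls1)$u2, tidy(cls2)$u2, tolerance = 1e-6)
})

test_that("permutation of elements permutes memberships identically", {
  set.seed(9)
  x <- c(runif(25, 0.05, 0.15), runif(25, 0.001, 0.01))
  perm <- sample.int(50)
  f1 <- fcm_two_cluster(x, fcm_config())
  f2 <- fcm_two_cluster(x[perm], fcm_config())
  expect_equal(f2$memberships, f1$memberships[perm, ], tolerance = 1e-12)
})

test_that("a run interpolating down and back up gives unimodal mean membership", {
  m <- coarse_mesh
  M <- n_elements(m)
  levels <- c(0.1, 0.06, 0.01, 0.06, 0.1) # down to 0.01 and back
  set.seed(6)
  series <- purrr::map_dfr(seq_along(levels), function(i) {
    tibble::tibble(time_s = i, element = 1:M,
                   sigma_S_per_m = levels[i] * exp(rnorm(M, 0, 0.02)))
  })
  cls <- classify_run(series)
  u_mean <- tidy(cls) |>
    dplyr::group_by(time_s) |>
    dplyr::summarize(u = mean(u2)) |>
    dplyr::pull(u)
  pk <- which.max(u_mean)
  expect_equal(pk, 3) # lowest conductivity frame
  expect_true(all(diff(u_mean[1:pk]) > 0))
  expect_true(all(diff(u_mean[pk:length(u_mean)]) < 0))
})
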