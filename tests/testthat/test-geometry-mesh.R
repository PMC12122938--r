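test_that("disk mesh satisfies geometric invariants at the vessel defaults", {
  m <- coarse_mesh
  expect_true(all(m$elements$area_mm2 > 0))
  # total area within 0.5% of pi r^2 at default resolution
  expect_lt(abs(sum(m$elements$area_mm2) - pi * 42^2) / (pi * 42^2), 0.005)
  # electrodes: 8 present, disjoint edge sets, >= 1 edge each
  expect_equal(sort(unique(m$electrodes$electrode)), 1:8)
  expect_false(any(duplicated(m$electrodes$edge)))
  # equally spaced at 45 degree pitch: electrode arc centers
  centers <- vapply(1:8, function(e) {
    ed <- m$electrodes[m$electrodes$electrode == e, ]
    nodes <- unique(c(ed$n1, ed$n2))
    atan2(mean(m$nodes$y_mm[nodes]), mean(m$nodes$x_mm[nodes])) * 180 / pi
  }, numeric(1))
  pitch <- diff(sort(centers %% 360))
  expect_equal(pitch, rep(45, 7), tolerance = 1e-6)
})

test_that("mesh refinement scales element count ~4x and converges in area", {
  m1 <- build_disk_mesh(42, 8, target_edge_mm = 10)
  m2 <- build_disk_mesh(42, 8, target_edge_mm = 5)
  m3 <- build_disk_mesh(42, 8, target_edge_mm = 2.5)
  ratio <- n_elements(m2) / n_elements(m1)
  expect_gte(ratio, 2.5); expect_lt(ratio, 6.5)
  areas <- vapply(list(m1, m2, m3), function(m) sum(m$elements$area_mm2), numeric(1))
  # monotone convergence toward pi r^2 from below
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas < pi * 42^2))
  expect_lt(abs(areas[3] - pi * 42^2) / (pi * 42^2), 0.005)
})

test_that("rotation by one electrode pitch maps electrode k onto k+1", {
  m <- coarse_mesh
  th <- 2 * pi / 8
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  for (e in 1:7) {
    ed <- m$electrodes[m$electrodes$electrode == e, ]
    ed_next <- m$electrodes[m$electrodes$electrode == e + 1, ]
    p <- as.matrix(m$nodes[unique(c(ed$n1, ed$n2)), c("x_mm", "y_mm")]) %*% t(rot)
    q <- as.matrix(m$nodes[unique(c(ed_next$n1, ed_next$n2)), c("x_mm", "y_mm")])
    # rotated node set equals the next electrode's node set (as point sets)
    d <- vapply(seq_len(nrow(p)), function(i) {
      min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
    }, numeric(1))
    expect_lt(max(d), 1e-9)
  }
})

test_that("parameter validation rejects degenerate geometry", {
  expect_error(build_disk_mesh(-1, 8), "radius")
  expect_error(build_disk_mesh(42, 3), "n_electrodes")
  expect_error(build_disk_mesh(42, 8, electrode_arc_deg = 60), "arc")
  expect_error(build_disk_mesh(42, 8, target_edge_mm = 0), "target_edge")
})

test_that("adjacent protocol has n(n-3) patterns, matching brute force", {
  for (n in c(4, 5, 8, 11, 16)) {
    p <- adjacent_protocol(n)
    expect_equal(nrow(p), n * (n - 3))
    expect_equal(nrow(p), enumerate_adjacent_oracle(n))
    # no measurement electrode touches its drive pair
    overlap <- mapply(function(dp, dn, mp, mn) length(intersect(c(dp, dn), c(mp, mn))),
                      p$drive_pos, p$drive_neg, p$meas_pos, p$meas_neg)
    expect_true(all(overlap == 0))
    # ordering: drives ascending, then measurement start ascending
    expect_true(all(diff(p$drive_pos) >= 0))
  }
  expect_error(adjacent_protocol(3), "4")
})

test_that("circular region masks follow centroid-in-circle geometry", {
  m <- coarse_mesh
  all_mask <- circular_region_mask(m, c(0, 0), 84)
  expect_equal(length(all_mask$element_indices), n_elements(m))

  a1 <- circular_region_mask(m, c(0, 0), 20)
  expect_lt(abs(a1$area_mm2 - pi * 100) / (pi * 100), 0.35) # coarse-mesh discretization
  # finer mesh tightens the discretization error
  a1f <- circular_region_mask(build_disk_mesh(42, 8, target_edge_mm = 3), c(0, 0), 20)
  expect_lt(abs(a1f$area_mm2 - pi * 100) / (pi * 100), 0.1)

  areas <- sampling_areas(m)
  expect_length(intersect(areas$area1$element_indices, areas$area2$element_indices), 0)
  # area 2 sits on the electrode-1 radius (+y), tangent to the wall
  expect_equal(areas$area2$center_mm, c(0, 32), tolerance = 1e-9)
  expect_error(circular_region_mask(m, c(200, 0), 10), "empty")
})

test_that("mesh round-trips through the tabular on-disk format", {
  dir <- withr::local_tempdir()
  write_mesh(coarse_mesh, dir)
  m2 <- read_mesh(dir, radius_mm = 42)
  expect_equal(m2$nodes$x_mm, coarse_mesh$nodes$x_mm)
  expect_equal(m2$elements$area_mm2, coarse_mesh$elements$area_mm2)
  expect_equal(m2$electrodes$length_mm, coarse_mesh$electrodes$length_mm)
  # forward voltages computed on the re-read mesh are identical
  v1 <- simulate_frame(coarse_mesh, homog_sigma(coarse_mesh), std_protocol)$voltage_V
  v2 <- simulate_frame(m2, homog_sigma(m2), std_protocol)$voltage_V
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("protocol round-trips through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_protocol(std_protocol, path)
  p2 <- read_protocol(path)
  expect_equal(p2$drive_pos, std_protocol$drive_pos)
  expect_equal(p2$meas_neg, std_protocol$meas_neg)
  expect_equal(n_patterns(p2), 40)
})
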