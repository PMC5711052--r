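test_that("four-voxel grid reproduces exhaustive voxel counting", {
  g <- grid_from_values(c(1, 2, 3, 4), shape = c(2, 2, 1))
  m <- full_mask(c(2, 2, 1))
  d <- compute_dvh(g, m, bin_width = 0.5)

  expect_equal(d$total_volume, 4 * voxel_volume_cc(g))
  # 3 of 4 voxels receive >= 2 Gy
  expect_equal(volume_at_dose(d, 2), 75)
  expect_equal(sum(d$differential), d$total_volume, tolerance = 1e-6)

  pm <- dose_point_metrics(g, m)
  expect_equal(pm$Dmean, 2.5)
  expect_equal(pm$Dmax, 4)
  expect_equal(pm$Dmin, 1)

  # D50 against the sort-based percentile (within one bin width)
  expect_lt(abs(dose_at_volume(d, 50) - 3), 0.5 + 1e-9)
})

test_that("uniform and single-voxel doses give degenerate curves", {
  g <- grid_from_values(rep(60, 8), shape = c(2, 2, 2))
  d <- compute_dvh(g, full_mask(c(2, 2, 2)), bin_width = 0.05)
  expect_equal(volume_at_dose(d, c(5, 30, 59.9)), c(100, 100, 100))
  expect_equal(volume_at_dose(d, 70), 0)
  expect_equal(dose_at_volume(d, 1), 60, tolerance = 0.05)
  expect_equal(dose_at_volume(d, 99), 60, tolerance = 0.05)

  one <- structure_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), "spot")
  g2 <- grid_from_values(c(7.3, rep(1, 7)), shape = c(2, 2, 2))
  pm <- dose_point_metrics(g2, one)
  expect_equal(pm$Dmax, 7.3)
  expect_equal(pm$Dmean, 7.3)
  d1 <- compute_dvh(g2, one, 0.05)
  expect_equal(d1$total_volume, voxel_volume_cc(g2))
})

test_that("point metrics handle zero-dose voxels and ordering", {
  g <- grid_from_values(c(0, 0, 10))
  pm <- dose_point_metrics(g, full_mask(c(3, 1, 1)))
  expect_equal(pm$Dmin, 0)
  expect_equal(pm$Dmean, 10 / 3)
  expect_equal(pm$Dmax, 10)
  expect_true(pm$Dmin <= pm$Dmean && pm$Dmean <= pm$Dmax)
})

test_that("errors name the structure and the geometry problem", {
  g <- grid_from_values(1:4, shape = c(2, 2, 1))
  empty <- structure_mask(array(FALSE, c(2, 2, 1)), "cord")
  expect_error(compute_dvh(g, empty), "cord")
  expect_error(dose_point_metrics(g, empty), "cord")
  wrong <- full_mask(c(2, 2, 2), "lung")
  expect_error(compute_dvh(g, wrong), "geometry mismatch")
  expect_error(compute_dvh(g, full_mask(c(2, 2, 1)), bin_width = 0), "bin_width")
  expect_error(dose_at_volume(compute_dvh(g, full_mask(c(2, 2, 1))), 0), "percent")
  expect_error(dose_at_volume(compute_dvh(g, full_mask(c(2, 2, 1))), 101), "percent")
})

test_that("DVH curve invariants hold on random grids", {
  set.seed(401)
  for (i in 1:25) {
    cs <- random_grid_case()
    d <- compute_dvh(cs$dose, cs$mask, bin_width = 0.5)
    expect_true(all(diff(d$cumulative) <= 1e-12))
    expect_equal(d$cumulative[1], 100)
    expect_equal(sum(d$differential), d$total_volume, tolerance = 1e-9)
    n <- length(d$differential)
    # cumulative at edge k equals the tail sum of the differential histogram
    k <- sample(n, 1)
    expect_equal(d$cumulative[k],
                 100 * sum(d$differential[k:n]) / d$total_volume,
                 tolerance = 1e-9)
  }
})

test_that("DVH path matches brute-force voxel counting within one bin", {
  set.seed(402)
  bw <- 0.5
  for (i in 1:40) {
    cs <- random_grid_case()
    d <- compute_dvh(cs$dose, cs$mask, bin_width = bw)
    doses <- cs$dose$values[cs$mask$mask]
    for (q in stats::runif(3, 0, max(doses))) {
      direct <- 100 * mean(doses >= q)
      j <- findInterval(q, d$bin_edges)
      bin_mass <- d$cumulative[j] - d$cumulative[min(j + 1, length(d$cumulative))]
      expect_lt(abs(volume_at_dose(d, q) - direct), bin_mass + 1e-9)
    }
    # Dx brackets the sort-based percentile within one bin width
    for (p in c(1, 25, 50, 75, 99)) {
      dx <- dose_at_volume(d, p)
      srt <- sort(doses, decreasing = TRUE)
      k <- max(1L, ceiling(p / 100 * length(doses)))
      expect_lt(abs(dx - srt[k]), bw + 1e-9)
    }
  }
})

test_that("refining the bin width converges and paths stay consistent", {
  set.seed(403)
  cs <- random_grid_case()
  doses <- cs$dose$values[cs$mask$mask]
  coarse <- compute_dvh(cs$dose, cs$mask, bin_width = 1)
  fine <- compute_dvh(cs$dose, cs$mask, bin_width = 0.1)
  for (q in c(10, 25, 40)) {
    expect_lt(abs(volume_at_dose(coarse, q) - volume_at_dose(fine, q)),
              100 / length(doses) + 1e-9)
  }
  for (p in c(10, 50, 90)) {
    expect_lt(abs(dose_at_volume(coarse, p) - dose_at_volume(fine, p)), 1 + 1e-9)
  }
  # volume_at_dose and dose_at_volume are mutually consistent on strictly
  # decreasing segments (plateaus legitimately resolve to the far edge)
  for (q in stats::quantile(doses, c(0.2, 0.5, 0.8))) {
    j <- findInterval(q, fine$bin_edges)
    decreasing <- fine$cumulative[j] > fine$cumulative[j + 1]
    if (decreasing) {
      v <- volume_at_dose(fine, q)
      expect_lt(abs(dose_at_volume(fine, v) - q), 0.1 + 1e-9)
    }
  }
  # Dmean from the differential DVH matches the voxel mean within bw/2
  expect_lt(abs(dvh_mean_dose(fine) - mean(doses)), 0.05 + 1e-9)
})
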