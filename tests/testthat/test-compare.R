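test_that("min-subtract/mean-divide normalization has min 0 and mean 1", {
  p <- normalize_minmean(prof(c(1, 3, 1, 3, 1, 3)))
  expect_equal(p$values, c(0, 2, 0, 2, 0, 2))
  q <- normalize_minmean(prof(F24))
  expect_equal(min(q$values), 0)
  expect_equal(max(q$values), 8)      # (5 - 1) / mean 0.5
  expect_equal(mean(q$values), 1, tolerance = 1e-12)
  set.seed(2)
  for (k in 1:10) {
    v <- runif(12, 0, 7)
    out <- normalize_minmean(prof(v))$values
    expect_equal(min(out), 0)
    expect_equal(mean(out), 1, tolerance = 1e-12)
  }
  expect_error(normalize_minmean(prof(rep(3, 6))), "degenerate")
})

test_that("profile difference sum handles equal and mismatched grids", {
  a <- prof(c(0, 2, 0, 2, 0, 2))
  b <- prof(c(2, 0, 2, 0, 2, 0))
  expect_equal(profile_difference_sum(a, a), 0)
  expect_equal(profile_difference_sum(a, b), 12)
  # fine-grid profile interpolated onto the coarse grid: a circular linear
  # ramp interpolates exactly, so the sum matches the dense-truth values
  fine_x <- seq(0, 359, by = 1)
  tri <- 1 + pmin(fine_x, 360 - fine_x) / 180          # circular triangle wave
  fine <- angular_profile(tri, 1)
  coarse_x <- seq(0, 345, by = 15)
  coarse <- angular_profile(rep(1, 24), 15)
  want <- sum(abs(1 - (1 + pmin(coarse_x, 360 - coarse_x) / 180)))
  expect_equal(profile_difference_sum(coarse, fine), want, tolerance = 1e-9)
})

test_that("profile difference sum is a pseudo-metric on a shared grid", {
  set.seed(17)
  for (k in 1:15) {
    a <- prof(runif(12, 0, 5)); b <- prof(runif(12, 0, 5))
    cc <- prof(runif(12, 0, 5))
    expect_equal(profile_difference_sum(a, b), profile_difference_sum(b, a))
    expect_gte(profile_difference_sum(a, b), 0)
    expect_equal(profile_difference_sum(a, a), 0)
    expect_lte(profile_difference_sum(a, cc),
               profile_difference_sum(a, b) + profile_difference_sum(b, cc) + 1e-12)
  }
})

test_that("peak-set matching assigns one-to-one within the 30 deg gate", {
  m <- match_peak_sets(c(30, 210), c(28, 212))
  expect_equal(m$n_peaks_delta, 0L)
  expect_equal(sort(m$position_deltas_deg), c(-2, 2))
  m2 <- match_peak_sets(c(30, 210), c(28, 150, 212))
  expect_equal(m2$n_peaks_delta, -1L)
  expect_equal(sort(m2$position_deltas_deg), c(-2, 2))
  expect_equal(m2$unmatched_ref, 2L)
  m3 <- match_peak_sets(c(10, 100, 190, 280), c(10, 100, 190, 280))
  expect_equal(m3$n_peaks_delta, 0L)
  expect_equal(m3$position_deltas_deg, rep(0, 4))
  # matching across the wrap and beyond-gate exclusion
  m4 <- match_peak_sets(c(359), c(2))
  expect_equal(m4$position_deltas_deg, -3)
  m5 <- match_peak_sets(c(0), c(60))
  expect_equal(nrow(m5$matches), 0L)
  expect_equal(m5$n_peaks_delta, 0L)
  # nearest-first greedy would pair 25 with 26 (total cost 11); the optimal
  # assignment pairs 25-20 and 30-26 (total cost 9)
  m6 <- match_peak_sets(c(25, 30), c(20, 26))
  expect_equal(nrow(m6$matches), 2L)
  expect_equal(sum(abs(m6$position_deltas_deg)), 9)
})

test_that("self-matching any peak set returns zero deltas", {
  set.seed(19)
  for (k in 1:10) {
    pos <- sort(runif(sample(1:6, 1), 0, 360))
    m <- match_peak_sets(pos, pos)
    expect_equal(m$n_peaks_delta, 0L)
    expect_equal(m$position_deltas_deg, rep(0, length(pos)))
  }
})

test_that("scattering patterns reduce to azimuthal line profiles", {
  theta <- seq(0, 80, by = 1); psi <- seq(0, 359, by = 1)
  iso <- scattering_pattern(matrix(3, length(theta), length(psi)), 1, 1)
  flat <- line_profile_from_pattern(iso, out_step_deg = 15)
  expect_equal(flat$values, rep(3, 24), tolerance = 1e-9)
  # two narrow lobes on the theta = 48 ring at psi = 45 and 225
  v <- matrix(0, length(theta), length(psi))
  lobes <- exp(-((theta - 48)^2) / (2 * 3^2)) %o%
    (exp(-(pmin(abs(psi - 45), 360 - abs(psi - 45))^2) / (2 * 3^2)) +
     exp(-(pmin(abs(psi - 225), 360 - abs(psi - 225))^2) / (2 * 3^2)))
  pat <- scattering_pattern(lobes, 1, 1)
  lp <- line_profile_from_pattern(pat, out_step_deg = 1)
  r <- analyze_profile(lp)
  expect_equal(sort(round(r$peaks$position_deg)), c(45, 225))
  expect_error(line_profile_from_pattern(pat, circle_theta_deg = 95),
               "outside")
})

test_that("azimuthal gaussian blur conserves the circular integral", {
  psi <- seq(0, 359, by = 1)
  row <- exp(-(pmin(abs(psi - 100), 360 - abs(psi - 100))^2) / (2 * 4^2))
  pat <- scattering_pattern(rbind(row, row, row), 1, 1)
  lp <- line_profile_from_pattern(pat, blur_fwhm_deg = 8,
                                  circle_theta_deg = 1, out_step_deg = 1)
  expect_equal(sum(lp$values), sum(row), tolerance = 0.01 * sum(row))
})

test_that("direction difference maps wrap axially with +90 boundary", {
  x <- map_image(matrix(c(10, 40, 90, -1), 2, 2), "dir_1")
  expect_true(all(direction_difference_map(x, x)$data[1:3] == 0))
  sli <- map_image(matrix(c(5, 90, 100, 10), 2, 2), "dir_1")
  ref <- map_image(matrix(c(175, 0, 80, -1), 2, 2), "dir_1")
  d <- direction_difference_map(sli, ref)
  expect_equal(d$data[1, 1], 10)    # 5 vs 175 wraps to +10
  expect_equal(d$data[2, 1], 90)    # exactly 90 reports +90
  expect_equal(d$data[1, 2], 20)
  expect_true(is.nan(d$data[2, 2])) # undefined reference pixel
  # antisymmetry away from the +90 boundary
  d2 <- direction_difference_map(ref, sli)
  expect_equal(d2$data[1, 1], -10)
  expect_equal(d2$data[1, 2], -20)
  expect_error(direction_difference_map(x, map_image(matrix(0, 1, 1), "dir_1")),
               "shape")
})

test_that("binned standard deviation recovers a known spread per bin", {
  z <- map_image(matrix(0, 4, 4), "diff", NaN)
  b <- map_image(matrix(runif(16), 4, 4), "ret", NaN)
  tab <- binned_std(z, b)
  expect_true(all(tab$sigma[tab$n > 0] == 0))
  expect_true(all(is.nan(tab$sigma[tab$n == 0])))
  set.seed(101)
  n <- 10000L
  vals <- map_image(matrix(rnorm(n, 0, 5), 100, 100), "diff", NaN)
  ret <- map_image(matrix(runif(n, 0.7, 0.7999), 100, 100), "ret", NaN)
  tab2 <- binned_std(vals, ret, bin_width = 0.1)
  row <- tab2[which.min(abs(tab2$bin_low - 0.7)), ]
  expect_equal(row$n, n)
  expect_equal(row$sigma, 5, tolerance = 0.2 / 5)
  expect_equal(sum(tab2$n), n)
})

test_that("retardation decreases monotonically with inclination", {
  expect_equal(retardation_from_inclination(0, 0.8), 0.8)
  expect_equal(retardation_from_inclination(90, 0.8), 0)
  expect_equal(retardation_from_inclination(60, 0.8), 0.2298, tolerance = 1e-3)
  a <- seq(0, 90, by = 1)
  r <- retardation_from_inclination(a, 0.8)
  expect_true(all(diff(r) < 0))
  expect_error(retardation_from_inclination(-5, 0.5), "alpha")
  expect_error(retardation_from_inclination(10, 1.5), "ret_max")
})
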