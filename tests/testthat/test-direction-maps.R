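test_that("opposite-peak pairing enforces the 180 +/- 35 deg rule", {
  p <- pair_peaks(c(20, 110, 200, 290))
  expect_equal(nrow(p), 2L)
  expect_equal(p, cbind(1:2, 3:4))
  expect_equal(nrow(pair_peaks(c(10, 70, 130, 190, 250, 310))), 3L)
  expect_equal(nrow(pair_peaks(c(20, 60, 200, 240))), 2L)
  expect_null(pair_peaks(c(20, 50, 120, 240)))
  # separation just outside tolerance
  expect_null(pair_peaks(c(0, 90, 144, 270)))
  expect_equal(nrow(pair_peaks(c(0, 90, 145, 270))), 2L)
  expect_error(pair_peaks(c(10, 190)), "pairing undefined")
  expect_error(pair_peaks(c(10, 20, 30, 40, 50)), "pairing undefined")
})

test_that("peak counts map to fiber directions per the 1/2/4/6 rules", {
  expect_equal(directions_from_peaks(c(30, 210))$directions_deg, 120)
  expect_equal(directions_from_peaks(70)$directions_deg, 70)
  expect_equal(directions_from_peaks(250)$directions_deg, 70)
  expect_equal(directions_from_peaks(c(20, 110, 200, 290))$directions_deg,
               c(20, 110))
  expect_equal(directions_from_peaks(c(170, 335))$directions_deg, 72.5)
  expect_equal(directions_from_peaks(c(10, 70, 130, 190, 250, 310))$directions_deg,
               c(40, 100, 160))   # pair midpoints 100, 160, 220 mod 180
  # 0, 3, 5 peaks or a rejected pairing give no directions
  expect_length(directions_from_peaks(numeric(0))$directions_deg, 0L)
  expect_length(directions_from_peaks(c(10, 100, 250))$directions_deg, 0L)
  expect_length(directions_from_peaks(c(20, 50, 120, 240))$directions_deg, 0L)
  expect_length(directions_from_peaks(c(1, 2, 3, 4, 5))$directions_deg, 0L)
})

test_that("two peaks 180 deg apart recover the perpendicular direction", {
  for (phi in seq(0, 175, by = 12.5)) {
    d <- directions_from_peaks(c((phi + 90) %% 360, (phi - 90) %% 360))
    expect_equal(axial_err(d$directions_deg, phi), 0, tolerance = 1e-9)
  }
})

test_that("peak distance folds to (0,180], is symmetric, 0 for merged peaks", {
  expect_equal(peak_distance(c(30, 210)), 180)
  expect_equal(peak_distance(c(210, 30)), 180)
  expect_equal(peak_distance(c(350, 20)), 30)
  expect_equal(peak_distance(42), 0)
  expect_true(is.nan(peak_distance(c(1, 2, 3, 4))))
  expect_true(is.nan(peak_distance(numeric(0))))
  set.seed(3)
  for (k in 1:20) {
    ab <- runif(2, 0, 360)
    expect_equal(peak_distance(ab), peak_distance(rev(ab)))
    expect_lte(peak_distance(ab), 180)
  }
})

test_that("parameter maps compose the per-pixel pipeline", {
  arr <- array(0, c(2, 2, 24))
  for (i in 1:2) for (j in 1:2) arr[i, j, ] <- F24
  maps <- build_parameter_maps(sli_stack(arr, stack_metadata(15)))
  expect_equal(maps$dir_1$data, matrix(120, 2, 2))
  expect_equal(maps$dir_2$data, matrix(-1, 2, 2))
  expect_equal(maps$distance$data, matrix(180, 2, 2))
  expect_equal(maps$peaks_prominent$data, matrix(2, 2, 2))
  expect_equal(maps$peaks_all$data, matrix(2, 2, 2))
  expect_equal(maps$avg$data, matrix(mean(F24), 2, 2))
  expect_equal(maps$prominence_avg$data, matrix(1, 2, 2))
  expect_equal(maps$width_avg$data, matrix(20, 2, 2))
})

test_that("constant stacks yield sentinel maps and zero peak counts", {
  maps <- build_parameter_maps(sli_stack(array(4, c(3, 3, 24)),
                                         stack_metadata(15)))
  expect_equal(maps$peaks_all$data, matrix(0, 3, 3))
  expect_equal(maps$dir_1$data, matrix(-1, 3, 3))
  expect_true(all(is.nan(maps$distance$data)))
  expect_equal(maps$avg$data, matrix(4, 3, 3))
})

test_that("rotating all profiles rotates all defined directions mod 180", {
  res <- synth_stack(cross2(70, shape = c(9, 9)))
  st <- res$stack
  s <- 3L  # shift by 3 samples = 45 deg
  rot <- st
  rot$data <- st$data[, , c((24 - s + 1):24, 1:(24 - s))]
  m1 <- build_parameter_maps(st)
  m2 <- build_parameter_maps(rot)
  for (nm in c("dir_1", "dir_2")) {
    def <- map_defined(m1[[nm]])
    expect_equal(def, map_defined(m2[[nm]]))
    got <- m2[[nm]]$data[def]
    want <- (m1[[nm]]$data[def] + s * 15) %% 180
    expect_equal(axial_err(got, want), rep(0, sum(def)), tolerance = 1e-6)
  }
})

test_that("axial median filter minimizes summed axial distance", {
  expect_equal(axial_median(rep(40, 9)), 40)
  expect_equal(axial_median(c(170, 178, 2)), 178)
  # equivalence with the ordinary median when the spread is < 90 deg
  set.seed(9)
  for (k in 1:25) {
    v <- runif(sample(3:9, 1), 10, 80)
    v <- v[order(v)]
    om <- v[ceiling(length(v) / 2)]  # lower ordinary median element
    if (length(v) %% 2 == 0) {
      cands <- v[c(length(v) / 2, length(v) / 2 + 1)]
      costs <- vapply(cands, function(a) sum(axial_err(a, v)), numeric(1))
      om <- min(cands[costs == min(costs)])
    }
    expect_equal(axial_median(v), om)
  }
})

test_that("median filter respects sentinels and is idempotent on constants", {
  m <- matrix(-1, 3, 3); m[1, 1] <- 170; m[1, 2] <- 178; m[2, 1] <- 2
  filt <- median_direction_filter(map_image(m, "dir_1"))
  expect_equal(filt$data[2, 2], 178)
  all40 <- map_image(matrix(40, 5, 5), "dir_1")
  expect_equal(median_direction_filter(all40)$data, all40$data)
  none <- map_image(matrix(-1, 4, 4), "dir_1")
  expect_equal(median_direction_filter(none)$data, none$data)
  # output values always come from the window
  set.seed(13)
  vals <- matrix(sample(c(-1, runif(8, 0, 180)), 36, replace = TRUE), 6, 6)
  out <- median_direction_filter(map_image(vals, "dir_1"))
  expect_true(all(out$data %in% c(-1, vals)))
  expect_error(median_direction_filter(map_image(m, "dir_1"), window = 4),
               "odd")
})

test_that("vector overlay emits one unit segment per defined direction", {
  one <- map_image(matrix(0, 1, 1), "dir_1")   # phi = 0: points up
  maps <- list(dir_1 = one)
  seg <- sample_vector_overlay(maps, stride = 1)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$x0, seg$x1)                  # vertical on screen
  expect_equal(abs(seg$y1 - seg$y0), 1)
  two <- list(dir_1 = map_image(matrix(30, 1, 1), "dir_1"),
              dir_2 = map_image(matrix(120, 1, 1), "dir_2"))
  expect_equal(nrow(sample_vector_overlay(two)), 2L)
  none <- list(dir_1 = map_image(matrix(-1, 2, 2), "dir_1"))
  expect_equal(nrow(sample_vector_overlay(none)), 0L)
  # stride subsamples the grid
  big <- list(dir_1 = map_image(matrix(90, 6, 6), "dir_1"))
  expect_equal(nrow(sample_vector_overlay(big, stride = 3)), 4L)
  # segments have unit length
  seg30 <- sample_vector_overlay(two)
  expect_equal(sqrt((seg30$x1 - seg30$x0)^2 + (seg30$y1 - seg30$y0)^2),
               rep(1, 2))
})
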