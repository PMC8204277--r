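#' Min-subtract / mean-divide normalization
#'
#' Normalization used before comparing line profiles across techniques: the
#' profile minimum is subtracted and the result divided by its average, so
#' profiles from instruments with different baselines and gains become
#' comparable. The output has minimum 0 and mean 1.
#'
#' @param p An `angular_profile`, not constant.
#' @return The normalized [angular_profile()].
#' @export
normalize_minmean <- function(p) {
  stopifnot(inherits(p, "angular_profile"))
  q <- p$values - min(p$values)
  m <- mean(q)
  if (m <= 0) stop("degenerate profile: constant intensity")
  angular_profile(q / m, p$step_deg, p$start_deg)
}

# circular linear interpolation of a full-circle profile at azimuths x_deg
.interp_circular <- function(values, step_deg, start_deg, x_deg) {
  n <- length(values)
  t <- ((x_deg - start_deg) / step_deg) %% n
  i0 <- floor(t)
  frac <- t - i0
  v0 <- values[(i0 %% n) + 1L]
  v1 <- values[((i0 + 1) %% n) + 1L]
  v0 + frac * (v1 - v0)
}

#' Sum of absolute differences between two line profiles
#'
#' Both profiles should first be normalized with [normalize_minmean()]. When
#' the azimuth grids differ (e.g. a 1-degree scatterometry profile against a
#' 15-degree SLI profile), `b` is linearly interpolated, circularly, onto
#' `a`'s grid before summing.
#'
#' @param a,b `angular_profile`s.
#' @return Nonnegative scalar, `sum(|a - b|)` over `a`'s grid.
#' @export
profile_difference_sum <- function(a, b) {
  stopifnot(inherits(a, "angular_profile"), inherits(b, "angular_profile"))
  bv <- if (length(b$values) == length(a$values) &&
            abs(b$step_deg - a$step_deg) < 1e-12 &&
            abs(b$start_deg - a$start_deg) < 1e-12) b$values
  else .interp_circular(b$values, b$step_deg, b$start_deg, profile_azimuths(a))
  sum(abs(a$values - bv))
}

# signed circular difference wrapped to (-180, 180]
.wrap180 <- function(d) {
  w <- d %% 360
  ifelse(w > 180, w - 360, w)
}

#' Match two peak-position sets across techniques
#'
#' Finds the one-to-one assignment between the two position sets that
#' matches as many peaks as possible within `match_tol_deg` of circular
#' distance and, among those, minimizes the total distance (exhaustive
#' search; peak sets are small). Used to compare SLI peaks (8\% prominence)
#' against scatterometry reference peaks (3\% prominence).
#'
#' @param sli_positions,ref_positions Corrected peak positions in degrees.
#' @param match_tol_deg Maximum circular distance for a valid match
#'   (default 30).
#' @return A list with `n_peaks_delta` (`length(sli) - length(ref)`),
#'   `position_deltas_deg` (signed `sli - ref` for matched pairs, wrapped to
#'   `(-180, 180]`), `matches` (two-column index matrix) and the unmatched
#'   indices of each set.
#' @export
match_peak_sets <- function(sli_positions, ref_positions,
                            match_tol_deg = 30) {
  ns <- length(sli_positions); nr <- length(ref_positions)
  cd <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }
  best <- list(n = -1L, cost = Inf, pairs = NULL)
  # recursive enumeration over assignments of sli peaks to ref peaks
  recurse <- function(i, used_ref, pairs, cost) {
    if (i > ns) {
      n_matched <- nrow(pairs)
      if (n_matched > best$n ||
          (n_matched == best$n && cost < best$cost))
        best <<- list(n = n_matched, cost = cost, pairs = pairs)
      return(invisible(NULL))
    }
    recurse(i + 1L, used_ref, pairs, cost)          # leave sli peak i unmatched
    for (j in seq_len(nr)) {
      if (used_ref[j]) next
      d <- cd(sli_positions[i], ref_positions[j])
      if (d > match_tol_deg) next
      used_ref[j] <- TRUE
      recurse(i + 1L, used_ref, rbind(pairs, c(i, j)), cost + d)
      used_ref[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nr), matrix(integer(0), 0, 2), 0)
  pairs <- best$pairs
  deltas <- if (nrow(pairs)) .wrap180(sli_positions[pairs[, 1]] -
                                      ref_positions[pairs[, 2]]) else numeric(0)
  list(n_peaks_delta = ns - nr,
       position_deltas_deg = deltas,
       matches = pairs,
       unmatched_sli = setdiff(seq_len(ns), pairs[, 1]),
       unmatched_ref = setdiff(seq_len(nr), pairs[, 2]))
}

#' Scattering pattern on an angular grid
#'
#' A 2D intensity distribution of scattered light in angular coordinates:
#' rows sample the polar angle theta from 0 to `theta_max_deg`, columns the
#' azimuth psi over the full circle.
#'
#' @param values Nonnegative numeric matrix (theta x psi).
#' @param theta_step_deg,psi_step_deg Grid resolutions in degrees.
#' @return An object of class `scattering_pattern`.
#' @export
scattering_pattern <- function(values, theta_step_deg, psi_step_deg) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("pattern intensities must be nonnegative")
  if (abs(ncol(values) * psi_step_deg - 360) > 1e-9)
    stop("azimuth axis must cover the full circle")
  structure(list(values = values, theta_step_deg = theta_step_deg,
                 psi_step_deg = psi_step_deg,
                 theta_max_deg = (nrow(values) - 1L) * theta_step_deg),
            class = "scattering_pattern")
}

.gauss_kernel <- function(sigma_samples) {
  if (sigma_samples <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_samples))
  k <- exp(-((-r:r)^2) / (2 * sigma_samples^2))
  k / sum(k)
}

# 1D convolution along matrix rows/cols; circular or replicate-padded
.conv_axis <- function(m, kernel, axis, circular) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(m)
  if (axis == 2L) return(t(.conv_axis(t(m), kernel, 1L, circular)))
  n <- nrow(m)
  idx <- if (circular) ((seq_len(n + 2L * r) - r - 1L) %% n) + 1L
         else pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * padded[(k - 1L) + seq_len(n), , drop = FALSE]
  out
}

#' Azimuthal line profile from a scattering pattern
#'
#' Post-processes a simulated or measured scattering pattern into a line
#' profile comparable with SLI profiles: the pattern is blurred with a 2D
#' Gaussian whose full width at half maximum matches the angular diameter of
#' the illumination aperture (default 8 degrees; the azimuth axis is treated
#' circularly, the polar axis with replicate padding), then sampled along
#' the circle at a fixed polar angle (default theta = 48 degrees, matching
#' an oblique illumination of that elevation).
#'
#' @param pat A [scattering_pattern()].
#' @param blur_fwhm_deg Gaussian blur FWHM in degrees (default 8). Set
#'   `fwhm = FALSE` to interpret the value as `2 * sigma` instead.
#' @param circle_theta_deg Polar angle of the sampling circle (default 48).
#' @param out_step_deg Azimuth step of the returned profile (default the
#'   pattern's own).
#' @param fwhm Interpret `blur_fwhm_deg` as FWHM (default `TRUE`).
#' @return An [angular_profile()] sampled at `out_step_deg`.
#' @export
line_profile_from_pattern <- function(pat, blur_fwhm_deg = 8,
                                      circle_theta_deg = 48,
                                      out_step_deg = pat$psi_step_deg,
                                      fwhm = TRUE) {
  stopifnot(inherits(pat, "scattering_pattern"))
  if (circle_theta_deg < 0 || circle_theta_deg > pat$theta_max_deg)
    stop("sampling circle theta = ", circle_theta_deg,
         " outside pattern polar range [0, ", pat$theta_max_deg, "]")
  sigma_deg <- if (fwhm) blur_fwhm_deg / (2 * sqrt(2 * log(2)))
               else blur_fwhm_deg / 2
  v <- .conv_axis(pat$values, .gauss_kernel(sigma_deg / pat$theta_step_deg),
                  1L, circular = FALSE)
  v <- .conv_axis(v, .gauss_kernel(sigma_deg / pat$psi_step_deg),
                  2L, circular = TRUE)
  t_idx <- circle_theta_deg / pat$theta_step_deg
  i0 <- floor(t_idx); frac <- t_idx - i0
  row0 <- v[i0 + 1L, ]
  row1 <- v[min(i0 + 2L, nrow(v)), ]
  ring <- row0 + frac * (row1 - row0)
  x <- seq(0, 360 - out_step_deg, by = out_step_deg)
  angular_profile(.interp_circular(ring, pat$psi_step_deg, 0, x),
                  out_step_deg, 0)
}

#' Axial difference between two direction maps
#'
#' Per-pixel signed difference `sli - ref` between co-registered direction
#' maps, wrapped to the axial range `(-90, 90]` (differences of exactly 90
#' degrees report +90). Pixels undefined in either map are sentinel `NaN`.
#'
#' @param sli_dir,ref_dir Direction [map_image()]s of the same shape.
#' @return A [map_image()] named `dir_diff`.
#' @export
direction_difference_map <- function(sli_dir, ref_dir) {
  stopifnot(inherits(sli_dir, "map_image"), inherits(ref_dir, "map_image"))
  if (!all(dim(sli_dir$data) == dim(ref_dir$data)))
    stop("direction maps must have the same shape")
  def <- map_defined(sli_dir) & map_defined(ref_dir)
  d <- (sli_dir$data - ref_dir$data) %% 180
  d <- ifelse(d > 90, d - 180, d)
  d[!def] <- NaN
  map_image(d, "dir_diff", NaN)
}

#' Standard deviation of map values binned by a second map
#'
#' Bins the defined pixels of `values` by the co-located value of `binner`
#' (e.g. direction differences binned by retardation) and reports the
#' population standard deviation and count per bin.
#'
#' @param values A [map_image()] (e.g. from [direction_difference_map()]).
#' @param binner A [map_image()] with values in `[0, 1]`, same shape.
#' @param bin_width Bin width on the binner scale (default 0.1).
#' @return A data frame with columns `bin_low`, `bin_high`, `sigma`, `n`
#'   (empty bins have `n = 0` and `sigma = NaN`).
#' @export
binned_std <- function(values, binner, bin_width = 0.1) {
  stopifnot(inherits(values, "map_image"), inherits(binner, "map_image"))
  if (!all(dim(values$data) == dim(binner$data)))
    stop("maps must have the same shape")
  def <- map_defined(values) & map_defined(binner)
  v <- values$data[def]; b <- binner$data[def]
  n_bins <- ceiling(1 / bin_width)
  lows <- (seq_len(n_bins) - 1L) * bin_width
  idx <- pmin(floor(b / bin_width + 1e-9), n_bins - 1L) + 1L
  sigma <- rep(NaN, n_bins); n <- integer(n_bins)
  for (k in seq_len(n_bins)) {
    x <- v[idx == k]
    n[k] <- length(x)
    if (n[k] > 0L) sigma[k] <- sqrt(mean((x - mean(x))^2))
  }
  data.frame(bin_low = lows, bin_high = lows + bin_width,
             sigma = sigma, n = n)
}

#' Retardation of a fiber bundle at a given inclination
#'
#' Closed-form link between the out-of-plane inclination alpha of a fiber
#' bundle and the birefringence retardation signal `|sin(delta)|` it
#' produces: `|sin(arcsin(ret_max) * cos(alpha)^2)|`, where `ret_max` is the
#' maximum retardation of the section (reached by in-plane fibers). The
#' retardation decreases monotonically from `ret_max` at alpha = 0 to 0 at
#' alpha = 90 degrees.
#'
#' @param alpha_deg Inclination in `[0, 90]` degrees.
#' @param ret_max Maximum retardation, in `[0, 1]`.
#' @return Retardation fraction in `[0, ret_max]`.
#' @export
retardation_from_inclination <- function(alpha_deg, ret_max) {
  if (any(alpha_deg < 0 | alpha_deg > 90))
    stop("alpha_deg must lie in [0, 90]")
  if (any(ret_max < 0 | ret_max > 1))
    stop("ret_max must lie in [0, 1]")
  abs(sin(asin(ret_max) * cos(alpha_deg * pi / 180)^2))
}
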