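#' In-plane fiber bundle for synthetic profiles
#'
#' A bundle contributes a pair of wrapped-Gaussian peaks to the azimuthal
#' profile, centred at `direction_deg + half_separation_deg` and
#' `direction_deg - half_separation_deg`. For in-plane fibers the two
#' scattering peaks sit at the direction +/- 90 degrees
#' (`half_separation_deg = 90`); decreasing the half-separation emulates
#' increasing out-of-plane inclination, moving the peaks together until they
#' merge into one broad peak at the direction itself.
#'
#' @param direction_deg Axial fiber direction in `[0, 180)`.
#' @param half_separation_deg Half the peak separation, in `(0, 90]`;
#'   90 = in-plane.
#' @param weight Relative amplitude of the bundle (> 0).
#' @param peak_sigma_deg Wrapped-Gaussian width parameter (> 0); about 20
#'   degrees matches the peak widths seen in measured profiles.
#' @return An object of class `sli_bundle`.
#' @export
bundle <- function(direction_deg, half_separation_deg = 90, weight = 1,
                   peak_sigma_deg = 20) {
  if (direction_deg < 0 || direction_deg >= 180)
    stop("direction_deg must lie in [0, 180)")
  if (half_separation_deg <= 0 || half_separation_deg > 90)
    stop("half_separation_deg must lie in (0, 90]")
  if (weight <= 0) stop("weight must be positive")
  if (peak_sigma_deg <= 0) stop("peak_sigma_deg must be positive")
  structure(list(direction_deg = direction_deg,
                 half_separation_deg = half_separation_deg,
                 weight = weight, peak_sigma_deg = peak_sigma_deg),
            class = "sli_bundle")
}

# wrapped Gaussian density shape (unnormalized, value 1 at x = 0)
.wrapped_gauss <- function(x_deg, sigma_deg) {
  out <- 0
  for (k in -3:3) out <- out + exp(-((x_deg + 360 * k)^2) / (2 * sigma_deg^2))
  out
}

# noiseless bundle contribution evaluated on an azimuth grid
.bundle_values <- function(b, phi_deg) {
  b$weight * (.wrapped_gauss(phi_deg - (b$direction_deg + b$half_separation_deg),
                             b$peak_sigma_deg) +
              .wrapped_gauss(phi_deg - (b$direction_deg - b$half_separation_deg),
                             b$peak_sigma_deg))
}

#' Synthesize one azimuthal profile with known ground truth
#'
#' The profile is `baseline + sum over bundles of paired wrapped-Gaussian
#' peaks`, optionally perturbed by multiplicative Gaussian noise
#' `(1 + eps)`, `eps ~ N(0, noise_sd)`.
#'
#' @param bundles A single [bundle()] or list of bundles.
#' @param step_deg Azimuth step of the grid (must divide 360).
#' @param baseline Constant intensity offset (default 1).
#' @param noise_sd Multiplicative noise standard deviation (default 0).
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @param start_deg Azimuth of the first sample.
#' @return A list with `profile` (an [angular_profile()]) and `truth` (a data
#'   frame of bundle parameters).
#' @export
synth_profile <- function(bundles, step_deg = 15, baseline = 1,
                          noise_sd = 0, seed = NULL, start_deg = 0) {
  if (inherits(bundles, "sli_bundle")) bundles <- list(bundles)
  if (length(bundles) == 0L) stop("need at least one bundle")
  phi <- (start_deg + seq(0, 360 - step_deg, by = step_deg)) %% 360
  v <- rep(baseline, length(phi))
  for (b in bundles) v <- v + .bundle_values(b, phi)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required for noisy profiles")
    set.seed(seed)
    v <- v * (1 + stats::rnorm(length(v), 0, noise_sd))
    v[v < 0] <- 0
  }
  truth <- data.frame(
    direction_deg = vapply(bundles, `[[`, numeric(1), "direction_deg"),
    half_separation_deg = vapply(bundles, `[[`, numeric(1),
                                 "half_separation_deg"),
    weight = vapply(bundles, `[[`, numeric(1), "weight"))
  list(profile = angular_profile(v, step_deg, start_deg), truth = truth)
}

#' Phantom specification
#'
#' Describes a synthetic stack as a set of regions (logical masks) each
#' carrying a list of fiber bundles; a pixel covered by several regions sees
#' the superposition of all their bundles over a shared baseline, mirroring
#' stacked tissue layers.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param regions List of `list(mask = <logical matrix>, bundles = <list of
#'   bundle()>)`.
#' @param baseline Constant offset (default 1).
#' @param noise_sd Multiplicative noise sd (default 0).
#' @param seed RNG seed (mandatory; drives the noise reproducibly).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, regions, baseline = 1, noise_sd = 0,
                         seed = 1L) {
  if (length(regions) == 0L) stop("empty region list")
  for (r in regions) {
    if (!is.logical(r$mask) || !all(dim(r$mask) == shape))
      stop("each region mask must be a logical matrix of the phantom shape")
    if (length(r$bundles) == 0L) stop("region without bundles")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shape = as.integer(shape), regions = regions,
                 baseline = baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Synthesize a whole SLI stack with ground-truth maps
#'
#' @param spec A [phantom_spec()].
#' @param step_deg Azimuth step (default 15).
#' @return A list with `stack` (an [sli_stack()]) and `truth`, a named list
#'   of ground-truth direction [map_image()]s (`dir_1`..`dir_3`, sentinel -1
#'   outside any region) plus `n_bundles`.
#' @export
synth_stack <- function(spec, step_deg = 15) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  phi <- seq(0, 360 - step_deg, by = step_deg)
  na <- length(phi)
  arr <- array(spec$baseline, c(nr, nc, na))
  for (r in spec$regions) {
    contrib <- rep(0, na)
    for (b in r$bundles) contrib <- contrib + .bundle_values(b, phi)
    idx <- which(r$mask)
    for (k in seq_len(na))
      arr[, , k][idx] <- arr[, , k][idx] + contrib[k]
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    arr <- arr * (1 + array(stats::rnorm(length(arr), 0, spec$noise_sd),
                            dim(arr)))
    arr[arr < 0] <- 0
  }
  dirs <- matrix(vector("list", nr * nc), nr, nc)
  gt <- lapply(1:3, function(k) matrix(-1, nr, nc))
  nb <- matrix(0, nr, nc)
  for (r in spec$regions) {
    ds <- vapply(r$bundles, `[[`, numeric(1), "direction_deg")
    idx <- which(r$mask)
    for (p in idx) dirs[[p]] <- c(dirs[[p]], ds)
  }
  for (p in seq_len(nr * nc)) {
    d <- sort(unique(dirs[[p]]))
    nb[p] <- length(d)
    for (k in seq_along(d)) if (k <= 3L) gt[[k]][p] <- d[k]
  }
  truth <- stats::setNames(lapply(1:3, function(k)
    map_image(gt[[k]], paste0("dir_", k))), c("dir_1", "dir_2", "dir_3"))
  truth$n_bundles <- map_image(nb, "n_bundles", NaN)
  list(stack = sli_stack(arr, stack_metadata(step_deg = step_deg)),
       truth = truth)
}

.band_masks <- function(nr, nc, frac = 1 / 3) {
  mid_r <- seq(floor(nr * (0.5 - frac / 2)) + 1L, ceiling(nr * (0.5 + frac / 2)))
  mid_c <- seq(floor(nc * (0.5 - frac / 2)) + 1L, ceiling(nc * (0.5 + frac / 2)))
  horiz <- matrix(FALSE, nr, nc); horiz[mid_r, ] <- TRUE
  vert <- matrix(FALSE, nr, nc); vert[, mid_c] <- TRUE
  diag_b <- matrix(FALSE, nr, nc)
  hw <- max(1L, round(min(nr, nc) * frac / 2))
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if (abs((i - nr / 2) + (j - nc / 2)) <= hw) diag_b[i, j] <- TRUE
  list(horiz = horiz, vert = vert, diag = diag_b)
}

#' Crossing-band phantom presets
#'
#' `cross2(angle)` lays two straight tissue bands over each other whose
#' fiber directions differ by `angle` degrees; `cross3(angle)` uses three
#' bands with directions spaced `angle` apart. These emulate stacked
#' sections of optic tract crossed at defined angles (e.g. 90, 70 or 55
#' degrees), with a central overlap region carrying all bundles.
#'
#' @param angle_deg Crossing angle between consecutive bundle directions.
#' @param shape `(rows, cols)` of the phantom (default `c(24, 24)`).
#' @param noise_sd Multiplicative noise sd (default 0, i.e. noiseless).
#' @param seed RNG seed.
#' @param peak_sigma_deg Peak width parameter passed to [bundle()].
#' @return A [phantom_spec()].
#' @name phantom_presets
#' @export
cross2 <- function(angle_deg, shape = c(24L, 24L), noise_sd = 0, seed = 1L,
                   peak_sigma_deg = 20) {
  if (angle_deg <= 0 || angle_deg >= 180) stop("angle must be in (0, 180)")
  m <- .band_masks(shape[1], shape[2])
  d1 <- (90 - angle_deg / 2) %% 180
  d2 <- (90 + angle_deg / 2) %% 180
  phantom_spec(shape, list(
    list(mask = m$horiz, bundles = list(bundle(d1, peak_sigma_deg = peak_sigma_deg))),
    list(mask = m$vert, bundles = list(bundle(d2, peak_sigma_deg = peak_sigma_deg)))),
    noise_sd = noise_sd, seed = seed)
}

#' @rdname phantom_presets
#' @export
cross3 <- function(angle_deg, shape = c(24L, 24L), noise_sd = 0, seed = 1L,
                   peak_sigma_deg = 20) {
  if (angle_deg <= 0 || 2 * angle_deg >= 180)
    stop("angle must be in (0, 90) for three distinct directions")
  m <- .band_masks(shape[1], shape[2])
  d <- (90 + c(-angle_deg, 0, angle_deg)) %% 180
  phantom_spec(shape, list(
    list(mask = m$horiz, bundles = list(bundle(d[1], peak_sigma_deg = peak_sigma_deg))),
    list(mask = m$vert, bundles = list(bundle(d[2], peak_sigma_deg = peak_sigma_deg))),
    list(mask = m$diag, bundles = list(bundle(d[3], peak_sigma_deg = peak_sigma_deg)))),
    noise_sd = noise_sd, seed = seed)
}
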