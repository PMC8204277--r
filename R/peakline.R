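#' Azimuthal intensity profile
#'
#' An `angular_profile` holds the transmitted light intensity of one image
#' pixel as a function of the illumination azimuth phi. The azimuth grid is
#' implicit: sample `i` (0-based) sits at `start_deg + i * step_deg`, with
#' phi = 0 at twelve o'clock and increasing clockwise.
#'
#' @param values Numeric vector of intensities, one per illumination azimuth.
#'   Must have length >= 6, cover the full circle (`length * step_deg == 360`)
#'   and contain only finite values.
#' @param step_deg Angular step between samples in degrees.
#' @param start_deg Azimuth of the first sample in degrees (default 0).
#' @return An object of class `angular_profile`.
#' @examples
#' p <- angular_profile(c(1, 2, 5, 2, 1, 1, 1, 1), step_deg = 45)
#' detect_peaks(p)
#' @export
angular_profile <- function(values, step_deg, start_deg = 0) {
  values <- as.numeric(values)
  if (length(values) < 6L)
    stop("angular profile needs at least 6 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("angular profile contains non-finite values")
  if (abs(length(values) * step_deg - 360) > 1e-9)
    stop("samples must cover 360 degrees: ", length(values), " x ", step_deg,
         " != 360")
  structure(list(values = values, step_deg = step_deg,
                 start_deg = start_deg %% 360),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  cat(sprintf("angular_profile: %d samples, step %g deg, start %g deg\n",
              length(x$values), x$step_deg, x$start_deg))
  print(stats::setNames(x$values,
                        sprintf("%g", (x$start_deg + x$step_deg *
                                       seq_along(x$values) - x$step_deg) %% 360)))
  invisible(x)
}

#' Azimuths of the profile samples
#' @param p An `angular_profile`.
#' @return Numeric vector of azimuths in degrees, in `[0, 360)`.
#' @export
profile_azimuths <- function(p) {
  (p$start_deg + (seq_along(p$values) - 1L) * p$step_deg) %% 360
}

# relative amplitude below which a profile is treated as flat (no peaks)
.FLAT_TOL <- 1e-9

.is_flat <- function(values) {
  m <- mean(abs(values))
  if (m == 0) return(TRUE)
  (max(values) - min(values)) < .FLAT_TOL * m
}

#' Normalize a profile by its mean intensity
#'
#' Divides every sample by the average intensity over all illumination
#' azimuths, so the returned profile has mean 1. This is the standard SLI
#' normalization applied before peak analysis.
#'
#' @param p An `angular_profile` with positive mean.
#' @return An `angular_profile` whose values average to 1.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "angular_profile"))
  m <- mean(p$values)
  if (m <= 0 || all(p$values == 0))
    stop("degenerate profile: mean intensity is not positive")
  angular_profile(p$values / m, p$step_deg, p$start_deg)
}

#' Detect peaks on a circular profile
#'
#' Finds local maxima taking the 360-degree periodicity into account: sample
#' `i` is a peak when it exceeds both circular neighbours. A plateau of equal
#' values that exceeds its two flanking samples yields a single peak at the
#' plateau's centre sample (the lower index for even-length plateaus).
#' Constant (flat) profiles yield no peaks.
#'
#' @param p An `angular_profile`.
#' @return A data frame of class `peak_set` with one row per peak and columns
#'   `index` (0-based sample index), `position_deg` (uncorrected azimuth),
#'   `prominence_rel` and `width_deg` (both `NA` until computed).
#' @seealso [compute_prominences()], [compute_widths()],
#'   [correct_peak_positions()]
#' @export
detect_peaks <- function(p) {
  stopifnot(inherits(p, "angular_profile"))
  idx <- .detect_peaks_idx(p$values)
  .peak_set(idx, p)
}

.peak_set <- function(idx, p) {
  structure(data.frame(index = idx,
                       position_deg = (p$start_deg + idx * p$step_deg) %% 360,
                       prominence_rel = rep(NA_real_, length(idx)),
                       width_deg = rep(NA_real_, length(idx))),
            class = c("peak_set", "data.frame"))
}

# circular local-maximum scan with plateau handling; returns 0-based indices
.detect_peaks_idx <- function(v) {
  n <- length(v)
  if (.is_flat(v)) return(integer(0))
  prev <- v[c(n, seq_len(n - 1L))]
  starts <- which(v != prev)          # 1-based run starts (circular runs)
  if (length(starts) == 0L) return(integer(0))
  out <- integer(0)
  nr <- length(starts)
  for (k in seq_len(nr)) {
    s <- starts[k]
    nxt <- starts[if (k == nr) 1L else k + 1L]
    len <- (nxt - s) %% n
    if (len == 0L) len <- n
    left <- v[if (s == 1L) n else s - 1L]
    right <- v[((s - 1L + len) %% n) + 1L]
    if (v[s] > left && v[s] > right) {
      centre <- (s - 1L + (len - 1L) %/% 2L) %% n   # 0-based, lower of centre pair
      out <- c(out, centre)
    }
  }
  sort(out)
}

#' Compute peak prominences
#'
#' The prominence of a peak is the vertical distance between its top and the
#' higher of the two neighbouring minima, where each minimum is taken between
#' the peak and the next strictly higher point walking circularly left and
#' right (a full circle if no higher point exists). The relative prominence
#' divides by the total signal amplitude `Imax - Imin` of the profile.
#'
#' @param p The `angular_profile` the peaks were detected on.
#' @param peaks A `peak_set` from [detect_peaks()].
#' @return `peaks` with `prominence_rel` filled in.
#' @export
compute_prominences <- function(p, peaks) {
  stopifnot(inherits(p, "angular_profile"), inherits(peaks, "peak_set"))
  v <- p$values
  amp <- max(v) - min(v)
  if (nrow(peaks) > 0L && amp <= 0)
    stop("degenerate profile: zero amplitude")
  peaks$prominence_rel <- vapply(peaks$index, function(i)
    .prominence(v, i) / amp, numeric(1))
  peaks
}

.prominence <- function(v, i) {        # i is 0-based
  n <- length(v)
  vp <- v[i + 1L]
  side_min <- function(dir) {
    lo <- vp
    for (j in seq_len(n - 1L)) {
      val <- v[((i + dir * j) %% n) + 1L]
      if (val > vp) break
      if (val < lo) lo <- val
    }
    lo
  }
  vp - max(side_min(-1L), side_min(1L))
}

#' Keep only prominent peaks
#'
#' Retains peaks whose relative prominence reaches the threshold, by default
#' 8\% of the total signal amplitude. Small peaks below the threshold are
#' treated as noise artifacts.
#'
#' @param peaks A `peak_set` with prominences computed.
#' @param threshold_rel Fraction of the total amplitude in `[0, 1]`.
#' @return The filtered `peak_set`, original order preserved.
#' @export
filter_prominent <- function(peaks, threshold_rel = 0.08) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!is.finite(threshold_rel) || threshold_rel < 0 || threshold_rel > 1)
    stop("threshold must lie in [0, 1]")
  if (anyNA(peaks$prominence_rel) && nrow(peaks) > 0L)
    stop("prominences must be computed before filtering")
  out <- peaks[peaks$prominence_rel >= threshold_rel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Compute peak widths
#'
#' The width is the full width of the peak at the height `peak value -
#' prominence / 2`, with the two crossing positions found by linear
#' interpolation between samples on the circular azimuth grid.
#'
#' @inheritParams compute_prominences
#' @return `peaks` with `width_deg` filled in.
#' @export
compute_widths <- function(p, peaks) {
  stopifnot(inherits(p, "angular_profile"), inherits(peaks, "peak_set"))
  if (nrow(peaks) == 0L) return(peaks)
  if (anyNA(peaks$prominence_rel))
    stop("prominences must be computed before widths")
  v <- p$values
  amp <- max(v) - min(v)
  peaks$width_deg <- vapply(seq_len(nrow(peaks)), function(k) {
    i <- peaks$index[k]
    h <- v[i + 1L] - peaks$prominence_rel[k] * amp / 2
    lr <- .flank_crossings(v, i, h, strict = FALSE)
    (lr[2] - lr[1]) * p$step_deg
  }, numeric(1))
  peaks
}

# Crossing of height h on both flanks of peak i (0-based), walking circularly.
# Returns c(left, right) in unwrapped index units (left <= i <= right).
# strict = TRUE additionally aborts (returns NA) when the flank turns upward
# again before reaching h, i.e. when the cut region would merge with a
# neighbouring peak's tip.
.flank_crossings <- function(v, i, h, strict = TRUE) {
  n <- length(v)
  walk <- function(dir) {
    prev <- v[i + 1L]
    for (j in seq_len(n)) {
      cur <- v[((i + dir * j) %% n) + 1L]
      if (cur <= h) {
        t <- if (prev == cur) 0 else (prev - h) / (prev - cur)
        return(i + dir * (j - 1L + t))
      }
      if (strict && cur > prev) return(NA_real_)
      prev <- cur
    }
    NA_real_
  }
  c(walk(-1L), walk(1L))
}

#' Correct peak positions using the tip geometric centre
#'
#' Reduces the discretization error of the azimuth grid: each peak's raw
#' sample position is replaced by the circular midpoint of the two
#' interpolated crossings of a cut placed just below the peak top, at
#' `peak value - tip_fraction * (Imax - Imin)` (default 6\% of the total
#' amplitude). If a flank rises again before crossing the cut (the tip would
#' merge with a neighbouring peak's tip), the raw sample position is kept.
#'
#' @inheritParams compute_prominences
#' @param tip_fraction Fraction of the total amplitude defining the cut depth.
#' @return `peaks` with `position_deg` set to the corrected azimuths.
#' @export
correct_peak_positions <- function(p, peaks, tip_fraction = 0.06) {
  stopifnot(inherits(p, "angular_profile"), inherits(peaks, "peak_set"))
  if (nrow(peaks) == 0L) return(peaks)
  v <- p$values
  amp <- max(v) - min(v)
  if (amp <= 0) stop("degenerate profile: zero amplitude")
  peaks$position_deg <- vapply(peaks$index, function(i) {
    h <- v[i + 1L] - tip_fraction * amp
    lr <- .flank_crossings(v, i, h, strict = TRUE)
    pos_idx <- if (anyNA(lr)) i else (lr[1] + lr[2]) / 2
    (p$start_deg + pos_idx * p$step_deg) %% 360
  }, numeric(1))
  peaks
}

#' Full single-profile peak analysis
#'
#' Convenience wrapper chaining normalization, peak detection, prominence,
#' width, tip-centre position correction and the prominence filter.
#'
#' @param p An `angular_profile` (raw intensities).
#' @param prominence_threshold Relative prominence cutoff (default 0.08).
#' @param tip_fraction Tip cut depth for the position correction
#'   (default 0.06).
#' @return A list with elements `profile` (normalized), `peaks_all` (all
#'   detected peaks with prominence, width and corrected position) and
#'   `peaks` (the prominent subset).
#' @export
analyze_profile <- function(p, prominence_threshold = 0.08,
                            tip_fraction = 0.06) {
  stopifnot(inherits(p, "angular_profile"))
  if (.is_flat(p$values)) {
    empty <- .peak_set(integer(0), p)
    return(list(profile = p, peaks_all = empty, peaks = empty))
  }
  pn <- normalize_profile(p)
  pk <- detect_peaks(pn)
  pk <- compute_prominences(pn, pk)
  pk <- compute_widths(pn, pk)
  pk <- correct_peak_positions(pn, pk, tip_fraction)
  list(profile = pn, peaks_all = pk,
       peaks = filter_prominent(pk, prominence_threshold))
}
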