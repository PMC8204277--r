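# axial distance between orientation angles in [0, 180)
.axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# circular midpoint of two azimuths (degrees), walking from p1 towards p2
.circ_midpoint <- function(p1, p2) (p1 + ((p2 - p1) %% 360) / 2) %% 360

#' Pair peaks lying roughly opposite each other
#'
#' For profiles with four or six prominent peaks the peaks are paired by
#' sorted order: peak `i` with peak `i + n/2`. The pairing is accepted only
#' if every pair's circular separation is within `tolerance_deg` of 180
#' degrees (default 180 +/- 35, which tolerates slightly inclined fibers);
#' otherwise no pairing is returned.
#'
#' @param positions_deg Sorted corrected peak positions in `[0, 360)`, length
#'   4 or 6.
#' @param tolerance_deg Allowed deviation of each pair separation from 180.
#' @return A two-column matrix of indices into `positions_deg` (one row per
#'   pair), or `NULL` if any pair fails the tolerance.
#' @export
pair_peaks <- function(positions_deg, tolerance_deg = 35) {
  n <- length(positions_deg)
  if (!n %in% c(4L, 6L))
    stop("pairing undefined for ", n, " peaks (needs 4 or 6)")
  if (is.unsorted(positions_deg))
    stop("positions must be sorted ascending")
  h <- n %/% 2L
  pairs <- cbind(seq_len(h), seq_len(h) + h)
  sep <- (positions_deg[pairs[, 2]] - positions_deg[pairs[, 1]]) %% 360
  if (all(abs(sep - 180) <= tolerance_deg)) pairs else NULL
}

#' Fiber directions from prominent peaks
#'
#' Maps a pixel's prominent peaks to up to three axial in-plane fiber
#' directions in `[0, 180)`:
#' one peak gives the peak position itself; two peaks give the circular
#' midpoint of the pair; four or six peaks give one direction per accepted
#' opposite pair (see [pair_peaks()]). For 0, 3, 5 or more than 6 peaks, or
#' when the pairing is rejected, no directions are computed.
#'
#' @param positions_deg Corrected positions of the prominent peaks, degrees.
#' @param pair_tolerance_deg Passed to [pair_peaks()].
#' @return A list with `directions_deg` (sorted ascending, possibly empty)
#'   and `n_used_peaks`.
#' @export
directions_from_peaks <- function(positions_deg, pair_tolerance_deg = 35) {
  pos <- sort(positions_deg %% 360)
  n <- length(pos)
  dirs <- if (n == 1L) {
    pos %% 180
  } else if (n == 2L) {
    .circ_midpoint(pos[1], pos[2]) %% 180
  } else if (n %in% c(4L, 6L)) {
    pairs <- pair_peaks(pos, pair_tolerance_deg)
    if (is.null(pairs)) numeric(0)
    else .circ_midpoint(pos[pairs[, 1]], pos[pairs[, 2]]) %% 180
  } else numeric(0)
  list(directions_deg = sort(dirs),
       n_used_peaks = if (length(dirs)) n else 0L)
}

#' Distance between two prominent peaks
#'
#' Defined for pixels with one or two prominent peaks: two peaks give their
#' circular separation folded to `(0, 180]`; a single peak gives 0 (the two
#' scattering peaks have merged); any other count gives `NaN`.
#'
#' @param positions_deg Corrected positions of the prominent peaks.
#' @return Distance in degrees, 0, or `NaN`.
#' @export
peak_distance <- function(positions_deg) {
  n <- length(positions_deg)
  if (n == 1L) return(0)
  if (n != 2L) return(NaN)
  s <- abs(positions_deg[2] - positions_deg[1]) %% 360
  min(s, 360 - s)
}

.MAP_NAMES <- c("avg", "peaks_all", "peaks_prominent", "prominence_avg",
                "width_avg", "distance", "dir_1", "dir_2", "dir_3")

#' Build the full parameter-map set of a stack
#'
#' Runs the per-pixel pipeline (normalize, detect peaks, prominences, widths,
#' tip-centre position correction, prominence filter, direction rules) over
#' every pixel and assembles nine parameter maps:
#' \describe{
#'   \item{avg}{mean non-normalized intensity (overall scattering)}
#'   \item{peaks_all}{number of detected peaks at prominence >= 0}
#'   \item{peaks_prominent}{number of peaks at the prominence threshold}
#'   \item{prominence_avg}{mean relative prominence over prominent peaks}
#'   \item{width_avg}{mean width (degrees) over prominent peaks}
#'   \item{distance}{separation of two prominent peaks (degrees); 0 for one
#'     peak; NaN otherwise}
#'   \item{dir_1, dir_2, dir_3}{up to three axial fiber directions, sorted
#'     ascending; sentinel -1 where not computed}
#' }
#' Flat pixels (relative amplitude below 1e-9) carry sentinels everywhere
#' except `avg`; their peak counts are 0.
#'
#' @param stack An [sli_stack()].
#' @param prominence_threshold Relative prominence cutoff (default 0.08).
#' @param tip_fraction Tip cut depth for position correction (default 0.06).
#' @param pair_tolerance_deg Pair-separation tolerance (default 35).
#' @return A named list of [map_image()]s of class `parameter_maps`.
#' @export
build_parameter_maps <- function(stack, prominence_threshold = 0.08,
                                 tip_fraction = 0.06,
                                 pair_tolerance_deg = 35) {
  stopifnot(inherits(stack, "sli_stack"))
  d <- dim(stack$data)
  nr <- d[1]; nc <- d[2]
  step <- stack$meta$step_deg; start <- stack$meta$start_deg
  m <- stats::setNames(
    lapply(.MAP_NAMES, function(nm)
      matrix(if (grepl("^dir", nm)) -1 else NaN, nr, nc)), .MAP_NAMES)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- stack$data[i, j, ]
      m$avg[i, j] <- mean(v)
      if (.is_flat(v)) { m$peaks_all[i, j] <- 0; m$peaks_prominent[i, j] <- 0
                         next }
      res <- analyze_profile(angular_profile(v, step, start),
                             prominence_threshold, tip_fraction)
      m$peaks_all[i, j] <- nrow(res$peaks_all)
      pk <- res$peaks
      m$peaks_prominent[i, j] <- nrow(pk)
      if (nrow(pk) > 0L) {
        m$prominence_avg[i, j] <- mean(pk$prominence_rel)
        m$width_avg[i, j] <- mean(pk$width_deg)
        m$distance[i, j] <- peak_distance(pk$position_deg)
        dirs <- directions_from_peaks(pk$position_deg,
                                      pair_tolerance_deg)$directions_deg
        for (k in seq_along(dirs))
          if (k <= 3L) m[[paste0("dir_", k)]][i, j] <- dirs[k]
      }
    }
  }
  structure(Map(map_image, m, .MAP_NAMES), class = "parameter_maps",
            names = .MAP_NAMES)
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- dim(x[[1]]$data)
  cat(sprintf("parameter_maps: %d maps of %d x %d pixels (%s)\n",
              length(x), d[1], d[2], paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Axial median filter for direction maps
#'
#' Replaces every pixel by the axial median of the defined direction values
#' in its `window` x `window` neighbourhood (clipped at the image border).
#' The axial median is the window value minimizing the summed axial distance
#' `d(a, b) = min(|a - b|, 180 - |a - b|)` to all defined window values; ties
#' resolve to the smaller angle. Windows without any defined value stay at
#' the sentinel.
#'
#' @param dir_map A direction [map_image()] (sentinel -1).
#' @param window Odd window edge length (default 3).
#' @return The filtered [map_image()].
#' @export
median_direction_filter <- function(dir_map, window = 3L) {
  stopifnot(inherits(dir_map, "map_image"))
  if (window %% 2L == 0L || window < 1L)
    stop("window size must be odd and positive")
  x <- dir_map$data
  nr <- nrow(x); nc <- ncol(x)
  h <- (window - 1L) %/% 2L
  out <- matrix(dir_map$undefined_sentinel, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      w <- x[max(1L, i - h):min(nr, i + h), max(1L, j - h):min(nc, j + h)]
      vals <- w[w != dir_map$undefined_sentinel]
      if (length(vals) == 0L) next
      out[i, j] <- axial_median(vals)
    }
  }
  map_image(out, dir_map$name, dir_map$undefined_sentinel)
}

#' Axial median of orientation angles
#'
#' The element of `values` minimizing the sum of axial distances to all
#' elements; ties resolve to the smaller angle.
#'
#' @param values Orientation angles in `[0, 180)`.
#' @return One element of `values`.
#' @export
axial_median <- function(values) {
  stopifnot(length(values) > 0L)
  cost <- vapply(values, function(a) sum(.axial_dist(a, values)), numeric(1))
  cand <- values[cost == min(cost)]
  min(cand)
}

#' Sample direction vectors for overlay rendering
#'
#' Produces one unit line segment per defined direction for every
#' `stride`-th pixel, for plotting fiber directions over a background map.
#' Image coordinates put x along columns and y along rows (increasing
#' downwards); an azimuth of 0 (twelve o'clock) points up, increasing
#' clockwise, so a direction phi maps to the unit vector
#' `(sin phi, -cos phi)`.
#'
#' @param maps A `parameter_maps` set (or named list with `dir_1`..`dir_3`).
#' @param stride Sample every `stride`-th pixel in both axes.
#' @return A data frame with columns `row`, `col`, `direction_deg`, `x0`,
#'   `y0`, `x1`, `y1`.
#' @export
sample_vector_overlay <- function(maps, stride = 1L) {
  if (stride < 1L) stop("stride must be >= 1")
  dir_names <- intersect(c("dir_1", "dir_2", "dir_3"), names(maps))
  rows <- integer(0); cols <- integer(0); dirs <- numeric(0)
  for (nm in dir_names) {
    m <- maps[[nm]]$data
    ri <- seq(1L, nrow(m), by = stride)
    ci <- seq(1L, ncol(m), by = stride)
    sub <- m[ri, ci, drop = FALSE]
    def <- which(sub != -1, arr.ind = TRUE)
    if (nrow(def) == 0L) next
    rows <- c(rows, ri[def[, 1]])
    cols <- c(cols, ci[def[, 2]])
    dirs <- c(dirs, sub[def])
  }
  rad <- dirs * pi / 180
  dx <- sin(rad) / 2; dy <- -cos(rad) / 2
  data.frame(row = rows, col = cols, direction_deg = dirs,
             x0 = cols - dx, y0 = rows - dy, x1 = cols + dx, y1 = rows + dy)
}
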