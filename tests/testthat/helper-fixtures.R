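# Shared fixtures and independent oracles, built in code.

# 24-sample profile (15 deg step) with two symmetric peaks at 30 and 210 deg
F24 <- c(1, 2, 5, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 5, 2, 1, 1, 1, 1, 1, 1, 1, 1)
# F24 with an asymmetric right flank on the first peak
F24b <- replace(F24, 4, 4)

prof <- function(v, step = 360 / length(v), start = 0)
  angular_profile(v, step, start)

# Independent brute-force oracle for circular peak detection: checks every
# sample individually by walking both flanks of its plateau. Returns 0-based
# indices of plateau-centre peaks (lower centre sample for even plateaus).
brute_peaks <- function(v) {
  n <- length(v)
  if (length(unique(v)) == 1L) return(integer(0))
  out <- integer(0)
  for (i in 0:(n - 1L)) {
    l <- 1L
    while (l < n && v[((i - l) %% n) + 1L] == v[i + 1L]) l <- l + 1L
    r <- 1L
    while (r < n && v[((i + r) %% n) + 1L] == v[i + 1L]) r <- r + 1L
    if (v[((i - l) %% n) + 1L] >= v[i + 1L]) next
    if (v[((i + r) %% n) + 1L] >= v[i + 1L]) next
    plateau_start <- i - l + 1L
    plateau_len <- l + r - 1L
    centre <- (plateau_start + (plateau_len - 1L) %/% 2L) %% n
    if (i == centre %% n) out <- c(out, i)
  }
  sort(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# axial error between two orientation angles, in [0, 90]
axial_err <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# signed circular error wrapped to (-180, 180]
wrap180 <- function(d) {
  w <- d %% 360
  ifelse(w > 180, w - 360, w)
}

# per-peak signed position errors of a corrected peak set against true
# peak azimuths (each detected peak matched to its nearest true peak)
peak_position_errors <- function(detected_deg, true_deg) {
  vapply(detected_deg, function(x) {
    d <- wrap180(x - true_deg)
    d[which.min(abs(d))]
  }, numeric(1))
}

# small noiseless two-peak profile generator used by several tests
two_peak_profile <- function(phi, sigma = 20, step = 15)
  synth_profile(bundle(phi, 90, peak_sigma_deg = sigma), step_deg = step)$profile
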