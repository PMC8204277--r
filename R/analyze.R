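#' Configuration for a full analysis run
#'
#' Bundles every tunable of the per-pixel pipeline plus I/O locations, so a
#' run is reproducible from its config alone.
#'
#' @param input Path to the input stack (TIFF or NIfTI).
#' @param out_dir Output directory for maps and the run report.
#' @param step_deg Azimuth step override (`NULL` = sidecar/default).
#' @param prominence_threshold Relative prominence cutoff (default 0.08).
#' @param tip_fraction Tip cut depth for position correction (default 0.06).
#' @param pair_tolerance_deg Pair-separation tolerance (default 35).
#' @param angle_offset_deg Fixed offset added to every output direction
#'   (mounting correction, default 0).
#' @param mirror If `TRUE`, directions are mirrored (`180 - phi`) before the
#'   offset is applied.
#' @param mask_avg_threshold Pixels whose average intensity falls below this
#'   value are masked out of all maps except `avg` (`NULL` = no masking).
#' @param prefix File-name prefix for the written maps.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, out_dir, step_deg = NULL,
                       prominence_threshold = 0.08, tip_fraction = 0.06,
                       pair_tolerance_deg = 35, angle_offset_deg = 0,
                       mirror = FALSE, mask_avg_threshold = NULL,
                       prefix = "slimaps") {
  structure(list(input = input, out_dir = out_dir, step_deg = step_deg,
                 prominence_threshold = prominence_threshold,
                 tip_fraction = tip_fraction,
                 pair_tolerance_deg = pair_tolerance_deg,
                 angle_offset_deg = angle_offset_deg, mirror = isTRUE(mirror),
                 mask_avg_threshold = mask_avg_threshold, prefix = prefix),
            class = "run_config")
}

.apply_frame_convention <- function(dir_map, angle_offset_deg, mirror) {
  x <- dir_map$data
  def <- x != -1
  v <- x[def]
  if (mirror) v <- (180 - v) %% 180
  v <- (v + angle_offset_deg) %% 180
  x[def] <- v
  map_image(x, dir_map$name, -1)
}

#' Run the full analysis pipeline on a stack file
#'
#' Reads the stack, builds all nine parameter maps, applies the
#' frame-convention options (mirror, angle offset) to the direction maps,
#' optionally masks low-intensity pixels, writes the maps as float32 TIFFs
#' and a JSON run report with the configuration and per-map summary
#' statistics.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `maps` (the `parameter_maps`), `files`
#'   (written paths) and `report` (the report list).
#' @export
run_analyze <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  override <- if (!is.null(cfg$step_deg)) stack_metadata(step_deg = cfg$step_deg)
  stack <- read_stack(cfg$input, meta_override = override)
  maps <- build_parameter_maps(stack,
                               prominence_threshold = cfg$prominence_threshold,
                               tip_fraction = cfg$tip_fraction,
                               pair_tolerance_deg = cfg$pair_tolerance_deg)
  if (cfg$mirror || cfg$angle_offset_deg != 0)
    for (nm in c("dir_1", "dir_2", "dir_3"))
      maps[[nm]] <- .apply_frame_convention(maps[[nm]], cfg$angle_offset_deg,
                                            cfg$mirror)
  if (!is.null(cfg$mask_avg_threshold)) {
    low <- maps$avg$data < cfg$mask_avg_threshold
    for (nm in names(maps)) {
      if (nm == "avg") next
      x <- maps[[nm]]$data
      x[low] <- maps[[nm]]$undefined_sentinel
      maps[[nm]] <- map_image(x, nm, maps[[nm]]$undefined_sentinel)
    }
  }
  files <- write_maps(maps, cfg$out_dir, prefix = cfg$prefix)
  if (all(maps$peaks_all$data == 0, na.rm = TRUE))
    warning("no peaks detected anywhere: stack appears flat")
  stats_of <- function(m) {
    def <- map_defined(m)
    list(defined = sum(def),
         min = if (any(def)) min(m$data[def]) else NA,
         max = if (any(def)) max(m$data[def]) else NA,
         mean = if (any(def)) mean(m$data[def]) else NA)
  }
  report <- list(package = "slimaps",
                 version = as.character(utils::packageVersion("slimaps")),
                 r_version = R.version.string,
                 config = unclass(cfg),
                 shape = dim(stack$data),
                 map_stats = lapply(maps, stats_of))
  report_path <- file.path(cfg$out_dir, paste0(cfg$prefix, "_report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(list(maps = maps, files = c(files, report_path), report = report))
}

#' Render a direction-vector overlay to PNG
#'
#' Draws unit direction segments (see [sample_vector_overlay()]) over an
#' optional background map, using image coordinates (origin top-left).
#'
#' @param maps A `parameter_maps` set.
#' @param path Output PNG path.
#' @param stride Pixel sampling stride (default 1).
#' @param background Name of the background map (default `"avg"`).
#' @return `path`, invisibly.
#' @export
render_overlay <- function(maps, path, stride = 1L, background = "avg") {
  seg <- sample_vector_overlay(maps, stride)
  bg <- maps[[background]]$data
  grDevices::png(path, width = 100 + 8 * ncol(bg), height = 100 + 8 * nrow(bg))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 2))
  graphics::image(t(bg)[, nrow(bg):1, drop = FALSE],
                  col = grDevices::gray.colors(64), axes = FALSE,
                  main = "fiber directions")
  if (nrow(seg) > 0L) {
    nr <- nrow(bg); nc <- ncol(bg)
    to_x <- function(c0) (c0 - 0.5) / nc
    to_y <- function(r0) 1 - (r0 - 0.5) / nr
    graphics::segments(to_x(seg$x0), to_y(seg$y0), to_x(seg$x1), to_y(seg$y1),
                       col = "blue", lwd = 2)
  }
  invisible(path)
}
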