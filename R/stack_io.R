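#' Angular metadata of an SLI measurement
#'
#' Describes the illumination-azimuth grid of an image stack: the angular
#' step between consecutive images, the azimuth of the first image (0 =
#' twelve o'clock) and the rotation sense. The standard measurement uses
#' 15-degree steps starting at twelve o'clock, rotating clockwise.
#'
#' @param step_deg Angular step between illumination azimuths, degrees; must
#'   divide 360.
#' @param start_deg Azimuth of the first image, degrees.
#' @param clockwise Logical rotation sense flag.
#' @param pixel_size_um Physical pixel size in micrometers, or `NA`.
#' @return An object of class `stack_metadata`.
#' @export
stack_metadata <- function(step_deg = 15, start_deg = 0, clockwise = TRUE,
                           pixel_size_um = NA_real_) {
  if (!is.finite(step_deg) || step_deg <= 0)
    stop("step_deg must be positive")
  if (abs(360 / step_deg - round(360 / step_deg)) > 1e-9)
    stop("360 must be divisible by step_deg, got ", step_deg)
  structure(list(step_deg = step_deg, start_deg = start_deg %% 360,
                 clockwise = isTRUE(clockwise),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "stack_metadata")
}

#' SLI image stack
#'
#' A 3D array of transmitted light intensities with axes (row, column,
#' angle): one 2D image per illumination azimuth. The angle axis follows the
#' clockwise azimuth grid described by the metadata.
#'
#' @param data 3D nonnegative array, angle as last axis (length >= 6).
#' @param meta A [stack_metadata()] object.
#' @return An object of class `sli_stack`.
#' @export
sli_stack <- function(data, meta = stack_metadata()) {
  stopifnot(inherits(meta, "stack_metadata"))
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop("stack data must be a 3D array (row, column, angle)")
  n_ang <- dim(data)[3]
  if (n_ang < 6L) stop("angle count < 6: got ", n_ang, " images")
  if (abs(n_ang * meta$step_deg - 360) > 1e-9)
    stop("step x count != 360: ", n_ang, " x ", meta$step_deg)
  if (!all(is.finite(data))) stop("stack contains non-finite intensities")
  if (any(data < 0)) stop("stack contains negative intensities")
  structure(list(data = data, meta = meta), class = "sli_stack")
}

#' @export
print.sli_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sli_stack: %d x %d pixels, %d azimuths (step %g deg, start %g deg, %s)\n",
              d[1], d[2], d[3], x$meta$step_deg, x$meta$start_deg,
              if (x$meta$clockwise) "clockwise" else "counter-clockwise"))
  invisible(x)
}

#' Extract the angular profile of one pixel
#' @param stack An `sli_stack`.
#' @param row,col 1-based pixel coordinates.
#' @return An [angular_profile()].
#' @export
pixel_profile <- function(stack, row, col) {
  stopifnot(inherits(stack, "sli_stack"))
  angular_profile(stack$data[row, col, ], stack$meta$step_deg,
                  stack$meta$start_deg)
}

#' 2D parameter map with an undefined-pixel sentinel
#'
#' @param data 2D numeric matrix.
#' @param name Map identifier (e.g. `"dir_1"`, `"avg"`).
#' @param undefined_sentinel Value marking pixels without a result: -1 for
#'   direction maps (impossible in `[0, 180)`), `NaN` otherwise.
#' @return An object of class `map_image`.
#' @export
map_image <- function(data, name,
                      undefined_sentinel = if (grepl("^dir", name)) -1 else NaN) {
  stopifnot(is.matrix(data))
  storage.mode(data) <- "double"
  if (grepl("^dir", name)) {
    def <- data != undefined_sentinel
    if (any(def & (data < 0 | data >= 180), na.rm = TRUE))
      stop("direction map values must lie in [0, 180) or equal the sentinel")
  }
  structure(list(data = data, name = name,
                 undefined_sentinel = undefined_sentinel),
            class = "map_image")
}

#' Logical mask of defined pixels in a map
#' @param m A `map_image`.
#' @return Logical matrix, `TRUE` where the pixel holds a result.
#' @export
map_defined <- function(m) {
  stopifnot(inherits(m, "map_image"))
  if (is.nan(m$undefined_sentinel)) !is.na(m$data)
  else m$data != m$undefined_sentinel & !is.na(m$data)
}

.strip_ext <- function(path) {
  p <- sub("\\.gz$", "", path)
  sub("\\.[A-Za-z0-9]+$", "", p)
}

.sidecar_path <- function(path) paste0(.strip_ext(path), ".meta.json")

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  j <- jsonlite::read_json(sc, simplifyVector = TRUE)
  stack_metadata(step_deg = j$step_deg %||% 15,
                 start_deg = j$start_deg %||% 0,
                 clockwise = j$clockwise %||% TRUE,
                 pixel_size_um = j$pixel_size_um %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an SLI image stack
#'
#' Reads a multi-page TIFF or a NIfTI volume together with its angular
#' metadata. Metadata is taken from a JSON sidecar `<stem>.meta.json` next to
#' the file if present, else from `meta_override`, else the defaults of the
#' standard measurement (15-degree steps, start at twelve o'clock,
#' clockwise). Counter-clockwise stacks are normalized on input by reordering
#' the angle axis onto the equivalent clockwise grid, so in-memory stacks are
#' always clockwise.
#'
#' @param path Path to a `.tif`/`.tiff` (multi-page, grayscale) or
#'   `.nii`/`.nii.gz` file, angle as page/last axis.
#' @param meta_override Optional [stack_metadata()] used when no sidecar
#'   exists.
#' @return An [sli_stack()].
#' @export
read_stack <- function(path, meta_override = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  meta <- .read_sidecar(path) %||% meta_override %||% stack_metadata()
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  arr <- if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff_pages(path)
    a <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) a[, , k] <- pages[[k]]
    a
  } else if (ext %in% c("nii", "hdr", "img")) {
    a <- as.array(RNifti::readNifti(path))
    a <- array(as.numeric(a), dim(a))
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
    a
  } else stop("unsupported stack format: .", ext,
              " (use multi-page TIFF or NIfTI)")
  if (!meta$clockwise) {
    n <- dim(arr)[3]
    arr <- arr[, , c(1L, n:2L), drop = FALSE]
    meta$clockwise <- TRUE
  }
  sli_stack(arr, meta)
}

#' Write an SLI stack with its metadata sidecar
#'
#' @param stack An [sli_stack()].
#' @param path Output path; `.tif` writes a multi-page float32 TIFF,
#'   `.nii`/`.nii.gz` a NIfTI volume. A `<stem>.meta.json` sidecar records the
#'   angular metadata.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "sli_stack"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    d <- dim(stack$data)
    pages <- lapply(seq_len(d[3]),
                    function(k) matrix(stack$data[, , k], d[1], d[2]))
    write_tiff_pages(pages, path)
  } else if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(stack$data, datatype = "float"), path)
  } else stop("unsupported stack format: .", ext)
  m <- stack$meta
  jsonlite::write_json(list(step_deg = m$step_deg, start_deg = m$start_deg,
                            clockwise = m$clockwise,
                            pixel_size_um = m$pixel_size_um),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write parameter maps to disk
#'
#' Each map is written as a single-page 32-bit float TIFF named
#' `<prefix>_<mapname>.tif`; sentinel values are preserved bit-exactly.
#'
#' @param maps A named list of [map_image()] objects (e.g. a
#'   `parameter_maps` set from [build_parameter_maps()]).
#' @param out_dir Output directory, created if needed.
#' @param prefix File-name prefix (default `"slimaps"`).
#' @param format `"tiff"` (default) or `"nifti"`.
#' @return Character vector of the written file paths.
#' @export
write_maps <- function(maps, out_dir, prefix = "slimaps", format = "tiff") {
  maps <- unclass(maps)
  maps <- Filter(function(m) inherits(m, "map_image"), maps)
  if (length(maps) == 0L) stop("no maps to write")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  format <- match.arg(format, c("tiff", "nifti"))
  vapply(maps, function(m) {
    f <- file.path(out_dir, paste0(prefix, "_", m$name,
                                   if (format == "tiff") ".tif" else ".nii"))
    if (format == "tiff") write_tiff_pages(m$data, f)
    else RNifti::writeNifti(RNifti::asNifti(m$data, datatype = "double"), f)
    f
  }, character(1))
}

#' Read one parameter map written by [write_maps()]
#'
#' @param path Path to a single-page float TIFF or NIfTI map.
#' @param name Map name; inferred from the file name if omitted.
#' @return A [map_image()].
#' @export
read_map <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("^[^_]*_", "", .strip_ext(basename(path)))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  data <- if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff_pages(path)
    if (length(pages) != 1L) stop("expected a single-page map, got ",
                                  length(pages), " pages")
    pages[[1]]
  } else {
    a <- as.array(RNifti::readNifti(path))
    a <- array(as.numeric(a), dim(a))
    if (length(dim(a)) > 2L) dim(a) <- dim(a)[1:2]
    a
  }
  map_image(data, name)
}
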