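#' Write and read image stacks as multi-page TIFF plus JSON sidecar
#'
#' Integer photon-count cubes are stored as 16-bit pages, floating-point
#' maps as 32-bit float pages rescaled into the unit interval (TIFF float
#' storage here is unit-ranged), with the affine `scale`/`offset` — and a
#' zero sentinel for `NA` pixels — recorded in the sidecar and undone on
#' read. The third array dimension becomes the page dimension. The JSON
#' sidecar (`<path>.json`) records the page semantics (`"time_bins"`,
#' `"sweep_angles"`, `"frames"`, or `"maps"`), pixel size and acquisition
#' metadata, so that the acquisition context can be reconstructed exactly
#' on read. Counts round-trip bit-identically; maps round-trip to 32-bit
#' float precision.
#'
#' @param cube 2-D or 3-D numeric array.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @param page_semantics What the pages mean.
#' @param acq Optional [acquisition_context()] stored in the sidecar.
#' @param extra Named list of extra sidecar fields (e.g. sweep angles,
#'   frame times).
#' @return `path`, invisibly.
#' @export
write_stack <- function(cube, path,
                        page_semantics = c("time_bins", "sweep_angles",
                                           "frames", "maps"),
                        acq = NULL, extra = list()) {
  page_semantics <- match.arg(page_semantics)
  if (length(dim(cube)) == 2) dim(cube) <- c(dim(cube), 1)
  stopifnot(length(dim(cube)) == 3)
  integer_data <- all(cube == round(cube), na.rm = TRUE) &&
    max(cube, na.rm = TRUE) <= 65535 && min(cube, na.rm = TRUE) >= 0 &&
    !anyNA(cube)
  if (integer_data) {
    pages <- lapply(seq_len(dim(cube)[3]), function(k) cube[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    offset <- 0; scale <- 1
  } else {
    # map to [0.25, 1]; NA pixels become the 0 sentinel
    rng <- range(cube, finite = TRUE)
    offset <- rng[1]
    scale <- max(rng[2] - rng[1], .Machine$double.eps)
    scaled <- 0.25 + 0.75 * (cube - offset) / scale
    scaled[is.na(cube)] <- 0
    pages <- lapply(seq_len(dim(cube)[3]), function(k) scaled[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  }
  side <- c(list(page_semantics = page_semantics,
                 n_pages = dim(cube)[3],
                 shape = dim(cube)[1:2],
                 dtype = if (integer_data) "uint16" else "float32",
                 offset = offset, scale = scale),
            extra)
  if (!is.null(acq))
    side$acq <- acq[c("pixel_size", "n_time_bins", "time_window",
                      "pulse_period", "exposure_scale", "dark_counts",
                      "psf_sigma")]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param path Path to a TIFF written by [write_stack()]; its `.json`
#'   sidecar must exist.
#' @return For `read_stack`: list with `data` (3-D array; counts are
#'   integer), `sidecar` (parsed JSON), and `acq` (an
#'   [acquisition_context()] if the sidecar holds one, else `NULL`).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stop("schema error: missing sidecar ", sc_path)
  side <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (fld in c("page_semantics", "n_pages", "shape", "dtype"))
    if (is.null(side[[fld]]))
      stop("schema error: sidecar missing field `", fld, "`")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (identical(side$dtype, "uint16")) {
    arr <- array(as.integer(round(arr * 65535)), dim = dim(arr))
  } else {
    na <- arr < 0.125 # the NA sentinel, with float-rounding headroom
    arr <- side$offset + (arr - 0.25) / 0.75 * side$scale
    arr[na] <- NA_real_
  }
  acq <- NULL
  if (!is.null(side$acq))
    acq <- do.call(acquisition_context, side$acq)
  list(data = arr, sidecar = side, acq = acq)
}
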