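#' Detect podosomes by intensity-based depletion thresholding
#'
#' Podosome cores exclude surface probes, so they appear as dark disks in
#' the probe intensity (or relative density) image. Pixels below
#' `threshold * background` are segmented into connected components;
#' touching components are separated by a distance-transform watershed with
#' a 2-pixel-wide dividing line; components are filtered to a plausible area
#' range; and an annular ring mask is attached to each core (from the core
#' boundary out to `core_radius + ring_width`, capped at `ring_max_radius`).
#'
#' @param intensity Image (matrix): probe intensity or relative density.
#' @param background Scalar (or matrix) background level of the cell-free or
#'   undisturbed bilayer; must be positive.
#' @param pixel_size Pixel edge (um).
#' @param threshold Depletion threshold as a fraction of background; pixels
#'   strictly below `threshold * background` are candidate core pixels.
#' @param min_area,max_area Area filter for cores (um^2).
#' @param ring_width Ring annulus width beyond the core radius (um).
#' @param ring_max_radius Cap on the ring outer radius (um).
#' @param frame Frame index stored in the records.
#' @return List of `podosome_record` objects: `id`, `frame`, `centroid`
#'   (row, col in px), `core_radius` (um, effective radius of the segmented
#'   area), `area` (um^2), `core_mask`, `ring_mask` (disjoint from the
#'   core), `flags`.
#' @export
detect_podosomes <- function(intensity, background, pixel_size = 0.1,
                             threshold = 0.7, min_area = 0.05,
                             max_area = 3, ring_width = 0.5,
                             ring_max_radius = 1.0, frame = 1L) {
  if (any(background <= 0)) stop("background must be positive")
  if (any(!is.finite(intensity))) stop("intensity image must be finite")
  mask <- intensity < threshold * background
  if (!any(mask)) return(list())

  lab <- split_touching(mask)
  px_area <- pixel_size ^ 2
  recs <- list()
  id <- 0L
  for (l in setdiff(sort(unique(as.vector(lab))), 0)) {
    sel <- lab == l
    area <- sum(sel) * px_area
    if (area < min_area || area > max_area) next
    id <- id + 1L
    idx <- which(sel, arr.ind = TRUE)
    ctr <- colMeans(idx)
    core_radius <- sqrt(area / pi)
    r_out_px <- min(core_radius + ring_width, ring_max_radius) / pixel_size
    d2 <- outer((seq_len(nrow(mask)) - ctr[1]) ^ 2,
                (seq_len(ncol(mask)) - ctr[2]) ^ 2, `+`)
    ring <- d2 <= r_out_px ^ 2 & !sel & d2 > (core_radius / pixel_size) ^ 2
    recs[[id]] <- structure(
      list(id = id, frame = frame, centroid = unname(ctr),
           core_radius = core_radius, area = area,
           core_mask = sel, ring_mask = ring, flags = character(0)),
      class = "podosome_record")
  }
  recs
}

# Label a binary mask; components touching each other are split along
# watershed lines of the distance transform, widened to a 2-pixel barrier.
split_touching <- function(mask) {
  m <- EBImage::Image(mask * 1)
  dm <- EBImage::distmap(m)
  ws <- EBImage::watershed(dm, tolerance = 0.5, ext = 1)
  lab <- EBImage::imageData(ws)
  # carve a 2-px line between adjacent different labels
  if (max(lab) > 1) {
    nr <- nrow(lab); nc <- ncol(lab)
    barrier <- matrix(FALSE, nr, nc)
    for (dr in c(-1L, 0L, 1L)) for (dc in c(-1L, 0L, 1L)) {
      if (dr == 0 && dc == 0) next
      sh <- shift_mat(lab, dr, dc)
      barrier <- barrier | (lab > 0 & sh > 0 & sh != lab)
    }
    lab[barrier] <- 0
  }
  lab
}

shift_mat <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rsrc <- rs - dr; csrc <- cs - dc
  ok_r <- rsrc >= 1 & rsrc <= nrow(m); ok_c <- csrc >= 1 & csrc <= ncol(m)
  out[rs[ok_r], cs[ok_c]] <- m[rsrc[ok_r], csrc[ok_c]]
  out
}

#' Depletion depth and effective core radius of a podosome
#'
#' Quantifies core depletion the standard way: the detected centroid is
#' dilated by 2 pixels and the mean intensity inside that small disk is
#' compared with the local background,
#' `depletion_pct = 100 * (1 - mean(I[disk]) / background)`. The effective
#' core radius is recomputed from the segmented core area.
#'
#' @param record A `podosome_record`.
#' @param intensity Image the record was detected on.
#' @param background Scalar background level.
#' @param dilate_px Dilation radius of the centroid disk (px).
#' @return List with `depletion_pct` and `core_radius` (um).
#' @export
depletion_metrics <- function(record, intensity, background, dilate_px = 2) {
  ctr <- record$centroid
  nr <- nrow(intensity); nc <- ncol(intensity)
  if (ctr[1] < 1 + dilate_px || ctr[1] > nr - dilate_px ||
      ctr[2] < 1 + dilate_px || ctr[2] > nc - dilate_px)
    stop("centroid-dilated disk exits the image")
  d2 <- outer((seq_len(nr) - ctr[1]) ^ 2, (seq_len(nc) - ctr[2]) ^ 2, `+`)
  disk <- d2 <= dilate_px ^ 2
  list(depletion_pct = 100 * (1 - mean(intensity[disk]) / background),
       core_radius = record$core_radius)
}

#' Ring tension and density statistics
#'
#' Per-podosome means of the percent-open and relative-density maps over
#' valid ring pixels, and the per-cell unweighted mean of podosome means.
#' Podosomes with fewer than `min_valid_pixels` valid ring pixels are
#' flagged and excluded from the cell summary.
#'
#' @param records List of `podosome_record`s.
#' @param percent_open Percent-open map (matrix).
#' @param density Relative-density map (matrix), or `NULL`.
#' @param valid_mask Logical validity mask aligned with the maps.
#' @param min_valid_pixels Minimum valid ring pixels per podosome.
#' @return List with `per_podosome` data frame (`id`, `mean_F`,
#'   `mean_density`, `n_valid`, `excluded`) and scalars `cell_mean_F`,
#'   `cell_mean_density`.
#' @export
ring_tension_stats <- function(records, percent_open, density = NULL,
                               valid_mask = NULL, min_valid_pixels = 5) {
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, nrow(percent_open), ncol(percent_open))
  rows <- lapply(records, function(rec) {
    sel <- rec$ring_mask & valid_mask & !is.na(percent_open)
    n <- sum(sel)
    data.frame(id = rec$id,
               mean_F = if (n) mean(percent_open[sel]) else NA_real_,
               mean_density = if (n && !is.null(density))
                 mean(density[sel]) else NA_real_,
               n_valid = n, excluded = n < min_valid_pixels)
  })
  per <- do.call(rbind, rows)
  keep <- !per$excluded
  if (!any(keep)) warning("no podosome has enough valid ring pixels")
  list(per_podosome = per,
       cell_mean_F = mean(per$mean_F[keep]),
       cell_mean_density = mean(per$mean_density[keep]))
}

#' Detect tension-free receptor clusters
#'
#' Bright puncta (relative density above `density_threshold`) within a size
#' range that do not contain or abut a depletion zone: any component whose
#' footprint comes within `exclusion_radius` of a detected podosome centroid
#' is discarded.
#'
#' @param density Relative-density (or intensity) image.
#' @param records Podosome records used for exclusion.
#' @param pixel_size Pixel edge (um).
#' @param density_threshold Minimum relative density of cluster pixels.
#' @param min_area,max_area Cluster area range (um^2).
#' @param exclusion_radius Distance (um) to the nearest podosome centroid
#'   below which a candidate is rejected.
#' @param dilate_px Radius (px) of the centroid disk over which
#'   `mean_density` is measured — the same convention as core depletion,
#'   which keeps the estimate free of diffraction-diluted edge pixels.
#' @return List of `cluster_record` objects: `id`, `frame`, `centroid`,
#'   `area` (um^2), `mask`, `mean_density` (centroid-disk mean).
#' @export
detect_clusters <- function(density, records = list(), pixel_size = 0.1,
                            density_threshold = 1.5, min_area = 0.05,
                            max_area = 5, exclusion_radius = 1.0,
                            dilate_px = 2) {
  mask <- density > density_threshold
  if (!any(mask)) return(list())
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  pod_ctrs <- if (length(records))
    do.call(rbind, lapply(records, `[[`, "centroid")) else NULL
  px_area <- pixel_size ^ 2
  out <- list(); id <- 0L
  for (l in setdiff(sort(unique(as.vector(lab))), 0)) {
    sel <- lab == l
    area <- sum(sel) * px_area
    if (area < min_area || area > max_area) next
    ctr <- colMeans(which(sel, arr.ind = TRUE))
    if (!is.null(pod_ctrs)) {
      dmin <- min(sqrt(rowSums(sweep(pod_ctrs, 2, ctr) ^ 2))) * pixel_size
      if (dmin < exclusion_radius) next
    }
    id <- id + 1L
    d2c <- outer((seq_len(nrow(density)) - ctr[1]) ^ 2,
                 (seq_len(ncol(density)) - ctr[2]) ^ 2, `+`)
    disk <- d2c <= dilate_px ^ 2
    out[[id]] <- structure(list(id = id, frame = 1L, centroid = unname(ctr),
                                area = area, mask = sel,
                                mean_density = mean(density[disk])),
                           class = "cluster_record")
  }
  out
}

#' Normalize podosome measurements by the brightest podosome per cell
#'
#' Scatter-plot convention for comparing podosomes across cells with
#' variable reporter expression: within each cell, every podosome's value is
#' divided by the value belonging to the podosome with the highest
#' brightness (e.g. actin-reporter intensity) in that cell.
#'
#' @param values Numeric vector of per-podosome measurements.
#' @param brightness Numeric vector used to pick the reference podosome.
#' @param cell Cell identifier per podosome.
#' @return Numeric vector of normalized values.
#' @export
normalize_by_brightest <- function(values, brightness, cell) {
  stopifnot(length(values) == length(brightness),
            length(values) == length(cell))
  out <- values
  for (cl in unique(cell)) {
    sel <- cell == cl
    ref <- values[sel][which.max(brightness[sel])]
    out[sel] <- values[sel] / ref
  }
  out
}
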