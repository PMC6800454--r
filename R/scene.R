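#' Scene configuration for the bilayer simulator
#'
#' Collects the ground-truth parameters of a synthetic cell-on-bilayer scene:
#' field geometry, podosome ring geometry (depleted core plus tension ring),
#' receptor clusters, and probe orientation in the ring. Defaults follow the
#' canonical modelled podosome: 1 um outer ring radius, 0.3 um depleted core,
#' 10% open probes in the ring, unit relative density in the ring and on the
#' bare bilayer.
#'
#' @param shape `c(rows, cols)` of the pixel grid.
#' @param pixel_size Pixel edge (um).
#' @param n_podosomes,n_clusters Counts of podosomes and of tension-free
#'   bright clusters to place.
#' @param core_radius,ring_outer_radius Podosome core and ring outer radii (um).
#' @param ring_fraction_open Fraction of probes mechanically open in the ring.
#' @param core_density Relative probe density in the depleted core
#'   (1 = bare bilayer).
#' @param ring_density Relative probe density in the ring.
#' @param cluster_radius,cluster_density Cluster geometry: disk radius (um)
#'   and relative density (> 1; clusters carry no tension).
#' @param ring_tilt,ring_azimuth Force orientation assigned to open probes in
#'   rings: tilt from the substrate normal and in-plane azimuth (degrees).
#' @param cell_margin Margin (um) between the cell footprint and field edge;
#'   the cell mask is the inset rectangle.
#' @param min_separation Minimum centre-to-centre distance between placed
#'   objects (um); default twice the ring outer radius.
#' @return A plain list of class `scene_config`.
#' @export
scene_config <- function(shape = c(96, 96),
                         pixel_size = 0.1,
                         n_podosomes = 5,
                         n_clusters = 0,
                         core_radius = 0.3,
                         ring_outer_radius = 1.0,
                         ring_fraction_open = 0.10,
                         core_density = 0.1,
                         ring_density = 1.0,
                         cluster_radius = 0.4,
                         cluster_density = 2.0,
                         ring_tilt = 30,
                         ring_azimuth = 40,
                         cell_margin = 0.5,
                         min_separation = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 4), pixel_size > 0,
            n_podosomes >= 0, n_clusters >= 0,
            core_radius > 0, ring_outer_radius > core_radius,
            ring_fraction_open >= 0, ring_fraction_open <= 1,
            core_density >= 0, ring_density >= 0, cluster_density >= 0)
  if (is.null(min_separation)) min_separation <- 2 * ring_outer_radius
  structure(as.list(environment()), class = "scene_config")
}

#' Build a seeded ground-truth scene
#'
#' Places non-overlapping podosomes and clusters uniformly at random inside
#' the cell footprint and rasterizes per-pixel fields of relative probe
#' density, fraction of open probes, and force orientation. The background
#' bilayer has density 1 everywhere; open probes exist only in podosome rings
#' inside the cell mask. Output is deterministic for a given
#' `(config, seed)` pair.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return An object of class `scene` with fields `shape`, `pixel_size`,
#'   `density_field`, `fraction_open_field`, `orientation_field` (list of
#'   `tilt`, `azimuth` matrices, degrees), `podosome_truth` and
#'   `cluster_truth` data frames (centroids in pixel units, radii in um),
#'   `cell_mask`, and `seed`.
#' @examples
#' sc <- build_scene(scene_config(n_podosomes = 2), seed = 7)
#' sc$podosome_truth
#' @export
build_scene <- function(config = scene_config(), seed = 1) {
  stopifnot(inherits(config, "scene_config"))
  px <- config$pixel_size
  nr <- config$shape[1]; nc <- config$shape[2]
  field_um <- c(nr, nc) * px
  if (2 * config$ring_outer_radius + 2 * config$cell_margin >
      min(field_um) && config$n_podosomes > 0)
    stop("field too small to contain a podosome within the cell margin")

  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }

  margin_px <- config$cell_margin / px
  cell_mask <- matrix(FALSE, nr, nc)
  cell_mask[ceiling(margin_px + 1):floor(nr - margin_px),
            ceiling(margin_px + 1):floor(nc - margin_px)] <- TRUE

  n_obj <- config$n_podosomes + config$n_clusters
  radii <- c(rep(config$ring_outer_radius, config$n_podosomes),
             rep(config$cluster_radius, config$n_clusters))
  centres <- withr_seed(place_objects(n_obj, radii, config$min_separation,
                                      field_um, config$cell_margin, seed))

  density <- matrix(1, nr, nc)
  fopen <- matrix(0, nr, nc)
  tilt <- matrix(NA_real_, nr, nc)
  azimuth <- matrix(NA_real_, nr, nc)

  row_um <- (seq_len(nr) - 0.5) * px
  col_um <- (seq_len(nc) - 0.5) * px

  pod <- NULL
  if (config$n_podosomes > 0) {
    for (i in seq_len(config$n_podosomes)) {
      ctr <- centres[i, ]
      d <- sqrt(outer(row_um - ctr[1], rep(1, nc)) ^ 2 +
                outer(rep(1, nr), col_um - ctr[2]) ^ 2)
      core <- d <= config$core_radius
      ring <- d > config$core_radius & d <= config$ring_outer_radius
      density[core] <- config$core_density
      density[ring] <- config$ring_density
      in_cell_ring <- ring & cell_mask
      fopen[in_cell_ring] <- config$ring_fraction_open
      tilt[in_cell_ring] <- config$ring_tilt
      azimuth[in_cell_ring] <- config$ring_azimuth
    }
    pod <- data.frame(
      row = centres[seq_len(config$n_podosomes), 1] / px + 0.5,
      col = centres[seq_len(config$n_podosomes), 2] / px + 0.5,
      core_radius = config$core_radius,
      ring_outer_radius = config$ring_outer_radius,
      ring_fraction_open = config$ring_fraction_open,
      core_density = config$core_density)
    # pixel-centre convention: um coordinate u maps to pixel index u/px + 0.5
  }

  clu <- NULL
  if (config$n_clusters > 0) {
    idx <- config$n_podosomes + seq_len(config$n_clusters)
    for (i in idx) {
      ctr <- centres[i, ]
      d <- sqrt(outer(row_um - ctr[1], rep(1, nc)) ^ 2 +
                outer(rep(1, nr), col_um - ctr[2]) ^ 2)
      density[d <= config$cluster_radius] <- config$cluster_density
    }
    clu <- data.frame(row = centres[idx, 1] / px + 0.5,
                      col = centres[idx, 2] / px + 0.5,
                      radius = config$cluster_radius,
                      density = config$cluster_density)
  }

  fopen[!cell_mask] <- 0
  structure(list(shape = c(nr, nc), pixel_size = px,
                 density_field = density, fraction_open_field = fopen,
                 orientation_field = list(tilt = tilt, azimuth = azimuth),
                 podosome_truth = pod, cluster_truth = clu,
                 cell_mask = cell_mask, config = config, seed = seed),
            class = "scene")
}

# Rejection-sample n non-overlapping object centres (um, row/col order).
place_objects <- function(n, radii, min_sep, field_um, margin, seed,
                          max_attempts = 2000L) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  centres <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    lo <- margin + radii[i]
    hi_r <- field_um[1] - margin - radii[i]
    hi_c <- field_um[2] - margin - radii[i]
    if (hi_r <= lo || hi_c <= lo)
      stop("object radius too large for the field (seed ", seed, ")")
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- c(stats::runif(1, lo, hi_r), stats::runif(1, lo, hi_c))
      if (i == 1 ||
          all(sqrt(rowSums(sweep(centres[seq_len(i - 1), , drop = FALSE],
                                 2, cand) ^ 2)) >= min_sep)) {
        centres[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place object ", i, " without overlap ",
                  "within ", max_attempts, " attempts (seed ", seed, ")")
  }
  centres
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("Synthetic bilayer scene %dx%d px (%.2g um/px), seed %d\n",
              x$shape[1], x$shape[2], x$pixel_size, x$seed))
  cat(sprintf("  podosomes: %d, clusters: %d\n",
              if (is.null(x$podosome_truth)) 0L else nrow(x$podosome_truth),
              if (is.null(x$cluster_truth)) 0L else nrow(x$cluster_truth)))
  invisible(x)
}
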