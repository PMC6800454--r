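#' Link podosome detections into tracks
#'
#' Greedy nearest-centroid assignment between consecutive frames: each
#' existing track claims its nearest unclaimed detection within the gating
#' radius (closest pairs first). Unassigned detections start new tracks; a
#' track born within `split_radius` of a live track is tagged `"split"`,
#' otherwise `"de-novo"`. No gap closing: a missed detection ends the track.
#'
#' @param frames List of per-frame detection lists (each a list of
#'   `podosome_record`s, e.g. from [detect_podosomes()] per frame).
#' @param gating_radius Maximum frame-to-frame centroid displacement (um).
#' @param pixel_size Pixel edge (um).
#' @param split_radius Birth distance (um) below which a new track is tagged
#'   as a split.
#' @return List of `track` objects: `id`, `lineage` (`"de-novo"` or
#'   `"split"`), `birth_frame`, `death_frame`, `records` (one per frame
#'   covered).
#' @export
link_tracks <- function(frames, gating_radius = 0.5, pixel_size = 0.1,
                        split_radius = 1.0) {
  tracks <- list()
  live <- integer(0) # indices into tracks still extendable
  for (fi in seq_along(frames)) {
    dets <- frames[[fi]]
    n_det <- length(dets)
    assigned_det <- rep(FALSE, n_det)
    assigned_trk <- rep(FALSE, length(live))
    if (length(live) && n_det) {
      trk_pos <- do.call(rbind, lapply(live, function(ti) {
        r <- tracks[[ti]]$records
        r[[length(r)]]$centroid
      }))
      det_pos <- do.call(rbind, lapply(dets, `[[`, "centroid"))
      dmat <- outer(trk_pos[, 1], det_pos[, 1], `-`) ^ 2 +
              outer(trk_pos[, 2], det_pos[, 2], `-`) ^ 2
      dmat <- sqrt(dmat) * pixel_size
      # closest-pair-first greedy matching
      repeat {
        m <- which.min(ifelse(outer(assigned_trk, assigned_det, `|`),
                              Inf, dmat))
        if (!length(m) || !is.finite(dmat[m]) ||
            dmat[m] > gating_radius) break
        ti <- (m - 1) %% length(live) + 1
        di <- (m - 1) %/% length(live) + 1
        if (dmat[ti, di] > gating_radius) break
        tk <- live[ti]
        tracks[[tk]]$records <- c(tracks[[tk]]$records, dets[di])
        tracks[[tk]]$death_frame <- fi
        assigned_trk[ti] <- TRUE; assigned_det[di] <- TRUE
        if (all(assigned_trk) || all(assigned_det)) break
      }
    }
    # tracks not extended die
    live <- live[assigned_trk]
    # unassigned detections found new tracks
    for (di in which(!assigned_det)) {
      lineage <- "de-novo"
      if (length(live)) {
        pos <- do.call(rbind, lapply(live, function(ti) {
          r <- tracks[[ti]]$records
          r[[length(r)]]$centroid
        }))
        dmin <- min(sqrt(rowSums(
          sweep(pos, 2, dets[[di]]$centroid) ^ 2))) * pixel_size
        if (dmin <= split_radius) lineage <- "split"
      }
      tracks[[length(tracks) + 1L]] <- structure(
        list(id = length(tracks) + 1L, lineage = lineage,
             birth_frame = fi, death_frame = fi, records = dets[di]),
        class = "track")
      live <- c(live, length(tracks))
    }
  }
  tracks
}

#' Podosome radius response to a perturbation, proximal vs distal
#'
#' For every track spanning the event, the percent change in core radius
#' between the nearest frames before and after `t_event`:
#' `100 * (r_after - r_before) / r_before`. Tracks are grouped by whether
#' their pre-event centroid lies inside the perturbed ROI (proximal) or not
#' (distal). Within each group, outliers beyond the median plus or minus 3
#' median absolute deviations are excluded; tracks absent on either side of
#' the event are dropped with a flag.
#'
#' @param tracks List of `track`s (records must carry `frame`,
#'   `core_radius`, `centroid`).
#' @param roi Logical ROI mask (or `list(center=, radius=)`,
#'   see [simulate_timeline()]).
#' @param frame_times Times (s) of the detection frames, by frame index.
#' @param t_event Perturbation time (s).
#' @param pixel_size Pixel edge (um).
#' @param mad_k Outlier cut in median absolute deviations.
#' @param shape Image shape in pixels; required when `roi` is given as a
#'   centre/radius list rather than a mask.
#' @return List with `per_track` data frame (`track_id`, `group`,
#'   `r_before`, `r_after`, `pct_change`, `outlier`), and group summaries
#'   `proximal_mean_pct`, `distal_mean_pct` over non-outliers.
#' @export
perturbation_response <- function(tracks, roi, frame_times, t_event,
                                  pixel_size = 0.1, mad_k = 3,
                                  shape = if (is.matrix(roi)) dim(roi)) {
  roim <- resolve_roi(roi, shape, pixel_size)
  rows <- list()
  for (tr in tracks) {
    fr <- vapply(tr$records, `[[`, numeric(1), "frame")
    tt <- frame_times[fr]
    before <- which(tt < t_event)
    after <- which(tt >= t_event)
    if (!length(before) || !length(after)) next # absent on one side
    bi <- before[which.max(tt[before])]
    ai <- after[which.min(tt[after])]
    rb <- tr$records[[bi]]$core_radius
    ra <- tr$records[[ai]]$core_radius
    ctr <- tr$records[[bi]]$centroid
    prox <- roim[round(ctr[1]), round(ctr[2])]
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = tr$id, group = if (prox) "proximal" else "distal",
      r_before = rb, r_after = ra,
      pct_change = 100 * (ra - rb) / rb)
  }
  if (!length(rows)) stop("no track spans the event")
  per <- do.call(rbind, rows)
  per$outlier <- FALSE
  for (g in unique(per$group)) {
    sel <- per$group == g
    med <- stats::median(per$pct_change[sel])
    madv <- stats::mad(per$pct_change[sel])
    if (madv > 0)
      per$outlier[sel] <- abs(per$pct_change[sel] - med) > mad_k * madv
  }
  grp_mean <- function(g) {
    v <- per$pct_change[per$group == g & !per$outlier]
    if (length(v)) mean(v) else NA_real_
  }
  list(per_track = per,
       proximal_mean_pct = grp_mean("proximal"),
       distal_mean_pct = grp_mean("distal"))
}
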