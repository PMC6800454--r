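#' Simulate a perturbation time-lapse of a scene
#'
#' Builds an event timeline: a sequence of snapshots of the scene's density
#' and tension (open-probe) channels at stated times, with perturbation
#' events in between. The cell-maintained pattern (depleted cores, tension
#' rings) is treated as a steady state; perturbations create a mobile
#' deficit relative to that steady state which relaxes by lateral diffusion
#' (the heat-equation propagator of [diffuse_field()]). This keeps frames
#' exactly stationary — and probe mass exactly conserved — in the absence of
#' events, while perturbed regions refill with the same kinetics as a FRAP
#' experiment of equal geometry. The tension channel is
#' `fraction_open * density(t)`: force-bearing sites are maintained by the
#' cell, so probes diffusing back into a ring are re-engaged on arrival.
#'
#' Event kinds:
#' \describe{
#'   \item{photocleave}{density and tension inside the ROI drop to
#'     `residual` at the event time; podosomes whose centroid lies inside
#'     the ROI retract: their ground-truth core radius shrinks by
#'     `response_factor`.}
#'   \item{tgt_sink}{irreversible rupture: open-probe density is removed at
#'     `rate` (fraction per second) for `duration` seconds wherever probes
#'     are under load (`fraction_open > 0`) and the applied force is at
#'     least the probe's rupture tolerance `t_tol`.}
#'   \item{bleach}{like photocleave but without a podosome response
#'     (photophysical, not mechanical).}
#' }
#'
#' @param scene A [build_scene()] result.
#' @param times Strictly increasing frame times (s).
#' @param events List of events, each a list with `time`, `kind`, `roi`
#'   (logical mask, or `list(center = c(row, col) px, radius = um)`), and
#'   kind-specific parameters (`residual`, `response_factor`, `rate`,
#'   `duration`, `applied_force`).
#' @param d_coef Lateral diffusion coefficient (um^2/s).
#' @param probe A [probe_species()] (supplies `t_tol` for tgt_sink events).
#' @return Object of class `event_timeline`: `times`, `frames` (list with
#'   `density` and `tension` matrices per frame), `core_radii` (matrix,
#'   frames x podosomes, um), `events`, `scene`, `d_coef`.
#' @export
simulate_timeline <- function(scene, times, events = list(),
                              d_coef = 1.4, probe = probe_species()) {
  stopifnot(inherits(scene, "scene"), all(diff(times) > 0))
  for (ev in events) {
    if (!ev$kind %in% c("photocleave", "tgt_sink", "bleach"))
      stop("unknown event kind: ", ev$kind)
    if (ev$time < times[1] || ev$time > times[length(times)])
      stop("event time outside the timeline span")
  }
  px <- scene$pixel_size
  steady_density <- scene$density_field
  fopen <- scene$fraction_open_field
  def_density <- matrix(0, scene$shape[1], scene$shape[2])

  n_pod <- if (is.null(scene$podosome_truth)) 0L else nrow(scene$podosome_truth)
  core_radii <- matrix(rep(if (n_pod) scene$podosome_truth$core_radius else
                             numeric(0), each = length(times)),
                       nrow = length(times))
  cur_cores <- if (n_pod) scene$podosome_truth$core_radius else numeric(0)

  ev_times <- vapply(events, `[[`, numeric(1), "time")
  frames <- vector("list", length(times))
  prev_t <- times[1]
  for (k in seq_along(times)) {
    t <- times[k]
    if (k > 1 && d_coef > 0 && max(abs(def_density)) > 0)
      def_density <- diffuse_field(def_density, d_coef, t - prev_t, px)
    # events firing in (prev_t, t]
    fire <- which(ev_times > ifelse(k == 1, -Inf, prev_t) & ev_times <= t)
    for (i in fire) {
      ev <- events[[i]]
      roi <- resolve_roi(ev$roi, scene$shape, px)
      if (ev$kind %in% c("photocleave", "bleach")) {
        res <- if (is.null(ev$residual)) 0 else ev$residual
        if (ev$kind == "photocleave" && n_pod) {
          # cell response: podosomes inside the roi retract, so the cell
          # stops excluding probes from the outer part of their old cores
          rf <- if (is.null(ev$response_factor)) 1 else ev$response_factor
          prox <- roi[cbind(round(scene$podosome_truth$row),
                            round(scene$podosome_truth$col))]
          if (rf != 1 && any(prox)) {
            for (pi in which(prox)) {
              ctr <- c(scene$podosome_truth$row[pi],
                       scene$podosome_truth$col[pi])
              d2 <- outer((seq_len(scene$shape[1]) - ctr[1]) ^ 2,
                          (seq_len(scene$shape[2]) - ctr[2]) ^ 2, `+`) *
                    px ^ 2
              freed <- d2 <= cur_cores[pi] ^ 2 &
                       d2 > (rf * cur_cores[pi]) ^ 2
              steady_density[freed] <- scene$config$ring_density
            }
            cur_cores[prox] <- cur_cores[prox] * rf
          }
        }
        cur_d <- steady_density + def_density
        def_density[roi] <- res * cur_d[roi] - steady_density[roi]
      } else { # tgt_sink
        f_app <- if (is.null(ev$applied_force)) probe$f_half else ev$applied_force
        if (!is.na(probe$t_tol) && f_app >= probe$t_tol) {
          rate <- if (is.null(ev$rate)) 1 else ev$rate
          dur <- if (is.null(ev$duration)) 1 else ev$duration
          frac <- 1 - exp(-rate * dur)
          sel <- roi & fopen > 0
          cur_d <- steady_density + def_density
          def_density[sel] <- def_density[sel] - frac * fopen[sel] * cur_d[sel]
        }
      }
    }
    core_radii[k, ] <- cur_cores
    dens_k <- pmax(steady_density + def_density, 0)
    frames[[k]] <- list(density = dens_k, tension = dens_k * fopen)
    prev_t <- t
  }
  structure(list(times = times, frames = frames, core_radii = core_radii,
                 events = events, scene = scene, d_coef = d_coef,
                 probe = probe),
            class = "event_timeline")
}

#' Add a perturbation event to a timeline
#'
#' Validates the event and re-simulates the timeline with it included.
#'
#' @param timeline An `event_timeline`.
#' @param event Event list (see [simulate_timeline()]).
#' @return A new `event_timeline`.
#' @export
apply_perturbation <- function(timeline, event) {
  stopifnot(inherits(timeline, "event_timeline"))
  if (!is.list(event) || is.null(event$kind) || is.null(event$time))
    stop("event must be a list with at least `time` and `kind`")
  roi <- resolve_roi(event$roi, timeline$scene$shape,
                     timeline$scene$pixel_size)
  if (!any(roi)) stop("event roi is empty or outside the field")
  simulate_timeline(timeline$scene, timeline$times,
                    c(timeline$events, list(event)), timeline$d_coef,
                    timeline$probe)
}

# Accept a logical mask or list(center = c(row, col) in px, radius in um).
resolve_roi <- function(roi, shape, pixel_size) {
  if (is.matrix(roi) && is.logical(roi)) {
    stopifnot(all(dim(roi) == shape))
    return(roi)
  }
  if (is.list(roi) && !is.null(roi$center) && !is.null(roi$radius)) {
    d2 <- outer((seq_len(shape[1]) - roi$center[1]) ^ 2,
                (seq_len(shape[2]) - roi$center[2]) ^ 2, `+`)
    return(d2 <= (roi$radius / pixel_size) ^ 2)
  }
  stop("roi must be a logical mask or list(center=, radius=)")
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("Event timeline: %d frames over %.3g-%.3g s, D = %.3g um^2/s\n",
              length(x$times), x$times[1], x$times[length(x$times)], x$d_coef))
  for (ev in x$events)
    cat(sprintf("  event: %s at t = %.3g s\n", ev$kind, ev$time))
  invisible(x)
}
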