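#' Fit a FRAP recovery and extract the half-time
#'
#' Normalizes the ROI mean intensity to the pre-bleach level, then fits the
#' post-bleach recovery to a single exponential
#' `I(t) = I_b + A * (1 - exp(-k * (t - t0)))` with the bleach depth `I_b`
#' and plateau both free. The half-time of 50% recovery relative to the
#' fitted plateau is `t_half = log(2) / k`. The half-time is invariant to
#' overall intensity scaling of the series.
#'
#' @param times Frame times (s).
#' @param roi_mean ROI mean intensities (same length).
#' @param t_bleach Bleach time (s); frames strictly before it are the
#'   pre-bleach baseline, frames at or after it (the first of which shows
#'   the bleached field) are fit.
#' @return Object of class `frap_fit`: `t_half` (s), coefficients
#'   (`bleach_depth`, `amplitude`, `rate`), the normalized series, and the
#'   plateau.
#' @seealso [diffusion_coefficient()]
#' @export
frap_halftime <- function(times, roi_mean, t_bleach = 0) {
  stopifnot(length(times) == length(roi_mean), all(diff(times) > 0))
  pre <- times < t_bleach
  if (!any(pre)) stop("no pre-bleach frames to normalize against")
  norm <- roi_mean / mean(roi_mean[pre])
  post <- times >= t_bleach
  if (sum(post) < 5) stop("need at least 5 post-bleach points")
  t <- times[post] - min(times[post])
  y <- norm[post]
  amp0 <- max(y) - min(y)
  if (amp0 <= 0.01)
    stop("no recovery observed: post-bleach amplitude ~ 0")
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ ib + a * (1 - exp(-k * t)), data = dat,
                      start = list(ib = min(y), a = amp0,
                                   k = 1 / max(t[2], stats::median(t))),
                      lower = c(0, 1e-6, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("FRAP fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(t_half = log(2) / co[["k"]],
                 coefficients = c(bleach_depth = co[["ib"]],
                                  amplitude = co[["a"]], rate = co[["k"]]),
                 plateau = co[["ib"]] + co[["a"]],
                 times = times, normalized = norm, t_bleach = t_bleach),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP recovery fit: t_half = %.3g s, plateau = %.3f\n",
              x$t_half, x$plateau))
  invisible(x)
}

#' @export
plot.frap_fit <- function(x, ...) {
  plot(x$times, x$normalized, xlab = "time (s)",
       ylab = "normalized ROI intensity", main = "FRAP recovery", ...)
  co <- x$coefficients
  post <- x$times > x$t_bleach
  t <- x$times[post]
  graphics::lines(t, co["bleach_depth"] +
                    co["amplitude"] * (1 - exp(-co["rate"] * (t - min(t)))))
  invisible(x)
}

#' Diffusion coefficient from bleach radius and recovery half-time
#'
#' `D = w^2 / (4 * t_half)` — the standard disk-bleach approximation
#' relating the recovery half-time to the lateral diffusion coefficient.
#'
#' @param w Bleach disk radius (um).
#' @param t_half Recovery half-time (s).
#' @return Diffusion coefficient (um^2/s).
#' @examples
#' diffusion_coefficient(w = 2, t_half = 0.709)  # ~1.41
#' @export
diffusion_coefficient <- function(w, t_half) {
  stopifnot(w > 0, t_half > 0)
  w ^ 2 / (4 * t_half)
}

#' Tension-signal time course around a perturbation
#'
#' Tracks the mean of a tension-channel image series inside an ROI across a
#' perturbation (e.g. photocleavage), normalized to the pre-event mean, and
#' estimates the recovery half-time with the same exponential model as FRAP.
#'
#' @param maps List (or 3-D array) of tension-channel images, one per frame.
#' @param times Frame times (s).
#' @param roi Logical ROI mask.
#' @param t_event Perturbation time (s).
#' @return List with `times`, `signal` (normalized ROI means), and `fit`
#'   (a `frap_fit` for the post-event recovery).
#' @export
recovery_after_cleavage <- function(maps, times, roi, t_event) {
  if (is.array(maps) && length(dim(maps)) == 3)
    maps <- lapply(seq_len(dim(maps)[3]), function(k) maps[, , k])
  stopifnot(length(maps) == length(times), any(roi))
  sig <- vapply(maps, function(m) mean(m[roi]), numeric(1))
  fit <- frap_halftime(times, sig, t_bleach = t_event)
  list(times = times, signal = fit$normalized, fit = fit)
}
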