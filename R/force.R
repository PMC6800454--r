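#' Anchor (biotinylated-lipid) surface density
#'
#' Number of biotinylated lipids per square micron of accessible leaflet:
#' `l = leaflet_factor * biotin_mol_fraction / area_per_lipid`, with the
#' lipid footprint given in nm^2 (1 um^2 = 1e6 nm^2).
#'
#' @param biotin_mol_fraction Mole fraction of biotinylated lipid (e.g.
#'   0.001 for 0.1 mol%).
#' @param area_per_lipid Lipid footprint (nm^2); default 0.72 nm^2, the
#'   common literature value for DOPC.
#' @param leaflet_factor Fraction of lipids in the accessible leaflet
#'   (1 if the mole fraction already refers to the upper leaflet, 0.5 if it
#'   partitions over both).
#' @return Anchor density (um^-2).
#' @examples
#' anchor_density(0.001)  # ~1.39e3 per um^2
#' @export
anchor_density <- function(biotin_mol_fraction, area_per_lipid = 0.72,
                           leaflet_factor = 1) {
  stopifnot(biotin_mol_fraction > 0, biotin_mol_fraction < 1,
            area_per_lipid > 0, leaflet_factor > 0)
  leaflet_factor * biotin_mol_fraction / (area_per_lipid * 1e-6)
}

#' Parameters of the podosome ring force model
#'
#' @param R Ring outer radius (um).
#' @param r Inner depletion (core) radius (um).
#' @param l Anchor density (um^-2), e.g. from [anchor_density()].
#' @param d Probes per biotinylated lipid (dimensionless; plausible band
#'   0.5--2).
#' @param rho Relative probe density in the ring (1 = bilayer background).
#' @param O Fraction of probes open per pixel.
#' @param f_int Per-receptor force (pN): a scalar, or a two-population
#'   mixture given as `list(force = c(f_low, f_high), weight = c(w_low,
#'   w_high))`; the mixture is collapsed to its weighted mean force.
#' @param d_band Two-sided probes-per-lipid band for confidence intervals.
#' @return Object of class `force_model_params`.
#' @export
force_model_params <- function(R = 1, r = 0.3, l = anchor_density(0.001),
                               d = 1, rho = 1, O = 0.1, f_int = 19,
                               d_band = c(0.5, 2)) {
  stopifnot(r > 0, R > r, l > 0, d > 0, rho >= 0, O >= 0, O <= 1)
  if (is.list(f_int)) {
    stopifnot(length(f_int$force) == length(f_int$weight),
              all(f_int$force >= 0), all(f_int$weight >= 0))
  } else stopifnot(all(f_int >= 0))
  structure(list(R = R, r = r, l = l, d = d, rho = rho, O = O,
                 f_int = f_int, d_band = sort(d_band)),
            class = "force_model_params")
}

effective_f_int <- function(f_int) {
  if (is.list(f_int))
    sum(f_int$force * f_int$weight) / sum(f_int$weight)
  else f_int
}

#' Net podosome ring tensile force
#'
#' Bookkeeping estimate of the net vertical tensile force a podosome ring
#' applies through its open probes:
#'
#'   `F_pod = pi * (R^2 - r^2) * (l * d) * (rho * F_int * O)`
#'
#' i.e. ring area times probe surface density times the per-area tension
#' carried by the open fraction. Returned in pN, with a confidence band from
#' evaluating `d` at the ends of its plausible range.
#'
#' @param params A [force_model_params()].
#' @return List with `f_pod_pN`, `f_pod_nN`, and `band_pN` (named low/high,
#'   at `d_band`).
#' @examples
#' podosome_force(force_model_params())  # ~7.5 nN at the canonical setting
#' @export
podosome_force <- function(params) {
  stopifnot(inherits(params, "force_model_params"))
  if (params$r >= params$R) stop("inner radius must be below outer radius")
  fi <- effective_f_int(params$f_int)
  area <- pi * (params$R ^ 2 - params$r ^ 2)
  per_d <- area * params$l * params$rho * fi * params$O
  f <- per_d * params$d
  list(f_pod_pN = f, f_pod_nN = f / 1000,
       band_pN = stats::setNames(per_d * params$d_band, c("low", "high")))
}

#' Ring force as a function of per-receptor force
#'
#' Evaluates the ring force model over a grid of per-receptor forces at the
#' central probes-per-lipid value and at the ends of its band. Linear in
#' `F_int` by construction.
#'
#' @param params A [force_model_params()]; its `f_int` is ignored.
#' @param f_int_grid Per-receptor forces (pN).
#' @return Data frame with `f_int_pN`, `f_pod_pN`, `f_pod_low_pN`,
#'   `f_pod_high_pN`.
#' @export
force_sweep <- function(params, f_int_grid = seq(0, 50, by = 1)) {
  stopifnot(length(f_int_grid) >= 1)
  area <- pi * (params$R ^ 2 - params$r ^ 2)
  base <- area * params$l * params$rho * params$O * f_int_grid
  data.frame(f_int_pN = f_int_grid,
             f_pod_pN = base * params$d,
             f_pod_low_pN = base * params$d_band[1],
             f_pod_high_pN = base * params$d_band[2])
}
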