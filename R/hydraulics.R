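#' Physical constants for theoretical conductance
#'
#' Density and viscosity of water as used in the Hagen--Poiseuille
#' conversion. The constants cancel in every percent-loss-of-conductance
#' ratio, so only their positivity matters for the reported results; the
#' conductances themselves are in internal (printed-constant) units, not SI.
#'
#' @param rho Water density (0.9982 g cm^-3).
#' @param eta Water viscosity (1.002, as conventionally printed).
#' @return A list of class `hydraulic_constants`.
#' @export
hydraulic_constants <- function(rho = 0.9982, eta = 1.002) {
  stopifnot(rho > 0, eta > 0)
  structure(list(rho = rho, eta = eta), class = "hydraulic_constants")
}

#' Conduit diameter from lumen area
#'
#' Assumes a circular conduit shape: `D = 2 * sqrt(A / pi)`.
#'
#' @param area_um2 Lumen area(s) in um^2 (vectorised, >= 0).
#' @return Diameter(s) in um.
#' @export
conduit_diameter <- function(area_um2) {
  if (any(area_um2 < 0, na.rm = TRUE)) abort("conduit areas must be non-negative")
  2 * sqrt(area_um2 / pi)
}

#' Theoretical hydraulic conductance of a conduit (Hagen--Poiseuille)
#'
#' `k_th = pi * rho * D^4 / (128 * eta)`: conductance scales with the fourth
#' power of the lumen diameter, so doubling the diameter multiplies k_th by
#' 16. Values are in internal units (the printed constants are used as-is);
#' only conductance ratios are meaningful downstream.
#'
#' @param diameter_um Conduit diameter(s) in um (vectorised, >= 0).
#' @param constants A [hydraulic_constants()] object.
#' @return Theoretical conductance(s), same length as `diameter_um`.
#' @export
theoretical_conductance <- function(diameter_um,
                                    constants = hydraulic_constants()) {
  stopifnot(inherits(constants, "hydraulic_constants"))
  if (any(diameter_um < 0, na.rm = TRUE)) abort("diameters must be non-negative")
  pi * constants$rho * diameter_um^4 / (128 * constants$eta)
}

#' Theoretical percent loss of conductance from a segmented scan pair
#'
#' Sums Hagen--Poiseuille conductances over the conduits that were already
#' gas-filled before cutting (the initial degree of embolism, from the
#' pre-cut scan) and over all conduits (from the post-cut scan, in which
#' cutting embolized 100% of the water-conducting conduits), and returns
#' their ratio as a percentage, clamped to [0, 100].
#'
#' @param embolized_areas Areas (um^2) of conduits embolized before cutting.
#' @param all_areas Areas (um^2) of all conduits in the post-cut reference.
#' @param constants A [hydraulic_constants()] object (cancels in the ratio).
#' @return PLC in percent: 0 for a fully functional vein, 100 when every
#'   conduit is embolized.
#' @export
theoretical_plc <- function(embolized_areas, all_areas,
                            constants = hydraulic_constants()) {
  if (length(all_areas) == 0L) {
    abort("post-cut scan yielded no conduits: cannot form the maximal-conductance reference")
  }
  k_init <- sum(theoretical_conductance(conduit_diameter(embolized_areas),
                                        constants))
  k_max <- sum(theoretical_conductance(conduit_diameter(all_areas), constants))
  min(100, max(0, 100 * k_init / k_max))
}
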