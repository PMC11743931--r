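# Unit conversions. Internally the mechanical sub-model works in
# micrometres and nanonewtons, so energies are in femtojoules (1 fJ = 1e-15 J);
# the CPM Hamiltonian is dimensionless, scaled by `energy_unit` joules.

#' Convert a tensile modulus to a bead-spring constant
#'
#' A fiber segment is approximated as a cylindrical rod of the given diameter
#' and length, so that `K = Y * A / L` with `A` the cross-sectional area.
#' With the defaults for collagen (`Y = 1e6` Pa, diameter 0.125 um, segment
#' length 0.4 um) this gives `K ~ 3.1e-2` N/m.
#'
#' @param Y tensile (Young's) modulus in Pa.
#' @param diameter rod diameter in metres.
#' @param segment_length rod (segment) length in metres.
#' @return spring constant in N/m.
#' @examples
#' modulus_to_spring_constant(1e6, 0.125e-6, 0.4e-6)
#' @export
modulus_to_spring_constant <- function(Y, diameter, segment_length) {
  stopifnot(Y > 0, diameter > 0, segment_length > 0)
  Y * pi * (diameter / 2)^2 / segment_length
}

#' Lattice and time unit conversions
#'
#' One lattice site corresponds to `lattice_spacing` micrometres (default
#' 0.25 um) and one model timestep to `step_duration` seconds (default
#' 2.88 s, so that 1e4 steps is roughly 8 hours).
#'
#' @param sites distance in lattice sites (or area in sites if `area = TRUE`).
#' @param steps number of model timesteps.
#' @param lattice_spacing physical size of one lattice site, micrometres.
#' @param step_duration physical duration of one timestep, seconds.
#' @param area if `TRUE`, convert an area (sites -> um^2).
#' @return micrometres (or um^2) for `sites_to_um`, seconds for
#'   `steps_to_seconds`.
#' @examples
#' sites_to_um(200)      # 50 um domain edge
#' steps_to_seconds(1e4) # 28800 s = 8 h
#' @export
sites_to_um <- function(sites, lattice_spacing = 0.25, area = FALSE) {
  if (area) sites * lattice_spacing^2 else sites * lattice_spacing
}

#' @rdname sites_to_um
#' @export
steps_to_seconds <- function(steps, step_duration = 2.88) {
  steps * step_duration
}
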