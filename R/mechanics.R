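# Potential energy, forces and overdamped relaxation of the fiber network.
# Units: positions um, forces nN, energies fJ (1 fJ = 1e-15 J).

#' Potential energy of a fiber network
#'
#' Sum of stretch-spring terms `(k/2)(r0 - |bi - bj|)^2` (fiber springs and
#' cross-links) and bending terms `(K_bend/2)(theta - theta_0)^2` over
#' consecutive bead triples.
#'
#' @param network a `fiber_network`.
#' @param strict error on degenerate (coincident-bead) angle triples; if
#'   `FALSE` such triples are skipped, as during the coupled dynamics where
#'   two adhesions may pin their beads to the same lattice site.
#' @return energy in fJ (multiply by 1e-15 for joules).
#' @export
network_energy <- function(network, strict = TRUE) {
  cpp_network_forces(network$pos, network$bond_i - 1L, network$bond_j - 1L,
                     network$bond_k, network$bond_r0,
                     network$ang_i - 1L, network$ang_j - 1L,
                     network$ang_k - 1L, network$ang_kb,
                     network$ang_th0, strict)$energy
}

#' Forces on all beads of a fiber network
#'
#' `F_i = -dU/db_i`, the exact gradient of [network_energy()].  Clamped and
#' adhesion-pinned beads report their force too; they are simply never
#' moved by the integrator.
#'
#' @param network a `fiber_network`.
#' @param strict see [network_energy()].
#' @return n x 2 matrix of forces, nN.
#' @export
network_forces <- function(network, strict = TRUE) {
  cpp_network_forces(network$pos, network$bond_i - 1L, network$bond_j - 1L,
                     network$bond_k, network$bond_r0,
                     network$ang_i - 1L, network$ang_j - 1L,
                     network$ang_k - 1L, network$ang_kb,
                     network$ang_th0, strict)$forces
}

# default timestep: 0.1 * gamma / stiffest spring constant (nN/um), with
# bending rigidity contributing K_bend / r0_min^2
stable_dt <- function(network, mechanics) {
  if (!is.null(mechanics$dt)) return(mechanics$dt)
  k_max <- if (length(network$bond_k) > 0) max(network$bond_k) else 0
  if (length(network$ang_kb) > 0 && length(network$bond_r0) > 0) {
    r_min <- max(min(network$bond_r0[!network$bond_cross]), 1e-3)
    k_max <- max(k_max, max(network$ang_kb) / r_min^2)
  }
  if (k_max <= 0) return(0.1 * mechanics$gamma_drag)
  0.1 * mechanics$gamma_drag / k_max
}

#' Relax a fiber network by overdamped Langevin dynamics
#'
#' Iterates `b_i <- b_i + (dt/gamma_drag)(F_i + W_i)` for every free bead
#' until the maximum potential force over free beads drops below
#' `force_tol` or `max_steps` substeps are exhausted.  Clamped beads and
#' beads in `pinned` (e.g. adhesion beads gripped by the cell) are
#' bit-identical before and after.  Noise uses the current R RNG state.
#'
#' @param network a `fiber_network`.
#' @param mechanics a [mechanics_params()] object.
#' @param pinned integer indices of additionally immobile beads (the
#'   network's `fa_bound` beads are always pinned).
#' @return the network with relaxed positions plus attributes `converged`
#'   and `steps`.
#' @export
relax_network <- function(network, mechanics = mechanics_params(),
                          pinned = integer()) {
  free <- !network$clamped & !network$fa_bound
  if (length(pinned) > 0) free[pinned] <- FALSE
  dt <- stable_dt(network, mechanics)
  res <- cpp_relax(network$pos, network$bond_i - 1L, network$bond_j - 1L,
                   network$bond_k, network$bond_r0,
                   network$ang_i - 1L, network$ang_j - 1L,
                   network$ang_k - 1L, network$ang_kb, network$ang_th0,
                   free, mechanics$gamma_drag, mechanics$T_ecm, dt,
                   as.integer(mechanics$max_steps), mechanics$force_tol,
                   as.integer(mechanics$check_every))
  if (!res$converged && mechanics$T_ecm == 0)
    message(sprintf("relaxation not converged after %d substeps", res$steps))
  network$pos <- res$pos
  attr(network, "converged") <- res$converged
  attr(network, "steps") <- res$steps
  network
}
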