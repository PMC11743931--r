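# Parameter containers.  All user-facing values are in physical units
# (N/m, N*m, Pa, um, s); conversion to internal units (um, nN, fJ for the
# mechanics; a dimensionless Hamiltonian for the CPM) happens in one place,
# cpm_model_coefficients() and network internals.

N_PER_M_TO_NN_PER_UM <- 1000      # 1 N/m == 1000 nN/um
J_TO_FJ <- 1e15                   # 1 J == 1e15 fJ (fJ = nN*um)

#' Cellular Potts model parameters
#'
#' Coefficients of the cell Hamiltonian
#' `H = lambda*A^2 + J * #(mismatched ordered neighbour pairs) -
#'  lambda_c * A/(A + A_h)`: quadratic contractility, interfacial line
#' tension, and a saturating substrate-adhesion gain.  Values are physical;
#' `energy_unit` (joules) sets the scale on which `H` is compared with the
#' dimensionless motility temperature `T`.
#'
#' @param lambda contractility coefficient, N m^-3.
#' @param J interfacial energy coefficient, N m^-1.
#' @param lambda_c substrate adhesion strength, N m.
#' @param A_h adhesion saturation area, um^2.  The default 3.125 um^2 is
#'   50 lattice sites; reading the adhesion saturation constant in lattice
#'   units is the only interpretation under which a cell without ECM
#'   contacts keeps a stable nonzero area, the stated calibration target of
#'   the substrate-adhesion term.
#' @param T motility temperature, dimensionless.
#' @param neighborhood neighbour stencil; only `"moore"` (second order) is
#'   implemented.
#' @param energy_unit energy scale in joules used to render `H` dimensionless.
#' @return an object of class `cpm_params`.
#' @export
cpm_params <- function(lambda = 4.96e7, J = 9.30e-3, lambda_c = 3.87e-13,
                       A_h = 3.125, T = 50, neighborhood = "moore",
                       energy_unit = 4e-17) {
  neighborhood <- match.arg(neighborhood, "moore")
  stopifnot(lambda >= 0, J >= 0, lambda_c >= 0, A_h >= 0, T > 0,
            energy_unit > 0)
  structure(list(lambda = lambda, J = J, lambda_c = lambda_c, A_h = A_h,
                 T = T, neighborhood = neighborhood,
                 energy_unit = energy_unit),
            class = "cpm_params")
}

#' Dimensionless CPM coefficients on a given lattice
#'
#' Converts physical Hamiltonian coefficients to the model units used by the
#' Metropolis dynamics: areas are counted in lattice sites and energies in
#' multiples of `energy_unit`.
#'
#' @param cpm a [cpm_params()] object.
#' @param lattice_spacing lattice site edge, um.
#' @return list with `lambda`, `J` (per ordered mismatched pair), `lambda_c`,
#'   `A_h` (lattice sites) and `T`, all dimensionless.
#' @export
cpm_model_coefficients <- function(cpm, lattice_spacing = 0.25) {
  l_m <- lattice_spacing * 1e-6                  # metres
  eps <- cpm$energy_unit
  list(lambda   = cpm$lambda * l_m^4 / eps,
       J        = cpm$J * l_m^2 / eps,
       lambda_c = cpm$lambda_c / eps,
       A_h      = cpm$A_h / lattice_spacing^2,   # um^2 -> sites
       T        = cpm$T)
}

#' Fiber network parameters
#'
#' Geometry and stiffness of the cross-linked bead-spring network.  Fibers
#' are `n_beads` beads joined by springs of stiffness `K_polymer` and rest
#' length `r_polymer`; consecutive bead triples carry a harmonic bending
#' potential `(K_bend/2)(theta - theta_0)^2`.  Cross-links are short springs
#' of stiffness `K_cross` joining beads of different fibers.  Orientations
#' are drawn from a von Mises distribution with mean `mu` and concentration
#' `kappa` (`kappa = 0` is isotropic).
#'
#' @param fiber_density fibers per um^2 of domain (default 0.48).
#' @param n_beads beads per fiber (>= 3).
#' @param r_polymer spring rest length, um.
#' @param K_polymer stretch stiffness, N/m.
#' @param K_bend bending rigidity, N m rad^-2.
#' @param theta_0 preferred interior angle, rad (straight fibers: pi).
#' @param K_cross cross-link stiffness, N/m (default equals `K_polymer`).
#' @param crosslink_density target cross-links per um^2 of domain.
#' @param crosslink_rest_length cross-link spring rest length, um.
#' @param capture_radius maximum bead-bead distance eligible for a
#'   cross-link, um.
#' @param mu,kappa von Mises mean direction (rad) and concentration.
#' @param domain domain extent `c(Lx, Ly)` in um.
#' @return an object of class `network_params`.
#' @export
network_params <- function(fiber_density = 0.48, n_beads = 31,
                           r_polymer = 0.4, K_polymer = 3.1e-2,
                           K_bend = 3.88e-15, theta_0 = pi,
                           K_cross = K_polymer, crosslink_density = 0.48,
                           crosslink_rest_length = 0.1, capture_radius = 0.5,
                           mu = 0, kappa = 0, domain = c(50, 50)) {
  stopifnot(n_beads >= 3, K_polymer >= 0, K_bend >= 0, K_cross >= 0,
            kappa >= 0, crosslink_density >= 0, fiber_density >= 0,
            r_polymer > 0, crosslink_rest_length >= 0, capture_radius > 0,
            length(domain) == 2, all(domain > 0))
  structure(list(fiber_density = fiber_density, n_beads = n_beads,
                 r_polymer = r_polymer, K_polymer = K_polymer,
                 K_bend = K_bend, theta_0 = theta_0, K_cross = K_cross,
                 crosslink_density = crosslink_density,
                 crosslink_rest_length = crosslink_rest_length,
                 capture_radius = capture_radius, mu = mu, kappa = kappa,
                 domain = as.numeric(domain)),
            class = "network_params")
}

#' Overdamped relaxation parameters for the fiber network
#'
#' The network relaxes by `b_i <- b_i + (dt/gamma_drag) * (F_i + W_i)` for
#' every free bead, with Gaussian noise of per-component variance
#' `gamma_drag * T_ecm / dt` (so that the squared noise magnitude averages
#' `2 gamma_drag T_ecm / dt`).
#'
#' @param gamma_drag drag coefficient (model units; absorbed in the time
#'   scale).
#' @param T_ecm noise level, fJ (near-deterministic at the default 0.001).
#' @param dt integration timestep; `NULL` selects `0.1 * gamma_drag / k_max`
#'   from the stiffest spring in the network.
#' @param max_steps cap on integration substeps per relaxation call.
#' @param force_tol convergence threshold on the maximum free-bead potential
#'   force, nN.
#' @param check_every convergence test interval, substeps.
#' @return an object of class `mechanics_params`.
#' @export
mechanics_params <- function(gamma_drag = 1, T_ecm = 0.001, dt = NULL,
                             max_steps = 1e4, force_tol = 1e-4,
                             check_every = 25) {
  stopifnot(gamma_drag > 0, T_ecm >= 0, is.null(dt) || dt > 0,
            max_steps >= 1, force_tol > 0, check_every >= 1)
  structure(list(gamma_drag = gamma_drag, T_ecm = T_ecm, dt = dt,
                 max_steps = max_steps, force_tol = force_tol,
                 check_every = check_every),
            class = "mechanics_params")
}

#' Focal adhesion parameters
#'
#' An FA is a cluster of `N` bound integrins obeying
#' `dN/dt = gamma (N_tot - N) - d0 d(f_star Phi / N) N`, with the catch-slip
#' rate `d(phi) = exp(phi - phi_s) + exp(phi_c - phi)`.  `Phi` is the
#' mechanical tension on the adhesion; `tension_source` selects between the
#' resultant ECM force on the pinned bead (`"ecm"`, default) and the
#' cytoskeletal spring force `K_cyto * |x - x_center|` (`"cytoskeletal"`);
#' the two coincide where the greedy adhesion displacement has stalled.
#'
#' @param gamma integrin binding rate, s^-1.
#' @param d0 base detachment rate, s^-1.
#' @param f_star force scale, N^-1 (converts tension per integrin to the
#'   dimensionless argument of `d`).
#' @param phi_s,phi_c slip and catch thresholds of `d(phi)`, dimensionless.
#' @param N_tot maximum integrins per FA.
#' @param N0 nascent FA size (also the offset of the retraction penalty).
#' @param N_h retraction-penalty saturation scale.
#' @param lambda_FA retraction penalty amplitude, model energy units.
#' @param K_cyto cytoskeletal spring constant, N/m.
#' @param N_min lower clamp on N (the ODE is singular at N = 0).
#' @param tau ODE integration horizon per coupling step, s.
#' @param tension_source `"ecm"` or `"cytoskeletal"` (see Details).
#' @param contraction_multiplier factor scaling the cell's contraction force
#'   `K_cyto` (the knob varied in contractility sweeps).
#' @return an object of class `fa_params`.
#' @export
fa_params <- function(gamma = 2.88, d0 = 2.88e-2, f_star = 1.29e10,
                      phi_s = 4.02, phi_c = 7.76, N_tot = 390, N0 = 25,
                      N_h = 100, lambda_FA = 800, K_cyto = 3.10e-4,
                      N_min = 1, tau = 2.88,
                      tension_source = c("ecm", "cytoskeletal"),
                      contraction_multiplier = 1) {
  tension_source <- match.arg(tension_source)
  stopifnot(gamma > 0, d0 > 0, f_star > 0, phi_c > phi_s, phi_s > 0,
            N_tot > 0, N0 > 0, N0 <= N_tot, N_h > 0, lambda_FA >= 0,
            K_cyto >= 0, N_min > 0, N_min <= N0, tau > 0,
            contraction_multiplier >= 0)
  structure(list(gamma = gamma, d0 = d0, f_star = f_star, phi_s = phi_s,
                 phi_c = phi_c, N_tot = N_tot, N0 = N0, N_h = N_h,
                 lambda_FA = lambda_FA, K_cyto = K_cyto, N_min = N_min,
                 tau = tau, tension_source = tension_source,
                 contraction_multiplier = contraction_multiplier),
            class = "fa_params")
}

#' Full simulation configuration
#'
#' Bundles the sub-model parameters with geometry, scheduling and seeding.
#' The scenario selects the network: `"grid"` (regular horizontal/vertical
#' strands cross-linked at intersections), `"isotropic"` (random fibers,
#' `kappa = 0`) or `"anisotropic"` (random fibers, `kappa = 10` unless
#' overridden in `network`).
#'
#' @param scenario one of `"isotropic"`, `"anisotropic"`, `"grid"`.
#' @param seed master RNG seed (integer); sub-model streams are derived from
#'   it so that, e.g., toggling ECM noise does not perturb the CPM draws.
#' @param lattice_size lattice edge in sites (domain edge =
#'   `lattice_size * lattice_spacing` um).
#' @param lattice_spacing site edge, um.
#' @param step_duration physical duration of one coupling step, s.
#' @param n_steps number of coupling steps.
#' @param cell_radius initial cell disc radius, lattice sites.
#' @param relax_every run the network relaxation every this many steps.
#' @param relax_max_steps substep budget for in-loop relaxations.
#' @param init_relax_max_steps substep budget for the initial relaxation.
#' @param output_every record trajectory rows every this many steps.
#' @param record snapshot content: subset of `"mask"`, `"beads"`, `"fas"`.
#' @param grid_spacing strand spacing for the grid scenario, um.
#' @param cpm,network,mechanics,fa sub-parameter objects (defaults used when
#'   `NULL`); for the scenarios, `network$domain` is forced to the lattice
#'   extent.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(scenario = c("isotropic", "anisotropic", "grid"),
                              seed = 1L, lattice_size = 200,
                              lattice_spacing = 0.25, step_duration = 2.88,
                              n_steps = 1e4, cell_radius = 20,
                              relax_every = 1, relax_max_steps = 200,
                              init_relax_max_steps = 2000,
                              output_every = 50,
                              record = c("mask", "beads", "fas"),
                              grid_spacing = 1,
                              cpm = NULL, network = NULL, mechanics = NULL,
                              fa = NULL) {
  scenario <- match.arg(scenario)
  record <- match.arg(record, several.ok = TRUE)
  stopifnot(n_steps >= 0, lattice_size >= 8, lattice_spacing > 0,
            cell_radius >= 1, cell_radius < lattice_size / 2,
            relax_every >= 1, output_every >= 1, grid_spacing > 0)
  extent <- c(lattice_size, lattice_size) * lattice_spacing
  if (is.null(cpm)) cpm <- cpm_params()
  if (is.null(network)) {
    network <- network_params(domain = extent,
                              kappa = if (scenario == "anisotropic") 10 else 0)
  } else {
    network$domain <- extent
  }
  if (is.null(mechanics)) mechanics <- mechanics_params()
  if (is.null(fa)) fa <- fa_params()
  stopifnot(inherits(cpm, "cpm_params"), inherits(network, "network_params"),
            inherits(mechanics, "mechanics_params"), inherits(fa, "fa_params"))
  structure(list(scenario = scenario, seed = as.integer(seed),
                 lattice_size = as.integer(lattice_size),
                 lattice_spacing = lattice_spacing,
                 step_duration = step_duration,
                 n_steps = as.integer(n_steps),
                 cell_radius = cell_radius,
                 relax_every = as.integer(relax_every),
                 relax_max_steps = as.integer(relax_max_steps),
                 init_relax_max_steps = as.integer(init_relax_max_steps),
                 output_every = as.integer(output_every), record = record,
                 grid_spacing = grid_spacing,
                 cpm = cpm, network = network, mechanics = mechanics,
                 fa = fa),
            class = "simulation_config")
}

#' Read / write a simulation configuration as YAML
#'
#' The file mirrors the parameter names of [cpm_params()],
#' [network_params()], [mechanics_params()], [fa_params()] and
#' [simulation_config()] under the keys `cpm`, `network`, `mechanics`, `fa`
#' and top-level scheduling fields.
#'
#' @param path file path.
#' @param config a `simulation_config` object.
#' @return `read_config` returns a `simulation_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sub <- function(name, ctor) {
    if (is.null(raw[[name]])) NULL else do.call(ctor, raw[[name]])
  }
  top <- raw[setdiff(names(raw), c("cpm", "network", "mechanics", "fa"))]
  do.call(simulation_config,
          c(top, list(cpm = sub("cpm", cpm_params),
                      network = sub("network", network_params),
                      mechanics = sub("mechanics", mechanics_params),
                      fa = sub("fa", fa_params))))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- unclass(config)
  for (name in c("cpm", "network", "mechanics", "fa"))
    out[[name]] <- unclass(out[[name]])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation configuration: scenario '%s'\n", x$scenario))
  cat(sprintf("  lattice %d x %d sites (%.1f x %.1f um), %d steps (%.1f h)\n",
              x$lattice_size, x$lattice_size,
              x$lattice_size * x$lattice_spacing,
              x$lattice_size * x$lattice_spacing,
              x$n_steps, x$n_steps * x$step_duration / 3600))
  cat(sprintf("  fibers: %.2f /um^2, K = %.3g N/m, kappa = %.3g; cross-links %.2f /um^2\n",
              x$network$fiber_density, x$network$K_polymer, x$network$kappa,
              x$network$crosslink_density))
  cat(sprintf("  FA: K_cyto = %.3g N/m, tension source '%s'; seed %d\n",
              x$fa$K_cyto, x$fa$tension_source, x$seed))
  invisible(x)
}
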