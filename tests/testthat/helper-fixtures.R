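# Shared fixtures, all built in code.

# CPM energy with raw model-unit coefficients (bypasses unit conversion)
model_energy <- function(grid, lambda, J, lambda_c, A_h) {
  fiberCPM:::cpp_cpm_energy(grid, lambda, J, lambda_c, A_h)
}

# cpm_params whose model coefficients equal the given dimensionless values
# on a 0.25 um lattice
toy_cpm <- function(lambda = 0, J = 0, lambda_c = 0, A_h_sites = 50, T = 50) {
  l_m <- 0.25e-6
  eps <- 1e-17
  cpm_params(lambda = lambda * eps / l_m^4, J = J * eps / l_m^2,
             lambda_c = lambda_c * eps, A_h = A_h_sites * 0.25^2, T = T,
             energy_unit = eps)
}

# hand-built network: pos (n x 2), bonds (i, j, k [nN/um], r0 [um],
# cross), angles (i, j, k, kb [fJ], th0)
make_net <- function(pos, fiber, bonds = NULL, angles = NULL,
                     domain = c(10, 10)) {
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), k = numeric(),
                        r0 = numeric(), cross = logical())
  if (is.null(angles))
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         kb = numeric(), th0 = numeric())
  fiberCPM:::new_fiber_network(pos, fiber, bonds$i, bonds$j, bonds$k,
                               bonds$r0, bonds$cross, angles$i, angles$j,
                               angles$k, angles$kb, angles$th0, domain)
}

# small desk-scale configuration used by the coupled-dynamics tests
desk_config <- function(seed = 1, scenario = "isotropic", n_steps = 100,
                        lattice_size = 48, cell_radius = 9, ...) {
  extent <- lattice_size * 0.25
  dots <- list(...)
  if (is.null(dots$network))
    dots$network <- network_params(domain = c(extent, extent),
                                   kappa = if (scenario == "anisotropic")
                                     10 else 0)
  if (is.null(dots$record)) dots$record <- "mask"
  if (is.null(dots$output_every)) dots$output_every <- max(1, n_steps %/% 4)
  do.call(simulation_config,
          c(list(scenario = scenario, seed = seed, n_steps = n_steps,
                 lattice_size = lattice_size, cell_radius = cell_radius,
                 relax_max_steps = 100, init_relax_max_steps = 500),
            dots))
}

# full Hamiltonian recomputation used as the brute-force oracle for
# incremental energy differences
brute_delta <- function(grid, source, target, lambda, J, lambda_c, A_h) {
  after <- grid
  after[target[1], target[2]] <- grid[source[1], source[2]]
  model_energy(after, lambda, J, lambda_c, A_h) -
    model_energy(grid, lambda, J, lambda_c, A_h)
}
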