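# Cellular Potts lattice: spin field, Hamiltonian, Metropolis dynamics.
# Spins are 0 (medium) or 1 (the single cell); the grid is an integer
# matrix whose [i, j] entry covers the physical square
# [(i-1)*l, i*l) x [(j-1)*l, j*l) um, l the lattice spacing.

#' Create a spin field with a centred disc-shaped cell
#'
#' @param size lattice edge, sites.
#' @param radius initial cell radius, sites (0 gives an empty lattice).
#' @return integer matrix of class `spin_field` with 0/1 spins.
#' @export
spin_field <- function(size, radius = 0) {
  stopifnot(size >= 1, radius >= 0)
  grid <- matrix(0L, size, size)
  if (radius > 0) {
    ctr <- (size + 1) / 2
    idx <- which(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2,
                       "+") <= radius^2)
    grid[idx] <- 1L
  }
  class(grid) <- c("spin_field", class(grid))
  grid
}

cell_area <- function(grid) sum(grid > 0)

# Cell centre of mass in um (site centres), or c(NA, NA) if empty.
cell_center <- function(grid, lattice_spacing = 0.25) {
  idx <- which(grid > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  (colMeans(idx) - 0.5) * lattice_spacing
}

#' Total CPM energy of a spin field
#'
#' Evaluates `H = lambda A^2 + J M - lambda_c A/(A + A_h)` in model units,
#' where `A` is the cell area in sites and `M` the number of ordered
#' mismatched Moore-neighbour pairs (each unordered interface pair counts
#' twice, following the double sum of the Hamiltonian).
#'
#' @param grid a [spin_field()] (any 0/1 integer matrix works).
#' @param cpm a [cpm_params()] object.
#' @param lattice_spacing site edge, um (enters the unit conversion).
#' @return dimensionless energy (units of `cpm$energy_unit`).
#' @export
total_energy <- function(grid, cpm = cpm_params(), lattice_spacing = 0.25) {
  co <- cpm_model_coefficients(cpm, lattice_spacing)
  cpp_cpm_energy(grid, co$lambda, co$J, co$lambda_c, co$A_h)
}

#' Energy change of a single copy attempt
#'
#' Copies the spin at `source` onto `target` (Moore neighbours) and returns
#' `H(after) - H(before)` plus, for retractions from a site holding focal
#' adhesions, the retraction penalty [retraction_penalty()].
#'
#' @param grid a [spin_field()].
#' @param source,target site coordinates `c(i, j)` (1-based row, column).
#' @param cpm a [cpm_params()] object.
#' @param fa_N integrin counts of the FAs at `target` (empty if none).
#' @param fa a [fa_params()] object (penalty constants).
#' @param lattice_spacing site edge, um.
#' @return scalar `Delta H` in model units.
#' @export
copy_attempt_delta <- function(grid, source, target, cpm = cpm_params(),
                               fa_N = numeric(), fa = fa_params(),
                               lattice_spacing = 0.25) {
  stopifnot(length(source) == 2, length(target) == 2)
  if (all(source == target)) stop("source and target must differ")
  if (max(abs(source - target)) > 1) stop("target is not a Moore neighbour")
  s_src <- grid[source[1], source[2]]
  s_tgt <- grid[target[1], target[2]]
  if (s_src == s_tgt) stop("source and target have equal spins")
  co <- cpm_model_coefficients(cpm, lattice_spacing)
  A <- cell_area(grid)
  A2 <- A + if (s_src > 0) 1 else -1
  adh <- function(a) if (a > 0) co$lambda_c * a / (a + co$A_h) else 0
  dH <- co$lambda * (A2^2 - A^2) - (adh(A2) - adh(A)) +
    co$J * cpp_interface_delta(grid, target[1] - 1L, target[2] - 1L, s_src)
  if (s_src == 0 && length(fa_N) > 0)
    dH <- dH + retraction_penalty(fa_N, fa)
  dH
}

#' Metropolis acceptance rule
#'
#' Accepts with probability 1 when `delta_h <= 0` and `exp(-delta_h / T)`
#' otherwise (energy-minimising convention).
#'
#' @param delta_h energy change(s), model units.
#' @param T motility temperature (> 0).
#' @return logical vector of acceptances (consumes one uniform draw per
#'   attempt with `delta_h > 0`).
#' @export
metropolis_accept <- function(delta_h, T) {
  stopifnot(T > 0)
  acc <- delta_h <= 0
  hot <- !acc
  if (any(hot)) acc[hot] <- runif(sum(hot)) < exp(-delta_h[hot] / T)
  acc
}

#' One Monte Carlo step of the coupled cell state
#'
#' Performs `length(grid)` elementary copy attempts (source site uniform,
#' target a uniform Moore neighbour; attempts with equal spins or targeting
#' the outermost lattice ring are consumed without effect).  Accepted
#' retractions remove the FAs left outside the cell; accepted extensions
#' over a site holding a free network bead create a nascent FA (`N = N0`)
#' bound to the bead nearest the site centre, which is pinned there.
#'
#' This is the low-level sweep; [simulation_step()] embeds it in the
#' operator-splitting cycle.  Uses the current R RNG state.
#'
#' @param state simulation state (see [initialize_state()]).
#' @param config a [simulation_config()].
#' @return the updated state; `state$events` holds the accepted copy events
#'   of this sweep (source/target linear indices, kind, FA bookkeeping).
#' @export
monte_carlo_step <- function(state, config) {
  co <- cpm_model_coefficients(config$cpm, config$lattice_spacing)
  fa <- config$fa
  net <- state$network
  res <- cpp_monte_carlo_step(
    state$grid, length(state$grid),
    co$lambda, co$J, co$lambda_c, co$A_h, co$T,
    as.integer(state$fas$site - 1L), state$fas$N,
    as.integer(state$fas$bead - 1L),
    fa$N0, fa$N_h, fa$lambda_FA,
    net$pos, !net$clamped & !net$fa_bound,
    config$lattice_spacing, TRUE)
  grid <- res$grid
  class(grid) <- class(state$grid)
  state$grid <- grid
  state$area <- res$area
  net$pos <- res$bead_pos
  net$fa_bound <- !res$bead_free & !net$clamped
  state$network <- net

  fas <- state$fas[res$fa_alive, , drop = FALSE]
  n_new <- length(res$created_bead)
  if (n_new > 0) {
    site <- res$created_site + 1L
    L <- nrow(grid)
    fas <- rbind(fas, data.frame(
      id = state$next_fa_id + seq_len(n_new) - 1L,
      site = site,
      x = (site - 1L) %% L + 1L,
      y = (site - 1L) %/% L + 1L,
      bead = res$created_bead + 1L,
      N = rep(fa$N0, n_new),
      Phi = rep(0, n_new)))
    state$next_fa_id <- state$next_fa_id + n_new
  }
  rownames(fas) <- NULL
  state$fas <- fas
  state$events <- data.frame(
    source = res$ev_source + 1L, target = res$ev_target + 1L,
    kind = c("extension", "retraction")[res$ev_kind],
    fa_created_bead = ifelse(res$ev_fa_created >= 0,
                             res$ev_fa_created + 1L, NA_integer_),
    fa_removed = res$ev_fa_removed)
  state
}
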