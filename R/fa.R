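# Focal adhesions: catch-slip integrin kinetics, tension, greedy
# displacement, retraction penalty, creation/removal.
# FA registry columns: id, site (column-major linear index), x, y (row,
# column), bead (index into the network), N (bound integrins), Phi
# (tension, newtons).

#' Catch-slip detachment rate factor
#'
#' `d(phi) = exp(phi - phi_s) + exp(phi_c - phi)`: detachment is high at
#' low tension (catch branch), minimal at `phi = (phi_s + phi_c)/2`, and
#' grows again at high tension (slip branch).
#'
#' @param phi tension per integrin (dimensionless, `f_star * Phi / N`).
#' @param fa a [fa_params()] object.
#' @return rate factor(s), dimensionless; exponents are capped at 500 to
#'   avoid overflow.
#' @export
catch_slip_rate <- function(phi, fa = fa_params()) {
  exp(pmin(phi - fa$phi_s, 500)) + exp(pmin(fa$phi_c - phi, 500))
}

#' Analytic steady state of the integrin cluster ODE at fixed phi
#'
#' For a per-integrin tension held constant, `dN/dt = 0` gives
#' `N* = gamma N_tot / (gamma + d0 d(phi))`.
#'
#' @param phi tension per integrin (dimensionless).
#' @param fa a [fa_params()] object.
#' @return steady-state integrin count(s).
#' @export
fa_steady_state <- function(phi, fa = fa_params()) {
  fa$gamma * fa$N_tot / (fa$gamma + fa$d0 * catch_slip_rate(phi, fa))
}

#' Retraction penalty for breaking the adhesions at a lattice site
#'
#' With `X = max(0, sum(N - N0))` over the FAs at the site, the penalty is
#' `lambda_FA * X / (X + N_h)`: nascent adhesions are free to release,
#' mature clusters add up to `lambda_FA` to the energy cost.
#'
#' @param fa_N integrin counts of the FAs at the site (non-empty).
#' @param fa a [fa_params()] object.
#' @return scalar penalty, model energy units.
#' @export
retraction_penalty <- function(fa_N, fa = fa_params()) {
  stopifnot(length(fa_N) >= 1)
  X <- max(0, sum(fa_N - fa$N0))
  fa$lambda_FA * X / (X + fa$N_h)
}

#' Cytoskeletal spring tension on an adhesion
#'
#' The cell's cytoskeleton is modelled as a spring joining each FA to the
#' cell centre: `Phi = K_cyto * |x - x_center|`.
#'
#' @param pos FA position(s), um; vector `c(x, y)` or an n x 2 matrix.
#' @param center cell centre, um.
#' @param fa a [fa_params()] object (`K_cyto`, scaled by
#'   `contraction_multiplier`).
#' @return tension(s) in newtons.
#' @export
fa_tension <- function(pos, center, fa = fa_params()) {
  pos <- matrix(pos, ncol = 2)
  d_um <- sqrt((pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2)
  fa$K_cyto * fa$contraction_multiplier * d_um * 1e-6
}

#' Advance the integrin cluster ODE
#'
#' Integrates `dN/dt = gamma (N_tot - N) - d0 d(f_star Phi / N) N` over a
#' duration `tau` at fixed tension `Phi`, by exponential (exact-linear)
#' substeps: within each substep the detachment rate is frozen at the
#' current `N`, for which the ODE is linear and solved exactly.  This is
#' unconditionally stable also deep in the slip regime, where the
#' detachment rate can exceed 1e20.  The result is clamped to
#' `[N_min, N_tot]`.
#'
#' @param N current integrin count(s).
#' @param Phi tension(s), newtons.
#' @param fa a [fa_params()] object.
#' @param tau integration time, s (default `fa$tau`, one coupling step).
#' @param n_sub number of substeps.
#' @return updated integrin count(s).
#' @export
integrate_integrins <- function(N, Phi, fa = fa_params(), tau = fa$tau,
                                n_sub = 10) {
  stopifnot(all(N > 0), all(Phi >= 0), tau > 0)
  dt <- tau / n_sub
  for (q in seq_len(n_sub)) {
    r <- fa$d0 * catch_slip_rate(fa$f_star * Phi / N, fa)
    Nstar <- fa$gamma * fa$N_tot / (fa$gamma + r)
    N <- Nstar + (N - Nstar) * exp(-(fa$gamma + r) * dt)
    N <- pmin(pmax(N, fa$N_min), fa$N_tot)
  }
  N
}

# bead -> incident bond indices (topology is static during a run)
bond_adjacency <- function(net) {
  n <- nrow(net$pos)
  adj <- vector("list", n)
  both <- c(net$bond_i, net$bond_j)
  eidx <- rep(seq_along(net$bond_i), 2)
  sp <- split(eidx, both)
  adj[as.integer(names(sp))] <- sp
  adj
}

# energy (fJ) of the springs incident to bead b if it sat at position p
local_ecm_energy <- function(net, adj, b, p) {
  e <- adj[[b]]
  if (is.null(e) || length(e) == 0) return(0)
  other <- ifelse(net$bond_i[e] == b, net$bond_j[e], net$bond_i[e])
  d <- sqrt((p[1] - net$pos[other, 1])^2 + (p[2] - net$pos[other, 2])^2)
  sum(0.5 * net$bond_k[e] * (net$bond_r0[e] - d)^2)
}

#' Greedy displacement of focal adhesions toward the cell centre
#'
#' For each FA, in ascending id order: the Moore-neighbour lattice site
#' whose offset best aligns with the direction to the cell centre is the
#' candidate; the move is accepted iff it lowers
#' `E = (K_cyto/2)|x - x_center|^2 + E_ecm`, where `E_ecm` sums only the
#' springs directly attached to the FA bead.  Moves are independent;
#' several FAs may end up on one site.  Candidates outside the cell mask
#' are rejected, which keeps every FA under the cell.
#'
#' @param state simulation state.
#' @param config a [simulation_config()].
#' @return the updated state; `state$fa_moves` counts accepted moves.
#' @export
displace_fas <- function(state, config) {
  fas <- state$fas
  state$fa_moves <- 0L
  if (nrow(fas) == 0) return(state)
  net <- state$network
  adj <- state$bond_adj
  ls <- config$lattice_spacing
  kc <- config$fa$K_cyto * config$fa$contraction_multiplier *
    N_PER_M_TO_NN_PER_UM                      # nN/um
  ctr <- state$center
  L <- nrow(state$grid)
  moves <- 0L
  for (q in order(fas$id)) {
    b <- fas$bead[q]
    p <- net$pos[b, ]
    dvec <- ctr - p
    if (sqrt(sum(dvec^2)) < ls / 2) next      # already at the centre site
    best <- best_center_neighbor(fas$x[q], fas$y[q], dvec)
    nx <- best[1]
    ny <- best[2]
    if (nx < 1 || nx > L || ny < 1 || ny > L) next
    if (state$grid[nx, ny] == 0) next         # keep the FA under the cell
    p_new <- (c(nx, ny) - 0.5) * ls
    E0 <- 0.5 * kc * sum((p - ctr)^2) + local_ecm_energy(net, adj, b, p)
    E1 <- 0.5 * kc * sum((p_new - ctr)^2) +
      local_ecm_energy(net, adj, b, p_new)
    if (E1 - E0 < 0) {
      net$pos[b, ] <- p_new
      fas$x[q] <- nx
      fas$y[q] <- ny
      fas$site[q] <- nx + (ny - 1L) * L
      moves <- moves + 1L
    }
  }
  state$network <- net
  state$fas <- fas
  state$fa_moves <- moves
  state
}

# Moore neighbour whose offset minimises the angle to dvec (um direction)
best_center_neighbor <- function(x, y, dvec) {
  di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cosang <- (di * dvec[1] + dj * dvec[2]) /
    (sqrt(di^2 + dj^2) * sqrt(sum(dvec^2)))
  k <- which.max(cosang)
  c(x + di[k], y + dj[k])
}

#' Create or remove a focal adhesion
#'
#' `create_fa` binds a free (unclamped, unbound) bead lying under `site`
#' into a nascent adhesion (`N = N0`), pinning the bead to the site centre;
#' `remove_fa` deletes an adhesion and frees its bead.
#'
#' @param state simulation state.
#' @param site lattice site `c(row, column)`, must be inside the cell.
#' @param bead bead index; must not be clamped or already bound.
#' @param id FA id to remove.
#' @param config a [simulation_config()].
#' @return the updated state.
#' @export
create_fa <- function(state, site, bead, config) {
  net <- state$network
  if (net$clamped[bead]) stop("cannot adhere to a clamped bead")
  if (net$fa_bound[bead]) stop("bead is already bound to an FA")
  if (state$grid[site[1], site[2]] == 0) stop("site is not inside the cell")
  L <- nrow(state$grid)
  net$fa_bound[bead] <- TRUE
  net$pos[bead, ] <- (site - 0.5) * config$lattice_spacing
  state$network <- net
  state$fas <- rbind(state$fas, data.frame(
    id = state$next_fa_id, site = site[1] + (site[2] - 1L) * L,
    x = site[1], y = site[2], bead = bead, N = config$fa$N0, Phi = 0))
  state$next_fa_id <- state$next_fa_id + 1L
  state
}

#' @rdname create_fa
#' @export
remove_fa <- function(state, id) {
  q <- which(state$fas$id == id)
  if (length(q) != 1) stop("no such FA")
  state$network$fa_bound[state$fas$bead[q]] <- FALSE
  state$fas <- state$fas[-q, , drop = FALSE]
  state
}

# recompute the tension column of the FA registry
recompute_tension <- function(state, config) {
  fas <- state$fas
  if (nrow(fas) == 0) return(state)
  if (config$fa$tension_source == "ecm") {
    F <- network_forces(state$network, strict = FALSE)
    f_nn <- sqrt(F[fas$bead, 1]^2 + F[fas$bead, 2]^2)
    fas$Phi <- f_nn * 1e-9                   # nN -> N
  } else {
    fas$Phi <- fa_tension(state$network$pos[fas$bead, , drop = FALSE],
                          state$center, config$fa)
  }
  state$fas <- fas
  state
}
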