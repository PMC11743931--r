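# Operator-splitting master loop: CPM sweep -> centre refresh -> greedy FA
# displacement -> ECM relaxation (FA beads pinned) -> tension update ->
# integrin ODE.  One coupling step corresponds to step_duration seconds.

#' Initialise the coupled simulation state
#'
#' Builds the scenario network (relaxing it to its unloaded state), places
#' a disc-shaped cell at the lattice centre, and sets up the per-sub-model
#' RNG streams derived from the master seed.
#'
#' @param config a [simulation_config()].
#' @return a state list (grid, area, center, network, fas, bond_adj,
#'   rng, step).
#' @export
initialize_state <- function(config) {
  streams <- make_rng_streams(config$seed)
  net <- stream_eval(streams, "network", {
    if (config$scenario == "grid") {
      generate_grid_network(config$network, config$grid_spacing)
    } else {
      generate_network(config$network)
    }
  })
  mech0 <- config$mechanics
  mech0$max_steps <- config$init_relax_max_steps
  net <- stream_eval(streams, "ecm", relax_network(net, mech0))
  grid <- spin_field(config$lattice_size, config$cell_radius)
  state <- list(
    grid = grid,
    area = cell_area(grid),
    center = cell_center(grid, config$lattice_spacing),
    network = net,
    fas = empty_fa_table(),
    next_fa_id = 1L,
    bond_adj = bond_adjacency(net),
    clamp_pos = net$pos[net$clamped, , drop = FALSE],
    rng = streams,
    step = 0L,
    events = NULL,
    fa_moves = 0L)
  audit_state(state, config)
  state
}

empty_fa_table <- function() {
  data.frame(id = integer(), site = integer(), x = integer(), y = integer(),
             bead = integer(), N = numeric(), Phi = numeric())
}

# consistency audit: FA <-> bead bijection, FAs under the cell, clamped
# beads immobile
audit_state <- function(state, config) {
  net <- state$network
  fas <- state$fas
  ok <- sum(net$fa_bound) == nrow(fas) &&
    !anyDuplicated(fas$bead) &&
    (nrow(fas) == 0 || all(net$fa_bound[fas$bead])) &&
    (nrow(fas) == 0 || all(state$grid[cbind(fas$x, fas$y)] > 0)) &&
    state$area == cell_area(state$grid) &&
    isTRUE(all.equal(net$pos[net$clamped, , drop = FALSE], state$clamp_pos,
                     check.attributes = FALSE))
  if (!ok) stop("state audit failed: FA/bead registry inconsistent")
  invisible(TRUE)
}

#' One operator-splitting step of the coupled model
#'
#' Executes, in order: (1) one CPM Monte Carlo sweep (with FA creation and
#' removal); (2) cell centre-of-mass refresh; (3) one greedy displacement
#' attempt per FA; (4) relaxation of the network with adhesion beads
#' pinned (every `relax_every` steps); (5) tension update for all FAs;
#' (6) one `step_duration` advance of every FA's integrin ODE.
#'
#' @param state simulation state from [initialize_state()].
#' @param config a [simulation_config()].
#' @return the updated state.
#' @export
simulation_step <- function(state, config) {
  state <- stream_eval(state$rng, "cpm", monte_carlo_step(state, config))
  state$center <- cell_center(state$grid, config$lattice_spacing)
  if (anyNA(state$center)) {     # cell vanished: nothing left to couple
    state$step <- state$step + 1L
    return(state)
  }
  state <- displace_fas(state, config)
  if (state$step %% config$relax_every == 0L) {
    mech <- config$mechanics
    mech$max_steps <- config$relax_max_steps
    state$network <- stream_eval(state$rng, "ecm",
                                 relax_network(state$network, mech))
  }
  state <- recompute_tension(state, config)
  if (nrow(state$fas) > 0) {
    state$fas$N <- integrate_integrins(state$fas$N, state$fas$Phi,
                                       config$fa,
                                       tau = config$step_duration)
  }
  state$step <- state$step + 1L
  audit_state(state, config)
  state
}

#' Run a full simulation
#'
#' Initialises the configured scenario and iterates [simulation_step()]
#' `n_steps` times, recording metrics (and optional snapshots) every
#' `output_every` steps, including the initial and final states.
#'
#' @param config a [simulation_config()].
#' @param verbose print progress messages.
#' @return a `cpm_trajectory`: list with `config`, `metrics` (one row per
#'   recorded step: step, time_s, area (sites), area_um2, center, ecc,
#'   n_fas, mean_N, median_Phi_nN, fa_moves), `snapshots` (per recorded
#'   step, the requested subset of mask/beads/fas), `initial_beads`, and
#'   `final_state`.
#' @export
run_simulation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  state <- initialize_state(config)
  rec_steps <- unique(c(0L, seq_len(config$n_steps)[
    seq_len(config$n_steps) %% config$output_every == 0L], config$n_steps))
  metrics <- vector("list", length(rec_steps))
  snapshots <- vector("list", length(rec_steps))
  initial_beads <- state$network$pos
  r <- 1L
  record <- function(state) {
    fas <- state$fas
    metrics[[r]] <<- data.frame(
      step = state$step,
      time_s = state$step * config$step_duration,
      area = state$area,
      area_um2 = sites_to_um(state$area, config$lattice_spacing, area = TRUE),
      center_x = state$center[1], center_y = state$center[2],
      eccentricity = if (state$area > 0) cell_eccentricity(state$grid)
                     else NA_real_,
      n_fas = nrow(fas),
      mean_N = if (nrow(fas) > 0) mean(fas$N) else NA_real_,
      median_Phi_nN = if (nrow(fas) > 0) median(fas$Phi) * 1e9 else NA_real_,
      fa_moves = state$fa_moves)
    snap <- list(step = state$step)
    if ("mask" %in% config$record) snap$mask <- state$grid > 0
    if ("beads" %in% config$record) snap$beads <- state$network$pos
    if ("fas" %in% config$record) snap$fas <- fas
    snapshots[[r]] <<- snap
    r <<- r + 1L
  }
  record(state)
  for (s in seq_len(config$n_steps)) {
    state <- simulation_step(state, config)
    if (s %in% rec_steps) record(state)
    if (verbose && s %% max(1L, config$n_steps %/% 10L) == 0L)
      message(sprintf("step %d/%d: area %d sites, %d FAs",
                      s, config$n_steps, state$area, nrow(state$fas)))
  }
  structure(list(config = config,
                 metrics = do.call(rbind, metrics),
                 snapshots = snapshots,
                 initial_beads = initial_beads,
                 final_state = state),
            class = "cpm_trajectory")
}

#' @export
print.cpm_trajectory <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Trajectory: scenario '%s', %d steps (%.1f h), seed %d\n",
              x$config$scenario, max(m$step),
              max(m$time_s) / 3600, x$config$seed))
  cat(sprintf("  cell area %d -> %d sites (%.1f -> %.1f um^2)\n",
              m$area[1], tail(m$area, 1), m$area_um2[1],
              tail(m$area_um2, 1)))
  cat(sprintf("  final: eccentricity %.3f, %d FAs, median tension %.2f nN\n",
              tail(m$eccentricity, 1), tail(m$n_fas, 1),
              tail(m$median_Phi_nN, 1)))
  invisible(x)
}

#' @export
summary.cpm_trajectory <- function(object, ...) {
  m <- object$metrics
  out <- list(
    scenario = object$config$scenario,
    steps = max(m$step),
    area_initial = m$area[1],
    area_final = tail(m$area, 1),
    area_change = tail(m$area, 1) - m$area[1],
    eccentricity_final = tail(m$eccentricity, 1),
    n_fas_final = tail(m$n_fas, 1),
    median_Phi_nN_final = tail(m$median_Phi_nN, 1),
    mean_N_final = tail(m$mean_N, 1))
  class(out) <- "summary.cpm_trajectory"
  out
}

#' @export
print.summary.cpm_trajectory <- function(x, ...) {
  cat(sprintf("Scenario '%s', %d steps\n", x$scenario, x$steps))
  cat(sprintf("  area: %d -> %d sites (change %+d)\n", x$area_initial,
              x$area_final, x$area_change))
  cat(sprintf("  eccentricity %.3f; FAs %d (mean N %.1f, median Phi %.2f nN)\n",
              x$eccentricity_final, x$n_fas_final, x$mean_N_final,
              x$median_Phi_nN_final))
  invisible(x)
}

#' Plot a trajectory
#'
#' Area and eccentricity time courses, plus (if recorded) the final cell
#' mask with the network and FAs overlaid.
#'
#' @param x a `cpm_trajectory`.
#' @param ... unused.
#' @export
plot.cpm_trajectory <- function(x, ...) {
  m <- x$metrics
  old <- graphics::par(mfrow = c(1, if (is.null(x$snapshots[[1]]$mask)) 2
                                    else 3))
  on.exit(graphics::par(old))
  plot(m$step, m$area_um2, type = "l", xlab = "step",
       ylab = "cell area (um^2)", main = "spreading")
  plot(m$step, m$eccentricity, type = "l", xlab = "step",
       ylab = "eccentricity", main = "elongation", ylim = c(0, 1))
  snap <- x$snapshots[[length(x$snapshots)]]
  if (!is.null(snap$mask)) {
    ls <- x$config$lattice_spacing
    graphics::image(seq_len(nrow(snap$mask)) * ls - ls / 2,
                    seq_len(ncol(snap$mask)) * ls - ls / 2,
                    snap$mask, col = c("white", "mistyrose"),
                    xlab = "x (um)", ylab = "y (um)", main = "final state",
                    useRaster = TRUE)
    if (!is.null(snap$beads))
      graphics::points(snap$beads, pch = ".", col = "grey50")
    if (!is.null(snap$fas) && nrow(snap$fas) > 0)
      graphics::points((snap$fas$x - 0.5) * ls, (snap$fas$y - 0.5) * ls,
                       pch = 19, col = "darkgreen",
                       cex = 0.4 + snap$fas$N / x$config$fa$N_tot)
  }
  invisible(x)
}

#' Write the cell mask as CSV or PGM
#'
#' @param grid a [spin_field()] (or logical mask).
#' @param path output file; `write_mask_csv` writes `x,y` rows of cell
#'   sites, `write_mask_pgm` a portable graymap.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(grid, path) {
  idx <- which(grid > 0, arr.ind = TRUE)
  write.csv(data.frame(x = idx[, 1], y = idx[, 2]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
write_mask_pgm <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(grid), ncol(grid)), "1"), con)
  apply(t(grid > 0) * 1L, 1, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Write the FA table as CSV
#'
#' Columns: id, site_x, site_y, bead_id, N, Phi_nN.
#'
#' @param fas the FA registry (`state$fas` or a snapshot).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fa_csv <- function(fas, path) {
  write.csv(data.frame(id = fas$id, site_x = fas$x, site_y = fas$y,
                       bead_id = fas$bead, N = fas$N,
                       Phi_nN = fas$Phi * 1e9),
            path, row.names = FALSE)
  invisible(path)
}
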