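# Fiber network construction.  Internal mechanical units: length um,
# force nN, energy fJ (= nN um = 1e-15 J); spring constants given in N/m
# are converted on construction (1 N/m = 1000 nN/um), bending rigidities
# in N m rad^-2 to fJ rad^-2 (x 1e15).

new_fiber_network <- function(pos, fiber, bond_i, bond_j, bond_k, bond_r0,
                              bond_cross, ang_i, ang_j, ang_k, ang_kb,
                              ang_th0, domain) {
  pos <- as.matrix(pos)
  inside <- pos[, 1] >= 0 & pos[, 1] <= domain[1] &
            pos[, 2] >= 0 & pos[, 2] <= domain[2]
  structure(list(
    pos = pos, fiber = as.integer(fiber),
    bond_i = as.integer(bond_i), bond_j = as.integer(bond_j),
    bond_k = as.numeric(bond_k), bond_r0 = as.numeric(bond_r0),
    bond_cross = as.logical(bond_cross),
    ang_i = as.integer(ang_i), ang_j = as.integer(ang_j),
    ang_k = as.integer(ang_k), ang_kb = as.numeric(ang_kb),
    ang_th0 = as.numeric(ang_th0),
    clamped = !inside,
    fa_bound = logical(nrow(pos)),
    domain = as.numeric(domain)), class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf(
    "Fiber network: %d beads on %d fibers, %d fiber springs, %d cross-links\n",
    nrow(x$pos), length(unique(x$fiber[x$fiber > 0])),
    sum(!x$bond_cross), sum(x$bond_cross)))
  cat(sprintf("  domain %.1f x %.1f um; %d clamped, %d adhesion-bound beads\n",
              x$domain[1], x$domain[2], sum(x$clamped), sum(x$fa_bound)))
  invisible(x)
}

#' Von Mises random angles
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on `[0, 2*pi)`.
#'
#' @param n number of draws.
#' @param mu mean direction, rad.
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0, n >= 0)
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (q in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[q] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

#' Sample the bead positions of one fiber
#'
#' The middle bead (`k = floor(n_beads / 2)`, 0-based) is placed uniformly
#' in the domain and the fiber laid out straight through it at an angle
#' drawn from the von Mises distribution: bead `i` sits at
#' `b_k + (i - k) * r_polymer * (cos(theta), sin(theta))`.  The middle bead
#' is always inside the domain; endpoints may extend beyond.
#'
#' @param params a [network_params()] object.
#' @param theta optional fixed orientation (skips the von Mises draw).
#' @param center optional fixed middle-bead position `c(x, y)` um.
#' @return `n_beads` x 2 matrix of positions, um.
#' @export
sample_fiber <- function(params, theta = NULL, center = NULL) {
  n <- params$n_beads
  k <- floor(n / 2)
  if (is.null(center))
    center <- c(runif(1, 0, params$domain[1]), runif(1, 0, params$domain[2]))
  if (is.null(theta)) theta <- rvonmises(1, params$mu, params$kappa)
  off <- (seq_len(n) - 1 - k) * params$r_polymer
  cbind(center[1] + off * cos(theta), center[2] + off * sin(theta))
}

# shared assembly of fiber bonds/angles from per-fiber bead counts
fiber_topology <- function(counts) {
  stops <- cumsum(counts)
  starts <- stops - counts + 1
  bi <- bj <- integer(0)
  ai <- aj <- ak <- integer(0)
  for (f in seq_along(counts)) {
    idx <- starts[f]:stops[f]
    bi <- c(bi, idx[-length(idx)])
    bj <- c(bj, idx[-1])
    if (counts[f] >= 3) {
      ai <- c(ai, idx[1:(counts[f] - 2)])
      aj <- c(aj, idx[2:(counts[f] - 1)])
      ak <- c(ak, idx[3:counts[f]])
    }
  }
  list(bi = bi, bj = bj, ai = ai, aj = aj, ak = ak)
}

#' Generate a random cross-linked fiber network
#'
#' Draws `round(fiber_density * domain area)` fibers with [sample_fiber()],
#' then adds cross-links: all bead pairs on distinct fibers within
#' `capture_radius` are enumerated, shuffled with the current RNG, and
#' accepted until `round(crosslink_density * domain area)` cross-links are
#' placed or candidates run out (with a warning).  Beads outside the domain
#' are clamped.
#'
#' @param params a [network_params()] object.
#' @param n_strands override the fiber count (default from
#'   `fiber_density`).
#' @return a `fiber_network`.
#' @export
generate_network <- function(params = network_params(), n_strands = NULL) {
  area <- prod(params$domain)
  if (is.null(n_strands)) n_strands <- round(params$fiber_density * area)
  n_strands <- as.integer(n_strands)
  stopifnot(n_strands >= 0)
  nb <- params$n_beads
  pos <- matrix(0, n_strands * nb, 2)
  for (f in seq_len(n_strands))
    pos[(f - 1) * nb + seq_len(nb), ] <- sample_fiber(params)
  fiber <- rep(seq_len(n_strands), each = nb)
  topo <- fiber_topology(rep(nb, n_strands))
  k_nn <- params$K_polymer * N_PER_M_TO_NN_PER_UM
  kb_fj <- params$K_bend * J_TO_FJ
  net <- new_fiber_network(
    pos, fiber,
    topo$bi, topo$bj, rep(k_nn, length(topo$bi)),
    rep(params$r_polymer, length(topo$bi)), rep(FALSE, length(topo$bi)),
    topo$ai, topo$aj, topo$ak, rep(kb_fj, length(topo$ai)),
    rep(params$theta_0, length(topo$ai)), params$domain)

  target <- round(params$crosslink_density * area)
  if (target > 0 && n_strands > 1) {
    cand <- cpp_crosslink_candidates(net$pos, net$fiber,
                                     params$capture_radius)
    if (nrow(cand) > 0) cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    if (nrow(cand) < target)
      warning(sprintf(
        "cross-link candidates exhausted: placed %d of %d requested",
        nrow(cand), target))
    take <- head(seq_len(nrow(cand)), target)
    if (length(take) > 0) {
      kx <- params$K_cross * N_PER_M_TO_NN_PER_UM
      net$bond_i <- c(net$bond_i, cand[take, 1] + 1L)
      net$bond_j <- c(net$bond_j, cand[take, 2] + 1L)
      net$bond_k <- c(net$bond_k, rep(kx, length(take)))
      net$bond_r0 <- c(net$bond_r0,
                       rep(params$crosslink_rest_length, length(take)))
      net$bond_cross <- c(net$bond_cross, rep(TRUE, length(take)))
    }
  }
  net
}

#' Generate a regular grid network
#'
#' Long vertical and horizontal strands spanning the domain (end beads
#' extend beyond the boundary and are therefore clamped), cross-linked at
#' every intersection.  Cross-link rest length equals the bead separation
#' at creation, so the undeformed grid is stress-free.
#'
#' @param params a [network_params()] object.
#' @param spacing strand spacing, um (must divide both domain edges).
#' @return a `fiber_network`.
#' @export
generate_grid_network <- function(params = network_params(), spacing = 1) {
  dom <- params$domain
  nv <- round(dom[1] / spacing)
  nh <- round(dom[2] / spacing)
  stopifnot(abs(nv * spacing - dom[1]) < 1e-9,
            abs(nh * spacing - dom[2]) < 1e-9, nv >= 1, nh >= 1)
  r <- params$r_polymer
  along_y <- seq(-r / 2, dom[2] + r / 2 + 1e-9, by = r)
  along_x <- seq(-r / 2, dom[1] + r / 2 + 1e-9, by = r)
  xv <- (seq_len(nv) - 0.5) * spacing
  yh <- (seq_len(nh) - 0.5) * spacing
  pos_list <- list()
  counts <- integer(0)
  for (x in xv) {
    pos_list[[length(pos_list) + 1]] <- cbind(rep(x, length(along_y)), along_y)
    counts <- c(counts, length(along_y))
  }
  for (y in yh) {
    pos_list[[length(pos_list) + 1]] <- cbind(along_x, rep(y, length(along_x)))
    counts <- c(counts, length(along_x))
  }
  pos <- do.call(rbind, pos_list)
  fiber <- rep(seq_along(counts), counts)
  topo <- fiber_topology(counts)
  k_nn <- params$K_polymer * N_PER_M_TO_NN_PER_UM
  kb_fj <- params$K_bend * J_TO_FJ
  net <- new_fiber_network(
    pos, fiber,
    topo$bi, topo$bj, rep(k_nn, length(topo$bi)),
    rep(r, length(topo$bi)), rep(FALSE, length(topo$bi)),
    topo$ai, topo$aj, topo$ak, rep(kb_fj, length(topo$ai)),
    rep(params$theta_0, length(topo$ai)), dom)

  # one cross-link per strand intersection (nearest beads on each strand)
  starts <- cumsum(counts) - counts
  kx <- params$K_cross * N_PER_M_TO_NN_PER_UM
  ci <- cj <- integer(0)
  cr <- numeric(0)
  for (v in seq_len(nv)) {
    for (h in seq_len(nh)) {
      bv <- starts[v] + which.min(abs(along_y - yh[h]))
      bh <- starts[nv + h] + which.min(abs(along_x - xv[v]))
      ci <- c(ci, bv)
      cj <- c(cj, bh)
      cr <- c(cr, sqrt(sum((net$pos[bv, ] - net$pos[bh, ])^2)))
    }
  }
  net$bond_i <- c(net$bond_i, ci)
  net$bond_j <- c(net$bond_j, cj)
  net$bond_k <- c(net$bond_k, rep(kx, length(ci)))
  net$bond_r0 <- c(net$bond_r0, cr)
  net$bond_cross <- c(net$bond_cross, rep(TRUE, length(ci)))
  net
}

#' Does a network percolate across the domain?
#'
#' Builds the graph of beads joined by fiber springs and cross-links and
#' asks whether some connected component touches both opposite sides of the
#' domain (x: beads at `x <= 0` and `x >= Lx`; likewise y).
#'
#' @param network a `fiber_network`.
#' @return list with logical `percolates` (either axis), `x` and `y`.
#' @export
is_percolated <- function(network) {
  n <- nrow(network$pos)
  if (n == 0 || length(network$bond_i) == 0)
    return(list(percolates = FALSE, x = FALSE, y = FALSE))
  g <- igraph::make_graph(rbind(network$bond_i, network$bond_j),
                          n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  eps <- 1e-9
  lo_x <- network$pos[, 1] <= eps
  hi_x <- network$pos[, 1] >= network$domain[1] - eps
  lo_y <- network$pos[, 2] <= eps
  hi_y <- network$pos[, 2] >= network$domain[2] - eps
  span <- function(lo, hi)
    length(intersect(unique(comp[lo]), unique(comp[hi]))) > 0
  px <- span(lo_x, hi_x)
  py <- span(lo_y, hi_y)
  list(percolates = px || py, x = px, y = py)
}

# structural audit used by tests and the state audit
validate_network <- function(net) {
  stopifnot(nrow(net$pos) == length(net$fiber),
            length(net$bond_i) == length(net$bond_j),
            all(net$bond_i >= 1), all(net$bond_j <= nrow(net$pos)),
            all(net$bond_i != net$bond_j))
  if (length(net$ang_i) > 0) {
    same_fiber <- net$fiber[net$ang_i] == net$fiber[net$ang_j] &
                  net$fiber[net$ang_j] == net$fiber[net$ang_k]
    consecutive <- (net$ang_j == net$ang_i + 1L) & (net$ang_k == net$ang_j + 1L)
    stopifnot(all(same_fiber), all(consecutive))
  }
  if (any(net$bond_cross))
    stopifnot(all(net$fiber[net$bond_i[net$bond_cross]] !=
                  net$fiber[net$bond_j[net$bond_cross]]))
  stopifnot(!any(net$fa_bound & net$clamped))
  invisible(TRUE)
}

#' Write / read a network as a CSV trio
#'
#' `beads.csv` (id, x, y, clamped, fiber_id, fa_bound), `bonds.csv`
#' (i, j, k_stiff, rest, is_crosslink; stiffness in nN/um) and `angles.csv`
#' (i, j, k, k_bend, theta_0; rigidity in fJ/rad^2) under `dir`.
#'
#' @param network a `fiber_network`.
#' @param dir directory (created if missing).
#' @return `write_network_csv` the directory, `read_network_csv` a
#'   `fiber_network`, invisibly/respectively.
#' @export
write_network_csv <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(id = seq_len(nrow(network$pos)),
                       x = network$pos[, 1], y = network$pos[, 2],
                       clamped = network$clamped, fiber_id = network$fiber,
                       fa_bound = network$fa_bound),
            file.path(dir, "beads.csv"), row.names = FALSE)
  write.csv(data.frame(i = network$bond_i, j = network$bond_j,
                       k_stiff = network$bond_k, rest = network$bond_r0,
                       is_crosslink = network$bond_cross),
            file.path(dir, "bonds.csv"), row.names = FALSE)
  write.csv(data.frame(i = network$ang_i, j = network$ang_j,
                       k = network$ang_k, k_bend = network$ang_kb,
                       theta_0 = network$ang_th0),
            file.path(dir, "angles.csv"), row.names = FALSE)
  writeLines(paste(network$domain, collapse = ","),
             file.path(dir, "domain.txt"))
  invisible(dir)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(dir) {
  beads <- read.csv(file.path(dir, "beads.csv"))
  bonds <- read.csv(file.path(dir, "bonds.csv"))
  angles <- read.csv(file.path(dir, "angles.csv"))
  domain <- as.numeric(strsplit(readLines(file.path(dir, "domain.txt")),
                                ",")[[1]])
  net <- new_fiber_network(cbind(beads$x, beads$y), beads$fiber_id,
                           bonds$i, bonds$j, bonds$k_stiff, bonds$rest,
                           bonds$is_crosslink, angles$i, angles$j, angles$k,
                           angles$k_bend, angles$theta_0, domain)
  net$fa_bound <- as.logical(beads$fa_bound)
  net
}

#' Write a network as legacy VTK polydata (for visualisation)
#'
#' @param network a `fiber_network`.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_network_vtk <- function(network, path) {
  n <- nrow(network$pos)
  ne <- length(network$bond_i)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fiber network", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.6f %.6f 0.0", network$pos[, 1], network$pos[, 2]),
             con)
  writeLines(sprintf("LINES %d %d", ne, 3 * ne), con)
  writeLines(sprintf("2 %d %d", network$bond_i - 1L, network$bond_j - 1L),
             con)
  writeLines(c(sprintf("CELL_DATA %d", ne), "SCALARS crosslink int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(network$bond_cross)), con)
  invisible(path)
}
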