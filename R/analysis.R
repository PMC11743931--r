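# Measurement statistics: nematic order, cell shape, FA geometry, binned
# occupancy/order time series with sigmoid onset fits, annulus alignment,
# bead displacement.

#' Nematic order parameter of fiber segments
#'
#' `S = |sum w exp(2 i theta)| / sum w` over segment orientations: 0 for an
#' isotropic set, 1 for perfect alignment.  Orientations are apolar
#' (theta and theta + pi are equivalent).
#'
#' @param angles segment orientations, rad.
#' @param weights optional weights (e.g. segment lengths).
#' @return scalar `S` in `[0, 1]`; `NA` (with a warning) for empty input.
#' @export
order_parameter <- function(angles, weights = NULL) {
  if (length(angles) == 0) {
    warning("order parameter undefined for empty input")
    return(NA_real_)
  }
  if (is.null(weights)) weights <- rep(1, length(angles))
  stopifnot(length(weights) == length(angles), all(weights >= 0))
  Mod(sum(weights * exp(2i * angles))) / sum(weights)
}

#' Orientations and lengths of fiber segments
#'
#' One entry per fiber spring (cross-links excluded): orientation, length
#' and midpoint.
#'
#' @param network a `fiber_network`.
#' @param pos optional bead positions overriding `network$pos` (e.g. a
#'   trajectory snapshot).
#' @return data.frame with `theta`, `length`, `mx`, `my`.
#' @export
segment_angles <- function(network, pos = NULL) {
  if (is.null(pos)) pos <- network$pos
  keep <- !network$bond_cross
  i <- network$bond_i[keep]
  j <- network$bond_j[keep]
  dx <- pos[j, 1] - pos[i, 1]
  dy <- pos[j, 2] - pos[i, 2]
  data.frame(theta = atan2(dy, dx), length = sqrt(dx^2 + dy^2),
             mx = (pos[i, 1] + pos[j, 1]) / 2,
             my = (pos[i, 2] + pos[j, 2]) / 2)
}

#' Cell eccentricity from the mask's second moments
#'
#' With eigenvalues `l1 >= l2` of the covariance matrix of the cell-site
#' centres, `e = sqrt(1 - l2/l1)`: 0 for a disc, 1 for a line.
#'
#' @param mask a [spin_field()] or logical matrix.
#' @return eccentricity in `[0, 1]`; a single-site mask gives 0.
#' @export
cell_eccentricity <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  if (nrow(idx) == 1) return(0)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(1 - max(0, ev[2]) / ev[1])
}

#' Major-axis length of a cell mask
#'
#' Full extent of the cell-site centres along the principal covariance
#' axis, in um; the "cell length" used as the annulus radius in
#' [annulus_alignment()].
#'
#' @param mask a [spin_field()] or logical matrix.
#' @param lattice_spacing site edge, um.
#' @return length in um.
#' @export
mask_major_axis <- function(mask, lattice_spacing = 0.25) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) return(lattice_spacing)
  v <- eigen(stats::cov(idx), symmetric = TRUE)$vectors[, 1]
  proj <- idx %*% v
  (max(proj) - min(proj) + 1) * lattice_spacing
}

#' Focal adhesion angles about the cell centre
#'
#' The signed acute angle between the centre-to-FA vector and a reference
#' axis, folded to the nematic half-circle `(-pi/2, pi/2]` (an FA at
#' bearing 135 degrees maps to -45 degrees).  FAs at the exact centre are
#' excluded.
#'
#' @param fas FA table with positions (`x`, `y` in lattice sites).
#' @param center cell centre, um.
#' @param lattice_spacing site edge, um.
#' @param reference_axis axis direction, rad (default 0, horizontal).
#' @return numeric vector of angles in `(-pi/2, pi/2]`.
#' @export
fa_angles <- function(fas, center, lattice_spacing = 0.25,
                      reference_axis = 0) {
  px <- (fas$x - 0.5) * lattice_spacing - center[1]
  py <- (fas$y - 0.5) * lattice_spacing - center[2]
  keep <- px^2 + py^2 > 0
  a <- atan2(py[keep], px[keep]) - reference_axis
  a <- (a + pi / 2) %% pi - pi / 2          # fold to (-pi/2, pi/2]
  a[a == -pi / 2] <- pi / 2
  a
}

#' Binned order / occupancy time series
#'
#' Subdivides the domain into square bins of `bin` x `bin` lattice sites
#' and computes, per bin and recorded step, the fiber order parameter
#' `S_i(t)` (segments assigned by midpoint, weighted by length) and the
#' cell occupancy fraction `C_i(t)`; both are then smoothed with a
#' trailing moving average over `window` recorded steps.
#'
#' @param trajectory a `cpm_trajectory` recorded with masks and beads.
#' @param bin bin edge, lattice sites.
#' @param window trailing moving-average window, recorded steps.
#' @return object of class `binned_series`: list with `steps`, bin centre
#'   coordinates `bx`, `by` (um), matrices `S` and `C` (bins x steps;
#'   bins with no segments at a time point carry `NA`), and `bin_index`
#'   helper fields.
#' @export
binned_series <- function(trajectory, bin = 5, window = 10) {
  config <- trajectory$config
  L <- config$lattice_size
  stopifnot(L %% bin == 0)
  nb <- L %/% bin
  ls <- config$lattice_spacing
  net <- trajectory$final_state$network
  snaps <- Filter(function(s) !is.null(s$mask) && !is.null(s$beads),
                  trajectory$snapshots)
  if (length(snaps) == 0)
    stop("trajectory was not recorded with masks and beads")
  steps <- vapply(snaps, `[[`, numeric(1), "step")
  S <- C <- matrix(NA_real_, nb * nb, length(snaps))
  for (t in seq_along(snaps)) {
    seg <- segment_angles(net, pos = snaps[[t]]$beads)
    gx <- floor(seg$mx / (bin * ls)) + 1
    gy <- floor(seg$my / (bin * ls)) + 1
    ok <- gx >= 1 & gx <= nb & gy >= 1 & gy <= nb
    bidx <- gx[ok] + (gy[ok] - 1) * nb
    for (b in unique(bidx)) {
      sel <- bidx == b
      S[b, t] <- order_parameter(seg$theta[ok][sel], seg$length[ok][sel])
    }
    occ <- snaps[[t]]$mask
    gcell <- matrix(0, nb, nb)
    idx <- which(occ, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      cb <- ((idx[, 1] - 1) %/% bin + 1) + ((idx[, 2] - 1) %/% bin) * nb
      tab <- table(cb)
      gcell[as.integer(names(tab))] <- as.integer(tab)
    }
    C[, t] <- as.vector(gcell) / bin^2
  }
  centers <- ((seq_len(nb) - 0.5) * bin) * ls
  out <- list(steps = steps,
              bx = rep(centers, nb), by = rep(centers, each = nb),
              S = trailing_mean(S, window), C = trailing_mean(C, window),
              bin = bin, window = window)
  class(out) <- "binned_series"
  out
}

# causal moving average over the trailing `window` columns (NA-tolerant)
trailing_mean <- function(m, window) {
  if (window <= 1) return(m)
  out <- m
  for (t in seq_len(ncol(m))) {
    cols <- max(1, t - window + 1):t
    out[, t] <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Fit a sigmoid onset curve to a time series
#'
#' Nonlinear least squares on `f(t) = L / (1 + exp(-k (t - t0)))`,
#' initialised from the series (plateau = max, `t0` = half-maximum
#' crossing, `k` from the rise interval) with `k` bounded positive.
#'
#' @param t time points.
#' @param y series values.
#' @return object of class `sigmoid_fit`: list with `L`, `k`, `t0`, `rss`
#'   and convergence flag `ok` (degenerate/constant series give
#'   `ok = FALSE`).
#' @export
fit_sigmoid <- function(t, y) {
  keep <- is.finite(y)
  t <- t[keep]
  y <- y[keep]
  bad <- list(L = NA_real_, k = NA_real_, t0 = NA_real_, rss = NA_real_,
              ok = FALSE)
  class(bad) <- "sigmoid_fit"
  if (length(y) < 4 || sd(y) < 1e-10) return(bad)
  Lmax <- max(y)
  half <- which(y >= Lmax / 2)
  t0_init <- t[half[1]]
  lo <- which(y <= 0.25 * Lmax)
  hi <- which(y >= 0.75 * Lmax)
  rise <- if (length(lo) > 0 && length(hi) > 0 && t[hi[1]] > t[max(lo)]) {
    t[hi[1]] - t[max(lo)]
  } else {
    diff(range(t)) / 4
  }
  k_init <- max(4 / max(rise, diff(range(t)) / length(t)), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (tt - t0))),
                      data = data.frame(tt = t, y = y),
                      start = list(L = Lmax, k = k_init, t0 = t0_init),
                      lower = c(L = 1e-12, k = 1e-9, t0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- coef(fit)
  span <- diff(range(t))
  out <- list(L = unname(p["L"]), k = unname(p["k"]), t0 = unname(p["t0"]),
              rss = sum(residuals(fit)^2),
              ok = is.finite(p["t0"]) &&
                p["t0"] > min(t) - span && p["t0"] < max(t) + span)
  class(out) <- "sigmoid_fit"
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("sigmoid fit: L = %.4g, k = %.4g, t0 = %.4g (rss %.3g)\n",
                x$L, x$k, x$t0, x$rss))
  } else {
    cat("sigmoid fit: not converged / degenerate\n")
  }
  invisible(x)
}

#' Onset lags between cell spreading and fiber alignment
#'
#' For every bin whose occupancy and order series both admit a sigmoid
#' fit, the lag `t0_cell - t0_S` between the fitted onset of cell
#' spreading and of fiber alignment.  Positive lags mean the matrix
#' aligns before the cell spreads over it.
#'
#' @param bs a [binned_series()].
#' @param bins optional bin indices to use (default: bins whose occupancy
#'   rises from below 0.2 to above 0.5, i.e. bins the cell invades).
#' @return data.frame with `bin`, `t0_cell`, `t0_S`, `lag`.
#' @export
onset_lags <- function(bs, bins = NULL) {
  if (is.null(bins)) {
    first <- apply(bs$C, 1, function(z) head(z[is.finite(z)], 1))
    last <- apply(bs$C, 1, function(z) tail(z[is.finite(z)], 1))
    bins <- which(vapply(first, length, 1L) > 0 &
                  unlist(first) < 0.2 & unlist(last) > 0.5)
  }
  rows <- lapply(bins, function(b) {
    fc <- fit_sigmoid(bs$steps, bs$C[b, ])
    fs <- fit_sigmoid(bs$steps, bs$S[b, ])
    if (!fc$ok || !fs$ok) return(NULL)
    data.frame(bin = b, t0_cell = fc$t0, t0_S = fs$t0,
               lag = fc$t0 - fs$t0)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(bin = integer(), t0_cell = numeric(),
                                      t0_S = numeric(), lag = numeric())
  out
}

#' Mean fiber alignment in an annulus around the cell
#'
#' Unweighted mean of the (final-time, unless `t` given) per-bin order
#' parameters over bins whose centres fall in the annulus between radius
#' `r` and `1.5 * r` around the cell centre, with `r` the cell length
#' (major-axis length by default).
#'
#' @param bs a [binned_series()].
#' @param center cell centre, um.
#' @param r annulus inner radius (cell length), um.
#' @param t column index into the series (default: last).
#' @return list with `mean_S` and `n_bins`; empty annuli give
#'   `mean_S = NA` and a warning.
#' @export
annulus_alignment <- function(bs, center, r, t = length(bs$steps)) {
  d <- sqrt((bs$bx - center[1])^2 + (bs$by - center[2])^2)
  sel <- d > r & d < 1.5 * r
  vals <- bs$S[sel, t]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    warning("no bins with defined order parameter in the annulus")
    return(list(mean_S = NA_real_, n_bins = 0L))
  }
  list(mean_S = mean(vals), n_bins = length(vals))
}

#' Mean bead displacement between two network states
#'
#' Mean Euclidean displacement over non-clamped beads.
#'
#' @param network a `fiber_network` (defines the clamp flags and topology).
#' @param pos0,pos1 bead position matrices (same bead indexing), um;
#'   `pos1` defaults to the network's current positions.
#' @return mean displacement, um.
#' @export
mean_displacement <- function(network, pos0, pos1 = network$pos) {
  if (!all(dim(pos0) == dim(pos1)))
    stop("bead sets differ between the two states")
  free <- !network$clamped
  mean(sqrt((pos1[free, 1] - pos0[free, 1])^2 +
            (pos1[free, 2] - pos0[free, 2])^2))
}
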