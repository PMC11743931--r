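test_that("Hamiltonian matches enumeration on small configurations", {
  # empty lattice: all three terms vanish
  expect_equal(model_energy(spin_field(9), 1, 1, 1, 50), 0)
  # single-site cell, Moore stencil: A^2 = 1 plus 16 ordered mismatched
  # pairs (8 seen from the cell site, 8 from the surrounding medium)
  g1 <- spin_field(11)
  g1[6, 6] <- 1L
  expect_equal(model_energy(g1, 1, 1, 0, 50), 17)
  # 2x2 cell: A^2 = 16 and 40 ordered mismatches
  g2 <- spin_field(12)
  g2[6:7, 6:7] <- 1L
  expect_equal(model_energy(g2, 1, 1, 0, 50), 56)
  # adhesion term: single site with lambda_c only
  expect_equal(model_energy(g1, 0, 0, 2, 1), -2 * 1 / (1 + 1))
  # physical-unit interface: total_energy agrees with model coefficients
  co <- cpm_model_coefficients(cpm_params(), 0.25)
  expect_equal(total_energy(g2, cpm_params()),
               model_energy(g2, co$lambda, co$J, co$lambda_c, co$A_h))
})

test_that("incremental copy-attempt energy equals the brute-force Hamiltonian difference", {
  set.seed(42)
  cpm <- toy_cpm(lambda = 0.02, J = 1.3, lambda_c = 40, A_h_sites = 50)
  co <- cpm_model_coefficients(cpm, 0.25)
  checked <- 0
  while (checked < 1000) {
    g <- spin_field(16)
    g[sample(length(g), 60)] <- 1L
    s <- c(sample(2:15, 1), sample(2:15, 1))
    k <- sample(8, 1)
    off <- rbind(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
    t_ <- s + off[k, ]
    if (g[s[1], s[2]] == g[t_[1], t_[2]]) next
    dh <- copy_attempt_delta(g, s, t_, cpm)
    expect_equal(dh, brute_delta(g, s, t_, co$lambda, co$J, co$lambda_c,
                                 co$A_h),
                 tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_equal(checked, 1000)
})

test_that("retraction penalty enters the copy-attempt energy only for retractions", {
  g <- spin_field(9)
  g[4:6, 4:6] <- 1L
  cpm <- toy_cpm(J = 1)
  fa <- fa_params()
  # extension onto a medium site: FA list ignored
  d_ext <- copy_attempt_delta(g, c(4, 4), c(3, 4), cpm, fa_N = numeric())
  expect_equal(copy_attempt_delta(g, c(4, 4), c(3, 4), cpm), d_ext)
  # retraction from a site with a nascent FA (N = N0): zero penalty
  d0 <- copy_attempt_delta(g, c(3, 4), c(4, 4), cpm)
  expect_equal(copy_attempt_delta(g, c(3, 4), c(4, 4), cpm, fa_N = fa$N0,
                                  fa = fa), d0)
  # half-saturated penalty: sum(N - N0) = N_h adds lambda_FA / 2 = 400
  dN <- copy_attempt_delta(g, c(3, 4), c(4, 4), cpm,
                           fa_N = fa$N0 + fa$N_h, fa = fa)
  expect_equal(dN - d0, fa$lambda_FA / 2)
  expect_equal(dN - d0, 400)
})

test_that("copy-attempt preconditions are enforced", {
  g <- spin_field(9, radius = 2)
  expect_error(copy_attempt_delta(g, c(5, 5), c(5, 5)), "differ")
  expect_error(copy_attempt_delta(g, c(2, 2), c(5, 5)), "neighbour")
  expect_error(copy_attempt_delta(g, c(5, 5), c(5, 6)), "equal spins")
})

test_that("Metropolis rule: downhill always, uphill with Boltzmann probability", {
  set.seed(7)
  expect_true(all(metropolis_accept(rep(-5, 100), T = 3)))
  expect_true(all(metropolis_accept(rep(0, 100), T = 3)))
  # dH = T log 2 accepted with probability 1/2
  T <- 17
  acc <- metropolis_accept(rep(T * log(2), 2e4), T = T)
  expect_equal(mean(acc), 0.5, tolerance = 0.02)
  # empirical rate matches exp(-c/T) within 3 binomial sigma
  c0 <- 1.7
  p <- exp(-c0 / T)
  acc2 <- metropolis_accept(rep(c0, 2e4), T = T)
  expect_lt(abs(mean(acc2) - p), 3 * sqrt(p * (1 - p) / 2e4))
})

test_that("a strict interface-energy minimum is frozen at vanishing temperature", {
  # half-plane cell: every single-site change raises the interface count,
  # so at T -> 0+ no attempt is accepted and the sweep is a no-op
  cfg <- desk_config(seed = 3, lattice_size = 16, cell_radius = 3,
                     network = network_params(fiber_density = 0,
                                              crosslink_density = 0,
                                              domain = c(4, 4)),
                     cpm = toy_cpm(J = 1, T = 1e-8))
  state <- initialize_state(cfg)
  g <- spin_field(16)
  g[, 1:8] <- 1L
  state$grid <- g
  state$area <- cell_area(g)
  set.seed(1)
  out <- monte_carlo_step(state, cfg)
  expect_identical(unclass(out$grid), unclass(g))
  expect_equal(nrow(out$events), 0)
})

test_that("Monte Carlo sweeps are deterministic under a fixed seed and keep spins binary", {
  cfg <- desk_config(seed = 5, n_steps = 0)
  state <- initialize_state(cfg)
  run_once <- function() {
    set.seed(99)
    monte_carlo_step(state, cfg)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$events, b$events)
  expect_identical(a$grid, b$grid)
  expect_identical(a$fas, b$fas)
  expect_true(all(a$grid %in% c(0L, 1L)))
  expect_equal(a$area, sum(a$grid > 0))
})

test_that("extension over a free bead creates one nascent FA bound to the nearest bead", {
  # all-extension-favourable parameters; a site next to the cell holds two
  # free beads at different distances from its centre
  cfg <- desk_config(seed = 2, lattice_size = 12, cell_radius = 2,
                     network = network_params(fiber_density = 0,
                                              crosslink_density = 0,
                                              domain = c(3, 3)),
                     cpm = toy_cpm(lambda_c = 5000, A_h_sites = 5, T = 1))
  state <- initialize_state(cfg)
  # place a 3-bead "fiber" so two beads share site (9, 6): centre (2.125, 1.375)
  net <- make_net(rbind(c(2.13, 1.38), c(2.20, 1.45), c(2.9, 2.9)),
                  fiber = c(1, 1, 1),
                  bonds = data.frame(i = c(1, 2), j = c(2, 3), k = 1,
                                     r0 = 0.1, cross = FALSE),
                  domain = c(3, 3))
  state$network <- net
  state$bond_adj <- fiberCPM:::bond_adjacency(net)
  state$clamp_pos <- net$pos[net$clamped, , drop = FALSE]
  set.seed(4)
  for (q in 1:12) state <- monte_carlo_step(state, cfg)
  expect_gt(nrow(state$fas), 0)
  hit <- state$fas[state$fas$x == 9 & state$fas$y == 6, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$bead, 1)              # nearest to the site centre
  expect_equal(hit$N, fa_params()$N0)    # nascent size
  expect_true(all(state$network$fa_bound[state$fas$bead]))
})

test_that("mean cell area decreases with contractility when adhesion is off", {
  areas <- vapply(c(0.005, 0.02, 0.08), function(lam) {
    cfg <- desk_config(seed = 8, lattice_size = 32, cell_radius = 8,
                       n_steps = 0,
                       network = network_params(fiber_density = 0,
                                                crosslink_density = 0,
                                                domain = c(8, 8)),
                       cpm = toy_cpm(lambda = lam, J = 0.3, T = 20))
    state <- initialize_state(cfg)
    set.seed(123)
    a <- numeric(60)
    for (q in 1:60) {
      state <- monte_carlo_step(state, cfg)
      a[q] <- state$area
    }
    mean(tail(a, 30))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})
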