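test_that("catch-slip rate: printed anchor points and convex shape", {
  fa <- fa_params()
  expect_equal(catch_slip_rate(4.02, fa), 1 + exp(7.76 - 4.02))
  expect_equal(catch_slip_rate(4.02, fa), 43.10, tolerance = 1e-3)
  mid <- (fa$phi_s + fa$phi_c) / 2
  expect_equal(mid, 5.89)
  expect_equal(catch_slip_rate(mid, fa), 2 * exp((fa$phi_c - fa$phi_s) / 2))
  expect_equal(catch_slip_rate(mid, fa), 12.98, tolerance = 1e-3)
  expect_equal(catch_slip_rate(0, fa), 2.345e3, tolerance = 1e-3)
  # strict convexity with a unique interior minimum at the midpoint
  grid <- seq(0, 12, by = 0.01)
  d <- catch_slip_rate(grid, fa)
  expect_true(all(diff(d, differences = 2) > 0))
  expect_equal(grid[which.min(d)], mid, tolerance = 1e-2)
})

test_that("integrin ODE: analytic steady states recovered within 1%", {
  fa <- fa_params()
  expect_equal(fa_steady_state(0, fa), 15.95, tolerance = 1e-3)
  expect_equal(fa_steady_state(5.89, fa), 345.2, tolerance = 1e-3)
  # zero tension: Phi = 0 means phi = 0 regardless of N
  N_inf <- integrate_integrins(200, Phi = 0, fa, tau = 50, n_sub = 200)
  expect_equal(N_inf, fa_steady_state(0, fa), tolerance = 0.01)
  # per-integrin tension held at the catch-slip minimum (phi constant):
  # emulate by fixing Phi = phi * N / f_star self-consistently at N*
  Nstar <- fa_steady_state(5.89, fa)
  Phi_star <- 5.89 * Nstar / fa$f_star
  N2 <- integrate_integrins(Nstar, Phi_star, fa, tau = 50, n_sub = 200)
  expect_equal(N2, Nstar, tolerance = 0.01)
  # at N_tot with no tension the cluster must shrink
  expect_lt(integrate_integrins(fa$N_tot, 0, fa, tau = 0.1), fa$N_tot)
  # clamping keeps N inside (0, N_tot]
  N3 <- integrate_integrins(300, Phi = 1e-7, fa, tau = 10)  # deep slip
  expect_gte(N3, fa$N_min)
  expect_lte(N3, fa$N_tot)
})

test_that("steady-state N versus constant per-integrin tension is unimodal with the catch-slip optimum", {
  fa <- fa_params()
  phis <- seq(0.5, 11, by = 0.1)
  Ns <- fa_steady_state(phis, fa)
  peak <- which.max(Ns)
  expect_equal(phis[peak], 5.9, tolerance = 0.02)
  expect_true(all(diff(Ns[1:peak]) > 0))
  expect_true(all(diff(Ns[peak:length(Ns)]) < 0))
})

test_that("retraction penalty follows the saturating Hill form", {
  fa <- fa_params()
  expect_equal(retraction_penalty(fa$N0, fa), 0)
  expect_equal(retraction_penalty(rep(fa$N0, 4), fa), 0)
  expect_equal(retraction_penalty(fa$N0 + fa$N_h, fa), fa$lambda_FA / 2)
  expect_equal(retraction_penalty(fa$N0 + fa$N_h, fa), 400)
  expect_lt(retraction_penalty(fa$N0 + 1e9, fa), fa$lambda_FA)
  expect_equal(retraction_penalty(fa$N0 + 1e9, fa), 800, tolerance = 1e-6)
  # shrunken clusters never reward retraction
  expect_equal(retraction_penalty(c(2, 3), fa), 0)
  expect_error(retraction_penalty(numeric(), fa))
})

test_that("cytoskeletal tension is Hookean in the centre distance", {
  fa <- fa_params()
  expect_equal(fa_tension(c(5, 5), c(5, 5), fa), 0)
  expect_equal(fa_tension(c(15, 5), c(5, 5), fa), 3.1e-9)    # 10 um
  expect_equal(fa_tension(c(5, 45), c(5, 5), fa), 12.4e-9)   # 40 um
  fa2 <- fa_params(contraction_multiplier = 2)
  expect_equal(fa_tension(c(15, 5), c(5, 5), fa2), 6.2e-9)
})

test_that("greedy displacement moves an unloaded FA centre-ward and respects ECM resistance", {
  cfg <- desk_config(seed = 1, lattice_size = 20, cell_radius = 8, n_steps = 0,
                     network = network_params(fiber_density = 0,
                                              crosslink_density = 0,
                                              domain = c(5, 5)))
  make_state <- function(net, fa_row) {
    g <- spin_field(20, radius = 8)
    list(grid = g, area = cell_area(g), center = c(2.5, 2.5),
         network = net, fas = fa_row,
         bond_adj = fiberCPM:::bond_adjacency(net),
         clamp_pos = net$pos[net$clamped, , drop = FALSE],
         next_fa_id = 2L, step = 0L)
  }
  fa_at <- function(x, y, bead = 1) data.frame(
    id = 1L, site = x + (y - 1L) * 20L, x = x, y = y, bead = bead,
    N = 25, Phi = 0)
  # no attached springs: the cytoskeletal term alone accepts the move
  net1 <- make_net(cbind(3.875, 2.625), fiber = 1, domain = c(5, 5))
  net1$fa_bound[1] <- TRUE
  st <- displace_fas(make_state(net1, fa_at(16L, 11L)), cfg)
  expect_equal(st$fa_moves, 1L)
  expect_equal(st$fas$x, 15L)
  expect_equal(st$network$pos[1, ], c(14.5, 10.5) * 0.25)
  # already at the centre site: no move
  netc <- make_net(cbind(2.625, 2.625), fiber = 1, domain = c(5, 5))
  netc$fa_bound[1] <- TRUE
  stc <- displace_fas(make_state(netc, fa_at(11L, 11L)), cfg)
  expect_equal(stc$fa_moves, 0L)
  # tethered outward by a very stiff pre-stretched spring: move rejected
  net2 <- make_net(rbind(c(3.875, 2.625), c(5.5, 2.625)), fiber = c(1, 2),
                   bonds = data.frame(i = 1, j = 2, k = 100 * 0.31,
                                      r0 = 0.5, cross = TRUE),
                   domain = c(5, 5))
  net2$fa_bound[1] <- TRUE
  st2 <- displace_fas(make_state(net2, fa_at(16L, 11L)), cfg)
  expect_equal(st2$fa_moves, 0L)
  expect_equal(st2$fas$x, 16L)
})

test_that("FA creation and removal are inverse operations with guarded preconditions", {
  cfg <- desk_config(seed = 6, lattice_size = 16, cell_radius = 5,
                     n_steps = 0,
                     network = network_params(fiber_density = 0,
                                              crosslink_density = 0,
                                              domain = c(4, 4)))
  state <- initialize_state(cfg)
  net <- make_net(rbind(c(2.0, 2.0), c(4.5, 2.0)), fiber = c(1, 2),
                  domain = c(4, 4))
  state$network <- net
  state$bond_adj <- fiberCPM:::bond_adjacency(net)
  state$clamp_pos <- net$pos[net$clamped, , drop = FALSE]
  expect_true(net$clamped[2])
  st <- create_fa(state, site = c(9L, 9L), bead = 1L, cfg)
  expect_true(st$network$fa_bound[1])
  expect_equal(st$fas$N, fa_params()$N0)
  expect_equal(st$network$pos[1, ], c(8.5, 8.5) * 0.25)
  expect_error(create_fa(st, site = c(8L, 8L), bead = 1L, cfg),
               "already bound")
  expect_error(create_fa(state, site = c(9L, 9L), bead = 2L, cfg),
               "clamped")
  expect_error(create_fa(state, site = c(1L, 1L), bead = 1L, cfg),
               "inside the cell")
  st2 <- remove_fa(st, id = st$fas$id[1])
  expect_false(st2$network$fa_bound[1])
  expect_equal(nrow(st2$fas), 0)
})

test_that("FA registry and bead flags stay bijective through coupled dynamics", {
  cfg <- desk_config(seed = 13, n_steps = 40)
  state <- initialize_state(cfg)
  for (q in 1:40) state <- simulation_step(state, cfg)  # audits internally
  expect_equal(sum(state$network$fa_bound), nrow(state$fas))
  expect_true(all(state$network$fa_bound[state$fas$bead]))
  expect_false(any(duplicated(state$fas$bead)))
  expect_true(all(state$grid[cbind(state$fas$x, state$fas$y)] > 0))
})
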