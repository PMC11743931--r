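# Two-bead and three-bead fixtures exercise the exact force expressions;
# generated networks feed the finite-difference oracle.

test_that("potential energy of simple spring configurations", {
  # all bonds at rest length, straight triples: U = 0
  pos <- cbind(c(0, 0.4, 0.8), 0)
  net <- make_net(pos, fiber = c(1, 1, 1),
                  bonds = data.frame(i = c(1, 2), j = c(2, 3), k = 31,
                                     r0 = 0.4, cross = FALSE),
                  angles = data.frame(i = 1, j = 2, k = 3, kb = 3.88,
                                      th0 = pi))
  expect_equal(network_energy(net), 0, tolerance = 1e-14)
  # one bond with K = 0.031 N/m stretched by 0.1 um: U = 1.55e-16 J
  st <- make_net(cbind(c(0, 0.5), 0), fiber = c(1, 1),
                 bonds = data.frame(i = 1, j = 2, k = 31, r0 = 0.4,
                                    cross = FALSE))
  expect_equal(network_energy(st) * 1e-15, 1.55e-16, tolerance = 1e-6)
  # bent triple at the preferred angle contributes nothing
  bent <- make_net(cbind(c(0, 0.4, 0.8), c(0, 0, 0.3)), fiber = c(1, 1, 1),
                   angles = data.frame(i = 1, j = 2, k = 3, kb = 2,
                                       th0 = pi))
  th <- pi - atan2(0.3, 0.4)
  expect_equal(network_energy(bent), 0.5 * 2 * (th - pi)^2)
  # degenerate triple errors in strict mode, is skipped otherwise
  bad <- make_net(rbind(c(0, 0), c(0, 0), c(1, 0)), fiber = c(1, 1, 1),
                  angles = data.frame(i = 1, j = 2, k = 3, kb = 1, th0 = pi))
  expect_error(network_energy(bad), "degenerate")
  expect_silent(network_energy(bad, strict = FALSE))
})

test_that("pair forces are equal, opposite, and along the bond axis", {
  net <- make_net(rbind(c(1, 1), c(2, 2.5)), fiber = c(1, 1),
                  bonds = data.frame(i = 1, j = 2, k = 10, r0 = 1,
                                     cross = FALSE))
  F <- network_forces(net)
  expect_equal(F[1, ], -F[2, ])
  dir <- (net$pos[2, ] - net$pos[1, ]) / sqrt(sum((net$pos[2, ] -
                                                   net$pos[1, ])^2))
  cross <- F[1, 1] * dir[2] - F[1, 2] * dir[1]
  expect_equal(cross, 0, tolerance = 1e-12)
  # stretched bond pulls the beads together
  expect_gt(sum(F[1, ] * dir), 0)
})

test_that("forces equal the negative numerical gradient of the energy", {
  set.seed(21)
  net <- generate_network(network_params(domain = c(5, 5), n_beads = 7,
                                         fiber_density = 0.6,
                                         crosslink_density = 2))
  # deform so stretch and bend terms are all active
  net$pos <- net$pos + matrix(rnorm(length(net$pos), sd = 0.05),
                              ncol = 2)
  F <- network_forces(net)
  h <- 1e-6
  for (b in sample(nrow(net$pos), 12)) {
    for (d in 1:2) {
      up <- net
      up$pos[b, d] <- up$pos[b, d] + h
      dn <- net
      dn$pos[b, d] <- dn$pos[b, d] - h
      fd <- -(network_energy(up) - network_energy(dn)) / (2 * h)
      expect_equal(F[b, d], fd, tolerance = 1e-4)
    }
  }
})

test_that("relaxation: fixed points, analytic minima, and straightening", {
  mech0 <- mechanics_params(T_ecm = 0, max_steps = 5000, force_tol = 1e-8)
  # already at a minimum: nothing moves
  rest <- make_net(cbind(c(0, 1), 0), fiber = c(1, 1),
                   bonds = data.frame(i = 1, j = 2, k = 5, r0 = 1,
                                      cross = FALSE))
  out <- relax_network(rest, mech0)
  expect_equal(out$pos, rest$pos)
  expect_true(attr(out, "converged"))
  # free bead tethered to a clamp at distance 2 r0 relaxes onto the
  # circle of radius r0 around the clamp
  teth <- make_net(rbind(c(-0.5, 5), c(0.3, 5)), fiber = c(1, 1),
                   bonds = data.frame(i = 1, j = 2, k = 5, r0 = 0.4,
                                      cross = FALSE))
  expect_true(teth$clamped[1] && !teth$clamped[2])
  out2 <- relax_network(teth, mech0)
  d <- sqrt(sum((out2$pos[2, ] - out2$pos[1, ])^2))
  expect_equal(d, 0.4, tolerance = 1e-3 * 0.4)
  expect_equal(out2$pos[1, ], teth$pos[1, ])     # clamp untouched
  # bent three-bead fiber with free ends straightens to theta = pi
  bent <- make_net(rbind(c(4, 4), c(4.4, 4), c(4.4, 4.4)),
                   fiber = c(1, 1, 1),
                   bonds = data.frame(i = c(1, 2), j = c(2, 3), k = 31,
                                      r0 = 0.4, cross = FALSE),
                   angles = data.frame(i = 1, j = 2, k = 3, kb = 3.88,
                                       th0 = pi))
  out3 <- relax_network(bent, mechanics_params(T_ecm = 0, max_steps = 2e4,
                                               force_tol = 1e-7))
  u <- out3$pos[1, ] - out3$pos[2, ]
  w <- out3$pos[3, ] - out3$pos[2, ]
  th <- acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2)))
  expect_equal(th, pi, tolerance = 1e-3)
})

test_that("noise-free relaxation is a strict energy descent with invariant pinned beads", {
  set.seed(33)
  net <- generate_network(network_params(domain = c(8, 8),
                                         crosslink_density = 1))
  net$fa_bound[which(!net$clamped)[1:5]] <- TRUE
  mech <- mechanics_params(T_ecm = 0, max_steps = 40, force_tol = 1e-12)
  energies <- network_energy(net)
  cur <- net
  for (q in 1:15) {
    cur <- suppressMessages(relax_network(cur, mech))
    energies <- c(energies, network_energy(cur))
  }
  expect_true(all(diff(energies) <= 1e-9))
  pinned <- cur$clamped | cur$fa_bound
  expect_identical(cur$pos[pinned, ], net$pos[pinned, ])
})

test_that("relaxed state is insensitive to halving the timestep", {
  set.seed(14)
  net <- generate_network(network_params(domain = c(6, 6),
                                         crosslink_density = 1.5))
  dt <- fiberCPM:::stable_dt(net, mechanics_params())
  r1 <- relax_network(net, mechanics_params(T_ecm = 0, dt = dt,
                                            max_steps = 3e4,
                                            force_tol = 1e-6))
  r2 <- relax_network(net, mechanics_params(T_ecm = 0, dt = dt / 2,
                                            max_steps = 6e4,
                                            force_tol = 1e-6))
  expect_lt(max(abs(r1$pos - r2$pos)), 1e-3)
})

test_that("energy is invariant under a global translation", {
  set.seed(3)
  net <- generate_network(network_params(domain = c(6, 6),
                                         crosslink_density = 1))
  shifted <- net
  shifted$pos <- sweep(net$pos, 2, c(3.2, -1.7), "+")
  expect_equal(network_energy(shifted), network_energy(net),
               tolerance = 1e-12)
})
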