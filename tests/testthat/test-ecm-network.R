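test_that("Voronoi generation is deterministic and pins the boundary", {
  a <- generate_voronoi_network(100, 100, 50, seed = 1)
  b <- generate_voronoi_network(100, 100, 50, seed = 1)
  expect_identical(a$positions, b$positions)
  expect_identical(a$fibres, b$fibres)
  expect_identical(a$rest_lengths, b$rest_lengths)
  c2 <- generate_voronoi_network(100, 100, 50, seed = 2)
  expect_false(isTRUE(all.equal(a$positions, c2$positions)))
  # boundary cut points are pinned; interior crosslinks are not
  on_edge <- a$positions[, 1] < 1e-6 | a$positions[, 1] > 100 - 1e-6 |
    a$positions[, 2] < 1e-6 | a$positions[, 2] > 100 - 1e-6
  expect_true(all(a$pinned[on_edge]))
  expect_false(any(a$pinned[!on_edge]))
  # load-free start: rest lengths equal generated lengths, zero net force
  expect_equal(a$rest_lengths, fibre_lengths(a))
  expect_equal(max(abs(net_elastic_forces(a))), 0)
})

test_that("generic interior Voronoi crosslinks have degree three", {
  net <- generate_voronoi_network(100, 100, 60, seed = 4,
                                  min_fibre_frac = 0)
  deg <- tabulate(c(net$fibres), nbins = nrow(net$positions))
  expect_true(all(deg[!net$pinned] == 3L))
})

test_that("tessellation matches an independent circumcircle construction", {
  # same seed points, Voronoi vertices recomputed by brute force
  w <- 60
  seeds <- fibranet:::with_seed(7L, matrix(runif(2L * 12L), ncol = 2)) * w
  net <- generate_voronoi_network(w, w, 12, seed = 7, min_fibre_frac = 0)
  ref <- brute_voronoi_vertices(seeds)
  inside <- ref[, 1] > 0 & ref[, 1] < w & ref[, 2] > 0 & ref[, 2] < w
  ref <- ref[inside, , drop = FALSE]
  got <- net$positions[!net$pinned, , drop = FALSE]
  expect_equal(nrow(got), nrow(ref))
  # match each brute-force vertex to a generated crosslink
  for (r in seq_len(nrow(ref))) {
    d <- sqrt(rowSums((got - matrix(ref[r, ], nrow(got), 2, byrow = TRUE))^2))
    expect_lt(min(d), 1e-6)
  }
})

test_that("generation is scale covariant", {
  small <- generate_voronoi_network(50, 50, 40, seed = 9)
  big <- generate_voronoi_network(100, 100, 40, seed = 9)
  expect_equal(big$positions, small$positions * 2, tolerance = 1e-6)
  expect_equal(big$rest_lengths, small$rest_lengths * 2, tolerance = 1e-6)
})

test_that("fibre tension follows the bilinear law", {
  net <- fibre_network(rbind(c(0, 0), c(10, 0)), rbind(c(1L, 2L)),
                       rest_lengths = 10, E_t = 1e7, area = 0.01,
                       compression_factor = 0.1)
  expect_equal(fibre_tension(net, 1, rbind(c(0, 0), c(11, 0))), 1e4)
  expect_equal(fibre_tension(net, 1, rbind(c(0, 0), c(10, 0))), 0)
  expect_equal(fibre_tension(net, 1, rbind(c(0, 0), c(9, 0))), -1e3)
  expect_error(fibre_tension(net, 1, rbind(c(0, 0), c(0, 0))), "zero length")
})

test_that("net elastic forces are Newton pairs and the energy gradient", {
  net <- generate_voronoi_network(50, 50, 20, seed = 3)
  pos <- net$positions + fibranet:::with_seed(5L,
    matrix(rnorm(2 * nrow(net$positions), sd = 0.4), ncol = 2))
  # endpoint contributions of one fibre cancel bit-exactly: isolate fibre 1
  f <- net$fibres[1, ]
  sub <- fibre_network(pos[f, ], rbind(c(1L, 2L)),
                       rest_lengths = net$rest_lengths[1],
                       E_t = net$E_t, area = net$area,
                       compression_factor = net$compression_factor)
  Fsub <- net_elastic_forces(sub, pos[f, ])
  expect_identical(Fsub[1, ], -Fsub[2, ])
  # total internal force over an unpinned network vanishes
  Fall <- net_elastic_forces(net, pos)
  expect_lt(max(abs(colSums(Fall))), 1e-7)
  # force field equals minus the finite-difference energy gradient
  x0 <- as.numeric(t(pos))
  efun <- function(x) elastic_energy(net, matrix(x, ncol = 2, byrow = TRUE))
  g <- fd_gradient(efun, x0, h = 1e-5)
  Fvec <- as.numeric(t(Fall))
  expect_lt(max(abs(Fvec + g)) / max(abs(Fvec)), 1e-5)
})

test_that("middle node force of a stretched chain matches finite differences", {
  pos <- rbind(c(0, 0), c(1.4, 0.2), c(2.2, 0))
  net <- fibre_network(pos, rbind(c(1L, 2L), c(2L, 3L)),
                       rest_lengths = c(1, 1), E_t = 1e6, area = 0.01)
  efun <- function(x) {
    p <- pos; p[2, ] <- x
    elastic_energy(net, p)
  }
  g <- fd_gradient(efun, pos[2, ], h = 1e-7)
  F2 <- net_elastic_forces(net, pos)[2, ]
  expect_lt(max(abs(F2 + g)) / max(abs(F2)), 1e-6)
})

test_that("relaxation follows the closed-form overdamped trajectory", {
  # one pinned, one free crosslink: x(t) = 1 + 0.5 exp(-(E_t A/(L0 eta)) t)
  net <- two_node_network(start = 1.5, L0 = 1, E_t = 1e5, area = 0.01,
                          eta = 1000)
  rel <- relax_network(net, tol = 1e-6, safety = 0.002, trace = TRUE)
  tr <- attr(rel, "trace")
  rate <- net$E_t * net$area / (1 * net$eta)
  sel <- seq(1, length(tr$times), length.out = 60)
  for (s in sel) {
    expected <- 1 + 0.5 * exp(-rate * tr$times[s])
    expect_lt(abs(tr$positions[[s]][2, 1] - expected) / expected, 1e-3)
  }
  expect_equal(rel$positions[2, 1], 1, tolerance = 1e-4)
  # reference lengths reset to the relaxed geometry
  expect_equal(rel$reference_lengths_t0, fibre_lengths(rel), tolerance = 1e-12)
})

test_that("relaxation is an energy descent and a no-op at rest", {
  net <- generate_voronoi_network(40, 40, 15, seed = 11)
  rested <- relax_network(net, tol = 1e-3)
  expect_equal(rested$positions, net$positions, tolerance = 1e-9)
  pos <- net$positions
  free <- !net$pinned
  pos[free, ] <- pos[free, ] + fibranet:::with_seed(2L,
    matrix(rnorm(2 * sum(free), sd = 0.3), ncol = 2))
  pert <- net
  pert$positions <- pos
  rel <- relax_network(pert, tol = 0.5, trace = TRUE)
  tr <- attr(rel, "trace")
  energies <- vapply(tr$positions, function(p) elastic_energy(net, p),
                     numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
  expect_error(relax_network(pert, tol = 1e-9, max_steps = 5L),
               "did not converge")
})

test_that("tensional stress selects fibres longer than at t = 0", {
  pos <- rbind(c(0, 0), c(10, 0), c(10, 10.8), c(0, 20))
  net <- fibre_network(pos, rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
                       rest_lengths = c(10, 10, 10), E_t = 1e7, area = 0.01)
  # fibre 1: 10 -> 11 (stretched); fibre 2: 10.8 -> 10.5 (shorter than t=0,
  # excluded although above rest length); fibre 3: shrinks, excluded
  newpos <- rbind(c(0, 0), c(11, 0), c(11, 10.5), c(11, 20))
  sig <- tensional_stress_field(net, newpos)
  expect_named(sig, "1")
  expect_equal(unname(sig["1"]), 1e6)
})

test_that("network CSV and JSON round-trips preserve the network", {
  net <- generate_voronoi_network(50, 50, 20, seed = 6, E_t = 5e6,
                                  area = 0.004, eta = 700,
                                  compression_factor = 0.2)
  td <- withr::local_tempdir()
  write_network_csv(net, file.path(td, "nodes.csv"), file.path(td, "edges.csv"))
  back <- read_network_csv(file.path(td, "nodes.csv"),
                           file.path(td, "edges.csv"),
                           E_t = 5e6, area = 0.004, eta = 700,
                           compression_factor = 0.2)
  expect_equal(back$positions, unname(net$positions), tolerance = 1e-12)
  expect_equal(back$fibres, unname(net$fibres))
  expect_equal(back$rest_lengths, net$rest_lengths, tolerance = 1e-12)
  expect_equal(back$pinned, net$pinned)
  jf <- file.path(td, "net.json")
  write_network_json(net, jf)
  jback <- read_network_json(jf)
  expect_equal(jback$positions, unname(net$positions), tolerance = 1e-12)
  expect_equal(jback$E_t, net$E_t)
  expect_equal(jback$area, net$area)
})

test_that("network invariants are validated", {
  expect_error(fibre_network(rbind(c(0, 0), c(1, 0)), rbind(c(1L, 1L))),
               "distinct")
  expect_error(fibre_network(rbind(c(0, 0), c(1, 0)),
                             rbind(c(1L, 2L), c(2L, 1L))), "duplicate")
  expect_error(fibre_network(rbind(c(0, 0), c(1, 0)), rbind(c(1L, 2L)),
                             rest_lengths = -1), "positive")
  expect_error(fibre_network(rbind(c(0, 0), c(1, 0)), rbind(c(1L, 2L)),
                             compression_factor = 2), "0, 1")
  # two 2-node components sharing no crosslink: disconnected
  expect_error(fibre_network(rbind(c(0, 0), c(1, 0), c(5, 5), c(6, 5)),
                             rbind(c(1L, 2L), c(3L, 4L))), "disconnected")
})
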