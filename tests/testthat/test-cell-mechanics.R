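test_that("cell constructors produce the documented geometries", {
  rc <- make_cell("round", c(5, 5), 10, n_vertices = 8L)
  expect_equal(rc$segment_rest_lengths, rep(10, 8))
  expect_equal(rc$natural_angles, rep(pi / 4, 8))
  el <- make_cell("elongated", c(0, 0), 20, orientation = pi / 6)
  axis <- c(cos(pi / 6), sin(pi / 6))
  expect_equal(el$vertices[1, ], -10 * axis, tolerance = 1e-12)
  expect_equal(el$vertices[2, ], 10 * axis, tolerance = 1e-12)
  expect_equal(el$natural_angles, pi)
  fan <- make_cell("fan", c(0, 0), 10, n_vertices = 5L)
  expect_equal(nrow(fan$vertices), 5L)
  expect_equal(sum(fan$natural_angles), 2 * pi)
  expect_error(make_cell("banana", c(0, 0), 1), "unknown shape_tag")
})

test_that("a freshly made cell is at structural equilibrium", {
  for (shape in c("round", "elongated", "fan")) {
    cl <- make_cell(shape, c(3, -2), 12, orientation = 0.7,
                    n_vertices = if (shape == "elongated") 2L else 6L)
    f <- structural_forces(cl)
    expect_lt(max(abs(f$vertices)), 1e-9)
    expect_lt(max(abs(f$centre)), 1e-9)
  }
})

test_that("spring, viscous and reaction terms behave as Kelvin-Voigt", {
  cl <- make_cell("elongated", c(0, 0), 20, k_seg = 100, gamma_seg = 50,
                  k_ang = 0)
  stretched <- cl$vertices
  stretched[2, ] <- c(11, 0)   # +1 um along the axis
  f <- structural_forces(cl, vertices = stretched)
  expect_equal(f$vertices[2, ], c(-100, 0), tolerance = 1e-12)
  # viscous branch: elongation rate 2 um/s on the axis
  fv <- structural_forces(cl, vertex_velocities = rbind(c(0, 0), c(2, 0)))
  expect_equal(fv$vertices[2, ], c(-50 * 2, 0), tolerance = 1e-12)
  # centre reaction is the exact negative of the vertex sum
  cl8 <- make_cell("round", c(0, 0), 10, n_vertices = 8L)
  disturbed <- cl8$vertices * 1.07
  f8 <- structural_forces(cl8, vertices = disturbed)
  expect_identical(f8$centre, -colSums(f8$vertices))
})

test_that("structural + contraction forces are minus the energy gradient", {
  cl <- make_cell("round", c(1, 2), 8, n_vertices = 5L, k_seg = 500,
                  gamma_seg = 0, k_ang = 300, F_co = 40)
  verts <- cl$vertices + fibranet:::with_seed(8L,
    matrix(rnorm(10, sd = 0.35), ncol = 2))
  x0 <- c(as.numeric(t(verts)), cl$centre)
  efun <- function(x) {
    v <- matrix(x[1:10], ncol = 2, byrow = TRUE)
    cell_energy(cl, vertices = v, centre = x[11:12],
                include_contraction = TRUE)
  }
  g <- fd_gradient(efun, x0, h = 1e-6)
  fs <- structural_forces(cl, vertices = verts)
  fc <- contraction_forces(cl, vertices = verts)
  Fvec <- c(as.numeric(t(fs$vertices + fc$vertices)), fs$centre + fc$centre)
  expect_lt(max(abs(Fvec + g)) / max(abs(Fvec)), 1e-5)
})

test_that("contraction forces point inward and cancel internally", {
  cl0 <- make_cell("round", c(0, 0), 10, n_vertices = 8L, F_co = 0)
  expect_equal(contraction_forces(cl0)$vertices, matrix(0, 8, 2))
  el <- make_cell("elongated", c(0, 0), 20, F_co = 2e4)
  f <- contraction_forces(el)
  expect_equal(f$vertices[1, ], c(2e4, 0), tolerance = 1e-12)
  expect_equal(f$vertices[2, ], c(-2e4, 0), tolerance = 1e-12)
  expect_equal(colSums(f$vertices) + f$centre, c(0, 0))
  rc <- make_cell("round", c(0, 0), 10, n_vertices = 8L, F_co = 3e3)
  expect_lt(max(abs(colSums(contraction_forces(rc)$vertices))), 1e-9)
})

test_that("cell forces are rotationally equivariant", {
  base <- make_cell("fan", c(0, 0), 9, n_vertices = 6L, k_seg = 700,
                    k_ang = 400, F_co = 120)
  pert <- fibranet:::with_seed(13L, matrix(rnorm(12, sd = 0.4), ncol = 2))
  v0 <- base$vertices + pert
  f0 <- structural_forces(base, vertices = v0)
  phi <- 0.9
  R <- rot2(phi)
  rotated <- make_cell("fan", c(0, 0), 9, n_vertices = 6L, k_seg = 700,
                       k_ang = 400, F_co = 120, orientation = phi)
  f1 <- structural_forces(rotated, vertices = v0 %*% t(R))
  expect_equal(f1$vertices, f0$vertices %*% t(R), tolerance = 1e-9)
  g0 <- contraction_forces(base, vertices = v0)
  g1 <- contraction_forces(rotated, vertices = v0 %*% t(R))
  expect_equal(g1$vertices, g0$vertices %*% t(R), tolerance = 1e-9)
})

test_that("an isolated contracting cell shrinks to the spring balance", {
  # equilibrium segment length L0 - F_co/k_seg (ECM absent)
  cfg <- build_named_scenario("single_round")
  cfg$network <- fibre_network(rbind(c(-1000, 0), c(-999, 0)),
                               rbind(c(1L, 2L)), pinned = c(TRUE, TRUE))
  cfg$cells <- list(list(shape = "round", centre = c(50, 50), size = 10,
                         n_vertices = 6L, F_co = 2e3, k_seg = 1e3,
                         fa_vertices = integer(0)))
  cfg$integration$activation_ramp <- 0
  st <- initialize_scenario(cfg)
  lens_of <- function(s) {
    fibranet:::row_norms(sweep(s$cells[[1]]$vertices, 2, s$cells[[1]]$centre))
  }
  traj <- run_simulation(st, 20)
  lens <- vapply(seq_along(traj$times), function(s) {
    v <- traj$vertices[s, , ]
    cn <- traj$centres[s, 1, ]
    mean(sqrt((v[, 1] - cn[1])^2 + (v[, 2] - cn[2])^2))
  }, numeric(1))
  expect_true(all(diff(lens) <= 1e-6))          # monotone shrink
  expect_equal(lens_of(traj$final_state), rep(10 - 2e3 / 1e3, 6),
               tolerance = 1e-3)
})
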