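# a small, fast scenario reused across integrator tests
small_cfg <- function(...) {
  build_named_scenario("single_round",
                       modifyList(list(seed = 2L,
                                       ecm = list(n_seeds = 120L)),
                                  list(...)))
}

test_that("initialization yields a relaxed, deterministic attached state", {
  cfg <- small_cfg()
  st <- initialize_scenario(cfg)
  f <- state_forces(st, active = FALSE)
  expect_lt(max(abs(f$crosslinks[!st$network$pinned, ])),
            cfg$integration$relax_tol)
  expect_lt(max(abs(do.call(rbind, f$vertices))), cfg$integration$relax_tol)
  st2 <- initialize_scenario(cfg)
  expect_identical(st$network$positions, st2$network$positions)
  expect_identical(st$cells[[1]]$vertices, st2$cells[[1]]$vertices)
  expect_equal(length(st$fas), 8L)
  # N_b starts at the zero-force binding equilibrium
  p <- st$config$fa_params
  expect_equal(st$fas[[1]]$N_b,
               p$K_on * st$fas[[1]]$N / (p$K_on + koff(0, p)))
})

test_that("two facing elongated cells hold exactly two adhesions each", {
  st <- initialize_scenario(build_named_scenario("two_elongated",
                                                 list(seed = 3L)))
  cells_of <- vapply(st$fas, function(f) f$cell_index, numeric(1))
  expect_equal(as.numeric(table(cells_of)), c(2, 2))
  # adhesion crosslinks are distinct and unpinned
  nodes <- vapply(st$fas, function(f) f$crosslink_index, numeric(1))
  expect_equal(anyDuplicated(nodes), 0L)
  expect_false(any(st$network$pinned[nodes]))
})

test_that("a vertex with no reachable crosslink is reported by name", {
  cfg <- small_cfg()
  cfg$cells[[1]]$centre <- c(5000, 5000)   # far outside the network
  expect_error(initialize_scenario(cfg), "vertex 1")
})

test_that("internal forces cancel globally at any state", {
  cfg <- small_cfg()
  st <- initialize_scenario(cfg)
  # perturb and check: with no pinned reactions, internal forces sum to 0
  st$network$positions <- st$network$positions +
    fibranet:::with_seed(21L,
      matrix(rnorm(2 * nrow(st$network$positions), sd = 0.2), ncol = 2))
  f <- state_forces(st, active = TRUE)   # contraction is internal too
  tot <- colSums(f$crosslinks) + colSums(do.call(rbind, f$vertices)) +
    colSums(f$centres)
  expect_lt(max(abs(tot)), 1e-7)
})

test_that("the reference R step matches the compiled integrator", {
  cfg <- small_cfg()
  st <- initialize_scenario(cfg)
  dt <- 1e-4
  r1 <- st
  for (i in 1:5) r1 <- sim_step(r1, dt)
  res <- fibranet:::call_core(st, t_end = 5 * dt, sample_dt = 5 * dt,
                              active = TRUE, fixed_dt = dt)
  expect_equal(r1$network$positions, res$pos, tolerance = 1e-10)
  expect_equal(r1$cells[[1]]$vertices,
               res$vertices[seq_len(8), , drop = FALSE], tolerance = 1e-10)
  expect_equal(vapply(r1$fas, function(f) f$N_b, numeric(1)),
               res$Nb_final, tolerance = 1e-10)
})

test_that("a passive equilibrium state does not move", {
  cfg <- small_cfg()
  st <- initialize_scenario(cfg)
  stepped <- sim_step(st, 1e-3, active = FALSE)
  expect_equal(stepped$network$positions, st$network$positions,
               tolerance = 1e-7)
  traj <- run_simulation(st, 0.5, active = FALSE)
  expect_equal(traj$final_state$network$positions, st$network$positions,
               tolerance = 1e-5)
  expect_equal(traj$final_state$cells[[1]]$vertices, st$cells[[1]]$vertices,
               tolerance = 1e-5)
})

test_that("halving the step changes a 1 s trajectory by less than 1e-3 um", {
  cfg <- small_cfg()
  st <- initialize_scenario(cfg)
  run_with <- function(safety) {
    s <- st
    s$config$integration$safety <- safety
    run_simulation(s, 1)$final_state
  }
  a <- run_with(0.2)
  b <- run_with(0.1)
  expect_lt(max(abs(a$network$positions - b$network$positions)), 1e-3)
  expect_lt(max(abs(a$cells[[1]]$vertices - b$cells[[1]]$vertices)), 1e-3)
})

test_that("trajectories are deterministic and strictly time-ordered", {
  cfg <- small_cfg()
  t1 <- run_simulation(initialize_scenario(cfg), 0.3)
  t2 <- run_simulation(initialize_scenario(cfg), 0.3)
  expect_identical(t1$crosslinks, t2$crosslinks)
  expect_identical(t1$N_b, t2$N_b)
  expect_true(all(diff(t1$times) > 0))
})

test_that("detachment events are recorded, permanent and force-free", {
  traj <- run_simulation(initialize_scenario(build_named_scenario("ladder")),
                         5)
  expect_gt(nrow(traj$events), 0)
  expect_true(all(traj$events$kind == "detachment"))
  fin <- traj$final_state
  att <- vapply(fin$fas, function(f) f$attached, logical(1))
  expect_false(all(att))
  expect_true(all(vapply(fin$fas[!att], function(f) f$N_b, numeric(1)) == 0))
  # after the event the recorded adhesion force is zero
  q <- traj$events$fa[1]
  after <- traj$times > traj$events$time[1] + 1e-9
  expect_true(all(traj$fa_force[after, q] == 0))
})

test_that("fan-shaped cells run attached with one adhesion per vertex", {
  cfg <- build_named_scenario("multi_fan", list(seed = 4L, n_cells = 3))
  st <- initialize_scenario(cfg)
  expect_equal(length(st$cells), 3L)
  expect_equal(length(st$fas), 15L)   # 5 vertices per fan cell
  tr <- run_simulation(st, 0.5)
  expect_equal(nrow(tr$events), 0L)
  expect_true(all(tr$fa_attached))
})

test_that("scenario configs round-trip through YAML", {
  cfg <- build_named_scenario("two_elongated", list(seed = 42L))
  td <- withr::local_tempdir()
  f <- file.path(td, "cfg.yaml")
  write_scenario_yaml(cfg, f)
  back <- read_scenario_yaml(f)
  expect_equal(back$seed, 42L)
  expect_equal(back$ecm$E_t, cfg$ecm$E_t)
  expect_equal(back$cells[[1]]$centre, cfg$cells[[1]]$centre)
  expect_equal(back$regions$high, cfg$regions$high, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(build_named_scenario("no_such"), "unknown scenario")
})
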