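# build a star network around crosslink 1 with unit p-norm directions
star_network <- function(dirs) {
  positions <- rbind(c(0, 0), dirs)
  fib <- cbind(1L, 1L + seq_len(nrow(dirs)))
  fibre_network(positions, fib,
                rest_lengths = sqrt(rowSums(dirs^2)), E_t = 1e6)
}

test_that("orientation tensor reproduces hand-computed examples", {
  # isotropic pair
  o <- orientation_tensor(star_network(rbind(c(1, 0), c(0, 1))),
                          crosslink_l = 1)
  expect_equal(o$tensor, diag(2) / 2, tolerance = 1e-12)
  expect_equal(o$anisotropy, 0)
  expect_true(o$degenerate)
  # collinear pair: full anisotropy along x
  o2 <- orientation_tensor(star_network(rbind(c(1, 0), c(-1, 0))),
                           crosslink_l = 1)
  expect_equal(sort(o2$eigenvalues), c(0, 1), tolerance = 1e-12)
  expect_equal(o2$anisotropy, 1)
  expect_equal(o2$alignment_angle, 0)
  # three directions at 0, 90 and 45 degrees (independent direct summation)
  dirs <- rbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  o3 <- orientation_tensor(star_network(dirs), crosslink_l = 1)
  P <- t(apply(dirs, 1, function(v) v / sqrt(sum(v^2))))
  ref <- Reduce(`+`, lapply(seq_len(3), function(i) tcrossprod(P[i, ]))) / 3
  expect_equal(o3$tensor, ref, tolerance = 1e-12)
  expect_equal(o3$tensor, rbind(c(1 / 2, 1 / 6), c(1 / 6, 1 / 2)),
               tolerance = 1e-12)
  expect_equal(o3$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(o3$anisotropy, 0.5, tolerance = 1e-12)
  expect_equal(o3$alignment_angle, 45, tolerance = 1e-9)
  expect_error(orientation_tensor(star_network(rbind(c(1, 0))),
                                  crosslink_l = 1), "fewer than 2")
})

test_that("orientation tensors are symmetric, PSD, unit trace everywhere", {
  net <- generate_voronoi_network(80, 80, 40, seed = 5)
  deg <- tabulate(c(net$fibres), nbins = nrow(net$positions))
  for (l in which(deg >= 2)) {
    o <- orientation_tensor(net, crosslink_l = l)
    expect_equal(o$tensor, t(o$tensor))
    expect_equal(sum(diag(o$tensor)), 1, tolerance = 1e-12)
    expect_true(all(o$eigenvalues >= -1e-12))
    expect_true(o$anisotropy >= 0 && o$anisotropy < 1 + 1e-12)
  }
})

test_that("orientation metrics are rotation equivariant", {
  net <- generate_voronoi_network(60, 60, 30, seed = 8)
  phi <- 25   # degrees
  R <- rot2(phi * pi / 180)
  rotated <- net
  rotated$positions <- net$positions %*% t(R)
  deg <- tabulate(c(net$fibres), nbins = nrow(net$positions))
  for (l in which(deg >= 2)[1:10]) {
    o0 <- orientation_tensor(net, crosslink_l = l)
    o1 <- orientation_tensor(rotated, crosslink_l = l)
    expect_equal(o1$anisotropy, o0$anisotropy, tolerance = 1e-9)
    d <- (o1$alignment_angle - o0$alignment_angle - phi) %% 180
    expect_true(min(d, 180 - d) < 1e-6)
  }
})

test_that("region statistics summarise the anisotropy sample", {
  # chain of collinear-fibre crosslinks: sigma = 1 everywhere, skewness 0
  xs <- seq(0, 10, by = 1)
  net <- fibre_network(cbind(xs, 0), cbind(seq_len(10), seq_len(10) + 1L),
                       E_t = 1e6)
  poly <- rbind(c(0.5, -1), c(9.5, -1), c(9.5, 1), c(0.5, 1))
  st <- region_alignment_stats(net, region_polygon = poly)
  expect_equal(st$mean_sigma, 1)
  expect_equal(st$skewness_sigma, 0)
  expect_equal(st$n, 9L)   # endpoints have a single incident fibre
  expect_error(
    region_alignment_stats(net, region_polygon = poly + 100), "fewer than 2")
})

test_that("alignment angles of a random relaxed network are near uniform", {
  net <- generate_voronoi_network(140, 140, 350, seed = 10)
  poly <- rbind(c(0, 0), c(140, 0), c(140, 140), c(0, 140))
  st <- region_alignment_stats(net, region_polygon = poly)
  counts <- st$theta_hist$counts
  expect_gt(min(counts), 0)
  expect_lt(sd(counts) / mean(counts), 0.45)
})

test_that("the anisotropy comparison is a Welch t-test", {
  x <- c(0.42, 0.55, 0.61, 0.48, 0.70)
  y <- c(0.30, 0.35, 0.51, 0.44, 0.29)
  expect_equal(compare_anisotropy(x, y), welch_p_hand(x, y),
               tolerance = 1e-10)
  expect_equal(compare_anisotropy(x, x), 1)
  a <- rnorm(100)
  expect_lt(compare_anisotropy(a, a + 10 * sd(a)), 1e-6)
  expect_error(compare_anisotropy(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(compare_anisotropy(c(1, 2), y), "at least 3")
})

# network whose tensional stresses take prescribed values: with E_t = 1 and
# rest length len/(1 + sigma), the stress of an edge is exactly sigma
stress_network <- function(positions, edges, sigma) {
  len <- sqrt(rowSums((positions[edges[, 2], , drop = FALSE] -
                         positions[edges[, 1], , drop = FALSE])^2))
  L0 <- len / (1 + sigma)
  fibre_network(positions, edges, rest_lengths = L0, E_t = 1,
                reference_lengths_t0 = L0)
}

test_that("the percolation path maximises stress on a hand-checked triangle", {
  pos <- rbind(c(0, 0), c(1, 0), c(0.5, 0.8))
  net <- stress_network(pos, rbind(c(1L, 2L), c(1L, 3L), c(3L, 2L)),
                        sigma = c(1, 3, 3))
  pr <- max_stress_path(net, source_crosslink = 1, target_crosslink = 2)
  expect_true(pr$exists)
  expect_equal(pr$path, c(1L, 3L, 2L))     # weight 2/3 beats direct 1
  expect_equal(pr$total_stress, 6)
  expect_equal(pr$mean_stress, 3)
  expect_equal(pr$tortuosity, 1 / (2 * sqrt(0.89)), tolerance = 1e-12)
  expect_error(max_stress_path(net, source_crosslink = 1,
                               target_crosslink = 1), "differ")
})

test_that("a straight two-fibre path has tortuosity one", {
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0))
  net <- stress_network(pos, rbind(c(1L, 2L), c(2L, 3L)), sigma = c(2, 2))
  pr <- max_stress_path(net, source_crosslink = 1, target_crosslink = 3)
  expect_equal(pr$tortuosity, 1, tolerance = 1e-12)
})

test_that("compressed-only networks carry no mechanical communication", {
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0))
  net <- fibre_network(pos, rbind(c(1L, 2L), c(2L, 3L)),
                       rest_lengths = c(1.5, 1.5), E_t = 1,
                       reference_lengths_t0 = c(1.2, 1.2))
  pr <- max_stress_path(net, source_crosslink = 1, target_crosslink = 3)
  expect_false(pr$exists)
  expect_equal(pr$mean_stress, 0)
  expect_equal(pr$tortuosity, 0)
})

test_that("Dijkstra equals brute-force enumeration on random small graphs", {
  for (case in 1:40) {
    gen <- fibranet:::with_seed(1000L + case, {
      n <- sample(4:8, 1)
      pos <- matrix(runif(2 * n, 0, 10), ncol = 2)
      full <- t(combn(n, 2))
      keep <- full[runif(nrow(full)) < 0.5, , drop = FALSE]
      # ensure a spanning path so the graph is connected
      keep <- unique(rbind(cbind(1:(n - 1), 2:n), keep))
      list(n = n, pos = pos, edges = keep,
           sigma = runif(nrow(keep), 0.1, 5))
    })
    net <- stress_network(gen$pos, gen$edges, gen$sigma)
    pr <- max_stress_path(net, source_crosslink = 1,
                          target_crosslink = gen$n)
    ref <- brute_best_path(gen$edges, 1 / gen$sigma, 1, gen$n, gen$n)
    expect_true(pr$exists)
    got_cost <- sum(1 / fibranet:::path_stresses(net, pr))
    expect_equal(got_cost, ref$cost, tolerance = 1e-9)
  }
})

test_that("path metrics are invariant under rotation", {
  gen <- fibranet:::with_seed(77L, {
    pos <- matrix(runif(12, 0, 5), ncol = 2)
    list(pos = pos)
  })
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L),
                 c(1L, 6L), c(2L, 5L))
  sigma <- c(1, 2, 3, 1.5, 2.5, 0.7, 4)
  net <- stress_network(gen$pos, edges, sigma)
  pr0 <- max_stress_path(net, source_crosslink = 1, target_crosslink = 4)
  R <- rot2(1.1)
  rot <- net
  rot$positions <- net$positions %*% t(R)
  prr <- max_stress_path(rot, source_crosslink = 1, target_crosslink = 4)
  expect_equal(prr$total_stress, pr0$total_stress, tolerance = 1e-9)
  expect_equal(prr$tortuosity, pr0$tortuosity, tolerance = 1e-9)
  expect_equal(prr$path, pr0$path)
})

# minimal synthetic trajectory for the force summary
fake_traj <- function(times, force) {
  structure(list(times = times,
                 fa_force = cbind(force, force * 0.5),
                 fa_attached = matrix(TRUE, length(times), 2)),
            class = "trajectory")
}

test_that("the interaction-force summary finds the peak of the mean curve", {
  tr <- fake_traj(0:5, c(10, 8, 6, 5, 4, 3))
  s <- interaction_force_summary(tr)
  expect_equal(s$peak_time, 0)
  expect_equal(s$peak_mean_force, mean(c(10, 5)))
  pulse <- fake_traj(0:4, c(1, 3, 7, 3, 1))
  expect_equal(interaction_force_summary(pulse)$peak_time, 2)
  expect_error(interaction_force_summary(structure(list(fa_force = NULL),
                                                   class = "trajectory")),
               "no focal-adhesion")
})
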