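# Independent oracles used by the tests.  Everything here is written from
# first principles (enumeration, finite differences, closed forms) and
# never calls the code paths it is used to check.

# --- brute-force Delaunay/Voronoi on a tiny seed set -----------------------
# A triple of seeds is a Delaunay triangle iff its circumcircle contains no
# other seed; interior Voronoi vertices are the circumcentres of Delaunay
# triangles.  O(n^4), fine for n <= 15.
circumcentre <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  c(ux, uy)
}

brute_voronoi_vertices <- function(seeds) {
  n <- nrow(seeds)
  out <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circumcentre(seeds[i, ], seeds[j, ], seeds[k, ])
    if (is.null(cc)) next
    r2 <- sum((seeds[i, ] - cc)^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- rowSums((seeds[others, , drop = FALSE] -
                     matrix(cc, length(others), 2, byrow = TRUE))^2)
    if (all(d2 > r2 * (1 + 1e-12))) out[[length(out) + 1L]] <- cc
  }
  do.call(rbind, out)
}

# --- exhaustive simple-path minimisation of sum(1/sigma) -------------------
brute_best_path <- function(edges, weights, from, to, n_nodes) {
  best <- list(cost = Inf, path = NULL)
  adj <- lapply(seq_len(n_nodes), function(v) {
    hit <- which(edges[, 1] == v | edges[, 2] == v)
    cbind(edge = hit, to = ifelse(edges[hit, 1] == v, edges[hit, 2],
                                  edges[hit, 1]))
  })
  recurse <- function(v, visited, cost, path) {
    if (cost >= best$cost) return()
    if (v == to) {
      best <<- list(cost = cost, path = path)
      return()
    }
    a <- adj[[v]]
    for (r in seq_len(nrow(a))) {
      nxt <- a[r, "to"]
      if (nxt %in% visited) next
      recurse(nxt, c(visited, nxt), cost + weights[a[r, "edge"]],
              c(path, nxt))
    }
  }
  recurse(from, from, 0, from)
  best
}

# --- Welch two-sample t-test from the textbook formulas --------------------
welch_p_hand <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

# --- finite-difference gradient of a scalar field --------------------------
fd_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# small two-crosslink network used in several tests: node 1 pinned at the
# origin, node 2 free at distance `start`, rest length L0
two_node_network <- function(start = 1.5, L0 = 1, E_t = 1e5, area = 0.01,
                             eta = 1000) {
  fibre_network(rbind(c(0, 0), c(start, 0)), rbind(c(1L, 2L)),
                rest_lengths = L0, pinned = c(TRUE, FALSE),
                E_t = E_t, area = area, eta = eta)
}

rot2 <- function(a) cbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
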