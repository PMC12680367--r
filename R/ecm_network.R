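#' Construct a crosslinked fibre network
#'
#' A `fibre_network` stores the extracellular-matrix (ECM) graph: crosslink
#' positions (the mobile degrees of freedom), fibres as crosslink index
#' pairs, per-fibre rest lengths, a pinned mask for boundary crosslinks and
#' the mechanical fibre parameters.  Fibres are bilinear springs: Young's
#' modulus `E_t` under stretch and `compression_factor * E_t` under
#' compression (a standard buckling approximation for fibrous networks).
#'
#' @param positions numeric matrix (n x 2), crosslink coordinates in um.
#' @param fibres integer matrix (m x 2), 1-based crosslink index pairs.
#' @param rest_lengths numeric vector (m), load-free fibre lengths L0 in um.
#'   Defaults to the current fibre lengths (a load-free network).
#' @param pinned logical vector (n), crosslinks held fixed during dynamics.
#' @param E_t Young's modulus of a stretched fibre, Pa (1 Pa = 1 pN/um^2).
#' @param compression_factor dimensionless factor rho in `[0, 1]`; the
#'   compressive modulus is `rho * E_t` (buckled fibres resist weakly).
#' @param area fibre cross-section area A, um^2.  Converts stress to force:
#'   tension = E_t * A * strain (pN).
#' @param eta damping coefficient of a crosslink, pN s/um.
#' @param reference_lengths_t0 per-fibre lengths at simulation start, um;
#'   the tensional-stress selection rule compares against these.
#'
#' @return An object of class `fibre_network`.
#' @seealso [generate_voronoi_network()], [net_elastic_forces()],
#'   [relax_network()], [tensional_stress_field()]
#' @export
fibre_network <- function(positions, fibres, rest_lengths = NULL,
                          pinned = NULL, E_t = 1e7,
                          compression_factor = 0.1, area = 0.002,
                          eta = 1000,
                          reference_lengths_t0 = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 2L) stopf("positions must be an n x 2 matrix")
  fibres <- matrix(as.integer(fibres), ncol = 2L)
  n <- nrow(positions)
  m <- nrow(fibres)
  if (m == 0L) stopf("network has no fibres")
  if (any(fibres < 1L | fibres > n)) stopf("fibre indices out of range")
  if (any(fibres[, 1] == fibres[, 2]))
    stopf("a fibre must join two distinct crosslinks")
  key <- paste(pmin(fibres[, 1], fibres[, 2]), pmax(fibres[, 1], fibres[, 2]))
  if (anyDuplicated(key)) stopf("duplicate fibres are not allowed")
  if (is.null(pinned)) pinned <- rep(FALSE, n)
  pinned <- as.logical(pinned)
  if (length(pinned) != n) stopf("pinned mask length must match crosslinks")
  lens <- fibre_lengths_(positions, fibres)
  if (is.null(rest_lengths)) rest_lengths <- lens
  rest_lengths <- as.numeric(rest_lengths)
  if (length(rest_lengths) != m || any(rest_lengths <= 0))
    stopf("rest_lengths must be positive, one per fibre")
  if (is.null(reference_lengths_t0)) reference_lengths_t0 <- lens
  if (E_t <= 0 || area <= 0 || eta <= 0)
    stopf("E_t, area and eta must be positive")
  if (compression_factor < 0 || compression_factor > 1)
    stopf("compression_factor must lie in [0, 1]")
  net <- structure(list(
    positions = positions, fibres = fibres,
    rest_lengths = rest_lengths, pinned = pinned,
    E_t = E_t, compression_factor = compression_factor,
    area = area, eta = eta,
    reference_lengths_t0 = as.numeric(reference_lengths_t0)
  ), class = "fibre_network")
  check_connected(net)
  net
}

fibre_lengths_ <- function(positions, fibres) {
  d <- positions[fibres[, 2], , drop = FALSE] -
    positions[fibres[, 1], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Current fibre lengths
#'
#' @param network a [fibre_network()].
#' @param positions optional crosslink positions overriding those stored in
#'   the network.
#' @return numeric vector of fibre lengths, um.
#' @export
fibre_lengths <- function(network, positions = NULL) {
  fibre_lengths_(positions %||% network$positions, network$fibres)
}

# The fibre graph must be connected on crosslinks that carry at least one
# fibre (isolated crosslinks are tolerated but never generated).
check_connected <- function(net) {
  g <- igraph::graph_from_edgelist(net$fibres, directed = FALSE)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  used <- which(deg > 0)
  if (length(unique(comp$membership[used])) > 1L)
    stopf("fibre graph is disconnected on non-isolated crosslinks")
  invisible(TRUE)
}

#' @export
print.fibre_network <- function(x, ...) {
  cat(sprintf(
    "<fibre_network> %d crosslinks (%d pinned), %d fibres\n",
    nrow(x$positions), sum(x$pinned), nrow(x$fibres)))
  cat(sprintf("  E_t = %.3g Pa, rho = %.3g, A = %.3g um^2, eta = %.3g pN s/um\n",
              x$E_t, x$compression_factor, x$area, x$eta))
  invisible(x)
}

#' Generate a random ECM network by Voronoi tessellation
#'
#' Scatters `n_seeds` uniform random seed points in the rectangular domain
#' and takes the Voronoi diagram of the seeds: Voronoi vertices become ECM
#' crosslinks and Voronoi edges become fibres.  Edges crossing the domain
#' boundary are clipped at the boundary and the cut points are pinned, so
#' the network is anchored along the domain edge.  Rest lengths equal the
#' generated lengths, i.e. the network starts load-free.  The construction
#' is deterministic for a fixed seed and scale-covariant: scaling the domain
#' scales all coordinates and rest lengths.
#'
#' Near-degenerate Voronoi vertices (co-circular seed quadruples) produce
#' sliver fibres orders of magnitude shorter than the typical edge; their
#' spring constants `E_t A / L0` would dominate the stable integration
#' step while contributing nothing mechanically.  Fibres shorter than
#' `min_fibre_frac` times the median edge length are therefore contracted
#' (endpoints merged at their midpoint) during generation.
#'
#' @param domain_width,domain_height domain size, um.
#' @param n_seeds number of Voronoi seed points (>= 4).
#' @param seed integer RNG seed.
#' @param min_fibre_frac sliver-contraction threshold, as a fraction of
#'   the median edge length (set 0 to keep the raw tessellation).
#' @param ... further arguments (mechanical parameters) passed to
#'   [fibre_network()].
#' @return a [fibre_network()].
#' @export
generate_voronoi_network <- function(domain_width, domain_height, n_seeds,
                                     seed, min_fibre_frac = 0.05, ...) {
  if (n_seeds < 4L) stopf("n_seeds must be at least 4")
  if (domain_width <= 0 || domain_height <= 0)
    stopf("domain dimensions must be positive")
  # unit-square uniforms scaled to the domain => scale covariance under a
  # fixed seed
  u <- with_seed(seed, matrix(runif(2L * n_seeds), ncol = 2L))
  sx <- u[, 1] * domain_width
  sy <- u[, 2] * domain_height
  dd <- tryCatch(
    deldir::deldir(sx, sy, rw = c(0, domain_width, 0, domain_height),
                   suppressMsge = TRUE),
    error = function(e) NULL)
  if (is.null(dd)) {
    # degenerate (e.g. collinear) seed set: perturb and retry
    message("degenerate seed set; regenerating with perturbed seeds")
    jit <- with_seed(seed + 1L,
                     matrix(rnorm(2L * n_seeds, sd = 1e-6), ncol = 2L))
    sx <- pmin(pmax(sx + jit[, 1] * domain_width, 0), domain_width)
    sy <- pmin(pmax(sy + jit[, 2] * domain_height, 0), domain_height)
    dd <- deldir::deldir(sx, sy, rw = c(0, domain_width, 0, domain_height),
                         suppressMsge = TRUE)
  }
  segs <- dd$dirsgs
  # merge endpoints into unique crosslinks (snap at a tolerance well below
  # any realistic edge length)
  tol <- 1e-9 * max(domain_width, domain_height)
  pts <- rbind(as.matrix(segs[, c("x1", "y1")]),
               as.matrix(segs[, c("x2", "y2")]))
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol))
  idx <- match(key, unique(key))
  positions <- pts[!duplicated(idx), , drop = FALSE]
  nseg <- nrow(segs)
  a <- idx[seq_len(nseg)]
  b <- idx[nseg + seq_len(nseg)]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  bp <- cbind(segs$bp1[keep], segs$bp2[keep])
  ekey <- paste(pmin(a, b), pmax(a, b))
  dup <- duplicated(ekey)
  a <- a[!dup]; b <- b[!dup]; bp <- bp[!dup, , drop = FALSE]
  # boundary cut points (deldir marks them) are pinned
  pinned <- rep(FALSE, nrow(positions))
  pinned[a[bp[, 1]]] <- TRUE
  pinned[b[bp[, 2]]] <- TRUE
  on_edge <- positions[, 1] < tol | positions[, 1] > domain_width - tol |
    positions[, 2] < tol | positions[, 2] > domain_height - tol
  pinned[on_edge] <- TRUE
  colnames(positions) <- NULL
  if (min_fibre_frac > 0) {
    merged <- contract_short_fibres(positions, cbind(a, b), pinned,
                                    min_fibre_frac)
    positions <- merged$positions
    ab <- merged$fibres
    pinned <- merged$pinned
  } else {
    ab <- cbind(a, b)
  }
  cl <- drop_inert_components(positions, ab, pinned)
  fibre_network(cl$positions, cl$fibres, pinned = cl$pinned, ...)
}

# Boundary clipping can strand small disconnected components in the domain
# corners (clipped tile slivers).  They are mechanically irrelevant, so
# only the largest connected component is kept, and crosslinks left
# without a fibre are removed.
drop_inert_components <- function(positions, fibres, pinned) {
  g <- igraph::graph_from_edgelist(fibres, directed = FALSE)
  if (igraph::vcount(g) < nrow(positions))
    g <- igraph::add_vertices(g, nrow(positions) - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which.max(tabulate(comp$membership[unique(c(fibres))],
                             nbins = comp$no))
  keep_edge <- comp$membership[fibres[, 1]] == main
  fibres <- fibres[keep_edge, , drop = FALSE]
  used <- sort(unique(c(fibres)))
  remap <- match(seq_len(nrow(positions)), used)
  list(positions = positions[used, , drop = FALSE],
       fibres = matrix(remap[fibres], ncol = 2),
       pinned = pinned[used])
}

# Contract fibres shorter than frac * median length: union-find over the
# short edges, merged crosslinks placed at their cluster mean (pinned
# status is inherited), duplicate edges and self-loops dropped.
contract_short_fibres <- function(positions, fibres, pinned, frac) {
  lens <- fibre_lengths_(positions, fibres)
  thr <- frac * stats::median(lens)
  parent <- seq_len(nrow(positions))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in which(lens < thr)) {
    ra <- find(fibres[e, 1]); rb <- find(fibres[e, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nrow(positions)), find, integer(1))
  newid <- match(root, unique(root))
  k <- max(newid)
  newpos <- matrix(0, k, 2)
  newpos[, 1] <- rowsum(positions[, 1], newid)[, 1] / tabulate(newid, k)
  newpos[, 2] <- rowsum(positions[, 2], newid)[, 1] / tabulate(newid, k)
  newpin <- as.logical(rowsum(as.numeric(pinned), newid)[, 1] > 0)
  # pinned clusters keep their original (boundary) coordinates
  for (i in which(newpin)) {
    orig <- which(newid == i & pinned)
    if (length(orig)) newpos[i, ] <- positions[orig[1], ]
  }
  a <- newid[fibres[, 1]]
  b <- newid[fibres[, 2]]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(pmin(a, b), pmax(a, b))
  dup <- duplicated(key)
  list(positions = newpos, fibres = cbind(a[!dup], b[!dup]),
       pinned = newpin)
}

#' Signed tension of a single fibre
#'
#' Bilinear law: with strain `s = (len - L0)/L0`, the tension is
#' `E_t * A * s` for `s >= 0` and `rho * E_t * A * s` for `s < 0`
#' (buckled fibres resist compression weakly).  Positive values are tensile.
#'
#' @param network a [fibre_network()].
#' @param fibre_index 1-based fibre index.
#' @param positions optional crosslink positions (defaults to the network's).
#' @return scalar tension, pN.
#' @export
fibre_tension <- function(network, fibre_index, positions = NULL) {
  positions <- positions %||% network$positions
  f <- network$fibres[fibre_index, ]
  len <- vec_norm(positions[f[2], ] - positions[f[1], ])
  if (len == 0) stopf("fibre %d has zero length (degenerate geometry)",
                      fibre_index)
  L0 <- network$rest_lengths[fibre_index]
  s <- (len - L0) / L0
  EA <- network$E_t * network$area
  if (s >= 0) EA * s else network$compression_factor * EA * s
}

#' Net elastic force on every crosslink
#'
#' Sums, at each crosslink, the tensions of the incident fibres directed
#' towards the respective neighbour.  The two endpoint contributions of a
#' fibre are exact opposites (Newton pairs), so the total over an unpinned
#' network vanishes.
#'
#' @inheritParams fibre_tension
#' @return numeric matrix (n x 2) of forces, pN.
#' @export
net_elastic_forces <- function(network, positions = NULL) {
  positions <- positions %||% network$positions
  fib <- network$fibres
  d <- positions[fib[, 2], , drop = FALSE] - positions[fib[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stopf("zero-length fibre (degenerate geometry)")
  L0 <- network$rest_lengths
  s <- (len - L0) / L0
  EA <- network$E_t * network$area
  tens <- ifelse(s >= 0, EA * s, network$compression_factor * EA * s)
  fx <- tens * d[, 1] / len
  fy <- tens * d[, 2] / len
  n <- nrow(positions)
  F <- matrix(0, n, 2)
  F[, 1] <- rowsum_vec(c(fx, -fx), c(fib[, 1], fib[, 2]), n)
  F[, 2] <- rowsum_vec(c(fy, -fy), c(fib[, 1], fib[, 2]), n)
  F
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Elastic energy of the network
#'
#' Piecewise-quadratic energy whose negative gradient is
#' [net_elastic_forces()]: `E = sum 1/2 * k_f * (len - L0)^2` with
#' `k_f = E_t * A / L0` for stretched and `rho * E_t * A / L0` for
#' compressed fibres.
#'
#' @inheritParams fibre_tension
#' @return scalar energy, pN um.
#' @export
elastic_energy <- function(network, positions = NULL) {
  positions <- positions %||% network$positions
  len <- fibre_lengths(network, positions)
  L0 <- network$rest_lengths
  EA <- network$E_t * network$area
  k <- ifelse(len >= L0, EA / L0, network$compression_factor * EA / L0)
  sum(0.5 * k * (len - L0)^2)
}

#' Relax a network to mechanical equilibrium
#'
#' Integrates the overdamped gradient flow `eta dx/dt = F_el` by forward
#' Euler with an adaptive step `dt = safety * eta / k_max` (k_max = stiffest
#' spring constant incident to any crosslink) until the largest per-node
#' force drops below `tol`.  Pinned crosslinks are held fixed.  On return,
#' `reference_lengths_t0` is reset to the post-relaxation lengths.
#'
#' @param network a [fibre_network()].
#' @param tol convergence tolerance on the max per-node force, pN.
#' @param safety step-size safety factor (stability bound is 2).
#' @param max_steps step budget; exceeding it is an error reporting the
#'   residual force.
#' @param trace if `TRUE`, attach the sampled trajectory (times and
#'   positions) as attribute `"trace"`.
#' @return the relaxed [fibre_network()].
#' @export
relax_network <- function(network, tol = 1e-3, safety = 0.2,
                          max_steps = 200000L, trace = FALSE) {
  if (tol <= 0) stopf("tol must be positive")
  pos <- network$positions
  free <- !network$pinned
  fib <- network$fibres
  EA <- network$E_t * network$area
  t_now <- 0
  tr_t <- numeric(0)
  tr_pos <- list()
  for (it in seq_len(max_steps)) {
    F <- net_elastic_forces(network, pos)
    maxF <- if (any(free)) max(abs(F[free, ])) else 0
    if (trace) {
      tr_t <- c(tr_t, t_now)
      tr_pos[[length(tr_pos) + 1L]] <- pos
    }
    if (maxF < tol) {
      net <- network
      net$positions <- pos
      net$reference_lengths_t0 <- fibre_lengths_(pos, fib)
      if (trace) {
        attr(net, "trace") <- list(times = tr_t, positions = tr_pos)
      }
      return(net)
    }
    len <- fibre_lengths_(pos, fib)
    kf <- ifelse(len >= network$rest_lengths, EA, network$compression_factor * EA) /
      network$rest_lengths
    kn <- numeric(nrow(pos))
    kacc <- rowsum(c(kf, kf), c(fib[, 1], fib[, 2]))
    kn[as.integer(rownames(kacc))] <- kacc[, 1]
    dt <- safety * network$eta / max(kn[free], 1e-12)
    pos[free, ] <- pos[free, ] + dt * F[free, ] / network$eta
    t_now <- t_now + dt
  }
  stopf("relaxation did not converge in %d steps (residual max force %.3g pN)",
        max_steps, maxF)
}

#' Tensional stress of currently stretched fibres
#'
#' For each fibre whose current length exceeds its length at simulation
#' start (`reference_lengths_t0`), the tensional stress is
#' `sigma = E_t * (len - L0) / L0`; all other fibres are absent from the
#' result.  Note the selection rule compares against the length at t = 0,
#' not the rest length, so a fibre shorter than at t = 0 is excluded even
#' if it is above its rest length.
#'
#' `min_elongation` is a numerical floor: explicit time stepping displaces
#' every free crosslink by sub-picometre amounts each step, so without a
#' floor roughly half of all far-field fibres register as "stretched" at
#' machine precision and that noise set can spuriously percolate.  The
#' default (1e-6 um) is orders of magnitude below any mechanically
#' meaningful deformation and orders of magnitude above integration noise.
#'
#' @inheritParams fibre_tension
#' @param min_elongation smallest elongation beyond the t = 0 length that
#'   counts as stretched, um.
#' @return named numeric vector: stress (Pa) indexed by fibre number.
#' @export
tensional_stress_field <- function(network, positions = NULL,
                                   min_elongation = 1e-6) {
  positions <- positions %||% network$positions
  len <- fibre_lengths(network, positions)
  sel <- which(len > network$reference_lengths_t0 + min_elongation)
  sigma <- network$E_t * (len[sel] - network$rest_lengths[sel]) /
    network$rest_lengths[sel]
  setNames(sigma, as.character(sel))
}
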