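#' Local fibre orientation tensor and anisotropy at a crosslink
#'
#' For crosslink `l` with neighbours `m`, builds the rest-length-normalised
#' direction vectors `p_{m,l} = (x_m - x_l) / L0_{m,l}` and the
#' second-moment tensor
#' `Theta_l = sum(p %o% p) / sum(|p|^2)`, which is symmetric, positive
#' semi-definite and has unit trace.  The principal eigenvector gives the
#' local alignment direction `theta_al` (degrees from the +x axis, folded
#' to (-90, 90]); the anisotropy parameter is
#' `sigma_al = 1 - lambda_min / lambda_max` (0 = isotropic, -> 1 strongly
#' aligned).
#'
#' @param network a [fibre_network()].
#' @param positions optional crosslink positions (defaults to the
#'   network's).
#' @param crosslink_l 1-based crosslink index with >= 2 incident fibres.
#' @return list of class `orientation_result`: `tensor` (2 x 2),
#'   `eigenvalues` (decreasing), `alignment_angle` (degrees),
#'   `anisotropy`, `degenerate` (TRUE when the eigenvalues tie and the
#'   angle is reported as 0 by convention).
#' @export
orientation_tensor <- function(network, positions = NULL, crosslink_l) {
  positions <- positions %||% network$positions
  fib <- network$fibres
  inc <- which(fib[, 1] == crosslink_l | fib[, 2] == crosslink_l)
  if (length(inc) < 2L)
    stopf("crosslink %d has fewer than 2 incident fibres; orientation undefined",
          crosslink_l)
  nb <- ifelse(fib[inc, 1] == crosslink_l, fib[inc, 2], fib[inc, 1])
  p <- (positions[nb, , drop = FALSE] -
          matrix(positions[crosslink_l, ], length(nb), 2, byrow = TRUE)) /
    network$rest_lengths[inc]
  Theta <- crossprod(p) / sum(p^2)
  eg <- eigen(Theta, symmetric = TRUE)
  lam <- eg$values
  degenerate <- abs(lam[1] - lam[2]) < 1e-12
  v <- eg$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90          # fold to (-90, 90]
  if (ang == -90) ang <- 90
  structure(list(tensor = Theta, eigenvalues = lam,
                 alignment_angle = if (degenerate) 0 else ang,
                 anisotropy = 1 - min(lam) / max(lam),
                 degenerate = degenerate),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("<orientation_result> sigma_al = %.4f, theta_al = %.2f deg%s\n",
              x$anisotropy, x$alignment_angle,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# crosslinks with >= 2 incident fibres inside a polygon
crosslinks_in_region <- function(network, positions, polygon) {
  deg <- tabulate(c(network$fibres), nbins = nrow(positions))
  inside <- mgcv::in.out(rbind(polygon, polygon[1, ]),
                         positions)
  which(inside & deg >= 2L)
}

#' Alignment statistics of the crosslinks inside a region
#'
#' Computes the per-crosslink anisotropy `sigma_al` and alignment angle
#' `theta_al` for every crosslink (with at least two incident fibres)
#' inside the polygon, and summarises the anisotropy sample by its mean
#' and adjusted Fisher-Pearson (bias-corrected) skewness, plus binned
#' histograms of both metrics.
#'
#' @inheritParams orientation_tensor
#' @param region_polygon k x 2 matrix of polygon vertices, um.
#' @param sigma_bins,theta_bins histogram bin counts over `[0, 1]` and
#'   `(-90, 90]`.
#' @return list: `mean_sigma`, `skewness_sigma`, `sigma`, `theta`,
#'   `crosslinks`, `sigma_hist`, `theta_hist`, `n`.
#' @export
region_alignment_stats <- function(network, positions = NULL, region_polygon,
                                   sigma_bins = 20L, theta_bins = 18L) {
  positions <- positions %||% network$positions
  idx <- crosslinks_in_region(network, positions, region_polygon)
  if (length(idx) < 2L)
    stopf("region contains fewer than 2 crosslinks with defined orientation")
  ors <- lapply(idx, function(l) orientation_tensor(network, positions, l))
  sigma <- vapply(ors, function(o) o$anisotropy, numeric(1))
  theta <- vapply(ors, function(o) o$alignment_angle, numeric(1))
  sk <- if (sd(sigma) == 0) 0 else e1071::skewness(sigma, type = 2)
  list(mean_sigma = mean(sigma), skewness_sigma = sk,
       sigma = sigma, theta = theta, crosslinks = idx,
       sigma_hist = hist(sigma, breaks = seq(0, 1, length.out = sigma_bins + 1),
                         plot = FALSE),
       theta_hist = hist(theta, breaks = seq(-90, 90, length.out = theta_bins + 1),
                         plot = FALSE),
       n = length(idx))
}

#' Compare two anisotropy samples
#'
#' Two-sided two-sample t-test p-value on the `sigma_al` samples; Welch
#' (unequal variances) by default, pooled-variance optionally.
#'
#' @param sample_a,sample_b numeric vectors (length >= 3).
#' @param pooled use the pooled-variance test instead of Welch.
#' @return p-value.
#' @export
compare_anisotropy <- function(sample_a, sample_b, pooled = FALSE) {
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stopf("each sample needs at least 3 values")
  if (sd(sample_a) == 0 && sd(sample_b) == 0)
    stopf("both samples have zero variance; the t-test is undefined")
  stats::t.test(sample_a, sample_b, var.equal = pooled)$p.value
}

#' Maximum-stress percolation path between two crosslinks
#'
#' Restricts the network to currently stretched fibres (those longer than
#' at t = 0, see [tensional_stress_field()]), weights each by the
#' reciprocal of its tensional stress, and finds the Dijkstra shortest
#' path between the source and target crosslinks — the connected path that
#' maximises stress transmission.  If no stretched-fibre path connects the
#' endpoints there is no mechanical communication and `exists` is `FALSE`.
#' Tortuosity is the Euclidean endpoint distance divided by the path
#' length (1 = straight path).
#'
#' @inheritParams orientation_tensor
#' @param source_crosslink,target_crosslink 1-based crosslink indices
#'   (typically the two adhesion-coupled crosslinks of interest).
#' @return list of class `percolation_result`: `exists`, `path`
#'   (crosslink index sequence), `total_stress` and `mean_stress` (Pa),
#'   `path_length` (um), `tortuosity`.
#' @export
max_stress_path <- function(network, positions = NULL, source_crosslink,
                            target_crosslink) {
  if (source_crosslink == target_crosslink)
    stopf("source and target crosslinks must differ")
  positions <- positions %||% network$positions
  stress <- tensional_stress_field(network, positions)
  none <- structure(list(exists = FALSE, path = integer(0), total_stress = 0,
                         mean_stress = 0, path_length = 0, tortuosity = 0),
                    class = "percolation_result")
  if (!length(stress)) return(none)
  sel <- as.integer(names(stress))
  ed <- network$fibres[sel, , drop = FALSE]
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  nmax <- max(ed)
  if (source_crosslink > nmax || target_crosslink > nmax) return(none)
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = source_crosslink, to = target_crosslink,
    weights = 1 / as.numeric(stress), output = "both",
    algorithm = "dijkstra"))
  path <- as.integer(sp$vpath[[1]])
  if (length(path) < 2L) return(none)
  eids <- as.integer(sp$epath[[1]])
  sig <- as.numeric(stress)[eids]
  lens <- fibre_lengths(network, positions)[sel][eids]
  plen <- sum(lens)
  structure(list(
    exists = TRUE, path = path,
    total_stress = sum(sig), mean_stress = mean(sig),
    path_length = plen,
    tortuosity = vec_norm(positions[target_crosslink, ] -
                            positions[source_crosslink, ]) / plen),
    class = "percolation_result")
}

# stresses of the fibres along a percolation path, in path order
path_stresses <- function(network, result, positions = NULL) {
  stress <- tensional_stress_field(network, positions)
  fib <- network$fibres
  vapply(seq_len(length(result$path) - 1L), function(i) {
    a <- result$path[i]
    b <- result$path[i + 1L]
    e <- which((fib[, 1] == a & fib[, 2] == b) |
                 (fib[, 1] == b & fib[, 2] == a))
    unname(stress[as.character(e)])
  }, numeric(1))
}

#' @export
print.percolation_result <- function(x, ...) {
  if (!x$exists) {
    cat("<percolation_result> no stretched-fibre path (no mechanical communication)\n")
  } else {
    cat(sprintf(
      "<percolation_result> %d crosslinks, mean stress %.4g Pa, tortuosity %.3f\n",
      length(x$path), x$mean_stress, x$tortuosity))
  }
  invisible(x)
}

#' Cell-ECM interaction force summary of a trajectory
#'
#' At each sampled time, the mean and standard deviation of the adhesion
#' force magnitudes `|F_ec| = N_b k_i |eps|` over all attached adhesions;
#' returns the peak of the mean curve and the time at which it occurs.
#'
#' @param trajectory a [run_simulation()] result.
#' @return list: `peak_mean_force` (pN), `peak_time` (s), `table` (data
#'   frame with `time`, `mean`, `sd`, `n_attached`).
#' @export
interaction_force_summary <- function(trajectory) {
  if (is.null(trajectory$fa_force) || ncol(trajectory$fa_force) == 0L)
    stopf("trajectory has no focal-adhesion force records")
  Fm <- trajectory$fa_force
  att <- trajectory$fa_attached
  mean_t <- vapply(seq_len(nrow(Fm)), function(s) {
    a <- att[s, ]
    if (!any(a)) 0 else mean(Fm[s, a])
  }, numeric(1))
  sd_t <- vapply(seq_len(nrow(Fm)), function(s) {
    a <- att[s, ]
    if (sum(a) < 2L) NA_real_ else sd(Fm[s, a])
  }, numeric(1))
  k <- which.max(mean_t)
  list(peak_mean_force = mean_t[k], peak_time = trajectory$times[k],
       table = data.frame(time = trajectory$times, mean = mean_t, sd = sd_t,
                          n_attached = rowSums(att)))
}
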