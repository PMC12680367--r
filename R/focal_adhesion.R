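#' Catch-bond integrin parameters
#'
#' Kinetic and mechanical constants of an integrin cluster.  Unbinding
#' follows the two-pathway catch--slip law
#' `K_off(F) = k_c * exp(-F/F_c) + k_s * exp(F/F_s)`:
#' the catch pathway (`k_c`, `F_c`) dominates at low force, so bond
#' lifetime first increases with load, while the slip pathway (`k_s`,
#' `F_s`) takes over at high force and lifetime decays exponentially.
#' Binding occurs at the constant rate `K_on`; each bound integrin is a
#' Hookean spring of stiffness `k_i` and rest length `L0_i`.
#'
#' Default rates are reconstructions calibrated to integrin-scale
#' measurements: off-rate minimiser near 26 pN and a zero-force off-rate of
#' ~5/s, giving a per-integrin bifurcation load of ~36 pN.
#'
#' @param K_on binding rate, 1/s.
#' @param k_c,F_c catch-pathway rate (1/s) and force scale (pN).
#' @param k_s,F_s slip-pathway rate (1/s) and force scale (pN).
#' @param k_i integrin spring stiffness, pN/um.
#' @param L0_i integrin rest length, um.
#' @return an object of class `catch_bond_params`.
#' @export
catch_bond_params <- function(K_on = 2, k_c = 5, F_c = 10,
                              k_s = 0.03, F_s = 10,
                              k_i = 1000, L0_i = 0.02) {
  p <- list(K_on = K_on, k_c = k_c, F_c = F_c, k_s = k_s, F_s = F_s,
            k_i = k_i, L0_i = L0_i)
  if (any(unlist(p) <= 0)) stopf("all catch-bond parameters must be > 0")
  structure(p, class = "catch_bond_params")
}

#' @export
print.catch_bond_params <- function(x, ...) {
  cat(sprintf(
    "<catch_bond_params> K_on=%.3g/s, k_c=%.3g/s @ F_c=%.3g pN, k_s=%.3g/s @ F_s=%.3g pN, k_i=%.3g pN/um, L0_i=%.3g um\n",
    x$K_on, x$k_c, x$F_c, x$k_s, x$F_s, x$k_i, x$L0_i))
  invisible(x)
}

#' Force-dependent integrin unbinding rate
#'
#' `K_off(F) = k_c exp(-F/F_c) + k_s exp(F/F_s)`.  Smooth in F, so its
#' derivative (needed by the bifurcation closed form) exists everywhere.
#' The slip exponent is capped at 500 to avoid floating-point overflow for
#' extreme transient loads.
#'
#' @param F tensile force per integrin, pN (>= 0); vectorised.
#' @param params a [catch_bond_params()].
#' @return unbinding rate, 1/s.
#' @export
koff <- function(F, params) {
  params$k_c * exp(-F / params$F_c) +
    params$k_s * exp(pmin(F / params$F_s, 500))
}

#' @rdname koff
#' @details `koff_prime()` is the analytic derivative dK_off/dF.
#' @export
koff_prime <- function(F, params) {
  -(params$k_c / params$F_c) * exp(-F / params$F_c) +
    (params$k_s / params$F_s) * exp(pmin(F / params$F_s, 500))
}

#' Force minimising the unbinding rate (maximal bond lifetime)
#'
#' Closed form for the two-pathway law:
#' `F* = F_c F_s / (F_c + F_s) * log(k_c F_s / (k_s F_c))`.
#'
#' @inheritParams koff
#' @return force, pN.
#' @export
koff_minimiser <- function(params) {
  with(params, F_c * F_s / (F_c + F_s) * log(k_c * F_s / (k_s * F_c)))
}

#' Construct a focal adhesion record
#'
#' Links one cell vertex to one ECM crosslink via a cluster of `N`
#' integrins in parallel.  The bound count `N_b` is a continuous mean-field
#' variable in `[0, N]`; once `attached` becomes `FALSE` the adhesion is
#' permanently broken (`N_b = 0`) — de novo re-formation is out of scope.
#'
#' @param cell_index,vertex_index,crosslink_index 1-based indices.
#' @param N total available integrins (conserved).
#' @param N_b initially bound integrins; defaults to the zero-force binding
#'   equilibrium `K_on N / (K_on + K_off(0))`.
#' @param params a [catch_bond_params()].
#' @param attached logical.
#' @return an object of class `focal_adhesion`.
#' @export
focal_adhesion <- function(cell_index, vertex_index, crosslink_index, N,
                           params = catch_bond_params(), N_b = NULL,
                           attached = TRUE) {
  if (is.null(N_b)) N_b <- params$K_on * N / (params$K_on + koff(0, params))
  if (N_b < 0 || N_b > N) stopf("N_b must lie in [0, N]")
  if (!attached && N_b != 0) stopf("a detached adhesion has N_b = 0")
  structure(list(cell_index = cell_index, vertex_index = vertex_index,
                 crosslink_index = crosslink_index, N = N, N_b = N_b,
                 params = params, attached = attached),
            class = "focal_adhesion")
}

#' Force exerted by a cluster of bound integrins
#'
#' All bound integrins share the same extension
#' `eps = ||x_vertex - x_crosslink|| - L0_i`, so the cluster force has
#' magnitude `N_b * k_i * eps` along the vertex-crosslink axis: it pulls
#' the vertex towards the crosslink when stretched (`eps > 0`) and pushes
#' apart when compressed.  The crosslink force is the exact negative
#' (Newton pair).
#'
#' @param fa a [focal_adhesion()].
#' @param vertex_pos,crosslink_pos 2-vectors, um.
#' @return list with `on_vertex` and `on_crosslink` force 2-vectors (pN)
#'   and the scalar `extension` (um).
#' @export
integrin_cluster_force <- function(fa, vertex_pos, crosslink_pos) {
  if (!fa$attached) {
    return(list(on_vertex = c(0, 0), on_crosslink = c(0, 0), extension = NA_real_))
  }
  d <- vertex_pos - crosslink_pos
  dist <- vec_norm(d)
  if (dist == 0) stopf("vertex and crosslink positions coincide")
  eps <- dist - fa$params$L0_i
  Fv <- -fa$N_b * fa$params$k_i * eps * d / dist
  list(on_vertex = Fv, on_crosslink = -Fv, extension = eps)
}

#' Mean-field binding kinetics of an integrin cluster
#'
#' `dN_b/dt = K_on N - (K_on + K_off(F_i)) N_b`, where `F_i` is the
#' tensile force on a single integrin (`k_i * max(eps, 0)`: compressed
#' integrins push but do not accelerate unbinding, since catch-bond data
#' are for tensile load).
#'
#' @param N_b bound integrins.
#' @param F_per_integrin tensile force per integrin, pN.
#' @param fa a [focal_adhesion()] (supplies `N` and kinetic parameters).
#' @return dN_b/dt, 1/s.
#' @export
binding_rhs <- function(N_b, F_per_integrin, fa) {
  p <- fa$params
  p$K_on * fa$N - (p$K_on + koff(F_per_integrin, p)) * N_b
}
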