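#' Reduced focal-adhesion dynamical system
#'
#' Two-variable mean-field model of a single adhesion under a constant
#' external load `F_ext`:
#' \deqn{\eta \, d\epsilon/dt = -2 k_i N_b \epsilon + F_{ext}, \qquad
#'       dN_b/dt = K_{on} N - (K_{on} + K_{off}(k_i \epsilon)) N_b,}
#' where `eps` is the common integrin stretch and `N_b` the bound count.
#' The factor 2 reflects the integrin cluster acting on both the cell and
#' ECM sides of the assembly.  `K_off` is evaluated at the tensile
#' per-integrin force `k_i * max(eps, 0)`.
#'
#' @param eps_b integrin stretch, um.
#' @param N_b bound integrins.
#' @param F_ext external force on the integrin assembly, pN (>= 0).
#' @param params a [catch_bond_params()].
#' @param N total available integrins.
#' @param eta damping coefficient of the assembly, pN s/um.
#' @return `reduced_rhs()`: numeric 2-vector `(deps/dt, dN_b/dt)`.
#' @export
reduced_rhs <- function(eps_b, N_b, F_ext, params, N, eta = 1000) {
  Fi <- params$k_i * max(eps_b, 0)
  c((-2 * params$k_i * N_b * eps_b + F_ext) / eta,
    params$K_on * N - (params$K_on + koff(Fi, params)) * N_b)
}

# h(eps) = force sustained at binding equilibrium for stretch eps; fixed
# points of the reduced system solve h(eps) = F_ext.
equilibrium_force_curve <- function(eps, params, N) {
  Fi <- params$k_i * pmax(eps, 0)
  Nb <- params$K_on * N / (params$K_on + koff(Fi, params))
  2 * params$k_i * Nb * eps
}

reduced_jacobian <- function(eps, N_b, params, N, eta) {
  ki <- params$k_i
  Fi <- ki * max(eps, 0)
  dkoff <- if (eps > 0) koff_prime(Fi, params) * ki else 0
  matrix(c(-2 * ki * N_b / eta, -2 * ki * eps / eta,
           -dkoff * N_b, -(params$K_on + koff(Fi, params))),
         2, 2, byrow = TRUE)
}

#' Saddle-node bifurcation point of the reduced adhesion system
#'
#' Solves the implicit scalar condition for the critical integrin stretch
#' `eps_BP`,
#' \deqn{\epsilon = \frac{K_{on} + K_{off}(k_i\epsilon)}
#'                       {k_i \, K_{off}'(k_i\epsilon)},}
#' by bracketed root finding on the branch where `K_off' > 0` (beyond the
#' off-rate minimiser), then evaluates the closed forms
#' `N_b^BP/N = K_on / (K_on + K_off(k_i eps_BP))` and
#' `F_BP = 2 k_i eps_BP N_b^BP`.  The stretch and bound fraction at the
#' fold depend only on the binding/unbinding rates, so they are independent
#' of `N` and the bifurcation force is exactly linear in `N`.
#'
#' @inheritParams reduced_rhs
#' @return list of class `bifurcation_result`: `F_BP` (pN), `eps_BP` (um),
#'   `bound_fraction_BP` (dimensionless).
#' @export
bifurcation_point <- function(params, N) {
  ki <- params$k_i
  psi <- function(eps) {
    Fi <- ki * eps
    eps * ki * koff_prime(Fi, params) - (params$K_on + koff(Fi, params))
  }
  lo <- koff_minimiser(params) / ki   # koff' = 0 here, so psi(lo) < 0
  hi <- lo * 1.5
  for (i in 1:200) {
    if (psi(hi) > 0) break
    hi <- hi * 1.5
  }
  if (psi(hi) <= 0)
    stopf("no bifurcation root found in stretch interval [%.3g, %.3g] um",
          lo, hi)
  eps_BP <- uniroot(psi, c(lo, hi), tol = 1e-14)$root
  frac <- params$K_on / (params$K_on + koff(ki * eps_BP, params))
  structure(list(F_BP = 2 * ki * eps_BP * frac * N,
                 eps_BP = eps_BP, bound_fraction_BP = frac),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("<bifurcation_result> F_BP = %.6g pN, eps_BP = %.6g um, N_b^BP/N = %.6g\n",
              x$F_BP, x$eps_BP, x$bound_fraction_BP))
  invisible(x)
}

#' Fixed points of the reduced adhesion system
#'
#' For `F_ext < F_BP` the system has a stable bound state coexisting with
#' an unstable (saddle) state; at the fold they merge and for
#' `F_ext > F_BP` no bound equilibrium exists (detachment).  Stability is
#' classified by the eigenvalues of the analytic Jacobian.
#'
#' @inheritParams reduced_rhs
#' @return a data frame with columns `eps`, `N_b`, `stability`
#'   (`"stable"`/`"unstable"`); zero rows when no equilibrium with bound
#'   integrins exists.
#' @export
fa_equilibria <- function(F_ext, params, N, eta = 1000) {
  empty <- data.frame(eps = numeric(0), N_b = numeric(0),
                      stability = character(0))
  classify <- function(eps) {
    Nb <- params$K_on * N / (params$K_on + koff(params$k_i * max(eps, 0), params))
    ev <- eigen(reduced_jacobian(eps, Nb, params, N, eta),
                only.values = TRUE)$values
    data.frame(eps = eps, N_b = Nb,
               stability = if (all(Re(ev) < 0)) "stable" else "unstable")
  }
  if (F_ext == 0) return(classify(0))
  if (F_ext < 0) stopf("F_ext must be >= 0")
  bp <- bifurcation_point(params, N)
  if (F_ext > bp$F_BP) return(empty)
  g <- function(eps) equilibrium_force_curve(eps, params, N) - F_ext
  # numerically at the fold itself: the two roots have merged
  if (g(bp$eps_BP) <= 0) return(classify(bp$eps_BP))
  # stable root below the fold stretch, unstable above
  out <- classify(uniroot(g, c(1e-15, bp$eps_BP), tol = 1e-14)$root)
  if (F_ext < bp$F_BP) {
    hi <- bp$eps_BP * 2
    for (i in 1:200) {
      if (g(hi) < 0) break
      hi <- hi * 2
    }
    if (g(hi) >= 0)
      stopf("failed to bracket the unstable equilibrium (scanned up to eps = %.3g um)", hi)
    out <- rbind(out, classify(uniroot(g, c(bp$eps_BP, hi), tol = 1e-14)$root))
  }
  out
}

reduced_ode_fn <- function(t, y, parms) {
  list(reduced_rhs(y[1], min(max(y[2], 0), parms$N), parms$F_ext,
                   parms$params, parms$N, parms$eta))
}

#' Integrate the reduced adhesion system
#'
#' Solves the two-variable system with `deSolve::lsoda` from a given
#' initial condition under constant load.
#'
#' @inheritParams reduced_rhs
#' @param eps0,N_b0 initial stretch (um) and bound count.
#' @param times output time grid, s.
#' @return matrix with columns `time`, `eps`, `N_b`.
#' @export
integrate_reduced <- function(eps0, N_b0, F_ext, params, N, times,
                              eta = 1000) {
  out <- deSolve::lsoda(c(eps = eps0, N_b = N_b0), times, reduced_ode_fn,
                        parms = list(F_ext = F_ext, params = params, N = N,
                                     eta = eta),
                        rtol = 1e-9, atol = 1e-9)
  colnames(out) <- c("time", "eps", "N_b")
  out
}

#' Classify an initial condition as attaching or detaching
#'
#' Integrates the reduced system from `(eps0, N_b0)`; the trajectory is
#' classified `"attach"` when it enters a ball of 1% (relative) radius
#' around the stable equilibrium and `"detach"` when the bound count drops
#' below one integrin.  An undecided trajectory at the horizon is an error,
#' never a silent default.
#'
#' @inheritParams integrate_reduced
#' @param horizon integration horizon, s; defaults to `50 / K_on`.
#' @param ball_radius relative attach-ball radius.
#' @return `"attach"` or `"detach"`.
#' @export
classify_basin <- function(eps0, N_b0, F_ext, params, N,
                           horizon = NULL, eta = 1000, ball_radius = 0.01) {
  horizon <- horizon %||% (50 / params$K_on)
  eq <- fa_equilibria(F_ext, params, N, eta)
  stable <- eq[eq$stability == "stable", ]
  r_eps <- r_Nb <- NA_real_
  if (nrow(stable) == 1L) {
    r_eps <- ball_radius * max(abs(stable$eps), params$L0_i)
    r_Nb <- ball_radius * max(stable$N_b, 1)
  }
  # terminate at whichever happens first: entry into the attach ball or
  # the bound count dropping below one integrin (detachment); the
  # detached trajectory has eps growing without bound, so integrating to
  # the horizon after the decision would be wasted stiffness
  rootfun <- function(t, y, parms) {
    d <- y[2] - 1
    a <- if (nrow(stable) == 1L) {
      max(abs(y[1] - stable$eps) / r_eps, abs(y[2] - stable$N_b) / r_Nb) - 1
    } else {
      1
    }
    c(d, a)
  }
  times <- seq(0, horizon, length.out = 2000L)
  tr <- deSolve::lsoda(c(eps = eps0, N_b = N_b0), times, reduced_ode_fn,
                       parms = list(F_ext = F_ext, params = params, N = N,
                                    eta = eta),
                       rtol = 1e-9, atol = 1e-9, rootfunc = rootfun)
  last <- tr[nrow(tr), ]
  if (last[["N_b"]] < 1 + 1e-6) return("detach")
  if (nrow(stable) == 1L &&
      abs(last[["eps"]] - stable$eps) <= r_eps * (1 + 1e-6) &&
      abs(last[["N_b"]] - stable$N_b) <= r_Nb * (1 + 1e-6))
    return("attach")
  stopf("trajectory undecided at horizon %.3g s (eps = %.3g, N_b = %.3g)",
        horizon, last[["eps"]], last[["N_b"]])
}

#' Bifurcation summary across integrin numbers
#'
#' Tabulates the fold (`F_BP`, `eps_BP`, bound fraction) for several values
#' of the total integrin number, plus a sampled stable/unstable branch
#' table for diagram plotting.  Backs the `bifurcate` CLI subcommand.
#'
#' @param N_values integer vector of total integrin numbers.
#' @param params a [catch_bond_params()].
#' @param n_branch number of force samples per branch.
#' @return list with data frames `points` and `branches`.
#' @export
bifurcation_table <- function(N_values, params = catch_bond_params(),
                              n_branch = 60L) {
  pts <- do.call(rbind, lapply(N_values, function(N) {
    bp <- bifurcation_point(params, N)
    data.frame(N = N, F_BP = bp$F_BP, eps_BP = bp$eps_BP,
               bound_fraction_BP = bp$bound_fraction_BP)
  }))
  branches <- do.call(rbind, lapply(N_values, function(N) {
    bp <- bifurcation_point(params, N)
    Fs <- seq(0, bp$F_BP * 0.999, length.out = n_branch)
    do.call(rbind, lapply(Fs, function(f) {
      eq <- fa_equilibria(f, params, N)
      if (nrow(eq)) cbind(N = N, F_ext = f, eq) else NULL
    }))
  }))
  list(points = pts, branches = branches)
}
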