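#' Simulation state of the coupled cell-ECM-adhesion system
#'
#' Internal constructor; use [initialize_scenario()] to build a valid state.
#' A state bundles the time, the [fibre_network()], the list of
#' [make_cell()] agents, the [focal_adhesion()] records, lagged node
#' velocities (for the Kelvin-Voigt dashpot) and the event log.
#'
#' @keywords internal
new_simulation_state <- function(time, network, cells, fas, config,
                                 velocities = NULL, events = NULL) {
  nv <- vapply(cells, function(cl) nrow(cl$vertices), integer(1))
  if (is.null(velocities)) {
    velocities <- list(
      vertices = lapply(nv, function(k) matrix(0, k, 2)),
      centres = matrix(0, length(cells), 2))
  }
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), kind = character(0),
                         fa = integer(0))
  }
  for (fa in fas) {
    if (fa$cell_index > length(cells) ||
        fa$vertex_index > nrow(cells[[fa$cell_index]]$vertices) ||
        fa$crosslink_index > nrow(network$positions))
      stopf("focal adhesion references a non-existent cell vertex or crosslink")
  }
  structure(list(time = time, network = network, cells = cells, fas = fas,
                 velocities = velocities, events = events, config = config),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf(
    "<simulation_state> t = %.4g s: %d crosslinks, %d cells, %d adhesions (%d attached), %d events\n",
    x$time, nrow(x$network$positions), length(x$cells), length(x$fas),
    sum(vapply(x$fas, function(f) f$attached, logical(1))),
    nrow(x$events)))
  invisible(x)
}

# global (stacked) vertex indices for each cell
vertex_offsets <- function(cells) {
  nv <- vapply(cells, function(cl) nrow(cl$vertices), integer(1))
  c(0L, cumsum(nv))[seq_along(cells)]
}

# Flatten a state into the argument list of the compiled core.
pack_state <- function(state) {
  net <- state$network
  cells <- state$cells
  off <- vertex_offsets(cells)
  verts <- do.call(rbind, lapply(cells, function(cl) cl$vertices))
  if (is.null(verts)) verts <- matrix(0, 0, 2)
  vert_cell <- rep.int(seq_along(cells) - 1L,
                       vapply(cells, function(cl) nrow(cl$vertices), integer(1)))
  seg_L0 <- unlist(lapply(cells, function(cl) cl$segment_rest_lengths))
  ang <- if (length(cells)) {
    do.call(rbind, lapply(seq_along(cells), function(i) {
      ap <- angle_pairs(nrow(cells[[i]]$vertices))
      cbind(ap[, 1] + off[i] - 1L, ap[, 2] + off[i] - 1L, i - 1L,
            cells[[i]]$natural_angles)
    }))
  } else {
    matrix(0, 0, 4)
  }
  ext <- matrix(0, nrow(verts), 2)
  for (i in seq_along(cells)) {
    pf <- cells[[i]]$ext_force
    if (!is.null(pf)) ext[off[i] + seq_len(nrow(pf)), ] <- pf
  }
  fas <- state$fas
  p <- state$config$fa_params
  list(
    pos = net$positions, fib = net$fibres - 1L, L0 = net$rest_lengths,
    ref0 = net$reference_lengths_t0, pinned = net$pinned,
    EtA = net$E_t * net$area, rho = net$compression_factor,
    eta_ecm = net$eta,
    cent = do.call(rbind, lapply(cells, function(cl) cl$centre)) %||%
      matrix(0, 0, 2),
    vert = verts, vert_cell = as.integer(vert_cell), seg_L0 = seg_L0,
    kseg = vapply(cells, function(cl) cl$k_seg, numeric(1)),
    gseg = vapply(cells, function(cl) cl$gamma_seg, numeric(1)),
    kang = vapply(cells, function(cl) cl$k_ang, numeric(1)),
    Fco = vapply(cells, function(cl) cl$F_co, numeric(1)),
    eta_cell = if (length(cells)) cells[[1]]$eta else 1000,
    ang_i = as.integer(ang[, 1]),
    ang_j = as.integer(ang[, 2]),
    ang_cell = as.integer(ang[, 3]),
    ang_th0 = as.numeric(ang[, 4]),
    ext = ext,
    fa_vert = vapply(fas, function(f) off[f$cell_index] + f$vertex_index - 1L,
                     integer(1)),
    fa_node = vapply(fas, function(f) f$crosslink_index - 1L, integer(1)),
    fa_N = vapply(fas, function(f) as.numeric(f$N), numeric(1)),
    fa_Nb = vapply(fas, function(f) f$N_b, numeric(1)),
    fa_att = vapply(fas, function(f) f$attached, logical(1)),
    ki = p$k_i, L0i = p$L0_i,
    Kon = p$K_on, kc = p$k_c, Fc = p$F_c, ks = p$k_s, Fs = p$F_s
  )
}

call_core <- function(state, t_end, sample_dt, active, relax_mode = FALSE,
                      tol = 1e-3, fixed_dt = 0, max_steps = 2e7) {
  a <- pack_state(state)
  icfg <- state$config$integration
  .core_run(a$pos, a$fib, a$L0, a$ref0, a$pinned, a$EtA, a$rho, a$eta_ecm,
            a$cent, a$vert, a$vert_cell, a$seg_L0, a$kseg, a$gseg, a$kang,
            a$Fco, a$eta_cell, a$ang_i, a$ang_j, a$ang_cell, a$ang_th0,
            a$ext, a$fa_vert, a$fa_node, a$fa_N, a$fa_Nb, a$fa_att,
            a$ki, a$L0i, a$Kon, a$kc, a$Fc, a$ks, a$Fs,
            state$time, t_end, icfg$safety, sample_dt,
            state$config$fa$detach_threshold %||% 1, active, relax_mode,
            tol, fixed_dt, as.integer(max_steps),
            icfg$activation_ramp %||% 0)
}

# Write the core's final state back into a simulation_state.
unpack_core <- function(state, res) {
  st <- state
  st$time <- res$time
  st$network$positions <- res$pos
  off <- vertex_offsets(st$cells)
  for (i in seq_along(st$cells)) {
    k <- nrow(st$cells[[i]]$vertices)
    st$cells[[i]]$vertices <- res$vertices[off[i] + seq_len(k), , drop = FALSE]
    st$cells[[i]]$centre <- res$centres[i, ]
    st$velocities$vertices[[i]] <- res$vel_vertices[off[i] + seq_len(k), ,
                                                    drop = FALSE]
  }
  st$velocities$centres <- res$vel_centres
  for (q in seq_along(st$fas)) {
    st$fas[[q]]$N_b <- res$Nb_final[q]
    st$fas[[q]]$attached <- res$attached_final[q] == 1
  }
  if (length(res$event_times)) {
    st$events <- rbind(st$events,
                       data.frame(time = res$event_times, kind = "detachment",
                                  fa = res$event_fa))
  }
  st
}

#' Net conservative + active forces on every node of a simulation state
#'
#' Assembles, at the current positions, the elastic ECM forces, cell
#' structural (spring + angular) forces, adhesion Newton pairs and
#' (optionally) the active contraction / external pulling forces.  The
#' Kelvin-Voigt dashpot contributes no force here: in the overdamped
#' formulation it enters the equations of motion as extra velocity-space
#' damping, handled exactly by the integrator's per-cell velocity solve.
#'
#' @param state a simulation state.
#' @param active include active contraction and external pulling forces.
#' @param contraction_scale myosin activation factor in `[0, 1]` applied
#'   to the contraction forces (the activation ramp of the integrator).
#' @return list with `crosslinks` (n x 2), `vertices` (list of per-cell
#'   matrices) and `centres` (n_cells x 2), all pN.
#' @export
state_forces <- function(state, active = TRUE, contraction_scale = 1) {
  net <- state$network
  FP <- net_elastic_forces(net)
  FV <- vector("list", length(state$cells))
  FC <- matrix(0, length(state$cells), 2)
  for (i in seq_along(state$cells)) {
    cl <- state$cells[[i]]
    stf <- structural_forces(cl)
    FV[[i]] <- stf$vertices
    FC[i, ] <- stf$centre
    if (active) {
      if (cl$F_co != 0 && contraction_scale > 0) {
        co <- contraction_forces(cl)
        # myosin stall floor: taper the constant contraction to zero below
        # ~15% of the segment rest length (no through-centre collapse)
        len <- row_norms(sweep(cl$vertices, 2, cl$centre))
        fl <- pmin(pmax((len / cl$segment_rest_lengths - 0.15) / 0.10, 0), 1)
        FV[[i]] <- FV[[i]] + contraction_scale * fl * co$vertices
        FC[i, ] <- FC[i, ] - colSums(contraction_scale * fl * co$vertices)
      }
      if (!is.null(cl$ext_force)) FV[[i]] <- FV[[i]] + cl$ext_force
    }
  }
  for (fa in state$fas) {
    if (!fa$attached) next
    cl <- state$cells[[fa$cell_index]]
    fr <- integrin_cluster_force(fa, cl$vertices[fa$vertex_index, ],
                                 net$positions[fa$crosslink_index, ])
    FV[[fa$cell_index]][fa$vertex_index, ] <-
      FV[[fa$cell_index]][fa$vertex_index, ] + fr$on_vertex
    FP[fa$crosslink_index, ] <- FP[fa$crosslink_index, ] + fr$on_crosslink
  }
  list(crosslinks = FP, vertices = FV, centres = FC)
}

#' Overdamped node velocities of a simulation state
#'
#' Solves `(eta I + D(x)) v = F` for the node velocities, where `F` are
#' the conservative + active forces from [state_forces()] and `D` is the
#' Kelvin-Voigt dashpot damping: each cell segment adds an axial rank-one
#' damper `gamma_seg u u'` between its vertex and the cell centre.  The
#' dashpot couples vertices to their centre only, so the solve reduces to
#' an exact 2 x 2 system per cell (Schur complement at the centre).
#' Pinned crosslinks have zero velocity.
#'
#' @param state a simulation state.
#' @param forces optional precomputed [state_forces()] result.
#' @param active include active forces when `forces` is missing.
#' @return list with `crosslinks`, `vertices` (per-cell list), `centres`,
#'   all um/s.
#' @export
state_velocities <- function(state, forces = NULL, active = TRUE) {
  f <- forces %||% state_forces(state, active)
  net <- state$network
  vP <- f$crosslinks / net$eta
  vP[net$pinned, ] <- 0
  vV <- vector("list", length(state$cells))
  vC <- matrix(0, length(state$cells), 2)
  for (i in seq_along(state$cells)) {
    cl <- state$cells[[i]]
    eta_c <- cl$eta
    gam <- cl$gamma_seg
    d <- sweep(cl$vertices, 2, cl$centre)
    u <- d / row_norms(d)
    if (gam > 0) {
      g <- gam * eta_c / (eta_c + gam)
      cf <- gam / (eta_c + gam)
      M <- diag(2) * eta_c
      for (k in seq_len(nrow(u))) M <- M + g * tcrossprod(u[k, ])
      pf <- rowSums(f$vertices[[i]] * u)
      rhs <- f$centres[i, ] + (g / eta_c) * colSums(pf * u)
      vC[i, ] <- solve(M, rhs)
      pv <- as.numeric(u %*% vC[i, ])
      vV[[i]] <- (f$vertices[[i]] - cf * pf * u) / eta_c + cf * pv * u
    } else {
      vC[i, ] <- f$centres[i, ] / eta_c
      vV[[i]] <- f$vertices[[i]] / eta_c
    }
  }
  list(crosslinks = vP, vertices = vV, centres = vC)
}

#' Advance the coupled system by one integration step
#'
#' Reference (R-level) implementation of a single Heun step of the
#' overdamped system: node velocities come from the damped force balance
#' of [state_velocities()] (crosslinks: `(F_el + F_ec)/eta_ecm`; cell
#' vertices and centres: the Kelvin-Voigt-damped balance of
#' `F_st + F_co + F_ec` and the centre reactions), and the bound-integrin
#' counts advance by an exact exponential update of the binding kinetics
#' with the adhesion force frozen over the step.  Detachment (`N_b` below
#' the threshold) is applied after the step and is permanent.  The
#' production path [run_simulation()] runs the identical scheme in
#' compiled code.
#'
#' @param state a simulation state from [initialize_scenario()].
#' @param dt time step, s (must respect the overdamped stability bound;
#'   [run_simulation()] chooses it adaptively).
#' @param active include active forces (contraction / pulling).
#' @return the advanced simulation state.
#' @export
sim_step <- function(state, dt, active = TRUE) {
  if (dt <= 0) stopf("dt must be positive")
  net <- state$network
  ramp <- state$config$integration$activation_ramp %||% 0
  act <- if (ramp > 0) min(state$time / ramp, 1) else 1
  v1 <- state_velocities(state,
                         forces = state_forces(state, active, act))
  # predictor
  pred <- state
  pred$network$positions <- net$positions + dt * v1$crosslinks
  for (i in seq_along(state$cells)) {
    pred$cells[[i]]$vertices <- state$cells[[i]]$vertices +
      dt * v1$vertices[[i]]
    pred$cells[[i]]$centre <- state$cells[[i]]$centre + dt * v1$centres[i, ]
  }
  v2 <- state_velocities(pred,
                         forces = state_forces(pred, active, act))
  # corrector
  new <- state
  new$time <- state$time + dt
  new$network$positions <- net$positions +
    dt * 0.5 * (v1$crosslinks + v2$crosslinks)
  for (i in seq_along(state$cells)) {
    vnew <- state$cells[[i]]$vertices +
      dt * 0.5 * (v1$vertices[[i]] + v2$vertices[[i]])
    cnew <- state$cells[[i]]$centre +
      dt * 0.5 * (v1$centres[i, ] + v2$centres[i, ])
    new$velocities$vertices[[i]] <- (vnew - state$cells[[i]]$vertices) / dt
    new$velocities$centres[i, ] <- (cnew - state$cells[[i]]$centre) / dt
    new$cells[[i]]$vertices <- vnew
    new$cells[[i]]$centre <- cnew
  }
  # binding kinetics: exact update for frozen force
  thr <- state$config$fa$detach_threshold %||% 1
  for (q in seq_along(new$fas)) {
    fa <- new$fas[[q]]
    if (!fa$attached) next
    p <- fa$params
    d <- new$cells[[fa$cell_index]]$vertices[fa$vertex_index, ] -
      new$network$positions[fa$crosslink_index, ]
    eps <- vec_norm(d) - p$L0_i
    lam <- p$K_on + koff(p$k_i * max(eps, 0), p)
    Nstar <- p$K_on * fa$N / lam
    fa$N_b <- Nstar + (fa$N_b - Nstar) * exp(-lam * dt)
    if (fa$N_b < thr) {
      fa$attached <- FALSE
      fa$N_b <- 0
      new$events <- rbind(new$events,
                          data.frame(time = new$time, kind = "detachment",
                                     fa = q))
    }
    new$fas[[q]] <- fa
  }
  new
}

#' Run a simulation and record a trajectory
#'
#' Advances the state with the compiled adaptive Heun integrator until
#' `t_end`, sampling snapshots every `sample_dt` (from the integration
#' config).  Detachment events are time-stamped in the event log.
#' Observers are functions applied to each sampled frame (a list with
#' `time`, `crosslinks`, `vertices`, `centres`, `N_b`, `fa_force`); their
#' results are stored in `trajectory$observations`.
#'
#' @param state a simulation state from [initialize_scenario()].
#' @param t_end end time, s.
#' @param observers optional named list of frame functions.
#' @param active include active forces (contraction / pulling).
#' @return an object of class `trajectory`; the advanced state is in
#'   `$final_state`.
#' @export
run_simulation <- function(state, t_end, observers = NULL, active = TRUE) {
  if (t_end <= state$time) stopf("t_end must exceed the current state time")
  icfg <- state$config$integration
  res <- call_core(state, t_end, icfg$sample_dt, active = active,
                   max_steps = icfg$max_steps %||% 2e7)
  traj <- build_trajectory(state, res)
  if (!is.null(observers)) {
    traj$observations <- lapply(observers, function(fn) {
      lapply(seq_along(traj$times), function(s) fn(trajectory_frame(traj, s)))
    })
  }
  traj
}

# core samples store x,y interleaved per node; split into [S, n, 2]
interleaved_to_array <- function(m, S, n) {
  m <- matrix(m, nrow = S)
  out <- array(0, c(S, n, 2))
  if (n > 0) {
    out[, , 1] <- m[, seq(1, 2 * n, by = 2), drop = FALSE]
    out[, , 2] <- m[, seq(2, 2 * n, by = 2), drop = FALSE]
  }
  out
}

build_trajectory <- function(state, res) {
  S <- length(res$times)
  n <- nrow(state$network$positions)
  nv <- sum(vapply(state$cells, function(cl) nrow(cl$vertices), integer(1)))
  nc <- length(state$cells)
  off <- vertex_offsets(state$cells)
  fa_tab <- if (length(state$fas)) {
    data.frame(
      fa = seq_along(state$fas),
      cell = vapply(state$fas, function(f) f$cell_index, numeric(1)),
      vertex = vapply(state$fas, function(f) f$vertex_index, numeric(1)),
      global_vertex = vapply(state$fas, function(f)
        off[f$cell_index] + f$vertex_index, numeric(1)),
      crosslink = vapply(state$fas, function(f) f$crosslink_index, numeric(1)),
      N = vapply(state$fas, function(f) as.numeric(f$N), numeric(1)))
  } else {
    data.frame()
  }
  structure(list(
    times = res$times,
    crosslinks = interleaved_to_array(res$P, S, n),
    vertices = interleaved_to_array(res$V, S, nv),
    centres = interleaved_to_array(res$C, S, nc),
    N_b = res$Nb, fa_force = res$fa_force, fa_eps = res$fa_eps,
    fa_attached = res$fa_attached == 1,
    fa_table = fa_tab,
    events = if (length(res$event_times))
      data.frame(time = res$event_times, kind = "detachment",
                 fa = res$event_fa)
    else data.frame(time = numeric(0), kind = character(0), fa = integer(0)),
    config = state$config,
    final_state = unpack_core(state, res)
  ), class = "trajectory")
}

#' Extract one sampled frame of a trajectory
#'
#' @param trajectory a [run_simulation()] result.
#' @param s sample index (1-based).
#' @return list with `time`, `crosslinks`, `vertices`, `centres`, `N_b`,
#'   `fa_force`, `fa_attached`.
#' @export
trajectory_frame <- function(trajectory, s) {
  list(time = trajectory$times[s],
       crosslinks = trajectory$crosslinks[s, , , drop = TRUE],
       vertices = trajectory$vertices[s, , , drop = FALSE][1, , ],
       centres = trajectory$centres[s, , , drop = FALSE][1, , ],
       N_b = trajectory$N_b[s, ],
       fa_force = trajectory$fa_force[s, ],
       fa_attached = trajectory$fa_attached[s, ])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames over [%.3g, %.3g] s, %d adhesions, %d detachment events\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    ncol(x$N_b), nrow(x$events)))
  invisible(x)
}

#' Initialize a scenario into a relaxed attached state
#'
#' Builds the ECM network (generated by seeded Voronoi tessellation or
#' taken from `config$network`), constructs the cells, forms one focal
#' adhesion per designated cell vertex to the nearest unpinned crosslink
#' within the capture radius (an error names any vertex with no candidate),
#' snaps each adhesion-bearing vertex to integrin rest separation from its
#' crosslink and resets the cell's rest geometry to the snapped
#' configuration, sets every `N_b` to the zero-force binding equilibrium
#' `K_on N / (K_on + K_off(0))`, and finally relaxes the fully coupled
#' passive system (`F_co = 0`, no pulling) below the force tolerance.
#' Deterministic for a fixed config seed.
#'
#' @param config a scenario configuration, see [build_named_scenario()].
#' @return a `simulation_state` at `t = 0`.
#' @export
initialize_scenario <- function(config) {
  if (!is.null(config$make_network))
    config$network <- config$make_network(config)
  net <- config$network %||% generate_voronoi_network(
    config$domain$width, config$domain$height,
    config$ecm$n_seeds, config$seed,
    E_t = config$ecm$E_t,
    compression_factor = config$ecm$compression_factor,
    area = config$ecm$area, eta = config$ecm$eta)
  params <- do.call(catch_bond_params, config$fa[names(config$fa) %in%
    names(formals(catch_bond_params))])
  config$fa_params <- params
  cells <- lapply(config$cells, function(cs) {
    cl <- make_cell(cs$shape, cs$centre, cs$size,
                    orientation = cs$orientation %||% 0,
                    n_vertices = cs$n_vertices %||% 8L,
                    k_seg = cs$k_seg %||% 1e4,
                    gamma_seg = cs$gamma_seg %||% 1000,
                    k_ang = cs$k_ang %||% 5e4,
                    F_co = cs$F_co %||% 0,
                    eta = cs$eta %||% 1000)
    if (!is.null(cs$pull)) {
      pf <- matrix(0, nrow(cl$vertices), 2)
      pf[cs$pull$vertex, ] <- cs$pull$force
      cl$ext_force <- pf
    }
    cl
  })
  mean_len <- mean(net$rest_lengths)
  capture <- (config$fa$capture_factor %||% 2.5) * mean_len
  fas <- list()
  used_nodes <- integer(0)
  for (i in seq_along(cells)) {
    cs <- config$cells[[i]]
    fa_vs <- cs$fa_vertices %||% seq_len(nrow(cells[[i]]$vertices))
    for (v in fa_vs) {
      pair <- NULL
      if (!is.null(config$fa_pairs)) {
        hit <- config$fa_pairs$cell == i & config$fa_pairs$vertex == v
        if (any(hit)) pair <- config$fa_pairs$crosslink[hit][1]
      }
      if (is.null(pair)) {
        vpos <- cells[[i]]$vertices[v, ]
        d <- row_norms(sweep(net$positions, 2, vpos))
        # the vertex will be snapped onto the chosen crosslink, so the
        # candidate must also keep the rebuilt segment length in a sane
        # band around the nominal one (a too-short segment would let the
        # constant contraction force drive the vertex through the centre)
        dseg <- row_norms(sweep(net$positions, 2, cells[[i]]$centre))
        L_nom <- cells[[i]]$segment_rest_lengths[v]
        cand <- which(!net$pinned & d <= capture &
                        dseg >= 0.6 * L_nom & dseg <= 1.9 * L_nom &
                        !(seq_along(d) %in% used_nodes))
        if (!length(cand))
          stopf("cell %d vertex %d has no suitable unpinned crosslink within the capture radius (%.3g um)",
                i, v, capture)
        pair <- cand[which.min(d[cand])]
      }
      used_nodes <- c(used_nodes, pair)
      # snap the vertex to integrin rest separation from the crosslink
      xl <- net$positions[pair, ]
      dir <- cells[[i]]$vertices[v, ] - xl
      if (vec_norm(dir) < 1e-12) dir <- cells[[i]]$centre - xl
      if (vec_norm(dir) < 1e-12) dir <- c(1, 0)
      dir <- dir / vec_norm(dir)
      cells[[i]]$vertices[v, ] <- xl + params$L0_i * dir
      fas[[length(fas) + 1L]] <- focal_adhesion(
        i, v, pair, N = cs$N_per_fa %||% 1000, params = params)
    }
    # rest geometry of the snapped configuration (equilibrium at creation)
    cells[[i]]$segment_rest_lengths <-
      row_norms(sweep(cells[[i]]$vertices, 2, cells[[i]]$centre))
    cells[[i]]$natural_angles <- cell_angles(cells[[i]])
  }
  state <- new_simulation_state(0, net, cells, fas, config)
  icfg <- config$integration
  res <- call_core(state, icfg$relax_t_max %||% 100, sample_dt = 0,
                   active = FALSE, relax_mode = TRUE,
                   tol = icfg$relax_tol %||% 1e-3,
                   max_steps = icfg$max_steps %||% 2e7)
  if (!res$converged)
    stopf("coupled passive relaxation did not converge (residual %.3g pN)",
          res$max_force)
  state <- unpack_core(state, res)
  state$time <- 0
  # a load-free start: reference lengths are the relaxed lengths
  state$network$reference_lengths_t0 <- fibre_lengths(state$network)
  state$velocities$vertices <- lapply(state$velocities$vertices,
                                      function(m) m * 0)
  state$velocities$centres <- state$velocities$centres * 0
  state
}
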