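#' Specification of a seeded parameter sweep
#'
#' @param scenario base scenario name (see [build_named_scenario()]).
#' @param parameter swept parameter: `"F_co"`, `"E_t"` or `"N"`.
#' @param values numeric vector of parameter values (non-empty).
#' @param realizations independent random-network realizations per value
#'   (>= 1); each gets its own seed derived from `base_seed`.
#' @param base_seed integer; realization seeds are
#'   `base_seed * 1000 + value_index * 100 + realization`.
#' @param t_end contraction time simulated per run, s.
#' @param overrides extra configuration overrides applied to every run.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(scenario, parameter, values, realizations = 5L,
                       base_seed = 1L, t_end = 5, overrides = list()) {
  if (!length(values)) stopf("values must be non-empty")
  if (realizations < 1L) stopf("realizations must be >= 1")
  structure(list(scenario = scenario, parameter = parameter,
                 values = as.numeric(values),
                 realizations = as.integer(realizations),
                 base_seed = as.integer(base_seed), t_end = t_end,
                 overrides = overrides),
            class = "sweep_spec")
}

# Common random numbers: realization r uses the same network seed at every
# swept value, so value-to-value differences reflect the parameter, not
# network-topology noise.
sweep_seed <- function(spec, vi, r) {
  spec$base_seed * 1000L + r
}

# Build, initialize and run one two-cell realization; return the per-run
# metric row used by both sweeps.
run_two_cell_case <- function(spec, vi, r) {
  value <- spec$values[vi]
  ov <- spec$overrides
  ov$seed <- sweep_seed(spec, vi, r)
  if (spec$parameter == "F_co") {
    ov$cells <- list(list(F_co = value), list(F_co = value))
  } else if (spec$parameter == "E_t") {
    ov$ecm <- modify_list_deep(ov$ecm %||% list(), list(E_t = value))
  } else if (spec$parameter == "N") {
    ov$cells <- list(list(N_per_fa = value), list(N_per_fa = value))
  } else {
    stopf("unknown swept parameter '%s'", spec$parameter)
  }
  cfg <- build_named_scenario(spec$scenario, ov)
  state <- initialize_scenario(cfg)
  # adhesion crosslinks of the facing (inner) vertices: cell 1 vertex 2,
  # cell 2 vertex 1
  fa_tab <- data.frame(
    cell = vapply(state$fas, function(f) f$cell_index, numeric(1)),
    vertex = vapply(state$fas, function(f) f$vertex_index, numeric(1)),
    crosslink = vapply(state$fas, function(f) f$crosslink_index, numeric(1)))
  src <- fa_tab$crosslink[fa_tab$cell == 1 & fa_tab$vertex == 2]
  dst <- fa_tab$crosslink[fa_tab$cell == 2 & fa_tab$vertex == 1]
  regions <- cfg$regions
  before <- list(
    high = region_alignment_stats(state$network, region_polygon = regions$high),
    low = region_alignment_stats(state$network, region_polygon = regions$low))
  path0 <- max_stress_path_after_perturbation(state, src, dst)
  traj <- run_simulation(state, spec$t_end)
  fin <- traj$final_state
  after <- list(
    high = region_alignment_stats(fin$network, region_polygon = regions$high),
    low = region_alignment_stats(fin$network, region_polygon = regions$low))
  path1 <- max_stress_path(fin$network,
                           source_crosslink = src, target_crosslink = dst)
  forces <- interaction_force_summary(traj)
  row <- data.frame(
    value = value, realization = r, seed = ov$seed,
    mean_sigma_high_t0 = before$high$mean_sigma,
    mean_sigma_low_t0 = before$low$mean_sigma,
    skew_sigma_high_t0 = before$high$skewness_sigma,
    skew_sigma_low_t0 = before$low$skewness_sigma,
    mean_sigma_high = after$high$mean_sigma,
    mean_sigma_low = after$low$mean_sigma,
    skew_sigma_high = after$high$skewness_sigma,
    skew_sigma_low = after$low$skewness_sigma,
    path_exists = path1$exists,
    mean_path_stress = path1$mean_stress,
    total_path_stress = path1$total_stress,
    tortuosity_t0 = path0$tortuosity,
    tortuosity = path1$tortuosity,
    peak_force = forces$peak_mean_force,
    peak_time = forces$peak_time,
    detachments = nrow(fin$events))
  attr(row, "samples") <- list(
    sigma_high_t0 = before$high$sigma, sigma_high = after$high$sigma,
    sigma_low_t0 = before$low$sigma, sigma_low = after$low$sigma,
    theta_high = after$high$theta)
  row
}

# tortuosity of the would-be path in the load-free start (all fibres are at
# their t = 0 lengths, so no stretched set exists; report the geometric
# tortuosity of the unweighted shortest path instead)
max_stress_path_after_perturbation <- function(state, src, dst) {
  net <- state$network
  g <- igraph::graph_from_edgelist(net$fibres, directed = FALSE)
  lens <- fibre_lengths(net)
  sp <- suppressWarnings(igraph::shortest_paths(g, from = src, to = dst,
                                                weights = lens,
                                                output = "epath"))
  eids <- as.integer(sp$epath[[1]])
  if (!length(eids)) return(list(exists = FALSE, tortuosity = 0))
  plen <- sum(lens[eids])
  list(exists = TRUE,
       tortuosity = vec_norm(net$positions[dst, ] - net$positions[src, ]) / plen)
}

#' Contraction-force sweep over two facing elongated cells
#'
#' For each contraction force and random-network realization: regional
#' anisotropy statistics before/after 5 s of contraction, percolation-path
#' stress and tortuosity, and the peak of the mean adhesion force with its
#' time.  A linear regression of the realization-averaged peak force on
#' the contraction force quantifies the linearity of force transmission.
#'
#' @param spec a [sweep_spec()] with `scenario = "two_elongated"` and
#'   `parameter = "F_co"`.
#' @return list of class `sweep_result`: `results` (one row per value x
#'   realization), `summary` (realization-averaged per value), `fit`
#'   (lm coefficients and R^2), `samples` (per-run anisotropy samples).
#' @export
run_contraction_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (spec$scenario != "two_elongated")
    stopf("contraction sweep is defined for the two_elongated scenario")
  out <- run_sweep_grid(spec)
  pk <- out$summary
  fit <- lm(peak_force ~ value, data = pk)
  out$fit <- list(coefficients = coef(fit),
                  r_squared = summary(fit)$r.squared)
  out
}

#' Stiffness sweep over two facing elongated cells
#'
#' Same per-run metrics as [run_contraction_sweep()], swept over the fibre
#' Young's modulus; realizations with no stretched-fibre percolation path
#' are flagged (`path_exists`) and detachment events are counted.
#'
#' @param spec a [sweep_spec()] with `scenario = "two_elongated"` and
#'   `parameter = "E_t"`.
#' @return a `sweep_result` list (no regression fit).
#' @export
run_stiffness_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (spec$scenario != "two_elongated")
    stopf("stiffness sweep is defined for the two_elongated scenario")
  run_sweep_grid(spec)
}

run_sweep_grid <- function(spec) {
  rows <- list()
  samples <- list()
  for (vi in seq_along(spec$values)) {
    for (r in seq_len(spec$realizations)) {
      row <- run_two_cell_case(spec, vi, r)
      samples[[sprintf("v%d_r%d", vi, r)]] <- attr(row, "samples")
      attr(row, "samples") <- NULL
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$value), function(d)
    data.frame(value = d$value[1],
               peak_force = mean(d$peak_force),
               peak_time = mean(d$peak_time),
               mean_sigma_high = mean(d$mean_sigma_high),
               skew_sigma_high = mean(d$skew_sigma_high),
               mean_path_stress = mean(d$mean_path_stress),
               tortuosity = mean(d$tortuosity),
               frac_with_path = mean(d$path_exists),
               detachments = sum(d$detachments))))
  summary <- summary[order(summary$value), ]
  rownames(summary) <- NULL
  structure(list(spec = spec, results = results, summary = summary,
                 samples = samples),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s sweep over %s: %d values x %d realizations\n",
              x$spec$scenario, x$spec$parameter, length(x$spec$values),
              x$spec$realizations))
  print(x$summary)
  if (!is.null(x$fit))
    cat(sprintf("peak force ~ %s: R^2 = %.4f\n", x$spec$parameter,
                x$fit$r_squared))
  invisible(x)
}

#' Simplified-topology pulling experiments
#'
#' Runs the zigzag and/or ladder scenarios at each requested fibre
#' Young's modulus and classifies the outcome: `"attached"` when both
#' adhesions retain bound integrins at the end of the run, `"detached"`
#' otherwise.  Also records whether detachment happened while the
#' instantaneous adhesion force was below the bifurcation force `F_BP`
#' (the dynamic-overshoot mechanism), and returns the `N_b/N` and stretch
#' time series of each run.
#'
#' @param topologies character vector, subset of `c("zigzag", "ladder")`.
#' @param E_t_values fibre Young's moduli to test, Pa.
#' @param t_end simulated time per run, s.
#' @param overrides configuration overrides applied to every run.
#' @return list of class `topology_result`: `outcomes` (data frame),
#'   `traces` (named list of per-run time series).
#' @export
run_topology_experiment <- function(topologies = c("zigzag", "ladder"),
                                    E_t_values = c(1e8, 1e6), t_end = 5,
                                    overrides = list()) {
  stopifnot(all(topologies %in% c("zigzag", "ladder")))
  rows <- list()
  traces <- list()
  for (topo in topologies) {
    for (Et in E_t_values) {
      ov <- modify_list_deep(overrides, list(ecm = list(E_t = Et)))
      cfg <- build_named_scenario(topo, ov)
      state <- initialize_scenario(cfg)
      bp <- bifurcation_point(state$config$fa_params, state$fas[[1]]$N)
      traj <- run_simulation(state, t_end)
      att <- vapply(traj$final_state$fas, function(f) f$attached, logical(1))
      detached <- !all(att)
      max_force <- max(traj$fa_force)
      # largest instantaneous per-adhesion force seen before any detachment
      below <- max_force < bp$F_BP
      key <- sprintf("%s_Et%.0e", topo, Et)
      traces[[key]] <- data.frame(
        time = traj$times,
        Nb_frac = rowMeans(traj$N_b) / mean(vapply(state$fas, function(f)
          as.numeric(f$N), numeric(1))),
        eps = rowMeans(traj$fa_eps, na.rm = TRUE),
        mean_force = interaction_force_summary(traj)$table$mean)
      rows[[length(rows) + 1L]] <- data.frame(
        topology = topo, E_t = Et,
        outcome = if (detached) "detached" else "attached",
        detach_time = if (detached) min(traj$events$time) else NA_real_,
        max_fa_force = max_force, F_BP = bp$F_BP,
        detached_below_F_BP = detached && below)
    }
  }
  structure(list(outcomes = do.call(rbind, rows), traces = traces),
            class = "topology_result")
}

#' @export
print.topology_result <- function(x, ...) {
  cat("<topology_result>\n")
  print(x$outcomes)
  invisible(x)
}
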