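#' Build the configuration of a named scenario
#'
#' Returns a complete scenario configuration with documented defaults:
#'
#' * `"single_round"`: one round 8-vertex cell (radius 10 um) on a random
#'   Voronoi ECM, `E_t = 1e7` Pa, `N = 857` integrins per adhesion,
#'   `F_co = 2e4` pN.
#' * `"two_elongated"`: two elongated cells (length 20 um) facing each
#'   other 80 um apart (centre to centre) on a random ECM,
#'   `E_t = 1e8` Pa, `N = 3000`, `F_co = 5e4` pN; includes the
#'   high/low-interaction analysis regions.
#' * `"zigzag"`: two cells joined by a single zigzag fibre path whose
#'   interior crosslinks are tethered by lateral fibres with pinned outer
#'   endpoints; constant outward pulling force `F_pu = 3.5e4` pN replaces
#'   contraction; `E_t = 1e8` Pa, `N = 1000`.
#' * `"ladder"`: two cells joined by two parallel fibre rails connected by
#'   transversal rungs, same pulling protocol; `E_t = 1e8` Pa by default
#'   (detaching regime), override `ecm$E_t = 1e6` for the soft attached
#'   regime.
#' * `"multi_fan"`: two (optionally three) contracting fan-shaped cells,
#'   `E_t = 1e6` Pa, `N = 1000`, `F_co = 6.6e3` pN.
#'
#' Mechanical constants with no printed source values (fibre cross-section,
#' compression factor, dampings, cell stiffnesses, catch-bond rates) are
#' reconstructed defaults; they are listed under `$notes` and can all be
#' overridden.
#'
#' @param name scenario name (see above).
#' @param overrides named nested list merged over the defaults, e.g.
#'   `list(ecm = list(E_t = 1e6), seed = 7)`.
#' @return a configuration list accepted by [initialize_scenario()].
#' @export
build_named_scenario <- function(name, overrides = list()) {
  base <- list(
    name = name,
    seed = 1L,
    domain = list(width = 200, height = 200),
    ecm = list(n_seeds = 300L, E_t = 1e7, compression_factor = 0.1,
               area = 0.002, eta = 1000),
    fa = list(K_on = 2, k_c = 5, F_c = 10, k_s = 0.03, F_s = 10,
              k_i = 1000, L0_i = 0.02, capture_factor = 2.5,
              detach_threshold = 1),
    integration = list(safety = 0.2, sample_dt = 0.01, t_end = 5,
                       activation_ramp = 0.3,
                       relax_tol = 1e-3, relax_t_max = 100,
                       max_steps = 2e7),
    notes = paste("compression_factor, area, eta, cell stiffnesses and",
                  "catch-bond rates are reconstructed defaults")
  )
  cfg <- switch(
    name,
    single_round = modify_list_deep(base, list(
      domain = list(width = 140, height = 140),
      ecm = list(n_seeds = 350L, E_t = 1e7),
      cells = list(list(shape = "round", centre = c(70, 70), size = 10,
                        n_vertices = 8L, F_co = 2e4, N_per_fa = 857)))),
    two_elongated = modify_list_deep(base, list(
      domain = list(width = 140, height = 140),
      ecm = list(E_t = 1e8, n_seeds = 350L),
      cells = list(
        list(shape = "elongated", centre = c(30, 70), size = 20,
             orientation = 0, F_co = 5e4, N_per_fa = 3000),
        list(shape = "elongated", centre = c(110, 70), size = 20,
             orientation = 0, F_co = 5e4, N_per_fa = 3000)),
      regions = two_cell_regions(c(30, 70), c(110, 70), inner_gap = 60,
                                 offset = 45))),
    zigzag = topology_scenario(base, topology = "zigzag"),
    ladder = topology_scenario(base, topology = "ladder"),
    multi_fan = {
      cells <- list(
        list(shape = "fan", centre = c(60, 100), size = 10,
             orientation = 0, n_vertices = 5L, F_co = 6.6e3,
             N_per_fa = 1000),
        list(shape = "fan", centre = c(140, 100), size = 10,
             orientation = pi, n_vertices = 5L, F_co = 6.6e3,
             N_per_fa = 1000))
      if (!is.null(overrides$n_cells) && overrides$n_cells >= 3) {
        cells[[3]] <- list(shape = "fan", centre = c(100, 160), size = 10,
                           orientation = -pi / 2, n_vertices = 5L,
                           F_co = 6.6e3, N_per_fa = 1000)
      }
      modify_list_deep(base, list(ecm = list(E_t = 1e6), cells = cells))
    },
    stopf("unknown scenario name '%s'", name)
  )
  overrides$n_cells <- NULL
  modify_list_deep(cfg, overrides)
}

# Shared setup of the simplified-topology pulling scenarios (two cells
# attached at one adhesion site each, pulled apart with constant force).
topology_scenario <- function(base, topology, F_pu = 3.5e4,
                              cell_len = 20, span = 20,
                              n_seg = if (topology == "zigzag") 6L else 4L) {
  netf <- if (topology == "zigzag") make_zigzag_network else make_ladder_network
  jun <- span / 2 + if (topology == "ladder") 4 else 0
  # the pull is applied at the adhesion-bearing vertex so that the load
  # reaches the integrin assembly directly rather than being low-pass
  # filtered by the cell's own viscoelastic segments
  cells <- list(
    list(shape = "elongated", centre = c(-jun - cell_len / 2, 0),
         size = cell_len, orientation = 0, F_co = 0, N_per_fa = 2000,
         fa_vertices = 2L, pull = list(vertex = 2L, force = c(-F_pu, 0))),
    list(shape = "elongated", centre = c(jun + cell_len / 2, 0),
         size = cell_len, orientation = 0, F_co = 0, N_per_fa = 2000,
         fa_vertices = 1L, pull = list(vertex = 1L, force = c(F_pu, 0))))
  # coarse fibre calibre: the topology experiments contrast architectures
  # at a fixed, deliberately stiff per-fibre force scale
  cfg <- modify_list_deep(base, list(
    ecm = list(E_t = 1e8, area = 0.01),
    cells = cells,
    topology = list(name = topology, F_pu = F_pu, span = span,
                    n_seg = n_seg),
    integration = list(t_end = 5)))
  cfg$make_network <- function(cfg) {
    netf(span = cfg$topology$span, n_seg = cfg$topology$n_seg,
         E_t = cfg$ecm$E_t,
         compression_factor = cfg$ecm$compression_factor,
         area = cfg$ecm$area, eta = cfg$ecm$eta)
  }
  cfg$network <- cfg$make_network(cfg)
  # attach each cell's inner vertex to the nearest path endpoint (junction)
  pj <- cfg$network$positions
  jL <- which(abs(pj[, 1] - min(pj[abs(pj[, 2]) < 1e-9, 1])) < 1e-9 &
                abs(pj[, 2]) < 1e-9)[1]
  jR <- which(abs(pj[, 1] - max(pj[abs(pj[, 2]) < 1e-9, 1])) < 1e-9 &
                abs(pj[, 2]) < 1e-9)[1]
  cfg$fa_pairs <- data.frame(cell = c(1L, 2L), vertex = c(2L, 1L),
                             crosslink = c(jL, jR))
  cfg
}

#' Simplified ECM topologies connecting two cells
#'
#' `make_zigzag_network()` builds a single zigzag path of fibres between
#' two junction crosslinks on the pulling axis; each interior crosslink is
#' tethered by a lateral fibre whose outer endpoint is pinned.  Pulling
#' straightens the zigzag: crosslinks travel transversally while the
#' (buckling-weak) compressed laterals yield, so the path has a low
#' effective stiffness even for stiff fibres.
#'
#' `make_ladder_network()` builds two parallel fibre rails joined by
#' transversal rungs, with a junction crosslink at each end connecting
#' both rails.  The rails lie along the pulling axis, so the structure is
#' effectively as stiff as its fibres.
#'
#' Geometries are parameters (pitch, amplitude, gap, rung count), not
#' fixed constants.
#'
#' @param span axial distance between the two junction crosslinks, um.
#' @param n_seg number of path segments (zigzag) or rail segments (ladder).
#' @param amplitude zigzag transversal amplitude, um.
#' @param lateral lateral tether length (zigzag), um.
#' @param gap rail separation (ladder), um.
#' @param stub junction-to-rail spacing (ladder), um.
#' @param ... mechanical parameters passed to [fibre_network()].
#' @return a [fibre_network()].
#' @name simple_topologies
NULL

#' @rdname simple_topologies
#' @export
make_zigzag_network <- function(span = 40, n_seg = 8, amplitude = 3,
                                lateral = 8, ...) {
  xs <- seq(-span / 2, span / 2, length.out = n_seg + 1)
  ys <- c(0, amplitude * (-1)^(seq_len(n_seg - 1)), 0)
  path <- cbind(xs, ys)
  np <- nrow(path)
  inner <- 2:(np - 1)
  outer <- cbind(path[inner, 1],
                 path[inner, 2] + sign(path[inner, 2]) * lateral)
  positions <- rbind(path, outer)
  fib <- rbind(cbind(1:(np - 1), 2:np),
               cbind(inner, np + seq_along(inner)))
  pinned <- c(rep(FALSE, np), rep(TRUE, nrow(outer)))
  fibre_network(positions, fib, pinned = pinned, ...)
}

#' @rdname simple_topologies
#' @export
make_ladder_network <- function(span = 40, n_seg = 8, gap = 4, stub = 4,
                                ...) {
  xs <- seq(-span / 2, span / 2, length.out = n_seg + 1)
  top <- cbind(xs, gap / 2)
  bot <- cbind(xs, -gap / 2)
  junL <- c(-span / 2 - stub, 0)
  junR <- c(span / 2 + stub, 0)
  positions <- rbind(junL, junR, top, bot)
  it <- 2 + seq_len(n_seg + 1)           # top rail indices
  ib <- 2 + n_seg + 1 + seq_len(n_seg + 1)  # bottom rail indices
  fib <- rbind(
    cbind(it[-length(it)], it[-1]),      # top rail
    cbind(ib[-length(ib)], ib[-1]),      # bottom rail
    cbind(it, ib),                       # rungs
    c(1, it[1]), c(1, ib[1]),            # left junction
    c(2, it[length(it)]), c(2, ib[length(ib)]))
  fibre_network(positions, fib, pinned = rep(FALSE, nrow(positions)), ...)
}

#' Analysis regions for a facing two-cell scenario
#'
#' The high-interaction region is a rhombus whose long diagonal is the
#' segment between the two cells' facing adhesion sites, with half-width a
#' quarter of that gap; the low-interaction region is the same rhombus
#' translated transversally away from the inter-cell axis.
#'
#' @param c1,c2 cell centres (2-vectors, um).
#' @param inner_gap distance between the facing vertices, um.
#' @param offset transversal displacement of the low-interaction region,
#'   um.
#' @return list of two 4 x 2 polygon matrices, `high` and `low`.
#' @export
two_cell_regions <- function(c1, c2, inner_gap, offset = 55) {
  axis <- (c2 - c1) / vec_norm(c2 - c1)
  nrm <- perp(axis)
  mid <- (c1 + c2) / 2
  p1 <- mid - axis * inner_gap / 2
  p2 <- mid + axis * inner_gap / 2
  w <- inner_gap / 4
  high <- rbind(p1, mid + nrm * w, p2, mid - nrm * w)
  low <- sweep(high, 2, nrm * offset, "+")
  list(high = high, low = low)
}

#' Read / write scenario configurations as YAML
#'
#' Functions (`make_network`) and matrices are not serialised; custom
#' networks should be written separately with [write_network_json()] and
#' referenced via `network_file`.
#'
#' @param config a scenario configuration list.
#' @param file path to a YAML file.
#' @return the configuration list.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_scenario_yaml <- function(config, file) {
  cfg <- config
  cfg$network <- NULL
  cfg$make_network <- NULL
  cfg$fa_params <- NULL
  if (!is.null(cfg$regions)) {
    cfg$regions <- lapply(cfg$regions, function(m)
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
  }
  yaml::write_yaml(cfg, file)
  invisible(config)
}

#' @rdname config_io
#' @export
read_scenario_yaml <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$regions)) {
    cfg$regions <- lapply(cfg$regions, function(p)
      do.call(rbind, lapply(p, as.numeric)))
  }
  for (i in seq_along(cfg$cells)) {
    cfg$cells[[i]]$centre <- as.numeric(cfg$cells[[i]]$centre)
    if (!is.null(cfg$cells[[i]]$pull))
      cfg$cells[[i]]$pull$force <- as.numeric(cfg$cells[[i]]$pull$force)
  }
  if (!is.null(cfg$network_file)) {
    cfg$network <- read_network_json(cfg$network_file)
  } else if (!is.null(cfg$name) &&
             cfg$name %in% c("zigzag", "ladder")) {
    cfg <- modify_list_deep(build_named_scenario(cfg$name), cfg)
  }
  if (!is.null(cfg$fa_pairs)) cfg$fa_pairs <- as.data.frame(cfg$fa_pairs)
  cfg
}
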