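#' Read and write fibre networks
#'
#' Two plain-text formats are supported: a CSV pair (`nodes.csv` with
#' columns `id,x,y,pinned` and `edges.csv` with columns
#' `id,node_a,node_b,rest_length`) and a single JSON document mirroring the
#' [fibre_network()] fields.  Loaders re-validate all network invariants.
#'
#' @param network a [fibre_network()].
#' @param nodes_file,edges_file CSV file paths.
#' @param file JSON file path.
#' @param ... mechanical parameters forwarded to [fibre_network()] when
#'   reading CSV (the CSV pair carries geometry only).
#' @return the network (readers) or the input, invisibly (writers).
#' @name network_io
NULL

#' @rdname network_io
#' @export
write_network_csv <- function(network, nodes_file, edges_file) {
  nodes <- data.frame(id = seq_len(nrow(network$positions)),
                      x = network$positions[, 1],
                      y = network$positions[, 2],
                      pinned = network$pinned)
  edges <- data.frame(id = seq_len(nrow(network$fibres)),
                      node_a = network$fibres[, 1],
                      node_b = network$fibres[, 2],
                      rest_length = network$rest_lengths)
  write.csv(nodes, nodes_file, row.names = FALSE)
  write.csv(edges, edges_file, row.names = FALSE)
  invisible(network)
}

#' @rdname network_io
#' @export
read_network_csv <- function(nodes_file, edges_file, ...) {
  nodes <- read.csv(nodes_file)
  edges <- read.csv(edges_file)
  need_n <- c("id", "x", "y", "pinned")
  need_e <- c("id", "node_a", "node_b", "rest_length")
  if (!all(need_n %in% names(nodes)))
    stopf("nodes.csv must have columns %s", paste(need_n, collapse = ","))
  if (!all(need_e %in% names(edges)))
    stopf("edges.csv must have columns %s", paste(need_e, collapse = ","))
  nodes <- nodes[order(nodes$id), ]
  fibre_network(cbind(nodes$x, nodes$y),
                cbind(edges$node_a, edges$node_b),
                rest_lengths = edges$rest_length,
                pinned = as.logical(nodes$pinned), ...)
}

#' @rdname network_io
#' @export
write_network_json <- function(network, file) {
  obj <- list(
    positions = unclass(network$positions),
    fibres = unclass(network$fibres),
    rest_lengths = network$rest_lengths,
    pinned = network$pinned,
    E_t = network$E_t,
    compression_factor = network$compression_factor,
    area = network$area,
    eta = network$eta,
    reference_lengths_t0 = network$reference_lengths_t0
  )
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(network)
}

#' @rdname network_io
#' @export
read_network_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  fibre_network(obj$positions, obj$fibres,
                rest_lengths = obj$rest_lengths,
                pinned = obj$pinned,
                E_t = obj$E_t,
                compression_factor = obj$compression_factor,
                area = obj$area, eta = obj$eta,
                reference_lengths_t0 = obj$reference_lengths_t0)
}
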