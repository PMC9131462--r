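## Plain-text interchange. TPMs travel as headerless CSV (row i = outgoing
## distribution of state i; node 0 = least-significant bit of the state
## index). Networks and results travel as JSON.

#' Read a transition matrix from CSV
#'
#' Expects a square numeric matrix with no header row. Rows whose sums
#' deviate from 1 by at most 1e-6 are renormalised with a warning; larger
#' deviations are rejected with the offending row index.
#'
#' @param path file path.
#' @param node_count optional number of binary nodes (inferred when the
#'   state count is a power of 2 and `node_count` is `NA`).
#' @return A [tpm()].
#' @export
read_tpm_csv <- function(path, node_count = NA) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "double"
  if (is.na(node_count)) node_count <- node_count_of(nrow(m))
  tpm(m, node_count = node_count)
}

#' Write a transition matrix to CSV
#'
#' @param x a [tpm()].
#' @param path file path.
#' @export
write_tpm_csv <- function(x, path) {
  stopifnot(inherits(x, "tpm"))
  utils::write.table(x$probs, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a Boolean network from JSON
#'
#' Format: `{"n_nodes": n, "nodes": [{"id": i, "parents": [...], "table":
#' [...]}, ...]}` with tables indexed by the parents' joint state (first
#' parent = least-significant bit).
#'
#' @param path file path.
#' @return A [boolean_network()].
#' @export
read_network_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  spec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  nodes <- spec$nodes
  ids <- vapply(nodes, function(nd) as.integer(nd$id), integer(1))
  ord <- order(ids)
  boolean_network(
    parents = lapply(nodes[ord], function(nd) as.integer(unlist(nd$parents))),
    tables  = lapply(nodes[ord], function(nd) as.numeric(unlist(nd$table))),
    labels  = vapply(nodes[ord], function(nd) nd$label %||% paste0("n", nd$id),
                     character(1)))
}

#' Write a Boolean network to JSON
#'
#' @param net a [boolean_network()].
#' @param path file path.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  nodes <- lapply(seq_len(net$n_nodes), function(i)
    list(id = i - 1L, label = net$labels[i],
         parents = net$parents[[i]], table = net$tables[[i]]))
  jsonlite::write_json(list(n_nodes = net$n_nodes, nodes = nodes), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise an analysis result to JSON
#'
#' Dispatches on the result class. PID results are written with canonical
#' antichain strings as keys; spectra list layer masses bottom-first;
#' ensembles carry the per-system table and the summary; EI decompositions
#' their three terms. Round-trips losslessly through [read_results_json()].
#'
#' @param result a `pid_result`, `pi_spectrum`, `scale_ensemble` or
#'   `ei_decomposition`.
#' @param path file path.
#' @export
write_results_json <- function(result, path) {
  payload <- as_results_list(result)
  nums <- rapply(payload, function(v) v, classes = c("numeric", "integer"),
                 how = "unlist")
  if (length(nums) && !all(is.finite(nums)))
    stop("refusing to serialise non-finite values")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a result written by [write_results_json()]
#'
#' @param path file path.
#' @return The parsed list (with a `type` field naming the original class).
#' @export
read_results_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

as_results_list <- function(result) UseMethod("as_results_list")

#' @export
as_results_list.pid_result <- function(result) {
  list(type = "pid_result",
       total_mi_bits = result$total_mi,
       n_sources = result$n_sources,
       atoms = as.list(result$atoms),
       heights = as.list(result$heights))
}

#' @export
as_results_list.pi_spectrum <- function(result) {
  list(type = "pi_spectrum",
       total_mi_bits = result$total_mi,
       n_sources = result$n_sources,
       spectrum = result$layer_mass,        # bottom layer first
       synergy_bias = result$synergy_bias,
       redundancy_bias = result$redundancy_bias)
}

#' @export
as_results_list.scale_ensemble <- function(result) {
  list(type = "scale_ensemble",
       summary = result$summary,
       systems = result$systems)
}

#' @export
as_results_list.ei_decomposition <- function(result) {
  list(type = "ei_decomposition",
       ei = result$ei,
       determinism = result$determinism,
       degeneracy = result$degeneracy,
       n_states = result$n_states)
}

#' @export
as_results_list.default <- function(result) {
  stop(sprintf("no JSON serialisation for class '%s'", class(result)[1]))
}
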