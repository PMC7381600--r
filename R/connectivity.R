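# Whole-cell connectivity of the myofibrillar matrix: connected components
# under serial + branch edges, the minimal lateral path across the cell, and
# the fraction of the cell width such a path spans.

#' Connected components of the sarcomere graph
#'
#' Partition of nodes under the union of serial and branch-event edges.
#' With no branch events every column is its own component; branches merge
#' components until — at the branching rates of mature muscle — the whole
#' cell is one connected matrix.
#'
#' @param graph A `myo_graph`.
#' @param edge_types Edge classes to use: `"serial"`, `"event"` or both
#'   (default).
#' @return List with `n_components`, `sizes` (node counts, decreasing),
#'   and `membership` (component id per node id).
#' @export
connected_components <- function(graph, edge_types = c("serial", "event")) {
  if (nrow(graph$nodes) == 0L) stop_myo("empty graph")
  ig <- graph_as_igraph(graph, edge_types)
  cm <- igraph::components(ig)
  list(
    n_components = cm$no,
    sizes = sort(as.integer(cm$csize), decreasing = TRUE),
    membership = as.integer(cm$membership)
  )
}

#' Minimal lateral path between two sarcomeres
#'
#' Shortest path by sarcomere count over serial and (by default) branch
#' edges — the "minimal path of connectivity" across the cell. Default
#' endpoints are the two z-interval-0 sarcomeres whose centroids are
#' farthest apart.
#'
#' @param graph A `myo_graph`.
#' @param source,target Node ids; `NULL` picks the default endpoints.
#' @param edge_types Edge classes the path may traverse; `"serial"` alone
#'   restricts the path to end-to-end z-disk connectivity.
#' @return List with `path` (ordered node ids, or `NULL` when source and
#'   target are disconnected), `length` (edge count or `NA`), and the
#'   endpoints used.
#' @export
minimal_lateral_path <- function(graph, source = NULL, target = NULL,
                                 edge_types = c("serial", "event")) {
  if (is.null(source) || is.null(target)) {
    ends <- default_endpoints(graph)
    source <- source %||% ends[1L]
    target <- target %||% ends[2L]
  }
  if (identical(source, target)) stop_myo("source and target must differ")
  ig <- graph_as_igraph(graph, edge_types)
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, from = source, to = target, output = "vpath")
  )
  vp <- as.integer(sp$vpath[[1L]])
  if (length(vp) == 0L) {
    return(list(path = NULL, length = NA_integer_, source = source, target = target))
  }
  list(path = vp, length = length(vp) - 1L, source = source, target = target)
}

default_endpoints <- function(graph) {
  first <- graph$nodes[graph$nodes$interval == 0L, ]
  if (nrow(first) < 2L) stop_myo("need at least two z-interval-0 sarcomeres for default endpoints")
  dm <- as.matrix(stats::dist(cbind(first$x, first$y)))
  idx <- which(dm == max(dm), arr.ind = TRUE)[1L, ]
  c(first$node_id[min(idx)], first$node_id[max(idx)])
}

#' Fraction of the cell width spanned by a path
#'
#' Projects the path's node footprints onto the source-to-target axis and
#' divides the spanned extent by the cell mask's extent along that axis.
#' Footprint extent (centroid plus or minus the equivalent circular radius)
#' is used, so a single column spans about its own diameter.
#'
#' @param path Node-id vector (e.g. `minimal_lateral_path()$path`).
#' @param graph The graph the path lives in.
#' @param bundle Optional `myo_bundle` supplying the cell mask; without it
#'   the ellipse recorded in the graph metadata is used.
#' @return Fraction in `[0, 1]`; 0 for a degenerate single-node path of
#'   zero footprint extent relative to the cell.
#' @export
width_span_fraction <- function(path, graph, bundle = NULL) {
  if (is.null(path) || length(path) == 0L) stop_myo("empty path")
  nd <- graph$nodes[match(path, graph$nodes$node_id), ]
  a <- c(nd$x[1L], nd$y[1L])
  b <- c(nd$x[nrow(nd)], nd$y[nrow(nd)])
  axis <- b - a
  if (sqrt(sum(axis^2)) < 1e-9) axis <- c(1, 0)
  axis <- axis / sqrt(sum(axis^2))
  proj <- nd$x * axis[1L] + nd$y * axis[2L]
  rad <- sqrt(nd$area / pi)
  span <- max(proj + rad) - min(proj - rad)

  if (!is.null(bundle)) {
    idx <- which(bundle$cell_mask, arr.ind = TRUE)
    mproj <- (idx[, 1L] - 0.5) * axis[1L] + (idx[, 2L] - 0.5) * axis[2L]
    cell_ext <- max(mproj) - min(mproj) + 1
  } else {
    cell <- graph$meta$cell
    if (is.null(cell)) stop_myo("no cell geometry available; supply a bundle")
    # extent of the ellipse along a direction
    cell_ext <- 2 * sqrt((cell$a * axis[1L])^2 + (cell$b * axis[2L])^2)
  }
  max(0, min(1, span / cell_ext))
}
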