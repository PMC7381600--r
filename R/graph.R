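# MyoGraph: one node per (column lineage, z-interval), serial edges across
# z-disks, and typed branch events. Built either from a ground-truth
# myo_network (network_graph) or from a labeled volume (build_graph).

new_myo_graph <- function(nodes, serial, events, meta) {
  g <- list(nodes = nodes, serial = serial, events = events, meta = meta)
  class(g) <- "myo_graph"
  g
}

#' Convert a sampled network to its ground-truth sarcomere graph
#'
#' Builds the graph of sarcomere nodes — one node per column (or transient
#' bridge piece) per z-interval it is alive in — with serial edges across
#' z-disks and the recorded branch events. This is the reference structure
#' that extraction from a rendered volume must recover.
#'
#' @param net A `myo_network` from [sample_network()].
#' @return A `myo_graph` with node table (`node_id`, `col`, `interval`,
#'   centroid, area, membrane distance in micrometres), serial edge table and
#'   event table.
#' @export
network_graph <- function(net) {
  stopifnot(inherits(net, "myo_network"))
  cfg <- net$config
  bounds <- c(net$z_disks, net$n_slices)
  M <- length(bounds) - 1L
  cols <- net$columns

  rows <- list()
  for (i in seq_len(nrow(cols))) {
    # transfer/trade wedges are event apparatus, not sarcomere nodes
    if (cols$kind[i] == "wedge") next
    alive <- which(cols$birth_slice[i] < bounds[-1L] & cols$death_slice[i] > bounds[-(M + 1L)])
    if (length(alive) == 0L) next
    if (cols$kind[i] == "seed") {
      cx <- cols$x[i]; cy <- cols$y[i]
      area <- pi * cols$radius[i]^2
    } else {
      off <- 0.7 * cols$radius[i]
      cx <- cols$x[i] + off * cols$dir_x[i]
      cy <- cols$y[i] + off * cols$dir_y[i]
      area <- pi * cols$radius[i]^2 * if (cols$perp_sign[i] == 0) 0.25 else 0.125
    }
    rows[[length(rows) + 1L]] <- data.frame(
      col = cols$col_id[i], interval = alive - 1L,
      x = cx, y = cy, area = area,
      col_birth_slice = cols$birth_slice[i], stringsAsFactors = FALSE
    )
  }
  nodes <- do.call(rbind, rows)
  nodes <- nodes[order(nodes$interval, nodes$col), ]
  nodes$node_id <- seq_len(nrow(nodes))
  nodes$label <- NA_integer_
  rownames(nodes) <- NULL

  nodes$memdist_um <- ellipse_boundary_distance(
    nodes$x, nodes$y, net$cell$cx, net$cell$cy, net$cell$a, net$cell$b
  ) * cfg$voxel_pitch_nm / 1000

  key <- paste(nodes$col, nodes$interval)
  id_of <- setNames(nodes$node_id, key)
  pre <- paste(nodes$col, nodes$interval + 1L)
  has_next <- pre %in% key
  serial <- data.frame(
    from = nodes$node_id[has_next],
    to = unname(id_of[pre[has_next]])
  )

  meta <- list(
    source = "truth", seed = net$seed,
    z_disks = net$z_disks, n_slices = net$n_slices,
    n_intervals = M, interval_len = net$interval_len,
    voxel_pitch_nm = cfg$voxel_pitch_nm,
    cell = net$cell, config = cfg
  )
  new_myo_graph(nodes, serial, net$events, meta)
}

# columns whose tracks count a given event, and the bridge id involved
event_participants <- function(ev) {
  switch(ev$type,
    split = c(ev$col_a, ev$bridge1),
    merge = c(ev$col_a, ev$bridge1),
    transfer = c(ev$col_a, ev$col_b),
    trade = c(ev$col_a, ev$col_b),
    ambiguous = c(ev$col_a, ev$col_b)
  )
}

# igraph over sarcomere nodes; serial edges always, event edges optionally
graph_as_igraph <- function(graph, edge_types = c("serial", "event")) {
  el <- NULL
  if ("serial" %in% edge_types && nrow(graph$serial) > 0L) {
    el <- cbind(graph$serial$from, graph$serial$to)
  }
  if ("event" %in% edge_types && nrow(graph$events) > 0L) {
    key <- paste(graph$nodes$col, graph$nodes$interval)
    id_of <- setNames(graph$nodes$node_id, key)
    for (i in seq_len(nrow(graph$events))) {
      ev <- graph$events[i, ]
      parts <- event_participants(ev)
      parts <- parts[!is.na(parts)]
      ids <- id_of[paste(parts, ev$interval)]
      ids <- ids[!is.na(ids)]
      # a participant may only exist in a neighbouring interval (event at a
      # boundary); fall back to its nearest-interval node
      if (length(ids) < 2L) {
        for (p in parts) {
          cand <- graph$nodes$node_id[graph$nodes$col == p]
          if (length(cand) > 0L && !any(cand %in% ids)) {
            ints <- graph$nodes$interval[graph$nodes$col == p]
            ids <- c(ids, cand[which.min(abs(ints - ev$interval))])
          }
        }
      }
      if (length(ids) >= 2L) {
        el <- rbind(el, cbind(ids[-length(ids)], ids[-1L]))
      }
    }
  }
  ig <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  if (!is.null(el)) ig <- igraph::add_edges(ig, t(el))
  ig
}

#' @export
print.myo_graph <- function(x, ...) {
  cat(sprintf("<myo_graph> %d nodes over %d z-intervals, %d serial edges, %d events (%s)\n",
              nrow(x$nodes), x$meta$n_intervals, nrow(x$serial), nrow(x$events),
              x$meta$source))
  invisible(x)
}
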