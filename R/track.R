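# Myofibril tracking: start-point enumeration at the first z-interval, the
# membrane-distance continuation rule at splits, and field-of-view
# filtering, mirroring the manual tracking routine used on the original
# segmentations.

#' Enumerate track start nodes
#'
#' One start node per sarcomere present in z-interval 0, numbered in
#' deterministic raster order of their centroids (row-major on y, then x),
#' so the numbering is invariant to label permutation.
#'
#' @param graph A `myo_graph`.
#' @return Node-id vector of start nodes, in raster order.
#' @export
seed_tracks <- function(graph) {
  first <- graph$nodes[graph$nodes$interval == 0L & graph$nodes$col_birth_slice == 0L, ]
  if (nrow(first) == 0L) stop_myo("graph has no sarcomeres in the first image")
  first$node_id[raster_order(first$x, first$y)]
}

#' Track one myofibril through the sarcomere graph
#'
#' Walks serial edges interval by interval from a start node. At a split the
#' walk continues with the child whose membrane distance is closest to the
#' track's starting membrane distance (ties broken toward the lower node
#' id); at a merge it continues with the merged lineage. Every incident
#' branch event — split, merge, transfer or trade touching the current
#' lineage — is counted once per track.
#'
#' @param graph A `myo_graph`.
#' @param start Node id of a z-interval-0 node.
#' @return A `myo_track`: list with `nodes` (ordered node ids),
#'   `sarcomeres_traversed`, `event_ids`, `event_types`, `start_memdist_um`,
#'   `in_fov` and `termination`.
#' @export
track_myofibril <- function(graph, start, .ctx = NULL) {
  nd <- graph$nodes
  srow <- nd[nd$node_id == start, ]
  if (nrow(srow) != 1L || srow$interval != 0L) {
    stop_myo("start must be a single node in z-interval 0")
  }
  M <- graph$meta$n_intervals
  ev <- graph$events
  if (is.null(.ctx)) .ctx <- track_context(graph)
  node_of <- .ctx$node_of
  ev_in_k <- .ctx$ev_by_interval

  start_md <- srow$memdist_um
  cur_col <- srow$col
  path <- integer(0)
  got_events <- integer(0)
  got_types <- character(0)
  term <- "end_of_volume"
  in_fov <- TRUE

  count_event <- function(ei) {
    if (!(ev$event_id[ei] %in% got_events)) {
      got_events <<- c(got_events, ev$event_id[ei])
      got_types <<- c(got_types, ev$type[ei])
    }
  }

  for (k in 0:(M - 1L)) {
    nid <- node_of[paste(cur_col, k)]
    if (is.na(nid) && nrow(ev) > 0L) {
      # a followed bridge may merge exactly at a z-disk: jump to its product
      me <- which(ev$type == "merge" &
                    (ev$bridge1 %in% cur_col | ev$bridge2 %in% cur_col))
      if (length(me) > 0L) {
        count_event(me[1L])
        cur_col <- ev$col_a[me[1L]]
        nid <- node_of[paste(cur_col, k)]
      }
    }
    if (is.na(nid)) { term <- "dangling serial end"; in_fov <- FALSE; break }
    path <- c(path, unname(nid))

    cand <- ev_in_k[[as.character(k)]]
    if (length(cand) > 0L) {
      inc <- cand[ev$col_a[cand] %in% cur_col | ev$col_b[cand] %in% cur_col |
                    ev$bridge1[cand] %in% cur_col | ev$bridge2[cand] %in% cur_col]
      for (ei in inc[order(ev$slice[inc])]) {
        count_event(ei)
        if (ev$type[ei] == "split" && identical(cur_col, ev$col_a[ei])) {
          cur_col <- choose_split_child(graph, ev[ei, ], k, start_md)
        } else if (ev$type[ei] == "merge" &&
                     (identical(cur_col, ev$bridge1[ei]) || identical(cur_col, ev$bridge2[ei]))) {
          cur_col <- ev$col_a[ei] # continue with the merged lineage
        }
      }
    }
  }

  structure(list(
    start = start, nodes = path,
    sarcomeres_traversed = length(path),
    event_ids = got_events, event_types = got_types,
    start_memdist_um = start_md,
    in_fov = in_fov && length(path) == M,
    termination = if (length(path) == M) "end_of_volume" else term
  ), class = "myo_track")
}

# membrane-distance continuation rule at a split: children are the parent's
# continuation (same lineage id) and the detached lineage; follow the one
# whose membrane distance at this interval is nearest the track's starting
# distance, ties toward the lower node id
choose_split_child <- function(graph, e, k, start_md) {
  nd <- graph$nodes
  cand_cols <- c(e$col_a, e$bridge1)
  rows <- nd[nd$col %in% cand_cols & nd$interval == k, ]
  if (nrow(rows) < 2L) return(e$col_a)
  d <- abs(rows$memdist_um - start_md)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.min(rows$node_id[best])]
  rows$col[best]
}

#' Track every myofibril from the first z-interval
#'
#' @param graph A `myo_graph`.
#' @return List of `myo_track`, in raster order of the start nodes.
#' @export
track_all <- function(graph) {
  ctx <- track_context(graph)
  lapply(seed_tracks(graph), function(s) track_myofibril(graph, s, .ctx = ctx))
}

track_context <- function(graph) {
  list(
    node_of = setNames(graph$nodes$node_id,
                       paste(graph$nodes$col, graph$nodes$interval)),
    ev_by_interval = split(seq_len(nrow(graph$events)), graph$events$interval)
  )
}

#' Field-of-view filter for tracks
#'
#' Retains only tracks whose serial structure stays within the dataset: the
#' track must reach the final z-interval, and none of its traversed nodes
#' may touch the lateral volume boundary (footprint centroid closer to the
#' boundary than its equivalent radius). Tracks from generated networks are
#' always interior to the cell mask.
#'
#' @param tracks List of `myo_track`.
#' @param graph The graph the tracks were computed on.
#' @param bundle Optional `myo_bundle` supplying the lateral grid extent;
#'   if omitted, only full-length termination is checked.
#' @return List with `retained` (tracks) and `excluded` (data frame of
#'   start node and reason).
#' @export
fov_filter <- function(tracks, graph, bundle = NULL) {
  nd <- graph$nodes
  reasons <- character(0)
  starts <- integer(0)
  keep <- logical(length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (!tr$in_fov) {
      reasons <- c(reasons, tr$termination); starts <- c(starts, tr$start)
      next
    }
    if (!is.null(bundle)) {
      dims <- dim(bundle$label_volume)
      rows <- nd[nd$node_id %in% tr$nodes, ]
      rad <- sqrt(rows$area / pi)
      hit <- rows$x - rad < 1 | rows$x + rad > dims[1L] - 1 |
        rows$y - rad < 1 | rows$y + rad > dims[2L] - 1
      if (any(hit)) {
        reasons <- c(reasons, "touches lateral boundary"); starts <- c(starts, tr$start)
        next
      }
    }
    keep[i] <- TRUE
  }
  list(
    retained = tracks[keep],
    excluded = data.frame(start = starts, reason = reasons,
                          stringsAsFactors = FALSE)
  )
}

#' @export
print.myo_track <- function(x, ...) {
  cat(sprintf("<myo_track> start node %d: %d sarcomeres, %d events (%s)%s\n",
              x$start, x$sarcomeres_traversed, length(x$event_ids),
              if (length(x$event_types)) paste(x$event_types, collapse = ",") else "none",
              if (x$in_fov) "" else paste0(" [not in FOV: ", x$termination, "]")))
  invisible(x)
}
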