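# Per-volume summary statistics over retained tracks and classified events.

track_event_counts <- function(tracks) {
  vapply(tracks, function(tr) length(tr$event_ids), integer(1))
}

#' Branch frequency per 10 serial sarcomeres
#'
#' `10 * (total branch events counted on the tracks) / (total sarcomeres
#' traversed)`. Splits and merges each count as one branch; a transfer or
#' trade touching the tracked sarcomere counts as one branch regardless of
#' donor/acceptor role.
#'
#' @param tracks List of `myo_track` (normally the retained set from
#'   [fov_filter()]).
#' @return Branches per 10 sarcomeres (numeric scalar).
#' @export
branch_frequency <- function(tracks) {
  ns <- sum(vapply(tracks, function(tr) as.numeric(tr$sarcomeres_traversed), numeric(1)))
  if (length(tracks) == 0L || ns == 0L) stop_myo("no sarcomeres traversed")
  10 * sum(track_event_counts(tracks)) / ns
}

#' Percentage of myofibrils with at least one branching sarcomere
#'
#' @param tracks List of `myo_track`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_branched <- function(tracks) {
  if (length(tracks) == 0L) stop_myo("no tracks")
  100 * mean(track_event_counts(tracks) > 0L)
}

#' Percentage of branches due to myofilament transfers
#'
#' `100 * (transfers + trades) / (all branch events)` over a classified
#' event table (volume-level, each physical event once).
#'
#' @param events Event data frame (from the generator truth or
#'   [classify_events()]). Ambiguous events are excluded from both counts.
#' @return Percentage, or `NA_real_` when there are no events (undefined,
#'   reported as missing rather than 0).
#' @export
transfer_share <- function(events) {
  ev <- events[events$type %in% c("split", "merge", "transfer", "trade"), , drop = FALSE]
  if (nrow(ev) == 0L) return(NA_real_)
  100 * sum(ev$type %in% c("transfer", "trade")) / nrow(ev)
}

#' Per-volume summary metrics
#'
#' Populates the full per-volume record: track and sarcomere totals, branch
#' frequencies per 10 sarcomeres overall and by class (splits+merges vs
#' transfers+trades, the two classes a static volume can distinguish),
#' percent branched, volume-level transfer share, and bookkeeping tallies.
#' Branch frequency is computed as events per 10 sarcomeres; with at most
#' one event per sarcomere interval this coincides with
#' sarcomeres-containing-branches per 10.
#'
#' @param tracks Retained tracks for the volume.
#' @param events Volume-level classified event table.
#' @param volume_id Identifier echoed into the output.
#' @param group Group label (e.g. muscle type) for downstream comparison.
#' @param suppressed Optional suppressed-event tally from the generator.
#' @return A one-row data frame of class `myo_metrics`.
#' @export
volume_summary <- function(tracks, events, volume_id = "volume", group = NA_character_,
                           suppressed = NULL) {
  n_tracks <- length(tracks)
  if (n_tracks == 0L) stop_myo("no tracks for volume %s", volume_id)
  ns <- sum(vapply(tracks, function(tr) as.numeric(tr$sarcomeres_traversed), numeric(1)))
  types <- lapply(tracks, function(tr) tr$event_types)
  n_split <- sum(vapply(types, function(x) sum(x %in% c("split", "merge")), integer(1)))
  n_xfer <- sum(vapply(types, function(x) sum(x %in% c("transfer", "trade")), integer(1)))
  out <- data.frame(
    volume_id = volume_id,
    group = group,
    n_tracks = n_tracks,
    n_sarcomeres = ns,
    mean_track_len = ns / n_tracks,
    branch_freq_per10 = 10 * (n_split + n_xfer) / ns,
    split_freq_per10 = 10 * n_split / ns,
    transfer_freq_per10 = 10 * n_xfer / ns,
    pct_branched = percent_branched(tracks),
    transfer_share_pct = transfer_share(events),
    n_events_volume = sum(events$type %in% c("split", "merge", "transfer", "trade")),
    n_ambiguous = sum(events$type == "ambiguous"),
    n_suppressed = if (is.null(suppressed)) 0L else sum(unlist(suppressed)),
    stringsAsFactors = FALSE
  )
  stopifnot(abs(out$branch_freq_per10 - out$split_freq_per10 - out$transfer_freq_per10) < 1e-9)
  class(out) <- c("myo_metrics", class(out))
  out
}

#' Run the full pipeline on one network and summarise it
#'
#' Convenience wrapper: ground-truth graph (or extraction from a rendered
#' bundle), tracking, FOV filtering, and [volume_summary()].
#'
#' @param net A `myo_network`.
#' @param from_render If `TRUE`, render the network and extract the graph
#'   from the labeled volume instead of using the ground-truth graph.
#' @param volume_id,group Passed to [volume_summary()].
#' @return A `myo_metrics` row.
#' @export
summarize_network <- function(net, from_render = FALSE,
                              volume_id = paste0("seed", net$seed),
                              group = net$config$muscle_type) {
  graph <- if (from_render) build_graph(render_volume(net)) else network_graph(net)
  tracks <- track_all(graph)
  kept <- fov_filter(tracks, graph)$retained
  volume_summary(kept, graph$events, volume_id = volume_id, group = group,
                 suppressed = if (from_render) net$suppressed else net$suppressed)
}
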