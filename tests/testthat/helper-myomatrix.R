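# Shared fixtures: small generator configs, hand-built graphs, and event
# matching against ground truth.

# compact config for fast rendering tests
desk_config <- function(preset = "slow_twitch", n_columns = 9, n_sarcomeres = 3,
                        jitter = 0, ...) {
  muscle_preset(preset, n_columns = n_columns, n_sarcomeres = n_sarcomeres,
                jitter_sd_vox = jitter, ...)
}

# multisets of (type, slice) agree exactly
same_event_multiset <- function(truth, got) {
  identical(sort(paste(truth$type, truth$slice)),
            sort(paste(got$type, got$slice)))
}

event_recall <- function(truth, got) {
  tt <- paste(truth$type, truth$slice)
  gt <- paste(got$type, got$slice)
  sum(!is.na(match(tt, gt))) / length(tt)
}

# hand-built myo_graph: nodes as data.frame(col, interval, x, y, area,
# memdist_um), serial edges derived from column continuity, plus events
hand_graph <- function(nodes, events = NULL, n_intervals = max(nodes$interval) + 1L,
                       interval_len = 40L, cell = NULL) {
  nodes <- nodes[order(nodes$interval, nodes$col), ]
  nodes$node_id <- seq_len(nrow(nodes))
  if (is.null(nodes$label)) nodes$label <- NA_integer_
  if (is.null(nodes$col_birth_slice)) nodes$col_birth_slice <- 0L
  rownames(nodes) <- NULL
  key <- paste(nodes$col, nodes$interval)
  id_of <- stats::setNames(nodes$node_id, key)
  nxt <- paste(nodes$col, nodes$interval + 1L)
  has <- nxt %in% key
  serial <- data.frame(from = nodes$node_id[has], to = unname(id_of[nxt[has]]))
  if (is.null(events)) {
    events <- data.frame(event_id = integer(), type = character(), slice = integer(),
                         interval = integer(), phase_fraction = numeric(),
                         col_a = integer(), col_b = integer(),
                         bridge1 = integer(), bridge2 = integer(),
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(events$event_id)) events$event_id <- seq_len(nrow(events))
    if (is.null(events$phase_fraction)) events$phase_fraction <- 0.5
    if (is.null(events$col_b)) events$col_b <- NA_integer_
    if (is.null(events$bridge1)) events$bridge1 <- NA_integer_
    if (is.null(events$bridge2)) events$bridge2 <- NA_integer_
  }
  meta <- list(source = "hand", n_intervals = n_intervals,
               interval_len = interval_len,
               z_disks = seq(0L, by = interval_len, length.out = n_intervals),
               n_slices = n_intervals * interval_len,
               voxel_pitch_nm = 50, cell = cell)
  myomatrix:::new_myo_graph(nodes, serial, events, meta)
}

# fake track objects for metric arithmetic tests
fake_track <- function(n_sarc, event_types = character(0)) {
  structure(list(start = 1L, nodes = seq_len(n_sarc),
                 sarcomeres_traversed = n_sarc,
                 event_ids = seq_along(event_types),
                 event_types = event_types,
                 start_memdist_um = 1, in_fov = TRUE,
                 termination = "end_of_volume"),
            class = "myo_track")
}

# hand-coded one-way ANOVA + Tukey-Kramer oracle (textbook formulas)
anova_tukey_oracle <- function(values, groups) {
  groups <- factor(as.character(groups))
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  gm <- mean(values)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((values - m[groups])^2)
  dfb <- k - 1
  dfw <- length(values) - k
  msw <- ssw / dfw
  Fv <- (ssb / dfb) / msw
  p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  pairs <- utils::combn(levels(groups), 2)
  padj <- apply(pairs, 2, function(pr) {
    se <- sqrt(msw / 2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    q <- abs(m[pr[2]] - m[pr[1]]) / se
    stats::ptukey(q, k, dfw, lower.tail = FALSE)
  })
  list(F = Fv, p = p,
       pair = paste(pairs[2, ], pairs[1, ], sep = "-"), p_adj = padj)
}
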