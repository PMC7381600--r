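test_that("an unbranched chain is tracked end to end with no events", {
  nodes <- data.frame(col = 1L, interval = 0:19, x = 10, y = 10,
                      area = 78.5, memdist_um = 1)
  g <- hand_graph(nodes)
  tr <- track_myofibril(g, seed_tracks(g)[1])
  expect_equal(tr$sarcomeres_traversed, 20L)
  expect_length(tr$event_ids, 0L)
  expect_true(tr$in_fov)
})

test_that("start nodes come from the first image, in raster order", {
  cfg <- generator_config(n_columns = 100, n_sarcomeres = 2, p_split = 0,
                          p_transfer = 0, p_trade = 0)
  g <- network_graph(sample_network(cfg, seed = 1))
  starts <- seed_tracks(g)
  expect_length(starts, 100L)
  ys <- g$nodes$y[match(starts, g$nodes$node_id)]
  expect_true(all(diff(round(ys, 6)) >= 0))
  # the fast-twitch preset seeds one track per published myofibril
  gf <- network_graph(sample_network(muscle_preset("fast_twitch"), seed = 2))
  expect_length(seed_tracks(gf), 193L)
})

test_that("splits follow the child closest to the starting membrane distance", {
  nodes <- data.frame(
    col = c(1L, 1L, 2L), interval = c(0L, 1L, 1L),
    x = c(10, 10, 16), y = c(10, 10, 10),
    area = 78.5, memdist_um = c(3.2, 3.0, 5.0)
  )
  ev <- data.frame(type = "split", slice = 45L, interval = 1L,
                   col_a = 1L, bridge1 = 2L)
  g <- hand_graph(nodes, ev, n_intervals = 2L)
  tr <- track_myofibril(g, seed_tracks(g)[1])
  expect_equal(tr$nodes, g$nodes$node_id[match(paste(c(1, 1), c(0, 1)),
                                               paste(g$nodes$col, g$nodes$interval))])
  expect_equal(tr$event_types, "split")

  # equidistant children: the lower node id wins
  nodes2 <- nodes
  nodes2$memdist_um <- c(3.0, 4.0, 2.0) # both children 1.0 from start
  g2 <- hand_graph(nodes2, ev, n_intervals = 2L)
  tr2 <- track_myofibril(g2, seed_tracks(g2)[1])
  chosen <- g2$nodes$col[match(tr2$nodes[2], g2$nodes$node_id)]
  lower_id <- g2$nodes$col[g2$nodes$interval == 1L][
    which.min(g2$nodes$node_id[g2$nodes$interval == 1L])]
  expect_equal(chosen, lower_id)
})

test_that("a track through a merge continues with the merged lineage", {
  # column 1 splits in interval 1; its bridge (col 3, nearer the start
  # distance than column 1's own continuation) merges into column 2 in
  # interval 2
  nodes <- data.frame(
    col = c(1L, 2L, 1L, 2L, 3L, 1L, 2L),
    interval = c(0L, 0L, 1L, 1L, 1L, 2L, 2L),
    x = c(10, 23, 10, 23, 15, 10, 23), y = 10,
    area = 78.5,
    memdist_um = c(3.2, 6, 3.6, 6, 3.1, 3.6, 6)
  )
  ev <- data.frame(type = c("split", "merge"), slice = c(50L, 85L),
                   interval = c(1L, 2L), col_a = c(1L, 2L),
                   bridge1 = c(3L, 3L))
  g <- hand_graph(nodes, ev, n_intervals = 3L)
  g$nodes$col_birth_slice[g$nodes$col == 3L] <- 50L
  tr <- track_myofibril(g, g$nodes$node_id[g$nodes$col == 1L & g$nodes$interval == 0L])
  expect_equal(tr$event_types, c("split", "merge"))
  final_col <- g$nodes$col[match(tr$nodes[3], g$nodes$node_id)]
  expect_equal(final_col, 2L) # ended on the merged lineage
  expect_true(tr$in_fov)
})

test_that("tracks ending before the final interval are excluded by the FOV filter", {
  nodes <- data.frame(col = c(1L, 2L, 2L, 2L), interval = c(0L, 0L, 1L, 2L),
                      x = c(5, 20, 20, 20), y = 5, area = 78.5, memdist_um = 1)
  g <- hand_graph(nodes, n_intervals = 3L)
  tracks <- track_all(g)
  out <- fov_filter(tracks, g)
  expect_length(out$retained, 1L)
  expect_equal(nrow(out$excluded), 1L)
  expect_match(out$excluded$reason, "dangling")
})

test_that("boundary-touching columns are excluded when a bundle is supplied", {
  vol <- array(0L, dim = c(20, 20, 4))
  vol[1:4, 9:12, ] <- 1L   # touches the x = 0 boundary
  vol[10:13, 9:12, ] <- 2L # interior
  mask <- matrix(TRUE, 20, 20)
  bun <- segmentation_bundle(vol, c(0L, 2L), mask)
  g <- build_graph(bun, taper_slices = 3L, min_overlap = 1)
  tracks <- track_all(g)
  out <- fov_filter(tracks, g, bun)
  expect_length(out$retained, 1L)
  expect_match(out$excluded$reason, "boundary")
})

test_that("branch counting on tracks is an unbiased rate estimator", {
  p <- 0.3
  freqs <- vapply(1:20, function(s) {
    cfg <- generator_config(n_columns = 49, n_sarcomeres = 8,
                            p_split = p * 0.8, p_transfer = p * 0.15,
                            p_trade = p * 0.05)
    g <- network_graph(sample_network(cfg, seed = 500 + s))
    branch_frequency(fov_filter(track_all(g), g)$retained)
  }, numeric(1))
  mc_se <- stats::sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 10 * p), 3 * mc_se)
})

test_that("tracking is deterministic and counts each event once per track", {
  net <- sample_network(desk_config("slow_twitch", n_columns = 12, n_sarcomeres = 4),
                        seed = 77)
  g <- network_graph(net)
  t1 <- track_all(g)
  t2 <- track_all(g)
  expect_identical(t1, t2)
  for (tr in t1) expect_false(any(duplicated(tr$event_ids)))
})
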