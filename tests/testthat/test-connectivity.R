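test_that("component counts follow the event structure", {
  cfg0 <- generator_config(n_columns = 10, n_sarcomeres = 2, p_split = 0,
                           p_transfer = 0, p_trade = 0)
  g0 <- network_graph(sample_network(cfg0, seed = 1))
  expect_equal(connected_components(g0)$n_components, 10L)

  # one transfer between two columns joins exactly two components
  nodes <- data.frame(col = rep(1:10, each = 2), interval = rep(0:1, 10),
                      x = rep(seq(5, 95, by = 10), each = 2), y = 10,
                      area = 78.5, memdist_um = 1)
  ev <- data.frame(type = "transfer", slice = 10L, interval = 0L,
                   col_a = 3L, col_b = 4L)
  g1 <- hand_graph(nodes, ev, n_intervals = 2L)
  expect_equal(connected_components(g1)$n_components, 9L)
})

test_that("minimal lateral paths traverse branch edges and report absence", {
  nodes <- data.frame(col = rep(1:3, each = 2), interval = rep(0:1, 3),
                      x = rep(c(5, 18, 31), each = 2), y = 10,
                      area = 78.5, memdist_um = 1)
  ev <- data.frame(type = "transfer", slice = 5L, interval = 0L,
                   col_a = 1L, col_b = 2L)
  g <- hand_graph(nodes, ev, n_intervals = 2L)
  n1 <- g$nodes$node_id[g$nodes$col == 1L & g$nodes$interval == 0L]
  n2 <- g$nodes$node_id[g$nodes$col == 2L & g$nodes$interval == 0L]
  n3 <- g$nodes$node_id[g$nodes$col == 3L & g$nodes$interval == 0L]
  p12 <- minimal_lateral_path(g, n1, n2)
  expect_equal(p12$path, c(n1, n2)) # two segments through the transfer edge
  expect_equal(p12$length, 1L)
  p13 <- minimal_lateral_path(g, n1, n3)
  expect_null(p13$path)
  expect_true(is.na(p13$length))
  expect_error(minimal_lateral_path(g, n1, n1), "differ")
  # serial-only mode cannot use the transfer edge
  expect_null(minimal_lateral_path(g, n1, n2, edge_types = "serial")$path)
})

test_that("BFS path lengths equal a brute-force shortest-path oracle", {
  net <- sample_network(desk_config("slow_twitch", n_columns = 12, n_sarcomeres = 4),
                        seed = 55)
  g <- network_graph(net)
  ig <- myomatrix:::graph_as_igraph(g)
  n <- nrow(g$nodes)
  expect_lte(n, 500L)
  # Floyd-Warshall on the adjacency matrix
  adj <- matrix(Inf, n, n)
  diag(adj) <- 0
  el <- igraph::as_edgelist(ig)
  for (r in seq_len(nrow(el))) {
    adj[el[r, 1], el[r, 2]] <- 1
    adj[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) {
    adj <- pmin(adj, outer(adj[, k], adj[k, ], `+`))
  }
  starts <- seed_tracks(g)
  pick <- starts[round(seq(1, length(starts), length.out = 4))]
  for (a in pick) for (b in pick) {
    if (a == b) next
    got <- minimal_lateral_path(g, a, b)
    want <- adj[a, b]
    if (is.infinite(want)) expect_null(got$path) else expect_equal(got$length, unname(want))
  }
})

test_that("width span fraction reflects footprint extent along the endpoint axis", {
  cell <- list(cx = 20, cy = 20, a = 20, b = 20)
  nodes <- data.frame(col = c(1L, 2L), interval = 0L,
                      x = c(5, 35), y = 20, area = pi * 25, memdist_um = 0)
  ev <- data.frame(type = "transfer", slice = 1L, interval = 0L,
                   col_a = 1L, col_b = 2L)
  g <- hand_graph(nodes, ev, n_intervals = 1L, cell = cell)
  p <- minimal_lateral_path(g)
  expect_equal(p$length, 1L)
  # centroids at the mask boundary plus footprint radii: spans the full width
  expect_gte(width_span_fraction(p$path, g), 0.95)
  # a single column spans about its own diameter over the cell diameter
  expect_equal(width_span_fraction(p$path[1], g), 10 / 40, tolerance = 0.05)
})

test_that("single-component frequency increases with branching rate", {
  frac_single <- function(preset, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- muscle_preset(preset, n_columns = 49, n_sarcomeres = 10)
      connected_components(network_graph(sample_network(cfg, seed = s)))$n_components == 1L
    }, logical(1)))
  }
  f_slow <- frac_single("slow_twitch", 1:12)
  f_late <- frac_single("postnatal_late", 1:12)
  expect_gt(f_slow, f_late)
})
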