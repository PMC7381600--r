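test_that("overlap tables match brute-force voxel enumeration", {
  net <- sample_network(desk_config("slow_twitch", n_sarcomeres = 2), seed = 9)
  b <- render_volume(net)
  for (t in c(0, 25, 60)) {
    got <- overlap_links(b, t, min_overlap = 1)
    a <- b$label_volume[, , t + 1]
    bb <- b$label_volume[, , t + 2]
    # exhaustive voxel scan oracle
    counts <- list()
    for (i in seq_along(a)) {
      if (a[i] > 0L && bb[i] > 0L) {
        k <- paste(a[i], bb[i])
        prev <- if (is.null(counts[[k]])) 0L else counts[[k]]
        counts[[k]] <- prev + 1L
      }
    }
    oracle <- data.frame(
      key = names(counts),
      voxels = as.integer(unlist(counts)), stringsAsFactors = FALSE
    )
    got$key <- paste(got$label_t, got$label_t1)
    expect_setequal(got$key, oracle$key)
    expect_equal(got$voxels[match(oracle$key, got$key)], oracle$voxels)
  }
})

test_that("simple overlap signatures come out as specified", {
  # identical consecutive slices: one self-link per label
  sl <- matrix(0L, 12, 12)
  sl[2:4, 2:4] <- 1L; sl[7:10, 7:10] <- 2L
  vol <- array(sl, dim = c(12, 12, 3))
  bun <- segmentation_bundle(vol, c(0L), matrix(TRUE, 12, 12))
  ov <- overlap_links(bun, 0, min_overlap = 1)
  expect_equal(ov, data.frame(label_t = c(1L, 2L), label_t1 = c(1L, 2L),
                              voxels = c(9L, 16L)))
  # label A covered by B and C on the next slice: rows (A,B) and (A,C)
  s2 <- matrix(0L, 12, 12)
  s2[2:4, 2:3] <- 5L; s2[2:4, 4] <- 6L
  vol2 <- array(0L, dim = c(12, 12, 2))
  vol2[, , 1][sl == 1L] <- 4L
  vol2[, , 2] <- s2
  bun2 <- segmentation_bundle(vol2, c(0L), matrix(TRUE, 12, 12))
  ov2 <- overlap_links(bun2, 0, min_overlap = 1)
  expect_setequal(paste(ov2$label_t, ov2$label_t1), c("4 5", "4 6"))
})

test_that("unbranched volumes give the expected graph and no events", {
  cfg <- generator_config(n_columns = 6, n_sarcomeres = 3, p_split = 0,
                          p_transfer = 0, p_trade = 0, jitter_sd_vox = 0)
  net <- sample_network(cfg, seed = 3)
  g <- build_graph(render_volume(net))
  expect_equal(nrow(g$nodes), 18L)
  expect_equal(nrow(g$serial), 12L)
  expect_equal(nrow(g$events), 0L)
})

test_that("extraction recovers ground truth exactly on noiseless renders", {
  for (s in 1:6) {
    net <- sample_network(desk_config(c("fast_twitch", "slow_twitch", "cardiac")[(s %% 3) + 1]),
                          seed = 100 + s)
    g <- build_graph(render_volume(net))
    expect_true(same_event_multiset(net$events, g$events))
    expect_equal(sum(g$events$type == "ambiguous"), 0L)
  }
})

test_that("a relabeling with full one-to-one overlap is a continuation, not an event", {
  cfg <- generator_config(n_columns = 4, n_sarcomeres = 2, p_split = 0,
                          p_transfer = 0, p_trade = 0, jitter_sd_vox = 0)
  net <- sample_network(cfg, seed = 1)
  b <- render_volume(net)
  vol <- b$label_volume
  # rename label 1 to 99 from slice 30 onward, mid-interval
  for (t in 31:dim(vol)[3]) vol[, , t][vol[, , t] == 1L] <- 99L
  b2 <- segmentation_bundle(vol, b$z_disk_slices, b$cell_mask, b$voxel_pitch_nm)
  g <- build_graph(b2, taper_slices = cfg$taper_slices)
  expect_equal(nrow(g$events), 0L)
  expect_equal(nrow(g$nodes), 8L)
})

test_that("extracted topology is invariant to label permutation", {
  net <- sample_network(desk_config("cardiac"), seed = 21)
  b <- render_volume(net)
  g1 <- build_graph(b)
  vol <- b$label_volume
  labs <- setdiff(unique(as.vector(vol)), 0L)
  perm <- setNames(sample(seq(201, 200 + length(labs))), labs)
  vol2 <- array(0L, dim = dim(vol))
  nz <- vol > 0L
  vol2[nz] <- as.integer(perm[as.character(vol[nz])])
  b2 <- segmentation_bundle(vol2, b$z_disk_slices, b$cell_mask, b$voxel_pitch_nm,
                            metadata = b$metadata)
  g2 <- build_graph(b2)
  expect_true(same_event_multiset(g1$events, g2$events))
  expect_equal(nrow(g1$nodes), nrow(g2$nodes))
  expect_equal(nrow(g1$serial), nrow(g2$serial))
})

test_that("mirroring the slice axis swaps splits and merges, transfers unchanged", {
  net <- sample_network(desk_config("fast_twitch", n_columns = 12, n_sarcomeres = 4),
                        seed = 31)
  b <- render_volume(net)
  g1 <- build_graph(b)
  nsl <- dim(b$label_volume)[3]
  vol2 <- b$label_volume[, , rev(seq_len(nsl))]
  zd <- sort(nsl - b$z_disk_slices)
  zd <- unique(c(0L, zd[zd < nsl]))
  b2 <- segmentation_bundle(vol2, zd, b$cell_mask, b$voxel_pitch_nm)
  g2 <- build_graph(b2, taper_slices = net$config$taper_slices)
  t1 <- table(factor(g1$events$type, levels = c("split", "merge", "transfer", "trade")))
  t2 <- table(factor(g2$events$type, levels = c("split", "merge", "transfer", "trade")))
  expect_equal(unname(t1[["split"]]), unname(t2[["merge"]]))
  expect_equal(unname(t1[["merge"]]), unname(t2[["split"]]))
  expect_equal(t1[["transfer"]] + t1[["trade"]], t2[["transfer"]] + t2[["trade"]])
})

test_that("trades are recovered as one trade, not two transfers", {
  cfg <- generator_config(n_columns = 4, n_sarcomeres = 2, p_split = 0,
                          p_transfer = 0, p_trade = 0.3, jitter_sd_vox = 0)
  found <- 0L
  for (s in 1:30) {
    net <- sample_network(cfg, seed = s)
    if (nrow(net$events) == 0L) next
    g <- build_graph(render_volume(net))
    expect_equal(sum(g$events$type == "trade"), sum(net$events$type == "trade"))
    expect_equal(sum(g$events$type == "transfer"), 0L)
    found <- found + sum(net$events$type == "trade")
    if (found >= 3L) break
  }
  expect_gte(found, 3L)
})

test_that("event recall stays above 0.95 under boundary jitter up to 1 voxel", {
  hits <- 0L; total <- 0L
  for (s in 1:12) {
    net <- sample_network(desk_config("slow_twitch", jitter = 1), seed = s)
    g <- build_graph(render_volume(net))
    tt <- paste(net$events$type, net$events$slice)
    gt <- paste(g$events$type, g$events$slice)
    hits <- hits + sum(!is.na(match(tt, gt)))
    total <- total + length(tt)
  }
  expect_gte(hits / total, 0.95)
})

test_that("band annotation follows the documented phase partition", {
  expect_equal(annotate_band(0.50), "H-zone")
  expect_equal(annotate_band(0.02), "z-disk-proximal")
  expect_equal(annotate_band(0.97), "z-disk-proximal")
  expect_equal(annotate_band(c(0.10, 0.85)), c("I-band", "I-band"))
  expect_equal(annotate_band(c(0.30, 0.70)), c("A-band", "A-band"))
  expect_error(annotate_band(1.2))
  set.seed(1)
  expect_setequal(unique(annotate_band(runif(500))),
                  c("z-disk-proximal", "I-band", "A-band", "H-zone"))
})

test_that("disconnected label footprints trigger a segmentation warning", {
  cfg <- generator_config(n_columns = 4, n_sarcomeres = 2, p_split = 0,
                          p_transfer = 0, p_trade = 0, jitter_sd_vox = 0)
  net <- sample_network(cfg, seed = 2)
  b <- render_volume(net)
  vol <- b$label_volume
  # plant a detached blob of label 1 far from its column, mid-life
  sl <- vol[, , 40]
  free <- which(sl == 0L & b$cell_mask, arr.ind = TRUE)
  px <- free[which.max(free[, 1]), ]
  vol[px[1], px[2], 40] <- 1L
  b2 <- segmentation_bundle(vol, b$z_disk_slices, b$cell_mask, b$voxel_pitch_nm)
  expect_warning(build_graph(b2, taper_slices = 6, check_connectivity = TRUE),
                 "4-connected")
})
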