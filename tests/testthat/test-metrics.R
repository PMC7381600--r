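test_that("branch frequency is events per ten sarcomeres", {
  tracks <- c(
    lapply(1:4, function(i) fake_track(20, c("split", "transfer"))),
    lapply(1:1, function(i) fake_track(20, c("split", "split", "split",
                                             "split", "split", "split",
                                             "split", "split")))
  )
  # 16 events over 100 sarcomeres
  expect_equal(branch_frequency(tracks), 1.6)
  expect_equal(branch_frequency(list(fake_track(10))), 0)
  expect_error(branch_frequency(list()), "sarcomeres")
})

test_that("percent branched and transfer share follow their definitions", {
  tracks <- list(fake_track(5, "split"), fake_track(5, "merge"),
                 fake_track(5, "trade"), fake_track(5))
  expect_equal(percent_branched(tracks), 75)
  ev <- data.frame(type = c(rep("split", 8), rep("transfer", 2)))
  expect_equal(transfer_share(ev), 20)
  expect_equal(transfer_share(data.frame(type = rep("transfer", 5))), 100)
  expect_true(is.na(transfer_share(data.frame(type = character(0)))))
})

test_that("volume summary enforces frequency additivity and handles empty volumes", {
  net <- sample_network(desk_config("cardiac", n_columns = 12, n_sarcomeres = 4),
                        seed = 15)
  sm <- summarize_network(net)
  expect_equal(sm$branch_freq_per10, sm$split_freq_per10 + sm$transfer_freq_per10)
  expect_gte(sm$n_sarcomeres, sm$n_tracks)
  expect_true(sm$pct_branched >= 0 && sm$pct_branched <= 100)

  empty <- volume_summary(list(fake_track(6), fake_track(6)),
                          data.frame(type = character(0)), "v0")
  expect_equal(empty$branch_freq_per10, 0)
  expect_equal(empty$pct_branched, 0)
  expect_true(is.na(empty$transfer_share_pct))
})

test_that("truth-graph metrics and render-extracted metrics agree on noiseless volumes", {
  net <- sample_network(desk_config("slow_twitch"), seed = 23)
  m_truth <- summarize_network(net)
  m_pipe <- summarize_network(net, from_render = TRUE)
  expect_equal(m_pipe$branch_freq_per10, m_truth$branch_freq_per10)
  expect_equal(m_pipe$pct_branched, m_truth$pct_branched)
  expect_equal(m_pipe$transfer_share_pct, m_truth$transfer_share_pct)
})

test_that("metrics are invariant to label permutation and slice-axis reversal", {
  net <- sample_network(desk_config("fast_twitch", n_columns = 12, n_sarcomeres = 4),
                        seed = 41)
  b <- render_volume(net)
  g1 <- build_graph(b)
  m1 <- volume_summary(fov_filter(track_all(g1), g1)$retained, g1$events, "v")

  vol <- b$label_volume
  labs <- setdiff(unique(as.vector(vol)), 0L)
  perm <- setNames(rev(seq(301, 300 + length(labs))), labs)
  vol2 <- array(0L, dim = dim(vol))
  nz <- vol > 0L
  vol2[nz] <- as.integer(perm[as.character(vol[nz])])
  b2 <- segmentation_bundle(vol2, b$z_disk_slices, b$cell_mask, b$voxel_pitch_nm)
  g2 <- build_graph(b2, taper_slices = net$config$taper_slices)
  m2 <- volume_summary(fov_filter(track_all(g2), g2)$retained, g2$events, "v")
  expect_equal(m2$branch_freq_per10, m1$branch_freq_per10)
  expect_equal(m2$pct_branched, m1$pct_branched)

  nsl <- dim(vol)[3]
  vol3 <- vol[, , rev(seq_len(nsl))]
  zd <- sort(nsl - b$z_disk_slices)
  zd <- unique(c(0L, zd[zd < nsl]))
  b3 <- segmentation_bundle(vol3, zd, b$cell_mask, b$voxel_pitch_nm)
  g3 <- build_graph(b3, taper_slices = net$config$taper_slices)
  m3 <- volume_summary(fov_filter(track_all(g3), g3)$retained, g3$events, "v")
  # split/merge pooling makes reversal neutral for class frequencies
  expect_equal(m3$split_freq_per10, m1$split_freq_per10)
  expect_equal(m3$transfer_freq_per10, m1$transfer_freq_per10)
})

test_that("percent branched matches the independent-event closed form", {
  p <- 0.16; M <- 13L
  pcts <- vapply(1:12, function(s) {
    cfg <- generator_config(n_columns = 64, n_sarcomeres = M,
                            p_split = p * 0.8, p_transfer = p * 0.16,
                            p_trade = p * 0.04)
    g <- network_graph(sample_network(cfg, seed = 700 + s))
    percent_branched(fov_filter(track_all(g), g)$retained)
  }, numeric(1))
  expected <- 100 * (1 - (1 - p)^M)
  half_width <- 100 * 1.96 * sqrt(expected / 100 * (1 - expected / 100) / 64)
  expect_lt(abs(mean(pcts) - expected), half_width)
})
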