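# Rendering a sampled network as a labeled volume.
#
# Footprints are convex analytic shapes on each slice: a seed column is its
# disk minus the "cap" regions currently detached or donated; a bridge/wedge
# is the detached cap, translated toward its acceptor during the final
# taper_slices before it merges. A new label starts at every branch point
# (split children, transfer-receiving merge products, and post-event
# continuations), mirroring the one-label-per-myofibrillar-segment tracing
# convention of manual segmentations.

#' Render a network as a labeled segmentation volume
#'
#' Rasterizes a [sample_network()] result into a voxel grid whose slice axis
#' is the fiber's long axis. Each myofibrillar segment receives a unique
#' positive 16-bit label (0 is background); labels change at every branch
#' point. The z-disk slice list and elliptical cell mask are attached.
#'
#' @param net A `myo_network`.
#' @param jitter_sd_vox Per-slice boundary jitter SD in voxels; defaults to
#'   the generator config value. Set to 0 for noiseless renders.
#' @return A `myo_bundle`: list with `label_volume` (integer array
#'   `[x, y, slice]`), `z_disk_slices` (0-based), `cell_mask` (logical
#'   matrix), `voxel_pitch_nm`, `metadata` (seed, config echo, suppressed
#'   tally), and `label_map` linking labels to ground-truth columns.
#' @export
render_volume <- function(net, jitter_sd_vox = net$config$jitter_sd_vox) {
  stopifnot(inherits(net, "myo_network"))
  cfg <- net$config
  cell <- net$cell
  n_slices <- net$n_slices
  nx <- ceiling(2 * (cell$a + cfg$column_radius_vox + 3))
  ny <- ceiling(2 * (cell$b + cfg$column_radius_vox + 3))
  if (nx < 8 || ny < 8 || nx * ny * n_slices > 2.5e8) {
    stop_myo("rendered grid %d x %d x %d is outside supported sizing", nx, ny, n_slices)
  }

  cuts <- build_cuts(net)
  epochs <- build_epochs(net)
  if (max(epochs$label) > 65535L) stop_myo("more than 65535 segments; reduce network size")

  xs <- seq_len(nx) - 0.5
  ys <- seq_len(ny) - 0.5
  cell_mask <- outer(xs, ys, function(x, y) {
    ((x - cell$cx) / cell$a)^2 + ((y - cell$cy) / cell$b)^2 <= 1
  })

  cols <- net$columns
  vol <- array(0L, dim = c(nx, ny, n_slices))
  # render seed columns first so transient pieces never overwrite them
  piece_order <- order(cols$kind != "seed", cols$col_id)

  # Boundary jitter: AR(1) along the slice axis (marginal SD = jitter_sd_vox,
  # lag-1 correlation 0.85), emulating tracing error that is correlated
  # across slices by contour interpolation. Stream derived from the network
  # seed so renders are reproducible.
  jit <- if (jitter_sd_vox > 0) {
    with_seed((net$seed + 104729L) %% .Machine$integer.max, {
      rho <- 0.85
      eps <- matrix(rnorm(2L * nrow(cols) * n_slices, 0, jitter_sd_vox),
                    nrow = 2L * nrow(cols))
      out <- eps
      for (t in 2:n_slices) {
        out[, t] <- rho * out[, t - 1L] + sqrt(1 - rho^2) * eps[, t]
      }
      out
    })
  } else NULL

  # jitter row per piece: detached pieces inherit the donor's jitter track
  # (the traced contour of a detaching wedge follows its parent's boundary)
  jrow <- vapply(seq_len(nrow(cols)), function(i) {
    if (cols$kind[i] == "seed") i else which(cols$col_id == cols$donor[i])[1L]
  }, integer(1))
  jx_col <- jy_col <- numeric(max(cols$col_id))

  for (t in seq_len(n_slices) - 1L) {
    sl <- matrix(0L, nx, ny)
    if (!is.null(jit)) {
      jx_col[cols$col_id] <- jit[2L * jrow - 1L, t + 1L]
      jy_col[cols$col_id] <- jit[2L * jrow, t + 1L]
    }
    for (pi in piece_order) {
      p <- cols[pi, ]
      if (p$birth_slice > t || p$death_slice <= t) next
      lab <- epoch_label(epochs, p$col_id, t)
      msk <- piece_footprint(p, cuts[[p$col_id]], t, nx, ny,
                             jx_col, jy_col, cfg$taper_slices, cols)
      if (is.null(msk)) next
      sub <- sl[msk$ix, msk$iy]
      put <- msk$mask & sub == 0L & cell_mask[msk$ix, msk$iy]
      sub[put] <- lab
      sl[msk$ix, msk$iy] <- sub
    }
    vol[, , t + 1L] <- prune_diagonal_slivers(sl)
  }

  bundle <- list(
    label_volume = vol,
    z_disk_slices = net$z_disks,
    cell_mask = cell_mask,
    voxel_pitch_nm = cfg$voxel_pitch_nm,
    metadata = list(
      source = "synthetic", seed = net$seed,
      muscle_type = cfg$muscle_type,
      cell = cell, suppressed = as.list(net$suppressed),
      config = cfg[c("n_columns", "n_sarcomeres", "p_split", "p_transfer",
                     "p_trade", "grid_pitch_vox", "column_radius_vox",
                     "sarcomere_len_slices", "taper_slices", "voxel_pitch_nm",
                     "jitter_sd_vox")]
    ),
    label_map = epochs
  )
  class(bundle) <- "myo_bundle"
  bundle
}

# per-column list of active cuts: rows (nx_, ny_, off, from, to, ref)
# removing the halfplane region {n . (p - centre) >= off} during slices
# [from, to); the cut plane rides the jitter track of column `ref`
build_cuts <- function(net) {
  cols <- net$columns
  Tt <- net$config$taper_slices
  cuts <- vector("list", max(cols$col_id))
  add <- function(col, dir, off, from, to, ref) {
    cuts[[col]] <<- rbind(cuts[[col]], c(dir[1], dir[2], off, from, to, ref))
  }
  for (i in seq_len(nrow(cols))) {
    p <- cols[i, ]
    if (p$kind == "seed") next
    d_dir <- c(p$dir_x, p$dir_y)
    if (p$perp_sign == 0) {
      # split bridge or transfer wedge: donor cut for the piece's lifetime,
      # acceptor carve while the piece crosses. The cut boundary coincides
      # with the wedge boundary (strict vs non-strict inequality), so the
      # partition is exact and per-slice labeled area is conserved. The
      # carve rides the donor's jitter track — it exists to accommodate the
      # wedge, which jitters with its donor — with one voxel of slack.
      add(p$donor, d_dir, p$u0, p$birth_slice, p$death_slice, p$donor)
      add(p$acceptor, -d_dir, p$u0 - 1, p$death_slice - Tt, p$death_slice, p$donor)
    } else {
      # trade wedge: full-cap cut on its donor. The cut serves both the
      # outgoing wedge (own jitter) and the reciprocal wedge's landing zone
      # (partner jitter); the slack absorbs the mismatch.
      add(p$donor, d_dir, p$u0 - 1, p$birth_slice, p$death_slice, p$donor)
    }
  }
  cuts
}

# label epochs: every piece gets one label per epoch; seed columns are
# relabeled at each branch point they participate in
build_epochs <- function(net) {
  cols <- net$columns
  ev <- net$events
  Tt <- net$config$taper_slices
  relabel <- lapply(seq_len(max(cols$col_id)), function(i) integer(0))
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$type == "split") {
        relabel[[e$col_a]] <- c(relabel[[e$col_a]], e$slice)
      } else if (e$type == "merge") {
        relabel[[e$col_a]] <- c(relabel[[e$col_a]], e$slice)
      } else if (e$type == "transfer") {
        relabel[[e$col_a]] <- c(relabel[[e$col_a]], e$slice)
        relabel[[e$col_b]] <- c(relabel[[e$col_b]], e$slice + Tt)
      } else if (e$type == "trade") {
        relabel[[e$col_a]] <- c(relabel[[e$col_a]], e$slice, e$slice + Tt)
        relabel[[e$col_b]] <- c(relabel[[e$col_b]], e$slice, e$slice + Tt)
      }
    }
  }
  out <- list()
  lab <- 0L
  for (i in seq_len(nrow(cols))) {
    p <- cols[i, ]
    brk <- sort(unique(c(p$birth_slice, relabel[[p$col_id]], p$death_slice)))
    brk <- brk[brk >= p$birth_slice & brk <= p$death_slice]
    for (j in seq_len(length(brk) - 1L)) {
      lab <- lab + 1L
      out[[length(out) + 1L]] <- data.frame(
        label = lab, col = p$col_id, kind = p$kind,
        start_slice = brk[j], end_slice = brk[j + 1L]
      )
    }
  }
  do.call(rbind, out)
}

epoch_label <- function(epochs, col, t) {
  hit <- epochs$col == col & epochs$start_slice <= t & epochs$end_slice > t
  epochs$label[hit][1L]
}

# rasterize one piece on slice t within its bounding box; jx_col/jy_col are
# the per-column jitter offsets on this slice
piece_footprint <- function(p, col_cuts, t, nx, ny, jx_col, jy_col, taper, cols) {
  r <- p$radius
  if (p$kind == "seed") {
    cx <- p$x + jx_col[p$col_id]; cy <- p$y + jy_col[p$col_id]
    bb <- bbox_idx(cx, cy, r + 1, nx, ny)
    if (is.null(bb)) return(NULL)
    X <- matrix(bb$xs, length(bb$xs), length(bb$ys))
    Y <- matrix(bb$ys, length(bb$xs), length(bb$ys), byrow = TRUE)
    m <- (X - cx)^2 + (Y - cy)^2 <= r^2
    if (!is.null(col_cuts)) {
      act <- col_cuts[, 4L] <= t & col_cuts[, 5L] > t
      for (ci in which(act)) {
        ref <- col_cuts[ci, 6L]
        ccx <- p$x + jx_col[ref]; ccy <- p$y + jy_col[ref]
        u <- col_cuts[ci, 1L] * (X - ccx) + col_cuts[ci, 2L] * (Y - ccy)
        m <- m & u < col_cuts[ci, 3L]
      }
    }
    return(list(ix = bb$ix, iy = bb$iy, mask = m))
  }
  # bridge / wedge: donor cap, translated toward the acceptor while crossing
  don <- cols[cols$col_id == p$donor, ]
  acc <- cols[cols$col_id == p$acceptor, ]
  n_vec <- c(p$dir_x, p$dir_y)
  dist <- sqrt((acc$x - don$x)^2 + (acc$y - don$y)^2)
  # arrival reaches two voxels into the acceptor disk so the overlap with
  # the merge product survives donor-vs-acceptor jitter mismatch; the strip
  # beyond the carve is clipped against the acceptor's kept footprint
  Delta <- dist - p$u0 - r + 2
  # parked at the donor cap on the first crossing slice, fully arrived in the
  # acceptor carve on the last slice before the merge
  delta <- if (t >= p$dwell_end) Delta * (t - p$dwell_end) / (taper - 1) else 0
  cx <- don$x + jx_col[p$col_id]; cy <- don$y + jy_col[p$col_id]
  scx <- cx + delta * n_vec[1]
  scy <- cy + delta * n_vec[2]
  bb <- bbox_idx(scx, scy, r + 1, nx, ny)
  if (is.null(bb)) return(NULL)
  X <- matrix(bb$xs, length(bb$xs), length(bb$ys))
  Y <- matrix(bb$ys, length(bb$xs), length(bb$ys), byrow = TRUE)
  # evaluate the donor-frame shape at the back-translated coordinates
  Xs <- X - delta * n_vec[1]
  Ys <- Y - delta * n_vec[2]
  u <- n_vec[1] * (Xs - cx) + n_vec[2] * (Ys - cy)
  m <- (Xs - cx)^2 + (Ys - cy)^2 <= r^2 & u >= p$u0
  if (p$perp_sign != 0) {
    v <- -n_vec[2] * (Xs - cx) + n_vec[1] * (Ys - cy)
    m <- m & p$perp_sign * v >= 0.5
  }
  list(ix = bb$ix, iy = bb$iy, mask = m)
}

# Remove voxels with no 4-neighbour of the same label (diagonal slivers at
# slanted chord/circle corners), so every label footprint is one
# 4-connected region. Iterated to erode short diagonal chains.
prune_diagonal_slivers <- function(sl, passes = 3L) {
  nx <- nrow(sl); ny <- ncol(sl)
  for (p in seq_len(passes)) {
    eqv <- sl[-1L, , drop = FALSE] == sl[-nx, , drop = FALSE]
    eqh <- sl[, -1L, drop = FALSE] == sl[, -ny, drop = FALSE]
    keep <- matrix(FALSE, nx, ny)
    keep[-nx, ] <- keep[-nx, ] | eqv
    keep[-1L, ] <- keep[-1L, ] | eqv
    keep[, -ny] <- keep[, -ny] | eqh
    keep[, -1L] <- keep[, -1L] | eqh
    drop <- sl > 0L & !keep
    if (!any(drop)) break
    sl[drop] <- 0L
  }
  sl
}

bbox_idx <- function(cx, cy, R, nx, ny) {
  ix <- max(1L, floor(cx - R)):min(nx, ceiling(cx + R + 1))
  iy <- max(1L, floor(cy - R)):min(ny, ceiling(cy + R + 1))
  if (length(ix) == 0L || length(iy) == 0L) return(NULL)
  list(ix = ix, iy = iy, xs = ix - 0.5, ys = iy - 0.5)
}
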