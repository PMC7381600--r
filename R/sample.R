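#' Sample a ground-truth myofibrillar branching network
#'
#' Draws a stochastic branching network under the model described in
#' [generator_config()]: parallel sarcomere columns on a jittered grid inside
#' an elliptical cell cross-section, with at most one event initiated per
#' column per sarcomere interval (multinomial draw over split / transfer /
#' trade at half the configured encounter rates; see Details).
#'
#' A *split* detaches a bridge within the parent's cross-section; the bridge
#' runs alongside for a little over twice the taper window and then merges
#' into a geometrically adjacent column, so each split initiation is recorded
#' as two events (the split and the downstream merge), matching how branch
#' ends are counted on tracked myofibrils. A *transfer* moves a wedge of the
#' donor's cross-section into an adjacent acceptor over `taper_slices`. A
#' *trade* is two reciprocal wedges exchanged at the same slice, recorded as
#' a single event. Events are placed at a uniform-random position within the
#' sarcomere interval (branch points occur in all sarcomeric bands).
#'
#' Events that cannot be placed — no adjacent partner with a free corridor,
#' or the column already carries three concurrent cuts — are re-drawn as
#' no-event and reported in the `suppressed` tally.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed; identical `(config, seed)` give identical
#'   networks.
#' @return An object of class `myo_network`: a list with `columns` (seed
#'   columns and transient bridge/wedge pieces), `events` (typed event
#'   table), `cell` (ellipse geometry), `z_disks`, `n_slices`, `suppressed`
#'   and the config echo.
#' @export
sample_network <- function(config, seed = config$seed) {
  validate_config(config)
  if (is.null(seed) || is.na(seed)) stop_myo("sample_network() needs an explicit seed")
  with_seed(seed, sample_network_impl(config, as.integer(seed)))
}

sample_network_impl <- function(cfg, seed) {
  N <- cfg$n_columns
  M <- cfg$n_sarcomeres
  L <- cfg$sarcomere_len_slices
  Tt <- cfg$taper_slices
  r <- cfg$column_radius_vox
  g <- cfg$grid_pitch_vox
  n_slices <- M * L

  lay <- layout_columns(cfg)
  cols <- data.frame(
    col_id = seq_len(N),
    kind = "seed",
    x = lay$x, y = lay$y,
    radius = r,
    birth_slice = 0L, death_slice = n_slices,
    donor = NA_integer_, acceptor = NA_integer_,
    u0 = NA_real_, dir_x = NA_real_, dir_y = NA_real_,
    perp_sign = 0, dwell_end = NA_integer_,
    stringsAsFactors = FALSE
  )

  # geometric adjacency among seed columns: orthogonal grid neighbours, whose
  # corridors are short enough for wedges to keep slice-to-slice overlap
  dmat <- as.matrix(stats::dist(cbind(lay$x, lay$y)))
  adj <- lapply(seq_len(N), function(i) {
    which(dmat[i, ] > 0 & dmat[i, ] <= 1.25 * g)
  })

  # chord offset giving a 25% cap of a radius-r disk
  u0 <- cap_offset(0.25) * r

  # per-(column, interval) multinomial initiation draws at half rates
  q <- c(cfg$p_split, cfg$p_transfer, cfg$p_trade) / 2
  u <- matrix(runif(N * M), N, M)
  type_code <- matrix(0L, N, M) # 0 none, 1 split, 2 transfer, 3 trade
  type_code[u < q[1] + q[2] + q[3]] <- 3L
  type_code[u < q[1] + q[2]] <- 2L
  type_code[u < q[1]] <- 1L

  init <- which(type_code > 0L, arr.ind = TRUE)
  ev_rows <- list()
  extra_cols <- list()
  suppressed <- c(split = 0L, transfer = 0L, trade = 0L)
  next_col <- N + 1L
  next_ev <- 1L

  if (nrow(init) > 0L) {
    ini <- data.frame(col = init[, 1L], interval = init[, 2L] - 1L)
    ini$type <- type_code[init]
    # uniform fractional position, leaving room for the crossing taper
    win <- L - Tt - 4L
    ini$s <- ini$interval * L + 2L + floor(runif(nrow(ini)) * (win + 1L))
    ini$span <- ifelse(ini$type == 1L,
                       2L * Tt + 2L + floor(runif(nrow(ini)) * 7L),
                       Tt)
    ord <- order(ini$s, ini$col)
    ini <- ini[ord, ]

    corridor_busy <- new.env(hash = TRUE, parent = emptyenv())
    cuts <- vector("list", N) # per seed column: matrix of (start, end)
    trans_slices <- vector("list", N) # label-transition slices per column

    n_active_cuts <- function(i, s, m) {
      cc <- cuts[[i]]
      if (is.null(cc)) return(0L)
      sum(cc[, 1L] <= m & cc[, 2L] >= s)
    }
    # label transitions an event would place on each participating column
    boundary_slices <- function(ty, s, m, c_id, d_id) {
      switch(ty,
             split = list(c = s, d = m),
             transfer = list(c = s, d = m),
             trade = list(c = c(s, m), d = c(s, m)))
    }
    boundaries_free <- function(ty, s, m, c_id, d_id) {
      b <- boundary_slices(ty, s, m, c_id, d_id)
      !any(b$c %in% trans_slices[[c_id]]) && !any(b$d %in% trans_slices[[d_id]])
    }

    for (ii in seq_len(nrow(ini))) {
      c_id <- ini$col[ii]; s <- ini$s[ii]; ty <- ini$type[ii]
      span <- ini$span[ii]
      m <- s + span
      if (m + Tt > n_slices - 1L) { # keep the merge taper inside the volume
        s <- n_slices - 1L - Tt - span
        m <- s + span
      }
      k <- s %/% L
      nbrs <- adj[[c_id]]
      # eligible partners: free corridor and spare cut capacity
      ok <- vapply(nbrs, function(d) {
        key <- paste(min(c_id, d), max(c_id, d))
        busy <- get0(key, envir = corridor_busy, ifnotfound = -1L)
        busy < s && n_active_cuts(d, s, m) < 3L
      }, logical(1L))
      nbrs <- nbrs[ok]
      tyname <- c("split", "transfer", "trade")[ty]
      if (length(nbrs) == 0L || n_active_cuts(c_id, s, m) >= 3L) {
        suppressed[tyname] <- suppressed[tyname] + 1L
        next
      }
      d_id <- if (length(nbrs) == 1L) nbrs else nbrs[floor(runif(1) * length(nbrs)) + 1L]
      # keep every label transition of a column on its own slice: slide the
      # event within its placement window to the nearest free position
      k_lo <- k * L + 2L
      k_hi <- (k + 1L) * L - Tt - 2L
      if (ty == 1L) k_hi <- min(k_hi, n_slices - 1L - Tt - span)
      cand <- seq(k_lo, k_hi)
      cand <- cand[order(abs(cand - s), cand)]
      s_free <- NA_integer_
      for (sc in cand) {
        if (boundaries_free(tyname, sc, sc + span, c_id, d_id)) { s_free <- sc; break }
      }
      key <- paste(min(c_id, d_id), max(c_id, d_id))
      if (is.na(s_free) ||
          get0(key, envir = corridor_busy, ifnotfound = -1L) >= s_free) {
        suppressed[tyname] <- suppressed[tyname] + 1L
        next
      }
      s <- s_free; m <- s + span
      bnd <- boundary_slices(tyname, s, m, c_id, d_id)
      trans_slices[[c_id]] <- c(trans_slices[[c_id]], bnd$c)
      trans_slices[[d_id]] <- c(trans_slices[[d_id]], bnd$d)
      assign(key, m + Tt, envir = corridor_busy)
      cuts[[c_id]] <- rbind(cuts[[c_id]], c(s, m))
      cuts[[d_id]] <- rbind(cuts[[d_id]], c(s, m))

      dvec <- c(lay$x[d_id] - lay$x[c_id], lay$y[d_id] - lay$y[c_id])
      dvec <- dvec / sqrt(sum(dvec^2))
      mk_piece <- function(id, kind, donor, acceptor, perp, dwell_end, birth, death) {
        data.frame(col_id = id, kind = kind,
                   x = lay$x[donor], y = lay$y[donor], radius = r,
                   birth_slice = birth, death_slice = death,
                   donor = donor, acceptor = acceptor, u0 = u0,
                   dir_x = if (donor == c_id) dvec[1] else -dvec[1],
                   dir_y = if (donor == c_id) dvec[2] else -dvec[2],
                   perp_sign = perp, dwell_end = dwell_end,
                   stringsAsFactors = FALSE)
      }
      mk_event <- function(type, slice, col_a, col_b, b1, b2 = NA_integer_) {
        data.frame(event_id = NA_integer_, type = type, slice = slice,
                   interval = slice %/% L, phase_fraction = (slice %% L) / L,
                   col_a = col_a, col_b = col_b,
                   bridge1 = b1, bridge2 = b2, stringsAsFactors = FALSE)
      }

      if (ty == 1L) { # split + downstream merge via a bridge
        b <- next_col; next_col <- next_col + 1L
        extra_cols[[length(extra_cols) + 1L]] <-
          mk_piece(b, "bridge", c_id, d_id, 0, m - Tt, s, m)
        ev_rows[[length(ev_rows) + 1L]] <- mk_event("split", s, c_id, NA_integer_, b)
        ev_rows[[length(ev_rows) + 1L]] <- mk_event("merge", m, d_id, NA_integer_, b)
      } else if (ty == 2L) { # transfer: wedge crosses immediately
        w <- next_col; next_col <- next_col + 1L
        extra_cols[[length(extra_cols) + 1L]] <-
          mk_piece(w, "wedge", c_id, d_id, 0, s, s, m)
        ev_rows[[length(ev_rows) + 1L]] <- mk_event("transfer", s, c_id, d_id, w)
      } else { # trade: reciprocal wedges, one recorded event
        w1 <- next_col; w2 <- next_col + 1L; next_col <- next_col + 2L
        extra_cols[[length(extra_cols) + 1L]] <-
          mk_piece(w1, "wedge", c_id, d_id, 1, s, s, m)
        extra_cols[[length(extra_cols) + 1L]] <-
          mk_piece(w2, "wedge", d_id, c_id, -1, s, s, m)
        ev_rows[[length(ev_rows) + 1L]] <- mk_event("trade", s, c_id, d_id, w1, w2)
      }
    }
  }

  if (length(extra_cols) > 0L) cols <- rbind(cols, do.call(rbind, extra_cols))
  events <- if (length(ev_rows) > 0L) do.call(rbind, ev_rows) else empty_events()
  if (nrow(events) > 0L) {
    events <- events[order(events$slice, events$col_a), ]
    events$event_id <- seq_len(nrow(events))
    rownames(events) <- NULL
  }

  net <- list(
    config = cfg, seed = seed,
    columns = cols, events = events,
    cell = lay$cell,
    n_slices = n_slices,
    z_disks = seq(0L, (M - 1L) * L, by = L),
    interval_len = L,
    suppressed = suppressed
  )
  class(net) <- "myo_network"
  net
}

empty_events <- function() {
  data.frame(event_id = integer(), type = character(), slice = integer(),
             interval = integer(), phase_fraction = numeric(),
             col_a = integer(), col_b = integer(),
             bridge1 = integer(), bridge2 = integer(),
             stringsAsFactors = FALSE)
}

# chord offset fraction q in [0,1] such that the cap {u >= q*r} of a unit
# disk has the requested area fraction
cap_offset <- function(frac) {
  f <- function(q) (acos(q) - q * sqrt(1 - q^2)) / pi - frac
  stats::uniroot(f, c(0, 1 - 1e-9))$root
}

# Lay seed columns on a square grid (with sub-voxel jitter) inside the cell
# ellipse; sizes the ellipse automatically when cfg$cell_axes_vox is NULL.
layout_columns <- function(cfg) {
  N <- cfg$n_columns
  g <- cfg$grid_pitch_vox
  r <- cfg$column_radius_vox
  k <- ceiling(sqrt(N) * 1.4) + 2L
  ij <- expand.grid(i = seq(-k, k), j = seq(-k, k))
  gx <- ij$i * g
  gy <- ij$j * g
  if (is.null(cfg$cell_axes_vox)) {
    # compact disk of the N grid sites closest to the centre
    ord <- order(gx^2 + gy^2, gy, gx)
    keep <- ord[seq_len(N)]
    gx <- gx[keep]; gy <- gy[keep]
    ext <- max(sqrt(gx^2 + gy^2))
    a <- b <- ext + r + 2
  } else {
    a <- cfg$cell_axes_vox[1]; b <- cfg$cell_axes_vox[2]
    fits <- ellipse_boundary_distance(gx, gy, 0, 0, a, b) >= r + 1
    if (sum(fits) < N) {
      stop_myo("cell ellipse holds only %d grid positions for %d columns", sum(fits), N)
    }
    ord <- order(!fits, gx^2 + gy^2, gy, gx)
    keep <- ord[seq_len(N)]
    gx <- gx[keep]; gy <- gy[keep]
  }
  # centre the coordinate frame so all voxel coordinates are positive
  cx <- a + r + 3
  cy <- b + r + 3
  jit <- matrix(runif(2L * N, -0.5, 0.5), ncol = 2L)
  list(x = gx + cx + jit[, 1L], y = gy + cy + jit[, 2L],
       cell = list(cx = cx, cy = cy, a = a, b = b))
}

#' Summary statistics of a ground-truth network
#'
#' Counts recorded events by type and expresses the totals per 10 sarcomere
#' intervals of the seed columns, the scale on which branch frequency is
#' reported for tracked myofibrils.
#'
#' @param net A `myo_network`.
#' @return A list with `n_events` (recorded events), per-type `counts`,
#'   `rate_per10` (branch ends encountered per 10 sarcomere intervals — a
#'   transfer or trade touches two columns and contributes two encounters)
#'   and the suppressed-event tally.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "myo_network"))
  ev <- net$events
  n_int <- net$config$n_columns * net$config$n_sarcomeres
  counts <- table(factor(ev$type, levels = c("split", "merge", "transfer", "trade")))
  touches <- counts[["split"]] + counts[["merge"]] +
    2L * (counts[["transfer"]] + counts[["trade"]])
  list(
    n_events = nrow(ev),
    counts = counts,
    rate_per10 = 10 * touches / n_int,
    suppressed = net$suppressed
  )
}

#' @export
print.myo_network <- function(x, ...) {
  st <- network_stats(x)
  cat(sprintf("<myo_network> %d columns x %d sarcomeres (%d slices), seed %d\n",
              x$config$n_columns, x$config$n_sarcomeres, x$n_slices, x$seed))
  cat(sprintf("  events: %d (split %d, merge %d, transfer %d, trade %d); %.2f per 10 sarcomeres\n",
              st$n_events, st$counts[["split"]], st$counts[["merge"]],
              st$counts[["transfer"]], st$counts[["trade"]], st$rate_per10))
  if (sum(x$suppressed) > 0) {
    cat("  suppressed:", paste(names(x$suppressed), x$suppressed, collapse = ", "), "\n")
  }
  invisible(x)
}
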