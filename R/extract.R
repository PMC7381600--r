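# Reconstruction of the sarcomere graph from a labeled volume.
#
# Consecutive-slice label overlaps define continuity; label transitions
# (fissions and fusions) are grouped into connected components and classified
# by their overlap signature. Column lineages ("chains") are carried through
# transitions by major-overlap inheritance: at a fission the child with the
# larger overlap continues the parent's lineage, at a fusion the product
# inherits the larger parent's lineage. A detached piece that fuses into a
# pre-existing adjacent lineage within the persistence window is a
# myofilament transfer; one that persists longer anchors a split at one end
# and a merge at the other. Reciprocal transfers between the same pair of
# lineages within the trade window are collapsed into a single trade.

#' Label overlap table between consecutive slices
#'
#' For slice `t` and `t + 1` (0-based), counts the voxels shared by each pair
#' of labels, keeping pairs with at least `min_overlap` shared voxels.
#'
#' @param bundle A `myo_bundle` (see [render_volume()] / [read_bundle()]).
#' @param t 0-based slice index, `0 <= t < n_slices - 1`.
#' @param min_overlap Minimum shared-voxel count; defaults to 4 scaled by
#'   `(50 / voxel_pitch_nm)^2`.
#' @return A data frame with columns `label_t`, `label_t1`, `voxels`.
#' @export
overlap_links <- function(bundle, t, min_overlap = default_min_overlap(bundle)) {
  nz <- dim(bundle$label_volume)[3L]
  if (t < 0 || t >= nz - 1L) stop_myo("slice index t = %d out of range [0, %d]", t, nz - 2L)
  overlap_pair(bundle$label_volume[, , t + 1L], bundle$label_volume[, , t + 2L], min_overlap)
}

overlap_pair <- function(a, b, min_overlap) {
  sel <- a > 0L & b > 0L
  if (!any(sel)) {
    return(data.frame(label_t = integer(), label_t1 = integer(), voxels = integer()))
  }
  key <- as.numeric(a[sel]) * 1e5 + as.numeric(b[sel])
  cnt <- table(key)
  kv <- as.numeric(names(cnt))
  out <- data.frame(label_t = as.integer(kv %/% 1e5),
                    label_t1 = as.integer(kv %% 1e5),
                    voxels = as.integer(cnt))
  out[out$voxels >= min_overlap, , drop = FALSE]
}

default_min_overlap <- function(bundle) {
  max(1L, as.integer(round(4 * (50 / bundle$voxel_pitch_nm)^2)))
}

#' Build the sarcomere graph from a labeled volume
#'
#' Scans the volume slice by slice, links labels by footprint overlap,
#' resolves column lineages through label changes (a one-to-one full-overlap
#' label change is a continuation, never an event), and classifies every
#' branch transition. Returns one node per (lineage, z-interval) with mean
#' area, centroid and membrane distance, serial edges across z-disks, and
#' the classified event table.
#'
#' @param bundle A `myo_bundle`.
#' @param min_overlap Minimum shared voxels for an overlap link.
#' @param taper_slices Slices over which event geometry develops; defaults
#'   to the value recorded in the bundle metadata, else 6.
#' @param persist_min_slices A fission child surviving at least this long is
#'   a split child rather than a transferring wedge; default `2 * taper`.
#' @param trade_window_slices Maximum slice distance for pairing reciprocal
#'   transfers into one trade; default `2 * taper`.
#' @param check_connectivity If `TRUE`, warn about label footprints that are
#'   not a single 4-connected region on a slice (possible segmentation
#'   error). Off by default (it is a full extra volume scan).
#' @param min_overlap_frac Transition links weaker than this fraction of the
#'   smaller participating footprint are treated as boundary-noise artifacts
#'   and ignored when grouping label transitions.
#' @return A `myo_graph`.
#' @export
build_graph <- function(bundle,
                        min_overlap = default_min_overlap(bundle),
                        taper_slices = NULL,
                        persist_min_slices = NULL,
                        trade_window_slices = NULL,
                        check_connectivity = FALSE,
                        min_overlap_frac = 0.35) {
  stopifnot(inherits(bundle, "myo_bundle"))
  taper <- taper_slices %||% (bundle$metadata$config$taper_slices %||% 6L)
  persist_min <- persist_min_slices %||% (2L * taper)
  trade_window <- trade_window_slices %||% (2L * taper)

  vol <- bundle$label_volume
  nsl <- dim(vol)[3L]
  bounds <- interval_bounds(bundle)

  sc <- scan_labels(vol)
  lab_stats <- sc$per_label # label, first, last
  per_slice <- sc$per_slice # slice, label, area, cx, cy

  if (check_connectivity) {
    warn_disconnected_footprints(vol, per_slice, lab_stats, taper)
  }

  # ---- transitions at every slice boundary -------------------------------
  chain_of <- integer(0) # names = label
  next_chain <- 0L
  new_chain <- function(lab) {
    next_chain <<- next_chain + 1L
    chain_of[as.character(lab)] <<- next_chain
    next_chain
  }
  for (lab in lab_stats$label[lab_stats$first == 0L]) new_chain(lab)

  fissions <- list(); fusions <- list(); ambiguous <- list()
  chain_birth <- list() # chain -> list(slice, fission_idx)
  chain_death <- list() # chain -> list(slice, fusion_idx)

  ps_area <- split(per_slice[, c("label", "area")], per_slice$slice)

  for (t in 0:(nsl - 2L)) {
    enders <- lab_stats$label[lab_stats$last == t]
    starters <- lab_stats$label[lab_stats$first == t + 1L]
    if (length(enders) == 0L && length(starters) == 0L) next
    ov <- overlap_pair(vol[, , t + 1L], vol[, , t + 2L], min_overlap)
    rel <- ov[ov$label_t %in% enders | ov$label_t1 %in% starters, , drop = FALSE]
    if (nrow(rel) > 0L) {
      # discard weak links (boundary-noise artifacts) relative to the
      # smaller footprint on either side
      a_t <- ps_area[[as.character(t)]]
      a_t1 <- ps_area[[as.character(t + 1L)]]
      sz_t <- a_t$area[match(rel$label_t, a_t$label)]
      sz_t1 <- a_t1$area[match(rel$label_t1, a_t1$label)]
      rel <- rel[rel$voxels >= min_overlap_frac * pmin(sz_t, sz_t1), , drop = FALSE]
    }

    # orphan starters: appear with no overlap support
    for (lab in setdiff(starters, rel$label_t1)) {
      new_chain(lab)
      ambiguous[[length(ambiguous) + 1L]] <-
        list(slice = t + 1L, labels = lab, note = "label appears without overlap")
    }
    for (lab in setdiff(enders, rel$label_t)) {
      ambiguous[[length(ambiguous) + 1L]] <-
        list(slice = t + 1L, labels = lab, note = "label ends without successor")
    }
    if (nrow(rel) == 0L) next

    # connected components of the bipartite transition graph
    comp <- components_bipartite(rel)
    for (cidx in seq_along(comp)) {
      rows <- rel[comp[[cidx]], , drop = FALSE]
      en <- unique(rows$label_t); en <- en[en %in% enders]
      st <- unique(rows$label_t1); st <- st[st %in% starters]
      others_t <- setdiff(unique(rows$label_t), en)
      others_t1 <- setdiff(unique(rows$label_t1), st)
      ne <- length(en); ns <- length(st)

      # continuing labels caught in the component (bystanders of a nearby
      # transition) do not change the signature of the enders/starters
      if (ne == 1L && ns == 1L) {
        chain_of[as.character(st)] <- chain_lookup(chain_of, en, new_chain)
      } else if (ne == 1L && ns >= 2L) {
        # fission: the child with the largest overlap continues the lineage,
        # every other child detaches as a new lineage
        ovs <- vapply(st, function(l) sum(rows$voxels[rows$label_t1 == l]), numeric(1))
        maj <- st[order(-ovs, st)][1L]
        pchain <- chain_lookup(chain_of, en, new_chain)
        chain_of[as.character(maj)] <- pchain
        for (mino in setdiff(st, maj)) {
          wchain <- new_chain(mino)
          fissions[[length(fissions) + 1L]] <-
            list(slice = t + 1L, parent_chain = pchain, minor_chain = wchain,
                 parent_label = en, major_label = maj, minor_label = mino)
          chain_birth[[as.character(wchain)]] <-
            list(slice = t + 1L, fission = length(fissions))
        }
      } else if (ne >= 2L && ns == 1L) {
        # fusion: the product inherits the largest parent's lineage, every
        # other parent lineage ends here
        ovs <- vapply(en, function(l) sum(rows$voxels[rows$label_t == l]), numeric(1))
        maj <- en[order(-ovs, en)][1L]
        mchain <- chain_lookup(chain_of, maj, new_chain)
        chain_of[as.character(st)] <- mchain
        for (mino in setdiff(en, maj)) {
          vchain <- chain_lookup(chain_of, mino, new_chain)
          fusions[[length(fusions) + 1L]] <-
            list(slice = t + 1L, product_chain = mchain, minor_chain = vchain,
                 major_label = maj, minor_label = mino, product_label = st)
          chain_death[[as.character(vchain)]] <-
            list(slice = t + 1L, fusion = length(fusions))
        }
      } else {
        for (lab in st) new_chain(lab)
        ambiguous[[length(ambiguous) + 1L]] <-
          list(slice = t + 1L, labels = c(en, st),
               note = sprintf("%d-to-%d transition", ne, ns))
      }
    }
  }

  # labels never assigned (isolated, no transitions)
  for (lab in setdiff(lab_stats$label, as.integer(names(chain_of)))) new_chain(lab)

  graph <- assemble_graph(bundle, bounds, per_slice, lab_stats, chain_of)
  graph$meta$transitions <- list(
    fissions = fissions, fusions = fusions, ambiguous = ambiguous,
    chain_birth = chain_birth, chain_death = chain_death,
    persist_min = persist_min, trade_window = trade_window,
    n_slices = nsl
  )
  graph$events <- classify_events(graph, bundle)
  drop_wedge_nodes(graph)
}

# transferring wedges are event apparatus, not sarcomere nodes: remove their
# lineages from the node table and rebuild ids and serial edges
drop_wedge_nodes <- function(graph) {
  ev <- graph$events
  wedges <- c(ev$bridge1[ev$type == "transfer"],
              ev$bridge1[ev$type == "trade"], ev$bridge2[ev$type == "trade"])
  wedges <- wedges[!is.na(wedges)]
  if (length(wedges) == 0L) return(graph)
  nodes <- graph$nodes[!(graph$nodes$col %in% wedges), ]
  nodes <- nodes[order(nodes$interval, nodes$col), ]
  nodes$node_id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL
  key <- paste(nodes$col, nodes$interval)
  id_of <- setNames(nodes$node_id, key)
  nxt <- paste(nodes$col, nodes$interval + 1L)
  has <- nxt %in% key
  graph$nodes <- nodes
  graph$serial <- data.frame(from = nodes$node_id[has], to = unname(id_of[nxt[has]]))
  graph
}

chain_lookup <- function(chain_of, lab, new_chain) {
  v <- chain_of[as.character(lab)]
  if (is.na(v)) new_chain(lab) else unname(v)
}

components_bipartite <- function(rel) {
  va <- paste0("a", rel$label_t)
  vb <- paste0("b", rel$label_t1)
  verts <- unique(c(va, vb))
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ia <- match(va, verts); ib <- match(vb, verts)
  for (r in seq_along(ia)) {
    ra <- find(ia[r]); rb <- find(ib[r])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(verts), find, integer(1))
  row_root <- roots[ia]
  split(seq_len(nrow(rel)), row_root)
}

# per-slice label areas/centroids and per-label slice spans
scan_labels <- function(vol) {
  nx <- dim(vol)[1L]; nsl <- dim(vol)[3L]
  acc <- vector("list", nsl)
  for (t in seq_len(nsl)) {
    sl <- vol[, , t]
    nz <- which(sl > 0L)
    if (length(nz) == 0L) next
    labs <- sl[nz]
    x <- ((nz - 1L) %% nx) + 0.5
    y <- ((nz - 1L) %/% nx) + 0.5
    agg <- rowsum(cbind(1, x, y), labs)
    acc[[t]] <- data.frame(slice = t - 1L,
                           label = as.integer(rownames(agg)),
                           area = agg[, 1L],
                           cx = agg[, 2L] / agg[, 1L],
                           cy = agg[, 3L] / agg[, 1L])
  }
  per_slice <- do.call(rbind, acc)
  if (is.null(per_slice)) stop_myo("label volume contains no labeled voxels")
  first <- tapply(per_slice$slice, per_slice$label, min)
  last <- tapply(per_slice$slice, per_slice$label, max)
  per_label <- data.frame(label = as.integer(names(first)),
                          first = as.integer(first),
                          last = as.integer(last))
  list(per_slice = per_slice, per_label = per_label)
}

interval_bounds <- function(bundle) {
  nsl <- dim(bundle$label_volume)[3L]
  zd <- sort(unique(as.integer(bundle$z_disk_slices)))
  if (length(zd) == 0L || zd[1L] != 0L) zd <- c(0L, zd)
  unique(c(zd, nsl))
}

assemble_graph <- function(bundle, bounds, per_slice, lab_stats, chain_of) {
  M <- length(bounds) - 1L
  per_slice$chain <- unname(chain_of[as.character(per_slice$label)])
  per_slice$interval <- findInterval(per_slice$slice, bounds, rightmost.closed = FALSE) - 1L
  key <- paste(per_slice$chain, per_slice$interval)
  agg <- rowsum(cbind(per_slice$area, per_slice$area * per_slice$cx,
                      per_slice$area * per_slice$cy, 1), key)
  parts <- strsplit(rownames(agg), " ")
  nodes <- data.frame(
    col = as.integer(vapply(parts, `[`, character(1), 1L)),
    interval = as.integer(vapply(parts, `[`, character(1), 2L)),
    area = agg[, 1L] / agg[, 4L],
    x = agg[, 2L] / agg[, 1L],
    y = agg[, 3L] / agg[, 1L]
  )
  # representative (first) label of the chain in that interval
  first_lab <- tapply(per_slice$label, key, function(l) l[1L])
  nodes$label <- as.integer(first_lab[paste(nodes$col, nodes$interval)])
  chain_first <- tapply(per_slice$slice, per_slice$chain, min)
  nodes$col_birth_slice <- as.integer(chain_first[as.character(nodes$col)])
  nodes <- nodes[order(nodes$interval, nodes$col), ]
  nodes$node_id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL

  nodes$memdist_um <- mask_boundary_distance(bundle$cell_mask, nodes$x, nodes$y) *
    bundle$voxel_pitch_nm / 1000

  nkey <- paste(nodes$col, nodes$interval)
  id_of <- setNames(nodes$node_id, nkey)
  nxt <- paste(nodes$col, nodes$interval + 1L)
  has <- nxt %in% nkey
  serial <- data.frame(from = nodes$node_id[has], to = unname(id_of[nxt[has]]))

  meta <- list(
    source = "extracted",
    seed = bundle$metadata$seed %||% NA_integer_,
    z_disks = bounds[-length(bounds)],
    n_slices = dim(bundle$label_volume)[3L],
    n_intervals = M,
    interval_len = stats::median(diff(bounds)),
    voxel_pitch_nm = bundle$voxel_pitch_nm,
    cell = bundle$metadata$cell %||% NULL,
    chain_map = chain_of
  )
  new_myo_graph(nodes, serial, empty_events(), meta)
}

#' Classify candidate branch transitions into typed events
#'
#' Applies the overlap-signature rules to the fission/fusion transitions
#' recorded by [build_graph()]: a fission whose detached child fuses into a
#' pre-existing adjacent lineage within the persistence window is one
#' transfer (donor = the fission parent, acceptor = the fusion survivor); a
#' longer-lived child anchors a split at the fission and a merge at the
#' fusion; reciprocal transfers between the same pair of lineages within the
#' trade window collapse into a single trade. Unmatched or malformed
#' transitions become events of type `"ambiguous"`, never silently dropped.
#'
#' @param graph A `myo_graph` from [build_graph()].
#' @param bundle The bundle the graph was built from.
#' @return An event data frame (one row per event).
#' @export
classify_events <- function(graph, bundle) {
  tr <- graph$meta$transitions
  if (is.null(tr)) stop_myo("graph carries no transition record; build it with build_graph()")
  bounds <- interval_bounds(bundle)
  persist_min <- tr$persist_min
  nsl <- tr$n_slices

  ev <- list()
  transfers <- list()
  used_fission <- logical(length(tr$fissions))
  used_fusion <- logical(length(tr$fusions))

  mk <- function(type, slice, col_a, col_b, b1, b2 = NA_integer_) {
    k <- findInterval(slice, bounds, rightmost.closed = FALSE) - 1L
    data.frame(event_id = NA_integer_, type = type, slice = slice,
               interval = k,
               phase_fraction = (slice - bounds[k + 1L]) / (bounds[k + 2L] - bounds[k + 1L]),
               col_a = col_a, col_b = col_b, bridge1 = b1, bridge2 = b2,
               stringsAsFactors = FALSE)
  }

  # pieces born at a fission: decide transfer vs split(+merge)
  for (fi in seq_along(tr$fissions)) {
    f <- tr$fissions[[fi]]
    w <- as.character(f$minor_chain)
    death <- tr$chain_death[[w]]
    if (!is.null(death)) {
      gi <- death$fusion
      g <- tr$fusions[[gi]]
      life <- g$slice - f$slice
      used_fission[fi] <- TRUE
      used_fusion[gi] <- TRUE
      if (life < persist_min) {
        transfers[[length(transfers) + 1L]] <-
          list(slice = f$slice, donor = f$parent_chain, acceptor = g$product_chain,
               wedge = f$minor_chain)
      } else {
        ev[[length(ev) + 1L]] <- mk("split", f$slice, f$parent_chain, NA_integer_, f$minor_chain)
        ev[[length(ev) + 1L]] <- mk("merge", g$slice, g$product_chain, NA_integer_, f$minor_chain)
      }
    } else {
      used_fission[fi] <- TRUE
      life <- nsl - f$slice
      if (life >= persist_min) {
        ev[[length(ev) + 1L]] <- mk("split", f$slice, f$parent_chain, NA_integer_, f$minor_chain)
      } else {
        ev[[length(ev) + 1L]] <- mk("ambiguous", f$slice, f$parent_chain, f$minor_chain, NA_integer_)
      }
    }
  }
  # fusions whose minor parent was not born at a fission (e.g. present from
  # the first slice): a plain merge
  for (gi in which(!used_fusion)) {
    g <- tr$fusions[[gi]]
    ev[[length(ev) + 1L]] <- mk("merge", g$slice, g$product_chain, NA_integer_, g$minor_chain)
  }

  # pair reciprocal transfers into trades
  if (length(transfers) > 0L) {
    tdf <- do.call(rbind, lapply(transfers, as.data.frame))
    tdf <- tdf[order(tdf$slice, tdf$donor), ]
    used <- logical(nrow(tdf))
    for (i in seq_len(nrow(tdf))) {
      if (used[i]) next
      j <- which(!used & seq_len(nrow(tdf)) > i &
                   tdf$donor == tdf$acceptor[i] & tdf$acceptor == tdf$donor[i] &
                   abs(tdf$slice - tdf$slice[i]) <= tr$trade_window)
      if (length(j) > 0L) {
        j <- j[1L]
        used[i] <- used[j] <- TRUE
        ev[[length(ev) + 1L]] <- mk("trade", min(tdf$slice[i], tdf$slice[j]),
                                    tdf$donor[i], tdf$donor[j],
                                    tdf$wedge[i], tdf$wedge[j])
      } else {
        used[i] <- TRUE
        ev[[length(ev) + 1L]] <- mk("transfer", tdf$slice[i], tdf$donor[i],
                                    tdf$acceptor[i], tdf$wedge[i])
      }
    }
  }
  # malformed transitions
  for (a in tr$ambiguous) {
    if (a$note %in% c("label ends without successor") && a$slice >= nsl - 1L) next
    ev[[length(ev) + 1L]] <- mk("ambiguous", a$slice, NA_integer_, NA_integer_, NA_integer_)
  }

  out <- if (length(ev) > 0L) do.call(rbind, ev) else empty_events()
  if (nrow(out) > 0L) {
    out <- out[order(out$slice, out$col_a), ]
    out$event_id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  out
}

#' Sarcomeric band of a branch event
#'
#' Maps the event's phase fraction within its z-interval to the sarcomeric
#' band partition used for annotation: z-disk-proximal `[0, 0.05) U
#' [0.95, 1)`, I-band `[0.05, 0.20) U [0.80, 0.95)`, A-band `[0.20, 0.45) U
#' [0.55, 0.80)`, H-zone `[0.45, 0.55)`. The fractions are a package
#' convention; the underlying observation is only that branch points occur
#' in all bands.
#'
#' @param phase_fraction Numeric vector of phase fractions in `[0, 1)`.
#' @return Character vector of band names.
#' @export
annotate_band <- function(phase_fraction) {
  stopifnot(all(phase_fraction >= 0 & phase_fraction < 1))
  p <- pmin(phase_fraction, 1 - phase_fraction) # fold around the sarcomere middle
  ifelse(p < 0.05, "z-disk-proximal",
         ifelse(p < 0.20, "I-band",
                ifelse(p < 0.45, "A-band", "H-zone")))
}

# Euclidean distance from points to the nearest cell-mask boundary pixel
mask_boundary_distance <- function(mask, x, y) {
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- mask
  inner <- pad[1:nx, 2:(ny + 1L)] & pad[3:(nx + 2L), 2:(ny + 1L)] &
    pad[2:(nx + 1L), 1:ny] & pad[2:(nx + 1L), 3:(ny + 2L)]
  boundary <- which(mask & !inner)
  bx <- ((boundary - 1L) %% nx) + 0.5
  by <- ((boundary - 1L) %/% nx) + 0.5
  vapply(seq_along(x), function(i) {
    sqrt(min((bx - x[i])^2 + (by - y[i])^2))
  }, numeric(1))
}

warn_disconnected_footprints <- function(vol, per_slice, lab_stats, taper) {
  for (i in seq_len(nrow(per_slice))) {
    row <- per_slice[i, ]
    st <- lab_stats[lab_stats$label == row$label, ]
    # skip taper windows at the ends of the label's life
    if (row$slice < st$first + taper || row$slice > st$last - taper) next
    sl <- vol[, , row$slice + 1L]
    if (count_components4(sl == row$label) > 1L) {
      warning(sprintf("label %d has multiple 4-connected regions on slice %d (possible segmentation error)",
                      row$label, row$slice), call. = FALSE)
    }
  }
}

# number of 4-connected components of a logical matrix (two-pass union-find)
count_components4 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  lab <- matrix(0L, nx, ny)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!m[i, j]) next
    up <- if (i > 1L && m[i - 1L, j]) lab[i - 1L, j] else 0L
    lf <- if (j > 1L && m[i, j - 1L]) lab[i, j - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else if (up > 0L && lf > 0L) {
      ru <- find(up); rl <- find(lf)
      if (ru != rl) parent[max(ru, rl)] <- min(ru, rl)
      lab[i, j] <- min(ru, rl)
    } else {
      lab[i, j] <- max(up, lf)
    }
  }
  if (nxt == 0L) return(0L)
  length(unique(vapply(seq_len(nxt), find, integer(1))))
}
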