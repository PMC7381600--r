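# File formats: multi-page 16-bit TIFF label volumes with a YAML sidecar
# (z-disk slices, voxel pitch, cell geometry, seed, config echo), node-link
# JSON graphs, and CSV event/metric tables. All round-trips are lossless.

#' Construct and validate a segmentation bundle
#'
#' The pipeline's input container: a labeled 3D volume (slice axis = fiber
#' long axis, 0 background, one label per myofibrillar segment), the z-disk
#' slice indices, the cell mask and the voxel pitch.
#'
#' @param label_volume Integer array `[x, y, slice]` of non-negative labels.
#' @param z_disk_slices Strictly increasing 0-based slice indices.
#' @param cell_mask Logical matrix matching the lateral dimensions.
#' @param voxel_pitch_nm Isotropic voxel size in nanometres.
#' @param metadata Optional named list (source, seed, config echo...).
#' @return A `myo_bundle`.
#' @export
segmentation_bundle <- function(label_volume, z_disk_slices, cell_mask,
                                voxel_pitch_nm = 50, metadata = list()) {
  if (length(dim(label_volume)) != 3L) stop_myo("label_volume must be a 3D array")
  storage.mode(label_volume) <- "integer"
  if (any(label_volume < 0L)) stop_myo("labels must be non-negative")
  nsl <- dim(label_volume)[3L]
  z <- as.integer(z_disk_slices)
  if (length(z) == 0L || any(diff(z) <= 0L)) stop_myo("z_disk_slices must be strictly increasing")
  if (z[1L] < 0L || z[length(z)] >= nsl) {
    stop_myo("z_disk_slices must lie in [0, %d]", nsl - 1L)
  }
  if (!identical(dim(cell_mask), dim(label_volume)[1:2])) {
    stop_myo("cell_mask dimensions %s do not match the volume's lateral dimensions %s",
             paste(dim(cell_mask), collapse = "x"),
             paste(dim(label_volume)[1:2], collapse = "x"))
  }
  outside <- label_volume > 0L & !as.vector(cell_mask)
  if (any(outside)) {
    stop_myo("%d labeled voxels lie outside the cell mask", sum(outside))
  }
  structure(list(label_volume = label_volume, z_disk_slices = z,
                 cell_mask = cell_mask, voxel_pitch_nm = voxel_pitch_nm,
                 metadata = metadata, label_map = NULL),
            class = "myo_bundle")
}

#' @export
print.myo_bundle <- function(x, ...) {
  d <- dim(x$label_volume)
  cat(sprintf("<myo_bundle> %d x %d x %d slices, %d labels, %d z-disks, %g nm/vox\n",
              d[1L], d[2L], d[3L], length(setdiff(unique(as.vector(x$label_volume)), 0L)),
              length(x$z_disk_slices), x$voxel_pitch_nm))
  invisible(x)
}

#' Write / read a segmentation bundle (TIFF + YAML sidecar)
#'
#' The label volume is stored as a multi-page 16-bit unsigned TIFF (slice
#' axis first), everything else in a YAML sidecar. `write_bundle` then
#' `read_bundle` is voxel-identical.
#'
#' @param bundle A `myo_bundle`.
#' @param volume_path Path of the `.tif` file.
#' @param meta_path Path of the YAML sidecar; defaults to `volume_path` with
#'   a `.yml` extension.
#' @return `read_bundle` returns a `myo_bundle`; `write_bundle` the paths,
#'   invisibly.
#' @export
write_bundle <- function(bundle, volume_path, meta_path = sidecar_path(volume_path)) {
  stopifnot(inherits(bundle, "myo_bundle"))
  vol <- bundle$label_volume
  if (max(vol) > 65535L) stop_myo("labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(vol)[3L]), function(t) vol[, , t] / 65535)
  tiff::writeTIFF(pages, volume_path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    n_slices = dim(vol)[3L],
    dim_x = dim(vol)[1L], dim_y = dim(vol)[2L],
    z_disk_slices = as.integer(bundle$z_disk_slices),
    voxel_pitch_nm = bundle$voxel_pitch_nm,
    cell_mask_rle = mask_to_rle(bundle$cell_mask),
    metadata = serialize_meta(bundle$metadata)
  )
  yaml::write_yaml(meta, meta_path)
  invisible(c(volume = volume_path, meta = meta_path))
}

#' @rdname write_bundle
#' @export
read_bundle <- function(volume_path, meta_path = sidecar_path(volume_path)) {
  if (!file.exists(volume_path)) stop_myo("volume file not found: %s", volume_path)
  if (!file.exists(meta_path)) stop_myo("metadata sidecar not found: %s", meta_path)
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(volume_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_slices) {
    stop_myo("%s: slice count mismatch — TIFF has %d pages, sidecar declares n_slices = %d (truncated file?)",
             volume_path, length(pages), meta$n_slices)
  }
  vol <- array(0L, dim = c(meta$dim_x, meta$dim_y, meta$n_slices))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (!identical(dim(pg)[1:2], c(meta$dim_x, meta$dim_y))) {
      stop_myo("%s: page %d is %s, sidecar declares %dx%d",
               volume_path, t, paste(dim(pg), collapse = "x"), meta$dim_x, meta$dim_y)
    }
    vol[, , t] <- as.integer(pg)
  }
  segmentation_bundle(
    vol, meta$z_disk_slices,
    rle_to_mask(meta$cell_mask_rle, meta$dim_x, meta$dim_y),
    voxel_pitch_nm = meta$voxel_pitch_nm,
    metadata = meta$metadata %||% list()
  )
}

sidecar_path <- function(volume_path) {
  paste0(tools::file_path_sans_ext(volume_path), ".yml")
}

mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  list(lengths = as.integer(r$lengths), values = as.logical(r$values))
}

rle_to_mask <- function(r, nx, ny) {
  v <- inverse.rle(structure(list(lengths = as.integer(unlist(r$lengths)),
                                  values = as.logical(unlist(r$values))),
                             class = "rle"))
  if (length(v) != nx * ny) stop_myo("cell mask run-length data does not match %dx%d", nx, ny)
  matrix(v, nx, ny)
}

# YAML-safe flattening of the metadata list (drops non-scalar entries like
# the full config object down to its scalar fields)
serialize_meta <- function(md) {
  flat <- lapply(md, function(x) {
    if (is.list(x)) lapply(x, function(y) if (is.atomic(y) && length(y) <= 8L) y else NULL)
    else if (is.atomic(x)) x else NULL
  })
  flat[!vapply(flat, is.null, logical(1))]
}

#' Write / read a sarcomere graph as node-link JSON
#'
#' @param graph A `myo_graph`.
#' @param path JSON file path.
#' @return `read_graph` returns a `myo_graph`; round-trips preserve all
#'   node, edge and event attributes (the transition record used only
#'   during classification is not serialized).
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "myo_graph"))
  meta <- graph$meta
  meta$transitions <- NULL
  meta$chain_map <- NULL
  meta$config <- NULL
  obj <- list(nodes = graph$nodes, links = graph$serial,
              events = graph$events, meta = meta)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop_myo("graph file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  events <- if (length(obj$events) > 0L) as.data.frame(obj$events) else empty_events()
  for (cn in c("col_a", "col_b", "bridge1", "bridge2")) {
    if (cn %in% names(events)) events[[cn]] <- as.integer(events[[cn]])
  }
  serial <- if (length(obj$links) > 0L) as.data.frame(obj$links) else
    data.frame(from = integer(), to = integer())
  meta <- obj$meta
  meta$z_disks <- as.integer(unlist(meta$z_disks))
  new_myo_graph(nodes, serial, events, meta)
}

#' Write / read event and metric tables as CSV
#'
#' @param events,metrics Data frames as produced by the pipeline.
#' @param path CSV file path.
#' @return The read functions return the data frame; writers the path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_myo("event file not found: %s", path)
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "type", "slice")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0L) {
    stop_myo("%s: missing required event columns: %s", path, paste(miss, collapse = ", "))
  }
  ev
}

#' @rdname write_events
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop_myo("metrics file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a generator configuration from a YAML file
#'
#' A declarative key-value file whose keys are [generator_config()]
#' arguments; unknown keys are an error naming the offending field.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read (e.g. CLI flags).
#' @return A `myo_config`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop_myo("config file not found: %s", path)
  kv <- yaml::read_yaml(path)
  over <- list(...)
  kv[names(over)] <- over
  known <- names(formals(generator_config))
  preset <- kv$preset
  kv$preset <- NULL
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0L) {
    stop_myo("%s: unknown config field(s): %s (expected among: %s)",
             path, paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }
  if (!is.null(preset)) do.call(muscle_preset, c(list(name = preset), kv))
  else do.call(generator_config, kv)
}
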