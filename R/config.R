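#' Generator configuration for synthetic myofibrillar networks
#'
#' Describes the stochastic model from which ground-truth branching networks
#' are sampled and rendered: a bundle of parallel sarcomere columns laid on a
#' jittered grid inside an elliptical cell cross-section, with regularly
#' spaced z-disks and per-sarcomere branch events of three kinds (splits,
#' myofilament transfers, and bidirectional trades).
#'
#' The event probabilities are expressed on the scale on which branch
#' frequency is measured: `p_split + p_transfer + p_trade` is the expected
#' number of branch events *encountered per sarcomere* by a myofibril track
#' (so 10 times the sum is the branches-per-10-sarcomeres frequency). Every
#' physical branch has two anchoring ends — a split on one myofibril and,
#' further along the fiber, a merge where the detached bridge rejoins a
#' neighbouring column, or the donor and acceptor side of a transfer — so the
#' generator initiates events at half these rates and records both ends.
#'
#' @param n_columns Number of parallel sarcomere columns (myofibrils) seeded
#'   at the first slice.
#' @param n_sarcomeres Serial sarcomeres per column.
#' @param p_split,p_transfer,p_trade Per-sarcomere, per-column encounter
#'   probabilities of each event class; their sum must be in `[0, 1]`.
#' @param grid_pitch_vox Centre-to-centre column spacing in voxels.
#' @param column_radius_vox Nominal column cross-section radius in voxels
#'   (must be at least 2).
#' @param sarcomere_len_slices Slices per sarcomere, i.e. the z-disk spacing.
#' @param cell_axes_vox Semi-axes `c(a, b)` of the elliptical cell mask, or
#'   `NULL` to size the ellipse automatically around the column grid.
#' @param voxel_pitch_nm Isotropic voxel size in nanometres.
#' @param jitter_sd_vox Standard deviation of per-slice boundary jitter
#'   applied when rendering.
#' @param taper_slices Slices over which an event's geometry develops (the
#'   time a detached wedge takes to cross to its acceptor column).
#' @param seed Default RNG seed recorded in the config; `sample_network()`
#'   takes an explicit seed that overrides it.
#' @param muscle_type Optional label recorded in outputs.
#'
#' @return An object of class `myo_config` (a named list).
#' @seealso [muscle_preset()] for configurations calibrated to published
#'   branch frequencies of specific muscle types.
#' @export
generator_config <- function(n_columns = 100,
                             n_sarcomeres = 25,
                             p_split = 0.10,
                             p_transfer = 0.04,
                             p_trade = 0.01,
                             grid_pitch_vox = 13,
                             column_radius_vox = 5,
                             sarcomere_len_slices = 40,
                             cell_axes_vox = NULL,
                             voxel_pitch_nm = 50,
                             jitter_sd_vox = 0.5,
                             taper_slices = 6,
                             seed = 1L,
                             muscle_type = NA_character_) {
  cfg <- list(
    n_columns = as.integer(n_columns),
    n_sarcomeres = as.integer(n_sarcomeres),
    p_split = p_split,
    p_transfer = p_transfer,
    p_trade = p_trade,
    grid_pitch_vox = grid_pitch_vox,
    column_radius_vox = column_radius_vox,
    sarcomere_len_slices = as.integer(sarcomere_len_slices),
    cell_axes_vox = cell_axes_vox,
    voxel_pitch_nm = voxel_pitch_nm,
    jitter_sd_vox = jitter_sd_vox,
    taper_slices = as.integer(taper_slices),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    muscle_type = muscle_type
  )
  class(cfg) <- "myo_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a [generator_config()]: probabilities
#' in range, geometric feasibility of the column grid inside the cell
#' ellipse, and enough slices per sarcomere for event geometry to develop.
#'
#' @param cfg A `myo_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "myo_config"))
  p <- c(cfg$p_split, cfg$p_transfer, cfg$p_trade)
  if (any(p < 0) || sum(p) > 1) {
    stop_myo("event probabilities must be non-negative with sum <= 1 (got sum %.3f)", sum(p))
  }
  if (cfg$n_columns < 1L) stop_myo("n_columns must be >= 1")
  if (cfg$n_sarcomeres < 1L) stop_myo("n_sarcomeres must be >= 1")
  if (cfg$column_radius_vox < 2) stop_myo("column_radius_vox must be >= 2")
  if (cfg$grid_pitch_vox <= 2 * cfg$column_radius_vox) {
    stop_myo("grid_pitch_vox (%.1f) must exceed the column diameter (%.1f) so footprints never overlap",
             cfg$grid_pitch_vox, 2 * cfg$column_radius_vox)
  }
  if (cfg$taper_slices < 3L) stop_myo("taper_slices must be >= 3")
  if (cfg$sarcomere_len_slices < 4L * cfg$taper_slices) {
    stop_myo("sarcomere_len_slices (%d) must be >= 4 * taper_slices (%d)",
             cfg$sarcomere_len_slices, 4L * cfg$taper_slices)
  }
  # bridge lifetime 2T+2..2T+8 plus crossing must fit in one sarcomere
  if (cfg$sarcomere_len_slices < 3L * cfg$taper_slices + 12L) {
    stop_myo("sarcomere_len_slices (%d) too short for bridge geometry; need >= 3*taper_slices + 12",
             cfg$sarcomere_len_slices)
  }
  if (!is.null(cfg$cell_axes_vox)) {
    if (length(cfg$cell_axes_vox) != 2L || any(cfg$cell_axes_vox <= 0)) {
      stop_myo("cell_axes_vox must be two positive semi-axes")
    }
    need <- cfg$n_columns * pi * cfg$column_radius_vox^2
    have <- pi * prod(cfg$cell_axes_vox)
    if (need > have) {
      stop_myo("cell ellipse area (%.0f vox^2) cannot hold %d columns of radius %.1f (need %.0f vox^2)",
               have, cfg$n_columns, cfg$column_radius_vox, need)
    }
  }
  invisible(cfg)
}

# Published per-10-sarcomere branch frequencies, transfer shares (% of all
# branches that are transfers/trades), percent-branched values and
# myofibril/sarcomere counts per muscle type. The postnatal myofibril and
# sarcomere totals follow the Results text (early 150/1401, late 141/1796);
# the corresponding figure legend swaps the two readings. Transfer shares for
# the postnatal stages and the trade fraction everywhere are package
# assumptions (15% and 20% of transfer-class events, respectively), as no
# published values exist.
.preset_table <- function() {
  data.frame(
    name = c("fast_twitch", "slow_twitch", "cardiac",
             "postnatal_early", "postnatal_late", "human_fast"),
    freq_per10 = c(1.6, 4.3, 2.2, 2.8, 1.3, 2.4),
    transfer_share_pct = c(34.8, 15.2, 13.8, 15.0, 15.0, 34.8),
    pct_branched = c(96.1, 99.4, 94.4, 97.9, 70.0, 100.0),
    n_myofibrils = c(193L, 110L, 167L, 150L, 141L, 60L),
    n_sarcomeres_total = c(3477L, 1396L, 2114L, 1401L, 1796L, 906L),
    stringsAsFactors = FALSE
  )
}

#' Muscle-type presets calibrated to published branch frequencies
#'
#' Returns a [generator_config()] whose total per-sarcomere event probability
#' times ten equals the published branches-per-10-sarcomeres frequency for
#' the given muscle type, whose transfer share matches the published
#' percentage of branches due to myofilament transfers, and whose column and
#' sarcomere counts match the published per-volume tracking totals
#' (myofibrils tracked, and mean track length rounded to whole sarcomeres).
#'
#' Presets: `fast_twitch` (1.6/10, 34.8% transfers, 193 myofibrils x 18
#' sarcomeres), `slow_twitch` (4.3/10, 15.2%, 110 x 13), `cardiac` (2.2/10,
#' 13.8%, 167 x 13), `postnatal_early` (2.8/10, 150 x 9), `postnatal_late`
#' (1.3/10, 141 x 13), `human_fast` (2.4/10, 60 x 15). Transfer shares for
#' the postnatal stages (15%) and the trade fraction (20% of transfer-class
#' events) are package assumptions.
#'
#' @param name One of `"fast_twitch"`, `"slow_twitch"`, `"cardiac"`,
#'   `"postnatal_early"`, `"postnatal_late"`, `"human_fast"`.
#' @param ... Overrides passed on to [generator_config()] (e.g. a smaller
#'   `n_columns` for desk-scale rendering).
#' @return A `myo_config`.
#' @export
#' @examples
#' cfg <- muscle_preset("slow_twitch")
#' 10 * (cfg$p_split + cfg$p_transfer + cfg$p_trade) # 4.3
muscle_preset <- function(name, ...) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1L || !(name %in% tab$name)) {
    stop_myo("unknown muscle preset %s; valid presets: %s",
             deparse(substitute(name)), paste(tab$name, collapse = ", "))
  }
  row <- tab[tab$name == name, ]
  total <- row$freq_per10 / 10
  share <- row$transfer_share_pct / 100
  trade_frac <- 0.2
  args <- list(
    n_columns = row$n_myofibrils,
    n_sarcomeres = as.integer(round(row$n_sarcomeres_total / row$n_myofibrils)),
    p_split = total * (1 - share),
    p_transfer = total * share * (1 - trade_frac),
    p_trade = total * share * trade_frac,
    muscle_type = name
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' @export
print.myo_config <- function(x, ...) {
  cat("<myo_config>", if (!is.na(x$muscle_type)) paste0("[", x$muscle_type, "]"), "\n")
  cat(sprintf("  columns: %d   sarcomeres: %d   (%d slices @ %g nm/vox)\n",
              x$n_columns, x$n_sarcomeres,
              x$n_columns * 0L + x$n_sarcomeres * x$sarcomere_len_slices,
              x$voxel_pitch_nm))
  cat(sprintf("  p_split: %.4f  p_transfer: %.4f  p_trade: %.4f  (%.2f branches / 10 sarcomeres)\n",
              x$p_split, x$p_transfer, x$p_trade,
              10 * (x$p_split + x$p_transfer + x$p_trade)))
  cat(sprintf("  grid pitch: %g  radius: %g  taper: %d  jitter sd: %g\n",
              x$grid_pitch_vox, x$column_radius_vox, x$taper_slices, x$jitter_sd_vox))
  invisible(x)
}
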