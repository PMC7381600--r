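#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov rnorm runif setNames pf ptukey TukeyHSD dist
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic raster order of 2D points: row-major on rounded centroids
# (y first, then x), invariant to input ordering and label permutation.
raster_order <- function(x, y) {
  order(round(y, 6), round(x, 6))
}

# Distance (vox) from points to the boundary of an axis-aligned ellipse
# centred at (cx, cy) with semi-axes (a, b), measured along the centre ray.
# Positive inside. A documented approximation of the true Euclidean distance,
# exact for circles.
ellipse_boundary_distance <- function(x, y, cx, cy, a, b) {
  dx <- x - cx
  dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  rho <- sqrt((dx / a)^2 + (dy / b)^2)
  out <- numeric(length(x))
  ctr <- rho < 1e-9
  out[ctr] <- min(a, b)
  nz <- !ctr
  # ray length from centre to boundary in this direction
  out[nz] <- r[nz] * (1 / rho[nz] - 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_myo <- function(...) stop(sprintf(...), call. = FALSE)
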