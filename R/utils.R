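# Internal helpers: argument checks, seeded evaluation, voxel geometry.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package internals do
#' not perturb user-level random streams. A `NULL` seed evaluates the
#' expression with the current stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Voxel volume in ml; spacing in mm (1 ml = 1000 mm^3).
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

# Linear index <-> (i, j, k) coordinate conversion for a 3-D array.
coord_to_linear <- function(coord, dims) {
  (coord[, 3] - 1) * dims[1] * dims[2] + (coord[, 2] - 1) * dims[1] + coord[, 1]
}

# Neighbour offsets for 6- or 26-connectivity.
neighbor_offsets <- function(connectivity = 26) {
  assert_that(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

# Offsets spanning a sphere of `volume_ml` around a voxel centre, on an
# anisotropic grid; membership by voxel-centre distance in mm.
sphere_offsets <- function(spacing, volume_ml = 1.0) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  rng <- lapply(spacing, function(s) seq(-ceiling(r / s), ceiling(r / s)))
  g <- as.matrix(expand.grid(di = rng[[1]], dj = rng[[2]], dk = rng[[3]]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g[d2 <= r^2, , drop = FALSE]
}
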