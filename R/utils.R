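# Internal helpers: seeding, interpolation, small geometry.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream derivation: mixes a base seed with up to three
# indices so that e.g. adding neurons to a cohort never changes the draws
# of existing trials. All arithmetic kept below 2^31 via modular reduction.
derive_seed <- function(seed, i = 0L, j = 0L, k = 0L) {
  m <- 2147483629
  s <- as.numeric(seed) %% m
  for (x in c(i, j, k)) {
    s <- (s * 48271 + as.numeric(x) * 16807 + 11) %% m
  }
  as.integer(s) + 1L
}

deg2rad <- function(d) d * pi / 180

# Unit vector for a direction in degrees CCW from +x.
unit_vec <- function(direction_deg) {
  a <- deg2rad(direction_deg)
  c(cos(a), sin(a))
}

# Bilinear interpolation of a matrix `map` defined on regular grids gx, gy
# (map[i, j] = value at gx[i], gy[j]) at arbitrary query points. Queries are
# clamped to the grid boundary. Vectorized over queries.
bilinear_interp <- function(map, gx, gy, px, py) {
  nx <- length(gx); ny <- length(gy)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  fx <- (px - gx[1]) / dx
  fy <- (py - gy[1]) / dy
  fx <- pmin(pmax(fx, 0), nx - 1)
  fy <- pmin(pmax(fy, 0), ny - 1)
  i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  v00 <- map[cbind(i0 + 1L, j0 + 1L)]
  v10 <- map[cbind(i0 + 2L, j0 + 1L)]
  v01 <- map[cbind(i0 + 1L, j0 + 2L)]
  v11 <- map[cbind(i0 + 2L, j0 + 2L)]
  v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
    v01 * (1 - tx) * ty + v11 * tx * ty
}

`%||%` <- function(a, b) if (is.null(a)) b else a
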