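# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371.0088 km (mean Earth radius).
#' Differences from ellipsoidal distances are sub-metre at the scales used
#' for site pooling.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distances in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Run code with a temporarily fixed RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic Latin-hypercube-style start points in [0,1]^d (n x d).
# Stratified midpoints with fixed coprime stride permutations, so multistart
# optimisation is reproducible without touching the RNG.
lhs_starts <- function(n, d) {
  strides <- c(1L, 7L, 11L, 13L, 17L, 19L, 23L, 29L)
  out <- matrix(0, n, d)
  for (j in seq_len(d)) {
    s <- strides[((j - 1L) %% length(strides)) + 1L]
    perm <- order((seq_len(n) * s) %% n + seq_len(n) / (n + 1))
    out[, j] <- (perm - 0.5) / n
  }
  out
}
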