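# Internal helpers shared across modules.

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# 0-based circular position -> 1-based R index.
pos_to_idx <- function(pos, len) {
  (as.integer(pos) %% len) + 1L
}

# Circular (shortest-arc) distance between 0-based positions.
circ_dist <- function(a, b, len) {
  d <- abs(((a - b) %% len))
  pmin(d, len - d)
}

# Arc length travelled from `from` to `to` going clockwise (increasing
# coordinates) on a circle of length `len`.
arc_cw <- function(from, to, len) {
  (to - from) %% len
}

# Indices (1-based) of the circular window [start0, start0 + width) given in
# 0-based coordinates.
window_idx <- function(start0, width, len) {
  pos_to_idx(seq.int(start0, length.out = width), len)
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", what, "` must be a single positive number"))
  }
}

check_position <- function(pos, len, what = "position") {
  if (any(!is.finite(pos)) || any(pos < 0) || any(pos >= len)) {
    abort(paste0("`", what, "` must lie in [0, genome length)"))
  }
}

# Cluster sorted numeric positions: new cluster whenever the gap to the
# previous position exceeds `gap`. Returns integer cluster ids.
cluster_positions <- function(pos, gap) {
  if (length(pos) == 0L) return(integer(0))
  c(0L, cumsum(diff(pos) > gap)) + 1L
}
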