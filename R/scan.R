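# Shared template-scanning machinery: Pearson correlation of a fixed
# template against circular windows at a regular step, computed with
# running sums (no per-window cor() calls).

# Correlate `template` with every window of `x` starting at 0, step, 2*step,
# ... (0-based, circular). Windows whose values are constant get r = 0 by
# convention (a flat window cannot match a structured template).
# Returns a tibble: start, center (0-based), r.
window_scan_corr <- function(x, template, step = 100) {
  len <- length(x)
  w <- length(template)
  if (w > len) abort("template longer than the track")
  tv <- as.numeric(template)
  t_mean <- mean(tv)
  t_ss <- sum((tv - t_mean)^2)
  if (t_ss <= 0) abort("template must not be constant")
  starts0 <- seq.int(0L, len - 1L, by = as.integer(step))
  xp <- c(as.numeric(x), as.numeric(x[seq_len(w)]))
  n <- length(starts0)
  S <- numeric(n); Sxx <- numeric(n); Sxt <- numeric(n)
  for (j in seq_len(w)) {
    v <- xp[starts0 + j]
    S <- S + v
    Sxx <- Sxx + v * v
    Sxt <- Sxt + v * tv[j]
  }
  num <- Sxt - S * t_mean
  varx <- pmax(Sxx - S * S / w, 0)
  den <- sqrt(varx * t_ss)
  r <- ifelse(den <= 1e-12 * max(1, abs(t_ss)), 0, num / den)
  r <- pmin(1, pmax(-1, r))
  tibble(start = starts0, center = starts0 + w %/% 2L, r = r)
}

# Merge candidate windows whose centers lie within `merge_distance` of each
# other (single linkage on the sorted centers, circular at the ends),
# keeping the maximum-r window per cluster; ties break to the smaller
# coordinate. Order-independent by construction.
merge_windows <- function(cand, merge_distance, genome_length = NULL) {
  if (nrow(cand) == 0L) return(cand)
  cand <- dplyr::arrange(cand, .data$center, dplyr::desc(.data$r))
  id <- cluster_positions(cand$center, merge_distance)
  # circular join of first and last cluster
  if (!is.null(genome_length) && max(id) > 1L) {
    wrap_gap <- genome_length - (max(cand$center) - min(cand$center))
    if (wrap_gap <= merge_distance) id[id == max(id)] <- 1L
  }
  cand$.cluster <- id
  out <- dplyr::slice_max(dplyr::group_by(cand, .data$.cluster),
                          order_by = .data$r, n = 1, with_ties = FALSE)
  out <- dplyr::ungroup(out)
  out$.cluster <- NULL
  dplyr::arrange(out, .data$center)
}

# Maximum of `values` over the circular window [center - half, center + half)
# for each center; masked positions (mask TRUE) are ignored. Returns NA when
# the whole window is masked.
window_max <- function(values, centers, half, mask = NULL) {
  len <- length(values)
  vapply(centers, function(c0) {
    idx <- window_idx(c0 - half, 2L * half, len)
    v <- values[idx]
    if (!is.null(mask)) v <- v[!mask[idx]]
    if (length(v) == 0L) NA_real_ else max(v)
  }, numeric(1))
}

# TRUE where the window around each center touches a masked position.
window_touches_mask <- function(mask, centers, half) {
  if (is.null(mask)) return(rep(FALSE, length(centers)))
  len <- length(mask)
  vapply(centers, function(c0) {
    any(mask[window_idx(c0 - half, 2L * half, len)])
  }, logical(1))
}
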