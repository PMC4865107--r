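# Marker-frequency analysis of replication, segmented breakpoint fitting,
# fork distances on the circular genome, and the replication-coupled
# "comet" occupancy null model.

#' Marker-frequency track
#'
#' Binned ratio of a replicating sample's input coverage to a
#' non-replicating reference, rescaled so the lowest-decile bins average 1
#' (the unreplicated baseline). Slope changes of the profile mark
#' replication-fork positions in synchronized populations. When the raw
#' (pre-rescale) profile is already flat the track is flagged
#' `fully_replicated` (a G2 population has uniformly doubled content, which
#' marker frequency cannot distinguish from G1).
#'
#' @param sample_input,reference_input [stranded_profile()]s; RPM
#'   normalization is applied internally.
#' @param bin Bin size in bp (default 10 kb).
#' @return A list of class `mf_track`: `values`, `bin_size`, `centers`,
#'   `fully_replicated`, `genome`.
#' @export
marker_frequency <- function(sample_input, reference_input, bin = 10000) {
  s <- bin_means(combine_strands(rpm_normalize(sample_input)), bin)
  r <- bin_means(combine_strands(rpm_normalize(reference_input)), bin)
  bad <- r <= 0
  v <- ifelse(bad, NA_real_, s / r)
  low <- quantile(v, 0.1, na.rm = TRUE)
  baseline <- mean(v[!is.na(v) & v <= low])
  flat <- (max(v, na.rm = TRUE) / min(v, na.rm = TRUE)) < 1.1
  v <- v / baseline
  structure(list(values = v, bin_size = as.integer(bin),
                 centers = (seq_along(v) - 1L) * as.integer(bin) +
                   as.integer(bin) %/% 2L,
                 fully_replicated = flat,
                 genome = sample_input$genome),
            class = "mf_track")
}

#' @export
print.mf_track <- function(x, ...) {
  cat(sprintf("<mf_track> %d bins of %d bp%s\n", length(x$values),
              x$bin_size,
              if (x$fully_replicated) " (flat: fully replicated or G1)" else ""))
  invisible(x)
}

#' @export
tidy.mf_track <- function(x, ...) {
  tibble(position = x$centers, marker_frequency = x$values)
}

# RSS of the least-squares line on y[i..j] for all intervals, via
# cumulative sums; returns a function rss(i, j) (1-based, inclusive).
make_interval_rss <- function(x, y) {
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cxy <- c(0, cumsum(x * y))
  cyy <- c(0, cumsum(y * y))
  function(i, j) {
    n <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    syy <- cyy[j + 1] - cyy[i]
    vxx <- sxx - sx * sx / n
    vxy <- sxy - sx * sy / n
    vyy <- syy - sy * sy / n
    ifelse(vxx <= 1e-12, pmax(vyy, 0), pmax(vyy - vxy * vxy / vxx, 0))
  }
}

#' Detect slope breakpoints in a marker-frequency profile
#'
#' Fits a segmented least-squares model (free line per segment, optimal
#' breakpoints by dynamic programming at bin resolution) to the circular
#' track cut at the dif site, and reports the breakpoint positions where
#' the slope changes. A track that a single line fits essentially as well
#' (relative RSS reduction below `min_improvement`) reports no breakpoints.
#'
#' @param mf An [marker_frequency()] track.
#' @param n_breaks Number of breakpoints to fit (default 2: one fork per
#'   replichore).
#' @param min_improvement Minimum relative RSS reduction over the
#'   single-segment fit for the breakpoints to be reported.
#' @return A list of class `breakpoint_fit`: `breakpoints` (0-based genome
#'   coordinates, sorted), `segment_slopes`, `rss`, `rss_null`, `n_breaks`.
#' @export
detect_slope_breaks <- function(mf, n_breaks = 2, min_improvement = 0.05) {
  v <- mf$values
  nb <- as.integer(n_breaks)
  if (length(v) < 3 * (nb + 1)) abort("too few bins for the requested breaks")
  len <- mf$genome$length
  nbin <- length(v)
  # rotate so the track starts at dif (cut the circle far from the forks)
  cut_bin <- (mf$genome$dif %/% mf$bin_size) %% nbin
  ord <- ((seq_len(nbin) - 1L + cut_bin) %% nbin) + 1L
  y <- v[ord]
  ok <- !is.na(y)
  y[!ok] <- mean(y[ok])
  x <- seq_len(nbin)
  rss <- make_interval_rss(x, y)
  min_seg <- 3L
  # DP over segment ends: best[k, j] = min RSS of k segments covering 1..j
  best <- matrix(Inf, nb + 1L, nbin)
  back <- matrix(0L, nb + 1L, nbin)
  js <- seq_len(nbin)
  best[1L, ] <- rss(rep(1L, nbin), js)
  for (k in seq_len(nb)) {
    for (j in seq.int(k * min_seg + min_seg, nbin)) {
      i_opts <- seq.int(k * min_seg, j - min_seg)
      tot <- best[k, i_opts] + rss(i_opts + 1L, rep(j, length(i_opts)))
      m <- which.min(tot)
      best[k + 1L, j] <- tot[m]
      back[k + 1L, j] <- i_opts[m]
    }
  }
  rss_null <- best[1L, nbin]
  rss_fit <- best[nb + 1L, nbin]
  if (!is.finite(rss_fit) ||
      rss_null < 1e-10 * max(1, sum(y^2)) ||
      (rss_null - rss_fit) / rss_null < min_improvement) {
    return(structure(list(breakpoints = numeric(0), segment_slopes = numeric(0),
                          rss = rss_null, rss_null = rss_null, n_breaks = 0L,
                          genome = mf$genome),
                     class = "breakpoint_fit"))
  }
  bounds <- integer(nb)
  j <- nbin
  for (k in rev(seq_len(nb))) {
    bounds[k] <- back[k + 1L, j]
    j <- bounds[k]
  }
  seg_edges <- c(0L, bounds, nbin)
  slopes <- vapply(seq_len(nb + 1L), function(s) {
    i <- seg_edges[s] + 1L; j2 <- seg_edges[s + 1L]
    coef(lm(y[i:j2] ~ x[i:j2]))[2]
  }, numeric(1))
  # bin index (rotated) -> genome coordinate of the bin boundary
  bp <- sort(((bounds + cut_bin) %% nbin) * mf$bin_size)
  structure(list(breakpoints = bp, segment_slopes = unname(slopes),
                 rss = rss_fit, rss_null = rss_null, n_breaks = nb,
                 genome = mf$genome),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$n_breaks == 0L) {
    cat("<breakpoint_fit> no breakpoints (profile fits a single line)\n")
  } else {
    cat(sprintf("<breakpoint_fit> %d breakpoint(s) at %s; rss %.4g (null %.4g)\n",
                x$n_breaks,
                paste(format(x$breakpoints, big.mark = ","), collapse = ", "),
                x$rss, x$rss_null))
  }
  invisible(x)
}

#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble(breakpoint = x$breakpoints)
}

#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble(n_breaks = x$n_breaks, rss = x$rss, rss_null = x$rss_null,
         improvement = ifelse(x$rss_null > 0, 1 - x$rss / x$rss_null, 0))
}

#' Replichore distances from oriC to two fork positions
#'
#' Arc distances along the two replichores from the origin to each
#' breakpoint; errors when both breakpoints map to the same replichore
#' (each fork travels its own arm).
#'
#' @param breakpoints Two 0-based genome positions.
#' @param oriC Origin coordinate.
#' @param genome_length Circular genome length.
#' @return One-row tibble: `d_clockwise`, `d_counterclockwise` (bp).
#' @export
fork_distances <- function(breakpoints, oriC, genome_length) {
  if (length(breakpoints) != 2L) abort("exactly two breakpoints are required")
  check_position(breakpoints, genome_length, "breakpoint")
  cw <- arc_cw(oriC, breakpoints, genome_length)
  ccw <- (genome_length - cw) %% genome_length
  # a breakpoint belongs to the replichore along which it is nearer to oriC;
  # a breakpoint sitting exactly at oriC (distance 0) can serve either arm
  on_cw <- cw <= ccw
  if (sum(on_cw) != 1L) {
    zero <- which(cw == 0 | ccw == 0)
    if (length(zero)) on_cw[zero[1]] <- (sum(on_cw) == 0L)
  }
  if (sum(on_cw) != 1L) {
    abort("both breakpoints lie on the same replichore")
  }
  tibble(d_clockwise = unname(cw[on_cw]),
         d_counterclockwise = unname(ccw[!on_cw]))
}

#' Comet-model parameters
#'
#' The null model of replication-coupled occupancy: the protein occupies a
#' comet of fixed genomic length trailing each replication fork, optionally
#' persisting for a fixed time after a locus is replicated. Fork speed is
#' deterministic, `v = L / C`.
#'
#' @param L Replichore length in bp.
#' @param C Replication (C) period in minutes.
#' @param D Post-replication (D) period in minutes.
#' @param T Doubling time in minutes; `T < C + D` means overlapping rounds.
#' @param comet_len Comet length in bp (clipped to `L` with a warning).
#' @param persistence Extra persistence time per locus in minutes.
#' @return A list of class `comet_params` (includes `v = L/C`).
#' @export
comet_params <- function(L = 2319500, C = 40, D = 20, T = C + D,
                         comet_len = 200000, persistence = 0) {
  stopifnot_scalar_pos(L, "L"); stopifnot_scalar_pos(C, "C")
  stopifnot_scalar_pos(T, "T")
  if (D < 0 || persistence < 0) abort("periods must be non-negative")
  if (comet_len < 0) abort("`comet_len` must be non-negative")
  if (comet_len > L) {
    warn("`comet_len` exceeds the replichore length; clipping")
    comet_len <- L
  }
  structure(list(L = L, C = C, D = D, T = T, v = L / C,
                 comet_len = comet_len, persistence = persistence,
                 overlapping_rounds = T < C + D),
            class = "comet_params")
}

#' Analytic comet-model occupancy and dosage
#'
#' Steady-state population averages over the exponential age distribution
#' (density proportional to `2^(-t/T)`). A locus at replichore coordinate
#' `s` is replicated `s/v` minutes into the C period and stays bound for
#' `comet_len/v + persistence` minutes (the comet passes over it, plus any
#' persistence). Dosage is the Cooper-Helmstetter copy number
#' `D(s) = 2^((C + D - s/v)/T)`; the bound fraction integrates to
#' `O(s) = 2 * D(s) * (1 - 2^(-dur/T))`, so occupancy is exactly
#' proportional to dosage for every parameterization — the model's testable
#' prediction.
#'
#' @param params A [comet_params()].
#' @param n_bins Number of grid points along the replichore.
#' @return A list of class `comet_occupancy`: tibble `track` with `s`
#'   (replichore coordinate, bp), `occupancy`, `dosage`; plus `params`.
#' @export
simulate_comet_occupancy <- function(params, n_bins = 200) {
  s <- (seq_len(n_bins) - 0.5) / n_bins * params$L
  t_rep <- s / params$v
  dosage <- 2^((params$C + params$D - t_rep) / params$T)
  # every copy of a locus stays bound for `dur` minutes after its
  # replication; with one replication event per doubling time the bound
  # window saturates at T
  dur <- min(params$comet_len / params$v + params$persistence, params$T)
  occupancy <- 2 * dosage * (1 - 2^(-dur / params$T))
  structure(list(track = tibble(s = s, occupancy = occupancy,
                                dosage = dosage),
                 params = params),
            class = "comet_occupancy")
}

#' @export
tidy.comet_occupancy <- function(x, ...) x$track

#' @export
glance.comet_occupancy <- function(x, ...) {
  tibble(comet_len = x$params$comet_len, persistence = x$params$persistence,
         C = x$params$C, D = x$params$D, T = x$params$T,
         overlapping_rounds = x$params$overlapping_rounds,
         flatness_cv = flatness_stat(x$track$occupancy, x$track$dosage))
}

#' Monte-Carlo comet-model oracle
#'
#' Samples `n_cells` cell ages from the steady-state age distribution and
#' counts, per locus, the chromosomal copies currently comet-bound. In the
#' deterministic replication schedule every copy of a locus is replicated
#' synchronously once per doubling time (at cycle phase `t_s mod T`), so a
#' cell's copies of the locus are all bound when the time since that event
#' is below `comet_len/v + persistence`, and unbound otherwise. Serves as
#' an independent check of the analytic integration.
#'
#' @param params A [comet_params()].
#' @param n_bins Grid points along the replichore.
#' @param n_cells Number of simulated cells.
#' @param seed Integer seed.
#' @return Tibble: `s`, `occupancy` (mean bound copies), `dosage`
#'   (mean copy number), `se_occupancy`.
#' @export
comet_occupancy_mc <- function(params, n_bins = 50, n_cells = 1e5,
                               seed = 1L) {
  s <- (seq_len(n_bins) - 0.5) / n_bins * params$L
  t_rep0 <- params$T - (params$C + params$D) + s / params$v
  dur <- params$comet_len / params$v + params$persistence
  T_ <- params$T
  with_seed(seed, {
    u <- runif(n_cells)
    age <- T_ * (1 - log2(2 - u))    # inverse CDF of w(t) ~ 2^(-t/T)
    occ <- matrix(0, n_cells, n_bins)
    dos <- matrix(0, n_cells, n_bins)
    for (b in seq_len(n_bins)) {
      # copies double at the locus replication event, halve at division
      copies <- 2^(floor((age - t_rep0[b]) / T_) + 1)
      phase <- t_rep0[b] %% T_
      delta <- (age - phase) %% T_   # time since the last replication of s
      dos[, b] <- copies
      occ[, b] <- copies * as.numeric(delta < dur)
    }
    tibble(s = s,
           occupancy = colMeans(occ),
           dosage = colMeans(dos),
           se_occupancy = apply(occ, 2, sd) / sqrt(n_cells))
  })
}

#' Coefficient of variation of occupancy over dosage
#'
#' The comet model predicts occupancy proportional to dosage, i.e. a flat
#' `O/D` ratio (CV near 0); a high CV — such as the terminus occupancy gap
#' in the data — rejects the model.
#'
#' @param occupancy,dosage Aligned numeric tracks; `dosage > 0`.
#' @return The coefficient of variation of `occupancy / dosage`.
#' @export
flatness_stat <- function(occupancy, dosage) {
  if (length(occupancy) != length(dosage)) abort("tracks must align")
  if (any(dosage <= 0)) abort("`dosage` must be positive")
  ratio <- occupancy / dosage
  m <- mean(ratio)
  if (m == 0) return(0)
  sd(ratio) / m
}
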