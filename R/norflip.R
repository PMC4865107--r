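# NorflIP cleavage-site caller: differential strand signal, template
# correlation scan at 100 bp steps, fold validation, cleavage-point
# estimation and shape measurement, cross-experiment overlap.

#' Parameters of the cleavage-site caller
#'
#' Defaults follow the published procedure: strand signals smoothed over
#' 200 bp and subtracted, a 600 bp template correlated at 100 bp steps over
#' the whole genome, candidates kept at Pearson r >= 0.72, validated at
#' IP/input fold > 2. A 2 kb template window is the documented alternative.
#'
#' @param smooth_window Strand smoothing window (bp).
#' @param template_window Template length (bp); 600 default, 2000 alternative.
#' @param scan_step Step of the sliding windows (bp).
#' @param r_min Minimum template Pearson correlation for a candidate.
#' @param fold_min Minimum IP/input enrichment for validation.
#' @param merge_distance Candidates closer than this merge (bp).
#' @param overlap_tolerance Midpoint distance for matching sites across
#'   experiments (bp).
#' @return A list of class `cleavage_params`.
#' @export
cleavage_params <- function(smooth_window = 200, template_window = 600,
                            scan_step = 100, r_min = 0.72, fold_min = 2,
                            merge_distance = 300, overlap_tolerance = 250) {
  if (r_min <= 0 || r_min >= 1) abort("`r_min` must lie in (0, 1)")
  structure(list(smooth_window = as.integer(smooth_window),
                 template_window = as.integer(template_window),
                 scan_step = as.integer(scan_step), r_min = r_min,
                 fold_min = fold_min,
                 merge_distance = as.integer(merge_distance),
                 overlap_tolerance = as.integer(overlap_tolerance)),
            class = "cleavage_params")
}

#' Differential (forward minus reverse) strand signal
#'
#' Library-normalizes the profile, smooths each strand over `window` bp and
#' subtracts reverse from forward. Cleavage sites appear as a positive lobe
#' followed by a negative lobe with the zero crossing at the cleavage point.
#'
#' @param profile A [stranded_profile()].
#' @param window Smoothing window in bp (default 200).
#' @param normalize RPM-normalize first (default `TRUE`).
#' @return Signed numeric per-position track.
#' @export
differential_track <- function(profile, window = 200, normalize = TRUE) {
  if (normalize) profile <- rpm_normalize(profile)
  smooth_circular(profile$fwd, window) - smooth_circular(profile$rev, window)
}

#' Extract a cleavage template from known strong sites
#'
#' Averages the differential-signal windows centered on the given positions
#' (the published procedure bootstraps its template from the two strongest
#' sites, dif and the 1.9 Mb site).
#'
#' @param diff Differential track from [differential_track()].
#' @param centers One or more 0-based site centers.
#' @param window Template length in bp.
#' @return Numeric template vector of length `window`.
#' @export
cleavage_template <- function(diff, centers, window = 600) {
  if (length(centers) < 1L) abort("at least one template center is required")
  len <- length(diff)
  if (length(centers) > 1L) {
    d <- outer(centers, centers, function(a, b) circ_dist(a, b, len))
    if (any(d[upper.tri(d)] < window)) {
      abort("template centers closer than the window overlap")
    }
  }
  w <- as.integer(window)
  acc <- numeric(w)
  for (c0 in centers) {
    acc <- acc + diff[window_idx(c0 - w %/% 2L, w, len)]
  }
  acc / length(centers)
}

#' Canonical (synthetic) cleavage template
#'
#' Builds the differential signal of a single noise-free canonical site and
#' returns the central window, providing a data-independent template with
#' the forward-lobe-first sign convention.
#'
#' @param shape A [shape_params()].
#' @param window Template length in bp.
#' @param smooth_window Strand smoothing applied before subtraction.
#' @return Numeric template vector of length `window`.
#' @export
canonical_cleavage_template <- function(shape = shape_params(), window = 600,
                                        smooth_window = 200) {
  pad <- 4L * smooth_window
  len <- as.integer(2L * (shape$fwd_span + shape$gap + shape$rev_span) +
                      2L * pad + window)
  g <- genome_spec(length = len, oriC = 0L, dif = 1L)
  c0 <- len %/% 2L
  exp <- plant_norflip_experiment(
    g, planted_sites(c0, fold = shape$peak_fold), shape = shape,
    depth = 5, noise = FALSE)
  d <- differential_track(exp$ip, window = smooth_window)
  d[window_idx(c0 - window %/% 2L, as.integer(window), len)]
}

#' Scan a differential track for template-shaped candidates
#'
#' Correlates the template against circular windows at `scan_step`
#' intervals, keeps windows with Pearson r at or above `r_min`, and merges
#' windows within `merge_distance`, keeping the maximum-correlation
#' window. The sign convention is forward-lobe-first and negative
#' correlations are never calls; because a mirrored (reverse-lobe-first)
#' site anti-correlates at its center (r = -1) yet still correlates
#' positively at half-template offsets (one lobe aligned, the rest flat),
#' a surviving candidate is additionally discarded when a more strongly
#' anti-correlated window lies within `merge_distance` of it — its region
#' is better explained by the mirrored shape.
#'
#' @param diff Differential track.
#' @param template Template vector (e.g. from
#'   [canonical_cleavage_template()] or [cleavage_template()]).
#' @param params A [cleavage_params()].
#' @return Tibble of candidates: `center`, `r`.
#' @export
scan_cleavage <- function(diff, template, params = cleavage_params()) {
  sc <- window_scan_corr(diff, template, step = params$scan_step)
  cand <- dplyr::filter(sc, .data$r >= params$r_min)
  cand <- merge_windows(cand, params$merge_distance, length(diff))
  if (nrow(cand)) {
    neg <- sc$center[sc$r < 0]
    neg_r <- -sc$r[sc$r < 0]
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      near <- circ_dist(neg, cand$center[i], length(diff)) <=
        params$merge_distance
      !any(neg_r[near] > cand$r[i])
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  dplyr::select(cand, dplyr::all_of(c("center", "r")))
}

#' Validate candidates by IP/input enrichment
#'
#' Keeps candidates whose maximum (unmasked) ratio within the template
#' window reaches `fold_min`; candidates falling entirely in masked
#' (artifact) regions are dropped.
#'
#' @param candidates Tibble with a `center` column (from [scan_cleavage()]).
#' @param ratio A [ratio_track()], artifact-masked where appropriate.
#' @param params A [cleavage_params()].
#' @return The validated candidates with a `fold` column.
#' @export
validate_sites <- function(candidates, ratio, params = cleavage_params()) {
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, fold = numeric(0)))
  }
  half <- params$template_window %/% 2L
  fold <- window_max(ratio$values, candidates$center, half, ratio$mask)
  out <- dplyr::mutate(candidates, fold = fold)
  dplyr::filter(out, !is.na(.data$fold), .data$fold >= params$fold_min)
}

# Locate the contiguous above-half-maximum block of `x` (raw strand signal)
# nearest/containing the argmax. Returns NULL when there is no enrichment,
# else list(start0, end0) half-open 0-based *local* coordinates.
find_block <- function(x, bg) {
  mx <- max(x)
  if (mx < 1.5 * bg || mx <= 0) return(NULL)
  thr <- (mx + bg) / 2
  above <- x > thr
  if (!any(above)) return(NULL)
  peak <- which.max(x)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(starts <= peak & ends >= peak & r$values)
  if (length(k) == 0L) return(NULL)
  list(start0 = starts[k] - 1L, end0 = ends[k])
}

#' Estimate the cleavage point of a candidate site
#'
#' Primary estimator: the center of the raw-read-depleted gap between the
#' forward-strand and reverse-strand read blocks. On a noiseless canonical
#' site this is exact and sits `(fwd_span + gap) / 2` (150 bp with default
#' shape) downstream of the forward-peak center. When no strand-offset gap
#' is detectable (e.g. a symmetric binding peak) the estimator falls back
#' to the zero crossing of the differential signal and flags the site.
#'
#' @param profile The IP [stranded_profile()] (raw counts or rates).
#' @param center Approximate 0-based site center (e.g. a scan candidate).
#' @param search_radius Half-width of the examined region (bp).
#' @param raw_smooth Light smoothing of the raw strand signal before block
#'   detection (bp; 0 keeps noiseless geometry exact, ~40 is adequate for
#'   Poisson noise at typical depths).
#' @return One-row tibble: `center_est`, `fwd_peak_center`, `offset`
#'   (cleavage point minus forward-peak center), `method`
#'   (`"gap"` or `"zero-crossing"`).
#' @export
estimate_cleavage_point <- function(profile, center, search_radius = 500,
                                    raw_smooth = 0) {
  len <- profile$genome$length
  width <- 2L * as.integer(search_radius)
  start0 <- as.integer(center) - as.integer(search_radius)
  idx <- window_idx(start0, width, len)
  f <- profile$fwd[idx]
  r <- profile$rev[idx]
  if (raw_smooth > 1) {
    f <- smooth_circular(f, raw_smooth)
    r <- smooth_circular(r, raw_smooth)
  }
  # background from the window flanks (outer quarters)
  flank <- c(seq_len(width %/% 4L), (width - width %/% 4L + 1L):width)
  bg_f <- median(f[flank]); bg_r <- median(r[flank])
  fb <- find_block(f, bg_f)
  rb <- find_block(r, bg_r)
  to_genome <- function(local0) (start0 + local0) %% len
  if (!is.null(fb) && !is.null(rb) && rb$start0 >= fb$end0) {
    est_local <- (fb$end0 + rb$start0) / 2
    fwd_center_local <- (fb$start0 + fb$end0) / 2
    return(tibble(center_est = to_genome(est_local),
                  fwd_peak_center = to_genome(fwd_center_local),
                  offset = est_local - fwd_center_local,
                  method = "gap"))
  }
  # fallback: zero crossing of the differential signal nearest the center
  d <- smooth_circular(f, max(raw_smooth, 50)) -
    smooth_circular(r, max(raw_smooth, 50))
  sgn <- sign(d)
  cross <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0)
  if (length(cross) == 0L) {
    return(tibble(center_est = as.numeric(center), fwd_peak_center = NA_real_,
                  offset = NA_real_, method = "zero-crossing"))
  }
  best <- cross[which.min(abs(cross - width / 2))]
  tibble(center_est = to_genome(best - 0.5), fwd_peak_center = NA_real_,
         offset = NA_real_, method = "zero-crossing")
}

#' Measure the geometric shape of a called site
#'
#' Measures, from the raw strand signal around a site: the forward and
#' reverse enrichment spans (widths at half-maximum above background), the
#' central gap (distance from the forward block end to the reverse block
#' start), and the raw-read depletion width (the contiguous central region
#' where the combined raw signal falls below half the background level).
#'
#' @inheritParams estimate_cleavage_point
#' @return One-row tibble: `fwd_span`, `rev_span`, `gap`, `read_depletion`.
#' @export
measure_shape <- function(profile, center, search_radius = 500,
                          raw_smooth = 0) {
  len <- profile$genome$length
  width <- 2L * as.integer(search_radius)
  start0 <- as.integer(center) - as.integer(search_radius)
  idx <- window_idx(start0, width, len)
  f <- profile$fwd[idx]
  r <- profile$rev[idx]
  if (raw_smooth > 1) {
    f <- smooth_circular(f, raw_smooth)
    r <- smooth_circular(r, raw_smooth)
  }
  flank <- c(seq_len(width %/% 4L), (width - width %/% 4L + 1L):width)
  bg_f <- median(f[flank]); bg_r <- median(r[flank])
  fb <- find_block(f, bg_f)
  rb <- find_block(r, bg_r)
  if (is.null(fb) || is.null(rb)) {
    abort("strand enrichment below 1.5x background; shape undefined")
  }
  comb <- f + r
  bg_c <- bg_f + bg_r
  # central contiguous run below half-background
  below <- comb < bg_c / 2
  mid <- which(below & abs(seq_len(width) - width / 2) <= width / 4)
  depletion <- if (length(mid) == 0L) 0L else {
    ctr <- mid[which.min(abs(mid - width / 2))]
    rl <- rle(below)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    k <- which(starts <= ctr & ends >= ctr)
    rl$lengths[k]
  }
  tibble(fwd_span = fb$end0 - fb$start0,
         rev_span = rb$end0 - rb$start0,
         gap = rb$start0 - fb$end0,
         read_depletion = as.integer(depletion))
}

#' Call cleavage sites from IP and input profiles
#'
#' The full pipeline: RPM-normalize, smooth, build the differential track,
#' scan with a template (canonical synthetic by default, or bootstrapped
#' from the strongest data sites with `template = "data"`), mask artifacts
#' via the mock IP, validate candidates by fold, then estimate the cleavage
#' point of each validated site.
#'
#' @param ip,input [stranded_profile()]s of the IP and input libraries.
#' @param mock Optional mock-IP profile used for artifact masking.
#' @param params A [cleavage_params()].
#' @param template `"canonical"`, `"data"`, or a numeric template vector.
#' @param shape [shape_params()] used for the canonical template.
#' @param raw_smooth Smoothing for the cleavage-point estimator (bp); use 0
#'   for noise-free data.
#' @return Tibble of called sites: `center` (estimated cleavage point),
#'   `scan_center`, `template_r`, `fold`, `fwd_peak_center`, `method`;
#'   class `cleavage_sites`.
#' @export
call_cleavage_sites <- function(ip, input, mock = NULL,
                                params = cleavage_params(),
                                template = "canonical",
                                shape = shape_params(), raw_smooth = 40) {
  genome <- ip$genome
  ipn <- rpm_normalize(ip)
  inn <- rpm_normalize(input)
  diff <- differential_track(ipn, window = params$smooth_window,
                             normalize = FALSE)
  ip_s <- smooth_circular(combine_strands(ipn), params$smooth_window)
  in_s <- smooth_circular(combine_strands(inn), params$smooth_window)
  ratio <- ratio_track(ip_s, in_s, genome)
  if (!is.null(mock)) {
    mock_s <- smooth_circular(combine_strands(rpm_normalize(mock)),
                              params$smooth_window)
    ratio <- mask_from_mock(ratio, ratio_track(mock_s, in_s, genome))
  }
  tmpl <- if (is.numeric(template)) {
    template
  } else if (identical(template, "canonical")) {
    canonical_cleavage_template(shape, params$template_window,
                                params$smooth_window)
  } else if (identical(template, "data")) {
    # bootstrap from the two strongest unmasked enrichment regions
    v <- ratio_values(ratio)
    bm <- sliding_mean(ifelse(is.na(v), 0, v), params$template_window,
                       step = params$scan_step)
    top <- dplyr::arrange(bm, dplyr::desc(.data$value))
    picks <- numeric(0)
    for (p in top$center) {
      if (all(circ_dist(p, picks, genome$length) > 2 * params$template_window)) {
        picks <- c(picks, p)
      }
      if (length(picks) == 2L) break
    }
    cleavage_template(diff, picks, params$template_window)
  } else {
    abort("`template` must be \"canonical\", \"data\", or a numeric vector")
  }
  cand <- scan_cleavage(diff, tmpl, params)
  cand <- validate_sites(cand, ratio, params)
  if (nrow(cand) == 0L) {
    out <- tibble(center = numeric(0), scan_center = integer(0),
                  template_r = numeric(0), fold = numeric(0),
                  fwd_peak_center = numeric(0), method = character(0))
    class(out) <- c("cleavage_sites", class(out))
    return(out)
  }
  est <- purrr::map(cand$center, function(c0) {
    estimate_cleavage_point(ip, c0, search_radius = params$template_window,
                            raw_smooth = raw_smooth)
  })
  est <- dplyr::bind_rows(est)
  out <- tibble(center = est$center_est, scan_center = cand$center,
                template_r = cand$r, fold = cand$fold,
                fwd_peak_center = est$fwd_peak_center, method = est$method)
  out <- dplyr::arrange(out, .data$center)
  class(out) <- c("cleavage_sites", class(out))
  out
}

#' Match site catalogs across experiments
#'
#' Pools the site midpoints of several experiments and clusters them
#' (single linkage, splitting where consecutive midpoints are more than
#' `tolerance` apart). Reports Venn-style counts: per-pair common sites,
#' sites common to all experiments, and the union list with support counts.
#'
#' @param site_lists A list of numeric midpoint vectors or of site tibbles
#'   with a `center` column.
#' @param tolerance Midpoint distance defining "the same site" (bp).
#' @param genome_length Optional circular length for wrap-around matching.
#' @return A list with `union` (tibble: `center`, `support`, per-experiment
#'   flags), `pair_counts` (tibble: `exp_a`, `exp_b`, `common`),
#'   `common_all`, and `n_union`.
#' @export
cross_experiment_overlap <- function(site_lists, tolerance = 250,
                                     genome_length = NULL) {
  if (length(site_lists) < 2L) abort("at least two site lists are required")
  centers <- purrr::map(site_lists, function(s) {
    if (is.data.frame(s)) as.numeric(s$center) else as.numeric(s)
  })
  nexp <- length(centers)
  pooled <- tibble(
    center = unlist(centers),
    exp = rep(seq_len(nexp), lengths(centers)))
  pooled <- dplyr::arrange(pooled, .data$center)
  id <- cluster_positions(pooled$center, tolerance)
  if (!is.null(genome_length) && length(id) && max(id) > 1L) {
    wrap_gap <- genome_length - (max(pooled$center) - min(pooled$center))
    if (wrap_gap <= tolerance) id[id == max(id)] <- 1L
  }
  pooled$.cluster <- id
  grp <- dplyr::group_by(pooled, .data$.cluster)
  un <- dplyr::summarise(grp,
                         center = mean(.data$center),
                         support = dplyr::n_distinct(.data$exp),
                         .groups = "drop")
  flags <- purrr::map(seq_len(nexp), function(e) {
    tapply(pooled$exp == e, pooled$.cluster, any)[as.character(un$.cluster)]
  })
  names(flags) <- paste0("in_exp", seq_len(nexp))
  un <- dplyr::bind_cols(dplyr::select(un, -dplyr::all_of(".cluster")),
                         as_tibble(purrr::map(flags, as.logical)))
  pairs <- utils::combn(nexp, 2)
  pair_counts <- tibble(
    exp_a = pairs[1, ], exp_b = pairs[2, ],
    common = purrr::map2_int(pairs[1, ], pairs[2, ], function(a, b) {
      sum(un[[paste0("in_exp", a)]] & un[[paste0("in_exp", b)]])
    }))
  list(union = un, pair_counts = pair_counts,
       common_all = sum(un$support == nexp), n_union = nrow(un))
}
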