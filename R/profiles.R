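# Coverage-track containers and core processing: circular smoothing,
# library normalization, IP/input ratios, masking, GC and copy-number
# normalization, sliding averages, track correlations.

#' Stranded per-base coverage profile
#'
#' Holds forward- and reverse-strand read counts (or rates, for noise-free
#' synthetic data) per genome position, together with the library size.
#'
#' @param fwd,rev Non-negative numeric vectors of length equal to the genome.
#' @param genome A [genome_spec()].
#' @param library_size Total reads; defaults to `sum(fwd) + sum(rev)`.
#' @return An object of class `stranded_profile`.
#' @export
stranded_profile <- function(fwd, rev, genome, library_size = NULL) {
  if (length(fwd) != genome$length || length(rev) != genome$length) {
    abort("strand vectors must match the genome length")
  }
  if (any(fwd < 0) || any(rev < 0)) abort("coverage must be non-negative")
  library_size <- library_size %||% (sum(fwd) + sum(rev))
  structure(list(fwd = as.numeric(fwd), rev = as.numeric(rev),
                 genome = genome, library_size = library_size,
                 rpm = FALSE),
            class = "stranded_profile")
}

#' @export
print.stranded_profile <- function(x, ...) {
  cat(sprintf("<stranded_profile> %s bp, library size %s%s\n",
              format(x$genome$length, big.mark = ","),
              format(round(x$library_size), big.mark = ","),
              if (x$rpm) " (RPM-normalized)" else ""))
  invisible(x)
}

#' @export
tidy.stranded_profile <- function(x, ...) {
  tibble(position = seq_len(x$genome$length) - 1L, fwd = x$fwd, rev = x$rev)
}

#' Centered moving average on a circular track
#'
#' Smooths a per-position track with a centered moving average that wraps
#' around the origin junction. For even windows the center is asymmetric:
#' `floor(window/2)` positions to the left, the remainder to the right. The
#' track total is conserved exactly.
#'
#' @param values Numeric per-position track.
#' @param window Window size in bp (`1` returns the input unchanged).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_circular <- function(values, window = 200) {
  stopifnot_scalar_pos(window, "window")
  window <- as.integer(window)
  len <- length(values)
  if (window > len) abort("`window` must not exceed the track length")
  if (window == 1L) return(as.numeric(values))
  left <- window %/% 2L
  right <- window - 1L - left
  xp <- c(if (left > 0) values[(len - left + 1L):len],
          values,
          if (right > 0) values[seq_len(right)])
  cs <- c(0, cumsum(as.numeric(xp)))
  (cs[(window + 1L):(window + len)] - cs[seq_len(len)]) / window
}

#' Scale a profile to reads per million
#'
#' Each strand is multiplied by `1e6 / library_size`, so the profile total
#' becomes one million.
#'
#' @param profile A [stranded_profile()].
#' @return The RPM-scaled profile.
#' @export
rpm_normalize <- function(profile) {
  if (profile$library_size <= 0) abort("cannot RPM-normalize an empty profile")
  if (profile$rpm) return(profile)
  k <- 1e6 / profile$library_size
  profile$fwd <- profile$fwd * k
  profile$rev <- profile$rev * k
  profile$rpm <- TRUE
  profile
}

#' Sum the two strands of a profile
#'
#' @param profile A [stranded_profile()].
#' @return Numeric per-position track `fwd + rev`.
#' @export
combine_strands <- function(profile) {
  profile$fwd + profile$rev
}

#' IP/input ratio track
#'
#' Computes `(ip + pseudocount) / (input + pseudocount)` per position from
#' two library-normalized tracks, optionally rescaling so the genome-wide
#' median is 1 (robust centering; the handful of strong peaks barely move
#' the median).
#'
#' @param ip,input Numeric per-position tracks (same length), typically
#'   smoothed RPM coverage.
#' @param genome A [genome_spec()].
#' @param pseudocount Value added to numerator and denominator. The default
#'   corresponds to one read per 200 bp smoothing window in the units of the
#'   mean input track (stabilizes low-coverage bins without biasing high
#'   ones).
#' @param center Logical; rescale to median 1 (default `TRUE`).
#' @param bin_size Bin size of the supplied tracks (1 for per-base).
#' @return An object of class `ratio_track`.
#' @export
ratio_track <- function(ip, input, genome, pseudocount = NULL,
                        center = TRUE, bin_size = 1L) {
  if (length(ip) != length(input)) abort("`ip` and `input` must align")
  if (is.null(pseudocount)) {
    pseudocount <- mean(input) / 200
    if (pseudocount <= 0) pseudocount <- 1e-9
  }
  if (all(input == 0) && pseudocount <= 0) {
    abort("all-zero input requires a positive pseudocount")
  }
  values <- (ip + pseudocount) / (input + pseudocount)
  if (isTRUE(center)) {
    med <- median(values)
    if (med > 0) values <- values / med
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 genome = genome, mask = NULL),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %d values (bin %d bp), %s\n",
              length(x$values), x$bin_size,
              if (is.null(x$mask)) "unmasked"
              else sprintf("%d positions masked", sum(x$mask))))
  invisible(x)
}

#' @export
tidy.ratio_track <- function(x, ...) {
  tibble(position = (seq_along(x$values) - 1L) * x$bin_size,
         ratio = x$values,
         masked = if (is.null(x$mask)) FALSE else x$mask)
}

# Values with masked positions set to NA.
ratio_values <- function(ratio, na_masked = TRUE) {
  v <- ratio$values
  if (na_masked && !is.null(ratio$mask)) v[ratio$mask] <- NA_real_
  v
}

#' Mask non-specific regions using a mock-IP ratio
#'
#' Positions where the (smoothed) mock-IP/input ratio reaches
#' `fold_threshold` are flagged as non-specific artifacts (rRNA/tRNA/IS-like
#' signal shared with mock immunoprecipitations) and masked; downstream
#' statistics and peak calls ignore masked positions. Positions below the
#' threshold are never masked.
#'
#' @param ratio The [ratio_track()] to annotate.
#' @param mock_ratio A `ratio_track` from the mock IP against the same input.
#' @param fold_threshold Mock enrichment at or above which positions are
#'   masked (default 2).
#' @param smooth_window Extra smoothing applied to the mock ratio before
#'   thresholding; `1` (default) assumes the track is already smoothed.
#' @return `ratio` with its mask set (union with any existing mask).
#' @export
mask_from_mock <- function(ratio, mock_ratio, fold_threshold = 2,
                           smooth_window = 1) {
  if (length(mock_ratio$values) != length(ratio$values)) {
    abort("`ratio` and `mock_ratio` must share binning")
  }
  m <- mock_ratio$values
  if (smooth_window > 1) m <- smooth_circular(m, smooth_window)
  mask <- m >= fold_threshold
  ratio$mask <- if (is.null(ratio$mask)) mask else (ratio$mask | mask)
  ratio
}

#' Masked intervals of a ratio track
#'
#' @param ratio A [ratio_track()].
#' @return Tibble of 0-based half-open `start`, `end` intervals (linear
#'   representation; a mask spanning the origin junction yields two rows).
#' @export
mask_intervals <- function(ratio) {
  m <- ratio$mask
  if (is.null(m) || !any(m)) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble(start = (starts[keep]) * ratio$bin_size,
         end = (ends[keep]) * ratio$bin_size)
}

#' Remove the GC-content trend from a ratio track
#'
#' Fits a least-squares line of the binned ratio against windowed GC
#' fraction and divides each position by the fitted value, then rescales so
#' the genome-wide mean is unchanged. Immunoprecipitation efficiency varies
#' with GC; this removes the linear component of that bias.
#'
#' @param ratio A per-base [ratio_track()].
#' @param genome A `genome_spec` with sequence (defaults to the track's).
#' @param window Bin size for the GC fit (default 60 kb).
#' @return The corrected `ratio_track`.
#' @export
gc_normalize <- function(ratio, genome = ratio$genome, window = 60000) {
  if (is.null(genome$sequence)) abort("GC normalization needs a genome sequence")
  gt <- gc_track(genome, window)
  v <- ratio$values
  bin_id <- pmin(length(gt$gc) - 1L,
                 (seq_along(v) - 1L) %/% as.integer(window)) + 1L
  ok <- if (is.null(ratio$mask)) rep(TRUE, length(v)) else !ratio$mask
  bin_mean <- tapply(v[ok], bin_id[ok], mean)
  gc_bin <- gt$gc[as.integer(names(bin_mean))]
  if (sd(gc_bin) < 1e-8) {
    warn("GC content is constant across windows; returning track unchanged")
    return(ratio)
  }
  fit <- lm(bin_mean ~ gc_bin)
  fitted_bin <- coef(fit)[1] + coef(fit)[2] * gt$gc
  fitted_bin[fitted_bin <= 0] <- min(fitted_bin[fitted_bin > 0])
  corrected <- v / fitted_bin[bin_id]
  corrected <- corrected * mean(v[ok]) / mean(corrected[ok])
  ratio$values <- corrected
  ratio
}

#' Divide a ratio track by a copy-number (dosage) track
#'
#' @param ratio A [ratio_track()].
#' @param dosage Positive numeric track of the same length (e.g. from
#'   [make_dosage_track()]).
#' @return The dosage-normalized `ratio_track`.
#' @export
dosage_normalize <- function(ratio, dosage) {
  if (length(dosage) != length(ratio$values)) {
    abort("`dosage` must align with the ratio track")
  }
  if (any(dosage <= 0)) abort("`dosage` must be strictly positive")
  ratio$values <- ratio$values / dosage
  ratio
}

#' Circular sliding mean reported at regular bin centers
#'
#' @param values Per-position numeric track.
#' @param window Averaging window in bp (e.g. 1 kb, 50 kb, 60 kb).
#' @param step Distance between reported centers; defaults to `window`
#'   (non-overlapping bins).
#' @return Tibble with `center` (0-based bp) and `value`.
#' @export
sliding_mean <- function(values, window, step = window) {
  stopifnot_scalar_pos(window, "window")
  len <- length(values)
  if (window > len) abort("`window` must not exceed the track length")
  sm <- smooth_circular(values, window)
  centers <- seq.int(0L, len - 1L, by = as.integer(step))
  tibble(center = centers, value = sm[centers + 1L])
}

#' Pearson correlation between two tracks after binning
#'
#' Tracks are averaged in non-overlapping bins and the Pearson correlation
#' of the binned values is returned. Replicate experiments are conventionally
#' compared on 1 kb bins.
#'
#' @param a,b Per-position numeric tracks of equal length.
#' @param bin Bin size in bp (default 1000).
#' @return Correlation in `[-1, 1]`.
#' @export
track_pearson <- function(a, b, bin = 1000) {
  if (length(a) != length(b)) abort("tracks must have equal length")
  ba <- bin_means(a, bin)
  bb <- bin_means(b, bin)
  if (sd(ba) == 0 || sd(bb) == 0) {
    abort("correlation undefined for a constant track")
  }
  cor(ba, bb)
}

# Non-overlapping bin means (last partial bin included).
bin_means <- function(values, bin) {
  bin <- as.integer(bin)
  if (bin <= 1L) return(as.numeric(values))
  id <- (seq_along(values) - 1L) %/% bin
  as.numeric(tapply(values, id, mean))
}
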