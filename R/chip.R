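# ChIP-seq binding-site detection: correlation with the dif-site signal
# shape, fold filtering, and the ori/ter non-specific binding bias.

#' Parameters of the binding-site caller
#'
#' The published filter keeps enriched regions (> 2 fold) whose IP/input
#' profile correlates with the dif-site signal at Pearson r > 0.7. The
#' template window length is not printed; 600 bp (the cleavage caller's
#' window) is the default, 2 kb the documented alternative.
#'
#' @param template_window Template length in bp.
#' @param r_min Minimum Pearson correlation with the template.
#' @param fold_min Minimum IP/input enrichment.
#' @param scan_step Sliding-window step in bp.
#' @param merge_distance Windows closer than this merge (bp).
#' @return A list of class `binding_params`.
#' @export
binding_params <- function(template_window = 600, r_min = 0.7, fold_min = 2,
                           scan_step = 100, merge_distance = 300) {
  if (r_min <= 0 || r_min >= 1) abort("`r_min` must lie in (0, 1)")
  if (fold_min <= 1) abort("`fold_min` must exceed 1")
  structure(list(template_window = as.integer(template_window),
                 r_min = r_min, fold_min = fold_min,
                 scan_step = as.integer(scan_step),
                 merge_distance = as.integer(merge_distance)),
            class = "binding_params")
}

#' Extract a binding template from a reference region
#'
#' Returns the ratio values on the window centered at `center` (typically
#' the dif site, the strongest genuine binding site). A masked center is an
#' error; a constant window is flagged unusable.
#'
#' @param ratio A [ratio_track()] (per-base).
#' @param center 0-based template center.
#' @param window Template length in bp.
#' @return Numeric template vector with attribute `usable`.
#' @export
template_from_region <- function(ratio, center, window = 600) {
  len <- length(ratio$values)
  idx <- window_idx(center - window %/% 2L, as.integer(window), len)
  if (!is.null(ratio$mask) && ratio$mask[pos_to_idx(center, len)]) {
    abort("template center is masked")
  }
  tmpl <- ratio$values[idx]
  attr(tmpl, "usable") <- sd(tmpl) > 1e-12
  tmpl
}

#' Scan a ratio track with a binding template
#'
#' Pearson correlation of the template against circular windows at
#' `step` intervals; constant windows get r = 0 by convention. Windows
#' touching masked positions are dropped.
#'
#' @param ratio A [ratio_track()].
#' @param template Template vector (see [template_from_region()]).
#' @param step Window step in bp.
#' @return Tibble: `start`, `center`, `r` per window.
#' @export
scan_template <- function(ratio, template, step = 100) {
  if (isFALSE(attr(template, "usable"))) {
    abort("template is constant and cannot be scanned")
  }
  sc <- window_scan_corr(ratio$values, as.numeric(template), step = step)
  if (!is.null(ratio$mask)) {
    keep <- !window_touches_mask(ratio$mask, sc$center,
                                 length(template) %/% 2L)
    sc <- sc[keep, , drop = FALSE]
  }
  sc
}

#' Call binding sites from a correlation scan
#'
#' Keeps windows with `r >= r_min` whose maximum unmasked ratio reaches
#' `fold_min`, merges windows within `merge_distance` (max-r window wins),
#' and returns the sites sorted by position.
#'
#' @param ratio A [ratio_track()].
#' @param corr_track Scan result from [scan_template()].
#' @param params A [binding_params()].
#' @return Tibble of class `binding_sites`: `start`, `end`, `midpoint`,
#'   `fold`, `template_r`.
#' @export
call_binding_sites <- function(ratio, corr_track, params = binding_params()) {
  cand <- dplyr::filter(corr_track, .data$r >= params$r_min)
  half <- params$template_window %/% 2L
  if (nrow(cand)) {
    fold <- window_max(ratio$values, cand$center, half, ratio$mask)
    cand <- dplyr::mutate(cand, fold = fold)
    cand <- dplyr::filter(cand, !is.na(.data$fold),
                          .data$fold >= params$fold_min)
  } else {
    cand <- dplyr::mutate(cand, fold = numeric(0))
  }
  cand <- merge_windows(cand, params$merge_distance, length(ratio$values))
  out <- tibble(start = cand$center - half, end = cand$center + half,
                midpoint = cand$center, fold = cand$fold,
                template_r = cand$r)
  out <- dplyr::arrange(out, .data$midpoint)
  class(out) <- c("binding_sites", class(out))
  out
}

#' ChIP binding-site pipeline
#'
#' Smooths and normalizes IP and input, builds the ratio track, masks
#' artifacts with the mock IP, extracts the template at `template_center`
#' (default: dif) and calls binding sites.
#'
#' @param ip,input,mock [stranded_profile()]s (mock optional).
#' @param template_center 0-based template center; defaults to the genome's
#'   dif coordinate.
#' @param params A [binding_params()].
#' @param smooth_window Coverage smoothing window (bp).
#' @return A `binding_sites` tibble (see [call_binding_sites()]).
#' @export
call_chip_sites <- function(ip, input, mock = NULL,
                            template_center = NULL,
                            params = binding_params(), smooth_window = 200) {
  genome <- ip$genome
  template_center <- template_center %||% genome$dif
  ip_s <- smooth_circular(combine_strands(rpm_normalize(ip)), smooth_window)
  in_s <- smooth_circular(combine_strands(rpm_normalize(input)), smooth_window)
  ratio <- ratio_track(ip_s, in_s, genome)
  if (!is.null(mock)) {
    mock_s <- smooth_circular(combine_strands(rpm_normalize(mock)),
                              smooth_window)
    ratio <- mask_from_mock(ratio, ratio_track(mock_s, in_s, genome))
  }
  tmpl <- template_from_region(ratio, template_center, params$template_window)
  sc <- scan_template(ratio, tmpl, step = params$scan_step)
  call_binding_sites(ratio, sc, params)
}

#' Origin/terminus non-specific binding bias
#'
#' Mean ratio over the oriC-centered arc (default 3 Mb) versus the
#' complementary terminus arc, plus the longest run of 60 kb bins whose
#' mean sits strictly below the genome-wide mean (the "depleted span").
#'
#' @param ratio A per-base [ratio_track()] (dosage-normalized for the
#'   published comparison).
#' @param genome A [genome_spec()]; defaults to the track's.
#' @param arc Width of the oriC-centered arc in bp.
#' @param bin Bin size for the depleted-span computation.
#' @return One-row tibble: `ori_mean`, `ter_mean`, `depleted_span_bp`.
#' @export
ori_ter_bias <- function(ratio, genome = ratio$genome, arc = 3e6,
                         bin = 60000) {
  v <- ratio_values(ratio)
  len <- genome$length
  pos <- seq_along(v) - 1L
  in_ori <- circ_dist(pos, genome$oriC, len) <= arc / 2
  ori_mean <- mean(v[in_ori], na.rm = TRUE)
  ter_mean <- mean(v[!in_ori], na.rm = TRUE)
  bm <- bin_means(ifelse(is.na(v), mean(v, na.rm = TRUE), v), bin)
  below <- bm < mean(bm)
  span <- 0L
  if (any(below)) {
    # longest circular run of below-mean bins
    r <- rle(c(below, below))
    runs <- r$lengths[r$values]
    span <- min(max(runs), length(bm)) * as.integer(bin)
  }
  tibble(ori_mean = ori_mean, ter_mean = ter_mean,
         depleted_span_bp = span)
}
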