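# Genomic-context statistics for called sites: spacing, density, gene
# localization, proximity to highly expressed transcription units, overlap
# enrichment, dinucleotide and GATC-spacing profiles, random controls.

#' Distances between consecutive sites in a region
#'
#' Successive differences of the sorted site positions falling in the
#' linear region `[region_start, region_end)` (no wrap inside a region).
#'
#' @param sites Numeric site midpoints (0-based) or a tibble with `center`.
#' @param region_start,region_end Region bounds; defaults cover everything.
#' @return A list: `distances`, `mean`, `median`, `n_sites`.
#' @export
consecutive_distances <- function(sites, region_start = -Inf,
                                  region_end = Inf) {
  pos <- site_centers(sites)
  pos <- sort(pos[pos >= region_start & pos < region_end])
  if (length(pos) < 2L) {
    return(list(distances = numeric(0), mean = NA_real_, median = NA_real_,
                n_sites = length(pos)))
  }
  d <- diff(pos)
  list(distances = d, mean = mean(d), median = median(d),
       n_sites = length(pos))
}

site_centers <- function(sites) {
  if (is.data.frame(sites)) as.numeric(sites$center) else as.numeric(sites)
}

#' Site density along the genome
#'
#' Histogram of site midpoints in circular bins.
#'
#' @param sites Site midpoints or tibble with `center`.
#' @param genome A [genome_spec()].
#' @param bin Bin size in bp (default 50 kb).
#' @return Tibble: `start`, `end`, `count`.
#' @export
site_density <- function(sites, genome, bin = 50000) {
  pos <- site_centers(sites) %% genome$length
  nbin <- ceiling(genome$length / bin)
  id <- pmin(floor(pos / bin), nbin - 1L)
  counts <- tabulate(id + 1L, nbins = nbin)
  starts <- (seq_len(nbin) - 1L) * bin
  tibble(start = starts, end = pmin(starts + bin, genome$length),
         count = counts)
}

#' Localization of sites relative to genes
#'
#' Classifies each site midpoint as genic or intergenic and, for genic
#' sites, reports the position within the gene normalized to `[0, 1]` and
#' oriented 5' to 3' (a site at the start of a minus-strand gene maps
#' to 1).
#'
#' @param sites Site midpoints or tibble with `center`.
#' @param genes Tibble with `start`, `end`, `strand` (non-overlapping).
#' @return A list: `frac_in_genes`, `frac_intergenic`,
#'   `normalized_positions` (per genic site), `per_site` tibble.
#' @export
gene_localization <- function(sites, genes) {
  pos <- site_centers(sites)
  if (nrow(genes) > 1L) {
    g <- dplyr::arrange(genes, .data$start)
    if (any(g$start[-1] < g$end[-nrow(g)])) abort("genes must not overlap")
  } else {
    g <- genes
  }
  k <- findInterval(pos, g$start)
  inside <- k >= 1 & pos < ifelse(k >= 1, g$end[pmax(k, 1)], -Inf)
  relpos <- rep(NA_real_, length(pos))
  gi <- which(inside)
  if (length(gi)) {
    kk <- k[gi]
    x <- (pos[gi] - g$start[kk]) / (g$end[kk] - g$start[kk])
    minus <- g$strand[kk] == "-"
    x[minus] <- 1 - x[minus]
    relpos[gi] <- x
  }
  per_site <- tibble(center = pos, in_gene = inside,
                     normalized_position = relpos)
  list(frac_in_genes = mean(inside),
       frac_intergenic = mean(!inside),
       normalized_positions = relpos[inside],
       per_site = per_site)
}

# Circular distance from each point to the nearest interval (0 when
# inside); intervals are 0-based half-open and must not wrap.
dist_to_intervals <- function(pos, starts, ends, genome_length) {
  if (length(starts) == 0L) return(rep(Inf, length(pos)))
  out <- rep(Inf, length(pos))
  for (i in seq_along(starts)) {
    d <- pmin(circ_dist(pos, starts[i], genome_length),
              circ_dist(pos, ends[i] - 1, genome_length))
    d[pos >= starts[i] & pos < ends[i]] <- 0
    out <- pmin(out, d)
  }
  out
}

#' Distance from sites to highly expressed transcription units
#'
#' Per-site circular distance to the nearest boundary of a transcription
#' unit with expression at or above `expr_threshold` (0 when the site lies
#' inside one), compared with a matched random control of equal size; the
#' two distance samples are compared with a one-way ANOVA F-test. Also
#' reports the fraction of sites within `distance_cut`.
#'
#' @param sites Site midpoints or tibble with `center`.
#' @param tus Tibble with `start`, `end`, `expression`.
#' @param genome A [genome_spec()].
#' @param expr_threshold Reads defining "highly expressed" (default 500,
#'   roughly the top decile).
#' @param distance_cut Proximity cutoff reported as a fraction (default 2 kb).
#' @param control_n Size of the random control (defaults to the site count).
#' @param seed Seed for the control draw.
#' @param exclusions Optional intervals the control must avoid.
#' @return A list: `distances`, `control_distances`, `median`,
#'   `control_median`, `p_value`, `frac_within_cut`.
#' @export
tu_proximity <- function(sites, tus, genome, expr_threshold = 500,
                         distance_cut = 2000, control_n = NULL, seed = 1L,
                         exclusions = NULL) {
  hot <- dplyr::filter(tus, .data$expression >= expr_threshold)
  if (nrow(hot) == 0L) abort("no transcription unit reaches `expr_threshold`")
  pos <- site_centers(sites)
  d <- dist_to_intervals(pos, hot$start, hot$end, genome$length)
  control_n <- control_n %||% length(pos)
  ctrl <- random_sites(control_n, genome, seed = seed,
                       exclusions = exclusions)
  dc <- dist_to_intervals(ctrl$center, hot$start, hot$end, genome$length)
  grp <- factor(rep(c("sites", "control"), c(length(d), length(dc))))
  p <- anova(lm(c(d, dc) ~ grp))[["Pr(>F)"]][1]
  list(distances = d, control_distances = dc,
       median = median(d), control_median = median(dc),
       p_value = p, frac_within_cut = mean(d <= distance_cut))
}

#' Gene-level overlap enrichment (Fisher's exact test)
#'
#' Builds the gene-level 2x2 table (gene carries a site? x gene carries a
#' feature?) over the gene universe and returns the one-sided (enrichment)
#' Fisher's exact p-value, with counts reported as
#' "common / total feature genes".
#'
#' @param sites Site midpoints or tibble with `center`.
#' @param features Tibble of feature intervals (`start`, `end`) or points
#'   (`position`).
#' @param genes Gene universe tibble (`start`, `end`).
#' @return One-row tibble: `n_common_genes`, `n_feature_genes`,
#'   `n_site_genes`, `n_genes`, `p_value`.
#' @export
overlap_fisher <- function(sites, features, genes) {
  if (nrow(genes) == 0L) abort("empty gene universe")
  pos <- site_centers(sites)
  has_site <- vapply(seq_len(nrow(genes)), function(i) {
    any(pos >= genes$start[i] & pos < genes$end[i])
  }, logical(1))
  if ("position" %in% names(features) && !"start" %in% names(features)) {
    fs <- features$position; fe <- features$position + 1L
  } else {
    fs <- features$start; fe <- features$end
  }
  has_feature <- vapply(seq_len(nrow(genes)), function(i) {
    any(fe > genes$start[i] & fs < genes$end[i])
  }, logical(1))
  tab <- table(factor(has_site, c(TRUE, FALSE)),
               factor(has_feature, c(TRUE, FALSE)))
  p <- fisher.test(tab, alternative = "greater")$p.value
  tibble(n_common_genes = sum(has_site & has_feature),
         n_feature_genes = sum(has_feature),
         n_site_genes = sum(has_site),
         n_genes = nrow(genes),
         p_value = p)
}

#' Positional dinucleotide frequency around sites
#'
#' For each offset in `[-window/2, window/2)`, the fraction of sites whose
#' sequence carries the given dinucleotide starting at that offset
#' (forward-strand counting; the default GC dinucleotide is its own
#' reverse complement, so strand does not matter for it).
#'
#' @param genome A `genome_spec` with sequence.
#' @param sites Site midpoints or tibble with `center`.
#' @param window Profile width in bp.
#' @param dinucleotide Two-letter string (default `"GC"`).
#' @return Tibble: `offset`, `frequency`.
#' @export
dinucleotide_profile <- function(genome, sites, window = 200,
                                 dinucleotide = "GC") {
  if (nchar(dinucleotide) != 2L) abort("`dinucleotide` must have 2 letters")
  b <- genome_bytes(genome)
  len <- genome$length
  d1 <- charToRaw(dinucleotide)[1]
  d2 <- charToRaw(dinucleotide)[2]
  pos <- as.integer(site_centers(sites))
  offsets <- seq.int(-(window %/% 2L), window %/% 2L - 1L)
  freq <- vapply(offsets, function(o) {
    p1 <- pos_to_idx(pos + o, len)
    p2 <- pos_to_idx(pos + o + 1L, len)
    mean(b[p1] == d1 & b[p2] == d2)
  }, numeric(1))
  tibble(offset = offsets, frequency = freq)
}

#' GATC spacing profile around sites
#'
#' Locates the GATC motifs flanking each site and reports the mean distance
#' between consecutive motifs at each rank around the site: rank 0 is the
#' motif gap containing the site, positive ranks count gaps downstream,
#' negative ranks upstream. A matched random control is computed the same
#' way. Sites with fewer than `k + 1` motifs on either side are skipped and
#' counted.
#'
#' @param genome A `genome_spec` with sequence.
#' @param sites Site midpoints or tibble with `center`.
#' @param k Number of flanking ranks on each side (default 20).
#' @param control_n Random-control size (defaults to the site count).
#' @param seed Seed for the control.
#' @param motif Motif string (default `"GATC"`).
#' @return A list: `profile` (tibble `rank`, `mean_spacing`,
#'   `control_spacing`), `n_sites_used`, `n_sites_skipped`.
#' @export
gatc_spacing <- function(genome, sites, k = 20, control_n = NULL, seed = 1L,
                         motif = "GATC") {
  mp <- motif_positions(genome, motif)
  if (length(mp) < 2L * k + 2L) abort("too few motif occurrences in genome")
  pos <- site_centers(sites)
  control_n <- control_n %||% length(pos)
  ctrl <- random_sites(control_n, genome, seed = seed)$center
  rank_spacings <- function(p) {
    j <- findInterval(p, mp)
    if (j < k + 1L || j + k + 1L > length(mp)) return(NULL)
    # gap r (r = 0 contains the site): between mp[j + r] and mp[j + r + 1]
    vapply(seq.int(-k, k), function(r) mp[j + r + 1L] - mp[j + r],
           numeric(1))
  }
  collect <- function(ps) {
    rows <- purrr::compact(purrr::map(as.numeric(ps), rank_spacings))
    list(mat = do.call(rbind, rows), skipped = length(ps) - length(rows))
  }
  site_res <- collect(pos)
  ctrl_res <- collect(ctrl)
  if (is.null(site_res$mat)) abort("no site has enough flanking motifs")
  tibble_out <- tibble(
    rank = seq.int(-k, k),
    mean_spacing = colMeans(site_res$mat),
    control_spacing = if (is.null(ctrl_res$mat)) NA_real_
                      else colMeans(ctrl_res$mat))
  list(profile = tibble_out,
       n_sites_used = nrow(site_res$mat),
       n_sites_skipped = site_res$skipped)
}

#' Uniform random control sites
#'
#' Draws `n` positions uniformly from the genome outside the exclusion
#' intervals; deterministic given the seed.
#'
#' @param n Number of sites.
#' @param genome A [genome_spec()].
#' @param seed Integer seed.
#' @param exclusions Optional tibble of intervals (`start`, `end`) to avoid.
#' @return Tibble with a `center` column.
#' @export
random_sites <- function(n, genome, seed = 1L, exclusions = NULL) {
  len <- genome$length
  if (n == 0L) return(tibble(center = integer(0)))
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(with_seed(seed,
                     tibble(center = as.integer(floor(runif(n, 0, len))))))
  }
  ex <- dplyr::arrange(exclusions, .data$start)
  # merge overlapping exclusions
  merged_start <- numeric(0); merged_end <- numeric(0)
  for (i in seq_len(nrow(ex))) {
    if (length(merged_end) && ex$start[i] <= merged_end[length(merged_end)]) {
      merged_end[length(merged_end)] <-
        max(merged_end[length(merged_end)], ex$end[i])
    } else {
      merged_start <- c(merged_start, ex$start[i])
      merged_end <- c(merged_end, ex$end[i])
    }
  }
  gap_start <- c(0, merged_end)
  gap_end <- c(merged_start, len)
  keep <- gap_end > gap_start
  gap_start <- gap_start[keep]; gap_end <- gap_end[keep]
  gl <- gap_end - gap_start
  if (sum(gl) <= 0) abort("exclusions cover the whole genome")
  with_seed(seed, {
    u <- runif(n, 0, sum(gl))
    cum <- cumsum(gl)
    g <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    off <- u - c(0, cum)[g]
    tibble(center = as.integer(floor(gap_start[g] + off)))
  })
}
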