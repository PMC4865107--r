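# Synthetic-data generator: genomes, annotations, and stranded
# IP/input/mock coverage with planted ground truth. The read model is
# per-base Poisson rates (the analyses all operate on coverage, not
# alignments); a noise-free mode returns the rate tracks directly so
# geometric assertions are exact.

#' Canonical NorflIP peak geometry
#'
#' The quinolone-trapped cleavage signature: a forward-strand enrichment
#' block and a reverse-strand block of ~170 bp each, separated by a 130 bp
#' non-enriched gap centered on the cleavage point, with a 100 bp central
#' window where raw reads are depleted (the covalently blocked 5' ends
#' ligate poorly and are rarely sequenced).
#'
#' @param fwd_span,rev_span Enrichment block widths in bp.
#' @param gap Non-enriched gap between the blocks, in bp.
#' @param read_depletion Width of the central raw-read depletion, in bp
#'   (must not exceed `gap`).
#' @param fragment_len Nominal library fragment length in bp (bookkeeping).
#' @param peak_fold Default enrichment of a planted site over background.
#' @return A list of class `shape_params`.
#' @export
shape_params <- function(fwd_span = 170, rev_span = 170, gap = 130,
                         read_depletion = 100, fragment_len = 250,
                         peak_fold = 10) {
  for (nm in c("fwd_span", "rev_span", "gap", "fragment_len")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (read_depletion < 0 || gap < read_depletion) {
    abort("`gap` must be at least `read_depletion`")
  }
  structure(list(fwd_span = as.integer(fwd_span),
                 rev_span = as.integer(rev_span),
                 gap = as.integer(gap),
                 read_depletion = as.integer(read_depletion),
                 fragment_len = as.integer(fragment_len),
                 peak_fold = peak_fold),
            class = "shape_params")
}

#' Planted ground-truth sites
#'
#' @param center 0-based positions of cleavage/binding points.
#' @param fold Enrichment over background (`>= 1`), recycled.
#' @param kind `"cleavage"` or `"binding"`, recycled.
#' @return Tibble with columns `center`, `fold`, `kind`.
#' @export
planted_sites <- function(center, fold = 10, kind = "cleavage") {
  if (any(fold < 1)) abort("`fold` must be >= 1")
  tibble(center = as.integer(center),
         fold = rep_len(as.numeric(fold), length(center)),
         kind = rep_len(kind, length(center)))
}

new_synthetic_experiment <- function(rates, genome, truth, artifacts,
                                     seed, noise) {
  draw <- function(rate, s_off) {
    if (!noise) return(rate)
    with_seed(seed + s_off, {
      # scalar-rate draw for the uniform background, then redraw the few
      # positions whose rate differs (much faster than a vector-rate draw)
      r0 <- rate[1]
      x <- rpois(length(rate), r0)
      idx <- which(rate != r0)
      if (length(idx)) x[idx] <- rpois(length(idx), rate[idx])
      x
    })
  }
  exp <- structure(list(
    rates = rates, genome = genome, truth = truth,
    artifacts = artifacts, seed = as.integer(seed), noise = noise
  ), class = "synthetic_experiment")
  exp$ip <- stranded_profile(draw(rates$ip_fwd, 1L), draw(rates$ip_rev, 2L),
                             genome)
  exp$input <- stranded_profile(draw(rates$input_fwd, 3L),
                                draw(rates$input_rev, 4L), genome)
  exp$mock <- stranded_profile(draw(rates$mock_fwd, 5L),
                               draw(rates$mock_rev, 6L), genome)
  exp
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("<synthetic_experiment> %s bp, %d planted site(s), %d artifact region(s), %s\n",
              format(x$genome$length, big.mark = ","), nrow(x$truth),
              nrow(x$artifacts),
              if (x$noise) sprintf("Poisson counts (seed %d)", x$seed)
              else "noise-free rates"))
  invisible(x)
}

base_rates <- function(len, depth, bg_rate) {
  list(ip_fwd = rep(bg_rate / 2, len), ip_rev = rep(bg_rate / 2, len),
       input_fwd = rep(depth / 2, len), input_rev = rep(depth / 2, len),
       mock_fwd = rep(depth / 2, len), mock_rev = rep(depth / 2, len))
}

check_site_spacing <- function(truth, min_spacing, len) {
  if (nrow(truth) < 2L) return(invisible(truth))
  pos <- sort(truth$center)
  gaps <- c(diff(pos), len - (pos[length(pos)] - pos[1]))
  if (any(gaps < min_spacing)) {
    warn(sprintf("%d planted site pair(s) closer than %d bp; templates may interfere",
                 sum(gaps < min_spacing), as.integer(min_spacing)))
  }
  invisible(truth)
}

#' Simulate a NorflIP experiment with planted cleavage sites
#'
#' Plants the canonical strand-asymmetric cleavage signature at each site
#' center `c`: the forward-strand rate is raised on
#' `[c - gap/2 - fwd_span, c - gap/2)`, the reverse-strand rate on
#' `[c + gap/2, c + gap/2 + rev_span)`, such that the combined (fwd+rev)
#' rate on a block equals `fold * bg_rate`; inside the central
#' `read_depletion` window both raw rates drop to
#' `depletion_frac * background` (0 by default: blocked 5' ends are not
#' sequenced). Input and mock are uniform at `depth`. With `noise = TRUE`
#' all tracks are Poisson draws from the rates, deterministic given `seed`.
#'
#' @param genome A [genome_spec()].
#' @param sites A [planted_sites()] tibble (possibly empty).
#' @param shape A [shape_params()].
#' @param depth Mean input reads per bp (fwd+rev combined).
#' @param bg_rate Mean IP background reads per bp (default `depth`).
#' @param noise Draw Poisson counts (`TRUE`) or return rates (`FALSE`).
#' @param seed Integer seed for the Poisson draws.
#' @param depletion_frac Fraction of background retained in the depletion
#'   window (default 0).
#' @param min_spacing Planted sites closer than this raise a warning
#'   (default 2 kb), since overlapping templates interfere.
#' @return A `synthetic_experiment` with `ip`, `input`, `mock` profiles and
#'   the ground truth.
#' @export
plant_norflip_experiment <- function(genome, sites = planted_sites(integer(0)),
                                     shape = shape_params(), depth = 5,
                                     bg_rate = depth, noise = TRUE, seed = 1L,
                                     depletion_frac = 0, min_spacing = 2000) {
  stopifnot_scalar_pos(depth, "depth")
  stopifnot_scalar_pos(bg_rate, "bg_rate")
  len <- genome$length
  if (nrow(sites)) check_position(sites$center, len, "site center")
  check_site_spacing(sites, min_spacing, len)
  r <- base_rates(len, depth, bg_rate)
  half_gap <- shape$gap / 2
  block_rate <- function(fold) fold * bg_rate - bg_rate / 2
  # batch all block indices so each rate track is written once
  fwd_idx <- integer(0); fwd_val <- numeric(0)
  rev_idx <- integer(0); rev_val <- numeric(0)
  for (i in seq_len(nrow(sites))) {
    c0 <- sites$center[i]
    v <- block_rate(sites$fold[i])
    fi <- window_idx(floor(c0 - half_gap) - shape$fwd_span, shape$fwd_span,
                     len)
    ri <- window_idx(ceiling(c0 + half_gap), shape$rev_span, len)
    fwd_idx <- c(fwd_idx, fi); fwd_val <- c(fwd_val, rep(v, length(fi)))
    rev_idx <- c(rev_idx, ri); rev_val <- c(rev_val, rep(v, length(ri)))
  }
  r$ip_fwd[fwd_idx] <- fwd_val
  r$ip_rev[rev_idx] <- rev_val
  # raw-read depletion at the cleavage point, applied after all blocks
  dep_idx <- unlist(lapply(sites$center, function(c0) {
    window_idx(c0 - shape$read_depletion %/% 2L, shape$read_depletion, len)
  }))
  if (length(dep_idx)) {
    r$ip_fwd[dep_idx] <- r$ip_fwd[dep_idx] * depletion_frac
    r$ip_rev[dep_idx] <- r$ip_rev[dep_idx] * depletion_frac
  }
  truth <- sites
  truth$kind <- rep_len("cleavage", nrow(truth))
  new_synthetic_experiment(r, genome, truth,
                           artifact_regions(integer(0), integer(0)),
                           seed, noise)
}

#' Simulate a ChIP experiment with planted symmetric binding sites
#'
#' Both strand rates are multiplied by `fold` on the symmetric interval
#' `[center - span/2, center + span/2)`, so the noise-free IP/input ratio
#' on the span equals `fold`.
#'
#' @inheritParams plant_norflip_experiment
#' @param span Width of the binding footprint in bp (default 200).
#' @return A `synthetic_experiment`.
#' @export
plant_chip_experiment <- function(genome, sites = planted_sites(integer(0), kind = "binding"),
                                  span = 200, depth = 10, bg_rate = depth,
                                  noise = TRUE, seed = 1L, min_spacing = 2000) {
  stopifnot_scalar_pos(depth, "depth")
  len <- genome$length
  if (nrow(sites)) check_position(sites$center, len, "site center")
  check_site_spacing(sites, min_spacing, len)
  r <- base_rates(len, depth, bg_rate)
  idx <- integer(0); fac <- numeric(0)
  for (i in seq_len(nrow(sites))) {
    ii <- window_idx(sites$center[i] - span %/% 2L, as.integer(span), len)
    idx <- c(idx, ii); fac <- c(fac, rep(sites$fold[i], length(ii)))
  }
  if (length(idx)) {
    r$ip_fwd[idx] <- r$ip_fwd[idx] * fac
    r$ip_rev[idx] <- r$ip_rev[idx] * fac
  }
  truth <- sites
  truth$kind <- rep_len("binding", nrow(truth))
  new_synthetic_experiment(r, genome, truth,
                           artifact_regions(integer(0), integer(0)),
                           seed, noise)
}

#' Artifact regions shared between IP and mock
#'
#' @param start,end 0-based half-open interval bounds.
#' @param fold Enrichment factor (> 1), recycled.
#' @param label Region label (`"rRNA-like"`, `"tRNA-like"`, `"IS-like"`).
#' @return Tibble with columns `start`, `end`, `fold`, `label`.
#' @export
artifact_regions <- function(start, end, fold = 20, label = "rRNA-like") {
  if (any(end <= start)) abort("artifact regions must satisfy start < end")
  if (length(start) && any(fold <= 1)) abort("artifact `fold` must exceed 1")
  tibble(start = as.integer(start), end = as.integer(end),
         fold = rep_len(as.numeric(fold), length(start)),
         label = rep_len(label, length(start)))
}

#' Add non-specific artifact signal to an experiment
#'
#' Multiplies the IP *and* mock rates by `fold` over each region (input is
#' unchanged), emulating the rRNA/tRNA/IS-like signal shared with mock
#' immunoprecipitations, then redraws the affected counts. The planted
#' truth is unchanged.
#'
#' @param exp A `synthetic_experiment`.
#' @param regions An [artifact_regions()] tibble; empty is the identity.
#' @return The modified experiment.
#' @export
add_artifacts <- function(exp, regions) {
  if (nrow(regions) == 0L) return(exp)
  len <- exp$genome$length
  check_position(c(regions$start, regions$end - 1L), len, "artifact region")
  r <- exp$rates
  idx <- integer(0); fac <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    ii <- window_idx(regions$start[i],
                     (regions$end[i] - regions$start[i]) %% len, len)
    idx <- c(idx, ii); fac <- c(fac, rep(regions$fold[i], length(ii)))
  }
  for (tr in c("ip_fwd", "ip_rev", "mock_fwd", "mock_rev")) {
    r[[tr]][idx] <- r[[tr]][idx] * fac
  }
  new_synthetic_experiment(r, exp$genome, exp$truth,
                           dplyr::bind_rows(exp$artifacts, regions),
                           exp$seed, exp$noise)
}

#' Population-average copy-number (gene dosage) track
#'
#' For an asynchronous exponential steady state, the mean copy number of a
#' locus at replichore distance `a` from `oriC` is
#' `2^(C * (1 - a/a_max) / T)`, monotone decreasing toward the terminus
#' with an ori:ter ratio of `2^(C/T)`. For a synchronized population with a
#' fork pair at given positions, dosage is a step: 2 on the replicated arcs
#' between `oriC` and each fork, 1 beyond.
#'
#' @param genome A [genome_spec()].
#' @param state A list: either `list(type = "async", C = <min>, T = <min>)`
#'   or `list(type = "sync", forks = c(pos1, pos2))` with 0-based fork
#'   positions on opposite replichores.
#' @return Per-position numeric dosage track of length `genome$length`.
#' @export
make_dosage_track <- function(genome, state) {
  len <- genome$length
  pos <- seq_len(len) - 1L
  if (identical(state$type, "async")) {
    C <- state$C; T_ <- state$T
    stopifnot_scalar_pos(C, "C"); stopifnot_scalar_pos(T_, "T")
    a <- circ_dist(pos, genome$oriC, len)
    2^(C * (1 - a / max(a)) / T_)
  } else if (identical(state$type, "sync")) {
    forks <- state$forks
    if (length(forks) != 2L) abort("`forks` must give two positions")
    check_position(forks, len, "fork position")
    # assign one fork per replichore, choosing the pairing with the least
    # total travel from oriC
    travel <- function(cw_fork, ccw_fork) {
      c(cw = arc_cw(genome$oriC, cw_fork, len),
        ccw = arc_cw(ccw_fork, genome$oriC, len))
    }
    a_opt <- travel(forks[1], forks[2])
    b_opt <- travel(forks[2], forks[1])
    tr <- if (sum(a_opt) <= sum(b_opt)) a_opt else b_opt
    a_cw <- arc_cw(genome$oriC, pos, len)    # clockwise arc from oriC
    a_ccw <- len - a_cw                      # counter-clockwise arc
    replicated <- (a_cw < tr[["cw"]]) | (a_ccw <= tr[["ccw"]])
    1 + as.numeric(replicated)
  } else {
    abort("`state$type` must be \"async\" or \"sync\"")
  }
}

#' Generate a synthetic annotation set
#'
#' Places `n_genes` non-overlapping gene intervals with random strands on
#' the genome; every gene is a transcription unit whose expression is drawn
#' from a heavy-tailed (log-normal) distribution, with
#' `n_tu_highly_expressed` of them forced above the conventional 500-read
#' "highly expressed" threshold. Fis sites are uniform points and H-NS
#' regions are uniform intervals (both may overlap genes).
#'
#' @param genome A [genome_spec()].
#' @param n_genes Number of genes.
#' @param n_tu_highly_expressed Number of highly expressed transcription units.
#' @param n_fis Number of Fis point sites.
#' @param n_hns_regions Number of H-NS bound regions.
#' @param seed Integer seed.
#' @param mean_gene_len Mean gene length in bp.
#' @param hns_len Mean H-NS region length in bp.
#' @return A list of class `annotation_set` with tibbles `genes`, `tus`,
#'   `fis_sites`, `hns_regions`.
#' @export
make_annotation <- function(genome, n_genes = 400, n_tu_highly_expressed = 40,
                            n_fis = 300, n_hns_regions = 30, seed = 1L,
                            mean_gene_len = 1000, hns_len = 5000) {
  len <- genome$length
  with_seed(seed, {
    gene_len <- if (n_genes > 0) {
      pmax(100L, as.integer(round(rgamma(n_genes, shape = 4,
                                         scale = mean_gene_len / 4))))
    } else integer(0)
    total <- sum(gene_len)
    if (total >= len) abort("genes do not fit in the genome without overlap")
    free <- len - total
    # random partition of the free space into n_genes + 1 gaps
    cuts <- sort(runif(n_genes, 0, free))
    gaps <- diff(c(0, cuts, free))
    starts <- as.integer(cumsum(gaps[seq_len(n_genes)]) +
                           c(0, cumsum(gene_len))[seq_len(n_genes)])
    genes <- tibble(
      start = starts, end = starts + gene_len,
      name = sprintf("gene%04d", seq_len(n_genes)),
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
    expr <- round(rlnorm(n_genes, meanlog = log(30), sdlog = 1.3))
    if (n_tu_highly_expressed > 0) {
      if (n_tu_highly_expressed > n_genes) {
        abort("more highly expressed TUs than genes")
      }
      hot <- sample.int(n_genes, n_tu_highly_expressed)
      expr[hot] <- round(runif(n_tu_highly_expressed, 500, 30000))
    }
    tus <- dplyr::mutate(genes, expression = expr)
    fis <- tibble(position = sort(as.integer(floor(runif(n_fis, 0, len)))))
    hstart <- as.integer(floor(runif(n_hns_regions, 0, len - hns_len)))
    hlen <- pmax(500L, as.integer(round(rgamma(n_hns_regions, shape = 4,
                                               scale = hns_len / 4))))
    hns <- tibble(start = sort(hstart), end = pmin(sort(hstart) + hlen, len))
    structure(list(genes = genes, tus = tus, fis_sites = fis,
                   hns_regions = hns, genome = genome),
              class = "annotation_set")
  })
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes/TUs (%d highly expressed), %d Fis sites, %d H-NS regions\n",
              nrow(x$genes), sum(x$tus$expression >= 500),
              nrow(x$fis_sites), nrow(x$hns_regions)))
  invisible(x)
}

#' Fraction of the genome outside genes
#'
#' @param annotation An [make_annotation()] result.
#' @return Scalar intergenic fraction.
#' @export
intergenic_fraction <- function(annotation) {
  1 - sum(annotation$genes$end - annotation$genes$start) /
    annotation$genome$length
}
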