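#' Describe a circular bacterial genome
#'
#' A `genome_spec` records the coordinate system every other function in the
#' package works in: a circular chromosome of a given length, with the
#' replication origin (`oriC`) and the chromosome-dimer resolution site
#' (`dif`) as landmark coordinates, and optionally the nucleotide sequence.
#' All coordinates in the package are 0-based, half-open (BED convention)
#' and wrap circularly.
#'
#' Defaults correspond to the *E. coli* K-12 chromosome rounded to the kb:
#' a 4,639 kb circle with `oriC` at 3,926 kb and `dif` at 1,588 kb.
#'
#' @param length Genome length in bp.
#' @param oriC 0-based coordinate of the replication origin.
#' @param dif 0-based coordinate of the dif site.
#' @param sequence Optional nucleotide string (A/C/G/T) of length `length`.
#' @param circular Logical; only circular genomes are currently supported.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(length = 4639000, oriC = 3926000, dif = 1588000,
                        sequence = NULL, circular = TRUE) {
  stopifnot_scalar_pos(length, "length")
  length <- as.integer(length)
  check_position(oriC, length, "oriC")
  check_position(dif, length, "dif")
  if (!isTRUE(circular)) abort("only circular genomes are supported")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length) {
      abort("`sequence` length must equal `length`")
    }
    if (grepl("[^ACGT]", sequence)) {
      abort("`sequence` alphabet must be A/C/G/T")
    }
  }
  structure(
    list(length = length, circular = TRUE, oriC = as.integer(oriC),
         dif = as.integer(dif), sequence = sequence),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> circular, %s bp; oriC = %s, dif = %s; sequence: %s\n",
              format(x$length, big.mark = ","),
              format(x$oriC, big.mark = ","),
              format(x$dif, big.mark = ","),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Generate a random genome sequence at a target GC content
#'
#' Draws an i.i.d. nucleotide sequence with the requested GC fraction
#' (G and C equiprobable, likewise A and T) and wraps it in a
#' [genome_spec()].
#'
#' @param length Genome length in bp.
#' @param oriC,dif Landmark coordinates (0-based).
#' @param gc_fraction Target GC fraction, strictly inside (0, 1).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A `genome_spec` with a sequence.
#' @export
make_genome <- function(length, oriC = floor(0.846 * length),
                        dif = floor(0.342 * length),
                        gc_fraction = 0.508, seed = 1L) {
  stopifnot_scalar_pos(length, "length")
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    abort("`gc_fraction` must lie in the open interval (0, 1)")
  }
  length <- as.integer(length)
  check_position(c(oriC, dif), length, "oriC/dif")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  genome_spec(length = length, oriC = oriC, dif = dif, sequence = seq)
}

#' GC fraction of a genome sequence
#'
#' @param genome A `genome_spec` carrying a sequence.
#' @return The fraction of G+C bases.
#' @export
gc_fraction <- function(genome) {
  b <- genome_bytes(genome)
  mean(b == charToRaw("G") | b == charToRaw("C"))
}

# Sequence as a raw byte vector (fast positional access).
genome_bytes <- function(genome) {
  if (is.null(genome$sequence)) abort("genome has no sequence")
  charToRaw(genome$sequence)
}

#' Windowed GC-content track
#'
#' GC fraction in non-overlapping windows tiling the genome (the last
#' window may be shorter).
#'
#' @param genome A `genome_spec` with sequence.
#' @param window Window size in bp.
#' @return A tibble with columns `start`, `end`, `gc`.
#' @export
gc_track <- function(genome, window = 60000) {
  stopifnot_scalar_pos(window, "window")
  b <- genome_bytes(genome)
  isgc <- as.numeric(b == charToRaw("G") | b == charToRaw("C"))
  len <- genome$length
  starts <- seq.int(0L, len - 1L, by = as.integer(window))
  ends <- pmin(starts + as.integer(window), len)
  cs <- c(0, cumsum(isgc))
  tibble(start = starts, end = ends,
         gc = (cs[ends + 1] - cs[starts + 1]) / (ends - starts))
}

#' Positions of a short motif in the genome sequence
#'
#' @param genome A `genome_spec` with sequence.
#' @param motif Motif string, e.g. `"GATC"`.
#' @return Sorted 0-based start positions (linear; occurrences spanning the
#'   origin junction are not reported).
#' @export
motif_positions <- function(genome, motif = "GATC") {
  m <- gregexpr(motif, genome$sequence, fixed = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}
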