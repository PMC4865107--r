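# Reading and writing the standard formats: per-strand coverage as
# bedGraph, masks as BED, genomes as FASTA, sites and annotations as TSV.
# Format handling is delegated to rtracklayer / Biostrings; plain TSV goes
# through readr.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(sprintf("package \"%s\" is required for this import/export", pkg))
  }
}

profile_chrom <- function(genome) "chr"

# Collapse a per-base numeric vector into run-length intervals (0-based).
runs_from_values <- function(values) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  tibble(start = ends - r$lengths, end = ends, value = r$values)
}

#' Write a per-base track as bedGraph
#'
#' Consecutive equal values are collapsed into intervals (standard bedGraph
#' run-length layout).
#'
#' @param values Per-base numeric track.
#' @param path Output file.
#' @param genome A [genome_spec()] (provides the sequence length).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path, genome) {
  need_pkg("rtracklayer"); need_pkg("GenomicRanges")
  runs <- runs_from_values(values)
  gr <- GenomicRanges::GRanges(
    seqnames = profile_chrom(genome),
    ranges = IRanges::IRanges(start = runs$start + 1L, end = runs$end),
    score = runs$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file as a per-base track
#'
#' @param path bedGraph file.
#' @param genome A [genome_spec()] giving the expected length.
#' @return Numeric per-base vector (positions not covered by the file are 0).
#' @export
read_bedgraph <- function(path, genome) {
  need_pkg("rtracklayer")
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- numeric(genome$length)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  v <- gr$score
  for (i in seq_along(s)) out[s[i]:e[i]] <- v[i]
  out
}

#' Write a stranded profile as a pair of bedGraph files
#'
#' @param profile A [stranded_profile()].
#' @param prefix Output path prefix; writes `<prefix>_fwd.bedgraph` and
#'   `<prefix>_rev.bedgraph`.
#' @return The two paths, invisibly.
#' @export
write_profile_bedgraph <- function(profile, prefix) {
  paths <- paste0(prefix, c("_fwd", "_rev"), ".bedgraph")
  write_bedgraph(profile$fwd, paths[1], profile$genome)
  write_bedgraph(profile$rev, paths[2], profile$genome)
  invisible(paths)
}

#' Read a stranded profile from a pair of bedGraph files
#'
#' @param fwd_path,rev_path Per-strand bedGraph files.
#' @param genome A [genome_spec()].
#' @return A [stranded_profile()].
#' @export
read_profile_bedgraph <- function(fwd_path, rev_path, genome) {
  stranded_profile(read_bedgraph(fwd_path, genome),
                   read_bedgraph(rev_path, genome), genome)
}

#' Write the mask of a ratio track as BED
#'
#' @param ratio A masked [ratio_track()].
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(ratio, path) {
  need_pkg("rtracklayer"); need_pkg("GenomicRanges")
  iv <- mask_intervals(ratio)
  gr <- GenomicRanges::GRanges(
    seqnames = profile_chrom(ratio$genome),
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a genome sequence as FASTA
#'
#' @param genome A `genome_spec` with sequence.
#' @param path Output FASTA file.
#' @param name Sequence name.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, name = "chr") {
  need_pkg("Biostrings")
  if (is.null(genome$sequence)) abort("genome has no sequence")
  set_ <- Biostrings::DNAStringSet(genome$sequence)
  names(set_) <- name
  Biostrings::writeXStringSet(set_, path)
  invisible(path)
}

#' Read the first sequence of a FASTA file into a genome spec
#'
#' @param path FASTA file.
#' @param oriC,dif Landmark coordinates for the resulting [genome_spec()].
#' @return A `genome_spec` with sequence.
#' @export
read_genome_fasta <- function(path, oriC = 0L, dif = 1L) {
  need_pkg("Biostrings")
  set_ <- Biostrings::readDNAStringSet(path)
  seq <- as.character(set_[[1]])
  genome_spec(length = nchar(seq), oriC = oriC, dif = dif, sequence = seq)
}

#' Write a site table as TSV
#'
#' @param sites A site tibble (e.g. from [call_cleavage_sites()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  need_pkg("readr")
  readr::write_tsv(sites, path)
  invisible(path)
}

#' Read a site table written by [write_sites_tsv()]
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_sites_tsv <- function(path) {
  need_pkg("readr")
  readr::read_tsv(path, show_col_types = FALSE)
}
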