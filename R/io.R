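#' Read and write genome sequences as FASTA
#'
#' Thin wrappers over `Biostrings` returning/accepting the named character
#' vectors the rest of the package works with.
#'
#' @param path FASTA file path.
#' @param sequences Named character vector of sequences (the locus-library
#'   mask character `+` is part of the DNA extended alphabet and round-trips).
#' @return `read_genome_fasta()`: a named character vector.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path
  )
  invisible(path)
}

tsv_header <- function(what) {
  paste0("# ", what, "; coordinates: 1-based inclusive; lengths in bases")
}

write_tsv_commented <- function(x, path, what) {
  writeLines(tsv_header(what), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write and read locus tables as TSV
#'
#' Columns are written 1-based inclusive with a comment header naming units
#' and the coordinate convention.
#'
#' @param loci Locus tibble.
#' @param path TSV path.
#' @return `read_loci_tsv()`: a locus tibble.
#' @export
write_loci_tsv <- function(loci, path) {
  write_tsv_commented(loci, path, "microsatellite loci")
}

#' @rdname write_loci_tsv
#' @export
read_loci_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write a locus library as masked FASTA
#'
#' @param library An `ssr_library` tibble.
#' @param path FASTA path.
#' @export
write_library_fasta <- function(library, path) {
  write_genome_fasta(setNames(library$seq, library$locus_id), path)
}

#' Write TE intervals as GFF3
#'
#' @param tes TE tibble (`chrom`, `start`, `end`, optionally `te_id`).
#' @param path GFF3 path.
#' @export
write_te_gff3 <- function(tes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    abort("Writing GFF3 needs the rtracklayer and GenomicRanges packages.")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tes$chrom,
    ranges = IRanges::IRanges(start = tes$start, end = tes$end),
    type = "transposable_element",
    ID = if ("te_id" %in% names(tes)) tes$te_id else
      paste0("TE", seq_len(nrow(tes)))
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read TE intervals from GFF3 or BED
#'
#' @param path Annotation path (`.gff3`/`.gff` or `.bed`).
#' @return A tibble `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_te_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading annotations needs the rtracklayer package.")
  }
  gr <- rtracklayer::import(path)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Write circos-ready conservation links
#'
#' One line per conserved position linking the progenitor locus window to
#' its subject interval, ready for a circos `links` track.
#'
#' @param records An `ssr_conservation` tibble with a `positions`
#'   list-column.
#' @param library The `ssr_library` the records came from.
#' @param path Output TSV path.
#' @export
write_circos_links <- function(records, library, path) {
  rows <- purrr::pmap(
    list(records$locus_id, records$positions),
    function(id, pos) {
      if (is.null(pos) || !is.data.frame(pos) || !nrow(pos)) return(NULL)
      lib <- library[library$locus_id == id, , drop = FALSE]
      tibble(
        source_chrom = lib$chrom, source_start = lib$window_start,
        source_end = lib$window_end,
        target_chrom = pos$subject_chrom, target_start = pos$sstart,
        target_end = pos$send, motif_length = lib$motif_length
      )
    }
  )
  links <- bind_rows(rows)
  if (!nrow(links)) {
    links <- tibble(
      source_chrom = character(0), source_start = integer(0),
      source_end = integer(0), target_chrom = character(0),
      target_start = integer(0), target_end = integer(0),
      motif_length = integer(0)
    )
  }
  write_tsv_commented(links, path, "conservation links (circos-ready)")
}
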