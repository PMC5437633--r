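#' Detection parameters for the microsatellite scanner
#'
#' All scoring constants of the seed-and-extend scan are pinned here. The
#' published search this reproduces names only the modified parameters
#' (maximum successive mismatch 3, minimum repeat length 15 nt, compound
#' association distance under 100 nt), so the remaining constants are fixed as
#' this package's definition and kept configurable.
#'
#' @param min_repeat_length Minimum reported tract length in bases.
#' @param max_successive_mismatch Longest tolerated run of consecutive
#'   mismatching bases inside a locus.
#' @param mismatch_penalty Score subtracted per mismatching base.
#' @param match_score Score added per base matching the expected phase base.
#' @param min_score Minimum reported locus score; with the defaults a perfect
#'   15-mer scores exactly 15.
#' @param compound_max_distance Two loci closer than this many bases form a
#'   compound and are excluded from genomic summaries.
#' @param motif_lengths Integer vector of motif lengths to search, a subset of
#'   1:6.
#' @return A list of class `ssr_detection_config`.
#' @export
detection_config <- function(min_repeat_length = 15L,
                             max_successive_mismatch = 3L,
                             mismatch_penalty = 5L,
                             match_score = 1L,
                             min_score = 15L,
                             compound_max_distance = 100L,
                             motif_lengths = 1:6) {
  cfg <- list(
    min_repeat_length = as.integer(min_repeat_length),
    max_successive_mismatch = as.integer(max_successive_mismatch),
    mismatch_penalty = as.integer(mismatch_penalty),
    match_score = as.integer(match_score),
    min_score = as.integer(min_score),
    compound_max_distance = as.integer(compound_max_distance),
    motif_lengths = sort(unique(as.integer(motif_lengths)))
  )
  stopifnot(
    cfg$min_repeat_length > 0, cfg$max_successive_mismatch > 0,
    cfg$mismatch_penalty > 0, cfg$match_score > 0, cfg$min_score > 0,
    cfg$compound_max_distance >= 0,
    all(cfg$motif_lengths %in% 1:6)
  )
  structure(cfg, class = "ssr_detection_config")
}

#' Scan DNA sequences for perfect and imperfect microsatellites
#'
#' `scan_sequence()` scans one DNA string; `scan_genome()` scans a named
#' character vector or a `Biostrings::DNAStringSet` and binds the results with
#' a `chrom` column. The scan is seed-and-extend: a seed is at least three
#' exact tandem copies of a primitive motif (at least 8 bases for 1-2 nt
#' motifs); extension scores `+match_score` per base matching the expected
#' phase base and `-mismatch_penalty` per mismatching base (`N` never
#' matches), terminating after a run of more than `max_successive_mismatch`
#' consecutive mismatches or when the score falls more than
#' `max_successive_mismatch * mismatch_penalty` below its running maximum,
#' then trims back to the maximal-score endpoints. Candidates shorter than
#' `min_repeat_length` or scoring below `min_score` are dropped; overlapping
#' candidates are resolved by higher score, ties by shorter motif, then
#' leftmost start, then lexicographic motif, so reported loci never overlap.
#'
#' @param seq A single DNA string over `A`,`C`,`G`,`T`,`N` (case-insensitive).
#' @param x Named character vector of sequences or a `DNAStringSet`.
#' @param config A [detection_config()].
#' @return A tibble with one row per locus: `chrom` (for `scan_genome()`),
#'   `start`, `end` (1-based inclusive), `motif` (as first detected, phase at
#'   `start`), `std_motif` (canonical class), `motif_length`, `length`,
#'   `mismatches`, `score`, `is_perfect`.
#' @examples
#' scan_sequence(paste0("ACGT", strrep("AG", 10), "TCCA"))
#' @export
scan_sequence <- function(seq, config = detection_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(empty_loci())
  if (grepl("[^ACGTN]", seq)) {
    abort("Sequence contains characters outside A, C, G, T, N.")
  }
  cand <- scan_candidates_cpp(
    seq, config$motif_lengths, config$max_successive_mismatch,
    config$match_score, config$mismatch_penalty
  )
  cand <- as_tibble(cand)
  cand <- cand[cand$end - cand$start + 1L >= config$min_repeat_length &
                 cand$score >= config$min_score, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_loci())
  cand$motif_length <- nchar(cand$motif)
  cand <- resolve_overlaps(cand)
  cand %>%
    mutate(
      std_motif = standardize_motifs(.data$motif),
      length = .data$end - .data$start + 1L,
      is_perfect = .data$mismatches == 0L
    ) %>%
    select(
      "start", "end", "motif", "std_motif", "motif_length",
      "length", "mismatches", "score", "is_perfect"
    ) %>%
    arrange(.data$start)
}

#' @rdname scan_sequence
#' @export
scan_genome <- function(x, config = detection_config()) {
  x <- as_sequence_vector(x)
  out <- purrr::imap(x, function(s, nm) {
    loci <- scan_sequence(s, config)
    if (nrow(loci)) dplyr::bind_cols(tibble(chrom = nm), loci) else NULL
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(dplyr::bind_cols(tibble(chrom = character(0)), empty_loci()))
  }
  out
}

empty_loci <- function() {
  tibble(
    start = integer(0), end = integer(0), motif = character(0),
    std_motif = character(0), motif_length = integer(0), length = integer(0),
    mismatches = integer(0), score = integer(0), is_perfect = logical(0)
  )
}

# Greedy non-overlap selection: score desc, shorter motif, leftmost start,
# lexicographic motif as the final deterministic tie-break.
resolve_overlaps <- function(cand) {
  cand <- cand[order(-cand$score, cand$motif_length, cand$start, cand$motif), ,
               drop = FALSE]
  n <- nrow(cand)
  keep <- logical(n)
  acc_start <- integer(0)
  acc_end <- integer(0)
  for (i in seq_len(n)) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!length(acc_start) || !any(s <= acc_end & e >= acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  cand[keep, , drop = FALSE]
}

as_sequence_vector <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) abort("`x` must be a named character vector or DNAStringSet.")
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    abort("Sequences must be named (chromosome ids).")
  }
  x
}

#' Flag and exclude compound microsatellites
#'
#' Two same-chromosome loci whose gap (bases strictly between them) is smaller
#' than `compound_max_distance` are associated into a compound; both members
#' are excluded from genomic summaries. `flag_compounds()` adds a logical
#' `compound` column (chains propagate: each locus is flagged if its gap to
#' either neighbour is under the threshold); `exclude_compounds()` returns the
#' surviving subset, order preserved.
#'
#' @param loci A locus tibble from [scan_genome()] (needs `chrom`, `start`,
#'   `end`).
#' @param config A [detection_config()]; only `compound_max_distance` is used.
#' @return `flag_compounds()`: `loci` with a `compound` column;
#'   `exclude_compounds()`: the non-compound subset (with the `compound`
#'   column dropped).
#' @examples
#' loci <- tibble::tibble(chrom = "c1", start = c(1L, 120L), end = c(20L, 140L))
#' flag_compounds(loci)$compound # gap 99 -> both TRUE
#' @export
flag_compounds <- function(loci, config = detection_config()) {
  stopifnot(all(c("chrom", "start", "end") %in% names(loci)))
  loci %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(
      gap_prev = .data$start - dplyr::lag(.data$end) - 1L,
      gap_next = dplyr::lead(.data$start) - .data$end - 1L,
      compound = (!is.na(.data$gap_prev) & .data$gap_prev < config$compound_max_distance) |
        (!is.na(.data$gap_next) & .data$gap_next < config$compound_max_distance)
    ) %>%
    ungroup() %>%
    select(-"gap_prev", -"gap_next")
}

#' @rdname flag_compounds
#' @export
exclude_compounds <- function(loci, config = detection_config()) {
  flag_compounds(loci, config) %>%
    filter(!.data$compound) %>%
    select(-"compound")
}

#' Summarize locus density and imperfection per motif-length class
#'
#' @param loci Locus tibble (compound-excluded for genomic summaries).
#' @param sequence_lengths Named numeric vector of chromosome lengths in
#'   bases.
#' @return A list with `genome` (per motif-length class: `n_loci`,
#'   `density_per_mb`, `percent_abundance`, `imperfection_percent`,
#'   `mean_repeat_length`, `mean_mismatch`) and `per_chromosome` (the same by
#'   chromosome). Percent abundance sums to 100 over classes.
#' @export
summarize_density <- function(loci, sequence_lengths) {
  if (length(sequence_lengths) == 0L || sum(sequence_lengths) <= 0) {
    abort("Total sequence length must be positive.")
  }
  total_mb <- sum(sequence_lengths) / 1e6
  genome <- loci %>%
    group_by(motif_length = .data$motif_length) %>%
    summarise(
      n_loci = dplyr::n(),
      imperfection_percent = 100 * mean(.data$mismatches > 0),
      mean_repeat_length = mean(.data$length),
      mean_mismatch = mean(.data$mismatches),
      .groups = "drop"
    ) %>%
    mutate(
      density_per_mb = .data$n_loci / total_mb,
      percent_abundance = 100 * .data$n_loci / sum(.data$n_loci)
    )
  per_chrom <- loci %>%
    group_by(chrom = .data$chrom, motif_length = .data$motif_length) %>%
    summarise(
      n_loci = dplyr::n(),
      imperfection_percent = 100 * mean(.data$mismatches > 0),
      mean_repeat_length = mean(.data$length),
      mean_mismatch = mean(.data$mismatches),
      .groups = "drop"
    ) %>%
    left_join(
      tibble(
        chrom = names(sequence_lengths),
        chrom_mb = as.numeric(sequence_lengths) / 1e6
      ),
      by = "chrom"
    ) %>%
    mutate(density_per_mb = .data$n_loci / .data$chrom_mb) %>%
    select(-"chrom_mb")
  list(genome = genome, per_chromosome = per_chrom)
}

#' Summarize microsatellites detected in coding sequences
#'
#' Applies to loci detected on a CDS FASTA with the same configuration, with
#' each gene treated as its own sequence (`chrom` = gene id).
#'
#' @param loci Locus tibble over genes (before compound exclusion).
#' @param cds_lengths Named numeric vector of CDS lengths in bases.
#' @param config A [detection_config()] (compound distance).
#' @return A list: `per_class` (per motif length: count, density per Mb of
#'   CDS, percent abundance, mean mismatch, mean repeat length), `genes`
#'   (genes with >= 1 repeat, genes with >= 1 mismatched repeat), and
#'   `n_compound` (loci removed as compound members).
#' @export
summarize_cds <- function(loci, cds_lengths, config = detection_config()) {
  flagged <- flag_compounds(loci, config)
  keep <- filter(flagged, !.data$compound)
  total_mb <- sum(cds_lengths) / 1e6
  per_class <- keep %>%
    group_by(motif_length = .data$motif_length) %>%
    summarise(
      n_loci = dplyr::n(),
      mean_repeat_length = mean(.data$length),
      mean_mismatch = mean(.data$mismatches),
      .groups = "drop"
    ) %>%
    mutate(
      density_per_mb = .data$n_loci / total_mb,
      percent_abundance = if (sum(.data$n_loci) > 0) {
        100 * .data$n_loci / sum(.data$n_loci)
      } else numeric(length(.data$n_loci))
    )
  list(
    per_class = per_class,
    genes = tibble(
      genes_with_repeat = dplyr::n_distinct(keep$chrom),
      genes_with_imperfect_repeat =
        dplyr::n_distinct(keep$chrom[keep$mismatches > 0])
    ),
    n_compound = sum(flagged$compound)
  )
}
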