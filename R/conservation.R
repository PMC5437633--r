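#' Parameters for the flank-based homology search
#'
#' The search locates exact-word seeds through an index of the subject
#' genome and extends them without gaps under X-drop termination (the
#' package's divergence model is substitution-only); HSPs are chained into
#' hits and scored with Karlin-Altschul E-values. `lambda` is solved exactly
#' from the match/mismatch score distribution at uniform base composition; `K`
#' is a pinned calibration constant (E-values are compared to a threshold
#' orders of magnitude away from both signal and noise).
#'
#' @param word_size Exact-match seed length.
#' @param match,mismatch Match reward and (negative) mismatch penalty.
#' @param xdrop Extension stops when the score falls this far below its
#'   running maximum.
#' @param min_hsp_score Minimum HSP score retained for clustering.
#' @param max_bucket Seed words occurring more often than this in the subject
#'   are skipped (repeat words carry no locus-specific signal).
#' @param K Karlin-Altschul K constant.
#' @param min_query_cover,min_identity Inclusive filter thresholds in percent.
#' @param max_evalue Inclusive E-value ceiling.
#' @param both_strands Search the reverse complement of each query too.
#' @return A list of class `ssr_search_config`.
#' @export
search_config <- function(word_size = 12L, match = 1L, mismatch = -2L,
                          xdrop = 20L, min_hsp_score = 24L, max_bucket = 64L,
                          K = 0.5, min_query_cover = 50, min_identity = 70,
                          max_evalue = 1e-10, both_strands = TRUE) {
  stopifnot(word_size >= 4, word_size <= 15, match > 0, mismatch < 0,
            xdrop > 0, min_hsp_score >= word_size, max_bucket > 0, K > 0,
            min_query_cover >= 0, min_identity >= 0, max_evalue >= 0)
  structure(
    list(word_size = as.integer(word_size), match = as.integer(match),
         mismatch = as.integer(mismatch), xdrop = as.integer(xdrop),
         min_hsp_score = as.integer(min_hsp_score),
         max_bucket = as.integer(max_bucket), K = K,
         min_query_cover = min_query_cover, min_identity = min_identity,
         max_evalue = max_evalue, both_strands = isTRUE(both_strands)),
    class = "ssr_search_config"
  )
}

karlin_lambda <- function(match, mismatch) {
  key <- paste(match, mismatch)
  if (is.null(the$lambda_cache)) the$lambda_cache <- list()
  if (!is.null(the$lambda_cache[[key]])) return(the$lambda_cache[[key]])
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lam <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  the$lambda_cache[[key]] <- lam
  lam
}

#' Build a hard-masked, flank-based locus library
#'
#' Each retained locus becomes one entry: up to `flank` bases of left flank,
#' the repeat tract replaced by the mask character, and up to `flank` bases of
#' right flank (flanks truncate at sequence ends). Excluded are 1-nt loci
#' (homopolymer sequencing artefacts), compound-flagged loci, and loci whose
#' flanked windows overlap another locus's flanked window.
#'
#' @param loci Locus tibble from [scan_genome()]; if it lacks a `compound`
#'   column, [flag_compounds()] is applied with default settings.
#' @param sequences Named character vector or `DNAStringSet` the loci were
#'   detected on.
#' @param flank Flank width in bases (350 by default).
#' @param mask_char Masking symbol; a dedicated character distinct from `N` so
#'   assembly gaps and masked tracts stay distinguishable.
#' @return A tibble of class `ssr_library`: `locus_id`, `chrom`,
#'   `window_start`, `window_end`, `mask_start`, `mask_end` (positions within
#'   the entry), `motif_length`, `std_motif`, `seq`.
#' @export
build_locus_library <- function(loci, sequences, flank = 350L,
                                mask_char = "+") {
  sequences <- as_sequence_vector(sequences)
  stopifnot(nchar(mask_char) == 1L, mask_char != "N")
  if (!"compound" %in% names(loci)) loci <- flag_compounds(loci)
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- paste0(loci$chrom, ":", loci$start, "-", loci$end)
  }
  seq_len_by_chrom <- nchar(sequences)
  if (!all(loci$chrom %in% names(sequences))) {
    abort("Locus chromosome not present in `sequences`.")
  }
  if (any(loci$start < 1L | loci$end > seq_len_by_chrom[loci$chrom])) {
    abort("Locus outside sequence bounds.")
  }

  win <- loci %>%
    mutate(
      window_start = pmax(1L, .data$start - as.integer(flank)),
      window_end = pmin(unname(seq_len_by_chrom[.data$chrom]),
                        .data$end + as.integer(flank))
    )
  # overlap of flanked windows against any other locus's window
  win <- win %>%
    group_by(.data$chrom) %>%
    arrange(.data$window_start, .by_group = TRUE) %>%
    mutate(
      overlaps = (!is.na(dplyr::lag(.data$window_end)) &
                    .data$window_start <= dplyr::lag(.data$window_end)) |
        (!is.na(dplyr::lead(.data$window_start)) &
           .data$window_end >= dplyr::lead(.data$window_start))
    ) %>%
    ungroup()

  keep <- win %>%
    filter(.data$motif_length >= 2L, !.data$compound, !.data$overlaps)
  entry_seq <- character(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    s <- substr(sequences[[keep$chrom[i]]], keep$window_start[i], keep$window_end[i])
    ms <- keep$start[i] - keep$window_start[i] + 1L
    me <- keep$end[i] - keep$window_start[i] + 1L
    substr(s, ms, me) <- strrep(mask_char, me - ms + 1L)
    entry_seq[i] <- s
  }
  out <- keep %>%
    mutate(
      mask_start = .data$start - .data$window_start + 1L,
      mask_end = .data$end - .data$window_start + 1L,
      seq = entry_seq
    ) %>%
    select(
      "locus_id", "chrom", "window_start", "window_end",
      "mask_start", "mask_end", "motif_length", "std_motif", "seq"
    )
  class(out) <- c("ssr_library", class(out))
  out
}

#' Search library entries (or sequences) against a subject genome
#'
#' Runs the seed-extend search and clusters HSPs into hits per (query,
#' chromosome, strand): HSPs on compatible diagonals (within 50) and within a
#' query length plus 500 bases on the subject are chained, so the two flank
#' alignments of a masked entry form one hit spanning the tract. Query cover
#' is the merged fraction of query columns aligned; identity is over aligned
#' columns only (mask characters are never aligned).
#'
#' @param queries An `ssr_library` tibble, or a named character vector.
#' @param subject Named character vector or `DNAStringSet`.
#' @param config A [search_config()].
#' @return Hits tibble: `query_id`, `subject_chrom`, `sstart`, `send`,
#'   `strand`, `query_cover`, `identity`, `score`, `bit_score`, `e_value`,
#'   `n_hsps`, sorted by `query_id` then `bit_score` descending.
#' @export
search_genome <- function(queries, subject, config = search_config()) {
  if (inherits(queries, "ssr_library") ||
      (is.data.frame(queries) && all(c("locus_id", "seq") %in% names(queries)))) {
    qseq <- setNames(queries$seq, queries$locus_id)
  } else {
    qseq <- as_sequence_vector(queries)
  }
  subject <- as_sequence_vector(subject)
  if (length(qseq) == 0L || length(subject) == 0L || sum(nchar(subject)) == 0L) {
    return(empty_hits())
  }
  hsps <- seed_extend_search_cpp(
    unname(qseq), unname(subject), config$word_size, config$match,
    config$mismatch, config$xdrop, config$min_hsp_score, config$max_bucket,
    config$both_strands
  )
  offsets <- attr(hsps, "chrom_offset")
  subject_total <- attr(hsps, "subject_total")
  hsps <- as_tibble(hsps)
  if (nrow(hsps) == 0L) return(empty_hits())

  # map concatenated coordinates back to chromosomes
  ci <- findInterval(hsps$sstart_global - 1L, offsets)
  hsps$subject_chrom <- names(subject)[ci]
  hsps$sstart <- hsps$sstart_global - offsets[ci]
  hsps$send <- hsps$send_global - offsets[ci]
  hsps$query_id <- names(qseq)[hsps$query_idx]
  hsps$diag <- hsps$sstart - hsps$qstart

  lam <- karlin_lambda(config$match, config$mismatch)
  qlens <- setNames(nchar(qseq), names(qseq))

  out <- cluster_hsps(hsps, qlens) %>%
    mutate(
      bit_score = (lam * .data$score - log(config$K)) / log(2),
      e_value = config$K * unname(qlens[.data$query_id]) * subject_total *
        exp(-lam * .data$score)
    ) %>%
    arrange(.data$query_id, dplyr::desc(.data$bit_score)) %>%
    select(
      "query_id", "subject_chrom", "sstart", "send", "strand",
      "query_cover", "identity", "score", "bit_score", "e_value", "n_hsps"
    )
  out
}

# Chain HSPs into hits: within (query, chromosome, strand), HSPs sorted by
# subject start open a new hit when they jump more than a query length plus
# 500 bases on the subject or drift more than 50 off the running diagonal.
# Query cover merges overlapping query intervals; identity is over aligned
# columns only. Fully vectorized — this step sees one row per HSP across all
# queries at once.
cluster_hsps <- function(hsps, qlens) {
  qlen <- unname(qlens[hsps$query_id])
  h <- hsps %>%
    mutate(qlen = qlen) %>%
    arrange(.data$query_idx, .data$subject_chrom, .data$strand, .data$sstart,
            .data$qstart)
  same <- with(h, query_idx == dplyr::lag(query_idx) &
                 subject_chrom == dplyr::lag(subject_chrom) &
                 strand == dplyr::lag(strand))
  same[1] <- FALSE
  near <- with(h, sstart - dplyr::lag(send) <= qlen + 500 &
                 abs(diag - dplyr::lag(diag)) <= 50)
  near[1] <- FALSE
  h$cluster <- cumsum(!(same & near))

  h <- h %>%
    arrange(.data$cluster, .data$qstart) %>%
    group_by(.data$cluster) %>%
    mutate(
      prev_max = dplyr::lag(cummax(.data$qend), default = 0L),
      contrib = pmax(0L, .data$qend - pmax(.data$qstart, .data$prev_max + 1L) + 1L)
    ) %>%
    summarise(
      query_id = .data$query_id[1],
      subject_chrom = .data$subject_chrom[1],
      strand = .data$strand[1],
      sstart = min(.data$sstart), send = max(.data$send),
      query_cover = 100 * sum(.data$contrib) / .data$qlen[1],
      identity = 100 * sum(.data$length - .data$mismatches) / sum(.data$length),
      score = sum(.data$score), n_hsps = dplyr::n(),
      .groups = "drop"
    )
  select(h, -"cluster")
}

empty_hits <- function() {
  tibble(
    query_id = character(0), subject_chrom = character(0),
    sstart = integer(0), send = integer(0), strand = integer(0),
    query_cover = numeric(0), identity = numeric(0), score = numeric(0),
    bit_score = numeric(0), e_value = numeric(0), n_hsps = integer(0)
  )
}

#' Apply the conservation hit filters (inclusive thresholds)
#'
#' A hit qualifies when query cover is at least `min_query_cover` percent,
#' identity at least `min_identity` percent and E-value at most `max_evalue`;
#' all three bounds are inclusive.
#'
#' @param hits Hits tibble from [search_genome()].
#' @param config A [search_config()] carrying the thresholds.
#' @return The qualifying subset of `hits`.
#' @export
filter_hits <- function(hits, config = search_config()) {
  filter(
    hits,
    .data$query_cover >= config$min_query_cover,
    .data$identity >= config$min_identity,
    .data$e_value <= config$max_evalue
  )
}

#' Discard library entries that are not unique within their own library
#'
#' Each entry is searched against all other entries of the same library; any
#' entry with a non-self hit passing the standard filters is discarded, since
#' its flanks could not distinguish its locus during cross-genome search.
#'
#' @param library An `ssr_library` tibble.
#' @param config A [search_config()].
#' @return The unique subset of the library.
#' @export
self_uniqueness_filter <- function(library, config = search_config()) {
  if (nrow(library) <= 1L) return(library)
  hits <- search_genome(library, setNames(library$seq, library$locus_id), config)
  offenders <- hits %>%
    filter(.data$query_id != .data$subject_chrom) %>%
    filter_hits(config) %>%
    pull(.data$query_id)
  library[!library$locus_id %in% unique(offenders), , drop = FALSE]
}

#' Assign conservation status to library entries
#'
#' Qualifying forward hits are reduced to non-overlapping candidate positions
#' (best bit score first). Zero candidates means `lost`; more than
#' `max_positions` candidate positions means `ambiguous` (duplication beyond
#' the allowed two physical positions); otherwise the candidate windows are
#' searched back against the progenitor genome and the entry is `conserved`
#' iff at least one candidate's reciprocal top qualifying hit overlaps the
#' original locus window by at least one base.
#'
#' @param library An `ssr_library` (after [self_uniqueness_filter()]).
#' @param subject Named character vector or `DNAStringSet`: the derived
#'   (sub)genome.
#' @param progenitor Named character vector or `DNAStringSet`: the genome the
#'   library was built from (for the reciprocal search).
#' @param config A [search_config()].
#' @param max_positions Allowed physical positions per locus (2 under a
#'   whole-genome duplication).
#' @param reciprocal_pad Bases added around each candidate window before the
#'   reciprocal search.
#' @return A tibble of class `ssr_conservation`: `locus_id`, `motif_length`,
#'   `std_motif`, `status` (`conserved`/`lost`/`ambiguous`), `n_positions`,
#'   `reciprocal_confirmed`, and a `positions` list-column of subject
#'   intervals.
#' @export
assign_conservation <- function(library, subject, progenitor,
                                config = search_config(), max_positions = 2L,
                                reciprocal_pad = 50L) {
  subject <- as_sequence_vector(subject)
  fwd <- filter_hits(search_genome(library, subject, config), config)

  # reduce each query's qualifying hits to non-overlapping candidate
  # positions, best bit score first; queries with a single hit need no work
  fwd <- arrange(fwd, .data$query_id, dplyr::desc(.data$bit_score))
  n_hits <- table(fwd$query_id)
  multi_ids <- names(n_hits[n_hits > 1L])
  cand <- fwd[!(fwd$query_id %in% multi_ids), , drop = FALSE]
  if (length(multi_ids)) {
    multis <- fwd[fwd$query_id %in% multi_ids, , drop = FALSE]
    cand <- bind_rows(
      cand,
      bind_rows(lapply(split(multis, multis$query_id), pick_positions))
    )
    cand <- arrange(cand, .data$query_id, dplyr::desc(.data$bit_score))
  }

  # reciprocal search of all candidate windows in one batch
  rec_conf <- rep(FALSE, nrow(cand))
  if (nrow(cand)) {
    top2 <- cand %>%
      group_by(.data$query_id) %>%
      dplyr::slice_head(n = max_positions) %>%
      ungroup()
    win_id <- paste0("w", seq_len(nrow(top2)))
    slen <- nchar(subject)
    wseq <- vapply(seq_len(nrow(top2)), function(i) {
      substr(
        subject[[top2$subject_chrom[i]]],
        max(1L, top2$sstart[i] - reciprocal_pad),
        min(slen[[top2$subject_chrom[i]]], top2$send[i] + reciprocal_pad)
      )
    }, character(1))
    rec <- filter_hits(
      search_genome(setNames(wseq, win_id), progenitor, config), config
    )
    rec_top <- rec %>%
      group_by(.data$query_id) %>%
      dplyr::slice_max(.data$bit_score, n = 1L, with_ties = FALSE) %>%
      ungroup()
    lib_win <- library[match(top2$query_id, library$locus_id), ,
                       drop = FALSE]
    rt <- rec_top[match(win_id, rec_top$query_id), , drop = FALSE]
    confirmed <- !is.na(rt$subject_chrom) &
      rt$subject_chrom == lib_win$chrom &
      rt$sstart <= lib_win$window_end & rt$send >= lib_win$window_start
    top2$confirmed <- confirmed
    cand <- left_join(
      cand,
      select(top2, "query_id", "subject_chrom", "sstart", "send", "confirmed"),
      by = c("query_id", "subject_chrom", "sstart", "send")
    )
    cand$confirmed[is.na(cand$confirmed)] <- FALSE
  } else {
    cand$confirmed <- logical(0)
  }

  summary <- cand %>%
    group_by(locus_id = .data$query_id) %>%
    summarise(
      n_candidates = dplyr::n(),
      n_confirmed = sum(.data$confirmed),
      positions = list(tibble(
        subject_chrom = subject_chrom[confirmed],
        sstart = sstart[confirmed],
        send = send[confirmed]
      )),
      .groups = "drop"
    )

  out <- library %>%
    select("locus_id", "motif_length", "std_motif") %>%
    left_join(summary, by = "locus_id") %>%
    mutate(
      n_candidates = dplyr::coalesce(.data$n_candidates, 0L),
      n_confirmed = dplyr::coalesce(.data$n_confirmed, 0L),
      status = dplyr::case_when(
        .data$n_candidates == 0L ~ "lost",
        .data$n_candidates > max_positions ~ "ambiguous",
        .data$n_confirmed >= 1L ~ "conserved",
        TRUE ~ "lost"
      ),
      n_positions = if_else(.data$status == "conserved", .data$n_confirmed, 0L),
      reciprocal_confirmed = .data$n_confirmed >= 1L
    ) %>%
    select(
      "locus_id", "motif_length", "std_motif", "status", "n_positions",
      "reciprocal_confirmed", "positions"
    )
  class(out) <- c("ssr_conservation", class(out))
  out
}

pick_positions <- function(h) {
  h <- h[order(-h$bit_score), , drop = FALSE]
  keep <- logical(nrow(h))
  acc_s <- integer(0); acc_e <- integer(0); acc_c <- character(0)
  for (i in seq_len(nrow(h))) {
    ov <- acc_c == h$subject_chrom[i] & h$sstart[i] <= acc_e & h$send[i] >= acc_s
    if (!any(ov)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, h$sstart[i]); acc_e <- c(acc_e, h$send[i])
      acc_c <- c(acc_c, h$subject_chrom[i])
    }
  }
  h[keep, , drop = FALSE]
}

#' Per-class conservation proportions
#'
#' @param records An `ssr_conservation` tibble.
#' @return A tibble per motif-length class: counts of conserved, lost and
#'   ambiguous loci, and `proportion_conserved` = conserved / (conserved +
#'   lost) with ambiguous excluded from the denominator (`NA` and
#'   `undefined = TRUE` when the denominator is empty).
#' @export
conservation_proportions <- function(records) {
  records %>%
    group_by(motif_length = .data$motif_length) %>%
    summarise(
      n_conserved = sum(.data$status == "conserved"),
      n_lost = sum(.data$status == "lost"),
      n_ambiguous = sum(.data$status == "ambiguous"),
      .groups = "drop"
    ) %>%
    mutate(
      proportion_conserved = if_else(
        .data$n_conserved + .data$n_lost > 0L,
        .data$n_conserved / (.data$n_conserved + .data$n_lost),
        NA_real_
      ),
      undefined = .data$n_conserved + .data$n_lost == 0L
    )
}

#' Read tabular hits from an external aligner
#'
#' Adapter for 12-column tabular alignment output (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore)
#' so real-genome runs can use an external gapped aligner while keeping the
#' package's filtering and conservation logic.
#'
#' @param path Path to the tabular file (tab-separated, no header).
#' @param query_lengths Named vector of query lengths, used to compute query
#'   cover.
#' @return A hits tibble compatible with [filter_hits()].
#' @export
read_tabular_hits <- function(path, query_lengths) {
  cols <- c("query_id", "subject_chrom", "identity", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "e_value",
            "bit_score")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       comment = "#")
  x %>%
    mutate(
      strand = if_else(.data$send >= .data$sstart, 1L, -1L),
      sstart2 = pmin(.data$sstart, .data$send),
      send2 = pmax(.data$sstart, .data$send),
      query_cover = 100 * (abs(.data$qend - .data$qstart) + 1) /
        unname(query_lengths[.data$query_id]),
      score = .data$bit_score, n_hsps = 1L
    ) %>%
    select(
      "query_id", "subject_chrom", sstart = "sstart2", send = "send2",
      "strand", "query_cover", "identity", "score", "bit_score", "e_value",
      "n_hsps"
    )
}
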