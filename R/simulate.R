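#' Configuration for the synthetic genome generator
#'
#' Defines the study conditions the simulator emulates: chromosomes of i.i.d.
#' background sequence at a stated GC content carrying planted microsatellite
#' tracts of known motif, length and mismatch count, plus planted
#' transposable-element intervals. Background is rejection-sampled so that no
#' unplanted tract passes the detector, which keeps truth tables exact.
#'
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bases.
#' @param gc_content Fraction of G+C in background sequence, in `[0, 1]`.
#' @param planted_loci_per_chromosome Number of planted microsatellites per
#'   chromosome.
#' @param motif_length_weights Named numeric vector over motif lengths
#'   `"1"`-`"6"`; sampling weights for the planted motif-length classes.
#' @param mismatch_count_distribution Named probability vector over mismatch
#'   counts `"0"`-`"4"`; must sum to 1. Requested counts are capped by what a
#'   tract can carry (see Details).
#' @param repeat_length_range Two-element integer vector, minimum >= 15;
#'   planted tract lengths are drawn uniformly within it (lower-bounded by the
#'   seed length of the drawn motif class).
#' @param te_per_chromosome Planted transposable-element intervals per
#'   chromosome.
#' @param te_length_range Two-element integer range of TE lengths in bases.
#'
#' @details Planted mismatches are substitutions only, never in the first
#'   `max(3k, 8)` bases (so a detection seed always exists) nor in the last
#'   full motif unit, and pairwise at least 6 bases apart (so the scanner's
#'   score never dips far enough to truncate the tract). The requested
#'   mismatch count is additionally capped so the locus still meets the
#'   detector's score threshold (`length - 6 * mismatches >= 15` at default
#'   scoring); the realized count is what the truth table records.
#' @return A list of class `ssr_simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3L,
                              chromosome_length = 200000L,
                              gc_content = 0.35,
                              planted_loci_per_chromosome = 150L,
                              motif_length_weights =
                                c("1" = 1, "2" = 1, "3" = 1, "4" = 1, "5" = 1, "6" = 1),
                              mismatch_count_distribution =
                                c("0" = 0.6, "1" = 0.2, "2" = 0.1, "3" = 0.07, "4" = 0.03),
                              repeat_length_range = c(15L, 80L),
                              te_per_chromosome = 20L,
                              te_length_range = c(500L, 3000L)) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    gc_content = gc_content,
    planted_loci_per_chromosome = as.integer(planted_loci_per_chromosome),
    motif_length_weights = motif_length_weights,
    mismatch_count_distribution = mismatch_count_distribution,
    repeat_length_range = as.integer(repeat_length_range),
    te_per_chromosome = as.integer(te_per_chromosome),
    te_length_range = as.integer(te_length_range)
  )
  w <- cfg$motif_length_weights
  p <- cfg$mismatch_count_distribution
  if (is.null(names(w)) || !all(names(w) %in% as.character(1:6)) || any(w < 0)) {
    abort("`motif_length_weights` must be non-negative and named by motif lengths 1-6.")
  }
  if (is.null(names(p)) || !all(names(p) %in% as.character(0:4)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9) {
    abort("`mismatch_count_distribution` must be a probability vector named '0'-'4' summing to 1.")
  }
  stopifnot(
    cfg$n_chromosomes > 0, cfg$chromosome_length > 0,
    cfg$gc_content >= 0, cfg$gc_content <= 1,
    cfg$planted_loci_per_chromosome >= 0,
    length(cfg$repeat_length_range) == 2L,
    cfg$repeat_length_range[1] >= 15L,
    cfg$repeat_length_range[2] >= cfg$repeat_length_range[1],
    length(cfg$te_length_range) == 2L, all(cfg$te_length_range > 0),
    cfg$te_per_chromosome >= 0
  )
  structure(cfg, class = "ssr_simulation_config")
}

ASCII_BASES <- c(65L, 67L, 71L, 84L) # A C G T

base_probs <- function(gc) {
  c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
}

seed_length <- function(k) as.integer(k * ifelse(k == 1L, 8L, ifelse(k == 2L, 4L, 3L)))

#' Generate a synthetic genome with planted microsatellites and TEs
#'
#' Chromosomes are i.i.d. background at the configured GC content; planted
#' repeat tracts are placed in evenly spaced slots with jitter, guaranteeing
#' at least 100 bases of non-repetitive sequence between tracts so no pair
#' merges into a compound. After assembly the chromosome is screened with the
#' detector: background windows producing unplanted calls, or calls that
#' disagree with a planted locus, are redrawn until the detector output
#' matches the truth table exactly (a locus that cannot be made recoverable is
#' removed from both sequence and truth).
#'
#' @param config A [simulation_config()].
#' @param detection A [detection_config()] used for the screening scans.
#' @return A list of class `ssr_genome`: `sequences` (named character vector),
#'   `truth` (tibble: `locus_id`, `chrom`, `start`, `end`, `motif`,
#'   `std_motif`, `motif_length`, `length`, `mismatches`), `tes` (tibble:
#'   `chrom`, `start`, `end`, `te_id`), and the `config`.
#' @export
generate_genome <- function(config = simulation_config(),
                            detection = detection_config()) {
  stopifnot(inherits(config, "ssr_simulation_config"))
  n_loci <- config$planted_loci_per_chromosome
  lmax <- config$repeat_length_range[2]
  slot <- if (n_loci > 0) config$chromosome_length %/% n_loci else config$chromosome_length
  if (n_loci > 0 && slot < lmax + 200L) {
    abort(paste0(
      "Chromosome too short for requested loci: need >= ",
      n_loci * (lmax + 200L), " bases for ", n_loci,
      " loci of up to ", lmax, " nt."
    ))
  }
  w <- config$motif_length_weights[config$motif_length_weights > 0]
  ks <- as.integer(names(w))
  if (n_loci > 0 && any(pmax(seed_length(ks), config$repeat_length_range[1]) > lmax)) {
    abort("repeat_length_range too narrow for the heaviest motif length (seed must fit).")
  }
  class_pool <- lapply(setNames(1:6, 1:6), function(k) enumerate_motif_classes(k)$motif_class)

  withr::with_seed(config$seed, {
    probs <- base_probs(config$gc_content)
    sequences <- character(config$n_chromosomes)
    names(sequences) <- paste0("chr", seq_len(config$n_chromosomes))
    truth_all <- list()
    tes_all <- list()

    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- names(sequences)[ci]
      L <- config$chromosome_length
      codes <- ASCII_BASES[sample.int(4L, L, replace = TRUE, prob = probs)]

      truth <- NULL
      if (n_loci > 0) {
        k <- ks[sample.int(length(ks), n_loci, replace = TRUE, prob = w)]
        motif <- vapply(k, function(kk) {
          pool <- class_pool[[kk]]
          pool[sample.int(length(pool), 1L)]
        }, character(1))
        lmin_eff <- pmax(config$repeat_length_range[1], seed_length(k))
        len <- lmin_eff + vapply(lmax - lmin_eff, function(r) sample.int(r + 1L, 1L) - 1L, integer(1))
        m_req <- as.integer(sample(
          names(config$mismatch_count_distribution), n_loci,
          replace = TRUE, prob = config$mismatch_count_distribution
        ))
        jitter <- sample.int(100L, n_loci, replace = TRUE) - 1L
        start <- (seq_len(n_loci) - 1L) * slot + 50L + jitter
        end <- start + len - 1L

        mm_real <- integer(n_loci)
        for (i in seq_len(n_loci)) {
          tract <- plant_tract(motif[i], len[i], m_req[i], detection)
          codes[start[i]:end[i]] <- tract$codes
          mm_real[i] <- tract$mismatches
        }
        truth <- tibble(
          locus_id = paste0(chrom, "_L", seq_len(n_loci)),
          chrom = chrom, start = start, end = end, motif = motif,
          std_motif = motif, motif_length = k, length = len,
          mismatches = mm_real
        )
      }

      cleaned <- screen_chromosome(codes, truth, detection, probs)
      codes <- cleaned$codes
      truth <- cleaned$truth
      sequences[ci] <- intToUtf8(codes)

      if (config$te_per_chromosome > 0) {
        tes_all[[chrom]] <- plant_tes(config, chrom, truth)
      }
      truth_all[[chrom]] <- truth
    }

    truth <- bind_rows(truth_all)
    if (is.null(truth) || nrow(truth) == 0L) {
      truth <- tibble(
        locus_id = character(0), chrom = character(0), start = integer(0),
        end = integer(0), motif = character(0), std_motif = character(0),
        motif_length = integer(0), length = integer(0), mismatches = integer(0)
      )
    }
    tes <- bind_rows(tes_all)
    if (is.null(tes) || nrow(tes) == 0L) {
      tes <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                    te_id = character(0))
    }
    structure(
      list(sequences = sequences, truth = truth, tes = tes, config = config),
      class = "ssr_genome"
    )
  })
}

# Build one repeat tract as integer ASCII codes with `m` substitutions placed
# under the spacing rules; returns the realized mismatch count.
plant_tract <- function(motif, len, m, detection) {
  k <- nchar(motif)
  mcodes <- utf8ToInt(motif)
  codes <- rep_len(mcodes, len)
  # cap by score threshold and by available substitution positions
  per_mm <- detection$match_score + detection$mismatch_penalty
  m_cap_score <- max(0L, (len * detection$match_score - detection$min_score) %/% per_mm)
  a <- seed_length(k) + 1L          # first allowed position (1-based in tract)
  # keep mismatches out of the last full unit and >= 5 bases from the tract
  # end, so max-score trimming never cuts the planted boundary
  b <- len - max(k, 5L)
  m_cap_pos <- if (b >= a) (b - a + 6L) %/% 6L else 0L
  m <- min(m, m_cap_score, m_cap_pos)
  if (m > 0L) {
    # sorted positions in a..b with pairwise spacing >= 6
    slots <- sort(sample.int(b - a + 1L - 5L * (m - 1L), m))
    pos <- a + slots - 1L + 5L * (seq_len(m) - 1L)
    for (p in pos) {
      alt <- setdiff(ASCII_BASES, codes[p])
      codes[p] <- alt[sample.int(3L, 1L)]
    }
  }
  list(codes = codes, mismatches = m)
}

# Rejection-screening: redraw background until the detector reproduces the
# truth table exactly and calls nothing else. Loci that stay unrecoverable
# (e.g. a substitution created a higher-scoring overlapping candidate) are
# erased and dropped from the truth.
screen_chromosome <- function(codes, truth, detection, probs,
                              max_iter = 40L, drop_after = 8L) {
  in_tract <- logical(length(codes))
  if (!is.null(truth) && nrow(truth)) {
    for (i in seq_len(nrow(truth))) in_tract[truth$start[i]:truth$end[i]] <- TRUE
  }
  fail_count <- if (!is.null(truth)) integer(nrow(truth)) else integer(0)
  replanted <- if (!is.null(truth)) logical(nrow(truth)) else logical(0)
  for (iter in seq_len(max_iter)) {
    calls <- scan_sequence(intToUtf8(codes), detection)
    key_call <- paste(calls$start, calls$end, calls$motif, calls$mismatches)
    if (!is.null(truth) && nrow(truth)) {
      key_truth <- paste(truth$start, truth$end, truth$motif, truth$mismatches)
    } else {
      key_truth <- character(0)
    }
    bad_call <- which(!(key_call %in% key_truth))
    bad_truth <- which(!(key_truth %in% key_call))
    if (!length(bad_call) && !length(bad_truth)) break

    fail_count[bad_truth] <- fail_count[bad_truth] + 1L
    stuck <- which(fail_count >= drop_after)
    # first fallback: replant the tract as a perfect repeat of the same
    # motif and length (perfect tracts only fail through their flanks, which
    # redrawing fixes); a locus that fails again after that is dropped
    replant <- stuck[!replanted[stuck]]
    if (length(replant)) {
      for (i in replant) {
        codes[truth$start[i]:truth$end[i]] <-
          rep_len(utf8ToInt(truth$motif[i]), truth$length[i])
      }
      truth$mismatches[replant] <- 0L
      replanted[replant] <- TRUE
      fail_count[replant] <- 0L
      stuck <- stuck[replanted[stuck] & fail_count[stuck] >= drop_after]
    }
    if (length(stuck)) {
      for (i in stuck) in_tract[truth$start[i]:truth$end[i]] <- FALSE
      truth <- truth[-stuck, , drop = FALSE]
      fail_count <- fail_count[-stuck]
      replanted <- replanted[-stuck]
      key_truth <- paste(truth$start, truth$end, truth$motif, truth$mismatches)
      bad_truth <- which(!(key_truth %in% key_call))
    }

    regions <- rbind(
      cbind(calls$start[bad_call], calls$end[bad_call]),
      if (!is.null(truth) && nrow(truth) && length(bad_truth)) {
        cbind(truth$start[bad_truth], truth$end[bad_truth])
      }
    )
    if (is.null(regions) || !nrow(regions)) next
    redraw <- logical(length(codes))
    for (r in seq_len(nrow(regions))) {
      lo <- max(1L, regions[r, 1] - 25L)
      hi <- min(length(codes), regions[r, 2] + 25L)
      redraw[lo:hi] <- TRUE
    }
    redraw <- redraw & !in_tract
    n_red <- sum(redraw)
    if (n_red) {
      codes[redraw] <- ASCII_BASES[sample.int(4L, n_red, replace = TRUE, prob = probs)]
    }
  }
  list(codes = codes, truth = truth)
}

plant_tes <- function(config, chrom, truth) {
  L <- config$chromosome_length
  n <- config$te_per_chromosome
  starts <- integer(0); ends <- integer(0)
  t_start <- if (!is.null(truth)) truth$start else integer(0)
  t_end <- if (!is.null(truth)) truth$end else integer(0)
  for (i in seq_len(n)) {
    for (attempt in 1:50) {
      len <- sample(config$te_length_range[1]:config$te_length_range[2], 1L)
      s <- sample.int(L - len, 1L)
      e <- s + len - 1L
      clash <- any(s <= t_end & e >= t_start) || any(s <= ends & e >= starts)
      if (!clash) {
        starts <- c(starts, s); ends <- c(ends, e)
        break
      }
    }
  }
  if (!length(starts)) return(NULL)
  ord <- order(starts)
  tibble(
    chrom = chrom, start = starts[ord], end = ends[ord],
    te_id = paste0(chrom, "_TE", seq_along(starts))
  )
}
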