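#' Progenitor-to-tetraploid evolution scenario
#'
#' Describes the simulated allopolyploid history: two diploid progenitors (A
#' and D) are carried into a tetraploid as A_T and D_T subgenomes over a
#' stated divergence time. Each progenitor locus is lost with a per-class
#' probability; flanking sequence accumulates substitutions at a per-base
#' rate. Loss erases the whole flanked locus window (tract plus 360 nt on
#' each side) with screened random sequence, modelling locus turnover: decay
#' is measured through flank-based homology, so a lost locus must no longer be
#' recognizable by its flanks.
#'
#' @param divergence_time Divergence time in million years (default 6, the
#'   median estimate for the cotton tetraploid WGD).
#' @param loss_probability Named vector over motif lengths `"1"`-`"6"`: the
#'   probability that a locus of that class is lost in the derived subgenome.
#'   Defaults are the per-class loss rates used throughout the package's
#'   simulations (2-nt fastest).
#' @param flank_substitution_rate Per-base substitution probability applied
#'   outside surviving repeat tracts.
#' @param duplication If `TRUE`, each progenitor chromosome enters the
#'   subgenome as two independently substituted copies (`_1`, `_2`),
#'   emulating retained whole-genome duplication; a surviving locus is then
#'   present at two physical positions.
#' @return A list of class `ssr_evolution_scenario`.
#' @export
evolution_scenario <- function(divergence_time = 6,
                               loss_probability =
                                 c("1" = 0.6, "2" = 0.6, "3" = 0.2,
                                   "4" = 0.15, "5" = 0.1, "6" = 0.15),
                               flank_substitution_rate = 0.01,
                               duplication = FALSE) {
  if (is.null(names(loss_probability)) ||
      !all(names(loss_probability) %in% as.character(1:6)) ||
      any(loss_probability < 0 | loss_probability > 1)) {
    abort("`loss_probability` must be in [0,1] and named by motif lengths 1-6.")
  }
  stopifnot(
    divergence_time > 0,
    flank_substitution_rate >= 0, flank_substitution_rate <= 1,
    is.logical(duplication)
  )
  structure(
    list(
      divergence_time = divergence_time,
      loss_probability = loss_probability,
      flank_substitution_rate = flank_substitution_rate,
      duplication = duplication
    ),
    class = "ssr_evolution_scenario"
  )
}

#' Evolve two progenitor genomes into a tetraploid with known conservation
#'
#' Each progenitor locus survives in its subgenome with probability
#' `1 - loss_probability[k]`; lost loci have their flanked window replaced by
#' screened random sequence; all sequence outside surviving tracts mutates at
#' the flank substitution rate. Coordinates are preserved (substitutions
#' only), so `conservation_truth` records the exact surviving positions.
#'
#' @param progenitor_A,progenitor_D `ssr_genome` objects from
#'   [generate_genome()] (D may be `NULL` for a single-subgenome scenario).
#' @param scenario An [evolution_scenario()].
#' @param seed Integer seed for loss draws and substitutions.
#' @return A list of class `ssr_tetraploid`: `sequences` (named vector; names
#'   are `A_T_<chrom>` / `D_T_<chrom>`, with `_1`/`_2` suffixes under
#'   duplication), `conservation_truth` (tibble: `locus_id`, `source_genome`,
#'   `motif_length`, `std_motif`, `surviving`, and for survivors the subject
#'   `chrom`, `start`, `end` of each copy), and the `scenario`.
#' @export
evolve_tetraploid <- function(progenitor_A, progenitor_D = NULL,
                              scenario = evolution_scenario(), seed = 1L) {
  stopifnot(inherits(progenitor_A, "ssr_genome"),
            inherits(scenario, "ssr_evolution_scenario"))
  withr::with_seed(as.integer(seed), {
    a <- evolve_subgenome(progenitor_A, "A", scenario)
    d <- if (!is.null(progenitor_D)) {
      stopifnot(inherits(progenitor_D, "ssr_genome"))
      evolve_subgenome(progenitor_D, "D", scenario)
    }
    structure(
      list(
        sequences = c(a$sequences, if (!is.null(d)) d$sequences),
        conservation_truth = bind_rows(a$truth, if (!is.null(d)) d$truth),
        scenario = scenario
      ),
      class = "ssr_tetraploid"
    )
  })
}

evolve_subgenome <- function(prog, label, scenario) {
  n_copies <- if (scenario$duplication) 2L else 1L
  probs <- base_probs(prog$config$gc_content)
  detection <- detection_config()

  truth <- prog$truth
  lost <- rbinom(nrow(truth), 1L,
                 scenario$loss_probability[as.character(truth$motif_length)]) == 1L

  sequences <- character(0)
  records <- list()
  for (ci in seq_along(prog$sequences)) {
    chrom <- names(prog$sequences)[ci]
    base_codes <- utf8ToInt(prog$sequences[[ci]])
    t_chr <- truth[truth$chrom == chrom, , drop = FALSE]
    lost_chr <- lost[truth$chrom == chrom]

    # erasure windows for lost loci, clipped halfway to neighbouring tracts
    erase <- erase_windows(t_chr, lost_chr, length(base_codes))

    for (cp in seq_len(n_copies)) {
      new_chrom <- paste0(label, "_T_", chrom, if (n_copies == 2L) paste0("_", cp))
      codes <- base_codes
      protect <- logical(length(codes))
      surv <- t_chr[!lost_chr, , drop = FALSE]
      for (i in seq_len(nrow(surv))) protect[surv$start[i]:surv$end[i]] <- TRUE

      if (nrow(erase)) {
        for (r in seq_len(nrow(erase))) {
          idx <- erase$lo[r]:erase$hi[r]
          codes[idx] <- ASCII_BASES[sample.int(4L, length(idx), replace = TRUE, prob = probs)]
        }
      }
      # flank substitutions outside surviving tracts
      mut <- runif(length(codes)) < scenario$flank_substitution_rate & !protect
      n_mut <- sum(mut)
      if (n_mut) {
        shift <- sample.int(3L, n_mut, replace = TRUE)
        cur <- match(codes[mut], ASCII_BASES)
        codes[mut] <- ASCII_BASES[((cur - 1L + shift) %% 4L) + 1L]
      }
      # re-screen so erased windows don't spawn accidental repeats; surviving
      # tracts are the expected truth for this copy
      cleaned <- screen_chromosome(codes, surv, detection, probs, max_iter = 25L,
                                   drop_after = 26L)
      sequences[new_chrom] <- intToUtf8(cleaned$codes)

      records[[new_chrom]] <- tibble(
        locus_id = t_chr$locus_id,
        source_genome = label,
        motif_length = t_chr$motif_length,
        std_motif = t_chr$std_motif,
        surviving = !lost_chr,
        chrom = if_else(!lost_chr, new_chrom, NA_character_),
        start = if_else(!lost_chr, t_chr$start, NA_integer_),
        end = if_else(!lost_chr, t_chr$end, NA_integer_)
      )
    }
  }
  list(sequences = sequences, truth = bind_rows(records))
}

erase_windows <- function(t_chr, lost_chr, L, pad = 360L) {
  if (!nrow(t_chr) || !any(lost_chr)) {
    return(tibble(lo = integer(0), hi = integer(0)))
  }
  prev_end <- dplyr::lag(t_chr$end, default = 0L)
  next_start <- dplyr::lead(t_chr$start, default = L + 1L)
  lo <- pmax(t_chr$start - pad, (prev_end + t_chr$start) %/% 2L + 1L, 1L)
  hi <- pmin(t_chr$end + pad, (t_chr$end + next_start) %/% 2L, L)
  tibble(lo = lo[lost_chr], hi = hi[lost_chr])
}
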