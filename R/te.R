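#' Count transposable elements near perfect and imperfect microsatellites
#'
#' A TE is "near" a locus when its interval overlaps the locus's flanked
#' window `[start - flank, end + flank]` by at least one base (windows are
#' clamped at position 1). Each (locus, TE) pair counts once, so one TE
#' sitting between two loci contributes to both. Each chromosome is an
#' independent segment.
#'
#' @param loci Locus tibble (`chrom`, `start`, `end`, `mismatches`).
#' @param tes TE interval tibble (`chrom`, `start`, `end`), e.g. from a GFF3
#'   or BED annotation.
#' @param flank Window half-width in bases (500 by default).
#' @return A tibble per chromosome: `n_perfect_loci`, `n_imperfect_loci`,
#'   `n_te_near_perfect`, `n_te_near_imperfect`.
#' @export
count_tes_near_loci <- function(loci, tes, flank = 500L) {
  stopifnot(all(c("chrom", "start", "end", "mismatches") %in% names(loci)),
            all(c("chrom", "start", "end") %in% names(tes)))
  chroms <- sort(unique(loci$chrom))
  purrr::map_dfr(chroms, function(ch) {
    l <- loci[loci$chrom == ch, , drop = FALSE]
    t <- tes[tes$chrom == ch, , drop = FALSE]
    ws <- pmax(1L, l$start - as.integer(flank))
    we <- l$end + as.integer(flank)
    near <- if (nrow(t)) {
      # pair counting: overlap matrix loci x TEs
      outer(ws, t$end, "<=") & outer(we, t$start, ">=")
    } else {
      matrix(FALSE, nrow(l), 0)
    }
    perfect <- l$mismatches == 0L
    tibble(
      chrom = ch,
      n_perfect_loci = sum(perfect),
      n_imperfect_loci = sum(!perfect),
      n_te_near_perfect = sum(near[perfect, , drop = FALSE]),
      n_te_near_imperfect = sum(near[!perfect, , drop = FALSE])
    )
  })
}

#' Correlate per-chromosome repeat counts with nearby-TE counts
#'
#' Pearson correlation (two-sided t-based p) between per-chromosome locus
#' counts and nearby-TE counts, computed separately for perfect and imperfect
#' loci, each with an ordinary least-squares fit of TE count on locus count.
#'
#' @param records Output of [count_tes_near_loci()] (>= 3 chromosomes).
#' @return A tibble with rows `perfect` and `imperfect`: `n_chromosomes`,
#'   `r`, `p_value`, `slope`, `intercept`, `undefined` (constant series).
#' @export
correlate_te_repeats <- function(records) {
  if (nrow(records) < 3L) abort("Need records for at least 3 chromosomes.")
  one <- function(set, x, y) {
    undef <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (undef) {
      return(tibble(set = set, n_chromosomes = length(x), r = NA_real_,
                    p_value = NA_real_, slope = NA_real_,
                    intercept = NA_real_, undefined = TRUE))
    }
    ct <- cor.test(x, y)
    fit <- coef(lm(y ~ x))
    tibble(set = set, n_chromosomes = length(x), r = unname(ct$estimate),
           p_value = ct$p.value, slope = unname(fit[2]),
           intercept = unname(fit[1]), undefined = FALSE)
  }
  bind_rows(
    one("perfect", records$n_perfect_loci, records$n_te_near_perfect),
    one("imperfect", records$n_imperfect_loci, records$n_te_near_imperfect)
  )
}
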