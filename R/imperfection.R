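#' Build the mismatch-by-length frequency datasets
#'
#' Counts loci per genome into two frequency matrices: dataset I covers
#' repeat lengths 20-24 nt with 0 or 1 mismatch, dataset II lengths 25-29 nt
#' with 1 or 2 mismatches. Loci shorter than 20 nt are excluded entirely
#' (they carry no mismatch under the detection thresholds). Every
#' (length, mismatch) cell is present and ordered even when empty.
#'
#' @param loci Locus tibble for several genomes with a `genome` column plus
#'   `length` and `mismatches`.
#' @return A list with `dataset_I` and `dataset_II`, each a tibble with a
#'   `genome` column and one integer count column per cell, named
#'   `L<length>_m<mismatch>`.
#' @export
build_mismatch_datasets <- function(loci) {
  stopifnot(all(c("genome", "length", "mismatches") %in% names(loci)))
  loci <- filter(loci, .data$length >= 20L)
  list(
    dataset_I = count_cells(loci, 20:24, 0:1),
    dataset_II = count_cells(loci, 25:29, 1:2)
  )
}

count_cells <- function(loci, lengths, mismatches) {
  genomes <- sort(unique(loci$genome))
  grid <- tidyr::expand_grid(genome = genomes, length = lengths,
                             mismatch = mismatches)
  counts <- loci %>%
    filter(.data$length %in% lengths, .data$mismatches %in% mismatches) %>%
    count(.data$genome, .data$length, mismatch = .data$mismatches)
  grid %>%
    left_join(counts, by = c("genome", "length", "mismatch")) %>%
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      cell = paste0("L", .data$length, "_m", .data$mismatch)
    ) %>%
    select("genome", "cell", "n") %>%
    tidyr::pivot_wider(names_from = "cell", values_from = "n")
}

#' Split a frequency dataset into its per-mismatch blocks
#'
#' @param dataset A dataset tibble from [build_mismatch_datasets()].
#' @param mismatch The mismatch level of the block to extract.
#' @return A tibble with `genome` plus that block's count columns.
#' @export
dataset_block <- function(dataset, mismatch) {
  cols <- grep(paste0("_m", mismatch, "$"), names(dataset), value = TRUE)
  if (!length(cols)) abort("No columns for that mismatch level.")
  select(dataset, "genome", dplyr::all_of(cols))
}

#' Canonical ordination of two frequency blocks with permutation test
#'
#' Computes principal coordinates of each block (Euclidean distances on the
#' count columns), retains leading axes explaining at least `variance_cutoff`
#' of the (positive-eigenvalue) variation, and measures the first squared
#' canonical correlation between the two axis sets. Significance is assessed
#' by permuting the row order of the second block; the p-value uses the
#' add-one rule, `p = (1 + #{permuted >= observed}) / (n_permutations + 1)`,
#' so it can never be zero.
#'
#' @param block_a,block_b Tibbles with a shared `genome` column and count
#'   columns (e.g. from [dataset_block()]), or plain numeric matrices with
#'   matching rows.
#' @param n_permutations Number of row permutations (9999 by default).
#' @param seed Integer seed for the permutations.
#' @param variance_cutoff Fraction of variation the retained principal
#'   coordinates must explain.
#' @return An object of class `ssr_cap` with elements `statistic` (first
#'   squared canonical correlation), `p_value`, `n_permutations`, `scores_a`,
#'   `scores_b` (retained axis scores) and `genomes`. `tidy()`, `glance()`
#'   and `autoplot()` methods are available.
#' @export
canonical_ordination <- function(block_a, block_b, n_permutations = 9999,
                                 seed = 1L, variance_cutoff = 0.95) {
  a <- block_matrix(block_a)
  b <- block_matrix(block_b)
  if (nrow(a) < 3L) abort("Canonical ordination needs at least 3 rows (genomes).")
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b))) {
    abort("Both blocks must cover the same genomes in the same order.")
  }
  sa <- pcoa_scores(a, variance_cutoff)
  sb <- pcoa_scores(b, variance_cutoff)
  stat <- first_sq_cancor(sa, sb)
  perm_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      first_sq_cancor(sa, sb[sample.int(nrow(sb)), , drop = FALSE])
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= stat)) / (n_permutations + 1)
  structure(
    list(
      statistic = stat, statistic_name = "first squared canonical correlation",
      p_value = p, n_permutations = n_permutations,
      scores_a = sa, scores_b = sb, genomes = rownames(a)
    ),
    class = "ssr_cap"
  )
}

block_matrix <- function(block) {
  if (is.data.frame(block)) {
    stopifnot("genome" %in% names(block))
    m <- as.matrix(block[setdiff(names(block), "genome")])
    rownames(m) <- block$genome
  } else {
    m <- as.matrix(block)
    if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  }
  storage.mode(m) <- "double"
  m
}

pcoa_scores <- function(m, variance_cutoff) {
  d <- dist(m)
  if (max(d) == 0) abort("Degenerate block: all rows identical (zero variance).")
  n <- nrow(m)
  # cmdscale warns whenever fewer than k eigenvalues are positive; the axis
  # retention below handles that case explicitly
  pc <- withCallingHandlers(
    cmdscale(d, k = n - 1L, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  eig <- pc$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(eig))
  cum <- cumsum(eig[pos]) / sum(eig[pos])
  keep <- seq_len(which(cum >= variance_cutoff)[1])
  # keep the axis count below n-1 so the canonical system stays identifiable
  keep <- keep[keep <= max(1L, n - 2L)]
  pc$points[, keep, drop = FALSE]
}

first_sq_cancor <- function(x, y) {
  cc <- cancor(x, y)
  cc$cor[1]^2
}

#' Pairwise Pearson correlations between mismatch levels along repeat length
#'
#' For each targeted repeat length, correlates the genome-wise frequency
#' vector of loci carrying `a` mismatches with that of `b` mismatches, for
#' every pair `a < b` of the requested levels. Frequencies are raw counts of
#' loci at exactly that repeat length.
#'
#' @param loci Locus tibble with `genome`, `length`, `mismatches`.
#' @param lengths Repeat lengths to target (default 30 to 80 by 5).
#' @param mismatches Mismatch levels to pair (default 1:4).
#' @param alpha Significance level for flagging (default 0.05).
#' @return A tibble: `length`, `mismatch_a`, `mismatch_b`, `n_genomes`, `r`,
#'   `p_value`, `significant`, `undefined` (constant vector, r undefined).
#' @export
pairwise_length_correlations <- function(loci, lengths = seq(30, 80, 5),
                                         mismatches = 1:4, alpha = 0.05) {
  genomes <- sort(unique(loci$genome))
  if (length(genomes) < 3L) abort("Need at least 3 genomes.")
  counts <- tidyr::expand_grid(genome = genomes, length = lengths,
                               mismatch = mismatches) %>%
    left_join(
      count(filter(loci, .data$length %in% lengths,
                   .data$mismatches %in% mismatches),
            .data$genome, .data$length, mismatch = .data$mismatches),
      by = c("genome", "length", "mismatch")
    ) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))

  pairs <- utils::combn(sort(mismatches), 2L)
  out <- list()
  for (L in lengths) {
    for (j in seq_len(ncol(pairs))) {
      va <- counts$n[counts$length == L & counts$mismatch == pairs[1, j]]
      vb <- counts$n[counts$length == L & counts$mismatch == pairs[2, j]]
      undef <- stats::sd(va) == 0 || stats::sd(vb) == 0
      if (undef) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- cor.test(va, vb)
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1]] <- tibble(
        length = L, mismatch_a = pairs[1, j], mismatch_b = pairs[2, j],
        n_genomes = length(genomes), r = r, p_value = p,
        significant = !undef & p <= alpha, undefined = undef
      )
    }
  }
  bind_rows(out)
}

#' Regress per-class mean mismatch on mean repeat length
#'
#' Groups one genome's loci by standardized motif, computes each class's mean
#' mismatch count and mean repeat length, and fits ordinary least squares of
#' mean mismatch on mean length.
#'
#' @param loci Locus tibble for one genome (`std_motif`, `length`,
#'   `mismatches`).
#' @param min_classes Minimum number of motif classes required.
#' @return A one-row tibble: `slope` (mismatch per base), `intercept`,
#'   `r_squared`, `p_value`, `n` (number of classes). The per-class means are
#'   attached as attribute `"class_means"`.
#' @export
regress_mismatch_on_length <- function(loci, min_classes = 3L) {
  means <- loci %>%
    group_by(std_motif = .data$std_motif) %>%
    summarise(
      mean_mismatch = mean(.data$mismatches),
      mean_length = mean(.data$length),
      .groups = "drop"
    )
  if (nrow(means) < min_classes) {
    abort(paste0("Need at least ", min_classes, " motif classes; got ",
                 nrow(means), "."))
  }
  fit <- lm(mean_mismatch ~ mean_length, data = means)
  # exact linear relationships are legitimate inputs (degenerate r^2 = 1)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  pv <- if (nrow(means) > 2 && sm$coefficients["mean_length", "Std. Error"] > 0) {
    sm$coefficients["mean_length", "Pr(>|t|)"]
  } else NA_real_
  out <- tibble(
    slope = unname(coef(fit)["mean_length"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    p_value = pv,
    n = nrow(means)
  )
  attr(out, "class_means") <- means
  out
}
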