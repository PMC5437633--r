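# Shared brute-force oracles and small fixture builders.

# Sequential Euclidean pseudo-F through per-column ANOVA: for Euclidean
# distances the multivariate partition equals the sum over response columns
# of the univariate sequential sums of squares.
brute_pseudo_f <- function(m, f1, f2) {
  ss1 <- 0; ss2 <- 0; ssr <- 0
  df <- NULL
  for (j in seq_len(ncol(m))) {
    fit <- stats::aov(m[, j] ~ f1 + f2)
    a <- summary(fit)[[1]]
    ss1 <- ss1 + a[["Sum Sq"]][1]
    ss2 <- ss2 + a[["Sum Sq"]][2]
    ssr <- ssr + a[["Sum Sq"]][3]
    df <- a[["Df"]]
  }
  c(
    f1 = (ss1 / df[1]) / (ssr / df[3]),
    f2 = (ss2 / df[2]) / (ssr / df[3])
  )
}

# All-pairs TE window counting, plain double loop.
brute_te_counts <- function(loci, tes, flank = 500L) {
  res <- NULL
  for (ch in sort(unique(loci$chrom))) {
    l <- loci[loci$chrom == ch, ]
    t <- tes[tes$chrom == ch, ]
    npp <- 0L; npi <- 0L
    for (i in seq_len(nrow(l))) {
      ws <- max(1L, l$start[i] - flank); we <- l$end[i] + flank
      cnt <- 0L
      for (j in seq_len(nrow(t))) {
        if (t$start[j] <= we && t$end[j] >= ws) cnt <- cnt + 1L
      }
      if (l$mismatches[i] == 0L) npp <- npp + cnt else npi <- npi + cnt
    }
    res <- rbind(res, data.frame(
      chrom = ch,
      n_perfect_loci = sum(l$mismatches == 0L),
      n_imperfect_loci = sum(l$mismatches > 0L),
      n_te_near_perfect = npp, n_te_near_imperfect = npi
    ))
  }
  res
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a locus tibble row builder for tests that construct loci directly
make_loci <- function(chrom, start, end, motif = "AG", mismatches = 0L,
                      genome = NULL) {
  out <- tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    motif = motif, std_motif = ssrdecay::complete_standardize(motif),
    motif_length = nchar(motif),
    length = as.integer(end - start + 1L),
    mismatches = as.integer(mismatches),
    score = as.integer((end - start + 1L) - 6L * mismatches),
    is_perfect = mismatches == 0L
  )
  if (!is.null(genome)) out$genome <- genome
  out
}
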