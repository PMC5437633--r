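# a tiny genome with well-separated loci for library-level tests
library_fixture <- function(seed = 101, n = 12, spacing = 1200L) {
  withr::with_seed(seed, {
    motifs <- c("AG", "ACT", "AAGT", "AACTG", "AT", "ACGTA")
    chrom <- character(0)
    pieces <- character(0)
    starts <- integer(0); ends <- integer(0); mot <- character(0)
    pos <- 1L
    for (i in seq_len(n)) {
      m <- motifs[(i - 1) %% length(motifs) + 1]
      tract <- strrep(m, ceiling(24 / nchar(m)))
      gap <- random_dna(spacing - nchar(tract))
      starts <- c(starts, pos + nchar(gap))
      ends <- c(ends, pos + nchar(gap) + nchar(tract) - 1L)
      mot <- c(mot, m)
      pieces <- c(pieces, gap, tract)
      pos <- pos + nchar(gap) + nchar(tract)
    }
    seqs <- c(chrA = paste0(paste(pieces, collapse = ""), random_dna(600)))
    loci <- make_loci("chrA", starts, ends, motif = mot)
    list(sequences = seqs, loci = loci)
  })
}

test_that("library entries carry truncated flanks and a fully masked tract", {
  fx <- library_fixture()
  lib <- build_locus_library(fx$loci, fx$sequences, flank = 350)
  expect_s3_class(lib, "ssr_library")
  # flanks truncate at the sequence start
  first <- lib[1, ]
  expect_equal(first$window_start, max(1L, fx$loci$start[1] - 350L))
  # the masked span is exactly the tract, and flanks carry no mask characters
  for (i in seq_len(nrow(lib))) {
    s <- lib$seq[i]
    tract <- substr(s, lib$mask_start[i], lib$mask_end[i])
    expect_equal(tract, strrep("+", nchar(tract)))
    expect_false(grepl("\\+", substr(s, 1, lib$mask_start[i] - 1)))
    expect_false(grepl("\\+", substr(s, lib$mask_end[i] + 1, nchar(s))))
    expect_equal(nchar(s), lib$window_end[i] - lib$window_start[i] + 1L)
  }
})

test_that("1-nt, compound and window-overlapping loci are excluded", {
  seqs <- c(chrA = random_dna(20000))
  loci <- rbind(
    make_loci("chrA", 5000, 5030, motif = "A"),          # 1-nt: excluded
    make_loci("chrA", 8000, 8030, motif = "AG"),         # window overlap pair
    make_loci("chrA", 8400, 8430, motif = "ACT"),        # (400 nt apart)
    make_loci("chrA", 15000, 15030, motif = "AAGT")      # retained
  )
  lib <- build_locus_library(loci, seqs, flank = 350)
  expect_equal(nrow(lib), 1L)
  expect_equal(lib$motif_length, 4L)
  # compound-flagged loci are excluded too
  loci2 <- rbind(
    make_loci("chrA", 3000, 3030, motif = "AG"),
    make_loci("chrA", 3100, 3130, motif = "ACT")         # gap 69: compound
  )
  expect_equal(nrow(build_locus_library(loci2, seqs)), 0L)
  expect_error(build_locus_library(make_loci("chrA", 19990, 20050), seqs),
               "bounds")
})

test_that("hit filters are inclusive at the published thresholds", {
  base <- tibble::tibble(
    query_id = "q", subject_chrom = "s", sstart = 1L, send = 100L,
    strand = 1L, query_cover = 50, identity = 70, score = 100,
    bit_score = 50, e_value = 1e-10, n_hsps = 1L
  )
  expect_equal(nrow(filter_hits(base)), 1L)
  for (tweak in list(
    c(query_cover = 49.999), c(identity = 69.999), c(e_value = 1.0001e-10)
  )) {
    h <- base
    h[[names(tweak)]] <- unname(tweak)
    expect_equal(nrow(filter_hits(h)), 0L)
  }
})

test_that("an entry searched against its own genome hits itself exactly", {
  fx <- library_fixture(seed = 103)
  lib <- build_locus_library(fx$loci, fx$sequences)
  hits <- search_genome(lib[3, ], fx$sequences)
  expect_gt(nrow(hits), 0L)
  top <- hits[1, ]
  expect_equal(top$identity, 100)
  expect_gte(top$query_cover, 50)
  expect_lte(top$e_value, 1e-10)
  expect_lte(top$sstart, lib$window_start[3] + 5L)
  expect_gte(top$send, lib$window_end[3] - 5L)
})

test_that("no qualifying hit arises from an unrelated random subject", {
  fx <- library_fixture(seed = 105)
  lib <- build_locus_library(fx$loci, fx$sequences)
  subject <- withr::with_seed(9, c(rand = random_dna(100000)))
  hits <- filter_hits(search_genome(lib, subject))
  expect_equal(nrow(hits), 0L)
})

test_that("heavy flank divergence is dropped by the identity filter", {
  fx <- library_fixture(seed = 107)
  lib <- build_locus_library(fx$loci, fx$sequences)
  entry <- lib[5, ]
  # homolog whose flanks carry 35% substitutions: aligned identity ~65%,
  # under the 70% floor
  hom <- withr::with_seed(31, {
    win <- substr(fx$sequences[["chrA"]], entry$window_start, entry$window_end)
    ch <- strsplit(win, "")[[1]]
    mut <- which(runif(length(ch)) < 0.35)
    shift <- sample(1:3, length(mut), replace = TRUE)
    ch[mut] <- c("A", "C", "G", "T")[
      (match(ch[mut], c("A", "C", "G", "T")) - 1 + shift) %% 4 + 1
    ]
    c(hom = paste0(random_dna(3000), paste(ch, collapse = ""), random_dna(3000)))
  })
  qualifying <- filter_hits(search_genome(entry, hom))
  expect_equal(nrow(qualifying), 0L)
})

test_that("mask characters are never aligned", {
  fx <- library_fixture(seed = 109)
  lib <- build_locus_library(fx$loci, fx$sequences)
  entry <- lib[2, ]
  # subject identical except the tract is replaced by unrelated sequence: if
  # masked columns were ever aligned, identity would fall below 100
  win <- substr(fx$sequences[["chrA"]], entry$window_start, entry$window_end)
  tract_len <- entry$mask_end - entry$mask_start + 1L
  subject <- withr::with_seed(41, {
    paste0(
      substr(win, 1, entry$mask_start - 1),
      random_dna(tract_len),
      substr(win, entry$mask_end + 1, nchar(win))
    )
  })
  hits <- search_genome(entry, c(s = subject))
  expect_gt(nrow(hits), 0L)
  expect_equal(hits$identity[1], 100)
})

test_that("self-uniqueness keeps distinct entries and drops duplicated flanks", {
  fx <- library_fixture(seed = 111)
  lib <- build_locus_library(fx$loci, fx$sequences)
  expect_equal(nrow(self_uniqueness_filter(lib)), nrow(lib))
  # two entries with identical flanks are both discarded
  dup <- lib[1:2, ]
  dup$seq[2] <- dup$seq[1]
  dup$locus_id[2] <- "copycat"
  expect_equal(nrow(self_uniqueness_filter(dup)), 0L)
  expect_equal(nrow(self_uniqueness_filter(lib[4, ])), 1L)
})

test_that("identity scenario: every library locus is conserved at one position", {
  g <- generate_genome(simulation_config(
    seed = 121, n_chromosomes = 1L, chromosome_length = 60000L,
    planted_loci_per_chromosome = 50L,
    motif_length_weights = c("2" = 1, "3" = 1, "4" = 1, "5" = 1, "6" = 1)
  ))
  loci <- flag_compounds(scan_genome(g$sequences))
  lib <- self_uniqueness_filter(build_locus_library(loci, g$sequences))
  rec <- assign_conservation(lib, g$sequences, g$sequences)
  expect_true(all(rec$status == "conserved"))
  expect_true(all(rec$n_positions == 1L))
  props <- conservation_proportions(rec)
  expect_true(all(props$proportion_conserved == 1))
})

test_that("a locus with erased window is lost; survivors are conserved", {
  g <- generate_genome(simulation_config(
    seed = 131, n_chromosomes = 1L, chromosome_length = 50000L,
    planted_loci_per_chromosome = 40L,
    motif_length_weights = c("2" = 1, "3" = 1, "4" = 1, "5" = 1, "6" = 1)
  ))
  tet <- evolve_tetraploid(g, NULL, evolution_scenario(
    loss_probability = c("2" = 0.5, "3" = 0.5, "4" = 0.5, "5" = 0.5, "6" = 0.5)
  ), seed = 3)
  loci <- flag_compounds(scan_genome(g$sequences))
  loci$locus_id <- g$truth$locus_id[match(
    paste(loci$chrom, loci$start), paste(g$truth$chrom, g$truth$start)
  )]
  lib <- self_uniqueness_filter(build_locus_library(loci, g$sequences))
  rec <- assign_conservation(lib, tet$sequences, g$sequences)
  truth <- tet$conservation_truth
  surv <- truth$surviving[match(rec$locus_id, truth$locus_id)]
  expect_equal(rec$status == "conserved", surv)
  # conserved positions point at the true surviving coordinates
  conserved <- which(rec$status == "conserved")
  for (i in conserved[seq_len(min(10, length(conserved)))] ) {
    pos <- rec$positions[[i]]
    tr <- truth[truth$locus_id == rec$locus_id[i], ]
    expect_true(pos$sstart[1] <= tr$start[1] && pos$send[1] >= tr$end[1])
  }
})

test_that("a simulated WGD subject yields two confirmed positions", {
  g <- generate_genome(simulation_config(
    seed = 141, n_chromosomes = 1L, chromosome_length = 50000L,
    planted_loci_per_chromosome = 40L,
    motif_length_weights = c("2" = 1, "3" = 1, "4" = 1, "5" = 1, "6" = 1)
  ))
  tet <- evolve_tetraploid(g, NULL, evolution_scenario(
    loss_probability = c("2" = 0, "3" = 0, "4" = 0, "5" = 0, "6" = 0),
    flank_substitution_rate = 0.005, duplication = TRUE
  ), seed = 6)
  loci <- flag_compounds(scan_genome(g$sequences))
  lib <- self_uniqueness_filter(build_locus_library(loci, g$sequences))
  rec <- assign_conservation(lib, tet$sequences, g$sequences)
  expect_gte(mean(rec$status == "conserved" & rec$n_positions == 2L), 0.95)
})

test_that("proportions recover planted per-class loss within binomial error", {
  g <- generate_genome(simulation_config(
    seed = 151, n_chromosomes = 2L, chromosome_length = 120000L,
    planted_loci_per_chromosome = 100L,
    motif_length_weights = c("2" = 1, "3" = 1, "4" = 1, "5" = 1, "6" = 1)
  ))
  tet <- evolve_tetraploid(g, NULL, evolution_scenario(
    loss_probability = c("2" = 0.8, "3" = 0.1, "4" = 0.1, "5" = 0.1, "6" = 0.1)
  ), seed = 9)
  loci <- flag_compounds(scan_genome(g$sequences))
  lib <- self_uniqueness_filter(build_locus_library(loci, g$sequences))
  rec <- assign_conservation(lib, tet$sequences, g$sequences)
  props <- conservation_proportions(rec)
  for (k in 2:6) {
    row <- props[props$motif_length == k, ]
    n <- row$n_conserved + row$n_lost
    p_surv <- if (k == 2) 0.2 else 0.9
    ci <- stats::qbinom(c(0.005, 0.995), n, p_surv) / n
    expect_gte(row$proportion_conserved, ci[1])
    expect_lte(row$proportion_conserved, ci[2])
  }
  # empty classes are flagged undefined
  empty <- conservation_proportions(rec[rec$motif_length != 6, ])
  expect_false(6 %in% empty$motif_length)
})

test_that("the tabular-hit adapter reproduces the standard columns", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    c("q1", "chr2", "98.5", "700", "10", "0", "1", "700", "5000", "5699",
      "1e-50", "1200"),
    collapse = "\t"
  ), tmp)
  hits <- read_tabular_hits(tmp, c(q1 = 1050))
  expect_equal(hits$query_cover, 100 * 700 / 1050)
  expect_equal(hits$identity, 98.5)
  expect_equal(hits$sstart, 5000)
  expect_equal(nrow(filter_hits(hits)), 1L)
})
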