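test_that("a perfect planted repeat is reported with exact boundaries", {
  loci <- scan_sequence(paste0("ACGT", strrep("AG", 10), "TCCA"))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 5L)
  expect_equal(loci$end, 24L)
  expect_equal(loci$motif, "AG")
  expect_equal(loci$length, 20L)
  expect_equal(loci$mismatches, 0L)
  expect_true(loci$is_perfect)
})

test_that("a single substitution inside a tract yields one imperfect locus", {
  # (AG)^12 A with the 13th base substituted to C: 25 bases, one mismatch
  s <- paste0(strrep("AG", 6), "C", "GAGAGAGAGAGA")
  expect_equal(nchar(s), 25L)
  loci <- scan_sequence(s)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$length, 25L)
  expect_equal(loci$mismatches, 1L)
  expect_equal(loci$score, 25L - 6L)
  # the oracle agrees
  expect_true(compare_scan_to_oracle(s))
})

test_that("more than three successive mismatches split a tract", {
  s <- paste0(strrep("AT", 8), "GGGG", strrep("AT", 8))
  loci <- scan_sequence(s)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$length, c(16L, 16L))
  expect_equal(loci$mismatches, c(0L, 0L))
  expect_true(compare_scan_to_oracle(s))
})

test_that("N never matches and invalid characters error", {
  # N inside a tract counts as a mismatch
  s <- paste0(strrep("AG", 6), "N", "GAGAGAGAGAGA")
  loci <- scan_sequence(s)
  expect_equal(loci$mismatches, 1L)
  # a run of N cannot seed anything
  expect_equal(nrow(scan_sequence(strrep("N", 60))), 0L)
  expect_equal(nrow(scan_sequence("")), 0L)
  expect_error(scan_sequence("ACGTX"), "outside")
})

test_that("reported loci never violate the detection thresholds", {
  cfg <- detection_config()
  withr::with_seed(7, {
    for (i in 1:150) {
      s <- random_scan_sequence()
      loci <- scan_genome(c(chr = s), cfg)
      if (!nrow(loci)) next
      expect_true(all(loci$length >= cfg$min_repeat_length))
      expect_true(all(loci$score >= cfg$min_score))
      expect_true(all(loci$end <= nchar(s)))
      # non-overlapping output
      if (nrow(loci) > 1) {
        expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
      }
      # no mismatch run longer than the limit inside any locus
      for (j in seq_len(nrow(loci))) {
        tract <- substr(s, loci$start[j], loci$end[j])
        expected <- strrep(loci$motif[j], ceiling(nchar(tract) / nchar(loci$motif[j])))
        a <- strsplit(toupper(tract), "")[[1]]
        b <- strsplit(expected, "")[[1]][seq_along(a)]
        mm <- a != b | a == "N"
        expect_equal(sum(mm), loci$mismatches[j])
        runs <- rle(mm)
        expect_true(all(runs$lengths[runs$values] <= cfg$max_successive_mismatch))
        # boundaries are matches
        expect_false(mm[1])
        expect_false(mm[length(mm)])
      }
    }
  })
})

test_that("scanning the reverse complement reflects the loci", {
  withr::with_seed(19, {
    for (i in 1:80) {
      s <- random_scan_sequence()
      n <- nchar(s)
      fwd <- scan_sequence(s)
      rev <- scan_sequence(revcomp(s))
      expect_equal(nrow(fwd), nrow(rev))
      if (!nrow(fwd)) next
      reflected <- data.frame(
        start = sort(n - rev$end + 1L),
        end = sort(n - rev$start + 1L)
      )
      expect_equal(sort(fwd$start), reflected$start)
      expect_equal(sort(fwd$end), reflected$end)
      expect_equal(
        sort(paste(n - rev$end + 1L, rev$std_motif, rev$mismatches)),
        sort(paste(fwd$start, fwd$std_motif, fwd$mismatches))
      )
    }
  })
})

test_that("raising the minimum repeat length never adds loci", {
  withr::with_seed(23, {
    for (i in 1:40) {
      s <- random_scan_sequence()
      n15 <- nrow(scan_sequence(s, detection_config(min_repeat_length = 15)))
      n20 <- nrow(scan_sequence(s, detection_config(min_repeat_length = 20)))
      n30 <- nrow(scan_sequence(s, detection_config(min_repeat_length = 30)))
      expect_true(n20 <= n15)
      expect_true(n30 <= n20)
    }
  })
})

test_that("compound exclusion applies the gap-under-100 rule", {
  gap99 <- make_loci("c1", c(1, 120), c(20, 140))     # gap 99
  expect_equal(flag_compounds(gap99)$compound, c(TRUE, TRUE))
  expect_equal(nrow(exclude_compounds(gap99)), 0L)

  gap100 <- make_loci("c1", c(1, 121), c(20, 141))    # gap 100
  expect_equal(flag_compounds(gap100)$compound, c(FALSE, FALSE))
  expect_equal(nrow(exclude_compounds(gap100)), 2L)

  single <- make_loci("c1", 1, 20)
  expect_equal(nrow(exclude_compounds(single)), 1L)

  # chains propagate: middle locus close to both neighbours removes all three
  chain <- make_loci("c1", c(1, 60, 120), c(20, 80, 140))
  expect_equal(flag_compounds(chain)$compound, c(TRUE, TRUE, TRUE))
  # different chromosomes never associate
  twochr <- make_loci(c("c1", "c2"), c(1, 30), c(20, 50))
  expect_equal(flag_compounds(twochr)$compound, c(FALSE, FALSE))
})

test_that("density summaries report loci per Mb and imperfection percent", {
  loci <- make_loci("c1", seq(1, by = 2000, length.out = 50),
                    seq(20, by = 2000, length.out = 50))
  ds <- summarize_density(loci, c(c1 = 10e6))
  expect_equal(ds$genome$density_per_mb, 5)
  expect_equal(ds$genome$imperfection_percent, 0)
  expect_equal(sum(ds$genome$percent_abundance), 100)

  loci$mismatches[1:15] <- 1L
  ds2 <- summarize_density(loci, c(c1 = 10e6))
  expect_equal(ds2$genome$imperfection_percent, 30)
  expect_error(summarize_density(loci, c(c1 = 0)), "positive")
})

test_that("CDS summaries count genes and compound members", {
  expect_equal(summarize_cds(make_loci(character(0), integer(0), integer(0)),
                             c(g1 = 1000))$genes$genes_with_repeat, 0L)
  loci <- make_loci(c("g1", "g2", "g3"), c(100, 100, 100), c(120, 120, 120),
                    motif = "ACT")
  cs <- summarize_cds(loci, c(g1 = 2000, g2 = 2000, g3 = 2000))
  expect_equal(cs$genes$genes_with_repeat, 3L)
  expect_equal(cs$genes$genes_with_imperfect_repeat, 0L)
  expect_equal(cs$n_compound, 0L)
  expect_equal(cs$per_class$n_loci, 3L)
  expect_equal(cs$per_class$density_per_mb, 3 / 0.006)
  # a compound pair on one gene is excluded from density but counted
  loci2 <- rbind(loci, make_loci("g1", 150, 170, motif = "AT"))
  cs2 <- summarize_cds(loci2, c(g1 = 2000, g2 = 2000, g3 = 2000))
  expect_equal(cs2$n_compound, 2L)
  expect_equal(sum(cs2$per_class$n_loci), 2L)
})

test_that("scanner and oracle agree on structured corner cases", {
  cases <- c(
    strrep("A", 40),                                  # homopolymer
    paste0(strrep("ACG", 12), "T", strrep("ACG", 3)), # mismatch near end
    paste0(strrep("AT", 10), strrep("TA", 10)),       # phase shift inside
    paste0(strrep("AAC", 8), strrep("ACA", 8)),       # rotated continuation
    paste0("ACGTN", strrep("AGAT", 8), "NNNN", strrep("AGAT", 8)),
    strrep("ATATATATATCATATATATAT", 3)
  )
  for (s in cases) expect_true(compare_scan_to_oracle(s))
})
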