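test_that("dataset construction follows the length/mismatch windows", {
  one <- make_loci("c1", 100, 121, mismatches = 1, genome = "g1") # length 22
  d <- build_mismatch_datasets(one)
  expect_equal(d$dataset_I$L22_m1, 1L)
  other_cols <- setdiff(names(d$dataset_I), c("genome", "L22_m1"))
  expect_true(all(as.matrix(d$dataset_I[other_cols]) == 0L))
  expect_true(all(as.matrix(d$dataset_II[-1]) == 0L))

  # length 19 appears in neither dataset
  short <- make_loci("c1", 100, 118, mismatches = 0, genome = "g1")
  d2 <- build_mismatch_datasets(short)
  expect_true(all(as.matrix(d2$dataset_I[-1]) == 0L))
  expect_true(all(as.matrix(d2$dataset_II[-1]) == 0L))

  # explicit, ordered cell universe
  expect_equal(ncol(d$dataset_I), 1L + 5L * 2L)
  expect_equal(ncol(d$dataset_II), 1L + 5L * 2L)
})

test_that("dataset counts match a direct tabulation of synthetic truth", {
  g1 <- generate_genome(simulation_config(
    seed = 51, n_chromosomes = 1L, chromosome_length = 40000L,
    planted_loci_per_chromosome = 30L, repeat_length_range = c(20L, 30L)
  ))
  g2 <- generate_genome(simulation_config(
    seed = 52, n_chromosomes = 1L, chromosome_length = 40000L,
    planted_loci_per_chromosome = 30L, repeat_length_range = c(20L, 30L)
  ))
  loci <- rbind(
    transform(g1$truth, genome = "g1"),
    transform(g2$truth, genome = "g2")
  )
  d <- build_mismatch_datasets(tibble::as_tibble(loci))
  for (gn in c("g1", "g2")) {
    for (L in 20:24) {
      for (m in 0:1) {
        expected <- sum(loci$genome == gn & loci$length == L &
                          loci$mismatches == m)
        got <- d$dataset_I[[paste0("L", L, "_m", m)]][d$dataset_I$genome == gn]
        expect_equal(got, expected)
      }
    }
  }
})

test_that("identical blocks give a first squared canonical correlation of 1", {
  withr::with_seed(1, {
    a <- matrix(rpois(13 * 5, 30), nrow = 13)
  })
  blk <- tibble::as_tibble(as.data.frame(a))
  blk$genome <- paste0("g", 1:13)
  cap <- canonical_ordination(blk, blk, n_permutations = 99, seed = 1)
  expect_equal(cap$statistic, 1.0, tolerance = 1e-10)
  expect_true(cap$p_value >= 1 / 100)
})

test_that("the statistic is invariant to positive column scaling", {
  withr::with_seed(2, {
    a <- matrix(rpois(13 * 5, 30), nrow = 13)
    b <- matrix(rpois(13 * 5, 30), nrow = 13)
  })
  rownames(a) <- rownames(b) <- paste0("g", 1:13)
  cap1 <- canonical_ordination(a, b, n_permutations = 9, seed = 1)
  cap2 <- canonical_ordination(a, b * 7, n_permutations = 9, seed = 1)
  expect_equal(cap1$statistic, cap2$statistic, tolerance = 1e-8)
})

test_that("ordination validates its inputs", {
  a <- matrix(rpois(6, 20), nrow = 2)
  expect_error(canonical_ordination(a, a, n_permutations = 9), "at least 3")
  flat <- matrix(5, nrow = 5, ncol = 3)
  ok <- matrix(rpois(15, 20), nrow = 5)
  rownames(flat) <- rownames(ok) <- paste0("g", 1:5)
  expect_error(canonical_ordination(flat, ok, n_permutations = 9), "Degenerate")
})

test_that("the permutation test is calibrated under the null", {
  reps <- 300
  rejections <- withr::with_seed(99, {
    sum(vapply(seq_len(reps), function(i) {
      a <- matrix(rpois(13 * 5, 25), nrow = 13)
      b <- matrix(rpois(13 * 5, 25), nrow = 13)
      rownames(a) <- rownames(b) <- paste0("g", 1:13)
      cap <- canonical_ordination(a, b, n_permutations = 199,
                                  seed = 1000 + i)
      cap$p_value <= 0.05
    }, logical(1)))
  })
  expect_gte(rejections / reps, 0.02)
  expect_lte(rejections / reps, 0.09)
})

test_that("permutation p-values are seeded and never zero", {
  withr::with_seed(3, {
    a <- matrix(rpois(10 * 4, 20), nrow = 10)
    b <- a + matrix(rpois(10 * 4, 3), nrow = 10)
  })
  rownames(a) <- rownames(b) <- paste0("g", 1:10)
  c1 <- canonical_ordination(a, b, n_permutations = 199, seed = 7)
  c2 <- canonical_ordination(a, b, n_permutations = 199, seed = 7)
  expect_identical(c1$p_value, c2$p_value)
  expect_gt(c1$p_value, 0)
  expect_gte(c1$p_value, 1 / 200)
})

test_that("pairwise length correlations hit the exact extremes", {
  # construct counts so mismatch-1 equals mismatch-2 (r = 1) and
  # mismatch-3 is anti-linear in mismatch-1 (r = -1)
  genomes <- paste0("g", 1:5)
  n1 <- c(2, 4, 6, 8, 10)
  rows <- list()
  for (i in seq_along(genomes)) {
    add <- function(m, count) {
      if (count > 0) {
        make_loci("c1", seq_len(count) * 1000,
                  seq_len(count) * 1000 + 29 + 6 * m,
                  mismatches = m, genome = genomes[i])
      }
    }
    rows[[i]] <- rbind(add(1, n1[i]), add(2, n1[i]), add(3, 12 - n1[i]))
  }
  loci <- dplyr::bind_rows(rows)
  loci$length <- 30L # all land in the length-30 bin
  loci$end <- loci$start + 29L
  res <- pairwise_length_correlations(loci, lengths = 30, mismatches = 1:3)
  r12 <- res$r[res$mismatch_a == 1 & res$mismatch_b == 2]
  r13 <- res$r[res$mismatch_a == 1 & res$mismatch_b == 3]
  expect_equal(r12, 1)
  expect_equal(r13, -1)
  # constant vectors are flagged undefined
  res30 <- pairwise_length_correlations(loci, lengths = 31, mismatches = 1:2)
  expect_true(all(res30$undefined))
})

test_that("sampling distribution of r is centred on the true correlation", {
  rho <- 0.8
  reps <- 150
  rs <- withr::with_seed(123, {
    vapply(seq_len(reps), function(i) {
      z1 <- rnorm(13)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(13)
      na <- pmax(0L, round(60 + 12 * z1))
      nb <- pmax(0L, round(60 + 12 * z2))
      rows <- lapply(1:13, function(g) {
        rbind(
          if (na[g] > 0) make_loci("c1", seq_len(na[g]) * 1000,
                                   seq_len(na[g]) * 1000 + 35,
                                   mismatches = 1, genome = paste0("g", g)),
          if (nb[g] > 0) make_loci("c1", seq_len(nb[g]) * 1000,
                                   seq_len(nb[g]) * 1000 + 41,
                                   mismatches = 2, genome = paste0("g", g))
        )
      })
      loci <- dplyr::bind_rows(rows)
      loci$length <- 35L
      res <- pairwise_length_correlations(loci, lengths = 35, mismatches = 1:2)
      res$r[1]
    }, numeric(1))
  })
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("mismatch-on-length regression recovers exact relationships", {
  # points exactly on y = 0.1 x - 1
  lens <- c(20, 30, 40, 50)
  loci <- dplyr::bind_rows(lapply(seq_along(lens), function(i) {
    l <- make_loci("c1", 1000 * i, 1000 * i + lens[i] - 1,
                   motif = c("AC", "AG", "AT", "CG")[i])
    l$mismatches <- 0.1 * lens[i] - 1
    l
  }))
  fit <- regress_mismatch_on_length(loci)
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  expect_equal(fit$intercept, -1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # constant mismatch means: slope 0
  loci$mismatches <- 2
  fit0 <- regress_mismatch_on_length(loci)
  expect_equal(fit0$slope, 0, tolerance = 1e-12)

  expect_error(
    regress_mismatch_on_length(make_loci("c1", c(1, 2000), c(30, 2030))),
    "at least 3"
  )
})
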