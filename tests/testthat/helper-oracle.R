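# Exhaustive oracle for the microsatellite scan, written independently of the
# package's C++ path: every position supplies a candidate motif for every
# motif length; seeds are located through vectorized pairwise-equality runs;
# extension, trimming, filtering and overlap resolution reimplement the
# detection rules in plain R.

oracle_scan <- function(seq, config = ssrdecay::detection_config()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(
    start = integer(0), end = integer(0), motif = character(0),
    mismatches = integer(0), score = integer(0)
  )
  if (n == 0L) return(empty)
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")

  cands <- list()
  for (k in config$motif_lengths) {
    copies <- if (k == 1L) 8L else if (k == 2L) 4L else 3L
    seedlen <- k * copies
    if (n < seedlen) next
    valid <- !is.na(code)
    eq <- code[seq_len(n - k)] == code[(k + 1):n] &
      valid[seq_len(n - k)] & valid[(k + 1):n]
    eq[is.na(eq)] <- FALSE
    need <- seedlen - k
    cs <- cumsum(c(0L, eq))
    upto <- n - seedlen + 1L
    if (upto < 1L) next
    seeds <- which(cs[(need + 1L):(need + upto)] - cs[seq_len(upto)] == need)
    for (p in seeds) {
      mo <- code[p:(p + k - 1L)]
      if (!oracle_primitive(mo)) next
      ext <- oracle_extend(code, p, k, n, config)
      s <- ext$s; e <- ext$e
      idx <- s:e
      expected <- mo[((idx - p) %% k) + 1L]
      mm <- sum(is.na(code[idx]) | code[idx] != expected)
      len <- e - s + 1L
      score <- (len - mm) * config$match_score - mm * config$mismatch_penalty
      if (len < config$min_repeat_length || score < config$min_score) next
      shift <- ((s - p) %% k + k) %% k
      motif0 <- paste(bases[mo[((shift + 0:(k - 1L)) %% k) + 1L]], collapse = "")
      cands[[length(cands) + 1L]] <- data.frame(
        start = s, end = e, motif = motif0, mismatches = mm, score = score
      )
    }
  }
  if (!length(cands)) return(empty)
  cand <- unique(do.call(rbind, cands))
  cand$motif_length <- nchar(cand$motif)
  cand <- cand[order(-cand$score, cand$motif_length, cand$start, cand$motif), ]
  taken_s <- integer(0); taken_e <- integer(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= taken_e & cand$end[i] >= taken_s)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, cand$start[i]); taken_e <- c(taken_e, cand$end[i])
    }
  }
  out <- cand[keep, c("start", "end", "motif", "mismatches", "score")]
  out[order(out$start), , drop = FALSE]
}

oracle_primitive <- function(mo) {
  k <- length(mo)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && all(mo == mo[((seq_len(k) - 1L) %% d) + 1L])) return(FALSE)
  }
  TRUE
}

oracle_extend <- function(code, p, k, n, config) {
  copies <- if (k == 1L) 8L else if (k == 2L) 4L else 3L
  seedlen <- k * copies
  mo <- code[p:(p + k - 1L)]
  drop_limit <- config$max_successive_mismatch * config$mismatch_penalty
  # right
  cum <- 0L; best <- 0L; run <- 0L; e <- p + seedlen - 1L
  i <- p + seedlen
  while (i <= n) {
    expc <- mo[((i - p) %% k) + 1L]
    if (!is.na(code[i]) && code[i] == expc) {
      cum <- cum + config$match_score; run <- 0L
      if (cum >= best) { best <- cum; e <- i }
    } else {
      cum <- cum - config$mismatch_penalty; run <- run + 1L
      if (run > config$max_successive_mismatch) break
      if (cum < best - drop_limit) break
    }
    i <- i + 1L
  }
  # left
  cum <- 0L; best <- 0L; run <- 0L; s <- p
  j <- p - 1L
  while (j >= 1L) {
    ph <- ((j - p) %% k + k) %% k
    expc <- mo[ph + 1L]
    if (!is.na(code[j]) && code[j] == expc) {
      cum <- cum + config$match_score; run <- 0L
      if (cum >= best) { best <- cum; s <- j }
    } else {
      cum <- cum - config$mismatch_penalty; run <- run + 1L
      if (run > config$max_successive_mismatch) break
      if (cum < best - drop_limit) break
    }
    j <- j - 1L
  }
  list(s = s, e = e)
}

# Random test sequences: plain i.i.d. background plus repeat-rich cases
# (planted tandem repeats with random substitutions and truncations), with
# occasional N characters.
random_scan_sequence <- function(max_len = 200L) {
  n <- sample(30:max_len, 1L)
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (runif(1) < 0.6) {
    # plant 1-2 mutated tandem repeats
    for (r in seq_len(sample(1:2, 1L))) {
      k <- sample(1:6, 1L)
      motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
      len <- sample(10:60, 1L)
      tract <- strsplit(strrep(motif, ceiling(len / k)), "")[[1]][1:len]
      nmut <- stats::rbinom(1L, len, 0.06)
      if (nmut > 0) {
        at <- sample(len, min(nmut, len))
        tract[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
      }
      pos <- sample(max(1L, n - len), 1L)
      s[pos:(pos + len - 1L)] <- tract
    }
  }
  if (runif(1) < 0.15) {
    s[sample(n, sample(1:3, 1L))] <- "N"
  }
  paste(s, collapse = "")
}

compare_scan_to_oracle <- function(seq, config = ssrdecay::detection_config()) {
  got <- as.data.frame(
    ssrdecay::scan_sequence(seq, config)[, c("start", "end", "motif",
                                             "mismatches", "score")]
  )
  want <- oracle_scan(seq, config)
  rownames(got) <- NULL; rownames(want) <- NULL
  identical(got, want)
}
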