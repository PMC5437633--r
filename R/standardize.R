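#' Motif canonicalization under rotation and reverse complementation
#'
#' Microsatellite motifs are equivalent up to the reading frame (cyclic
#' rotation) and the strand (reverse complementation). `partial_standardize()`
#' collapses rotations only, so `"GA"` becomes `"AG"`; `complete_standardize()`
#' additionally collapses strands, so `"AG"`, `"GA"`, `"TC"` and `"CT"` all map
#' to the single class `"AG"`. The canonical representative is the
#' lexicographically smallest string (`A < C < G < T`) over the full orbit,
#' which makes outputs bit-stable.
#'
#' Both functions require primitive motifs (minimal period equal to the motif
#' length): `"ATAT"` is not a motif of length 4 but two copies of `"AT"`, and
#' accepting it would double-count classes.
#'
#' @param motif Character vector of DNA motifs over `A`,`C`,`G`,`T`, each of
#'   length 1-6 and primitive.
#' @return A character vector of canonical motifs, same length as `motif`.
#' @examples
#' partial_standardize(c("GA", "TGA"))
#' complete_standardize(c("CT", "GAATC"))
#' @seealso [enumerate_motif_classes()]
#' @export
partial_standardize <- function(motif) {
  validate_motifs(motif)
  vapply(motif, function(m) min(rotations(m)), character(1), USE.NAMES = FALSE)
}

#' @rdname partial_standardize
#' @export
complete_standardize <- function(motif) {
  validate_motifs(motif)
  vapply(
    motif,
    function(m) min(c(rotations(m), rotations(revcomp(m)))),
    character(1),
    USE.NAMES = FALSE
  )
}

#' Enumerate the canonical motif-class universe
#'
#' Enumerates all `4^k` DNA strings of length `k`, drops the non-primitive
#' ones (minimal period shorter than `k`), maps the rest through
#' [complete_standardize()] and returns the distinct classes. For
#' `k = 1, ..., 6` this yields 2, 4, 10, 33, 102 and 350 classes.
#'
#' @param k Motif length, an integer from 1 to 6.
#' @return A tibble with columns `motif_class` (canonical motif) and
#'   `motif_length`, one row per class, sorted lexicographically.
#' @examples
#' enumerate_motif_classes(2)
#' nrow(enumerate_motif_classes(6))
#' @export
enumerate_motif_classes <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k > 6 || k != as.integer(k)) {
    abort("`k` must be a single integer between 1 and 6.")
  }
  k <- as.integer(k)
  all_motifs <- all_kmers(k)
  primitive <- all_motifs[vapply(all_motifs, is_primitive, logical(1))]
  classes <- sort(unique(complete_standardize(primitive)))
  tibble(motif_class = classes, motif_length = k)
}

#' Map motifs to canonical classes through a cached lookup
#'
#' Vectorized, memoised wrapper around [complete_standardize()] used by the
#' detection module; the lookup table over all primitive motifs of length <= 6
#' is built once per session.
#'
#' @param motif Character vector of primitive motifs (length 1-6).
#' @return Character vector of canonical class labels.
#' @export
standardize_motifs <- function(motif) {
  if (length(motif) == 0L) return(character(0))
  if (is.null(the$std_lookup)) {
    all_prim <- unlist(lapply(1:6, function(k) {
      m <- all_kmers(k)
      m[vapply(m, is_primitive, logical(1))]
    }))
    the$std_lookup <- setNames(complete_standardize(all_prim), all_prim)
  }
  out <- unname(the$std_lookup[motif])
  if (anyNA(out)) {
    bad <- unique(motif[is.na(out)])
    abort(paste0("Non-primitive or invalid motif(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over `A`,`C`,`G`,`T`,`N` (and the mask character).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  doubled <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), character(1))
}

is_primitive <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(TRUE)
  divisors <- which(k %% seq_len(k - 1L) == 0L)
  for (d in divisors) {
    if (strrep(substr(m, 1L, d), k / d) == m) return(FALSE)
  }
  TRUE
}

primitive_root <- function(m) {
  k <- nchar(m)
  for (d in seq_len(k)) {
    if (k %% d == 0L && strrep(substr(m, 1L, d), k / d) == m) {
      return(substr(m, 1L, d))
    }
  }
  m
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)))
}

validate_motifs <- function(motif) {
  if (!is.character(motif)) abort("`motif` must be a character vector.")
  if (any(!grepl("^[ACGT]+$", motif))) {
    abort("Motifs must be non-empty strings over A, C, G, T.")
  }
  if (any(nchar(motif) > 6L)) abort("Motif length must be 1-6.")
  nonprim <- !vapply(motif, is_primitive, logical(1))
  if (any(nonprim)) {
    m <- motif[nonprim][1]
    abort(paste0(
      "Motif '", m, "' is not primitive; its primitive root is '",
      primitive_root(m), "'."
    ))
  }
  invisible(motif)
}
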