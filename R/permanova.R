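#' Permutational multivariate analysis of variance (pseudo-F)
#'
#' Partitions the sum of squared inter-point distances among rows of a
#' response matrix by one or more categorical factors, with sequential
#' (ordered) terms, and assesses each term's pseudo-F by permuting row
#' labels. The partition follows the Gower-centered inner-product form: with
#' `G` the doubly centered matrix of `-d^2/2` and `H_j` the hat matrix of the
#' design including terms up to `j`, the sequential explained sum of squares
#' is `tr(H_j G) - tr(H_{j-1} G)` and the residual is `tr((I - H_full) G)`.
#' For Euclidean distances this equals the classical centroid-based
#' partition. Permutation p-values use the add-one rule and so are never 0.
#'
#' @param response Numeric matrix or tibble of response rows (count columns).
#' @param factors A data frame (or named list) of per-row categorical
#'   factors; terms enter in the order given.
#' @param n_permutations Number of random row permutations (999 by default).
#' @param seed Integer seed for the permutations.
#' @param method Distance: `"euclidean"` (default) or `"bray"`
#'   (Bray-Curtis).
#' @param exhaustive If `TRUE`, enumerate all `n!` row orderings instead of
#'   sampling (only for small n); the p-value is then the exact permutation
#'   tail probability including the observed ordering.
#' @return An object of class `ssr_permanova`: `terms` tibble (`term`, `df`,
#'   `sum_sq`, `statistic`, `p_value`), `total_ss`, `df_total`, `degenerate`
#'   flag, `n_permutations`, `method`. `tidy()` and `glance()` methods are
#'   available.
#' @examples
#' x <- matrix(rnorm(40), nrow = 10)
#' f <- data.frame(g = rep(c("a", "b"), each = 5))
#' permanova(x, f, n_permutations = 99)
#' @export
permanova <- function(response, factors, n_permutations = 999, seed = 1L,
                      method = c("euclidean", "bray"), exhaustive = FALSE) {
  method <- match.arg(method)
  m <- block_matrix_noname(response)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  n <- nrow(m)
  stopifnot(nrow(factors) == n, ncol(factors) >= 1L)
  for (nm in names(factors)) {
    factors[[nm]] <- factor(factors[[nm]])
    if (nlevels(factors[[nm]]) < 2L) {
      abort(paste0("Factor '", nm, "' has a single level."))
    }
  }

  d <- compute_dist(m, method)
  G <- gower_center(as.matrix(d)^2)
  total_ss <- sum(diag(G))
  if (total_ss <= sqrt(.Machine$double.eps)) {
    return(structure(
      list(
        terms = tibble(term = names(factors), df = NA_integer_,
                       sum_sq = NA_real_, statistic = NA_real_,
                       p_value = NA_real_),
        total_ss = 0, df_total = n - 1L, degenerate = TRUE,
        n_permutations = 0L, method = method
      ),
      class = "ssr_permanova"
    ))
  }

  hats <- sequential_hats(factors)
  stats_obs <- pseudo_f(G, hats)

  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(p) {
      pseudo_f(G[p, p, drop = FALSE], hats)$statistic
    }, numeric(nrow(stats_obs)))
    f_perm <- matrix(f_perm, nrow = nrow(stats_obs))
    pvals <- rowMeans(f_perm >= stats_obs$statistic - f_tol(stats_obs$statistic))
    n_used <- length(perms)
  } else {
    f_perm <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_permutations), function(i) {
        p <- sample.int(n)
        pseudo_f(G[p, p, drop = FALSE], hats)$statistic
      }, numeric(nrow(stats_obs)))
    })
    f_perm <- matrix(f_perm, nrow = nrow(stats_obs))
    pvals <- (1 + rowSums(f_perm >= stats_obs$statistic - f_tol(stats_obs$statistic))) /
      (n_permutations + 1)
    n_used <- n_permutations
  }

  structure(
    list(
      terms = mutate(stats_obs, p_value = pvals),
      total_ss = total_ss, df_total = n - 1L, degenerate = FALSE,
      n_permutations = n_used, method = method
    ),
    class = "ssr_permanova"
  )
}

block_matrix_noname <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  }
  storage.mode(x) <- "double"
  x
}

compute_dist <- function(m, method) {
  if (method == "euclidean") return(dist(m))
  # Bray-Curtis on non-negative rows
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(m[i, ] + m[j, ])
      d[i, j] <- d[j, i] <- if (denom > 0) sum(abs(m[i, ] - m[j, ])) / denom else 0
    }
  }
  stats::as.dist(d)
}

gower_center <- function(d2) {
  a <- -d2 / 2
  n <- nrow(a)
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

sequential_hats <- function(factors) {
  terms <- names(factors)
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  prev_rank <- 1L
  for (j in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(j)], collapse = "+")))
    X <- stats::model.matrix(fml, data = factors)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    dfs[j] <- q$rank - prev_rank
    prev_rank <- q$rank
  }
  list(H = hats, df = dfs, terms = terms, rank_full = prev_rank)
}

pseudo_f <- function(G, hats) {
  n <- nrow(G)
  tr_prev <- 0
  ss <- numeric(length(hats$H))
  for (j in seq_along(hats$H)) {
    tr_j <- sum(hats$H[[j]] * G)
    ss[j] <- tr_j - tr_prev
    tr_prev <- tr_j
  }
  ss_res <- sum(diag(G)) - tr_prev
  df_res <- n - hats$rank_full
  tibble(
    term = hats$terms,
    df = hats$df,
    sum_sq = ss,
    statistic = (ss / hats$df) / (ss_res / df_res)
  )
}

# comparison tolerance: permuting the Gower matrix reproduces an equivalent
# relabeling's statistic only up to floating-point noise
f_tol <- function(stat) 1e-8 * pmax(1, abs(stat))

all_permutations <- function(n) {
  if (n > 8L) abort("Exhaustive enumeration is limited to n <= 8.")
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
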