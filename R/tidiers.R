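#' @export
print.ssr_permanova <- function(x, ...) {
  cat("Permutational multivariate ANOVA (", x$method, " distance)\n", sep = "")
  if (x$degenerate) {
    cat("Degenerate input: total sum of squares is zero; pseudo-F undefined.\n")
  } else {
    print(as.data.frame(x$terms), row.names = FALSE)
    cat("Total SS:", format(x$total_ss), " permutations:", x$n_permutations, "\n")
  }
  invisible(x)
}

#' Tidy a PERMANOVA fit
#'
#' @param x An `ssr_permanova` object.
#' @param ... Unused.
#' @return One row per sequential term: `term`, `df`, `sum_sq`, `statistic`
#'   (pseudo-F), `p_value`.
#' @method tidy ssr_permanova
#' @export
tidy.ssr_permanova <- function(x, ...) x$terms

#' @rdname tidy.ssr_permanova
#' @method glance ssr_permanova
#' @export
glance.ssr_permanova <- function(x, ...) {
  tibble(
    total_ss = x$total_ss, df_total = x$df_total,
    n_permutations = x$n_permutations, method = x$method,
    degenerate = x$degenerate
  )
}

#' @export
print.ssr_cap <- function(x, ...) {
  cat("Canonical ordination (principal coordinates + canonical correlation)\n")
  cat("First squared canonical correlation:", format(x$statistic), "\n")
  cat("Permutation p-value:", format(x$p_value),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Tidy a canonical-ordination result
#'
#' @param x An `ssr_cap` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic` (first squared canonical
#'   correlation), `statistic_name`, `p_value`, `n_permutations`.
#' @method tidy ssr_cap
#' @export
tidy.ssr_cap <- function(x, ...) {
  tibble(
    statistic = x$statistic, statistic_name = x$statistic_name,
    p_value = x$p_value, n_permutations = x$n_permutations
  )
}

#' @rdname tidy.ssr_cap
#' @method glance ssr_cap
#' @export
glance.ssr_cap <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value,
    n_genomes = length(x$genomes),
    n_axes_a = ncol(x$scores_a), n_axes_b = ncol(x$scores_b),
    n_permutations = x$n_permutations
  )
}
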