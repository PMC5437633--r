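#' Exponential microsatellite decay rate from a conserved fraction
#'
#' Assuming steady loss of loci over the divergence time `t`, the conserved
#' fraction `C` implies a per-million-year decay rate `lambda = -ln(C) / t`;
#' `C = 1` gives `lambda = 0` and `exp(-lambda * t)` reproduces `C`.
#'
#' @param conserved_fraction Conserved fraction(s) in `(0, 1]`.
#' @param divergence_time Divergence time in million years (default 6).
#' @return Decay rate(s) in events per million years.
#' @examples
#' decay_rate(0.5) # log(2)/6
#' @export
decay_rate <- function(conserved_fraction, divergence_time = 6) {
  stopifnot(divergence_time > 0)
  if (any(conserved_fraction <= 0 | conserved_fraction > 1, na.rm = TRUE)) {
    abort("`conserved_fraction` must be in (0, 1]; complete loss (C = 0) has no finite rate.")
  }
  -log(conserved_fraction) / divergence_time
}

#' Per-class decay estimates with contrasts against the pooled rate
#'
#' Converts per-class conservation into decay rates and contrasts each class
#' against the rate of all loci pooled: `relative_loss` is the loss-fraction
#' difference `(1 - C_k) - (1 - C_overall)` (the quantity plotted against the
#' `y = 0` reference line) and `relative_decay` is `lambda_k -
#' lambda_overall`. Classes with complete loss are flagged and excluded from
#' rate contrasts rather than reported as infinite.
#'
#' @param records An `ssr_conservation` tibble (from [assign_conservation()]),
#'   or a proportions tibble from [conservation_proportions()] (pooling then
#'   uses the class counts).
#' @param divergence_time Divergence time in million years.
#' @return A tibble with one row per motif-length class plus an `"overall"`
#'   row: `class`, `n_conserved`, `n_lost`, `conserved_fraction`,
#'   `decay_rate`, `relative_loss`, `relative_decay`, `complete_loss`,
#'   `undefined`.
#' @export
estimate_decay <- function(records, divergence_time = 6) {
  props <- if (inherits(records, "ssr_conservation")) {
    conservation_proportions(records)
  } else {
    records
  }
  stopifnot(all(c("motif_length", "n_conserved", "n_lost") %in% names(props)))
  overall_c <- sum(props$n_conserved) / (sum(props$n_conserved) + sum(props$n_lost))
  per <- props %>%
    mutate(
      class = as.character(.data$motif_length),
      denom = .data$n_conserved + .data$n_lost,
      conserved_fraction = if_else(.data$denom > 0L,
                                   .data$n_conserved / .data$denom, NA_real_),
      undefined = .data$denom == 0L,
      complete_loss = !.data$undefined & .data$conserved_fraction == 0
    )
  rate <- function(C, t) if_else(is.na(C) | C <= 0, NA_real_, -log(C) / t)
  lam_all <- rate(overall_c, divergence_time)
  out <- per %>%
    mutate(
      decay_rate = rate(.data$conserved_fraction, divergence_time),
      relative_loss = (1 - .data$conserved_fraction) - (1 - overall_c),
      relative_decay = .data$decay_rate - lam_all
    ) %>%
    select(
      "class", "n_conserved", "n_lost", "conserved_fraction", "decay_rate",
      "relative_loss", "relative_decay", "complete_loss", "undefined"
    )
  bind_rows(
    out,
    tibble(
      class = "overall",
      n_conserved = sum(props$n_conserved), n_lost = sum(props$n_lost),
      conserved_fraction = overall_c,
      decay_rate = lam_all, relative_loss = 0, relative_decay = 0,
      complete_loss = !is.na(overall_c) && overall_c == 0,
      undefined = is.na(overall_c)
    )
  )
}

#' Relative abundance of a focal genome's repeat classes over a reference
#'
#' `(focal density - reference density) / reference density` per class: 0
#' when the densities are equal, -1 when the class is absent from the focal
#' genome, and undefined (flagged) when the reference class has zero density.
#'
#' @param focal,reference Per-class density tibbles (e.g. the `genome`
#'   element of [summarize_density()]), sharing `class_col` and
#'   `density_col`.
#' @param class_col Name of the class column (default `"motif_length"`).
#' @param density_col Name of the density column (default
#'   `"density_per_mb"`).
#' @return A tibble: class column, `focal_density`, `reference_density`,
#'   `relative_abundance`, `undefined`.
#' @export
relative_abundance <- function(focal, reference,
                               class_col = "motif_length",
                               density_col = "density_per_mb") {
  f <- focal %>%
    select(dplyr::all_of(c(class_col, density_col))) %>%
    rename(focal_density = dplyr::all_of(density_col))
  r <- reference %>%
    select(dplyr::all_of(c(class_col, density_col))) %>%
    rename(reference_density = dplyr::all_of(density_col))
  dplyr::full_join(f, r, by = class_col) %>%
    mutate(
      focal_density = dplyr::coalesce(.data$focal_density, 0),
      reference_density = dplyr::coalesce(.data$reference_density, 0),
      undefined = .data$reference_density == 0,
      relative_abundance = if_else(
        .data$undefined, NA_real_,
        (.data$focal_density - .data$reference_density) / .data$reference_density
      )
    )
}

#' Nonparametric group comparisons for decay and abundance contrasts
#'
#' Delegates to the standard rank-based tests: Kruskal-Wallis across groups,
#' Friedman over a complete block design (e.g. motif classes measured on each
#' chromosome), or pairwise two-sided t-tests.
#'
#' @param data A tibble in long format.
#' @param value,group,block Column names (strings) for the response, the
#'   grouping factor, and (Friedman only) the blocking factor.
#' @param test One of `"kruskal_wallis"`, `"friedman"`, `"pairwise_t"`.
#' @param p_adjust Adjustment method for pairwise t-tests (default `"none"`,
#'   significance judged at 0.05 two-sided).
#' @return For the omnibus tests a one-row tibble (`method`, `statistic`,
#'   `df`, `p_value`); for `pairwise_t` a tibble of group pairs with
#'   `p_value`.
#' @export
compare_groups <- function(data, value, group, block = NULL,
                           test = c("kruskal_wallis", "friedman", "pairwise_t"),
                           p_adjust = "none") {
  test <- match.arg(test)
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("Need at least 2 groups.")
  constant <- length(unique(v)) == 1L
  if (test == "kruskal_wallis") {
    if (constant) {
      return(tibble(method = "Kruskal-Wallis", statistic = 0,
                    df = nlevels(g) - 1, p_value = 1))
    }
    kt <- kruskal.test(v, g)
    return(tibble(method = "Kruskal-Wallis", statistic = unname(kt$statistic),
                  df = unname(kt$parameter), p_value = kt$p.value))
  }
  if (test == "friedman") {
    if (is.null(block)) abort("Friedman test needs a `block` column.")
    b <- factor(data[[block]])
    tab <- table(g, b)
    if (any(tab != 1L)) {
      abort("Friedman test needs a complete, unreplicated block design.")
    }
    if (constant) {
      return(tibble(method = "Friedman", statistic = 0,
                    df = nlevels(g) - 1, p_value = 1))
    }
    ft <- friedman.test(v, g, b)
    return(tibble(method = "Friedman", statistic = unname(ft$statistic),
                  df = unname(ft$parameter), p_value = ft$p.value))
  }
  pt <- pairwise.t.test(v, g, p.adjust.method = p_adjust, pool.sd = FALSE)
  as_tibble(as.data.frame(as.table(pt$p.value)), .name_repair = "minimal") %>%
    stats::setNames(c("group_a", "group_b", "p_value")) %>%
    filter(!is.na(.data$p_value)) %>%
    mutate(significant = .data$p_value <= 0.05)
}
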