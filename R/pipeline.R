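#' Declare a pipeline run: genomes, comparisons, seed
#'
#' @param genomes Tibble with columns `id`, `fasta` (path), `role`
#'   (`"progenitor"`, `"tetraploid"` or `"reference"`), and optionally `te`
#'   (annotation path, `NA` when absent).
#' @param comparisons Tibble with columns `query` (progenitor id) and
#'   `subject` (derived genome id); both must be declared in `genomes`.
#' @param seed Global seed; per-stage seeds are derived from it so stages
#'   stay reproducible independently.
#' @return A validated list of class `ssr_manifest`.
#' @export
run_manifest <- function(genomes, comparisons = NULL, seed = 1L) {
  genomes <- as_tibble(genomes)
  stopifnot(all(c("id", "fasta", "role") %in% names(genomes)))
  if (anyDuplicated(genomes$id)) abort("Duplicate genome ids in manifest.")
  if (!all(genomes$role %in% c("progenitor", "tetraploid", "reference"))) {
    abort("Genome roles must be progenitor, tetraploid or reference.")
  }
  if (!is.null(comparisons)) {
    comparisons <- as_tibble(comparisons)
    stopifnot(all(c("query", "subject") %in% names(comparisons)))
    undeclared <- setdiff(c(comparisons$query, comparisons$subject), genomes$id)
    if (length(undeclared)) {
      abort(paste0("Comparison references undeclared genome(s): ",
                   paste(undeclared, collapse = ", ")))
    }
  }
  missing <- genomes$fasta[!file.exists(genomes$fasta)]
  if (length(missing)) {
    abort(paste0("Missing input file(s): ", paste(missing, collapse = ", ")))
  }
  structure(
    list(genomes = genomes, comparisons = comparisons, seed = as.integer(seed)),
    class = "ssr_manifest"
  )
}

stage_seed <- function(seed, stage) {
  # cheap deterministic fan-out that stays within 32-bit integer range
  (as.integer(seed) * 1103L + match(stage, c(
    "simulate", "scan", "imperfection", "te", "conserve", "decay"
  )) * 7919L) %% 2147483562L
}

#' Run the full pipeline over a manifest
#'
#' Stages run in dependency order: scan each genome (detection,
#' standardization, compound exclusion, density summaries), build the
#' mismatch-by-length datasets and run the imperfection analyses (when at
#' least 3 genomes are declared), count TEs near loci where annotations are
#' given, then for every comparison pair build the progenitor library, filter
#' it for self-uniqueness, assign conservation against the subject and
#' estimate decay. Every stage writes TSV outputs (1-based inclusive
#' coordinates, commented units header) plus a machine-readable
#' `summary.json`; a log records parameters and derived seeds. Stages whose
#' outputs already exist are skipped unless `overwrite = TRUE`, so partial
#' reruns resume.
#'
#' @param manifest An [run_manifest()] object.
#' @param out_dir Output directory (created if needed).
#' @param detection A [detection_config()].
#' @param search A [search_config()].
#' @param divergence_time Divergence time (million years) for decay rates.
#' @param n_permutations Permutations for the imperfection tests.
#' @param overwrite Recompute stages whose outputs already exist.
#' @return Invisibly, a list with the per-genome loci, density summaries,
#'   analysis results, conservation records and decay tables, plus the paths
#'   written.
#' @export
run_pipeline <- function(manifest, out_dir,
                         detection = detection_config(),
                         search = search_config(),
                         divergence_time = 6,
                         n_permutations = 999,
                         overwrite = FALSE) {
  stopifnot(inherits(manifest, "ssr_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(paste0(..., "\n"), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  log_line("ssrdecay pipeline; package version ",
           as.character(utils::packageVersion("ssrdecay")))
  log_line("global seed ", manifest$seed)

  # stage: scan
  loci_by_genome <- list()
  lengths_by_genome <- list()
  density_by_genome <- list()
  for (i in seq_len(nrow(manifest$genomes))) {
    id <- manifest$genomes$id[i]
    loci_path <- file.path(out_dir, paste0("loci_", id, ".tsv"))
    seqs <- read_genome_fasta(manifest$genomes$fasta[i])
    lengths_by_genome[[id]] <- setNames(nchar(seqs), names(seqs))
    if (file.exists(loci_path) && !overwrite) {
      log_line("scan: reusing ", loci_path)
      loci <- read_loci_tsv(loci_path)
    } else {
      loci <- scan_genome(seqs, detection) %>% flag_compounds(detection)
      write_loci_tsv(loci, loci_path)
      log_line("scan: ", id, " -> ", nrow(loci), " loci")
    }
    loci_by_genome[[id]] <- loci
    keep <- filter(loci, !.data$compound)
    density_by_genome[[id]] <- summarize_density(keep, lengths_by_genome[[id]])
    write_tsv_commented(
      density_by_genome[[id]]$genome,
      file.path(out_dir, paste0("density_", id, ".tsv")),
      "per-class locus density (loci per Mb)"
    )
  }

  # stage: imperfection analyses (needs >= 3 genomes)
  analyses <- NULL
  if (nrow(manifest$genomes) >= 3L) {
    all_loci <- bind_rows(purrr::imap(
      loci_by_genome,
      ~ mutate(filter(.x, !.data$compound), genome = .y)
    ))
    datasets <- build_mismatch_datasets(all_loci)
    write_tsv_commented(datasets$dataset_I,
                        file.path(out_dir, "dataset_I.tsv"),
                        "locus counts, length 20-24 nt x mismatch 0-1")
    write_tsv_commented(datasets$dataset_II,
                        file.path(out_dir, "dataset_II.tsv"),
                        "locus counts, length 25-29 nt x mismatch 1-2")
    cap <- tryCatch(
      canonical_ordination(
        dataset_block(datasets$dataset_I, 0),
        dataset_block(datasets$dataset_I, 1),
        n_permutations = n_permutations,
        seed = stage_seed(manifest$seed, "imperfection")
      ),
      error = function(e) {
        log_line("imperfection: canonical ordination skipped (", conditionMessage(e), ")")
        NULL
      }
    )
    analyses <- list(datasets = datasets, cap = cap)
    log_line("imperfection: datasets built for ", length(loci_by_genome), " genomes")
  }

  # stage: TE proximity
  te_results <- list()
  if ("te" %in% names(manifest$genomes)) {
    for (i in seq_len(nrow(manifest$genomes))) {
      id <- manifest$genomes$id[i]
      te_path <- manifest$genomes$te[i]
      if (is.na(te_path) || !nzchar(te_path)) next
      tes <- read_te_annotation(te_path)
      rec <- count_tes_near_loci(
        filter(loci_by_genome[[id]], !.data$compound), tes
      )
      te_results[[id]] <- list(
        records = rec,
        correlation = if (nrow(rec) >= 3) correlate_te_repeats(rec)
      )
      write_tsv_commented(rec, file.path(out_dir, paste0("te_", id, ".tsv")),
                          "TE counts within 500 nt of loci")
    }
  }

  # stage: conservation + decay
  conservation <- list()
  decay <- list()
  if (!is.null(manifest$comparisons)) {
    for (i in seq_len(nrow(manifest$comparisons))) {
      q <- manifest$comparisons$query[i]
      s <- manifest$comparisons$subject[i]
      pair <- paste0(q, "_vs_", s)
      prog_seqs <- read_genome_fasta(
        manifest$genomes$fasta[manifest$genomes$id == q]
      )
      subj_seqs <- read_genome_fasta(
        manifest$genomes$fasta[manifest$genomes$id == s]
      )
      lib <- build_locus_library(loci_by_genome[[q]], prog_seqs) %>%
        self_uniqueness_filter(search)
      records <- assign_conservation(lib, subj_seqs, prog_seqs, search)
      conservation[[pair]] <- records
      decay[[pair]] <- estimate_decay(records, divergence_time)
      write_tsv_commented(
        select(records, -"positions"),
        file.path(out_dir, paste0("conservation_", pair, ".tsv")),
        "conservation verdicts per progenitor locus"
      )
      write_circos_links(records, lib,
                         file.path(out_dir, paste0("links_", pair, ".tsv")))
      write_tsv_commented(
        decay[[pair]],
        file.path(out_dir, paste0("decay_", pair, ".tsv")),
        "per-class decay rates (per million years)"
      )
      log_line("conserve: ", pair, " -> ",
               sum(records$status == "conserved"), "/", nrow(records),
               " conserved")
    }
  }

  summary <- list(
    seed = manifest$seed,
    genomes = manifest$genomes$id,
    n_loci = purrr::map_int(loci_by_genome, nrow),
    density = purrr::map(density_by_genome, ~ .x$genome),
    cap = if (!is.null(analyses$cap)) {
      list(statistic = analyses$cap$statistic, p_value = analyses$cap$p_value)
    },
    conservation = purrr::map(conservation, ~ as.list(table(.x$status))),
    decay = purrr::map(decay, ~ select(.x, "class", "conserved_fraction",
                                       "decay_rate"))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    loci = loci_by_genome, density = density_by_genome, analyses = analyses,
    te = te_results, conservation = conservation, decay = decay,
    out_dir = out_dir
  ))
}

#' Simulate a demo study and write its inputs to disk
#'
#' Generates two progenitor genomes, evolves them into a tetraploid under the
#' default scenario, writes all FASTA/GFF3 inputs under `dir` and returns a
#' ready [run_manifest()] comparing each progenitor with the tetraploid.
#'
#' @param dir Directory for the generated inputs.
#' @param seed Global seed.
#' @param config_A,config_D [simulation_config()]s for the two progenitors
#'   (defaults are small, minute-scale genomes).
#' @param scenario An [evolution_scenario()].
#' @return A list: `manifest`, plus the in-memory `progenitor_A`,
#'   `progenitor_D` and `tetraploid` objects.
#' @export
simulate_study <- function(dir, seed = 1L,
                           config_A = simulation_config(
                             seed = stage_seed(seed, "simulate"),
                             n_chromosomes = 2L, chromosome_length = 60000L,
                             planted_loci_per_chromosome = 50L
                           ),
                           config_D = simulation_config(
                             seed = stage_seed(seed, "simulate") + 1L,
                             n_chromosomes = 2L, chromosome_length = 60000L,
                             planted_loci_per_chromosome = 50L
                           ),
                           scenario = evolution_scenario()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prog_a <- generate_genome(config_A)
  prog_d <- generate_genome(config_D)
  tetra <- evolve_tetraploid(prog_a, prog_d, scenario,
                             seed = stage_seed(seed, "simulate") + 2L)
  pa <- file.path(dir, "progenitor_A.fa")
  pd <- file.path(dir, "progenitor_D.fa")
  pt <- file.path(dir, "tetraploid.fa")
  write_genome_fasta(prog_a$sequences, pa)
  write_genome_fasta(prog_d$sequences, pd)
  write_genome_fasta(tetra$sequences, pt)
  write_tsv_commented(prog_a$truth, file.path(dir, "truth_A.tsv"),
                      "planted locus truth")
  write_tsv_commented(prog_d$truth, file.path(dir, "truth_D.tsv"),
                      "planted locus truth")
  te_a <- file.path(dir, "te_A.gff3")
  has_te <- requireNamespace("rtracklayer", quietly = TRUE) &&
    nrow(prog_a$tes) > 0
  if (has_te) write_te_gff3(prog_a$tes, te_a)
  manifest <- run_manifest(
    genomes = tibble(
      id = c("A", "D", "T"),
      fasta = c(pa, pd, pt),
      role = c("progenitor", "progenitor", "tetraploid"),
      te = c(if (has_te) te_a else NA_character_, NA_character_, NA_character_)
    ),
    comparisons = tibble(query = c("A", "D"), subject = c("T", "T")),
    seed = seed
  )
  list(manifest = manifest, progenitor_A = prog_a, progenitor_D = prog_d,
       tetraploid = tetra)
}
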