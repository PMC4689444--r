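# End-to-end orchestration: trim -> artifact filter -> merge ->
# {content profiling, SSR mining -> primer design} -> summary statistics,
# with per-stage record accounting and a survey-style one-row summary.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with validation. Unknown arguments are
#' rejected by normal argument matching; invalid values fail here, before
#' any stage runs.
#'
#' @param species_label Label used in the summary row.
#' @param trim A [trim_config()].
#' @param copy_windows An [ssr_copy_windows()] tibble.
#' @param min_flank Minimum non-repetitive flank in bases (default 15).
#' @param identity_threshold Fragment-collapse identity (default 0.95).
#' @param min_cluster_overlap Minimum aligned bases for collapse
#'   (default 50).
#' @param primer A [primer_constraints()].
#' @param repeat_min_score Minimum score for repeat classification
#'   (default 30).
#' @param evalue_cutoff Gene-likeness expectation cutoff (default 1e-5).
#' @param pg_per_mbp_constant Mbp per pg for genome sizing (default 978).
#' @param genome_size_mbp Genome size for coverage, `NA` when unknown.
#' @param seed Seed for the merge tie-break.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(species_label = "synthetic",
                            trim = trim_config(),
                            copy_windows = ssr_copy_windows(),
                            min_flank = 15L,
                            identity_threshold = 0.95,
                            min_cluster_overlap = 50L,
                            primer = primer_constraints(),
                            repeat_min_score = 30L,
                            evalue_cutoff = 1e-5,
                            pg_per_mbp_constant = 978,
                            genome_size_mbp = NA_real_,
                            seed = 1L) {
  stopifnot(inherits(trim, "trim_config"),
            inherits(primer, "primer_constraints"))
  if (min_flank < 0) abort("min_flank must be non-negative")
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1]")
  }
  if (evalue_cutoff <= 0) abort("evalue_cutoff must be positive")
  if (pg_per_mbp_constant <= 0) abort("pg_per_mbp_constant must be positive")
  structure(
    list(species_label = species_label, trim = trim,
         copy_windows = copy_windows, min_flank = as.integer(min_flank),
         identity_threshold = identity_threshold,
         min_cluster_overlap = as.integer(min_cluster_overlap),
         primer = primer, repeat_min_score = as.integer(repeat_min_score),
         evalue_cutoff = evalue_cutoff,
         pg_per_mbp_constant = pg_per_mbp_constant,
         genome_size_mbp = genome_size_mbp, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Percent of PALs whose source fragment is gene-like
#'
#' Reported overall and restricted to trinucleotide loci. With zero PALs
#' the percentages are undefined (`NA`), not 0.
#'
#' @param pals PAL tibble from [design_pals()].
#' @param gene_like_ids Fragment ids found gene-like by
#'   [find_gene_like()].
#' @return One-row tibble: `pct_pals_gene`, `pct_tri_pals_gene`.
#' @export
pal_gene_overlap <- function(pals, gene_like_ids) {
  pct <- function(x) {
    if (length(x) == 0) NA_real_ else 100 * mean(x %in% gene_like_ids)
  }
  tibble(pct_pals_gene = pct(pals$fragment_id),
         pct_tri_pals_gene = pct(pals$fragment_id[pals$period == 3L]))
}

#' Run the survey pipeline end to end
#'
#' Executes trimming, artifact filtering and merging, then content
#' profiling on the merged (reconstructed) fragments and SSR mining plus
#' primer design on all fragments, and assembles a survey-style one-row
#' summary (coverage, GC%, gSSR and PAL counts and densities, gene
#' overlap). Deterministic given `config$seed`.
#'
#' @param pairs Read-pair tibble (e.g. from [simulate_reads()] or
#'   [read_fastq_pair()]).
#' @param config A [pipeline_config()].
#' @param repeat_library,proteins,transcripts Optional tibbles (`id`,
#'   `seq`) for repeat classification, gene-likeness and reference-gene
#'   representation; stages without inputs are skipped.
#' @param outdir Optional directory; when given, all stage tables are
#'   written as TSV (plus fragments as FASTA and a run manifest).
#' @return A `gssr_run` list: `fragments`, `tally`, `profile`,
#'   `loci_all`, `loci_filtered`, `loci`, `pals`, `ssr_stats`,
#'   `pal_stats`, `summary`, `config`. `glance()` returns the summary
#'   row; `tidy()` the per-stage record tally.
#' @export
run_pipeline <- function(pairs, config = pipeline_config(),
                         repeat_library = NULL, proteins = NULL,
                         transcripts = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n_input <- nrow(pairs)
  trimmed <- trim_pairs(pairs, config$trim)
  n_trim_drop <- n_input - nrow(trimmed)
  flagged <- flag_artifact_pairs(trimmed, config$trim$artifact_tail_len)
  clean <- filter(flagged, !.data$artifact)
  n_artifact <- sum(flagged$artifact)
  fragments <- merge_pairs(clean, config$trim, seed = config$seed)
  n_merged <- sum(fragments$origin == "merged")
  n_unmerged_pairs <- nrow(clean) - n_merged
  tally <- tibble(
    stage = c("input_pairs", "discarded_trim", "artifact_pairs",
              "merged_pairs", "unmerged_pairs"),
    n = c(n_input, n_trim_drop, n_artifact, n_merged, n_unmerged_pairs))

  merged <- filter(fragments, .data$origin == "merged")
  merged_bases <- sum(nchar(merged$seq))
  total_bases <- sum(nchar(fragments$seq))
  profile <- list(
    species_label = config$species_label,
    total_fragment_bases = total_bases,
    merged_fragment_bases = merged_bases,
    gc_percent = if (nrow(merged) > 0) gc_content(merged) else NA_real_,
    coverage_x = estimate_coverage(merged_bases, config$genome_size_mbp),
    percent_merged = if (nrow(clean) > 0) 100 * n_merged / nrow(clean)
                     else NA_real_)
  profile$repeats <- if (!is.null(repeat_library) && nrow(merged) > 0) {
    classify_repeats(merged, repeat_library, config$repeat_min_score)
  }
  gene <- NULL
  if (!is.null(proteins) && nrow(fragments) > 0) {
    gene <- find_gene_like(fragments, proteins, config$evalue_cutoff)
    profile$gene_fraction <-
      if (nrow(merged) > 0) {
        100 * sum(merged$id %in% gene$gene_like_ids) / nrow(merged)
      } else NA_real_
    if (!is.null(transcripts)) {
      gl <- filter(fragments, .data$id %in% gene$gene_like_ids)
      profile$representation <- gene_representation(gl, transcripts)
    }
  }
  profile$gene_like <- gene

  loci_all <- find_perfect_ssrs(fragments, config$copy_windows)
  loci_filtered <- apply_flank_and_compound_filters(
    loci_all, fragments, config$min_flank)
  loci <- collapse_loci(loci_filtered, fragments,
                        config$identity_threshold,
                        config$min_cluster_overlap)
  pals <- design_pals(loci, fragments, config$primer)
  sstats <- ssr_statistics(loci, total_bases)
  pstats <- pal_statistics(pals, loci, total_bases)
  overlap <- pal_gene_overlap(pals, gene$gene_like_ids %||% character())

  summary <- tibble(
    species_label = config$species_label,
    coverage_x = profile$coverage_x,
    gc_percent = round(profile$gc_percent, 1),
    n_gssrs = nrow(loci),
    n_gssrs_precollapse = nrow(loci_filtered),
    n_pals = nrow(pals),
    gssrs_per_mb = round(sstats$loci_per_mb, 1),
    pals_per_mb = round(pstats$pals_per_mb, 1),
    pct_pals_gene = round(overlap$pct_pals_gene, 1),
    pct_tri_pals_gene = round(overlap$pct_tri_pals_gene, 1))

  run <- structure(
    list(fragments = fragments, tally = tally, profile = profile,
         loci_all = loci_all, loci_filtered = loci_filtered, loci = loci,
         pals = pals, ssr_stats = sstats, pal_stats = pstats,
         summary = summary, config = config),
    class = "gssr_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
glance.gssr_run <- function(x, ...) x$summary

#' @export
tidy.gssr_run <- function(x, ...) x$tally

#' @export
print.gssr_run <- function(x, ...) {
  cat("Genome survey run:", x$config$species_label, "\n")
  print(x$tally)
  print(x$summary)
  invisible(x)
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_stage_tsv(run$tally, p("stage_tally.tsv"))
  write_fasta_tbl(run$fragments, p("fragments.fasta"))
  write_stage_tsv(run$loci_filtered, p("ssr_loci.tsv"))
  write_stage_tsv(select(run$loci, -dplyr::any_of("cluster")),
                  p("ssr_loci_collapsed.tsv"))
  write_stage_tsv(run$pals, p("pals.tsv"))
  write_stage_tsv(tidy(run$ssr_stats), p("motif_frequency.tsv"))
  write_stage_tsv(run$summary, p("summary.tsv"))
  cfg <- run$config
  manifest <- c(
    paste0("species_label\t", cfg$species_label),
    paste0("seed\t", cfg$seed),
    paste0("min_flank\t", cfg$min_flank),
    paste0("identity_threshold\t", cfg$identity_threshold),
    paste0("min_cluster_overlap\t", cfg$min_cluster_overlap),
    paste0("repeat_min_score\t", cfg$repeat_min_score),
    paste0("evalue_cutoff\t", format(cfg$evalue_cutoff)),
    paste0("pg_per_mbp_constant\t", cfg$pg_per_mbp_constant),
    paste0("genome_size_mbp\t", cfg$genome_size_mbp),
    paste0("window_size\t", cfg$trim$window_size),
    paste0("window_qual\t", cfg$trim$window_qual),
    paste0("min_len\t", cfg$trim$min_len),
    paste0("artifact_tail_len\t", cfg$trim$artifact_tail_len),
    paste0("min_overlap\t", cfg$trim$min_overlap),
    paste0("max_mismatch_ratio\t", cfg$trim$max_mismatch_ratio),
    paste0("copy_windows\t",
           paste(sprintf("%d:%d-%d", cfg$copy_windows$period,
                         cfg$copy_windows$min_copies,
                         cfg$copy_windows$max_copies), collapse = ",")),
    paste0("primer_opt_size\t", cfg$primer$opt_size),
    paste0("primer_min_size\t", cfg$primer$min_size),
    paste0("primer_max_size\t", cfg$primer$max_size),
    paste0("primer_product_size_range\t",
           paste(cfg$primer$product_range, collapse = "-")),
    paste0("primer_opt_tm\t", cfg$primer$opt_tm),
    paste0("primer_min_tm\t", cfg$primer$min_tm),
    paste0("primer_max_tm\t", cfg$primer$max_tm),
    paste0("primer_min_gc\t", cfg$primer$min_gc),
    paste0("primer_max_gc\t", cfg$primer$max_gc),
    paste0("primer_max_poly_x\t", cfg$primer$max_poly_x),
    paste0("primer_gc_clamp\t", cfg$primer$gc_clamp),
    paste0("dust_level\t", cfg$primer$dust_level))
  writeLines(manifest, p("run_manifest.tsv"))
  invisible(run)
}
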