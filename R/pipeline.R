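# End-to-end orchestration: concordance -> annotation -> placement null ->
# enrichment -> motif discovery/scanning, with a run manifest recording
# per-stage seeds, wall times and output digests. Stages hand off plain
# tibbles; files are written only when an output directory is given.

#' Run the full downstream pipeline
#'
#' Chains the analysis stages on two replicate peak lists and a genome:
#' replicate concordance filtering, TSC annotation, the Monte Carlo
#' placement null, functional-category and gene-list enrichment, and (when
#' the genome carries sequence) motif discovery on the top-ranked peaks plus
#' a consensus scan back over them. All randomness derives from
#' `config$rng_seed`. If `out_dir` is given, the merged annotated peak
#' table, enrichment tables and motif files are written there and digested
#' in the manifest.
#'
#' @param rep1,rep2 per-replicate peak tibbles (see [read_peaks()]).
#' @param genome a `genome_model`.
#' @param config an [analysis_config()].
#' @param gene_lists optional named list of gene-list tibbles for
#'   [genelist_enrichment()].
#' @param operon_map optional operon table applied to each gene list.
#' @param discover_motif run EM motif discovery (needs sequence).
#' @param motif_restarts EM restarts.
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result`: merged, annotations, summary,
#'   null, categories, list_enrichment, motif, motif_hits, manifest.
#' @export
run_pipeline <- function(rep1, rep2, genome, config = analysis_config(),
                         gene_lists = NULL, operon_map = NULL,
                         discover_motif = TRUE, motif_restarts = 10,
                         out_dir = NULL) {
  t0 <- Sys.time()
  stages <- list()
  stage <- function(name, expr) {
    tic <- Sys.time()
    val <- force(expr)
    stages[[name]] <<- tibble(
      stage = name,
      seconds = as.numeric(difftime(Sys.time(), tic, units = "secs")))
    val
  }

  merged <- stage("concordance",
                  filter_concordant(rep1, rep2, config$concordance_cutoff))
  assert_that(nrow(merged) > 0, "no concordant peaks at this cutoff")
  report <- concordance_report(rep1, rep2, config$concordance_cutoff)
  annotations <- stage("annotate", annotate_all(merged, genome, config))
  nullres <- stage("nullmodel", null_comparison(annotations, genome, config))
  categories <- NULL
  if (any(!is.na(genome$genes$category))) {
    categories <- stage("enrich_categories",
                        category_table(annotations, genome))
  }
  list_enrichment <- NULL
  if (!is.null(gene_lists)) {
    list_enrichment <- stage("enrich_lists", purrr::map_dfr(
      gene_lists, function(gl) {
        genelist_enrichment(annotations, gl, genome,
                            operon_map = operon_map)
      }))
  }
  motif <- NULL; motif_hits <- NULL; flanks <- NULL
  if (discover_motif && !is.null(genome$sequence)) {
    flanks <- extract_flanks(annotations, genome, config$flank)
    top <- partition_ranked(flanks, top_n = config$top_n_for_motif,
                            partition_size = config$top_n_for_motif)[[1]]
    motif <- stage("motif_discover", em_discover(
      top$sequence, width = config$motif_width,
      n_restarts = motif_restarts,
      rng_seed = derive_seed(config$rng_seed, "motif")))
    motif_hits <- stage("motif_scan", {
      seqs <- setNames(top$sequence, top$sequence_id)
      scan_iupac(seqs, motif$consensus_iupac)
    })
  }

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_peak_table(annotations, p("peaks_annotated.tsv"))
    readr::write_tsv(report, p("concordance_report.tsv"), progress = FALSE)
    if (!is.null(categories)) {
      readr::write_tsv(categories, p("category_enrichment.tsv"),
                       progress = FALSE)
    }
    if (!is.null(list_enrichment)) {
      readr::write_tsv(list_enrichment, p("list_enrichment.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(tidy(nullres), p("null_region_counts.tsv"),
                     progress = FALSE)
    if (!is.null(motif)) {
      write_meme(motif, p("motif.meme"))
      readr::write_tsv(motif_hits, p("motif_hits.tsv"), progress = FALSE)
    }
    outputs <- list.files(out_dir, full.names = TRUE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("chipregulon")),
    config = unclass(config),
    seed = config$rng_seed,
    stage_seeds = list(nullmodel = derive_seed(config$rng_seed, "nullmodel"),
                       motif = derive_seed(config$rng_seed, "motif")),
    stages = bind_rows(stages),
    outputs = tibble(path = outputs,
                     digest = unname(vapply(outputs, digest_file,
                                            character(1)))),
    wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(merged = merged, report = report,
                 annotations = annotations,
                 summary = annotation_summary(annotations),
                 null = nullres, categories = categories,
                 list_enrichment = list_enrichment,
                 motif = motif, motif_hits = motif_hits,
                 flanks = flanks, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pipeline_result> %d merged peaks (%d coding / %d noncoding); %d promoter sites, %d divergent, %d genes\n",
    s$n_peaks, s$n_coding, s$n_noncoding, s$n_promoter_sites,
    s$n_divergent, s$n_promoter_genes))
  if (!is.null(x$motif)) {
    cat(sprintf("  motif: %s (total IC %.1f bits)\n",
                x$motif$consensus_iupac, sum(x$motif$ic)))
  }
  invisible(x)
}

#' One-command synthetic demonstration
#'
#' Generates a synthetic study and runs the full pipeline on it; the return
#' value carries both the ground truth and the pipeline result, so recovery
#' can be checked directly.
#'
#' @param seed top-level seed.
#' @param out_dir optional output directory.
#' @param motif_restarts EM restarts (default 5 keeps the demo quick).
#' @param ... passed to [synthesize_study()].
#' @return list with `study` and `result`.
#' @export
demo_pipeline <- function(seed = 1L, out_dir = NULL, motif_restarts = 5,
                          ...) {
  study <- synthesize_study(seed = seed, ...)
  result <- run_pipeline(study$rep1, study$rep2, study$genome,
                         config = study$config,
                         gene_lists = study$lists,
                         discover_motif = TRUE,
                         motif_restarts = motif_restarts,
                         out_dir = out_dir)
  list(study = study, result = result)
}

#' Fraction of shared true sites recovered by the merged peak set
#'
#' A shared site counts as recovered when a merged peak lies within
#' `tolerance` bp of its planted coordinate.
#'
#' @param study a `synthetic_study`.
#' @param merged merged peak tibble from [filter_concordant()].
#' @param tolerance bp.
#' @return scalar fraction in `[0, 1]`.
#' @export
site_recovery <- function(study, merged, tolerance = 50) {
  shared <- filter(study$true_sites,
                   .data$site_id %in% study$shared_sites)
  if (nrow(shared) == 0) return(NA_real_)
  hit <- vapply(shared$coordinate, function(cc) {
    any(abs(merged$coordinate - cc) <= tolerance)
  }, logical(1))
  mean(hit)
}
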