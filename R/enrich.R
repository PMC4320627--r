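# Category and gene-list enrichment. The expected count for a category is
# its genome-wide gene count scaled by the ratio of genes near a binding site
# to all categorized genes; significance is a two-sided Fisher's exact test
# on the gene-level 2x2 table. Counting is gene-level: a gene counts once no
# matter how many peaks hit its promoter window, and divergent sites count
# toward both flanking genes.

#' Expected gene count near binding sites
#'
#' `raw = n_genome * near_total / genome_total`, the category's genome-wide
#' gene count multiplied by the ratio of genes near a binding site to all
#' genes in the universe. The displayed value rounds halves away from zero.
#'
#' @param n_genome genes in the category genome-wide.
#' @param near_total genes near a binding site (promoter-window hits),
#'   genome-wide.
#' @param genome_total genes in the universe (> 0).
#' @return tibble with columns raw, rounded.
#' @export
#' @examples
#' expected_count(410, 1393, 7379)  # rounds to 77
expected_count <- function(n_genome, near_total, genome_total) {
  assert_that(all(genome_total > 0), "genome_total must be > 0")
  assert_that(all(n_genome <= genome_total),
              "n_genome cannot exceed genome_total")
  raw <- n_genome * near_total / genome_total
  tibble(raw = raw, rounded = round_half_away(raw))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than that of the observed table
#' (the minimum-likelihood rule, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d nonnegative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)`.
#' @return the two-sided p-value.
#' @export
#' @examples
#' fisher_2x2(5, 5, 5, 5)  # identical proportions -> 1
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  assert_that(all(counts >= 0) && all(counts == floor(counts)),
              "cell counts must be nonnegative integers")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  fisher.test(tab)$p.value
}

# Distinct genes with >= 1 promoter-window hit across annotated peaks.
promoter_hit_genes <- function(annotations) {
  unique(unlist(lapply(annotations$promoter_hits, function(h) h$gene_id)))
}

enrichment_row <- function(label, member_ids, hit_ids, universe_ids) {
  n_genome <- length(member_ids)
  n_observed <- length(intersect(member_ids, hit_ids))
  near_total <- length(hit_ids)
  genome_total <- length(universe_ids)
  exp <- expected_count(n_genome, near_total, genome_total)
  p <- fisher_2x2(n_observed, n_genome - n_observed,
                  near_total - n_observed,
                  (genome_total - n_genome) - (near_total - n_observed))
  tibble(label = label, n_genome = n_genome, n_observed = n_observed,
         n_expected_raw = exp$raw, n_expected = exp$rounded, p_value = p)
}

#' Functional-category enrichment table
#'
#' One row per functional category: genome-wide gene count, observed count of
#' distinct category genes with a promoter-window hit, the expected count,
#' and a two-sided Fisher's exact p-value against the rest of the categorized
#' universe. Raw p-values are reported row by row; a Benjamini-Hochberg
#' `fdr` column is appended as an optional extra.
#'
#' @param annotations annotated peaks from [annotate_all()].
#' @param genome a `genome_model` whose genes carry categories.
#' @param with_fdr append the BH-adjusted column (default TRUE).
#' @return tibble of enrichment rows plus a `Total` row.
#' @export
category_table <- function(annotations, genome, with_fdr = TRUE) {
  g <- filter(genome$genes, !is.na(.data$category))
  assert_that(nrow(g) > 0, "no genes carry a functional category")
  universe <- g$gene_id
  hit_ids <- intersect(promoter_hit_genes(annotations), universe)
  cats <- sort(unique(g$category))
  rows <- purrr::map_dfr(cats, function(cc) {
    enrichment_row(cc, g$gene_id[g$category == cc], hit_ids, universe)
  })
  if (with_fdr) rows$fdr <- p.adjust(rows$p_value, method = "BH")
  total <- tibble(label = "Total",
                  n_genome = length(universe),
                  n_observed = length(hit_ids),
                  n_expected_raw = sum(rows$n_expected_raw),
                  n_expected = round_half_away(sum(rows$n_expected_raw)),
                  p_value = NA_real_)
  if (with_fdr) total$fdr <- NA_real_
  bind_rows(rows, total)
}

#' Gene-list enrichment
#'
#' As [category_table()] for an arbitrary validated gene list; optionally
#' collapses the list to operon promoter regions first (drops members
#' downstream of the first gene of their operon).
#'
#' @param annotations annotated peaks from [annotate_all()].
#' @param gene_list tibble from [gene_list()] (nonempty).
#' @param genome a `genome_model`.
#' @param operon_map optional operon table; when supplied the list is passed
#'   through [collapse_to_promoter_regions()].
#' @param universe optional character vector of gene ids defining the test
#'   universe; defaults to categorized genes when categories exist, else all
#'   genes.
#' @return one-row enrichment tibble.
#' @export
genelist_enrichment <- function(annotations, gene_list, genome,
                                operon_map = NULL, universe = NULL) {
  assert_that(nrow(gene_list) > 0, "empty gene list")
  if (!is.null(operon_map)) {
    gene_list <- collapse_to_promoter_regions(gene_list, operon_map)
  }
  if (is.null(universe)) {
    categorized <- genome$genes$gene_id[!is.na(genome$genes$category)]
    universe <- if (length(categorized) > 0) categorized
                else genome$genes$gene_id
  }
  members <- intersect(unique(gene_list$gene_id), universe)
  assert_that(length(members) > 0, "gene list has no members in the universe")
  hit_ids <- intersect(promoter_hit_genes(annotations), universe)
  enrichment_row(gene_list$name[1], members, hit_ids, universe)
}

#' Compare two gene lists
#'
#' @param list_a,list_b gene-list tibbles or character vectors of gene ids.
#' @return list with sorted character vectors `intersection`, `a_only`,
#'   `b_only`.
#' @export
compare_lists <- function(list_a, list_b) {
  ids <- function(x) if (is.data.frame(x)) unique(x$gene_id) else unique(x)
  a <- ids(list_a); b <- ids(list_b)
  list(intersection = sort(intersect(a, b)),
       a_only = sort(setdiff(a, b)),
       b_only = sort(setdiff(b, a)))
}
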