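# Peak annotation relative to gene structure: coding/non-coding class,
# signed distance to the nearest predicted translation start codon (TSC),
# promoter-window gene hits including divergent gene pairs, and operon-aware
# collapsing of gene lists to promoter regions.

#' Signed distance from a site to a gene's predicted TSC
#'
#' Negative values lie upstream of the start codon in the gene's reading
#' orientation: `d = site - tsc` for forward-strand genes and
#' `d = tsc - site` for reverse-strand genes (upstream of a reverse gene lies
#' genomically rightward).
#'
#' @param coordinate site coordinate(s), bp.
#' @param tsc predicted TSC coordinate(s), bp.
#' @param strand gene strand(s), "+" or "-".
#' @return signed distance(s) in bp.
#' @export
#' @examples
#' signed_distance(950, 1000, "+")   # -50, upstream
#' signed_distance(2050, 2000, "-")  # -50, upstream of a reverse gene
signed_distance <- function(coordinate, tsc, strand) {
  ifelse(strand == "+", coordinate - tsc, tsc - coordinate)
}

# Per-peak nearest-TSC lookup; exact |distance| ties return all tied genes.
nearest_tsc_one <- function(coord, genes, tsc_sorted, ord) {
  i <- findInterval(coord, tsc_sorted)
  d_left <- if (i >= 1) coord - tsc_sorted[i] else Inf
  d_right <- if (i < length(tsc_sorted)) tsc_sorted[i + 1] - coord else Inf
  dmin <- min(d_left, d_right)
  hit_tsc <- c(if (d_left == dmin) coord - dmin,
               if (d_right == dmin) coord + dmin)
  idx <- ord[tsc_sorted %in% hit_tsc]
  tibble(gene_id = genes$gene_id[idx],
         distance = signed_distance(coord, genes$tsc[idx],
                                    genes$strand[idx]),
         strand = genes$strand[idx])
}

#' Gene(s) with the predicted TSC nearest a peak
#'
#' @param coordinate peak coordinate(s).
#' @param genome a `genome_model` with at least one gene.
#' @return list (one element per coordinate) of tibbles with columns gene_id,
#'   distance (signed), strand; more than one row only when two TSCs are
#'   exactly equidistant.
#' @export
nearest_tsc <- function(coordinate, genome) {
  assert_that(nrow(genome$genes) > 0, "genome has no genes")
  ord <- order(genome$genes$tsc)
  tsc_sorted <- genome$genes$tsc[ord]
  lapply(coordinate, nearest_tsc_one, genes = genome$genes,
         tsc_sorted = tsc_sorted, ord = ord)
}

# Vectorised signed distance to the single nearest TSC (ties resolve to the
# leftward candidate); used for histograms over many random sites.
nearest_tsc_distance <- function(coordinate, genome) {
  ord <- order(genome$genes$tsc)
  tscs <- genome$genes$tsc[ord]
  strands <- genome$genes$strand[ord]
  i <- findInterval(coordinate, tscs)
  left <- pmax(i, 1L)
  right <- pmin(i + 1L, length(tscs))
  d_left <- ifelse(i >= 1L, coordinate - tscs[left], Inf)
  d_right <- ifelse(i < length(tscs), tscs[right] - coordinate, Inf)
  use_left <- d_left <= d_right
  idx <- ifelse(use_left, left, right)
  signed_distance(coordinate, tscs[idx], strands[idx])
}

#' Classify sites as coding or non-coding
#'
#' A site is coding iff it falls within any gene's half-open coding span
#' `[coding_start, coding_end)`; overlapping genes make a position coding if
#' any span covers it.
#'
#' @param coordinate site coordinate(s).
#' @param genome a `genome_model`.
#' @return character vector, "coding" or "noncoding".
#' @export
classify_region <- function(coordinate, genome) {
  sites <- IRanges::IRanges(start = coordinate + 1, width = 1)
  hits <- IRanges::countOverlaps(sites, coding_iranges(genome))
  ifelse(hits > 0, "coding", "noncoding")
}

#' Promoter-window gene hits for peaks
#'
#' All genes whose signed TSC distance to a peak lies inside the promoter
#' window (both ends inclusive). A peak is flagged divergent when its hits
#' include an opposite-strand pair whose TSCs flank the peak (two genes
#' transcribed away from each other sharing the intergenic region).
#'
#' @param coordinate peak coordinate(s).
#' @param genome a `genome_model`.
#' @param window length-2 signed window, default `c(-400, 100)`.
#' @return tibble with one row per (peak, gene) hit: peak_index, coordinate,
#'   gene_id, distance, strand, tsc.
#' @export
promoter_hits <- function(coordinate, genome, window = c(-400, 100)) {
  g <- genome$genes
  lo <- window[1]; hi <- window[2]
  win_start <- ifelse(g$strand == "+", g$tsc + lo, g$tsc - hi)
  win_end <- ifelse(g$strand == "+", g$tsc + hi, g$tsc - lo)
  wins <- IRanges::IRanges(start = win_start + 1, end = win_end + 1)
  sites <- IRanges::IRanges(start = coordinate + 1, width = 1)
  ov <- IRanges::findOverlaps(sites, wins)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  tibble(peak_index = qi,
         coordinate = coordinate[qi],
         gene_id = g$gene_id[si],
         distance = signed_distance(coordinate[qi], g$tsc[si],
                                    g$strand[si]),
         strand = g$strand[si],
         tsc = g$tsc[si])
}

divergent_flag <- function(hits_one) {
  if (nrow(hits_one) < 2) return(FALSE)
  any(hits_one$strand == "-" & hits_one$tsc <= hits_one$coordinate) &&
    any(hits_one$strand == "+" & hits_one$tsc >= hits_one$coordinate)
}

#' Collapse a gene list to operon promoter regions
#'
#' Drops list members that sit downstream of the first gene of their operon
#' (operon_position > 1); genes without operon information are retained.
#'
#' @param gene_list tibble with columns name, gene_id (see [gene_list()]).
#' @param operon_map tibble with columns gene_id, operon_id, operon_position
#'   (may be empty or `NULL`).
#' @param genome optional `genome_model`; list members unknown to the genome
#'   are skipped with a warning.
#' @return the collapsed gene-list tibble.
#' @export
collapse_to_promoter_regions <- function(gene_list, operon_map = NULL,
                                         genome = NULL) {
  out <- gene_list
  if (!is.null(genome)) {
    unknown <- setdiff(out$gene_id, genome$genes$gene_id)
    if (length(unknown) > 0) {
      warn(sprintf("%d unknown gene ids skipped", length(unknown)))
      out <- filter(out, !.data$gene_id %in% unknown)
    }
  }
  if (is.null(operon_map) || nrow(operon_map) == 0) return(out)
  internal <- operon_map$gene_id[!is.na(operon_map$operon_position) &
                                   operon_map$operon_position > 1]
  filter(out, !.data$gene_id %in% internal)
}

#' Annotate merged peaks against a genome
#'
#' One annotation per merged peak: region class, nearest-TSC gene(s) with the
#' signed distance, promoter-window hits and the divergent-gene flag.
#'
#' @param merged_peaks tibble from [filter_concordant()] (any tibble with a
#'   `coordinate` column works; `overall_rank` is carried through or assigned
#'   by row).
#' @param genome a `genome_model`.
#' @param config an [analysis_config()]; supplies the promoter window.
#' @return tibble with one row per peak and columns overall_rank, coordinate,
#'   any replicate columns present, region_class, nearest (list of tibbles),
#'   nearest_gene_id, nearest_gene_distance, promoter_hits (list of tibbles),
#'   n_promoter_hits, divergent. The promoter window used is stored in the
#'   `promoter_window` attribute.
#' @export
annotate_all <- function(merged_peaks, genome, config = analysis_config()) {
  assert_that(nrow(merged_peaks) > 0, "no peaks to annotate")
  assert_that(all(merged_peaks$coordinate >= 0 &
                    merged_peaks$coordinate < genome$length),
              "peak coordinate outside the genome")
  out <- as_tibble(merged_peaks)
  if (!"overall_rank" %in% names(out)) out$overall_rank <- seq_len(nrow(out))
  out$region_class <- classify_region(out$coordinate, genome)
  out$nearest <- nearest_tsc(out$coordinate, genome)
  out$nearest_gene_id <- vapply(out$nearest, function(x) x$gene_id[1], "")
  out$nearest_gene_distance <-
    vapply(out$nearest, function(x) x$distance[1], numeric(1))
  hits <- promoter_hits(out$coordinate, genome, config$promoter_window)
  split_hits <- split(hits, factor(hits$peak_index,
                                   levels = seq_len(nrow(out))))
  out$promoter_hits <- lapply(split_hits, function(h) {
    select(h, "gene_id", "distance", "strand", "tsc")
  })
  out$n_promoter_hits <- vapply(out$promoter_hits, nrow, integer(1))
  out$divergent <- vapply(seq_len(nrow(out)), function(i) {
    h <- split_hits[[i]]
    divergent_flag(h)
  }, logical(1))
  attr(out, "promoter_window") <- config$promoter_window
  out
}

#' Summarise a peak annotation table
#'
#' @param annotations tibble from [annotate_all()].
#' @return one-row tibble: peak count, coding/non-coding counts, promoter
#'   sites (peaks with >= 1 promoter hit), divergent sites, and the number of
#'   distinct promoter-hit genes.
#' @export
annotation_summary <- function(annotations) {
  hit_genes <- unique(unlist(lapply(annotations$promoter_hits,
                                    function(h) h$gene_id)))
  tibble(
    n_peaks = nrow(annotations),
    n_coding = sum(annotations$region_class == "coding"),
    n_noncoding = sum(annotations$region_class == "noncoding"),
    n_promoter_sites = sum(annotations$n_promoter_hits > 0),
    n_divergent = sum(annotations$divergent),
    n_promoter_genes = length(hit_genes)
  )
}
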