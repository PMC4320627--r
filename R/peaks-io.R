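# Per-replicate peak tables: ingestion, ranking, and the merged-peak table
# writer. A peak is the single coordinate of its enrichment maximum.

#' Build a per-replicate peak table
#'
#' Peaks are sorted by coordinate; `rank_in_replicate` is assigned by
#' descending enrichment with ties broken toward the lower coordinate.
#'
#' @param coordinate bp positions of peak maxima (0-based).
#' @param enrichment nonnegative enrichment scores.
#' @param replicate_id replicate label.
#' @param genome optional `genome_model`; coordinates are validated against
#'   its length.
#' @return tibble with columns replicate_id, coordinate, enrichment,
#'   rank_in_replicate.
#' @export
peak_table <- function(coordinate, enrichment, replicate_id = "rep",
                       genome = NULL) {
  assert_that(length(coordinate) == length(enrichment),
              "coordinate and enrichment lengths differ")
  assert_that(all(is.finite(coordinate)) && all(coordinate >= 0),
              "peak coordinates must be nonnegative")
  assert_that(all(is.finite(enrichment)) && all(enrichment >= 0),
              "enrichment scores must be nonnegative")
  if (!is.null(genome)) {
    assert_that(all(coordinate < genome$length),
                "peak coordinate beyond genome length")
  }
  out <- tibble(replicate_id = replicate_id,
                coordinate = as.numeric(coordinate),
                enrichment = as.numeric(enrichment))
  ord <- order(-out$enrichment, out$coordinate)
  out$rank_in_replicate <- integer(nrow(out))
  out$rank_in_replicate[ord] <- seq_len(nrow(out))
  arrange(out, .data$coordinate)
}

#' Read a peak list from TSV or BED
#'
#' Accepts either a 2+-column TSV (`coordinate`, `enrichment`, header
#' optional) or a BED-like file (`chrom`, `start`, `end`, `score`), in which
#' case the peak coordinate is the interval midpoint. Ranks are assigned as in
#' [peak_table()].
#'
#' @param path input file; `.bed` extension selects BED parsing, otherwise a
#'   file whose first line has >= 4 columns with a non-numeric first field is
#'   treated as BED.
#' @param replicate_id label for this replicate.
#' @param genome optional `genome_model` for coordinate validation.
#' @return tibble as from [peak_table()].
#' @export
read_peaks <- function(path, replicate_id = basename(path), genome = NULL) {
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1]]
  looks_bed <- grepl("\\.bed$", path, ignore.case = TRUE) ||
    (length(first) >= 4 && is.na(suppressWarnings(as.numeric(first[1]))) &&
       !identical(tolower(first[1]), "coordinate"))
  if (looks_bed) {
    df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
    assert_that(ncol(df) >= 4, "BED peak file needs chrom/start/end/score")
    start <- suppressWarnings(as.numeric(df[[2]]))
    end <- suppressWarnings(as.numeric(df[[3]]))
    score <- suppressWarnings(as.numeric(df[[ncol(df)]]))
    if (anyNA(start) || anyNA(end)) abort("non-numeric BED interval bounds")
    if (anyNA(score)) abort("non-numeric peak score")
    coord <- floor((start + end) / 2)
  } else {
    df <- readr::read_tsv(path, progress = FALSE, comment = "#",
                          col_types = readr::cols(.default = "c"))
    if (!all(c("coordinate", "enrichment") %in% names(df))) {
      df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                            comment = "#",
                            col_types = readr::cols(.default = "c"))
      names(df)[1:2] <- c("coordinate", "enrichment")
    }
    coord <- suppressWarnings(as.numeric(df$coordinate))
    score <- suppressWarnings(as.numeric(df$enrichment))
    if (anyNA(coord)) abort("non-numeric peak coordinate")
    if (anyNA(score)) abort("non-numeric enrichment score")
  }
  if (any(coord < 0)) abort("negative peak coordinate")
  peak_table(coord, score, replicate_id = replicate_id, genome = genome)
}

#' Write a per-replicate peak table as TSV
#'
#' @param peaks tibble from [peak_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(select(peaks, "coordinate", "enrichment"), path,
                   progress = FALSE)
  invisible(path)
}

# Canonical column set of the merged, annotated peak table.
peak_table_columns <- c(
  "overall_rank", "coordinate", "rank_rep1", "rank_rep2",
  "coordinate_rep1", "coordinate_rep2", "nearest_gene_id",
  "nearest_gene_distance", "region_class", "promoter_hits", "divergent"
)

#' Write the merged, annotated peak table
#'
#' One row per merged peak, sorted by overall rank, with the averaged
#' coordinate, per-replicate ranks and maxima, the gene whose predicted TSC is
#' nearest, the signed peak-to-TSC distance, the coding/non-coding class, the
#' promoter-window gene hits (comma-separated `gene_id:distance`), and the
#' divergent-gene flag.
#'
#' @param annotations tibble from [annotate_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(annotations, path) {
  missing_cols <- setdiff(peak_table_columns, names(annotations))
  assert_that(length(missing_cols) == 0,
              paste("peaks are not annotated; missing:",
                    paste(missing_cols, collapse = ", ")))
  out <- annotations %>%
    mutate(promoter_hits = vapply(.data$promoter_hits, function(h) {
      if (is.null(h) || nrow(h) == 0) return("")
      paste(sprintf("%s:%d", h$gene_id, as.integer(h$distance)),
            collapse = ",")
    }, character(1))) %>%
    select(dplyr::all_of(peak_table_columns)) %>%
    arrange(.data$overall_rank)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a merged peak table written by [write_peak_table()]
#'
#' @param path TSV path.
#' @return tibble with the canonical columns; `promoter_hits` is re-expanded
#'   into a list-column.
#' @export
read_peak_table <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, col_types = readr::cols(
    promoter_hits = "c", region_class = "c", nearest_gene_id = "c",
    divergent = "l", .default = "d"))
  df$promoter_hits <- lapply(df$promoter_hits, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble(gene_id = character(), distance = numeric()))
    }
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble(gene_id = vapply(parts, `[`, "", 1),
           distance = as.numeric(vapply(parts, `[`, "", 2)))
  })
  df
}
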