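# Genome model: one chromosome, an ordered gene table, optional sequence.
# Internal coordinates are 0-based half-open; GFF3 I/O converts at the
# boundary. A site s is inside gene g iff coding_start <= s < coding_end.

#' Construct a genome model
#'
#' @param chromosome_id chromosome name.
#' @param length chromosome length in bp (> 0).
#' @param genes tibble with columns `gene_id`, `strand` ("+"/"-"),
#'   `coding_start`, `coding_end` (0-based half-open); optional `category`,
#'   `operon_id`, `operon_position`. The derived `tsc` column (predicted
#'   translation start codon: `coding_start` on "+", `coding_end - 1` on "-")
#'   is added if absent.
#' @param sequence optional [Biostrings::DNAStringSet] of length 1 (or a
#'   single character string) holding the chromosome sequence.
#' @param circular logical flag, metadata only: distance computations stay
#'   linear.
#' @return object of class `genome_model`.
#' @export
genome_model <- function(chromosome_id, length, genes,
                         sequence = NULL, circular = TRUE) {
  assert_that(is.numeric(length) && length > 0, "genome length must be > 0")
  genes <- as_tibble(genes)
  needed <- c("gene_id", "strand", "coding_start", "coding_end")
  missing_cols <- setdiff(needed, names(genes))
  assert_that(length(missing_cols) == 0,
              paste("genes table missing columns:",
                    paste(missing_cols, collapse = ", ")))
  assert_that(all(genes$strand %in% c("+", "-")),
              "gene strand must be '+' or '-'")
  assert_that(all(genes$coding_start < genes$coding_end),
              "every gene needs coding_start < coding_end")
  assert_that(all(genes$coding_start >= 0 & genes$coding_end <= length),
              "gene coding span outside [0, genome length)")
  if (!"tsc" %in% names(genes)) {
    genes$tsc <- ifelse(genes$strand == "+",
                        genes$coding_start, genes$coding_end - 1)
  }
  for (opt in c("category", "operon_id")) {
    if (!opt %in% names(genes)) genes[[opt]] <- NA_character_
  }
  if (!"operon_position" %in% names(genes)) {
    genes$operon_position <- NA_integer_
  }
  genes <- arrange(genes, .data$coding_start)
  if (!is.null(sequence)) {
    if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
    assert_that(length(sequence) == 1L,
                "single-chromosome model: sequence must have one entry")
    assert_that(Biostrings::width(sequence)[1] == length,
                "sequence length does not match declared genome length")
    names(sequence) <- chromosome_id
  }
  structure(list(chromosome_id = chromosome_id,
                 length = as.numeric(length),
                 circular = isTRUE(circular),
                 genes = genes,
                 sequence = sequence),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %s: %s bp, %d genes, coding fraction %.3f%s\n",
              x$chromosome_id, format(x$length, big.mark = ","),
              nrow(x$genes), coding_fraction(x),
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

#' @rdname genome_model
#' @param x a `genome_model`.
#' @param ... unused.
#' @method tidy genome_model
#' @export
tidy.genome_model <- function(x, ...) x$genes

#' @rdname genome_model
#' @method glance genome_model
#' @export
glance.genome_model <- function(x, ...) {
  tibble(chromosome_id = x$chromosome_id,
         length = x$length,
         n_genes = nrow(x$genes),
         coding_fraction = coding_fraction(x),
         has_sequence = !is.null(x$sequence))
}

#' Fraction of the genome covered by annotated coding spans
#'
#' Overlapping genes are counted once (union of coding intervals).
#'
#' @param genome a `genome_model`.
#' @return scalar in (0, 1].
#' @export
coding_fraction <- function(genome) {
  ir <- IRanges::reduce(coding_iranges(genome))
  sum(IRanges::width(ir)) / genome$length
}

# Coding spans as IRanges in 1-based closed coordinates for IRanges math.
coding_iranges <- function(genome) {
  IRanges::IRanges(start = genome$genes$coding_start + 1,
                   end = genome$genes$coding_end)
}

#' Read a genome model from GFF3
#'
#' Reads `gene` (or `CDS` when no gene features are present) records from a
#' single-chromosome GFF3 file and converts 1-based inclusive coordinates to
#' the package's 0-based half-open convention. Functional categories, which
#' GFF3 rarely carries, come from a separate two-column TSV
#' (`gene_id`, `category`); an operon map TSV (`gene_id`, `operon_id`,
#' `operon_position`) can be joined the same way.
#'
#' @param path GFF3 file.
#' @param category_table optional path to a gene_id/category TSV.
#' @param operon_table optional path to a gene_id/operon_id/operon_position
#'   TSV.
#' @param sequence optional FASTA path or `DNAStringSet` with the chromosome
#'   sequence.
#' @return a [genome_model()].
#' @export
read_gff3 <- function(path, category_table = NULL, operon_table = NULL,
                      sequence = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  chroms <- GenomicRanges::seqnames(gr)
  chrom_ids <- unique(as.character(chroms))
  assert_that(length(chrom_ids) == 1L,
              "single-chromosome model: multi-chromosome GFF3 not supported")
  keep <- gr$type %in% "gene"
  if (!any(keep)) keep <- gr$type %in% "CDS"
  assert_that(any(keep), "GFF3 contains no gene or CDS features")
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    lt <- gr$locus_tag
    if (!is.null(lt)) ids <- ifelse(is.na(ids) | is.null(ids), lt, ids)
  }
  assert_that(!is.null(ids) && !anyNA(ids),
              "every gene feature needs an ID or locus_tag attribute")
  declared <- GenomeInfoDb::seqlengths(gr)[chrom_ids]
  if (is.na(declared)) {
    # rtracklayer drops the sequence-region pragma; recover it ourselves.
    hdr <- grep("^##sequence-region", readLines(path, n = 50L, warn = FALSE),
                value = TRUE)
    if (length(hdr) > 0) {
      fields <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
      if (length(fields) >= 4 && fields[2] == chrom_ids) {
        declared <- as.numeric(fields[4])
      }
    }
  }
  glen <- if (!is.na(declared)) as.numeric(declared) else
    max(GenomicRanges::end(gr))
  if (!is.na(declared)) {
    bad <- GenomicRanges::end(gr) > glen | GenomicRanges::start(gr) < 1
    if (any(bad)) {
      abort(sprintf("gene %s lies outside the declared sequence region",
                    ids[which(bad)[1]]))
    }
  }
  genes <- tibble(
    gene_id = as.character(ids),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    coding_start = GenomicRanges::start(gr) - 1,
    coding_end = as.numeric(GenomicRanges::end(gr))
  )
  if (!is.null(category_table)) {
    cats <- read_categories(category_table)
    genes <- left_join(genes, cats, by = "gene_id")
  }
  if (!is.null(operon_table)) {
    ops <- read_operons(operon_table)
    genes <- left_join(genes, ops, by = "gene_id")
  }
  if (is.character(sequence)) {
    sequence <- Biostrings::readDNAStringSet(sequence)
  }
  genome_model(chromosome_id = chrom_ids, length = glen, genes = genes,
               sequence = sequence)
}

#' Write a genome model to GFF3
#'
#' Converts back to 1-based inclusive coordinates and declares the sequence
#' region so that `read_gff3(write_gff3(x))` round-trips spans and strands.
#'
#' @param genome a `genome_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genome$chromosome_id,
    ranges = IRanges::IRanges(start = g$coding_start + 1, end = g$coding_end),
    strand = g$strand
  )
  gr$type <- "gene"
  gr$source <- "chipregulon"
  gr$ID <- g$gene_id
  gr$Name <- g$gene_id
  GenomeInfoDb::seqlengths(gr) <- setNames(genome$length,
                                           genome$chromosome_id)
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer does not emit the sequence-region pragma; declare it so the
  # chromosome length survives a round trip.
  lines <- readLines(path, warn = FALSE)
  pragma <- sprintf("##sequence-region %s 1 %d", genome$chromosome_id,
                    as.integer(genome$length))
  writeLines(append(lines, pragma, after = 1L), path)
  invisible(path)
}

#' Write the genome sequence as FASTA
#'
#' @param genome a `genome_model` carrying a sequence.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  assert_that(!is.null(genome$sequence), "genome model has no sequence")
  Biostrings::writeXStringSet(genome$sequence, path)
  invisible(path)
}

#' Read a gene_id/category table
#'
#' @param path two-column TSV (`gene_id`, `category`), with or without a
#'   header line.
#' @return tibble with columns gene_id, category.
#' @export
read_categories <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("gene_id", "category") %in% names(df))) {
    df <- readr::read_tsv(path, col_names = c("gene_id", "category"),
                          col_types = "cc", progress = FALSE)
  }
  select(df, "gene_id", "category")
}

#' Read an operon membership table
#'
#' @param path TSV with columns `gene_id`, `operon_id`, `operon_position`
#'   (position 1 = first gene of the operon).
#' @return tibble.
#' @export
read_operons <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("gene_id", "operon_id", "operon_position") %in% names(df))) {
    df <- readr::read_tsv(
      path, col_names = c("gene_id", "operon_id", "operon_position"),
      col_types = "ccc", progress = FALSE)
  }
  mutate(select(df, "gene_id", "operon_id", "operon_position"),
         operon_position = as.integer(.data$operon_position))
}

#' Read a plain-text gene list
#'
#' One gene id per line (a single-column file); lines starting with `#` are
#' ignored. When `genome` is given, unknown ids are dropped with a warning.
#'
#' @param path file path.
#' @param name list name; defaults to the file name without extension.
#' @param genome optional `genome_model` used to validate membership.
#' @return a tibble with columns `name`, `gene_id`.
#' @export
read_gene_list <- function(path, name = NULL, genome = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  gene_list(ids, name = name, genome = genome)
}

#' Build a validated gene list
#'
#' @param gene_ids character vector of member gene ids (duplicates dropped).
#' @inheritParams read_gene_list
#' @return a tibble with columns `name`, `gene_id`.
#' @export
gene_list <- function(gene_ids, name = "list", genome = NULL) {
  ids <- unique(as.character(gene_ids))
  if (!is.null(genome)) {
    unknown <- setdiff(ids, genome$genes$gene_id)
    if (length(unknown) > 0) {
      warn(sprintf("%d gene ids not in the genome were dropped from '%s'",
                   length(unknown), name))
      ids <- setdiff(ids, unknown)
    }
  }
  tibble(name = name, gene_id = ids)
}
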