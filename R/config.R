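#' Analysis configuration
#'
#' Bundles the tunable constants used across the pipeline. Defaults are the
#' study conditions for a gene-dense bacterial genome: replicate peaks within
#' 65 bp are treated as concordant, a promoter window from 400 bp upstream to
#' 100 bp downstream of a predicted translation start codon (TSC) links a peak
#' to a gene, motif discovery uses the top 500 peaks with 50 bp of flanking
#' sequence on each side, partitioned into sets of 50.
#'
#' @param concordance_cutoff bp; maximum replicate-maxima distance for a
#'   concordant pair.
#' @param promoter_window length-2 numeric, signed bp relative to the TSC,
#'   both ends inclusive (negative = upstream).
#' @param flank bp of flanking sequence extracted on each side of a peak
#'   maximum.
#' @param motif_width motif width in positions.
#' @param top_n_for_motif number of top-ranked peaks used for discovery.
#' @param partition_size ranked sequences per partition.
#' @param mc_replicates Monte Carlo replicates for the placement null.
#' @param rng_seed integer seed driving all randomness.
#' @return a list of class `analysis_config`.
#' @export
#' @examples
#' analysis_config(rng_seed = 1)
analysis_config <- function(concordance_cutoff = 65,
                            promoter_window = c(-400, 100),
                            flank = 50,
                            motif_width = 15,
                            top_n_for_motif = 500,
                            partition_size = 50,
                            mc_replicates = 1,
                            rng_seed = 1L) {
  assert_that(length(promoter_window) == 2 &&
                promoter_window[1] < promoter_window[2],
              "promoter_window must be c(lower, upper) with lower < upper")
  for (nm in c("concordance_cutoff", "flank", "motif_width",
               "top_n_for_motif", "partition_size", "mc_replicates")) {
    v <- get(nm)
    assert_that(is.numeric(v) && length(v) == 1 && v >= 0,
                paste0(nm, " must be a nonnegative scalar"))
  }
  structure(list(
    concordance_cutoff = concordance_cutoff,
    promoter_window = as.numeric(promoter_window),
    flank = flank,
    motif_width = motif_width,
    top_n_for_motif = top_n_for_motif,
    partition_size = partition_size,
    mc_replicates = mc_replicates,
    rng_seed = as.integer(rng_seed)
  ), class = "analysis_config")
}

#' Read a key=value configuration file
#'
#' Plain-text `key = value` lines mapping 1:1 onto [analysis_config()]
#' arguments. `promoter_window` is written as `lower:upper`.
#'
#' @param path file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    v <- if (keys[i] == "promoter_window") {
      as.numeric(strsplit(vals[i], ":", fixed = TRUE)[[1]])
    } else {
      as.numeric(vals[i])
    }
    args[[keys[i]]] <- v
  }
  do.call(analysis_config, args)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ":")))
  }
  invisible(x)
}
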