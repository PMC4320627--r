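# Simplified kernel-density peak detection: Gaussian KDE of strand-shifted
# read starts, enrichment over a depth-scaled control, and the
# control-partition false-positive-rate procedure. This deliberately captures
# only the spirit of KDE-based callers (density + control comparison); no
# per-peak q-values or broad-peak handling.

#' Build a read-start set
#'
#' @param position read 5' start positions (bp, 0-based).
#' @param strand "+" or "-" per read.
#' @param label "chip" or "control".
#' @return tibble with columns position, strand and a `label` attribute.
#' @export
read_set <- function(position, strand, label = "chip") {
  assert_that(length(position) == length(strand),
              "position and strand lengths differ")
  assert_that(all(strand %in% c("+", "-")), "read strand must be '+' or '-'")
  assert_that(all(position >= 0), "read positions must be nonnegative")
  out <- tibble(position = as.numeric(position),
                strand = as.character(strand))
  attr(out, "label") <- label
  out
}

#' Read a read-start table from TSV
#'
#' Two columns: position, strand.
#'
#' @param path TSV path (header optional).
#' @param label set label.
#' @return tibble as from [read_set()].
#' @export
read_reads <- function(path, label = "chip") {
  df <- readr::read_tsv(path, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("position", "strand") %in% names(df))) {
    df <- readr::read_tsv(path, col_names = c("position", "strand"),
                          col_types = "cc", progress = FALSE)
  }
  read_set(as.numeric(df$position), df$strand, label = label)
}

#' Peak-calling parameters
#'
#' @param bandwidth Gaussian kernel standard deviation in bp.
#' @param shift bp by which forward reads are shifted right and reverse reads
#'   left before density estimation (half the expected fragment size).
#' @param enrichment_threshold minimum chip/control density fold at a peak.
#' @param min_chip_density minimum chip density at a peak (reads/bp);
#'   `NULL` means 5 x the genome-wide mean chip density.
#' @param pseudocount density floor added to the scaled control; `NULL` means
#'   0.25 x the genome-wide mean chip density.
#' @param grid_step density evaluation grid step in bp.
#' @return list of class `peak_call_params`.
#' @export
peak_call_params <- function(bandwidth = 30, shift = 50,
                             enrichment_threshold = 10,
                             min_chip_density = NULL, pseudocount = NULL,
                             grid_step = 10) {
  assert_that(bandwidth > 0 && shift > 0 && enrichment_threshold > 0 &&
                grid_step > 0, "peak-calling parameters must be positive")
  structure(list(bandwidth = bandwidth, shift = shift,
                 enrichment_threshold = enrichment_threshold,
                 min_chip_density = min_chip_density,
                 pseudocount = pseudocount, grid_step = grid_step),
            class = "peak_call_params")
}

shifted_positions <- function(reads, shift) {
  reads$position + ifelse(reads$strand == "+", shift, -shift)
}

#' Kernel density profile of strand-shifted read starts
#'
#' Forward reads are shifted `+shift`, reverse reads `-shift`, then a Gaussian
#' kernel density (sd = bandwidth) is evaluated on a regular grid over
#' `[0, genome_length]`. The profile is scaled to reads/bp, so
#' `sum(density) * grid_step` approximates the read count.
#'
#' @param reads tibble from [read_set()].
#' @param params [peak_call_params()].
#' @param genome_length chromosome length in bp.
#' @return tibble with columns position, density.
#' @export
density_profile <- function(reads, params = peak_call_params(),
                            genome_length) {
  assert_that(nrow(reads) > 0, "empty read set")
  x <- shifted_positions(reads, params$shift)
  n_grid <- floor(genome_length / params$grid_step) + 1
  d <- density(x, bw = params$bandwidth, kernel = "gaussian",
               from = 0, to = genome_length, n = n_grid)
  tibble(position = d$x, density = d$y * length(x))
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Parabolic refinement of a grid maximum to ~1 bp.
refine_maximum <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  x[i] + delta * (x[2] - x[1])
}

#' Call enrichment peaks from chip and control read sets
#'
#' Peaks sit at local maxima of the chip density where the fold ratio over the
#' depth-scaled control (plus a pseudocount floor) reaches
#' `enrichment_threshold` and the chip density reaches `min_chip_density`.
#' The control is scaled by (chip reads)/(control reads). Maxima closer than
#' `2 * bandwidth` are merged keeping the higher one, and each surviving
#' maximum is refined to ~1 bp by parabolic interpolation. The enrichment
#' score is the fold ratio at the maximum.
#'
#' A control with fewer than 10 reads triggers a warning and a
#' pseudocount-only background instead of an error, so toy examples stay
#' runnable.
#'
#' @inheritParams density_profile
#' @param chip chip read set.
#' @param control control (mock IP) read set.
#' @return peak tibble as from [peak_table()].
#' @export
call_peaks <- function(chip, control, params = peak_call_params(),
                       genome_length) {
  assert_that(nrow(chip) > 0, "empty chip read set")
  assert_that(max(chip$position) < genome_length &&
                (nrow(control) == 0 || max(control$position) < genome_length),
              "read positions beyond genome length")
  chip_prof <- density_profile(chip, params, genome_length)
  mean_chip <- nrow(chip) / genome_length
  min_dens <- params$min_chip_density %||% (5 * mean_chip)
  pseudo <- params$pseudocount %||% (0.25 * mean_chip)
  if (nrow(control) < 10) {
    warn("control has < 10 reads; using pseudocount-only background")
    ctrl_scaled <- rep(0, nrow(chip_prof))
  } else {
    ctrl_prof <- density_profile(control, params, genome_length)
    ctrl_scaled <- ctrl_prof$density * (nrow(chip) / nrow(control))
  }
  ratio <- chip_prof$density / (ctrl_scaled + pseudo)
  idx <- local_maxima(chip_prof$density)
  idx <- idx[ratio[idx] >= params$enrichment_threshold &
               chip_prof$density[idx] >= min_dens]
  if (length(idx) == 0) {
    return(peak_table(numeric(0), numeric(0), replicate_id = "called"))
  }
  # Merge maxima closer than 2*bandwidth, keeping the higher chip density.
  idx <- idx[order(-chip_prof$density[idx])]
  kept <- integer(0)
  for (i in idx) {
    if (all(abs(chip_prof$position[i] - chip_prof$position[kept]) >=
              2 * params$bandwidth)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  coord <- vapply(kept, function(i) {
    refine_maximum(chip_prof$position, chip_prof$density, i)
  }, numeric(1))
  coord <- pmin(pmax(round(coord), 0), genome_length - 1)
  peak_table(coord, ratio[kept], replicate_id = "called")
}

#' Estimate the false-positive rate by control partitioning
#'
#' The control reads are split randomly in half; one half is treated as if it
#' were a ChIP-enriched sample and called against the other half as
#' background. The number of pseudo-peaks detected, relative to the real chip
#' peak count, estimates the false-positive rate of the detection procedure.
#'
#' @param control control read set (>= 2 reads).
#' @param chip_peak_count number of peaks called in the real chip sample
#'   (> 0).
#' @param params [peak_call_params()].
#' @param genome_length chromosome length in bp.
#' @param seed integer seed for the random split.
#' @return false-positive rate as a percentage.
#' @export
estimate_fpr <- function(control, chip_peak_count,
                         params = peak_call_params(), genome_length,
                         seed = 1L) {
  assert_that(nrow(control) >= 2, "control needs at least 2 reads")
  assert_that(is_count(chip_peak_count), "chip_peak_count must be > 0")
  n <- nrow(control)
  if (floor(n / 2) < 10) {
    warn("control too small to partition; pseudocount-only estimate is 0")
    return(0)
  }
  set.seed(seed)
  half <- sample.int(n, floor(n / 2))
  pseudo_chip <- control[half, , drop = FALSE]
  background <- control[-half, , drop = FALSE]
  pseudo <- call_peaks(pseudo_chip, background, params, genome_length)
  100 * nrow(pseudo) / chip_peak_count
}

`%||%` <- function(a, b) if (is.null(a)) b else a
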