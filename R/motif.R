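# Motif discovery and scanning. Discovery is an expectation-maximization
# under the OOPS model (one occurrence per sequence, either strand) with a
# 0-order background estimated from the input; scanning matches a degenerate
# IUPAC consensus on both strands via Biostrings.

DNA_BASES <- c("A", "C", "G", "T")

# Enumeration order doubles as the consensus tie-break order within a
# degeneracy-class size.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

#' Extract fixed-width sequences around peak maxima
#'
#' One sequence of length `2 * flank + 1` per peak, centered on the merged
#' coordinate. Peaks too close to a chromosome end are clamped to the sequence
#' boundary and flagged.
#'
#' @param merged_peaks tibble with `coordinate` (and optionally
#'   `overall_rank`) columns.
#' @param genome a `genome_model` carrying a sequence.
#' @param flank bp of flanking sequence on each side of the maximum.
#' @return tibble with columns sequence_id, overall_rank, coordinate, start,
#'   end (0-based half-open), clamped, sequence.
#' @export
extract_flanks <- function(merged_peaks, genome, flank = 50) {
  assert_that(!is.null(genome$sequence), "genome model has no sequence")
  assert_that(flank > 0, "flank must be positive")
  coord <- merged_peaks$coordinate
  assert_that(all(coord >= 0 & coord < genome$length),
              "peak coordinate outside the sequence")
  width <- 2 * flank + 1
  start <- pmax(coord - flank, 0)
  start <- pmin(start, genome$length - width)
  clamped <- start != coord - flank
  seqs <- Biostrings::extractAt(
    genome$sequence[[1]],
    IRanges::IRanges(start = start + 1, width = width))
  rank <- if ("overall_rank" %in% names(merged_peaks)) {
    merged_peaks$overall_rank
  } else {
    seq_along(coord)
  }
  tibble(sequence_id = sprintf("peak_%04d", rank),
         overall_rank = rank,
         coordinate = coord,
         start = start,
         end = start + width,
         clamped = clamped,
         sequence = as.character(seqs))
}

#' Partition ranked sequences into ordered sets
#'
#' Takes the `top_n` sequences in rank order and chunks them into groups of
#' `partition_size`, preserving order (the last group may be smaller).
#'
#' @param sequences tibble with an `overall_rank` column (e.g. from
#'   [extract_flanks()]).
#' @param top_n number of top-ranked sequences to keep; capped at the number
#'   available.
#' @param partition_size sequences per partition.
#' @return list of tibbles.
#' @export
partition_ranked <- function(sequences, top_n = 500, partition_size = 50) {
  ranked <- arrange(sequences, .data$overall_rank)
  top_n <- min(top_n, nrow(ranked))
  ranked <- ranked[seq_len(top_n), , drop = FALSE]
  grp <- ceiling(seq_len(top_n) / partition_size)
  lapply(split(seq_len(top_n), grp), function(i) ranked[i, , drop = FALSE])
}

# Integer-code a sequence (A=1 C=2 G=3 T=4, anything else NA).
encode_seq <- function(s) {
  m <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
  m
}

revcomp_code <- function(code) rev(5L - code)

# Window index matrix: w x npos, column j holds codes of the window at j.
window_matrix <- function(code, w) {
  npos <- length(code) - w + 1L
  idx <- outer(seq_len(w) - 1L, seq_len(npos), `+`)
  matrix(code[idx], nrow = w)
}

#' Per-column information content of a motif
#'
#' `ic[j] = sum_b p[j][b] * log2(p[j][b] / q[b])` with `0 * log 0 = 0`; for a
#' uniform background this is `2 + sum_b p log2 p`, between 0 and 2 bits.
#'
#' @param pwm 4 x width probability matrix (rows A, C, G, T) or a `motif`
#'   object.
#' @param background length-4 base distribution, default uniform.
#' @return numeric vector of per-column bits.
#' @export
information_content <- function(pwm, background = rep(0.25, 4)) {
  if (inherits(pwm, "motif")) pwm <- pwm$pwm
  apply(pwm, 2, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[nz]))
  })
}

#' Degenerate IUPAC consensus from a PWM
#'
#' Per column, the smallest IUPAC degeneracy class whose summed frequency
#' reaches `threshold` (ties between classes of the same size resolve to the
#' higher summed frequency, then to a fixed enumeration of the codes); if no
#' 1-3 base class reaches it, the column is N.
#'
#' @param pwm 4 x width probability matrix (rows A, C, G, T) or a `motif`.
#' @param threshold summed-frequency threshold in `[0.5, 1)`.
#' @return IUPAC consensus string.
#' @export
consensus_from_pwm <- function(pwm, threshold = 0.85) {
  if (inherits(pwm, "motif")) pwm <- pwm$pwm
  assert_that(threshold >= 0.5 && threshold < 1,
              "threshold must be in [0.5, 1)")
  codes <- names(IUPAC_SETS)
  sizes <- lengths(IUPAC_SETS)
  paste(apply(pwm, 2, function(p) {
    names(p) <- DNA_BASES
    sums <- vapply(IUPAC_SETS, function(b) sum(p[b]), numeric(1))
    for (k in 1:4) {
      cand <- codes[sizes == k & sums >= threshold]
      if (length(cand) > 0) {
        return(cand[order(-sums[cand], match(cand, codes))][1])
      }
    }
    "N"
  }), collapse = "")
}

# Build a PWM (and counts) from aligned site strings.
pwm_from_sites <- function(sites, pseudocount = 0) {
  mat <- do.call(rbind, lapply(sites, encode_seq))
  counts <- vapply(seq_len(ncol(mat)), function(j) {
    tabulate(mat[, j], nbins = 4)
  }, numeric(4))
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  rownames(counts) <- rownames(probs) <- DNA_BASES
  list(counts = counts, pwm = probs)
}

new_motif <- function(pwm, counts, n_sites, log_likelihood = NA_real_,
                      background = rep(0.25, 4),
                      consensus_threshold = 0.85) {
  structure(list(
    width = ncol(pwm),
    pwm = pwm,
    counts = counts,
    ic = information_content(pwm, rep(0.25, 4)),
    consensus_iupac = consensus_from_pwm(pwm, consensus_threshold),
    n_sites = n_sites,
    background = background,
    log_likelihood = log_likelihood
  ), class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> width %d, %d sites, consensus %s, total IC %.1f bits\n",
              x$width, x$n_sites, x$consensus_iupac, sum(x$ic)))
  invisible(x)
}

#' @rdname em_discover
#' @param x a `motif`.
#' @param ... unused.
#' @method tidy motif
#' @export
tidy.motif <- function(x, ...) {
  tibble(position = rep(seq_len(x$width), each = 4),
         base = rep(DNA_BASES, x$width),
         probability = as.vector(x$pwm),
         count = as.vector(x$counts)) %>%
    left_join(tibble(position = seq_len(x$width), ic = x$ic),
              by = "position")
}

#' @rdname em_discover
#' @method glance motif
#' @export
glance.motif <- function(x, ...) {
  tibble(width = x$width, n_sites = x$n_sites,
         consensus = x$consensus_iupac, total_ic = sum(x$ic),
         log_likelihood = x$log_likelihood)
}

# Per-sequence one-hot window matrices (w x npos per base and strand),
# computed once per discovery since they depend only on the sequences.
onehot_windows <- function(fwd_mats, rev_mats) {
  lapply(seq_along(fwd_mats), function(s) {
    fm <- fwd_mats[[s]]; rm_ <- rev_mats[[s]]
    list(f = lapply(1:4, function(b) (fm == b) * 1),
         r = lapply(1:4, function(b) (rm_ == b) * 1),
         npos = ncol(fm))
  })
}

# One EM run from a given starting PWM. Returns the re-estimated PWM, the
# expected base counts from the final E-step, the data log-likelihood trace
# and the monotone MAP objective trace.
em_run <- function(codes, onehots, pwm0, background,
                   max_iter, tol, pseudocount) {
  w <- ncol(pwm0)
  nseq <- length(onehots)
  log_bg <- log(background)
  # Background log-probability of each full sequence: part of the OOPS
  # likelihood that does not depend on the site position.
  full_bg <- vapply(codes, function(cd) sum(log_bg[cd]), numeric(1))
  pwm <- pwm0
  ll_trace <- numeric(0)
  obj_trace <- numeric(0)
  counts <- matrix(0, nrow = 4, ncol = w)
  for (iter in seq_len(max_iter)) {
    log_ratio <- log(pwm) - log_bg
    ll <- 0
    counts <- matrix(0, nrow = 4, ncol = w)
    for (s in seq_len(nseq)) {
      oh <- onehots[[s]]
      npos <- oh$npos
      sf <- numeric(npos); sr <- numeric(npos)
      for (b in 1:4) {
        sf <- sf + as.vector(crossprod(oh$f[[b]], log_ratio[b, ]))
        sr <- sr + as.vector(crossprod(oh$r[[b]], log_ratio[b, ]))
      }
      sc <- c(sf, sr)
      m <- max(sc)
      post <- exp(sc - m)
      z <- sum(post)
      post <- post / z
      ll <- ll + full_bg[s] + m + log(z) - log(2 * npos)
      pf <- post[seq_len(npos)]
      pr <- post[npos + seq_len(npos)]
      for (b in 1:4) {
        counts[b, ] <- counts[b, ] + as.vector(oh$f[[b]] %*% pf) +
          as.vector(oh$r[[b]] %*% pr)
      }
    }
    ll_trace <- c(ll_trace, ll)
    # The pseudocount M-step is the MAP update under a Dirichlet prior, so
    # the EM-monotone objective is the likelihood plus the prior term.
    obj_trace <- c(obj_trace, ll + pseudocount * sum(log(pwm)))
    pwm <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
    if (iter > 1 && abs(obj_trace[iter] - obj_trace[iter - 1]) < tol) break
  }
  rownames(pwm) <- DNA_BASES
  list(pwm = pwm, counts = counts, ll_trace = ll_trace,
       obj_trace = obj_trace,
       log_likelihood = ll_trace[length(ll_trace)])
}

# Shift a PWM one column left or right, filling the entering column with the
# background distribution. Used by the post-convergence shift refinement.
shift_pwm <- function(pwm, dshift, background) {
  w <- ncol(pwm)
  out <- matrix(rep(background, w), nrow = 4)
  if (dshift == 1) {
    out[, seq_len(w - 1)] <- pwm[, 2:w]
  } else {
    out[, 2:w] <- pwm[, seq_len(w - 1)]
  }
  rownames(out) <- rownames(pwm)
  out
}

#' Discover a motif by EM under the OOPS model
#'
#' Expectation-maximization assuming one motif occurrence per sequence on
#' either strand, with a 0-order background estimated from the input
#' composition. The E-step computes the posterior over (position, strand) for
#' each sequence; the M-step re-estimates the position weight matrix with a
#' pseudocount. Each restart is seeded from a subsequence drawn from the
#' lexicographically sorted multiset of all windows, so a fixed seed with a
#' single restart gives a result independent of sequence input order. The
#' best restart by final log-likelihood wins. The log-likelihood is
#' non-decreasing across iterations and is checked on every run.
#'
#' @param sequences character vector of DNA sequences (or a tibble with a
#'   `sequence` column), each at least `width` long.
#' @param width motif width (>= 4).
#' @param n_restarts EM restarts from different seed subsequences.
#' @param rng_seed integer seed.
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood change declaring convergence.
#' @param pseudocount per-base pseudocount in the M-step. The pseudocount
#'   makes each M-step the MAP update under a Dirichlet prior, so the
#'   monotone EM objective is the log-likelihood plus the prior term; that
#'   penalized objective is asserted non-decreasing on every run.
#' @param consensus_threshold threshold for the reported IUPAC consensus.
#' @return a `motif` object; `log_likelihood` holds the winning restart's
#'   final data log-likelihood, attribute `ll_trace` its per-iteration trace
#'   and attribute `obj_trace` the monotone penalized objective.
#' @export
em_discover <- function(sequences, width = 15, n_restarts = 10,
                        rng_seed = 1L, max_iter = 100, tol = 1e-4,
                        pseudocount = 0.25, consensus_threshold = 0.85) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  sequences <- toupper(sequences)
  assert_that(width >= 4, "width must be >= 4")
  lens <- nchar(sequences)
  assert_that(all(lens >= width),
              "every sequence must be at least `width` long")
  codes <- lapply(sequences, encode_seq)
  assert_that(!anyNA(unlist(codes)),
              "sequences must contain only A/C/G/T for discovery")
  fwd_mats <- lapply(codes, window_matrix, w = width)
  rev_mats <- lapply(codes, function(cd) window_matrix(revcomp_code(cd),
                                                       w = width))
  onehots <- onehot_windows(fwd_mats, rev_mats)
  base_freq <- tabulate(unlist(codes), nbins = 4)
  background <- (base_freq + 1) / sum(base_freq + 1)
  # order-invariant seed pool: all windows, sorted
  all_windows <- sort(unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - width + 1), width:n)
  })))
  set.seed(rng_seed)
  seed_idx <- sample.int(length(all_windows), n_restarts, replace = TRUE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    seed_site <- all_windows[seed_idx[r]]
    sc <- encode_seq(seed_site)
    pwm0 <- matrix(rep(background, width), nrow = 4)
    for (k in seq_len(width)) {
      pwm0[, k] <- 0.3 * pwm0[, k]
      pwm0[sc[k], k] <- pwm0[sc[k], k] + 0.7
    }
    run <- em_run(codes, onehots, pwm0, background,
                  max_iter, tol, pseudocount)
    if (any(diff(run$obj_trace) < -1e-6)) {
      abort("EM objective decreased; this indicates a bug")
    }
    if (is.null(best) || run$log_likelihood > best$log_likelihood) {
      best <- run
    }
  }
  # Shift refinement (as in MEME's column-shifting heuristic): EM can lock
  # onto a frame one column off the optimum; restart from +-1-shifted PWMs
  # and keep any strictly better objective.
  repeat {
    improved <- FALSE
    for (dshift in c(-1L, 1L)) {
      pwm_s <- shift_pwm(best$pwm, dshift, background)
      run <- em_run(codes, onehots, pwm_s, background,
                    max_iter, tol, pseudocount)
      if (any(diff(run$obj_trace) < -1e-6)) {
        abort("EM objective decreased; this indicates a bug")
      }
      best_obj <- best$obj_trace[length(best$obj_trace)]
      if (run$obj_trace[length(run$obj_trace)] > best_obj + tol) {
        best <- run
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  rownames(best$counts) <- DNA_BASES
  m <- new_motif(best$pwm, best$counts, n_sites = length(sequences),
                 log_likelihood = best$log_likelihood,
                 background = background,
                 consensus_threshold = consensus_threshold)
  attr(m, "ll_trace") <- best$ll_trace
  attr(m, "obj_trace") <- best$obj_trace
  m
}

#' Scan a sequence for a degenerate IUPAC pattern
#'
#' Reports every offset (and strand, when enabled) whose bases are each
#' compatible with the corresponding IUPAC code. Overlapping hits are all
#' reported. Reverse-strand hits carry forward-strand offsets with
#' `matched_text` as read on the reverse strand. Subject bases are taken
#' literally: an N or other ambiguity code in the scanned sequence fails
#' every pattern position except N.
#'
#' @param sequence a DNA string (character scalar) or named character vector.
#' @param pattern IUPAC pattern, case-insensitive.
#' @param both_strands also scan the reverse strand (default TRUE).
#' @param sequence_id id recorded in the output (defaults to names or
#'   "seq").
#' @return tibble with columns sequence_id, offset (0-based, forward
#'   strand), strand, matched_text.
#' @export
#' @examples
#' scan_iupac("TGTCAAAAAAAAGAC", "TGTYNNNNNNNNRAC")
scan_iupac <- function(sequence, pattern, both_strands = TRUE,
                       sequence_id = NULL) {
  pattern <- toupper(pattern)
  assert_that(all(strsplit(pattern, "")[[1]] %in% names(IUPAC_SETS)),
              "pattern contains a non-IUPAC character")
  if (length(sequence) > 1) {
    ids <- sequence_id %||% (names(sequence) %||%
                               sprintf("seq_%d", seq_along(sequence)))
    return(purrr::map_dfr(seq_along(sequence), function(i) {
      scan_iupac(sequence[[i]], pattern, both_strands, ids[[i]])
    }))
  }
  sequence_id <- sequence_id %||% (names(sequence) %||% "seq")
  subj <- Biostrings::DNAString(toupper(as.character(sequence)))
  pat <- Biostrings::DNAString(pattern)
  hit_tbl <- function(m, strand) {
    if (length(m) == 0) {
      return(tibble(sequence_id = character(), offset = integer(),
                    strand = character(), matched_text = character()))
    }
    txt <- as.character(Biostrings::extractAt(subj, as(m, "IRanges")))
    if (strand == "-") {
      txt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(txt)))
    }
    tibble(sequence_id = sequence_id,
           offset = Biostrings::start(m) - 1L,
           strand = strand,
           matched_text = txt)
  }
  fwd <- Biostrings::matchPattern(pat, subj, fixed = "subject")
  out <- hit_tbl(fwd, "+")
  if (both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    rev_hits <- Biostrings::matchPattern(rc, subj, fixed = "subject")
    out <- bind_rows(out, hit_tbl(rev_hits, "-"))
  }
  arrange(out, .data$offset, .data$strand)
}

#' Write a motif in MEME minimal motif text format
#'
#' @param motif a `motif` object.
#' @param path output file.
#' @param name motif name written to the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motif, path, name = "MOTIF_1") {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", DNA_BASES, motif$background),
          collapse = " "), "",
    sprintf("MOTIF %s %s", name, motif$consensus_iupac),
    sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      motif$width, motif$n_sites),
    apply(motif$pwm, 2, function(p) {
      paste(sprintf("%.6f", p), collapse = "  ")
    })
  )
  writeLines(lines, path)
  invisible(path)
}
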