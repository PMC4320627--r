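# Shared fixtures and independent oracles, built in code at test time.

MRPC_PATTERN <- "TGTYNNNNNNNNRAC"

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Random background sequences each carrying one exact planted pattern
# instance at a recorded offset (0-based).
make_motif_seqs <- function(n = 50, len = 101, pattern = MRPC_PATTERN,
                            gc = 0.69, seed = 1) {
  set.seed(seed)
  w <- nchar(pattern)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  offsets <- integer(n)
  seqs <- vapply(seq_len(n), function(i) {
    bg <- paste(sample(names(probs), len, TRUE, prob = probs),
                collapse = "")
    inst <- sample_motif_instance(pattern)
    pos <- sample.int(len - w + 1, 1)
    offsets[i] <<- pos - 1L
    substr(bg, pos, pos + w - 1) <- inst
    bg
  }, character(1))
  list(seqs = seqs, offsets = offsets)
}

# TRUE when every constrained (non-N) pattern position admits the consensus
# call, in either reading frame of the double-stranded motif.
consensus_matches <- function(consensus, pattern = MRPC_PATTERN) {
  sets <- chipregulon:::IUPAC_SETS
  one_frame <- function(cons, pat) {
    cs <- strsplit(cons, "")[[1]]
    ps <- strsplit(pat, "")[[1]]
    length(cs) == length(ps) &&
      all(vapply(seq_along(ps), function(i) {
        ps[i] == "N" || all(sets[[cs[i]]] %in% sets[[ps[i]]])
      }, logical(1)))
  }
  one_frame(consensus, pattern) ||
    one_frame(consensus, revcomp_chr(pattern))
}

# Brute-force nearest-neighbour distances: all pairs, no sorting tricks.
brute_nearest <- function(a, b) {
  vapply(a, function(x) min(abs(x - b)), numeric(1))
}

# Brute-force exhaustive two-sided Fisher p by hypergeometric enumeration.
brute_fisher <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form median of |X - Y| for X, Y iid Laplace(0, b):
# P(|X - Y| <= d) = 1 - exp(-d/b) * (1 + d / (2b)).
laplace_diff_median <- function(b) {
  stats::uniroot(function(d) 1 - exp(-d / b) * (1 + d / (2 * b)) - 0.5,
                 c(0, 20 * b))$root
}

# Tiny deterministic genome for geometry tests: explicit gene placements.
toy_genome <- function(length = 10000,
                       starts = c(1000, 3000, 5000, 8000),
                       ends = c(2000, 4200, 6400, 9500),
                       strands = c("+", "-", "+", "-"),
                       categories = NULL, sequence = NULL) {
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", seq_along(starts)),
    strand = strands, coding_start = starts, coding_end = ends)
  if (!is.null(categories)) genes$category <- categories
  genome_model("chr", length, genes, sequence = sequence)
}

# Minimal annotation table carrying just the promoter-hit gene ids, for
# enrichment tests that do not need real peaks.
fake_annotations <- function(hit_gene_ids) {
  tibble::tibble(
    coordinate = 0,
    promoter_hits = list(tibble::tibble(
      gene_id = hit_gene_ids, distance = -50, strand = "+", tsc = 0))
  )
}
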