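# Synthetic study generator. Emulates the structure of a transcription-factor
# ChIP-seq study on a gene-dense bacterial genome: >90% coding sequence,
# promoter-biased true binding sites carrying a degenerate palindromic motif,
# two replicate peak lists where shared true sites recur with small jitter
# while false peaks scatter, and gene lists/categories with planted
# enrichment. Every draw is reproducible from (parameters, seed) and the
# ground truth is returned alongside the data.

rlaplace <- function(n, scale) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

# Default functional-category table: label + sampling probability, loosely
# echoing a bacterial annotation's category mix with a large
# hypothetical-protein class.
default_categories <- function() {
  tibble(
    category = c("hypothetical proteins", "unknown function",
                 "regulatory functions", "signal transduction",
                 "energy metabolism", "cell envelope", "protein fate",
                 "transport and binding proteins"),
    prob = c(0.36, 0.16, 0.08, 0.08, 0.09, 0.09, 0.06, 0.08)
  )
}

#' Generate a synthetic gene-dense genome
#'
#' Alternating gene/intergap layout: gene lengths are gamma-distributed
#' around `mean_gene_length`, gap lengths exponential with the mean implied
#' by `coding_fraction`, strands i.i.d., sequence i.i.d. at the requested GC
#' content, and categories multinomial from `category_table`.
#'
#' @param n_genes number of genes.
#' @param mean_gene_length mean coding-span length in bp.
#' @param coding_fraction target fraction of the chromosome covered by
#'   coding spans, in (0, 1); the realized value lands within about 2% for
#'   a few hundred genes.
#' @param gc_content sequence GC fraction.
#' @param seed integer seed.
#' @param forward_prob probability a gene is on the forward strand.
#' @param category_table tibble with columns category, prob (or `NULL` for
#'   no categories).
#' @param operon_prob probability a gene opens/extends an operon run with
#'   its same-strand predecessor (0 disables operons).
#' @param with_sequence generate the chromosome sequence (default TRUE).
#' @param chromosome_id chromosome name.
#' @return a [genome_model()].
#' @export
make_genome <- function(n_genes = 800, mean_gene_length = 1125,
                        coding_fraction = 0.9, gc_content = 0.69,
                        seed = 1L, forward_prob = 0.5,
                        category_table = default_categories(),
                        operon_prob = 0, with_sequence = TRUE,
                        chromosome_id = "chr") {
  assert_that(coding_fraction > 0 && coding_fraction < 1,
              "coding_fraction must be in (0, 1)")
  assert_that(is_count(n_genes), "n_genes must be a positive integer")
  set.seed(seed)
  shape <- 6
  gene_len <- pmax(100, round(rgamma(n_genes, shape = shape,
                                     scale = mean_gene_length / shape)))
  mean_gap <- mean_gene_length * (1 / coding_fraction - 1)
  gap_len <- pmax(2, round(rexp(n_genes, rate = 1 / mean_gap)))
  starts <- cumsum(c(gap_len[1], head(gene_len, -1) + gap_len[-1]))
  ends <- starts + gene_len
  glen <- ends[n_genes] + gap_len[1]
  strand <- ifelse(runif(n_genes) < forward_prob, "+", "-")
  genes <- tibble(gene_id = sprintf("G%04d", seq_len(n_genes)),
                  strand = strand,
                  coding_start = starts, coding_end = ends)
  if (!is.null(category_table)) {
    genes$category <- sample(category_table$category, n_genes,
                             replace = TRUE, prob = category_table$prob)
  }
  if (operon_prob > 0) {
    op_id <- integer(n_genes); op_pos <- integer(n_genes)
    current <- 0L; pos <- 0L
    for (i in seq_len(n_genes)) {
      extend <- i > 1 && strand[i] == strand[i - 1] &&
        op_id[i - 1] > 0 && runif(1) < operon_prob
      open <- i < n_genes && strand[i + 1] == strand[i] &&
        runif(1) < operon_prob
      if (extend) {
        op_id[i] <- current; pos <- pos + 1L; op_pos[i] <- pos
      } else if (open) {
        current <- current + 1L; op_id[i] <- current
        pos <- 1L; op_pos[i] <- 1L
      }
    }
    genes$operon_id <- ifelse(op_id > 0, sprintf("op%03d", op_id),
                              NA_character_)
    genes$operon_position <- ifelse(op_id > 0, op_pos, NA_integer_)
  }
  sequence <- NULL
  if (with_sequence) {
    probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
               G = gc_content / 2, T = (1 - gc_content) / 2)
    sequence <- paste(sample(names(probs), glen, replace = TRUE,
                             prob = probs), collapse = "")
  }
  genome_model(chromosome_id = chromosome_id, length = glen,
               genes = genes, sequence = sequence)
}

#' Sample a motif instance compatible with an IUPAC pattern
#'
#' Each position draws uniformly from the bases its IUPAC code allows.
#'
#' @param pattern IUPAC pattern, default the imperfect palindrome
#'   `TGTYN8RAC`.
#' @param n number of instances.
#' @return character vector of instances.
#' @export
sample_motif_instance <- function(pattern = "TGTYNNNNNNNNRAC", n = 1) {
  sets <- IUPAC_SETS[strsplit(toupper(pattern), "")[[1]]]
  vapply(seq_len(n), function(i) {
    paste(vapply(sets, function(b) b[sample.int(length(b), 1)], ""),
          collapse = "")
  }, character(1))
}

#' Plant motif-bearing binding sites into a genome
#'
#' With probability `promoter_bias` a site is placed at a signed TSC distance
#' drawn from `distance_sampler` relative to a randomly chosen target gene
#' (weighted by `category_bias` if given); otherwise it is placed uniformly.
#' A motif instance compatible with `motif_pattern` is written into the
#' sequence centered on the site, reverse-complemented with probability 1/2.
#' Collisions (two sites within `min_separation`) are re-drawn a bounded
#' number of times.
#'
#' @param genome a sequence-bearing `genome_model`.
#' @param n_sites number of true sites.
#' @param promoter_bias probability a site targets a gene promoter.
#' @param distance_sampler function(n) returning signed TSC distances for
#'   promoter-targeted sites; default uniform integers on `[-250, 0]`.
#' @param motif_pattern IUPAC pattern planted at each site.
#' @param category_bias optional list(category =, fold =): genes of that
#'   category are `fold` times as likely to be chosen as targets.
#' @param min_separation minimum distance between planted sites.
#' @param seed integer seed.
#' @return list with `genome` (sequence updated) and `true_sites` tibble:
#'   site_id, coordinate, target_gene, target_distance, promoter_targeted,
#'   motif, motif_strand, motif_start.
#' @export
plant_sites <- function(genome, n_sites = 150, promoter_bias = 0.8,
                        distance_sampler = function(n) {
                          sample(-250:0, n, replace = TRUE)
                        },
                        motif_pattern = "TGTYNNNNNNNNRAC",
                        category_bias = NULL, min_separation = 200,
                        seed = 1L) {
  assert_that(is_count(n_sites), "n_sites must be a positive integer")
  assert_that(!is.null(genome$sequence), "genome model has no sequence")
  set.seed(seed)
  g <- genome$genes
  w <- nchar(motif_pattern)
  half <- (w - 1) %/% 2
  weights <- rep(1, nrow(g))
  if (!is.null(category_bias)) {
    weights[!is.na(g$category) &
              g$category == category_bias$category] <- category_bias$fold
  }
  coords <- numeric(0)
  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    placed <- FALSE
    for (try in 1:50) {
      targeted <- runif(1) < promoter_bias
      if (targeted) {
        gi <- sample.int(nrow(g), 1, prob = weights)
        d <- distance_sampler(1)
        coord <- if (g$strand[gi] == "+") g$tsc[gi] + d else g$tsc[gi] - d
      } else {
        gi <- NA_integer_; d <- NA_real_
        coord <- sample.int(genome$length, 1) - 1
      }
      if (coord - half < 0 || coord + half >= genome$length) next
      if (length(coords) > 0 && min(abs(coord - coords)) < min_separation)
        next
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place site without collision; lower n_sites")
    coords <- c(coords, coord)
    rows[[i]] <- tibble(
      site_id = sprintf("site_%03d", i),
      coordinate = coord,
      target_gene = if (targeted) g$gene_id[gi] else NA_character_,
      target_distance = d,
      promoter_targeted = targeted
    )
  }
  sites <- bind_rows(rows)
  inst <- sample_motif_instance(motif_pattern, n_sites)
  on_reverse <- runif(n_sites) < 0.5
  planted <- ifelse(on_reverse,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAStringSet(inst))),
                    inst)
  seq_chr <- as.character(genome$sequence[[1]])
  for (i in seq_len(n_sites)) {
    s0 <- sites$coordinate[i] - half
    substr(seq_chr, s0 + 1, s0 + w) <- planted[i]
  }
  sites$motif <- inst
  sites$motif_strand <- ifelse(on_reverse, "-", "+")
  sites$motif_start <- sites$coordinate - half
  genome$sequence <- Biostrings::DNAStringSet(seq_chr)
  names(genome$sequence) <- genome$chromosome_id
  list(genome = genome, true_sites = sites)
}

#' Simulate two replicate peak lists from true sites
#'
#' A `shared_fraction` of true sites appears in both replicates with
#' independent Laplace(0, `jitter_scale`) coordinate noise (rounded to bp);
#' the remaining true sites alternate between replicates; each replicate
#' additionally gets `n_false_per_replicate` uniformly placed false peaks.
#' Enrichment scores are log-normal, higher for true sites.
#'
#' @param true_sites tibble from [plant_sites()].
#' @param genome a `genome_model` (for the length).
#' @param shared_fraction fraction of true sites present in both replicates.
#' @param jitter_scale Laplace scale of the replicate coordinate noise (bp).
#' @param n_false_per_replicate false peaks per replicate.
#' @param true_meanlog,true_sdlog,false_meanlog,false_sdlog log-normal
#'   enrichment parameters for true and false peaks.
#' @param seed integer seed.
#' @return list with `rep1`, `rep2` (peak tibbles), `shared_sites`
#'   (site ids present in both), and `truth` (per-site placement table).
#' @export
simulate_replicate_peaks <- function(true_sites, genome,
                                     shared_fraction = 0.75,
                                     jitter_scale = 6,
                                     n_false_per_replicate = 50,
                                     true_meanlog = log(30),
                                     true_sdlog = 0.35,
                                     false_meanlog = log(12),
                                     false_sdlog = 0.3,
                                     seed = 1L) {
  assert_that(shared_fraction >= 0 && shared_fraction <= 1,
              "shared_fraction must be in [0, 1]")
  set.seed(seed)
  n <- nrow(true_sites)
  n_shared <- round(shared_fraction * n)
  shared_idx <- sort(sample.int(n, n_shared))
  rest <- setdiff(seq_len(n), shared_idx)
  rep1_only <- rest[seq_along(rest) %% 2 == 1]
  rep2_only <- rest[seq_along(rest) %% 2 == 0]
  clamp <- function(x) pmin(pmax(round(x), 0), genome$length - 1)
  jitter <- function(coord) clamp(coord + rlaplace(length(coord),
                                                   jitter_scale))
  mk_rep <- function(true_idx, label) {
    tc <- jitter(true_sites$coordinate[true_idx])
    te <- rlnorm(length(true_idx), true_meanlog, true_sdlog)
    fc <- sample.int(genome$length, n_false_per_replicate) - 1
    fe <- rlnorm(n_false_per_replicate, false_meanlog, false_sdlog)
    peak_table(c(tc, fc), c(te, fe), replicate_id = label, genome = genome)
  }
  rep1 <- mk_rep(c(shared_idx, rep1_only), "rep1")
  rep2 <- mk_rep(c(shared_idx, rep2_only), "rep2")
  list(rep1 = rep1, rep2 = rep2,
       shared_sites = true_sites$site_id[shared_idx],
       truth = mutate(true_sites,
                      in_rep1 = dplyr::row_number() %in%
                        c(shared_idx, rep1_only),
                      in_rep2 = dplyr::row_number() %in%
                        c(shared_idx, rep2_only)))
}

#' Generate gene lists with planted enrichment
#'
#' For `fold != 1` the list draws `k ~ Binomial(size, fold * H / N)` members
#' from the promoter-hit genes (H of N universe genes) and `size - k` from
#' the rest, so the expected observed count is `fold` times the expected
#' count under independence. `fold = 1` samples the list uniformly from the
#' whole universe, the exact independence null (the overlap is then
#' hypergeometric given the margins).
#'
#' @param genome a `genome_model`.
#' @param promoter_hit_gene_ids character vector of genes with a
#'   promoter-window hit (the enrichment target).
#' @param list_specs tibble with columns name, size, fold.
#' @param seed integer seed.
#' @return list with `lists` (named list of gene-list tibbles) and `truth`
#'   (spec table with the realized overlap).
#' @export
make_gene_lists <- function(genome, promoter_hit_gene_ids, list_specs,
                            seed = 1L) {
  set.seed(seed)
  universe <- genome$genes$gene_id
  hits <- intersect(promoter_hit_gene_ids, universe)
  nonhits <- setdiff(universe, hits)
  out <- list(); realized <- integer(nrow(list_specs))
  for (i in seq_len(nrow(list_specs))) {
    size <- list_specs$size[i]; fold <- list_specs$fold[i]
    assert_that(is_count(size) && size <= length(universe),
                "list size must be a positive integer <= gene count")
    p_hit <- fold * length(hits) / length(universe)
    assert_that(p_hit <= 1 && size <= length(universe),
                sprintf("infeasible fold %.2f for list '%s'", fold,
                        list_specs$name[i]))
    if (fold == 1) {
      members <- sample(universe, size)
      k <- length(intersect(members, hits))
    } else {
      k <- rbinom(1, size, p_hit)
      k <- min(k, length(hits), size)
      k <- max(k, size - length(nonhits))
      members <- c(sample(hits, k), sample(nonhits, size - k))
    }
    out[[list_specs$name[i]]] <- gene_list(members,
                                           name = list_specs$name[i])
    realized[i] <- k
  }
  list(lists = out,
       truth = mutate(list_specs, n_hit_members = realized))
}

#' Simulate chip and control read starts
#'
#' Chip reads: per true site, `reads_per_site` fragment-aware starts
#' (forward-strand 5' starts upstream of the site, reverse downstream, at
#' offsets around half the fragment size) plus a uniform background; the
#' control is uniform only, depth-matched to the chip total.
#'
#' @param genome a `genome_model`.
#' @param true_sites tibble from [plant_sites()] (may have zero rows).
#' @param reads_per_site chip reads per true site.
#' @param background_depth background read density in reads/bp.
#' @param fragment_size expected fragment size in bp.
#' @param seed integer seed.
#' @return list with `chip` and `control` read sets (see [read_set()]).
#' @export
simulate_reads <- function(genome, true_sites, reads_per_site = 300,
                           background_depth = 0.02, fragment_size = 100,
                           seed = 1L) {
  assert_that(reads_per_site >= 0 && background_depth > 0,
              "depths must be positive")
  set.seed(seed)
  clamp <- function(x) pmin(pmax(round(x), 0), genome$length - 1)
  n_sites <- nrow(true_sites)
  site_pos <- strand <- NULL
  if (n_sites > 0 && reads_per_site > 0) {
    centers <- rep(true_sites$coordinate, each = reads_per_site)
    n_site_reads <- length(centers)
    fwd <- runif(n_site_reads) < 0.5
    offset <- pmax(0, rnorm(n_site_reads, mean = fragment_size / 2,
                            sd = fragment_size / 4))
    site_pos <- clamp(ifelse(fwd, centers - offset, centers + offset))
    strand <- ifelse(fwd, "+", "-")
  }
  n_bg <- round(background_depth * genome$length)
  bg_pos <- sample.int(genome$length, n_bg, replace = TRUE) - 1
  bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
  chip <- read_set(c(site_pos, bg_pos), c(strand, bg_strand),
                   label = "chip")
  n_ctrl <- nrow(chip)
  ctrl <- read_set(sample.int(genome$length, n_ctrl, replace = TRUE) - 1,
                   sample(c("+", "-"), n_ctrl, replace = TRUE),
                   label = "control")
  list(chip = chip, control = ctrl)
}

#' Generate a complete synthetic study with recorded ground truth
#'
#' Convenience wrapper: genome + planted sites + replicate peaks + gene
#' lists, with per-stage seeds derived from one top-level seed. Defaults are
#' the package's toy study conditions: a 1 Mb chromosome, 800 genes, 90%
#' coding, GC 0.69, 150 true sites with 80% promoter bias, 75% of sites
#' shared between replicates with Laplace(0, 6) jitter, 50 false peaks per
#' replicate, one gene category planted at 3x site-targeting weight, and an
#' "up_regulated"-style list planted at 1.7x enrichment.
#'
#' @param seed top-level integer seed.
#' @param n_genes,n_sites,promoter_bias,shared_fraction,jitter_scale,
#'   n_false_per_replicate,gc_content main generator knobs (see the
#'   individual generators).
#' @param enriched_category category receiving 3x site-targeting weight
#'   (`NULL` disables).
#' @param list_specs gene-list specs passed to [make_gene_lists()]; the
#'   default plants one 1.7x-enriched list among null lists.
#' @param config an [analysis_config()].
#' @param with_sequence carry the genome sequence (needed for motif work).
#' @return list of class `synthetic_study` with elements genome, true_sites,
#'   rep1, rep2, shared_sites, peak_truth, lists, list_truth,
#'   planted_category, config, seeds.
#' @export
synthesize_study <- function(seed = 1L, n_genes = 800, n_sites = 150,
                             promoter_bias = 0.8, shared_fraction = 0.75,
                             jitter_scale = 6, n_false_per_replicate = 50,
                             gc_content = 0.69,
                             enriched_category = "regulatory functions",
                             list_specs = NULL,
                             config = analysis_config(rng_seed = seed),
                             with_sequence = TRUE) {
  seeds <- list(genome = derive_seed(seed, "genome"),
                sites = derive_seed(seed, "sites"),
                peaks = derive_seed(seed, "peaks"),
                lists = derive_seed(seed, "lists"))
  assert_that(isTRUE(with_sequence),
              "synthesize_study requires with_sequence = TRUE")
  genome <- make_genome(n_genes = n_genes, gc_content = gc_content,
                        seed = seeds$genome, operon_prob = 0.25,
                        with_sequence = TRUE)
  category_bias <- if (is.null(enriched_category)) NULL else
    list(category = enriched_category, fold = 3)
  planted <- plant_sites(genome, n_sites = n_sites,
                         promoter_bias = promoter_bias,
                         category_bias = category_bias,
                         seed = seeds$sites)
  genome <- planted$genome
  true_sites <- planted$true_sites
  sim <- simulate_replicate_peaks(true_sites, genome,
                                  shared_fraction = shared_fraction,
                                  jitter_scale = jitter_scale,
                                  n_false_per_replicate =
                                    n_false_per_replicate,
                                  seed = seeds$peaks)
  # Promoter-hit genes of the planted sites define the enrichment target.
  site_hits <- promoter_hits(true_sites$coordinate, genome,
                             config$promoter_window)
  hit_genes <- unique(site_hits$gene_id)
  if (is.null(list_specs)) {
    list_specs <- tibble(
      name = c("up_regulated", "down_regulated", "directly_involved"),
      size = c(45, 45, 20),
      fold = c(1.7, 1, 1))
  }
  gl <- make_gene_lists(genome, hit_genes, list_specs, seed = seeds$lists)
  structure(list(genome = genome, true_sites = true_sites,
                 rep1 = sim$rep1, rep2 = sim$rep2,
                 shared_sites = sim$shared_sites, peak_truth = sim$truth,
                 lists = gl$lists, list_truth = gl$truth,
                 planted_category = enriched_category,
                 config = config, seeds = seeds),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d genes / %s bp, %d true sites (%d shared), %d+%d peaks\n",
    nrow(x$genome$genes), format(x$genome$length, big.mark = ","),
    nrow(x$true_sites), length(x$shared_sites),
    nrow(x$rep1), nrow(x$rep2)))
  invisible(x)
}
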