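# The synthetic study generator: construction guarantees and recorded
# ground truth.

test_that("generated genomes hit the requested coding fraction and are
           byte-reproducible", {
  g <- make_genome(n_genes = 200, coding_fraction = 0.9, seed = 42)
  cf <- coding_fraction(g)
  expect_gte(cf, 0.88)
  expect_lte(cf, 0.92)
  # identical seed -> byte-identical FASTA and GFF3
  g2 <- make_genome(n_genes = 200, coding_fraction = 0.9, seed = 42)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); f2 <- file.path(d, "b.fa")
  write_genome_fasta(g, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  gf1 <- file.path(d, "a.gff3"); gf2 <- file.path(d, "b.gff3")
  write_gff3(g, gf1); write_gff3(g2, gf2)
  expect_identical(grep("^##date", readLines(gf1), invert = TRUE,
                        value = TRUE),
                   grep("^##date", readLines(gf2), invert = TRUE,
                        value = TRUE))
})

test_that("strand probability 1 places every gene on the forward strand", {
  g <- make_genome(n_genes = 50, seed = 1, forward_prob = 1,
                   with_sequence = FALSE)
  expect_true(all(g$genes$strand == "+"))
})

test_that("fully promoter-biased planted sites all annotate as promoter
           hits and carry their motif", {
  g <- make_genome(n_genes = 300, seed = 44)
  pl <- plant_sites(g, n_sites = 60, promoter_bias = 1, seed = 44)
  ann <- annotate_all(tibble::tibble(coordinate = pl$true_sites$coordinate),
                      pl$genome, analysis_config())
  expect_true(all(ann$n_promoter_hits > 0))
  # every planted instance is recovered by an IUPAC scan at its offset
  seq_chr <- as.character(pl$genome$sequence[[1]])
  hits <- scan_iupac(seq_chr, MRPC_PATTERN)
  expect_true(all(pl$true_sites$motif_start %in% hits$offset))
  # strand bookkeeping: the recorded instance matches the genome text
  for (i in sample(nrow(pl$true_sites), 10)) {
    s <- pl$true_sites[i, ]
    text <- substr(seq_chr, s$motif_start + 1, s$motif_start + 15)
    expected <- if (s$motif_strand == "+") s$motif else revcomp_chr(s$motif)
    expect_equal(text, expected)
  }
})

test_that("unbiased placement hits promoter windows at the genome's window
           coverage rate", {
  g <- make_genome(n_genes = 300, seed = 45)
  pl <- plant_sites(g, n_sites = 150, promoter_bias = 0, seed = 45)
  ann <- annotate_all(tibble::tibble(coordinate = pl$true_sites$coordinate),
                      pl$genome, analysis_config())
  obs <- mean(ann$n_promoter_hits > 0)
  # expected rate = fraction of the genome lying in any promoter window
  gg <- g$genes
  win <- IRanges::reduce(IRanges::IRanges(
    start = ifelse(gg$strand == "+", gg$tsc - 400, gg$tsc - 100) + 1,
    end = ifelse(gg$strand == "+", gg$tsc + 100, gg$tsc + 400) + 1))
  expected <- sum(IRanges::width(win)) / g$length
  se <- sqrt(expected * (1 - expected) / 150)
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("zero-jitter fully-shared replicates are recovered exactly at any
           cutoff", {
  g <- make_genome(n_genes = 200, seed = 46)
  pl <- plant_sites(g, n_sites = 40, seed = 46)
  sim <- simulate_replicate_peaks(pl$true_sites, pl$genome,
                                  shared_fraction = 1, jitter_scale = 0,
                                  n_false_per_replicate = 0, seed = 46)
  m0 <- filter_concordant(sim$rep1, sim$rep2, 0)
  expect_equal(nrow(m0), 40)
  expect_true(all(m0$replicate_distance == 0))
  expect_setequal(m0$coordinate, pl$true_sites$coordinate)
})

test_that("false peaks survive the concordance cutoff at no more than the
           Poisson chance-collision rate", {
  g <- make_genome(n_genes = 800, seed = 47)
  pl <- plant_sites(g, n_sites = 50, seed = 47)
  survived <- 0; total <- 0
  for (s in 1:5) {
    sim <- simulate_replicate_peaks(pl$true_sites, pl$genome,
                                    shared_fraction = 1, jitter_scale = 3,
                                    n_false_per_replicate = 150,
                                    seed = 400 + s)
    m <- filter_concordant(sim$rep1, sim$rep2, 65)
    true_coords <- pl$true_sites$coordinate
    is_false_pair <- vapply(m$coordinate, function(cc) {
      min(abs(cc - true_coords)) > 65
    }, logical(1))
    survived <- survived + sum(is_false_pair)
    total <- total + 150 * 2
  }
  rate <- survived / total
  # chance collision: a false peak pairs if another peak of the other
  # replicate lands within the cutoff window
  density <- nrow(sim$rep2) / g$length
  bound <- 1 - exp(-2 * 66 * density)
  se <- sqrt(bound * (1 - bound) / total)
  expect_lte(rate, bound + 3 * se)
})

test_that("gene lists realize the requested enrichment fold and reject
           impossible requests", {
  g <- make_genome(n_genes = 500, seed = 48, with_sequence = FALSE)
  hits <- g$genes$gene_id[1:100]
  specs <- tibble::tibble(name = c("hot", "null"), size = c(50, 50),
                          fold = c(2, 1))
  gl <- make_gene_lists(g, hits, specs, seed = 48)
  expect_named(gl$lists, c("hot", "null"))
  expect_equal(nrow(gl$lists$hot), 50)
  expect_equal(gl$truth$n_hit_members[1],
               length(intersect(gl$lists$hot$gene_id, hits)))
  expect_error(make_gene_lists(g, hits,
                               tibble::tibble(name = "z", size = 0,
                                              fold = 1), seed = 1),
               "positive integer")
  expect_error(make_gene_lists(g, hits,
                               tibble::tibble(name = "z", size = 10,
                                              fold = 9), seed = 1),
               "infeasible")
})

test_that("read simulation is depth-matched, strand-balanced and closes the
           loop with peak calling", {
  g <- make_genome(n_genes = 100, seed = 49)
  # no sites: chip and control are both uniform and equally deep
  rd0 <- simulate_reads(g, tibble::tibble(coordinate = numeric(0)),
                        reads_per_site = 0, background_depth = 0.01,
                        seed = 49)
  expect_equal(nrow(rd0$chip), nrow(rd0$control))
  expect_lt(abs(mean(rd0$chip$position) - mean(rd0$control$position)),
            4 * g$length / sqrt(12 * nrow(rd0$chip)))
  # one site: call_peaks finds it within 50 bp
  pl <- plant_sites(g, n_sites = 1, seed = 50)
  rd <- simulate_reads(pl$genome, pl$true_sites, reads_per_site = 500,
                       background_depth = 0.02, seed = 50)
  frac_fwd <- mean(rd$chip$strand[seq_len(500)] == "+")
  expect_lt(abs(frac_fwd - 0.5), 4 * sqrt(0.25 / 500))
  pk <- call_peaks(rd$chip, rd$control, peak_call_params(),
                   pl$genome$length)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$coordinate - pl$true_sites$coordinate), 50)
})

test_that("the packaged study object is reproducible from its seed", {
  s1 <- synthesize_study(seed = 11, n_genes = 150, n_sites = 30)
  s2 <- synthesize_study(seed = 11, n_genes = 150, n_sites = 30)
  expect_identical(s1$true_sites, s2$true_sites)
  expect_identical(s1$rep1, s2$rep1)
  expect_identical(as.character(s1$genome$sequence[[1]]),
                   as.character(s2$genome$sequence[[1]]))
  expect_identical(s1$lists, s2$lists)
})
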