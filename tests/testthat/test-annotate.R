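# Peak placement relative to gene structure: signed TSC distances, region
# classes, promoter windows, divergent genes, operon collapsing.

test_that("signed distance follows the reading-orientation convention", {
  expect_equal(signed_distance(1000, 1000, "+"), 0)
  expect_equal(signed_distance(950, 1000, "+"), -50)
  expect_equal(signed_distance(2050, 2000, "-"), -50)
  expect_equal(signed_distance(1100, 1000, "+"), 100)
  expect_equal(signed_distance(1900, 2000, "-"), 100)
})

test_that("nearest TSC minimizes |distance| and returns exact ties", {
  g <- genome_model("chr", 10000, tibble::tibble(
    gene_id = c("gA", "gB"), strand = c("+", "+"),
    coding_start = c(2000, 4000), coding_end = c(2900, 4900)))
  nt <- nearest_tsc(c(2100, 3000, 100), g)
  expect_equal(nt[[1]]$gene_id, "gA")
  expect_equal(nt[[1]]$distance, 100)
  expect_setequal(nt[[2]]$gene_id, c("gA", "gB"))  # equidistant tie
  expect_equal(nt[[3]]$gene_id, "gA")
  single <- genome_model("chr", 1000, tibble::tibble(
    gene_id = "only", strand = "-", coding_start = 100, coding_end = 400))
  expect_equal(nearest_tsc(c(1, 999), single)[[2]]$gene_id, "only")
})

test_that("region classification respects the half-open coding span", {
  g <- toy_genome()
  expect_equal(classify_region(1500, g), "coding")
  expect_equal(classify_region(2500, g), "noncoding")
  expect_equal(classify_region(1000, g), "coding")     # exactly at start
  expect_equal(classify_region(2000, g), "noncoding")  # exactly at end
})

test_that("promoter window is inclusive at both bounds", {
  g <- genome_model("chr", 20000, tibble::tibble(
    gene_id = "gF", strand = "+", coding_start = 5000, coding_end = 6000))
  expect_equal(nrow(promoter_hits(5000 - 400, g)), 1)
  expect_equal(nrow(promoter_hits(5000 - 401, g)), 0)
  expect_equal(nrow(promoter_hits(5000 + 100, g)), 1)
  expect_equal(nrow(promoter_hits(5000 + 101, g)), 0)
})

test_that("divergent genes are two opposite-strand windows flanking the
           peak", {
  g <- genome_model("chr", 20000, tibble::tibble(
    gene_id = c("gR", "gF"), strand = c("-", "+"),
    coding_start = c(3800, 5000), coding_end = c(4801, 6000)))
  # gR tsc = 4800, gF tsc = 5000; peak between them
  h <- promoter_hits(4900, g)
  expect_equal(nrow(h), 2)
  expect_true(all(h$distance == -100))
  ann <- annotate_all(tibble::tibble(coordinate = 4900), g)
  expect_true(ann$divergent)
  # a peak upstream of only the forward gene is not divergent
  ann2 <- annotate_all(tibble::tibble(coordinate = 3500), g)
  expect_false(ann2$divergent)
})

test_that("promoter hits agree with a brute-force scan over all genes", {
  set.seed(23)
  for (i in 1:10) {
    g <- make_genome(n_genes = 60, seed = i, with_sequence = FALSE)
    peaks <- sample.int(g$length, 40) - 1
    hits <- promoter_hits(peaks, g)
    for (j in seq_along(peaks)) {
      d <- signed_distance(peaks[j], g$genes$tsc, g$genes$strand)
      expected <- g$genes$gene_id[d >= -400 & d <= 100]
      got <- hits$gene_id[hits$peak_index == j]
      expect_setequal(got, expected)
    }
  }
})

test_that("operon collapsing keeps first genes and genes without operon
           info", {
  ops <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        operon_id = "op1", operon_position = 1:3)
  gl <- gene_list(c("g1", "g2", "g3"), "l")
  expect_equal(collapse_to_promoter_regions(gl, ops)$gene_id, "g1")
  free <- gene_list(c("x1", "x2"), "free")
  expect_equal(collapse_to_promoter_regions(free, ops)$gene_id,
               c("x1", "x2"))
  expect_equal(nrow(collapse_to_promoter_regions(gl, NULL)), 3)
})

test_that("a planted 345-member list with operon structure collapses to
           207 promoter regions", {
  # 69 three-gene operons contribute 2 internal members each: 345 - 138 = 207
  op_genes <- sprintf("og%03d", 1:207)
  ops <- dplyr::bind_rows(lapply(1:69, function(k) {
    tibble::tibble(gene_id = sprintf("op%02d_g%d", k, 1:3),
                   operon_id = sprintf("op%02d", k),
                   operon_position = 1:3)
  }))
  members <- c(ops$gene_id, sprintf("solo%03d", 1:138))
  expect_length(members, 345)
  gl <- gene_list(members, "interesting")
  collapsed <- collapse_to_promoter_regions(gl, ops)
  expect_equal(nrow(collapsed), 207)
})

test_that("annotation counts satisfy the region and divergence identities", {
  study <- synthesize_study(seed = 3)
  merged <- filter_concordant(study$rep1, study$rep2, 65)
  ann <- annotate_all(merged, study$genome, study$config)
  s <- annotation_summary(ann)
  expect_equal(s$n_coding + s$n_noncoding, s$n_peaks)
  # each divergent site contributes exactly one extra distinct gene when it
  # hits exactly two genes
  two_hit_divergent <- sum(ann$divergent & ann$n_promoter_hits == 2)
  if (all(ann$n_promoter_hits[ann$divergent] == 2) &&
      !anyDuplicated(unlist(lapply(ann$promoter_hits, `[[`, "gene_id")))) {
    expect_equal(s$n_promoter_genes, s$n_promoter_sites + s$n_divergent)
  }
  # every planted promoter-targeted site at d in [-250, 0] must be a
  # promoter hit when annotated directly
  targeted <- study$true_sites[study$true_sites$promoter_targeted, ]
  ann_t <- annotate_all(tibble::tibble(coordinate = targeted$coordinate),
                        study$genome, study$config)
  expect_true(all(ann_t$n_promoter_hits > 0))
})

test_that("annotation is invariant under genome reflection", {
  g <- make_genome(n_genes = 50, seed = 9, with_sequence = FALSE)
  peaks <- c(500, 5000, 20000, 33333)
  cfg <- analysis_config()
  ann <- annotate_all(tibble::tibble(coordinate = peaks), g, cfg)
  # reflect: x -> L - 1 - x, strands flip, spans mirror
  L <- g$length
  rg <- genome_model("chr", L, tibble::tibble(
    gene_id = g$genes$gene_id,
    strand = ifelse(g$genes$strand == "+", "-", "+"),
    coding_start = L - g$genes$coding_end,
    coding_end = L - g$genes$coding_start))
  ann_r <- annotate_all(tibble::tibble(coordinate = L - 1 - peaks), rg, cfg)
  expect_equal(ann_r$region_class, ann$region_class)
  expect_equal(ann_r$nearest_gene_distance, ann$nearest_gene_distance)
  expect_equal(ann_r$n_promoter_hits, ann$n_promoter_hits)
  expect_equal(ann_r$divergent, ann$divergent)
})
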