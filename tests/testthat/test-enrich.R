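# Expected counts, Fisher's exact test, and the enrichment tables.

test_that("expected counts reproduce the published formula values", {
  expect_equal(expected_count(95, 1393, 7379)$rounded, 18)
  expect_equal(expected_count(410, 1393, 7379)$rounded, 77)
  expect_equal(expected_count(424, 1393, 7379)$rounded, 80)
  expect_equal(expected_count(2812, 1393, 7379)$rounded, 531)
  expect_equal(expected_count(74, 1393, 7379)$rounded, 14)
  expect_equal(expected_count(0, 1393, 7379)$rounded, 0)
  expect_error(expected_count(5, 10, 0), "> 0")
})

test_that("expected counts round half away from zero and are linear", {
  expect_equal(round_half_away(c(2.5, 3.5, -2.5, 0.49)), c(3, 4, -3, 0))
  e1 <- expected_count(100, 500, 1000)$raw
  e2 <- expected_count(200, 500, 1000)$raw
  expect_equal(e2, 2 * e1)
  # a partition of the genome sums to near_total exactly
  sizes <- c(120, 305, 75, 500)
  expect_equal(sum(expected_count(sizes, 333, sum(sizes))$raw), 333)
})

test_that("fisher_2x2 matches brute-force hypergeometric enumeration", {
  expect_equal(fisher_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_2x2(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    n_tot <- sample(4:60, 1)
    a <- sample(0:n_tot, 1)
    b <- sample(0:(n_tot - a), 1)
    c <- sample(0:(n_tot - a - b), 1)
    d <- n_tot - a - b - c
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(fisher_2x2(a, b, c, d), brute_fisher(a, b, c, d),
                 tolerance = 1e-7)
  }
  expect_error(fisher_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("fisher_2x2 is invariant under transposition and joint row/column
           swaps", {
  set.seed(37)
  for (i in 1:25) {
    x <- sample(0:30, 4, replace = TRUE)
    if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0 ||
        (x[1] + x[3]) == 0 || (x[2] + x[4]) == 0) next
    p <- fisher_2x2(x[1], x[2], x[3], x[4])
    expect_equal(fisher_2x2(x[1], x[3], x[2], x[4]), p)  # transpose
    expect_equal(fisher_2x2(x[4], x[3], x[2], x[1]), p)  # both swapped
  }
})

test_that("category table counts distinct promoter-hit genes and its raw
           expected column sums to the near total", {
  cats <- rep(c("alpha", "beta", "gamma"), times = c(50, 30, 20))
  g <- genome_model("chr", 1e6, tibble::tibble(
    gene_id = sprintf("g%03d", 1:100), strand = "+",
    coding_start = seq(0, by = 10000, length.out = 100),
    coding_end = seq(5000, by = 10000, length.out = 100),
    category = cats))
  hit_genes <- sprintf("g%03d", c(1:15, 51:60, 81:84))
  ann <- fake_annotations(hit_genes)
  tab <- category_table(ann, g)
  expect_equal(tab$n_observed[tab$label == "Total"], length(hit_genes))
  rows <- tab[tab$label != "Total", ]
  expect_equal(sum(rows$n_expected_raw), length(hit_genes))
  # a gene hit twice still counts once
  ann2 <- fake_annotations(c(hit_genes, hit_genes[1]))
  tab2 <- category_table(ann2, g)
  expect_equal(tab2$n_observed[tab2$label == "Total"], length(hit_genes))
})

test_that("a single-category genome yields p = 1 (no contrast)", {
  g <- genome_model("chr", 1e5, tibble::tibble(
    gene_id = sprintf("g%02d", 1:20), strand = "+",
    coding_start = seq(0, by = 5000, length.out = 20),
    coding_end = seq(2000, by = 5000, length.out = 20),
    category = "only"))
  tab <- category_table(fake_annotations(sprintf("g%02d", 1:7)), g)
  expect_equal(tab$p_value[tab$label == "only"], 1)
  expect_equal(tab$n_observed[tab$label == "only"], 7)
})

test_that("with no planted enrichment the exact test is calibrated or
           conservative", {
  set.seed(41)
  cats <- sample(sprintf("c%d", 1:8), 800, replace = TRUE)
  g <- genome_model("chr", 8e6, tibble::tibble(
    gene_id = sprintf("g%04d", 1:800), strand = "+",
    coding_start = seq(0, by = 10000, length.out = 800),
    coding_end = seq(5000, by = 10000, length.out = 800),
    category = cats))
  p_all <- unlist(lapply(1:200, function(i) {
    hits <- sample(g$genes$gene_id, 150)
    tab <- category_table(fake_annotations(hits), g, with_fdr = FALSE)
    tab$p_value[tab$label != "Total"]
  }))
  expect_lte(mean(p_all < 0.05), 0.07)
})

test_that("gene-list enrichment handles degenerate and collapsed lists", {
  g <- genome_model("chr", 1e5, tibble::tibble(
    gene_id = sprintf("g%02d", 1:20), strand = "+",
    coding_start = seq(0, by = 5000, length.out = 20),
    coding_end = seq(2000, by = 5000, length.out = 20),
    category = "only"))
  ann <- fake_annotations(sprintf("g%02d", 1:7))
  # list = all genes -> no contrast
  row <- genelist_enrichment(ann, gene_list(g$genes$gene_id, "all"), g)
  expect_equal(row$p_value, 1)
  expect_equal(row$n_observed, 7)
  expect_error(genelist_enrichment(ann, gene_list(character(0), "e"), g),
               "empty")
  # operon collapsing drops downstream members before testing
  ops <- tibble::tibble(gene_id = c("g01", "g02"), operon_id = "op1",
                        operon_position = 1:2)
  row2 <- genelist_enrichment(ann, gene_list(c("g01", "g02", "g10"), "l"),
                              g, operon_map = ops)
  expect_equal(row2$n_genome, 2)  # g02 dropped
})

test_that("a strongly depleted list is detected by the two-sided test", {
  g <- genome_model("chr", 1e7, tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000), strand = "+",
    coding_start = seq(0, by = 10000, length.out = 1000),
    coding_end = seq(5000, by = 10000, length.out = 1000),
    category = "cat"))
  hits <- sprintf("g%04d", 1:400)
  disjoint <- gene_list(sprintf("g%04d", 901:1000), "cold")
  row <- genelist_enrichment(fake_annotations(hits), disjoint, g)
  expect_equal(row$n_observed, 0)
  expect_lte(row$p_value, 0.05)
})

test_that("list comparison is plain set algebra with stable ordering", {
  cmp <- compare_lists(c("g1", "g2"), c("g2", "g3"))
  expect_equal(cmp$intersection, "g2")
  expect_equal(cmp$a_only, "g1")
  expect_equal(cmp$b_only, "g3")
  expect_equal(compare_lists(c("a"), c("b"))$intersection, character(0))
  expect_equal(compare_lists(c("a"), c("a", "b"))$a_only, character(0))
})
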