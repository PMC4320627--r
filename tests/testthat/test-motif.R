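# Flank extraction, EM motif discovery, IUPAC scanning, information content
# and consensus calling.

test_that("flank extraction is centered, fixed-width and clamps at ends", {
  g <- make_genome(n_genes = 30, seed = 15)
  peaks <- tibble::tibble(coordinate = c(10, 5000, g$length - 5),
                          overall_rank = 1:3)
  fl <- extract_flanks(peaks, g, flank = 50)
  expect_true(all(nchar(fl$sequence) == 101))
  expect_true(fl$clamped[1])
  expect_false(fl$clamped[2])
  expect_true(fl$clamped[3])
  # center base of an unclamped window equals the genome base at the peak
  center <- substr(fl$sequence[2], 51, 51)
  expect_equal(center,
               as.character(Biostrings::extractAt(
                 g$sequence[[1]], IRanges::IRanges(5001, 5001))[[1]]))
  expect_error(extract_flanks(tibble::tibble(coordinate = 1e9), g, 50),
               "outside")
})

test_that("ranked partitioning preserves order and chunk sizes", {
  seqs <- tibble::tibble(overall_rank = sample(1:500),
                         sequence = sprintf("s%03d", 1:500))
  parts <- partition_ranked(seqs, top_n = 500, partition_size = 50)
  expect_length(parts, 10)
  expect_true(all(vapply(parts, nrow, integer(1)) == 50))
  expect_equal(parts[[1]]$overall_rank, 1:50)
  expect_equal(parts[[10]]$overall_rank, 451:500)
  parts2 <- partition_ranked(seqs[1:55, ], top_n = 55, partition_size = 50)
  expect_equal(vapply(parts2, nrow, integer(1)), c(`1` = 50L, `2` = 5L))
  parts3 <- partition_ranked(seqs[1:30, ], top_n = 30, partition_size = 50)
  expect_length(parts3, 1)
})

test_that("information content spans 0 to 2 bits against a uniform
           background", {
  pwm <- matrix(c(1, 0, 0, 0,
                  0.25, 0.25, 0.25, 0.25,
                  0.5, 0.5, 0, 0), nrow = 4)
  ic <- information_content(pwm)
  expect_equal(ic, c(2, 0, 1))
})

test_that("consensus calling picks the smallest covering IUPAC class", {
  col <- function(a, c, g, t) matrix(c(a, c, g, t), nrow = 4)
  expect_equal(consensus_from_pwm(col(0.02, 0.02, 0.01, 0.95), 0.8), "T")
  expect_equal(consensus_from_pwm(col(0.03, 0.5, 0.02, 0.45), 0.8), "Y")
  # the ACG class reaches 0.8 exactly: >= rule gives V, not N
  expect_equal(consensus_from_pwm(col(0.3, 0.3, 0.2, 0.2), 0.8), "V")
  expect_equal(consensus_from_pwm(col(0.3, 0.3, 0.25, 0.15), 0.9), "N")
})

test_that("a PWM from exact planted sites has 2 bits at conserved
           positions", {
  sites <- c("TGTCAAAAAAAAGAC", "TGTTCCCCCCCCAAC",
             "TGTCGGGGGGGGGAC", "TGTTTTTTTTTTAAC")
  pwm <- chipregulon:::pwm_from_sites(sites, pseudocount = 0)$pwm
  ic <- information_content(pwm)
  conserved <- c(1, 2, 3, 14, 15)  # T G T A C fixed in all four sites
  expect_equal(ic[conserved], rep(2, 5))
})

test_that("IUPAC scanning matches degenerate codes on both strands", {
  hits <- scan_iupac("TGTCAAAAAAAAGAC", MRPC_PATTERN)
  expect_equal(nrow(hits[hits$strand == "+", ]), 1)
  expect_equal(hits$offset[hits$strand == "+"], 0)
  # the reverse complement is found on the minus strand at the same window
  rc <- revcomp_chr("TGTCAAAAAAAAGAC")
  hits_rc <- scan_iupac(rc, MRPC_PATTERN)
  expect_equal(nrow(hits_rc[hits_rc$strand == "-", ]), 1)
  expect_equal(hits_rc$offset[hits_rc$strand == "-"], 0)
  expect_equal(hits_rc$matched_text[hits_rc$strand == "-"],
               "TGTCAAAAAAAAGAC")
  # one incompatible base rejects the match ('A' at a Y position)
  expect_equal(nrow(scan_iupac("TGTAAAAAAAAAGAC", MRPC_PATTERN)), 0)
  expect_error(scan_iupac("ACGT", "AXGT"), "non-IUPAC")
  # subject bases are literal: N in the sequence fails a non-N pattern
  expect_equal(nrow(scan_iupac("TGTNAAAAAAAAGAC", MRPC_PATTERN)), 0)
})

test_that("scanning a sequence and its reverse complement yields mirrored
           hit sets", {
  set.seed(19)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    pat <- "TGCRYA"
    h_fwd <- scan_iupac(s, pat)
    h_rev <- scan_iupac(revcomp_chr(s), pat)
    expect_equal(nrow(h_fwd), nrow(h_rev))
    # offsets map o -> len - w - o with the strand flipped
    mapped <- sort((300 - nchar(pat)) - h_rev$offset)
    expect_equal(sort(h_fwd$offset), mapped)
    expect_setequal(h_fwd$matched_text, h_rev$matched_text)
  }
})

test_that("EM discovery recovers a planted degenerate palindrome and its
           objective never decreases", {
  fix <- make_motif_seqs(n = 50, seed = 101)
  m <- em_discover(fix$seqs, width = 15, n_restarts = 5, rng_seed = 1)
  expect_true(consensus_matches(m$consensus_iupac))
  expect_true(all(diff(attr(m, "obj_trace")) >= -1e-6))
  expect_equal(m$width, 15)
  expect_true(all(abs(colSums(m$pwm) - 1) < 1e-9))
  expect_true(all(m$ic >= 0 & m$ic <= 2 + 1e-9))
})

test_that("EM is invariant to sequence input order for a fixed seed", {
  fix <- make_motif_seqs(n = 30, seed = 102)
  m1 <- em_discover(fix$seqs, width = 15, n_restarts = 1, rng_seed = 7)
  m2 <- em_discover(rev(fix$seqs), width = 15, n_restarts = 1, rng_seed = 7)
  expect_equal(m1$pwm, m2$pwm, tolerance = 1e-8)
  expect_equal(m1$consensus_iupac, m2$consensus_iupac)
})

test_that("uniform random sequences yield only weakly informative columns,
           well below planted-motif conservation", {
  set.seed(103)
  seqs <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, character(1))
  m <- em_discover(seqs, width = 15, n_restarts = 3, rng_seed = 2)
  # best-restart selection concentrates some noise; planted conserved
  # columns sit near 2 bits, the noise ceiling stays well under 1.5
  expect_lt(max(m$ic), 1.5)
  expect_lt(sum(m$ic), 8)
})

test_that("scanning the discovered consensus back over the training set
           recovers planted offsets", {
  fix <- make_motif_seqs(n = 200, seed = 104)
  m <- em_discover(fix$seqs, width = 15, n_restarts = 5, rng_seed = 3)
  recovered <- vapply(seq_along(fix$seqs), function(i) {
    h <- scan_iupac(fix$seqs[i], m$consensus_iupac)
    fix$offsets[i] %in% h$offset
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("motif objects expose tidy/glance views and MEME text output", {
  fix <- make_motif_seqs(n = 30, seed = 105)
  m <- em_discover(fix$seqs, width = 15, n_restarts = 2, rng_seed = 4)
  td <- tidy(m)
  expect_equal(nrow(td), 4 * 15)
  expect_equal(unique(td$position), 1:15)
  gl <- glance(m)
  expect_equal(gl$width, 15)
  expect_true(is.finite(gl$log_likelihood))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(m, path)
  lines <- readLines(path)
  expect_true(any(grepl("^MOTIF", lines)))
  expect_true(any(grepl("letter-probability matrix", lines)))
  expect_length(grep("^[0-9.]+ ", lines), 15)
})

test_that("sequences shorter than the width are rejected", {
  expect_error(em_discover(c("ACGTACGT", "ACG"), width = 6), "at least")
  expect_error(em_discover("ACGTACGTAC", width = 3), ">= 4")
})
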