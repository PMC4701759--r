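# Pairwise identity, concatenated arrays, intergenic layout, direct repeats.

linear_scoring <- list(match = 2, mismatch = -1, gap_open = 0,
                       gap_extend = 2)

test_that("identity of simple pairs matches hand-derived values", {
  r <- align_identity("ACGTACGT", "ACGTACGT")
  expect_equal(r$identity_pct, 100)
  expect_equal(r$alignment_length, 8L)
  # one terminal mismatch out of four columns
  r2 <- align_identity("ACGT", "ACGA",
                       scoring = list(match = 1, mismatch = -1,
                                      gap_open = 0, gap_extend = 2))
  expect_equal(r2$identity_pct, 75)
  expect_identical(r2$aligned_a, "ACGT")
  expect_identical(r2$aligned_b, "ACGA")
  expect_error(align_identity("", "ACGT"), "empty")
})

test_that("global alignment equals exhaustive enumeration on short strings", {
  set.seed(101)
  for (rep in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1),
                      replace = TRUE), collapse = "")
    r <- align_identity(a, b, mode = "global", scoring = linear_scoring)
    oracle <- enumerate_global_alignments(a, b, 2, -1, 2)
    expect_equal(r$score, oracle$score)
    expect_true(any(abs(r$identity_pct - oracle$identity_pcts) < 1e-9))
  }
})

test_that("local alignment score equals exhaustive segment enumeration", {
  set.seed(103)
  for (rep in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
               collapse = "")
    r <- align_identity(a, b, mode = "local", scoring = linear_scoring)
    expect_equal(r$score, enumerate_local_score(a, b, 2, -1, 2))
  }
})

test_that("identity is symmetric in its arguments", {
  set.seed(107)
  for (rep in 1:8) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1),
                      replace = TRUE), collapse = "")
    for (mode in c("global", "local")) {
      expect_equal(align_identity(a, b, mode)$identity_pct,
                   align_identity(b, a, mode)$identity_pct)
    }
  }
})

test_that("protein alignment uses BLOSUM62 defaults", {
  r <- align_identity("MKWVTFISLLFLFSSAYS", "MKWVTFISLLFLFSSAYS",
                      type = "protein")
  expect_equal(r$identity_pct, 100)
  # conservative substitution still aligns without gaps
  r2 <- align_identity("MKWVTFISLL", "MKWVTYISLL", type = "protein")
  expect_equal(r2$alignment_length, 10L)
  expect_equal(r2$identities, 9L)
})

test_that("concatenated-array identity equals aligning the concatenation", {
  p1 <- c("ACGTACGAAT", "ACGTACGAAT")
  p2 <- c("TTGCACCA", "TTGCACGA")
  r <- concat_identity(list(p1, p2), mode = "global")
  direct <- align_identity(paste0(p1[1], p2[1]), paste0(p1[2], p2[2]),
                           mode = "global")
  expect_equal(r$identity_pct, direct$identity_pct)
  expect_equal(r$score, direct$score)
  # single pair reduces to align_identity; identical pairs give 100%
  expect_equal(concat_identity(list(p1))$identity_pct,
               align_identity(p1[1], p1[2])$identity_pct)
  expect_equal(concat_identity(list(c("ACGT", "ACGT"),
                                    c("GGCC", "GGCC")))$identity_pct, 100)
  expect_error(concat_identity(list()), "at least one")
})

test_that("intergenic layout reports gaps, adjacency and overlap", {
  arr <- gene_array(data.frame(
    locus_tag = c("g1", "g2", "g3", "g4"),
    start = c(1L, 11L, 18L, 40L),
    end = c(10L, 17L, 30L, 50L),
    strand = c("+", "+", "-", "+")))
  lay <- intergenic_layout(arr)
  expect_identical(lay$gap_bp, c(0L, 0L, 9L))
  over <- gene_array(data.frame(locus_tag = c("a", "b"),
                                start = c(1L, 8L), end = c(10L, 20L),
                                strand = "+"))
  expect_identical(intergenic_layout(over)$gap_bp, -3L)
})

test_that("ORF lengths plus gaps plus flanks add to the sequence length", {
  set.seed(109)
  for (rep in 1:6) {
    n_orf <- sample(2:6, 1)
    starts <- sort(sample(5:400, n_orf))
    ends <- starts + sample(10:40, n_orf, replace = TRUE)
    # enforce non-overlap for the bookkeeping identity
    for (i in seq_len(n_orf - 1))
      ends[i] <- min(ends[i], starts[i + 1] - 1)
    L <- max(ends) + sample(0:20, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    arr <- gene_array(data.frame(locus_tag = paste0("g", 1:n_orf),
                                 start = starts, end = ends, strand = "+"),
                      sequence = seq)
    lay <- intergenic_layout(arr)
    left_flank <- starts[1] - 1
    right_flank <- L - ends[n_orf]
    expect_equal(sum(ends - starts + 1) + sum(lay$gap_bp) +
                   left_flank + right_flank, L)
  }
})

test_that("minus-strand ORFs are reverse-complemented on extraction", {
  seqn <- "AAATTTGGGCCC"
  arr <- gene_array(data.frame(locus_tag = c("f", "r"),
                               start = c(1L, 7L), end = c(6L, 12L),
                               strand = c("+", "-")), sequence = seqn)
  expect_identical(orf_sequence(arr, "f"), "AAATTT")
  expect_identical(orf_sequence(arr, "r"), "GGGCCC")  # revcomp of GGGCCC
})

test_that("direct repeats match hand enumeration on small cases", {
  r <- find_direct_repeats("ACGTACGT", min_len = 4)
  expect_equal(nrow(r), 1L)
  expect_equal(unlist(r[1, c("pos1", "pos2", "length")], use.names = FALSE),
               c(1L, 5L, 4L))
  # homopolymer: overlapping candidates collapse to the maximal
  # non-overlapping pair
  r2 <- find_direct_repeats("AAAAAA", min_len = 3)
  expect_equal(nrow(r2), 1L)
  expect_equal(unlist(r2[1, c("pos1", "pos2", "length")],
                      use.names = FALSE), c(1L, 4L, 3L))
  expect_equal(nrow(find_direct_repeats("ACGTGCTA", min_len = 4)), 0L)
})

test_that("direct repeats equal the brute-force scan on random sequences", {
  set.seed(113)
  for (rep in 1:8) {
    n <- sample(30:120, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    mm <- sample(0:1, 1)
    got <- find_direct_repeats(s, min_len = 5, max_mismatch = mm)
    want <- bf_direct_repeats(s, min_len = 5, max_mismatch = mm)
    expect_equal(got, want)
  }
  # a planted distant repeat in a 200-mer is recovered
  set.seed(127)
  core <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE),
                collapse = "")
  s <- paste0(paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                    collapse = ""), core,
              paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = ""), core,
              paste(sample(c("A", "C", "G", "T"), 32, replace = TRUE),
                    collapse = ""))
  got <- find_direct_repeats(s, min_len = 12)
  want <- bf_direct_repeats(s, min_len = 12)
  expect_equal(got, want)
  expect_true(any(got$length >= 14))
})

test_that("a shuffled 125-mer rarely contains long exact repeats", {
  set.seed(131)
  hits <- vapply(1:10, function(k) {
    s <- paste(sample(c("A", "C", "G", "T"), 125, replace = TRUE),
               collapse = "")
    nrow(find_direct_repeats(s, min_len = 8))
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.3)
})
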