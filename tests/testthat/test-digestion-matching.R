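# Tryptic digestion, peptide matching, coverage, filters, refined search,
# group aggregation.

test_that("tryptic digestion applies the K/R-not-before-P rule", {
  expect_identical(tryptic_digest("AAAA")$peptide, "AAAA")
  # KP suppression: the K before P is not a cleavage site
  expect_identical(tryptic_digest("AKPAKG")$peptide, c("AKPAK", "G"))
  d <- tryptic_digest("MKRAAAKPGGGR", min_len = 1, max_missed = 1)
  zero <- d[d$missed == 0, ]
  expect_identical(zero$peptide, c("MK", "R", "AAAKPGGGR"))
  # missed-cleavage combinations join adjacent fragments
  expect_true("MKR" %in% d$peptide)
  expect_true("RAAAKPGGGR" %in% d$peptide)
})

test_that("zero-missed peptides partition the sequence", {
  set.seed(5)
  for (k in 1:25) {
    s <- random_aa(sample(10:200, 1))
    d <- tryptic_digest(s, min_len = 1, max_missed = 0)
    expect_identical(paste(d$peptide, collapse = ""), s)
    expect_identical(d$start[1], 1L)
    expect_identical(d$end[nrow(d)], nchar(s))
  }
  expect_equal(nrow(tryptic_digest("")), 0L)
})

test_that("min_len drops short peptides without breaking positions", {
  d <- tryptic_digest("MKRAAAAAAK", min_len = 6)
  expect_identical(d$peptide, "AAAAAAK")
  expect_identical(d$start, 4L)
  expect_identical(d$end, 10L)
})

test_that("peptide matching equals a brute-force substring scan", {
  set.seed(13)
  for (rep in 1:5) {
    db <- make_db(vapply(rep(60, 12), random_aa, character(1)))
    # draw peptides from real proteins plus decoys that match nothing
    pool <- unlist(lapply(db$sequence, function(s) {
      st <- sample(1:40, 6)
      substring(s, st, st + sample(6:12, 6, replace = TRUE))
    }))
    pool <- c(pool, vapply(rep(15, 8), random_aa, character(1)))
    ev <- evidence_table(
      peptide = sample(pool, 120, replace = TRUE),
      dataset_id = sample(c("D", "E", "F", "G"), 120, replace = TRUE),
      confidence = sample(c(0.99, 0.5), 120, replace = TRUE),
      dataset_ids = c("D", "E", "F", "G")
    )
    dm <- map_peptides(ev, db)
    expect_identical(dm$counts, bf_detection_counts(ev, db))
    # totals are unions over data sets
    for (p in dm$proteins) {
      u <- unique(unlist(dm$peptides[[p]]))
      expect_equal(dm$total_unique[[p]], length(u))
    }
  }
})

test_that("shared peptides credit every containing protein and are flagged", {
  db <- make_db(c("AAACCCGGGTTTWWW", "CCCGGG", "WWWYYY"))
  ev <- evidence_table(c("CCCGGG", "WWW"), c("D", "D"),
                       dataset_ids = c("D", "E"))
  dm <- map_peptides(ev, db)
  expect_equal(dm$counts["P001", "D"], 2L)
  expect_equal(dm$counts["P002", "D"], 1L)
  expect_equal(dm$counts["P003", "D"], 1L)
  expect_setequal(dm$shared_peptides, c("CCCGGG", "WWW"))
})

test_that("unmatched peptides go to the pool, empty evidence gives zeros", {
  db <- make_db(c("AAACCC", "GGGTTT"))
  ev <- evidence_table(c("AAA", "YYYYY"), c("D", "E"),
                       dataset_ids = c("D", "E"))
  dm <- map_peptides(ev, db)
  expect_identical(dm$unmatched$peptide, "YYYYY")
  ev0 <- evidence_table(character(0), character(0),
                        dataset_ids = c("D", "E"))
  dm0 <- map_peptides(ev0, db)
  expect_true(all(dm0$counts == 0L))
  expect_true(all(dm0$coverage_pct == 0))
})

test_that("low-confidence rows are excluded from counting", {
  db <- make_db(c("AAACCCGGG"))
  ev <- evidence_table(c("AAA", "CCC"), c("D", "D"),
                       confidence = c(0.99, 0.80),
                       dataset_ids = "D")
  dm <- map_peptides(ev, db)
  expect_equal(dm$counts["P001", "D"], 1L)
})

test_that("coverage is the union of all peptide occurrence intervals", {
  set.seed(3)
  s <- random_aa(100)
  p1 <- substr(s, 1, 10)
  p2 <- substr(s, 6, 20)
  expect_equal(compute_coverage(s, c(p1, p2)), 20)  # [1,10] u [6,20]
  expect_equal(compute_coverage(s, s), 100)
  expect_error(compute_coverage(s, "ZZZZZ"), "not a substring")
  expect_identical(format_pep_cov(2, 5.2), "2/5")
})

test_that("coverage is monotone in the matched-peptide set", {
  set.seed(9)
  s <- random_aa(150)
  st <- sort(sample(1:120, 8))
  peps <- substring(s, st, st + 14)
  covs <- vapply(seq_along(peps), function(k)
    compute_coverage(s, peps[seq_len(k)]), numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("stringent filter needs >=2 peptides in one data set", {
  db <- make_db(c("AACCAACC", "GGTTGGTT", "MMHHMMHH"))
  # P001: one peptide in each of 4 sets; P002: two in one set; P003: none
  ev <- evidence_table(
    peptide = c("AACC", "ACCA", "CCAA", "CAAC", "GGTT", "TTGG"),
    dataset_id = c("D", "E", "F", "G", "D", "D"),
    dataset_ids = c("D", "E", "F", "G")
  )
  dm <- map_peptides(ev, db)
  expect_equal(dm$counts["P001", ], c(D = 1L, E = 1L, F = 1L, G = 1L))
  stringent <- apply_detection_filter(dm, "stringent")
  relaxed <- apply_detection_filter(dm, "relaxed")
  expect_false("P001" %in% stringent)   # (1,1,1,1) fails stringent
  expect_true("P001" %in% relaxed)
  expect_true("P002" %in% stringent)    # (2,0,0,0) passes both
  expect_true("P002" %in% relaxed)
  expect_false("P003" %in% relaxed)     # (0,0,0,0) fails both
  expect_error(apply_detection_filter(dm, "bogus"))
})

test_that("stringent set is a subset of relaxed on random matrices", {
  set.seed(17)
  for (rep in 1:10) {
    db <- make_db(vapply(rep(50, 8), random_aa, character(1)))
    pool <- unlist(lapply(db$sequence, sample_peptides, k = 4))
    n <- 60
    ev <- evidence_table(sample(pool, n, replace = TRUE),
                         sample(c("D", "E", "F", "G"), n, replace = TRUE),
                         dataset_ids = c("D", "E", "F", "G"))
    dm <- map_peptides(ev, db)
    expect_true(all(apply_detection_filter(dm, "stringent") %in%
                      apply_detection_filter(dm, "relaxed")))
  }
})

test_that("refined search finds planted peptides and never loses counts", {
  set.seed(23)
  old_db <- make_db(vapply(rep(60, 5), random_aa, character(1)))
  new_db <- make_db(vapply(rep(60, 3), random_aa, character(1)),
                    prefix = "N")
  planted <- substring(new_db$sequence[1], c(1, 12, 25, 33, 44),
                       c(9, 20, 32, 41, 52))
  known <- substring(old_db$sequence[2], c(1, 15), c(10, 24))
  ev <- evidence_table(c(known, planted),
                       rep(c("D", "E"), length.out = 7),
                       dataset_ids = c("D", "E"))
  dm <- map_peptides(ev, old_db)
  expect_equal(sort(unique(dm$unmatched$peptide)), sort(unique(planted)))
  rs <- refined_search(dm, new_db)
  expect_setequal(unique(rs$new_peptides$peptide), unique(planted))
  expect_true(all(rs$new_peptides$locus_tag %in% new_db$locus_tag))
  # previously matched counts never decrease
  expect_true(all(rs$matrix$counts[old_db$locus_tag, ] >= dm$counts))
  expect_gte(sum(rs$matrix$counts), sum(dm$counts))
  # empty augmentation changes nothing
  rs0 <- refined_search(dm, make_db(character(0)))
  expect_identical(rs0$matrix$counts, dm$counts)
  expect_equal(nrow(rs0$new_peptides), 0L)
})

test_that("refined search is monotone on random fixtures", {
  set.seed(31)
  for (rep in 1:5) {
    db <- make_db(vapply(rep(50, 6), random_aa, character(1)))
    extra <- make_db(vapply(rep(50, 3), random_aa, character(1)),
                     prefix = "N")
    pool <- c(
      unlist(lapply(db$sequence, function(s) substr(s, 3, 12))),
      unlist(lapply(extra$sequence, function(s) substr(s, 5, 16))),
      vapply(rep(11, 4), random_aa, character(1))
    )
    ev <- evidence_table(sample(pool, 30, replace = TRUE),
                         sample(c("D", "E"), 30, replace = TRUE),
                         dataset_ids = c("D", "E"))
    dm <- map_peptides(ev, db)
    rs <- refined_search(dm, extra)
    expect_gte(sum(rs$matrix$counts), sum(dm$counts))
    expect_true(all(rs$matrix$counts[db$locus_tag, ] >= dm$counts))
  }
})

test_that("group aggregation unions member peptides", {
  db <- make_db(c("AAAACCCCKGGGG", "AAAACCCCKWWWW", "MMMMHHHH"))
  ev <- evidence_table(c("AAAACCCCK", "GGGG", "WWWW", "MMMM"),
                       c("D", "D", "D", "E"),
                       dataset_ids = c("D", "E"))
  dm <- map_peptides(ev, db)
  groups <- data.frame(group_id = c("g1", "g1", "P003"),
                       locus_tag = c("P001", "P002", "P003"),
                       representative = c(TRUE, FALSE, TRUE))
  agg <- aggregate_by_group(dm, groups)
  # shared peptide counted once, member-specific ones added
  expect_equal(agg$counts["g1", "D"], 3L)
  expect_equal(agg$counts["P003", "E"], 1L)
  # group count bounded by member counts
  expect_gte(agg$counts["g1", "D"], max(dm$counts[c("P001", "P002"), "D"]))
  expect_lte(agg$counts["g1", "D"], sum(dm$counts[c("P001", "P002"), "D"]))
  bad <- rbind(groups, data.frame(group_id = "g2", locus_tag = "P001",
                                  representative = TRUE))
  expect_error(aggregate_by_group(dm, bad), "more than one group")
})

test_that("singleton groups reproduce the input matrix, random unions match", {
  set.seed(41)
  db <- make_db(vapply(rep(50, 6), random_aa, character(1)))
  pool <- unlist(lapply(db$sequence, sample_peptides, k = 5))
  ev <- evidence_table(sample(pool, 40, replace = TRUE),
                       sample(c("D", "E", "F"), 40, replace = TRUE),
                       dataset_ids = c("D", "E", "F"))
  dm <- map_peptides(ev, db)
  singles <- data.frame(group_id = db$locus_tag, locus_tag = db$locus_tag,
                        representative = TRUE)
  agg1 <- aggregate_by_group(dm, singles)
  expect_identical(agg1$counts, dm$counts)
  expect_equal(agg1$coverage_pct, dm$coverage_pct)
  # random grouping equals brute-force union of member peptides
  gid <- sample(c("gA", "gB"), 6, replace = TRUE)
  groups <- data.frame(group_id = gid, locus_tag = db$locus_tag,
                       representative = !duplicated(gid))
  agg2 <- aggregate_by_group(dm, groups)
  for (g in unique(gid)) {
    members <- db$locus_tag[gid == g]
    for (d in dm$datasets) {
      u <- unique(unlist(lapply(members, function(m) dm$peptides[[m]][[d]])))
      expect_equal(agg2$counts[g, d], length(u))
    }
  }
})
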