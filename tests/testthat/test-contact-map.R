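test_that("fixture contact maps carry the published NF1 counts", {
  fx <- nf1_fixture_paths()
  h <- read_contact_map(fx[["hindiii_map"]])
  n <- read_contact_map(fx[["ncoi_map"]])

  expect_equal(h$enzyme_label, "HindIII")
  expect_equal(h$bin_size, 1e6)
  expect_equal(contact_count(h, "chr17", 29, "chr17", 28), 703)
  expect_equal(contact_count(h, "chr17", 28, "chr17", 29), 703)  # symmetry
  expect_equal(contact_count(n, "chr17", 29, "chr17", 28), 255)
  expect_equal(contact_count(n, "chr17", 29, "chr1", 0), 21)
  expect_equal(contact_count(n, "chr17", 29, "chr17", 50), 0)    # missing pair
})

test_that("contact map I/O round-trips and rejects malformed input", {
  # header-only file -> empty map
  empty_path <- tempfile(fileext = ".tsv")
  writeLines(c("# enzyme_label=e", "# bin_size=1000000",
               "chromA\tbinA\tchromB\tbinB\tcount"), empty_path)
  empty <- read_contact_map(empty_path)
  expect_equal(nrow(empty$entries), 0)
  expect_equal(empty$bin_size, 1e6)

  # random maps round-trip exactly and serialise deterministically
  for (seed in 1:20) {
    set.seed(seed)
    m <- random_contact_map()
    p1 <- tempfile(); p2 <- tempfile()
    write_contact_map(m, p1)
    back <- read_contact_map(p1)
    expect_equal(back$entries, m$entries)
    expect_equal(back$bin_size, m$bin_size)
    write_contact_map(back, p2)
    expect_identical(readLines(p1), readLines(p2))
  }

  bad <- tempfile()
  writeLines(c("chromA\tbinA\tchromB\tbinB\tcount", "c1\t1\tc1\t2"), bad)
  expect_error(read_contact_map(bad), "line 2", class = "regscout_parse_error")
  writeLines(c("chromA\tbinA\tchromB\tbinB\tcount", "c1\t1\tc1\t2\t-4"), bad)
  expect_error(read_contact_map(bad), class = "regscout_parse_error")
  writeLines(c("chromA\tbinA\tchromB\tbinB\tcount", "c1\tx\tc1\t2\t4"), bad)
  expect_error(read_contact_map(bad), class = "regscout_parse_error")

  # both orientations with different counts -> inconsistent
  asym <- tempfile()
  writeLines(c("chromA\tbinA\tchromB\tbinB\tcount",
               "c1\t1\tc1\t2\t5", "c1\t2\tc1\t1\t7"), asym)
  expect_error(read_contact_map(asym), class = "regscout_consistency_error")
  # ... and with equal counts -> one stored pair
  writeLines(c("chromA\tbinA\tchromB\tbinB\tcount",
               "c1\t1\tc1\t2\t5", "c1\t2\tc1\t1\t5"), asym)
  expect_equal(nrow(read_contact_map(asym)$entries), 1)
})

test_that("stored pairs are symmetric under an exhaustive lookup sweep", {
  fx <- nf1_fixture_paths()
  for (path in fx[c("hindiii_map", "ncoi_map")]) {
    m <- read_contact_map(path)
    e <- m$entries
    for (i in seq_len(nrow(e))) {
      expect_equal(contact_count(m, e$chromA[i], e$binA[i], e$chromB[i], e$binB[i]),
                   contact_count(m, e$chromB[i], e$binB[i], e$chromA[i], e$binA[i]))
    }
    expect_true(all(e$count >= 0))
  }
})

test_that("rank_partners reproduces the NF1 ranking and matches brute force", {
  fx <- nf1_fixture_paths()
  h <- read_contact_map(fx[["hindiii_map"]])
  anchor <- nf1_anchor()

  r <- rank_partners(h, anchor, scope = "intra")
  expect_equal(r$index, c(28, 31, 32))
  expect_equal(r$count, c(703, 222, 59))
  expect_true(all(diff(r$count) <= 0))
  expect_false(any(r$chrom == anchor$chrom & r$index == anchor$index))

  # empty map -> empty ranking
  expect_equal(nrow(rank_partners(contact_map(), bin_of_position("c1", 5, 1e6))), 0)

  # bin-size mismatch
  expect_error(rank_partners(h, bin_of_position("chr17", 29421945, 1e5)),
               class = "regscout_incompatible_resolution")

  for (seed in 1:20) {
    set.seed(seed)
    m <- random_contact_map()
    a <- data.frame(chrom = "c1", index = sample(0:5, 1), bin_size = 10)
    for (sc in c("intra", "inter", "all")) {
      got <- ranking_df(rank_partners(m, a, scope = sc))
      expect_equal(got, oracle_rank(m, a, sc), info = sprintf("seed %d scope %s", seed, sc))
    }
    # scope=all is the re-sorted merge of intra and inter
    merged <- rbind(ranking_df(rank_partners(m, a, "intra")),
                    ranking_df(rank_partners(m, a, "inter")))
    merged <- merged[order(-merged$count, merged$chrom, merged$index), ]
    rownames(merged) <- NULL
    expect_equal(ranking_df(rank_partners(m, a, "all")), merged)
  }
})

test_that("consensus partner ordering favours multi-map support then best rank", {
  fx <- nf1_fixture_paths()
  anchor <- nf1_anchor()
  rh <- rank_partners(read_contact_map(fx[["hindiii_map"]]), anchor, "intra")
  rn <- rank_partners(read_contact_map(fx[["ncoi_map"]]), anchor, "intra")

  cons <- consensus_top_partners(list(rh, rn), k = 2)
  expect_equal(cons$index[1:2], c(28, 31))     # both in both maps' top-2
  expect_equal(cons$n_maps[1:2], c(2, 2))

  # single ranking, k = 1 -> that ranking's top bin
  expect_equal(consensus_top_partners(list(rh), k = 1)$index, 28)

  # mixed anchors rejected
  r_other <- rank_partners(read_contact_map(fx[["hindiii_map"]]),
                           bin_of_position("chr17", 28500000, 1e6), "intra")
  expect_error(consensus_top_partners(list(rh, r_other), k = 1),
               class = "regscout_input_error")

  # random rankings vs exhaustive enumeration over the union of top-k sets
  for (seed in 1:10) {
    set.seed(seed)
    a <- data.frame(chrom = "c1", index = 2L, bin_size = 10)
    maps <- list(random_contact_map(), random_contact_map())
    rks <- lapply(maps, rank_partners, anchor = a, scope = "all")
    k <- 3
    got <- consensus_top_partners(rks, k)
    tops <- lapply(rks, function(r) utils::head(as.data.frame(r), k))
    union_bins <- unique(do.call(rbind, lapply(tops, `[`, c("chrom", "index"))))
    if (nrow(union_bins) == 0) {
      expect_equal(nrow(got), 0)
      next
    }
    exp_stats <- do.call(rbind, lapply(seq_len(nrow(union_bins)), function(i) {
      ranks <- vapply(tops, function(t) {
        w <- which(t$chrom == union_bins$chrom[i] & t$index == union_bins$index[i])
        if (length(w)) w[1] else NA_integer_
      }, integer(1))
      data.frame(chrom = union_bins$chrom[i], index = union_bins$index[i],
                 n_maps = sum(!is.na(ranks)), best_rank = min(ranks, na.rm = TRUE))
    }))
    exp_stats <- exp_stats[order(-exp_stats$n_maps, exp_stats$best_rank,
                                 exp_stats$chrom, exp_stats$index), ]
    rownames(exp_stats) <- NULL
    expect_equal(got, exp_stats)
  }
})
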