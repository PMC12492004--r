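test_that("anchor ranking numbers paired anchors 0..k-1 with deterministic ties", {
  map <- permMap(0:4)
  r <- rankAnchors(map)
  expect_equal(sort(r$ref_rank), 0:4)
  expect_equal(r$query_rank[order(r$ref_rank)], 0:4)

  # an unpaired gene interleaved among paired ones occupies no rank
  chroms <- data.frame(name = "c1", length = 10000L)
  ref <- AnchorSet("R", chroms,
    data.frame(gene_id = sprintf("r%d", 1:6), chrom = "c1",
               start = (1:6) * 100L, end = (1:6) * 100L + 10L,
               strand = "+"))
  qry <- AnchorSet("Q", chroms,
    data.frame(gene_id = sprintf("q%d", 1:5), chrom = "c1",
               start = (1:5) * 100L, end = (1:5) * 100L + 10L,
               strand = "+"))
  map2 <- makeHomologyMap(ref, qry,
    data.frame(ref_id = sprintf("r%d", c(1, 2, 4, 5, 6)),
               query_id = sprintf("q%d", 1:5)))
  r2 <- rankAnchors(map2)
  expect_equal(sort(r2$ref_rank), 0:4)

  # identical midpoints: order by start then gene_id
  ref3 <- AnchorSet("R", chroms,
    data.frame(gene_id = c("b", "a"), chrom = "c1",
               start = c(100L, 90L), end = c(120L, 130L), strand = "+"))
  qry3 <- AnchorSet("Q", chroms,
    data.frame(gene_id = c("x", "y"), chrom = "c1",
               start = c(100L, 200L), end = c(110L, 210L), strand = "+"))
  map3 <- makeHomologyMap(ref3, qry3,
    data.frame(ref_id = c("a", "b"), query_id = c("x", "y")))
  r3 <- rankAnchors(map3)
  expect_equal(r3$ref_rank[r3$ref_id == "a"], 0L)  # smaller start wins
  expect_equal(r3$ref_rank[r3$ref_id == "b"], 1L)
})

test_that("chainBlocks reproduces the worked run-segmentation examples", {
  # identity permutation -> one forward block
  b <- chainBlocks(rankAnchors(permMap(0:9)), maxGap = 1,
                   minBlockAnchors = 3)
  expect_equal(nrow(b), 1L)
  expect_equal(b$orientation, "+")
  expect_equal(b$n_anchors, 10L)

  # 0,1,2,6,5,4,3,7,8,9 -> three blocks (+3, -4, +3)
  map <- permMap(c(0, 1, 2, 6, 5, 4, 3, 7, 8, 9))
  b2 <- chainBlocks(rankAnchors(map), maxGap = 1, minBlockAnchors = 3)
  expect_equal(b2$orientation, c("+", "-", "+"))
  expect_equal(b2$n_anchors, c(3L, 4L, 3L))

  # same input, minimum 5 anchors -> nothing retained, all 10 orphaned
  b3 <- chainBlocks(rankAnchors(map), maxGap = 1, minBlockAnchors = 5)
  expect_equal(nrow(b3), 0L)
  expect_equal(nrow(attr(b3, "residues")), 10L)

  expect_error(chainBlocks(rankAnchors(map), maxGap = 0), "maxGap")
  expect_error(chainBlocks(rankAnchors(map), minBlockAnchors = 1),
               "minBlockAnchors")
})

test_that("blocks partition their anchors and never overlap", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    ranked <- rankAnchors(permMap(sample(n) - 1L))
    blocks <- chainBlocks(ranked, maxGap = sample(1:3, 1),
                          minBlockAnchors = 2)
    ids <- unlist(strsplit(blocks$anchor_ids, ","))
    expect_equal(anyDuplicated(ids), 0L)
    expect_true(all(ids %in% ranked$ref_id))
    expect_equal(length(ids) + nrow(attr(blocks, "residues")), n)
  }
})

test_that("chaining agrees with the brute-force maximal-run oracle", {
  # the direct ranked-frame builder matches the full construction path
  p0 <- c(0, 3, 1, 2, 4)
  expect_equal(rankAnchors(permMap(p0)), rankedFromPerm(p0))

  # exhaustive over all permutations of up to 6 anchors, two gap settings
  for (n in 2:6) {
    for (perm in allPerms(n)) {
      for (gap in c(1L, 2L)) {
        runs <- karyotypeR:::.chainRuns(rankedFromPerm(perm - 1L), gap)
        oracle <- oracleRuns(perm - 1L, gap)
        expect_equal(lapply(runs, function(r) sort(r$rows)),
                     lapply(oracle, function(r) sort(r$members)))
        expect_equal(vapply(runs, `[[`, "", "orientation"),
                     vapply(oracle, `[[`, "", "orientation"))
      }
    }
  }
  # seeded random sample at n = 8
  set.seed(7)
  for (rep in 1:100) {
    perm <- sample(8L) - 1L
    gap <- sample(1:3, 1)
    runs <- karyotypeR:::.chainRuns(rankedFromPerm(perm), gap)
    oracle <- oracleRuns(perm, gap)
    expect_equal(lapply(runs, function(r) sort(r$rows)),
                 lapply(oracle, function(r) sort(r$members)))
  }
})

test_that("reversing a query chromosome flips orientations but not the partition", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(12:30, 1)
    map <- permMap(sample(n) - 1L)
    b <- chainBlocks(rankAnchors(map), maxGap = 2, minBlockAnchors = 2)
    fl <- flipQueryChrom(map, "c1")
    b2 <- chainBlocks(rankAnchors(fl), maxGap = 2, minBlockAnchors = 2)
    expect_equal(b2$anchor_ids, b$anchor_ids)
    expect_equal(b2$n_anchors, b$n_anchors)
    expect_equal(b2$orientation, chartr("+-", "-+", b$orientation))
  }
})

test_that("raising maxGap never increases the number of maximal runs", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(8:60, 1)
    ranked <- rankedFromPerm(sample(n) - 1L)
    counts <- vapply(1:5, function(g)
      length(karyotypeR:::.chainRuns(ranked, g)), 0L)
    expect_true(all(diff(counts) <= 0L))
  }
})
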