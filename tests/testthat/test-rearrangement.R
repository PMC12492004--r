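test_that("classification separates collinear, inversion and translocated blocks", {
  # identity genome: everything collinear
  map <- permMap(0:9)
  calls <- classifyCalls(chainBlocks(rankAnchors(map), maxGap = 1,
                                     minBlockAnchors = 3), map)
  expect_true(all(calls$call_type == "collinear"))

  # internal reversed segment: dominant orientation is +, middle block
  # called an inversion
  map2 <- permMap(c(0, 1, 2, 6, 5, 4, 3, 7, 8, 9))
  calls2 <- classifyCalls(chainBlocks(rankAnchors(map2), maxGap = 1,
                                      minBlockAnchors = 3), map2)
  expect_equal(calls2$call_type, c("collinear", "inversion", "collinear"))
  expect_equal(calls2$span_bp, calls2$ref_end - calls2$ref_start + 1L)

  # 95 anchors to the plurality partner chrA, 5 to chrB: the chrB block is
  # a translocation/insertion
  n <- 100L
  qchrom <- rep(c("chrA", "chrB", "chrA"), c(40L, 5L, 55L))
  qrank <- c(0:39, 0:4, 40:94)
  map3 <- rankMap(rep("chr1", n), qchrom, qrank)
  calls3 <- classifyCalls(chainBlocks(rankAnchors(map3), maxGap = 1,
                                      minBlockAnchors = 3), map3)
  expect_equal(calls3$call_type[calls3$query_chrom == "chrB"],
               "translocation_insertion")
  expect_true(all(calls3$call_type[calls3$query_chrom == "chrA"] ==
                  "collinear"))

  map11 <- permMap(0:10)
  expect_error(classifyCalls(chainBlocks(rankAnchors(map11), maxGap = 1,
                                         minBlockAnchors = 3), map),
               "absent")
})

test_that("macro-inversion filtering respects the span threshold", {
  calls <- data.frame(
    call_id = c("C1", "C2", "C3"),
    call_type = c("inversion", "inversion", "collinear"),
    block_id = c("B1", "B2", "B3"), ref_chrom = "c1",
    ref_start = c(1L, 1L, 1L),
    ref_end = c(2000000L, 500000L, 5000000L),
    query_chrom = "c1", query_start = 1L, query_end = 2L,
    orientation = "-", n_anchors = 5L,
    span_bp = c(2000000L, 500000L, 5000000L), macro_flag = FALSE,
    stringsAsFactors = FALSE)
  macro <- detectMacroInversions(calls, minSpanBp = 1000000)
  expect_equal(macro$call_id, "C1")
  expect_true(all(macro$macro_flag))
  expect_equal(nrow(detectMacroInversions(calls[3, ], 1000000)), 0L)
  expect_error(detectMacroInversions(calls, minSpanBp = 0), "positive")
})

test_that("chromosome correspondence flags fusion- and fission-like patterns", {
  # bijective: everything one-to-one
  corr <- chromosomeCorrespondence(permMap(0:9), 0.2)
  expect_true(all(corr$refEvents$one_to_one))
  expect_false(any(corr$refEvents$fission_like))
  expect_false(any(corr$queryEvents$fusion_like))

  # ref chr1 + chr2 each send ~50% of query chrA's anchors -> fusion-like
  mapF <- rankMap(rep(c("chr1", "chr2"), each = 10L),
                  rep("chrA", 20L), c(0:9, 10:19))
  corrF <- chromosomeCorrespondence(mapF, 0.2)
  expect_true(corrF$queryEvents$fusion_like[
    corrF$queryEvents$query_chrom == "chrA"])
  expect_false(any(corrF$refEvents$fission_like))

  # ref chr1 splits 60/40 over chrA/chrB -> fission-like at threshold 0.2
  mapS <- rankMap(rep("chr1", 10L),
                  rep(c("chrA", "chrB"), c(6L, 4L)), c(0:5, 0:3))
  corrS <- chromosomeCorrespondence(mapS, 0.2)
  expect_true(corrS$refEvents$fission_like[
    corrS$refEvents$ref_chrom == "chr1"])

  # fractions per ref chromosome sum to one
  expect_equal(as.numeric(tapply(corrS$table$ref_fraction,
                                 corrS$table$ref_chrom, sum)), 1)
  expect_error(chromosomeCorrespondence(mapS, 0.6), "0.5")
  expect_error(chromosomeCorrespondence(mapS, 0), "0.5")
})

test_that("rearrangement index matches hand-derived breakpoint counts", {
  # identity: zero everywhere
  idx0 <- computeRearrangementIndex(permMap(0:99))
  expect_equal(idx0$R_i, 0)
  expect_equal(idx0$n_adjacencies, 99L)

  # 11 anchors, internal inversion of ranks 3-6: 2 intra / 10 adjacencies
  idx1 <- computeRearrangementIndex(permMap(c(0:2, 6:3, 7:10)))
  expect_equal(idx1$n_adjacencies, 10L)
  expect_equal(idx1$C_i, 0.2)
  expect_equal(idx1$S_i, 0)
  expect_equal(idx1$R_i, 0.2)

  # two 11-anchor chromosomes, 3-anchor segment moved from chrom1 into
  # chrom2: 2 inter flanking the excision, 1 intra at the insertion gap
  refChrom <- rep(c("chr1", "chr2"), each = 11L)
  queryChrom <- c(rep("q1", 4L), rep("q2", 3L), rep("q1", 4L),
                  rep("q2", 11L))
  queryRank <- c(0:3, 5:7, 4:7, c(0:4, 8:13))
  map <- rankMap(refChrom, queryChrom, queryRank)
  idx2 <- computeRearrangementIndex(map)
  expect_equal(idx2$n_adjacencies, 20L)
  expect_equal(idx2$n_inter, 2L)
  expect_equal(idx2$n_intra, 1L)
  expect_equal(idx2$C_i, 0.05)
  expect_equal(idx2$S_i, 0.10)
  expect_equal(idx2$R_i, 0.15)

  # single anchor per chromosome: no adjacency, index undefined
  expect_error(computeRearrangementIndex(
    rankMap(c("c1", "c2"), c("q1", "q2"), c(0L, 0L))), "undefined")
})

test_that("index invariants: bounds, self-comparison, flips, planted inversions", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    idx <- computeRearrangementIndex(permMap(sample(n) - 1L))
    expect_gte(idx$C_i, 0)
    expect_gte(idx$S_i, 0)
    expect_lte(idx$R_i, 1)
    expect_equal(idx$R_i, idx$C_i + idx$S_i)
  }

  # whole-chromosome flip changes no counts (adjacency test is unsigned)
  map <- permMap(sample(40) - 1L)
  a <- computeRearrangementIndex(map)
  b <- computeRearrangementIndex(flipQueryChrom(map, "c1"))
  expect_equal(a[c("n_adjacencies", "n_intra", "n_inter")],
               b[c("n_adjacencies", "n_intra", "n_inter")])

  # k non-overlapping, non-adjacent internal inversions add exactly 2k
  # intra breakpoints
  for (k in 1:4) {
    n <- 60L
    perm <- 0:(n - 1L)
    starts <- seq(5L, by = 12L, length.out = k)
    for (s in starts) perm[(s:(s + 5L)) + 1L] <- rev(perm[(s:(s + 5L)) + 1L])
    idx <- computeRearrangementIndex(permMap(perm))
    expect_equal(idx$n_intra, 2L * k)
    expect_equal(idx$n_inter, 0L)
  }
})

test_that("uniform shuffles drive R_i towards one", {
  set.seed(31)
  r <- vapply(1:200, function(i)
    computeRearrangementIndex(permMap(sample(100) - 1L))$R_i, 0)
  expect_gt(mean(r), 0.9)
})

test_that("genesInCalls reports half-open overlaps on the chosen side", {
  calls <- data.frame(call_id = "C0001", call_type = "inversion",
                      block_id = "B0001", ref_chrom = "c1",
                      ref_start = 151L, ref_end = 400L,
                      query_chrom = "q1", query_start = 1L,
                      query_end = 100L, orientation = "-",
                      n_anchors = 5L, span_bp = 250L, macro_flag = FALSE,
                      stringsAsFactors = FALSE)
  genes <- AnchorSet("G", data.frame(name = "c1", length = 1000L),
    data.frame(gene_id = c("inside", "touching_end", "outside"),
               chrom = "c1", start = c(100L, 400L, 500L),
               end = c(200L, 500L, 600L), strand = "+"))
  hits <- genesInCalls(calls, genes, side = "ref")
  expect_equal(hits$gene_id, "inside")
  expect_equal(nrow(genesInCalls(calls[0, ], genes, "ref")), 0L)
  expect_error(genesInCalls(calls, genes, side = "nope"))
})
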