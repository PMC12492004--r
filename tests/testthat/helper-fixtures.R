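# Fixture builders and independent brute-force oracles shared by the
# suite. Oracles are deliberately written as plain loops over the
# definitions, independent of the package's vectorised code paths.

# Two AnchorSets over one shared chromosome layout; the query-rank
# permutation (0-based) decides which query gene each ref gene pairs to,
# so query ranks along the ref order equal `perm`.
permMap <- function(perm, chromName = "c1") {
  n <- length(perm)
  chroms <- data.frame(name = chromName, length = 1000L * (n + 1L))
  coords <- data.frame(chrom = chromName, start = (1:n) * 1000L,
                       end = (1:n) * 1000L + 10L, strand = "+")
  ref <- AnchorSet("R", chroms,
                   cbind(gene_id = sprintf("r%03d", 1:n), coords))
  qry <- AnchorSet("Q", chroms,
                   cbind(gene_id = sprintf("q%03d", 1:n), coords))
  makeHomologyMap(ref, qry,
                  data.frame(ref_id = sprintf("r%03d", 1:n),
                             query_id = sprintf("q%03d", perm + 1L)))
}

# General map: ref genes laid out on refChrom in given order; query genes
# placed so that gene i gets query chromosome queryChrom[i] and query rank
# queryRank[i] (0-based within its query chromosome).
rankMap <- function(refChrom, queryChrom, queryRank) {
  n <- length(refChrom)
  mkcoords <- function(chrom, pos)
    data.frame(chrom = chrom, start = (pos + 1L) * 1000L,
               end = (pos + 1L) * 1000L + 10L, strand = "+")
  ref_pos <- stats::ave(seq_len(n), refChrom, FUN = seq_along) - 1L
  rchroms <- data.frame(name = unique(refChrom),
                        length = 1000L * (n + 2L))
  ref <- AnchorSet("R", rchroms,
                   cbind(gene_id = sprintf("r%03d", 1:n),
                         mkcoords(refChrom, ref_pos)))
  qchroms <- data.frame(name = unique(queryChrom),
                        length = 1000L * (n + 2L))
  qry <- AnchorSet("Q", qchroms,
                   cbind(gene_id = sprintf("q%03d", 1:n),
                         mkcoords(queryChrom, queryRank)))
  makeHomologyMap(ref, qry,
                  data.frame(ref_id = sprintf("r%03d", 1:n),
                             query_id = sprintf("q%03d", 1:n)))
}

# Reverse the gene order of one query chromosome (mirror coordinates and
# complement strands), returning the flipped map.
flipQueryChrom <- function(map, chrom) {
  q <- queryGenome(map)
  af <- anchorFrame(q)
  ch <- chromosomes(q)
  L <- ch$length[match(chrom, ch$name)]
  sel <- af$chrom == chrom
  new_start <- L - af$end[sel]
  new_end <- L - af$start[sel]
  af$start[sel] <- new_start
  af$end[sel] <- new_end
  af$strand[sel] <- ifelse(af$strand[sel] == "+", "-", "+")
  q2 <- AnchorSet(genomeId(q), ch, af)
  makeHomologyMap(refGenome(map), q2, anchorPairs(map))
}

# Ranked-anchor frame built directly from a query-rank permutation
# (0-based), bypassing S4 construction; equivalent to
# rankAnchors(permMap(perm)) and much cheaper for exhaustive sweeps.
rankedFromPerm <- function(perm, refChrom = "c1", queryChrom = "c1") {
  n <- length(perm)
  p <- as.integer(perm)
  data.frame(ref_id = sprintf("r%03d", 1:n),
             query_id = sprintf("q%03d", p + 1L),
             ref_chrom = refChrom, ref_rank = 0:(n - 1L),
             ref_start = (1:n) * 1000L + 1L, ref_end = (1:n) * 1000L + 10L,
             query_chrom = queryChrom, query_rank = p,
             query_start = (p + 1L) * 1000L + 1L,
             query_end = (p + 1L) * 1000L + 10L,
             stringsAsFactors = FALSE)
}

# Brute-force adjacency enumerator: plain loop over the definition of a
# conserved adjacency (same query chromosome, |query rank difference| = 1).
oracleBreakpoints <- function(ranked) {
  counts <- c(adjacencies = 0L, intra = 0L, inter = 0L)
  for (ch in unique(ranked$ref_chrom)) {
    sub <- ranked[ranked$ref_chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$ref_rank), , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      counts["adjacencies"] <- counts["adjacencies"] + 1L
      if (sub$query_chrom[i] != sub$query_chrom[i + 1L])
        counts["inter"] <- counts["inter"] + 1L
      else if (abs(sub$query_rank[i + 1L] - sub$query_rank[i]) != 1L)
        counts["intra"] <- counts["intra"] + 1L
    }
  }
  counts
}

# Brute-force maximal monotone run enumerator over one chromosome pair:
# starting from the leftmost unassigned anchor, extend while the next step
# keeps |query jump| within maxGap and the established direction.
oracleRuns <- function(perm, maxGap) {
  n <- length(perm)
  assigned <- rep(FALSE, n)
  runs <- list()
  while (any(!assigned)) {
    s <- which(!assigned)[1L]
    run <- s
    dir <- 0L
    i <- s
    while (i < n && !assigned[i + 1L]) {
      dq <- perm[i + 1L] - perm[i]
      if (abs(dq) < 1L || abs(dq) > maxGap) break
      if (dir != 0L && sign(dq) != dir) break
      dir <- sign(dq)
      run <- c(run, i + 1L)
      i <- i + 1L
    }
    assigned[run] <- TRUE
    runs[[length(runs) + 1L]] <-
      list(members = run, orientation = if (dir < 0L) "-" else "+")
  }
  runs
}

# All permutations of 1..n in lexicographic-ish recursive order.
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L))
    for (i in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

# Closed-form K2P evaluation used as the independent oracle.
oracleK2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# Build a sequence pair with exactly nTs transitions and nTv transversions
# over n sites (rest identical).
seqPairWithChanges <- function(n, nTs, nTv) {
  a <- rep("A", n)
  b <- a
  if (nTs > 0) b[seq_len(nTs)] <- "G"
  if (nTv > 0) b[nTs + seq_len(nTv)] <- "C"
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}
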