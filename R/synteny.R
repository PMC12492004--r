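# Anchor ranking and collinear block chaining.
#
# Chaining works in rank space (gene adjacency), not base-pair space:
# within each chromosome the paired anchors are numbered 0..k-1 by the
# deterministic key (midpoint, start, gene_id), and blocks are maximal
# monotone runs of those ranks. Base-pair spans are derived afterwards,
# which makes the blocks robust to unequal intergenic distances.

.locFrame <- function(x) {
  gr <- x@anchors
  s <- BiocGenerics::start(gr)
  e <- BiocGenerics::end(gr)
  data.frame(gene_id = mcols(gr)$gene_id,
             chrom = as.character(seqnames(gr)),
             start = s, end = e, mid = (s + e) / 2,
             stringsAsFactors = FALSE)
}

.rankWithin <- function(chrom, mid, start, gene_id) {
  r <- integer(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- order(mid[i], start[i], gene_id[i])
    r[i[o]] <- seq_along(i) - 1L
  }
  r
}

#' Rank paired anchors along their chromosomes
#'
#' For each chromosome of the reference and of the query, the anchors that
#' take part in the one-to-one pairing are numbered `0..k-1` by the
#' deterministic ordering key (midpoint, then start, then gene id).
#' Unpaired genes are ignored and do not occupy ranks.
#'
#' @param map a validated [HomologyMap-class].
#' @return `data.frame` with one row per ortholog pair: `ref_id`,
#'   `query_id`, `ref_chrom`, `ref_rank`, `ref_start`, `ref_end`,
#'   `query_chrom`, `query_rank`, `query_start`, `query_end` (1-based
#'   closed coordinates), ordered by `ref_chrom` then `ref_rank`.
#' @export
rankAnchors <- function(map) {
  stopifnot(is(map, "HomologyMap"))
  p <- map@pairs
  rloc <- .locFrame(map@ref)
  qloc <- .locFrame(map@query)
  ri <- match(p$ref_id, rloc$gene_id)
  qi <- match(p$query_id, qloc$gene_id)
  out <- data.frame(
    ref_id = p$ref_id, query_id = p$query_id,
    ref_chrom = rloc$chrom[ri],
    ref_rank = .rankWithin(rloc$chrom[ri], rloc$mid[ri], rloc$start[ri],
                           rloc$gene_id[ri]),
    ref_start = rloc$start[ri], ref_end = rloc$end[ri],
    query_chrom = qloc$chrom[qi],
    query_rank = .rankWithin(qloc$chrom[qi], qloc$mid[qi], qloc$start[qi],
                             qloc$gene_id[qi]),
    query_start = qloc$start[qi], query_end = qloc$end[qi],
    stringsAsFactors = FALSE)
  out <- out[order(out$ref_chrom, out$ref_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Greedy left-to-right maximal-run segmentation of one chromosome-pair
# subsequence (rows of `ranked` already restricted and ordered by ref_rank).
# A step is admissible iff the ref-rank jump and the absolute query-rank
# jump are both <= maxGap and the query direction matches the run's sign.
# Greedy maximal extension minimises the number of runs here because step
# admissibility is local, so every contiguous sub-run of a valid run is
# valid.
.segmentRuns <- function(refRank, queryRank, maxGap) {
  n <- length(refRank)
  if (n == 0L) return(integer(0))
  run <- integer(n)
  run[1L] <- 1L
  cur <- 1L
  sign_cur <- 0L
  for (i in seq_len(n - 1L)) {
    dr <- refRank[i + 1L] - refRank[i]
    dq <- queryRank[i + 1L] - queryRank[i]
    s <- sign(dq)
    ok <- dr <= maxGap && abs(dq) >= 1L && abs(dq) <= maxGap &&
      (sign_cur == 0L || s == sign_cur)
    if (ok) {
      sign_cur <- s
    } else {
      cur <- cur + 1L
      sign_cur <- 0L
    }
    run[i + 1L] <- cur
  }
  run
}

# All maximal runs (before the min-anchor filter), as a data.frame of row
# indices into `ranked` plus run ids and orientations. Shared by
# chainBlocks() and the property tests.
.chainRuns <- function(ranked, maxGap) {
  key <- paste(ranked$ref_chrom, ranked$query_chrom, sep = "\r")
  o <- order(ranked$ref_chrom, ranked$ref_rank)
  runs <- vector("list", 0L)
  run_counter <- 0L
  for (k in unique(key[o])) {
    idx <- o[key[o] == k]
    rid <- .segmentRuns(ranked$ref_rank[idx], ranked$query_rank[idx], maxGap)
    for (r in unique(rid)) {
      run_counter <- run_counter + 1L
      rows <- idx[rid == r]
      dq <- if (length(rows) >= 2L)
        ranked$query_rank[rows[2L]] - ranked$query_rank[rows[1L]] else 0L
      runs[[run_counter]] <- list(rows = rows,
                                  orientation = if (dq < 0L) "-" else "+")
    }
  }
  runs
}

#' Chain ranked anchors into oriented collinear synteny blocks
#'
#' Within each (reference chromosome, query chromosome) pair the paired
#' anchors are scanned in reference order and greedily extended into
#' maximal runs whose query ranks advance monotonically with a constant
#' sign, with both the reference and the query rank jump of every step
#' bounded by `maxGap`. Runs shorter than `minBlockAnchors` are discarded
#' into a residue table rather than silently dropped. Every anchor belongs
#' to at most one block.
#'
#' @param ranked ranked anchor `data.frame` from [rankAnchors()].
#' @param maxGap maximum rank jump (in rank units, >= 1) tolerated within
#'   a block on either genome. Default 2.
#' @param minBlockAnchors minimum anchors per reported block (>= 2).
#'   Default 5.
#' @return `data.frame` of blocks in reference coordinate order with
#'   columns `block_id`, `ref_chrom`, `ref_start`, `ref_end`,
#'   `query_chrom`, `query_start`, `query_end`, `orientation`,
#'   `n_anchors`, `anchor_ids` (comma-separated ref gene ids in run
#'   order). Discarded anchors are attached as `attr(x, "residues")`; the
#'   parameters as `attr(x, "maxGap")` and `attr(x, "minBlockAnchors")`.
#' @export
chainBlocks <- function(ranked, maxGap = 2L, minBlockAnchors = 5L) {
  if (!is.numeric(maxGap) || maxGap < 1)
    stop("maxGap must be >= 1")
  if (!is.numeric(minBlockAnchors) || minBlockAnchors < 2)
    stop("minBlockAnchors must be >= 2")
  maxGap <- as.integer(maxGap)
  minBlockAnchors <- as.integer(minBlockAnchors)
  runs <- .chainRuns(ranked, maxGap)
  keep <- vapply(runs, function(r) length(r$rows) >= minBlockAnchors, TRUE)
  kept <- runs[keep]
  rows_list <- lapply(kept, `[[`, "rows")
  blocks <- data.frame(
    ref_chrom = vapply(kept, function(r) ranked$ref_chrom[r$rows[1L]], ""),
    ref_start = vapply(kept, function(r)
      min(ranked$ref_start[r$rows]), 0L),
    ref_end = vapply(kept, function(r) max(ranked$ref_end[r$rows]), 0L),
    query_chrom = vapply(kept, function(r)
      ranked$query_chrom[r$rows[1L]], ""),
    query_start = vapply(kept, function(r)
      min(ranked$query_start[r$rows]), 0L),
    query_end = vapply(kept, function(r)
      max(ranked$query_end[r$rows]), 0L),
    orientation = vapply(kept, `[[`, "", "orientation"),
    n_anchors = vapply(kept, function(r) length(r$rows), 0L),
    anchor_ids = vapply(kept, function(r)
      paste(ranked$ref_id[r$rows], collapse = ","), ""),
    stringsAsFactors = FALSE)
  o <- order(blocks$ref_chrom, blocks$ref_start, blocks$ref_end)
  blocks <- blocks[o, , drop = FALSE]
  blocks <- cbind(block_id = sprintf("B%04d", seq_len(nrow(blocks))),
                  blocks, stringsAsFactors = FALSE)
  rownames(blocks) <- NULL
  in_block <- unlist(rows_list, use.names = FALSE)
  residues <- ranked[setdiff(seq_len(nrow(ranked)), in_block), ,
                     drop = FALSE]
  rownames(residues) <- NULL
  attr(blocks, "residues") <- residues
  attr(blocks, "maxGap") <- maxGap
  attr(blocks, "minBlockAnchors") <- minBlockAnchors
  blocks
}
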