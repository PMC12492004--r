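# Rearrangement classification and breakpoint indices.
#
# The index treats the reference genome's anchor adjacencies as the unit of
# comparison: an adjacency is conserved iff the two genes sit on the same
# query chromosome at adjacent ranks; otherwise it is a breakpoint,
# intra-chromosomal (C_i numerator) when both genes still share a query
# chromosome and inter-chromosomal (S_i numerator) when they do not.

#' Per-adjacency breakpoint classification
#'
#' The computational core of [computeRearrangementIndex()]: walks the
#' consecutive ranked anchor pairs of every reference chromosome and labels
#' each adjacency `conserved` (same query chromosome, query ranks adjacent),
#' `intra` (same query chromosome, ranks not adjacent) or `inter`
#' (different query chromosomes). The adjacency test is unsigned, so
#' whole-chromosome flips of the query change nothing.
#'
#' @param ranked ranked anchor `data.frame` from [rankAnchors()].
#' @return `data.frame` with one row per reference adjacency: `ref_chrom`,
#'   `left_id`, `right_id`, `status`.
#' @export
adjacencyBreakpoints <- function(ranked) {
  o <- order(ranked$ref_chrom, ranked$ref_rank)
  chr <- ranked$ref_chrom[o]
  qc <- ranked$query_chrom[o]
  qr <- ranked$query_rank[o]
  id <- ranked$ref_id[o]
  n <- length(chr)
  if (n < 2L)
    return(data.frame(ref_chrom = character(), left_id = character(),
                      right_id = character(), status = character(),
                      stringsAsFactors = FALSE))
  i <- seq_len(n - 1L)
  same_ref <- chr[i] == chr[i + 1L]
  same_q <- qc[i] == qc[i + 1L]
  adj_q <- abs(qr[i + 1L] - qr[i]) == 1L
  status <- ifelse(!same_q, "inter", ifelse(adj_q, "conserved", "intra"))
  data.frame(ref_chrom = chr[i], left_id = id[i], right_id = id[i + 1L],
             status = status, stringsAsFactors = FALSE)[same_ref, ,
                                                        drop = FALSE]
}

#' Compute the rearrangement index (C_i, S_i, R_i) for a genome pair
#'
#' Quantifies genome shuffling between the reference and query of a
#' [HomologyMap-class] as breakpoint fractions over reference-genome
#' anchor adjacencies: `C_i = n_intra / n_adjacencies` (intra-chromosomal
#' component), `S_i = n_inter / n_adjacencies` (inter-chromosomal
#' component), and `R_i = C_i + S_i`. A self-comparison yields
#' `R_i = 0`; a fully shuffled genome approaches 1. The index is
#' directional (reference to query); compute both directions by swapping
#' the map or use the `index` CLI subcommand which does so by default.
#'
#' @param map a validated [HomologyMap-class] with at least two paired
#'   anchors on some reference chromosome.
#' @return one-row `data.frame`: `ref_genome`, `query_genome`,
#'   `n_adjacencies`, `n_intra`, `n_inter`, `C_i`, `S_i`, `R_i`.
#' @export
computeRearrangementIndex <- function(map) {
  ranked <- rankAnchors(map)
  adj <- adjacencyBreakpoints(ranked)
  if (nrow(adj) == 0L)
    stop("rearrangement index undefined: no reference adjacencies ",
         "(need >= 2 paired anchors on one reference chromosome)")
  n_adj <- nrow(adj)
  n_intra <- sum(adj$status == "intra")
  n_inter <- sum(adj$status == "inter")
  data.frame(ref_genome = map@ref@genomeId,
             query_genome = map@query@genomeId,
             n_adjacencies = n_adj, n_intra = n_intra, n_inter = n_inter,
             C_i = n_intra / n_adj, S_i = n_inter / n_adj,
             R_i = (n_intra + n_inter) / n_adj,
             stringsAsFactors = FALSE)
}

#' Swap the direction of a HomologyMap
#'
#' @param map a [HomologyMap-class].
#' @return the map with reference and query exchanged.
#' @export
swapMap <- function(map) {
  p <- map@pairs
  new("HomologyMap", ref = map@query, query = map@ref,
      pairs = data.frame(ref_id = p$query_id, query_id = p$ref_id,
                         score = p$score, stringsAsFactors = FALSE),
      nDropped = map@nDropped)
}

#' Classify synteny blocks into rearrangement calls
#'
#' For each reference chromosome the majority-partner query chromosome is
#' the one holding the plurality of its paired anchors (ties broken by
#' lexicographically smallest query chromosome name). Blocks lying on the
#' majority partner are `collinear` or `inversion` depending on whether
#' their orientation matches the anchor-count-weighted dominant orientation
#' of that chromosome pair (ties default to `+`); blocks on any other
#' query chromosome are `translocation_insertion`.
#'
#' @param blocks block `data.frame` from [chainBlocks()] built from the
#'   same map.
#' @param map the [HomologyMap-class] the blocks came from.
#' @return `data.frame` of calls in block order: `call_id`, `call_type`,
#'   `block_id`, coordinates and `orientation` as in the block table,
#'   `n_anchors`, `span_bp` (reference span length) and `macro_flag`
#'   (all `FALSE`; see [detectMacroInversions()]).
#' @export
classifyCalls <- function(blocks, map) {
  ranked <- rankAnchors(map)
  known <- ranked$ref_id
  block_anchors <- strsplit(blocks$anchor_ids, ",", fixed = TRUE)
  missing <- setdiff(unlist(block_anchors), known)
  if (length(missing))
    stop("block anchor(s) absent from the homology map: ",
         paste(utils::head(missing, 5L), collapse = ", "))

  # plurality query partner per ref chromosome, over all paired anchors
  partner <- vapply(split(ranked$query_chrom, ranked$ref_chrom),
                    function(qc) {
                      tab <- table(qc)
                      names(tab)[order(-tab, names(tab))][1L]
                    }, "")

  # anchor-count-weighted dominant orientation per chromosome pair
  pair_key <- paste(blocks$ref_chrom, blocks$query_chrom, sep = "\r")
  dom <- vapply(split(seq_len(nrow(blocks)), pair_key), function(i) {
    w <- tapply(blocks$n_anchors[i], blocks$orientation[i], sum)
    plus <- if ("+" %in% names(w)) w[["+"]] else 0L
    minus <- if ("-" %in% names(w)) w[["-"]] else 0L
    if (minus > plus) "-" else "+"
  }, "")

  on_partner <- blocks$query_chrom == partner[blocks$ref_chrom]
  matches_dom <- blocks$orientation == dom[pair_key]
  call_type <- ifelse(!on_partner, "translocation_insertion",
                      ifelse(matches_dom, "collinear", "inversion"))
  out <- data.frame(
    call_id = sprintf("C%04d", seq_len(nrow(blocks))),
    call_type = call_type,
    block_id = blocks$block_id,
    ref_chrom = blocks$ref_chrom,
    ref_start = blocks$ref_start, ref_end = blocks$ref_end,
    query_chrom = blocks$query_chrom,
    query_start = blocks$query_start, query_end = blocks$query_end,
    orientation = blocks$orientation,
    n_anchors = blocks$n_anchors,
    span_bp = blocks$ref_end - blocks$ref_start + 1L,
    macro_flag = FALSE,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter inversion calls down to macro-fragment inversions
#'
#' Retains inversion calls whose reference span is at least `minSpanBp`
#' and sets their `macro_flag`; input order is preserved. The threshold
#' for "macro" is configurable (default 1 Mb).
#'
#' @param calls call `data.frame` from [classifyCalls()].
#' @param minSpanBp minimum reference span in bp (> 0).
#' @export
detectMacroInversions <- function(calls, minSpanBp = 1e6) {
  if (!is.numeric(minSpanBp) || length(minSpanBp) != 1L || minSpanBp <= 0)
    stop("minSpanBp must be a positive number")
  keep <- calls$call_type == "inversion" & calls$span_bp >= minSpanBp
  out <- calls[keep, , drop = FALSE]
  out$macro_flag <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  attr(out, "minSpanBp") <- minSpanBp
  out
}

#' Chromosome correspondence and fusion/fission flags
#'
#' Cross-tabulates paired anchors by (reference chromosome, query
#' chromosome). A reference chromosome is `fission_like` when at least two
#' query partners each hold at least `minPartnerFraction` of its anchors; a
#' query chromosome is `fusion_like` when at least two reference
#' chromosomes each contribute at least `minPartnerFraction` of its
#' anchors. Chromosomes with exactly one major partner and no flag are
#' `one_to_one`.
#'
#' @param map a validated [HomologyMap-class].
#' @param minPartnerFraction fraction in (0, 0.5] a partner must hold to
#'   count as major. Default 0.2.
#' @return list with elements `table` (`ref_chrom`, `query_chrom`,
#'   `n_anchors`, `ref_fraction`, `query_fraction`), `refEvents`
#'   (`ref_chrom`, `n_major_partners`, `one_to_one`, `fission_like`),
#'   `queryEvents` (`query_chrom`, `n_major_partners`, `one_to_one`,
#'   `fusion_like`) and `minPartnerFraction`.
#' @export
chromosomeCorrespondence <- function(map, minPartnerFraction = 0.2) {
  if (!is.numeric(minPartnerFraction) || length(minPartnerFraction) != 1L ||
      minPartnerFraction <= 0 || minPartnerFraction > 0.5)
    stop("minPartnerFraction must lie in (0, 0.5]")
  ranked <- rankAnchors(map)
  tab <- as.data.frame(table(ref_chrom = ranked$ref_chrom,
                             query_chrom = ranked$query_chrom),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3L] <- "n_anchors"
  ref_tot <- tapply(tab$n_anchors, tab$ref_chrom, sum)
  query_tot <- tapply(tab$n_anchors, tab$query_chrom, sum)
  tab$ref_fraction <- tab$n_anchors / as.vector(ref_tot[tab$ref_chrom])
  tab$query_fraction <- tab$n_anchors /
    as.vector(query_tot[tab$query_chrom])
  tab <- tab[order(tab$ref_chrom, -tab$n_anchors, tab$query_chrom), ,
             drop = FALSE]
  rownames(tab) <- NULL

  ref_major <- tapply(tab$ref_fraction >= minPartnerFraction,
                      tab$ref_chrom, sum)
  refEvents <- data.frame(ref_chrom = names(ref_major),
                          n_major_partners = as.integer(ref_major),
                          stringsAsFactors = FALSE)
  refEvents$fission_like <- refEvents$n_major_partners >= 2L
  refEvents$one_to_one <- refEvents$n_major_partners == 1L
  query_major <- tapply(tab$query_fraction >= minPartnerFraction,
                        tab$query_chrom, sum)
  queryEvents <- data.frame(query_chrom = names(query_major),
                            n_major_partners = as.integer(query_major),
                            stringsAsFactors = FALSE)
  queryEvents$fusion_like <- queryEvents$n_major_partners >= 2L
  queryEvents$one_to_one <- queryEvents$n_major_partners == 1L
  list(table = tab, refEvents = refEvents, queryEvents = queryEvents,
       minPartnerFraction = minPartnerFraction)
}

#' Genes overlapping rearrangement call spans
#'
#' Intersects gene annotation with the genomic extents of calls on the
#' chosen genome side (half-open interval overlap), yielding the
#' per-call gene lists used as input for external enrichment tools.
#'
#' @param calls call `data.frame` from [classifyCalls()] or
#'   [detectMacroInversions()].
#' @param genes an [AnchorSet-class] (typically the full gene annotation
#'   of the corresponding genome, not just paired anchors).
#' @param side `"ref"` or `"query"`: which call span to intersect.
#' @return `data.frame` with columns `call_id` and `gene_id`, one row per
#'   overlapping (call, gene) pair, in call order.
#' @export
genesInCalls <- function(calls, genes, side = c("ref", "query")) {
  side <- match.arg(side)
  stopifnot(is(genes, "AnchorSet"))
  if (nrow(calls) == 0L)
    return(data.frame(call_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  chrom <- calls[[paste0(side, "_chrom")]]
  gr_calls <- GRanges(seqnames = chrom,
                      ranges = IRanges(start = calls[[paste0(side, "_start")]],
                                       end = calls[[paste0(side, "_end")]]))
  gr_genes <- genes@anchors
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_calls, gr_genes, ignore.strand = TRUE))
  out <- data.frame(
    call_id = calls$call_id[S4Vectors::queryHits(hits)],
    gene_id = mcols(gr_genes)$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  out <- out[order(match(out$call_id, calls$call_id), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
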