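#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqinfo<-
#'   seqlevels seqlevels<-
#' @importFrom S4Vectors mcols mcols<-
NULL

#' AnchorSet: one genome's karyotype with gene anchors
#'
#' An `AnchorSet` holds the chromosome complement of one genome (names and
#' lengths, stored as a [GenomeInfoDb::Seqinfo]) together with its gene
#' anchors as a [GenomicRanges::GRanges] carrying a `gene_id` metadata
#' column. Anchors are the positional substrate of all synteny computation:
#' only genes that are later paired across genomes take part in ranking and
#' block chaining.
#'
#' Coordinates are stored in the GRanges convention (1-based, closed).
#' All BED readers and writers in the package convert to and from the
#' 0-based half-open file convention, so files round-trip exactly.
#'
#' @slot genomeId single string naming the genome.
#' @slot anchors `GRanges` of gene anchors; `mcols()$gene_id` must be a
#'   unique character vector, strand must be `+` or `-`, and every range
#'   must lie within its chromosome's length.
#'
#' @examples
#' chroms <- data.frame(name = "chr1", length = 1000)
#' genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
#'                     start = c(10, 300), end = c(100, 400),
#'                     strand = c("+", "-"))
#' AnchorSet("toy", chroms, genes)
#' @export
setClass("AnchorSet",
  representation(genomeId = "character", anchors = "GRanges"))

setValidity("AnchorSet", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
      !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  gr <- object@anchors
  si <- seqinfo(gr)
  lens <- seqlengths(si)
  if (anyNA(lens))
    msg <- c(msg, "all chromosomes must have a known length")
  if (any(lens <= 0, na.rm = TRUE))
    msg <- c(msg, "chromosome lengths must be positive")
  if (anyDuplicated(seqnames(si)))
    msg <- c(msg, "chromosome names must be unique")
  gid <- mcols(gr)$gene_id
  if (is.null(gid) || !is.character(gid) || anyNA(gid))
    msg <- c(msg, "anchors must carry a character gene_id column")
  else if (anyDuplicated(gid))
    msg <- c(msg, paste0("duplicated gene_id: ",
                         paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  if (length(gr)) {
    if (any(!as.character(BiocGenerics::strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "anchor strand must be '+' or '-'")
    ends <- BiocGenerics::end(gr)
    maxlen <- lens[as.character(seqnames(gr))]
    if (any(ends > maxlen))
      msg <- c(msg, "anchor coordinates exceed chromosome length")
    if (any(BiocGenerics::start(gr) < 1L))
      msg <- c(msg, "anchor start below chromosome start")
  }
  if (length(msg)) msg else TRUE
})

#' HomologyMap: one-to-one ortholog pairing between two genomes
#'
#' A `HomologyMap` binds a reference and a query [AnchorSet] with a strictly
#' one-to-one table of ortholog gene pairs. It is the substrate of anchor
#' ranking, synteny-block chaining, rearrangement classification and the
#' breakpoint indices. Construction enforces one-to-oneness; duplicate
#' pairs in input tables are resolved beforehand (see [readAnchorPairs()]
#' and [makeHomologyMap()]).
#'
#' @slot ref,query the two [AnchorSet] objects being compared.
#' @slot pairs `data.frame` with character columns `ref_id`, `query_id`
#'   and a numeric `score` (may be `NA`).
#' @slot nDropped number of input pairs removed by duplicate resolution.
#' @export
setClass("HomologyMap",
  representation(ref = "AnchorSet", query = "AnchorSet",
                 pairs = "data.frame", nDropped = "integer"))

setValidity("HomologyMap", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("ref_id", "query_id", "score") %in% names(p)))
    return("pairs must have columns ref_id, query_id, score")
  if (anyDuplicated(p$ref_id))
    msg <- c(msg, "pairing not one-to-one: duplicated ref_id")
  if (anyDuplicated(p$query_id))
    msg <- c(msg, "pairing not one-to-one: duplicated query_id")
  bad_r <- setdiff(p$ref_id, mcols(object@ref@anchors)$gene_id)
  if (length(bad_r))
    msg <- c(msg, paste0("ref gene(s) absent from AnchorSet: ",
                         paste(utils::head(bad_r, 5L), collapse = ", ")))
  bad_q <- setdiff(p$query_id, mcols(object@query@anchors)$gene_id)
  if (length(bad_q))
    msg <- c(msg, paste0("query gene(s) absent from AnchorSet: ",
                         paste(utils::head(bad_q, 5L), collapse = ", ")))
  if (length(object@nDropped) != 1L || is.na(object@nDropped))
    msg <- c(msg, "nDropped must be a single integer")
  if (length(msg)) msg else TRUE
})
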