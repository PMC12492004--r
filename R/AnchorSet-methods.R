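#' Construct an AnchorSet
#'
#' @param genomeId single string naming the genome.
#' @param chromosomes `data.frame` with columns `name` and `length`
#'   (base pairs), e.g. from [readChromTable()].
#' @param anchors either a `GRanges` with a `gene_id` metadata column
#'   (1-based closed coordinates), or a `data.frame` with columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand` in the 0-based half-open
#'   BED convention, e.g. from [readGeneBed()].
#' @return a validated [AnchorSet-class] object.
#' @export
AnchorSet <- function(genomeId, chromosomes, anchors) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  si <- Seqinfo(seqnames = as.character(chromosomes$name),
                seqlengths = as.integer(chromosomes$length))
  if (is.data.frame(anchors)) {
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(anchors)))
      stop("anchor data.frame needs columns: ", paste(need, collapse = ", "))
    strand <- if ("strand" %in% names(anchors)) anchors$strand else "+"
    strand[is.na(strand) | strand == "*"] <- "+"
    bad <- anchors$start >= anchors$end
    if (any(bad))
      stop("anchor end <= start for gene(s): ",
           paste(utils::head(anchors$gene_id[bad], 5L), collapse = ", "))
    unknown <- setdiff(unique(anchors$chrom), seqnames(si))
    if (length(unknown))
      stop("anchor on unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    # out-of-bound ranges are reported by the class validity check below,
    # not by the transient GRanges warning
    gr <- suppressWarnings(
      GRanges(seqnames = factor(anchors$chrom, levels = seqnames(si)),
              ranges = IRanges(start = anchors$start + 1L,
                               end = anchors$end),
              strand = strand, seqinfo = si))
    mcols(gr)$gene_id <- as.character(anchors$gene_id)
  } else if (is(anchors, "GRanges")) {
    gr <- anchors
    GenomeInfoDb::seqlevels(gr) <- seqnames(si)
    seqinfo(gr) <- si
  } else stop("anchors must be a data.frame or GRanges")
  new("AnchorSet", genomeId = as.character(genomeId), anchors = gr)
}

#' @rdname AnchorSet
#' @param x an `AnchorSet` (or, for `refGenome`/`queryGenome`, a
#'   `HomologyMap`).
#' @export
genomeId <- function(x) x@genomeId

#' @rdname AnchorSet
#' @export
chromosomes <- function(x) {
  si <- seqinfo(x@anchors)
  data.frame(name = seqnames(si), length = unname(seqlengths(si)),
             stringsAsFactors = FALSE)
}

#' @rdname AnchorSet
#' @export
anchors <- function(x) x@anchors

#' @rdname AnchorSet
#' @export
nAnchors <- function(x) length(x@anchors)

#' Anchors as a BED-convention data.frame
#'
#' Returns the anchors of an [AnchorSet-class] as a `data.frame` with
#' 0-based half-open coordinates (columns `gene_id`, `chrom`, `start`,
#' `end`, `strand`), the inverse of the `data.frame` path of [AnchorSet()].
#'
#' @param x an `AnchorSet`.
#' @export
anchorFrame <- function(x) {
  gr <- x@anchors
  data.frame(gene_id = mcols(gr)$gene_id,
             chrom = as.character(seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

setMethod("show", "AnchorSet", function(object) {
  cat("AnchorSet '", object@genomeId, "': ",
      length(seqlengths(object@anchors)), " chromosomes, ",
      length(object@anchors), " gene anchors\n", sep = "")
})

#' Construct a HomologyMap
#'
#' Binds two [AnchorSet-class] objects with an ortholog pair table and
#' resolves duplicated pairings. Under the default `"best-score"` policy a
#' gene appearing in several pairs keeps the pair with the highest score
#' (ties, or all-`NA` scores, broken by lexicographic partner gene id);
#' `"strict"` refuses any duplication.
#'
#' @param ref,query the two [AnchorSet-class] objects.
#' @param pairs `data.frame` whose first two columns are ref and query gene
#'   ids; optional numeric third column `score`.
#' @param duplicates duplicate-resolution policy, `"best-score"` or
#'   `"strict"`.
#' @return a validated [HomologyMap-class]; the number of pairs dropped by
#'   duplicate resolution is available via `nDropped()`.
#' @export
makeHomologyMap <- function(ref, query, pairs,
                            duplicates = c("best-score", "strict")) {
  duplicates <- match.arg(duplicates)
  stopifnot(is(ref, "AnchorSet"), is(query, "AnchorSet"),
            is.data.frame(pairs), ncol(pairs) >= 2L)
  p <- data.frame(ref_id = as.character(pairs[[1L]]),
                  query_id = as.character(pairs[[2L]]),
                  score = if (ncol(pairs) >= 3L) as.numeric(pairs[[3L]])
                          else NA_real_,
                  stringsAsFactors = FALSE)
  n_in <- nrow(p)
  dup <- duplicated(p$ref_id) | duplicated(p$query_id) |
    duplicated(p$ref_id, fromLast = TRUE) |
    duplicated(p$query_id, fromLast = TRUE)
  if (any(dup)) {
    if (duplicates == "strict")
      stop("duplicated ortholog pairing for gene(s): ",
           paste(utils::head(unique(c(p$ref_id[dup], p$query_id[dup])), 5L),
                 collapse = ", "))
    # best-score greedy: order by score desc then partner ids, keep a pair
    # only if neither gene was claimed by a better-scoring pair
    sc <- p$score
    sc[is.na(sc)] <- -Inf
    o <- order(-sc, p$ref_id, p$query_id)
    p <- p[o, , drop = FALSE]
    keep <- logical(nrow(p))
    seen_r <- new.env(parent = emptyenv())
    seen_q <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(p))) {
      r <- p$ref_id[i]; q <- p$query_id[i]
      if (is.null(seen_r[[r]]) && is.null(seen_q[[q]])) {
        keep[i] <- TRUE
        seen_r[[r]] <- TRUE
        seen_q[[q]] <- TRUE
      }
    }
    p <- p[keep, , drop = FALSE]
    p <- p[order(p$ref_id), , drop = FALSE]
  }
  rownames(p) <- NULL
  new("HomologyMap", ref = ref, query = query, pairs = p,
      nDropped = as.integer(n_in - nrow(p)))
}

#' @rdname AnchorSet
#' @export
refGenome <- function(x) x@ref

#' @rdname AnchorSet
#' @export
queryGenome <- function(x) x@query

#' @rdname makeHomologyMap
#' @param x a `HomologyMap`.
#' @export
anchorPairs <- function(x) x@pairs

#' @rdname makeHomologyMap
#' @export
nDropped <- function(x) x@nDropped

setMethod("show", "HomologyMap", function(object) {
  cat("HomologyMap ", object@ref@genomeId, " -> ", object@query@genomeId,
      ": ", nrow(object@pairs), " one-to-one ortholog pairs",
      if (object@nDropped > 0L)
        paste0(" (", object@nDropped, " duplicate pairs dropped)"),
      "\n", sep = "")
})

#' Restrict a HomologyMap to a chromosome subset
#'
#' Drops pairs whose ref or query anchor lies on any of the named
#' chromosomes; used e.g. to exclude allosomes from index computation.
#'
#' @param map a [HomologyMap-class].
#' @param refChroms,queryChroms chromosome names to drop on each side.
#' @export
dropChromosomes <- function(map, refChroms = character(),
                            queryChroms = character()) {
  p <- map@pairs
  rloc <- anchorFrame(map@ref)
  qloc <- anchorFrame(map@query)
  rchr <- rloc$chrom[match(p$ref_id, rloc$gene_id)]
  qchr <- qloc$chrom[match(p$query_id, qloc$gene_id)]
  keep <- !(rchr %in% refChroms) & !(qchr %in% queryChroms)
  new("HomologyMap", ref = map@ref, query = map@query,
      pairs = p[keep, , drop = FALSE], nDropped = map@nDropped)
}
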