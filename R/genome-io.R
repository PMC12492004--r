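#' @importFrom utils read.table write.table head
NULL

# ---- readers -------------------------------------------------------------

#' Read a chromosome table
#'
#' Reads a two-column tab-delimited table of chromosome `name` and `length`
#' (base pairs). Lines starting with `#` are ignored. Input order is
#' preserved.
#'
#' @param path path to the TSV file.
#' @param minLengthBp optional length floor: chromosomes shorter than this
#'   (e.g. unplaced scaffolds) are dropped. The default `0` keeps
#'   everything.
#' @return `data.frame` with columns `name` (character) and `length`
#'   (integer).
#' @export
readChromTable <- function(path, minLengthBp = 0) {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    col.names = c("name", "length"), colClasses = "character",
                    fill = TRUE, blank.lines.skip = TRUE)
  len <- suppressWarnings(as.numeric(raw$length))
  bad <- which(is.na(len) | !nzchar(raw$name))
  if (length(bad))
    stop("malformed chromosome table row(s) ", paste(bad, collapse = ", "),
         " in ", path)
  nonpos <- which(len <= 0)
  if (length(nonpos))
    stop("non-positive length for chromosome(s): ",
         paste(raw$name[nonpos], collapse = ", "))
  dups <- unique(raw$name[duplicated(raw$name)])
  if (length(dups))
    stop("duplicated chromosome name(s): ", paste(dups, collapse = ", "))
  out <- data.frame(name = raw$name, length = as.integer(len),
                    stringsAsFactors = FALSE)
  out[out$length >= minLengthBp, , drop = FALSE]
}

#' Read gene anchors from a BED file
#'
#' Parses a BED3+ file (gene id in column 4, strand in column 6; a missing
#' strand defaults to `+`) via [rtracklayer::import()] and validates every
#' interval against the chromosome table: unknown chromosomes, empty
#' intervals and out-of-bounds coordinates are hard errors.
#'
#' @param path path to the BED file.
#' @param chroms chromosome `data.frame` from [readChromTable()].
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
readGeneBed <- function(path, chroms) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED file ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  nm <- mcols(gr)$name
  if (is.null(nm) || anyNA(nm))
    stop("BED file ", path, " lacks a gene id in column 4")
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), chroms$name)
  if (length(unknown))
    stop("BED anchors on chromosome(s) absent from the chromosome table: ",
         paste(unknown, collapse = ", "))
  str <- as.character(BiocGenerics::strand(gr))
  str[str == "*"] <- "+"
  out <- data.frame(gene_id = as.character(nm), chrom = chr,
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    strand = str, stringsAsFactors = FALSE)
  bad <- out$start >= out$end
  if (any(bad))
    stop("empty or inverted interval (end <= start) for gene(s): ",
         paste(head(out$gene_id[bad], 5L), collapse = ", "))
  lim <- chroms$length[match(out$chrom, chroms$name)]
  oob <- out$end > lim | out$start < 0L
  if (any(oob))
    stop("out-of-bounds anchor(s): ",
         paste(head(out$gene_id[oob], 5L), collapse = ", "))
  if (anyDuplicated(out$gene_id))
    stop("duplicated gene_id in ", path, ": ",
         paste(head(unique(out$gene_id[duplicated(out$gene_id)]), 5L),
               collapse = ", "))
  out
}

#' Read an ortholog anchor-pair table into a HomologyMap
#'
#' Reads a 2-3 column TSV of `(ref gene_id, query gene_id[, score])` and
#' builds a validated one-to-one [HomologyMap-class]. Duplicated pairings
#' are resolved by [makeHomologyMap()]'s policy; the number of dropped
#' pairs is reported in a message and via `nDropped()`.
#'
#' @param path path to the pair TSV.
#' @param ref,query the two [AnchorSet-class] objects the ids refer to.
#' @inheritParams makeHomologyMap
#' @export
readAnchorPairs <- function(path, ref, query,
                            duplicates = c("best-score", "strict")) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(tab) < 2L)
    stop("anchor pair table ", path, " needs at least two columns")
  map <- makeHomologyMap(ref, query, tab, duplicates = duplicates)
  if (nDropped(map) > 0L)
    message("readAnchorPairs: dropped ", nDropped(map),
            " duplicated pair(s) from ", path)
  map
}

#' Read a genome (chromosome table + gene BED) into an AnchorSet
#'
#' @param genomeId name for the genome.
#' @param chromPath chromosome table TSV (see [readChromTable()]).
#' @param bedPath gene BED file (see [readGeneBed()]).
#' @param minLengthBp chromosome length floor passed to [readChromTable()].
#' @export
readAnchorSet <- function(genomeId, chromPath, bedPath, minLengthBp = 0) {
  chroms <- readChromTable(chromPath, minLengthBp = minLengthBp)
  genes <- readGeneBed(bedPath, chroms)
  AnchorSet(genomeId, chroms, genes)
}

# ---- generic TSV writer/reader with parameter headers --------------------

.writeTsv <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(params))
    writeLines(paste0("# ", k, "=", params[[k]]), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.readTsv <- function(path, colClasses) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(body) == 1L) {
    df <- as.data.frame(lapply(colClasses[header], function(cl)
      vector(cl, 0L)), stringsAsFactors = FALSE)
    names(df) <- header
    return(df)
  }
  df <- read.table(text = body[-1L], sep = "\t", header = FALSE,
                   col.names = header, colClasses = unname(colClasses[header]),
                   stringsAsFactors = FALSE, quote = "")
  df
}

.writeBed <- function(chrom, start1, end1, name, score, strand, path) {
  df <- data.frame(chrom = chrom, start = start1 - 1L, end = end1,
                   name = name, score = score, strand = strand,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- blocks --------------------------------------------------------------

.blockCols <- c(block_id = "character", ref_chrom = "character",
                ref_start = "integer", ref_end = "integer",
                query_chrom = "character", query_start = "integer",
                query_end = "integer", orientation = "character",
                n_anchors = "integer", anchor_ids = "character")

#' Write and read synteny block tables
#'
#' Blocks are written as a tab-delimited table (coordinates converted to
#' 0-based half-open) preceded by `#` header lines echoing the chaining
#' parameters, plus an optional companion BED of the block extents on the
#' reference genome. `readBlocks()` inverts `writeBlocks()` exactly.
#'
#' @param blocks block `data.frame` from [chainBlocks()].
#' @param path output TSV path.
#' @param bedPath optional companion BED path (ref coordinates).
#' @export
writeBlocks <- function(blocks, path, bedPath = NULL) {
  out <- blocks
  out$ref_start <- out$ref_start - 1L
  out$query_start <- out$query_start - 1L
  params <- list(object = "synteny_blocks",
                 coordinates = "0-based half-open",
                 max_gap = attr(blocks, "maxGap"),
                 min_block_anchors = attr(blocks, "minBlockAnchors"))
  .writeTsv(out, path, params[!vapply(params, is.null, TRUE)])
  if (!is.null(bedPath))
    .writeBed(blocks$ref_chrom, blocks$ref_start, blocks$ref_end,
              blocks$block_id, blocks$n_anchors, blocks$orientation,
              bedPath)
  invisible(path)
}

#' @rdname writeBlocks
#' @export
readBlocks <- function(path) {
  df <- .readTsv(path, .blockCols)
  df$ref_start <- df$ref_start + 1L
  df$query_start <- df$query_start + 1L
  df
}

# ---- calls ---------------------------------------------------------------

.callCols <- c(call_id = "character", call_type = "character",
               block_id = "character", ref_chrom = "character",
               ref_start = "integer", ref_end = "integer",
               query_chrom = "character", query_start = "integer",
               query_end = "integer", orientation = "character",
               n_anchors = "integer", span_bp = "integer",
               macro_flag = "logical")

#' Write and read rearrangement call tables
#'
#' Same conventions as [writeBlocks()]: TSV with `#` parameter headers and
#' 0-based half-open coordinates, optional companion BED on reference
#' coordinates, exact round-trip via `readCalls()`.
#'
#' @param calls call `data.frame` from [classifyCalls()] or
#'   [detectMacroInversions()].
#' @param path output TSV path.
#' @param bedPath optional companion BED path.
#' @export
writeCalls <- function(calls, path, bedPath = NULL) {
  out <- calls
  out$ref_start <- out$ref_start - 1L
  out$query_start <- out$query_start - 1L
  params <- list(object = "rearrangement_calls",
                 coordinates = "0-based half-open",
                 macro_threshold_bp = attr(calls, "minSpanBp"))
  .writeTsv(out, path, params[!vapply(params, is.null, TRUE)])
  if (!is.null(bedPath))
    .writeBed(calls$ref_chrom, calls$ref_start, calls$ref_end,
              paste(calls$call_id, calls$call_type, sep = "|"),
              calls$n_anchors, calls$orientation, bedPath)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  df <- .readTsv(path, .callCols)
  df$ref_start <- df$ref_start + 1L
  df$query_start <- df$query_start + 1L
  df
}

# ---- rearrangement index -------------------------------------------------

.indexCols <- c(ref_genome = "character", query_genome = "character",
                n_adjacencies = "integer", n_intra = "integer",
                n_inter = "integer", C_i = "numeric", S_i = "numeric",
                R_i = "numeric")

#' Write and read rearrangement index tables
#'
#' The index definition (breakpoint fractions over reference adjacencies)
#' is echoed in the `#` header so a table is interpretable on its own.
#'
#' @param index one- or multi-row index `data.frame` from
#'   [computeRearrangementIndex()].
#' @param path output TSV path.
#' @export
writeIndex <- function(index, path) {
  params <- list(object = "rearrangement_index",
    definition = paste("C_i=n_intra/n_adjacencies;",
                       "S_i=n_inter/n_adjacencies; R_i=C_i+S_i;",
                       "adjacency conserved iff same query chromosome",
                       "and |query_rank difference|=1"))
  .writeTsv(index, path, params)
  invisible(path)
}

#' @rdname writeIndex
#' @export
readIndex <- function(path) .readTsv(path, .indexCols)
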