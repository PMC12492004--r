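# Karyotype-evolution simulator with ground-truth operation logs.
#
# The simulator emulates whale-scale karyotypes (the balaenopterid
# 2n = 44 complement corresponds to 22 distinct chromosomes) as evenly
# spaced gene anchors, applies inversions, translocations, fusions and
# fissions sequentially, and returns the derived genome together with the
# exact operation log and the trivial one-to-one homology map. Every
# pipeline stage can therefore be validated against known ground truth
# without any external data.

#' Simulation configuration
#'
#' Bundles and validates all simulator parameters. All randomness in
#' [simulateAncestor()] and [applyOperations()] derives from `seed`.
#'
#' @param nChromosomes number of chromosomes in the ancestor. Default 22,
#'   the distinct-chromosome count of a 2n = 44 karyotype.
#' @param anchorsPerChromosome gene anchors per chromosome. Default 45
#'   (whale chromosomes carry on the order of 900 anchor genes; the
#'   default is that density scaled down 20-fold to keep simulations
#'   fast).
#' @param chromosomeLengthBp ancestor chromosome length in bp. Default
#'   1e8, a typical whale chromosome scale.
#' @param nInversions,nTranslocations,nFusions,nFissions operation counts
#'   (all >= 0).
#' @param segmentRange two integers: inversion/translocation segment size
#'   is drawn uniformly from this range (in anchors). Default `c(5, 10)`.
#' @param invertOnMoveProb probability that a translocated segment is also
#'   inverted. Default 0.5.
#' @param nonOverlapping if `TRUE`, every operation is confined to
#'   chromosomes untouched by any other operation and to chromosome
#'   interiors, so each planted operation leaves its textbook breakpoint
#'   signature undisturbed (used by exact-recovery tests). Default `FALSE`:
#'   later operations may compound earlier ones.
#' @param seed integer seed fixing all randomness.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(nChromosomes = 22L, anchorsPerChromosome = 45L,
                      chromosomeLengthBp = 1e8,
                      nInversions = 0L, nTranslocations = 0L,
                      nFusions = 0L, nFissions = 0L,
                      segmentRange = c(5L, 10L),
                      invertOnMoveProb = 0.5,
                      nonOverlapping = FALSE, seed = 1L) {
  cfg <- list(nChromosomes = as.integer(nChromosomes),
              anchorsPerChromosome = as.integer(anchorsPerChromosome),
              chromosomeLengthBp = as.numeric(chromosomeLengthBp),
              nInversions = as.integer(nInversions),
              nTranslocations = as.integer(nTranslocations),
              nFusions = as.integer(nFusions),
              nFissions = as.integer(nFissions),
              segmentRange = as.integer(segmentRange),
              invertOnMoveProb = as.numeric(invertOnMoveProb),
              nonOverlapping = isTRUE(nonOverlapping),
              seed = as.integer(seed))
  counts <- c(cfg$nInversions, cfg$nTranslocations, cfg$nFusions,
              cfg$nFissions)
  if (any(is.na(counts)) || any(counts < 0L))
    stop("operation counts must be non-negative")
  if (cfg$nChromosomes < 1L || cfg$anchorsPerChromosome < 2L)
    stop("need at least 1 chromosome and 2 anchors per chromosome")
  if (length(cfg$segmentRange) != 2L || cfg$segmentRange[1L] < 2L ||
      cfg$segmentRange[2L] < cfg$segmentRange[1L])
    stop("segmentRange must be two integers with 2 <= min <= max")
  if (cfg$segmentRange[2L] > cfg$anchorsPerChromosome)
    stop("segment max exceeds anchorsPerChromosome")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  class(cfg) <- "SimConfig"
  cfg
}

#' Whale-like simulation preset
#'
#' A ready-made [simConfig()] mimicking a balaenopterid-style comparison:
#' 22 chromosomes, 45 anchors each, 100 Mb chromosomes, a handful of
#' inversions plus a couple of inter-chromosomal translocations.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [simConfig()].
#' @export
whaleLikeConfig <- function(seed = 1L, ...) {
  defaults <- list(nChromosomes = 22L, anchorsPerChromosome = 45L,
                   chromosomeLengthBp = 1e8, nInversions = 4L,
                   nTranslocations = 2L, segmentRange = c(5L, 10L),
                   seed = seed)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(simConfig, defaults)
}

.chromNames <- function(n) sprintf("chr%02d", seq_len(n))

.layoutSlot <- function(config)
  max(1, floor(config$chromosomeLengthBp / config$anchorsPerChromosome))

# genome state used during simulation: named list of list(ids, strand)
.stateFromAnchorSet <- function(x) {
  loc <- .locFrame(x)
  str <- as.character(BiocGenerics::strand(x@anchors))
  state <- list()
  for (ch in chromosomes(x)$name) {
    i <- which(loc$chrom == ch)
    o <- order(loc$mid[i], loc$start[i], loc$gene_id[i])
    state[[ch]] <- list(ids = loc$gene_id[i][o], strand = str[i][o])
  }
  state
}

# evenly spaced slots with a seed-determined jitter; consumes the current
# RNG stream (callers set the seed), so ancestor and derived genomes use
# the identical layout procedure and a zero-operation simulation
# reproduces the ancestor's coordinates exactly
.layoutRows <- function(ids, strand, chrom, slot) {
  k <- length(ids)
  if (k == 0L) return(NULL)
  w <- max(1L, as.integer(slot %/% 4))
  i <- seq_len(k)
  jitter <- as.integer(round(stats::runif(k, -slot / 8, slot / 8)))
  center <- (i - 0.5) * slot + jitter
  start1 <- pmax((i - 1L) * slot + 1L,
                 pmin(as.integer(round(center - w / 2)),
                      as.integer(i * slot - w)))
  data.frame(gene_id = ids, chrom = chrom, start = start1 - 1L,
             end = start1 + w - 1L, strand = strand,
             stringsAsFactors = FALSE)
}

.anchorSetFromState <- function(state, config, genomeId) {
  slot <- .layoutSlot(config)
  set.seed(config$seed)
  rows <- lapply(names(state), function(ch)
    .layoutRows(state[[ch]]$ids, state[[ch]]$strand, ch, slot))
  anchors <- do.call(rbind, rows)
  chroms <- data.frame(
    name = names(state),
    length = vapply(state, function(s)
      as.integer(max(1L, length(s$ids)) * slot), 0L),
    stringsAsFactors = FALSE)
  AnchorSet(genomeId, chroms, anchors)
}

#' Simulate an ancestral genome of evenly spaced gene anchors
#'
#' Places `anchorsPerChromosome` anchors per chromosome at regular slots
#' with a small seed-determined jitter, all on the `+` strand, with gene
#' ids encoding chromosome and index (`g<chrom>_<index>`).
#'
#' @param config a [simConfig()].
#' @return an [AnchorSet-class] named `ancestor_seed<seed>`.
#' @export
simulateAncestor <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  slot <- .layoutSlot(config)
  if (slot < 8)
    stop("anchors too dense for chromosome length (slot = ", slot, " bp)")
  nm <- .chromNames(config$nChromosomes)
  k <- config$anchorsPerChromosome
  state <- stats::setNames(lapply(nm, function(ch)
    list(ids = sprintf("g%s_%04d", ch, seq_len(k)),
         strand = rep("+", k))), nm)
  .anchorSetFromState(state, config,
                      sprintf("ancestor_seed%d", config$seed))
}

.flipStrand <- function(s) ifelse(s == "+", "-", "+")

# deterministic application of one logged operation to a genome state
.applyOp <- function(state, op) {
  type <- op$op_type
  if (type == "inversion") {
    ch <- op$chrom
    i <- op$seg_start:op$seg_end
    state[[ch]]$ids[i] <- rev(state[[ch]]$ids[i])
    state[[ch]]$strand[i] <- rev(.flipStrand(state[[ch]]$strand[i]))
  } else if (type == "translocation") {
    a <- op$chrom; b <- op$chrom2
    i <- op$seg_start:op$seg_end
    seg_ids <- state[[a]]$ids[i]
    seg_str <- state[[a]]$strand[i]
    if (isTRUE(op$inverted)) {
      seg_ids <- rev(seg_ids)
      seg_str <- rev(.flipStrand(seg_str))
    }
    state[[a]]$ids <- state[[a]]$ids[-i]
    state[[a]]$strand <- state[[a]]$strand[-i]
    p <- op$dest_pos
    state[[b]]$ids <- append(state[[b]]$ids, seg_ids, after = p)
    state[[b]]$strand <- append(state[[b]]$strand, seg_str, after = p)
  } else if (type == "fusion") {
    a <- op$chrom; b <- op$chrom2
    fused <- paste0(a, "+", b)
    merged <- list(ids = c(state[[a]]$ids, state[[b]]$ids),
                   strand = c(state[[a]]$strand, state[[b]]$strand))
    pos <- match(a, names(state))
    state[[a]] <- merged
    names(state)[pos] <- fused
    state[[b]] <- NULL
  } else if (type == "fission") {
    ch <- op$chrom
    j <- op$seg_start
    ids <- state[[ch]]$ids; str <- state[[ch]]$strand
    pos <- match(ch, names(state))
    left <- list(ids = ids[seq_len(j)], strand = str[seq_len(j)])
    right <- list(ids = ids[-seq_len(j)], strand = str[-seq_len(j)])
    state[[ch]] <- left
    names(state)[pos] <- paste0(ch, ".1")
    state <- append(state, stats::setNames(list(right),
                                           paste0(ch, ".2")),
                    after = pos)
  } else stop("unknown operation type: ", type)
  state
}

.emptyLog <- function() {
  data.frame(op_index = integer(), op_type = character(),
             chrom = character(), chrom2 = character(),
             seg_start = integer(), seg_end = integer(),
             dest_pos = integer(), inverted = logical(),
             stringsAsFactors = FALSE)
}

#' Apply simulated rearrangement operations to a genome
#'
#' Draws the configured numbers of inversions, translocations, fusions and
#' fissions in seed-determined random order and applies them sequentially:
#' an inversion reverses a contiguous anchor segment and flips its strands;
#' a translocation excises a segment and inserts it at a drawn position on
#' another chromosome (optionally inverted); a fusion concatenates two
#' chromosomes; a fission splits one at a drawn anchor boundary. Infeasible
#' draws are retried up to 100 times, then fail.
#'
#' In `nonOverlapping` mode each operation claims its chromosome(s)
#' exclusively and segments stay clear of chromosome ends, so planted
#' operations remain individually recoverable (see [simConfig()]).
#'
#' @param genome ancestral [AnchorSet-class] (typically from
#'   [simulateAncestor()] with the same config).
#' @param config a [simConfig()].
#' @return list with `genome` (the derived [AnchorSet-class]), `log` (the
#'   operation log `data.frame`, seed attached as `attr(, "seed")`) and
#'   `map` (the ancestor-to-derived [HomologyMap-class], one-to-one by
#'   gene id).
#' @export
applyOperations <- function(genome, config) {
  stopifnot(is(genome, "AnchorSet"), inherits(config, "SimConfig"))
  set.seed(config$seed)
  state <- .stateFromAnchorSet(genome)
  ops <- rep(c("inversion", "translocation", "fusion", "fission"),
             c(config$nInversions, config$nTranslocations,
               config$nFusions, config$nFissions))
  ops <- ops[sample.int(length(ops))]
  if (config$nonOverlapping) {
    need <- config$nInversions + 2L * config$nTranslocations +
      2L * config$nFusions + config$nFissions
    if (need > length(state))
      stop("nonOverlapping mode needs ", need,
           " distinct chromosomes but only ", length(state),
           " are available")
  }
  used <- character()
  log <- .emptyLog()
  pick <- function(candidates) {
    if (length(candidates) == 0L) return(NA_character_)
    candidates[sample.int(length(candidates), 1L)]
  }
  for (t in seq_along(ops)) {
    type <- ops[t]
    op <- NULL
    for (try in seq_len(100L)) {
      avail <- names(state)
      if (config$nonOverlapping) avail <- setdiff(avail, used)
      klen <- vapply(state[avail], function(s) length(s$ids), 0L)
      margin <- if (config$nonOverlapping) 2L else 0L
      if (type == "inversion") {
        cand <- avail[klen >= config$segmentRange[1L] + margin]
        ch <- pick(cand)
        if (is.na(ch)) next
        k <- length(state[[ch]]$ids)
        seg <- sample(seq(config$segmentRange[1L],
                          min(config$segmentRange[2L], k - margin)), 1L)
        lo <- if (config$nonOverlapping) 2L else 1L
        hi <- k - seg + 1L - (margin %/% 2L)
        s <- if (lo >= hi) lo else sample(seq(lo, hi), 1L)
        op <- list(op_type = type, chrom = ch, chrom2 = NA_character_,
                   seg_start = s, seg_end = s + seg - 1L,
                   dest_pos = NA_integer_, inverted = NA)
      } else if (type == "translocation") {
        cand <- avail[klen >= config$segmentRange[1L] + margin]
        a <- pick(cand)
        if (is.na(a)) next
        b <- pick(setdiff(avail[klen >= 2L], a))
        if (is.na(b)) next
        k <- length(state[[a]]$ids)
        seg <- sample(seq(config$segmentRange[1L],
                          min(config$segmentRange[2L], k - margin)), 1L)
        lo <- if (config$nonOverlapping) 2L else 1L
        hi <- k - seg + 1L - (margin %/% 2L)
        s <- if (lo >= hi) lo else sample(seq(lo, hi), 1L)
        kb <- length(state[[b]]$ids)
        p <- if (config$nonOverlapping) sample(seq(1L, kb - 1L), 1L)
             else sample(seq(0L, kb), 1L)
        op <- list(op_type = type, chrom = a, chrom2 = b,
                   seg_start = s, seg_end = s + seg - 1L, dest_pos = p,
                   inverted = stats::runif(1L) < config$invertOnMoveProb)
      } else if (type == "fusion") {
        cand <- avail[klen >= 1L]
        if (length(cand) < 2L) next
        a <- pick(cand)
        b <- pick(setdiff(cand, a))
        op <- list(op_type = type, chrom = a, chrom2 = b,
                   seg_start = NA_integer_, seg_end = NA_integer_,
                   dest_pos = NA_integer_, inverted = NA)
      } else { # fission
        cand <- avail[klen >= 2L]
        ch <- pick(cand)
        if (is.na(ch)) next
        k <- length(state[[ch]]$ids)
        j <- sample(seq_len(k - 1L), 1L)
        op <- list(op_type = type, chrom = ch, chrom2 = NA_character_,
                   seg_start = j, seg_end = NA_integer_,
                   dest_pos = NA_integer_, inverted = NA)
      }
      if (!is.null(op)) break
    }
    if (is.null(op))
      stop("could not draw a feasible ", type, " after 100 attempts")
    op$op_index <- t
    state <- .applyOp(state, op)
    used <- union(used, c(op$chrom, op$chrom2,
                          if (op$op_type == "fusion")
                            paste0(op$chrom, "+", op$chrom2),
                          if (op$op_type == "fission")
                            paste0(op$chrom, c(".1", ".2"))))
    used <- used[!is.na(used)]
    log <- rbind(log, data.frame(op[c("op_index", "op_type", "chrom",
                                      "chrom2", "seg_start", "seg_end",
                                      "dest_pos", "inverted")],
                                 stringsAsFactors = FALSE))
  }
  rownames(log) <- NULL
  attr(log, "seed") <- config$seed
  derived <- .anchorSetFromState(state, config,
                                 sprintf("derived_seed%d", config$seed))
  ids <- mcols(genome@anchors)$gene_id
  map <- makeHomologyMap(genome, derived,
                         data.frame(ref_id = ids, query_id = ids,
                                    stringsAsFactors = FALSE))
  list(genome = derived, log = log, map = map)
}

#' Replay an operation log deterministically
#'
#' Re-applies a ground-truth operation log to the ancestor without any
#' randomness; the result is bit-identical to the derived genome returned
#' by [applyOperations()].
#'
#' @param ancestor the ancestral [AnchorSet-class].
#' @param log operation log `data.frame` from [applyOperations()].
#' @param config the [simConfig()] used (needed for the coordinate
#'   layout).
#' @export
replayOperationLog <- function(ancestor, log, config) {
  state <- .stateFromAnchorSet(ancestor)
  for (i in seq_len(nrow(log)))
    state <- .applyOp(state, as.list(log[i, ]))
  .anchorSetFromState(state, config,
                      sprintf("derived_seed%d", config$seed))
}

#' Simulate a pair of sequences under the Kimura 2-parameter model
#'
#' Draws a uniform-random ancestral sequence and evolves two descendants,
#' each for distance `dTrue / 2`, using the exact closed-form K2P
#' substitution probabilities (per-site independent substitution) with
#' transition/transversion rate ratio `kappa`. The expected K2P distance
#' between the two descendants is `dTrue`.
#'
#' @param nSites alignment length in sites.
#' @param dTrue true pairwise distance in substitutions/site (>= 0).
#' @param kappa transition/transversion rate ratio (> 0). Default 4.
#' @param seed integer seed.
#' @return [Biostrings::DNAStringSet] of the two aligned descendant
#'   sequences, named `seqA` and `seqB`.
#' @export
simulateK2pPair <- function(nSites, dTrue, kappa = 4, seed = 1L) {
  if (dTrue < 0) stop("dTrue must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  set.seed(as.integer(seed))
  bases <- DNA_BASES
  anc <- sample(bases, nSites, replace = TRUE)
  # rates normalised so that alpha + 2 beta = 1 substitution per unit time
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  evolve <- function(seq, t) {
    if (t == 0) return(seq)
    e1 <- exp(-4 * beta * t)
    e2 <- exp(-2 * (alpha + beta) * t)
    p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    p_tv <- 0.25 - 0.25 * e1          # per transversion target
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    u <- stats::runif(length(seq))
    out <- seq
    out[u < p_ts] <- ts_partner[seq[u < p_ts]]
    sel <- u >= p_ts & u < p_ts + p_tv
    out[sel] <- tv1[seq[sel]]
    sel <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
    out[sel] <- tv2[seq[sel]]
    out
  }
  a <- evolve(anc, dTrue / 2)
  b <- evolve(anc, dTrue / 2)
  DNAStringSet(c(seqA = paste(a, collapse = ""),
                 seqB = paste(b, collapse = "")))
}
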