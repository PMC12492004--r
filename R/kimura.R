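# Kimura 2-parameter distances with pairwise deletion.
#
# Transitions are A<->G and C<->T; every other mismatch is a transversion.
# Sites where either sequence carries anything but A/C/G/T (gaps, ambiguity
# codes) are excluded per pair ("pairwise deletion"), so each matrix entry
# uses its own comparable-site count.

.seqToChars <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("sequences must be single character strings or DNAString objects")
  strsplit(toupper(x), "", fixed = TRUE)[[1L]]
}

.PURINES <- c("A", "G")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the transition proportion `P`, transversion proportion `Q` and
#' the K2P distance `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` in
#' substitutions per site, over the sites where both sequences carry an
#' unambiguous A/C/G/T.
#'
#' @param seqA,seqB aligned sequences of equal length: character strings or
#'   [Biostrings::DNAString] objects.
#' @return object of class `K2PResult`: a list with `n_sites`, `P`, `Q`,
#'   `d`.
#' @section Errors: unequal lengths, zero comparable sites, and saturation
#'   (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`, where the log-correction is
#'   undefined) are errors; saturation carries the condition class
#'   `k2p_saturated`.
#' @examples
#' k2pDistance("ACGTACGT", "ACGTACGA")
#' @export
k2pDistance <- function(seqA, seqB) {
  a <- .seqToChars(seqA)
  b <- .seqToChars(seqB)
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length (",
         length(a), " vs ", length(b), ")")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L)
    stop("no comparable sites (all positions gapped or ambiguous)")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  transition <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("k2p_saturated", "error", "condition"),
                   list(message = sprintf(
                     "saturated: K2P correction undefined (P=%.4f, Q=%.4f)",
                     P, Q), call = sys.call(-1L))))
  structure(list(n_sites = n, P = P, Q = Q,
                 d = -0.5 * log(w1) - 0.25 * log(w2)),
            class = "K2PResult")
}

#' @export
print.K2PResult <- function(x, ...) {
  cat(sprintf(
    "K2P distance: d = %.6f (P = %.4f, Q = %.4f over %d sites)\n",
    x$d, x$P, x$Q, x$n_sites))
  invisible(x)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Computes all pairwise K2P distances of a multiple alignment with
#' pairwise deletion of gapped/ambiguous sites. Saturated pairs (where the
#' log-correction is undefined) are reported as `NA` with a warning rather
#' than failing the whole matrix.
#'
#' @param alignment a [Biostrings::DNAStringSet] of equal-length aligned
#'   sequences, or the path of an aligned multi-FASTA file.
#' @return symmetric numeric matrix of distances with a zero diagonal,
#'   dimnames taken from the sequence names.
#' @export
k2pMatrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- readDNAStringSet(alignment)
  if (!is(alignment, "DNAStringSet"))
    stop("alignment must be a DNAStringSet or the path of a FASTA file")
  if (length(unique(width(alignment))) > 1L)
    stop("sequences are not aligned: unequal lengths")
  n <- length(alignment)
  nms <- names(alignment)
  if (is.null(nms)) nms <- paste0("seq", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  chars <- lapply(seq_len(n), function(i) .seqToChars(alignment[[i]]))
  saturated <- character()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- tryCatch(k2pDistance(paste(chars[[i]], collapse = ""),
                                paste(chars[[j]], collapse = ""))$d,
                    k2p_saturated = function(e) NA_real_)
      if (is.na(d))
        saturated <- c(saturated, paste0(nms[i], " vs ", nms[j]))
      m[i, j] <- m[j, i] <- d
    }
  }
  if (length(saturated))
    warning("saturated pair(s) reported as NA: ",
            paste(saturated, collapse = "; "))
  m
}

#' Distance-threshold species delimitation report
#'
#' Summarises a K2P distance matrix by species labels: for every pair of
#' species the minimum, maximum and mean between-species distance plus a
#' flag marking pairs whose mean distance exceeds the delimitation
#' threshold (2% is the conventional mammalian cox1 cutoff); for every
#' species with two or more sequences, the maximum within-species
#' distance.
#'
#' @param mat symmetric distance matrix from [k2pMatrix()].
#' @param labels species assignment: a named character vector
#'   (names = sequence ids) or a two-column `data.frame` (id, species)
#'   covering every row of `mat`.
#' @param threshold delimitation distance threshold. Default 0.02.
#' @return list with `inter` (`species_a`, `species_b`, `n_pairs`,
#'   `min_dist`, `max_dist`, `mean_dist`, `exceeds_threshold`), `intra`
#'   (`species`, `n_seqs`, `max_intra_dist`) and `threshold`.
#' @export
delimitSpecies <- function(mat, labels, threshold = 0.02) {
  if (is.data.frame(labels)) {
    lv <- as.character(labels[[2L]])
    names(lv) <- as.character(labels[[1L]])
    labels <- lv
  }
  ids <- rownames(mat)
  if (!all(ids %in% names(labels)))
    stop("labels missing for sequence(s): ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  sp <- unname(labels[ids])
  species <- sort(unique(sp))
  inter <- list()
  if (length(species) >= 2L) {
    cmb <- utils::combn(species, 2L)
    inter <- lapply(seq_len(ncol(cmb)), function(k) {
      v <- mat[sp == cmb[1L, k], sp == cmb[2L, k], drop = FALSE]
      v <- as.vector(v)
      data.frame(species_a = cmb[1L, k], species_b = cmb[2L, k],
                 n_pairs = length(v),
                 min_dist = min(v, na.rm = TRUE),
                 max_dist = max(v, na.rm = TRUE),
                 mean_dist = mean(v, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
  }
  inter <- if (length(inter)) do.call(rbind, inter) else
    data.frame(species_a = character(), species_b = character(),
               n_pairs = integer(), min_dist = numeric(),
               max_dist = numeric(), mean_dist = numeric(),
               stringsAsFactors = FALSE)
  inter$exceeds_threshold <- inter$mean_dist > threshold

  multi <- species[vapply(species, function(s) sum(sp == s), 0L) >= 2L]
  if (length(multi) == 0L) {
    warning("all species are singletons: no within-species distances")
    intra <- data.frame(species = character(), n_seqs = integer(),
                        max_intra_dist = numeric(), stringsAsFactors = FALSE)
  } else {
    intra <- do.call(rbind, lapply(multi, function(s) {
      sub <- mat[sp == s, sp == s, drop = FALSE]
      data.frame(species = s, n_seqs = sum(sp == s),
                 max_intra_dist = max(sub[upper.tri(sub)], na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(inter) <- rownames(intra) <- NULL
  list(inter = inter, intra = intra, threshold = threshold)
}
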