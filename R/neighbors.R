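#' Hamming distance between equal-length sequences
#'
#' Counts mismatching positions. N is treated as matching nothing,
#' including another N: an ambiguous base can never attest agreement.
#'
#' @param a,b character strings of equal length.
#' @return Integer mismatch count.
#' @examples
#' hammingDistance("ACGT", "ACGA")
#' hammingDistance("NN", "NN")  # 2
#' @export
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hammingDistance requires equal-length sequences")
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  rn <- charToRaw("N")
  sum(ra != rb | ra == rn | rb == rn)
}

#' Best (largest) overlap placement of two reads
#'
#' Two reads that share k-mers may do so at several relative shifts; the
#' algorithm uses the largest overlap between the pair. Each shared anchor
#' (posR, posN) induces the offset posR - posN, placing neighbor position j
#' against read position j + offset. Among the distinct offsets the
#' placement maximizing overlap length wins; ties are broken by fewer
#' mismatches, then smaller absolute offset, then smaller signed offset,
#' so the result is deterministic.
#'
#' @param a sequence of the read R (character).
#' @param b sequence of the candidate neighbor R' (character).
#' @param anchors two-column matrix or data.frame of shared k-mer start
#'   positions \code{(posR, posN)}, 1-based; at least one row.
#'
#' @return A list with \code{offset}, \code{length} (overlap length in
#'   bases) and \code{mismatches} (Hamming distance inside the overlap).
#' @examples
#' bestOverlap("AAAACCCC", "CCCCGGGG", cbind(5, 1))
#' @export
bestOverlap <- function(a, b, anchors) {
  anchors <- as.matrix(anchors)[, 1:2, drop = FALSE]
  if (nrow(anchors) == 0L)
    stop("bestOverlap needs at least one anchor")
  offsets <- sort(unique(as.integer(anchors[, 1L] - anchors[, 2L])))
  la <- nchar(a)
  lb <- nchar(b)
  best <- NULL
  for (off in offsets) {
    startA <- max(1L, 1L + off)
    endA <- min(la, off + lb)
    len <- endA - startA + 1L
    if (len < 1L) next                       # cannot occur for a real anchor
    mm <- hammingDistance(substr(a, startA, endA),
                          substr(b, startA - off, endA - off))
    cand <- list(offset = off, length = len, mismatches = mm)
    if (is.null(best) ||
        len > best$length ||
        (len == best$length && (mm < best$mismatches ||
          (mm == best$mismatches && abs(off) < abs(best$offset)))))
      best <- cand
  }
  best
}

#' Select true neighbors by overlap length and Hamming distance
#'
#' Prunes each candidate set C(R) down to the true neighbors T(R): a
#' candidate is retained iff its best overlap with R is at least
#' \code{minOverlap} bases long and contains at most \code{maxMismatch}
#' mismatches. Candidates sharing a k-mer by chance rarely survive this
#' filter, so T(R) consists of reads that very likely originate from the
#' same genomic region as R.
#'
#' @param candidates a [CandidateSet-class] derived from \code{reads}.
#' @param reads the [ReadSet-class] the candidates were computed over.
#' @param params an [ECParams-class]; \code{minOverlap} and
#'   \code{maxMismatch} are used.
#'
#' @return A [NeighborList-class].
#' @export
trueNeighbors <- function(candidates, reads, params = ecParams()) {
  stopifnot(methods::is(candidates, "CandidateSet"),
            methods::is(reads, "ReadSet"),
            methods::is(params, "ECParams"))
  if (length(candidates@candidates) != length(reads))
    stop("candidate set was computed over a different number of reads")
  seqs <- reads@seqs
  empty <- data.frame(neighbor = integer(), offset = integer(),
                      length = integer(), mismatches = integer())
  nb <- lapply(seq_along(seqs), function(i) {
    d <- candidates@candidates[[i]]
    if (nrow(d) == 0L) return(empty)
    rows <- lapply(unique(d$neighbor), function(j) {
      ov <- bestOverlap(seqs[i], seqs[j],
                        d[d$neighbor == j, c("posR", "posN")])
      if (ov$length >= params@minOverlap && ov$mismatches <= params@maxMismatch)
        data.frame(neighbor = j, offset = ov$offset, length = ov$length,
                   mismatches = ov$mismatches)
      else NULL
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) empty else out
  })
  methods::new("NeighborList", neighbors = nb)
}

#' @describeIn trueNeighbors neighbors retained for read \code{i}: a
#'   data.frame with columns \code{neighbor}, \code{offset},
#'   \code{length}, \code{mismatches}.
#' @param x a NeighborList.
#' @param i read index.
#' @export
neighborsOf <- function(x, i) {
  stopifnot(methods::is(x, "NeighborList"))
  x@neighbors[[i]]
}

#' @describeIn trueNeighbors display summary.
#' @param object a NeighborList.
#' @export
setMethod("show", "NeighborList", function(object) {
  sizes <- vapply(object@neighbors, nrow, integer(1))
  cat(sprintf("NeighborList over %d reads; mean |T(R)| = %.2f, max = %d\n",
              length(object@neighbors),
              if (length(sizes)) mean(sizes) else 0,
              if (length(sizes)) max(sizes) else 0L))
  invisible(NULL)
})
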