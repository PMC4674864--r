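#' Build the k-mer bucket index over a read set
#'
#' Decomposes every read into its overlapping k-mers and records each
#' occurrence in the bucket keyed by the exact k-mer string. A read of
#' length r contributes at most r - k + 1 occurrences; k-mers containing N
#' are skipped (an ambiguous base cannot attest sequence identity), and
#' reads shorter than k contribute nothing (a message reports how many).
#' Exact keying makes the bucket structure collision-free, so two
#' occurrences share a bucket exactly when their k-mers are identical.
#'
#' @param reads a [ReadSet-class].
#' @param k k-mer length (>= 1).
#'
#' @return A [KmerIndex-class].
#' @examples
#' idx <- buildKmerIndex(ReadSet(c("ACGTA", "ACGTT")), k = 4)
#' idx
#' @export
buildKmerIndex <- function(reads, k) {
  stopifnot(methods::is(reads, "ReadSet"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a single integer >= 1")
  if (k > 31L)
    stop("k must be <= 31 (2-bit packed keys)")
  nshort <- sum(nchar(reads@seqs) < k)
  if (nshort > 0L)
    message(nshort, " read(s) shorter than k = ", k, " contribute no k-mers")
  b <- cpp_kmer_index(reads@seqs, k)
  methods::new("KmerIndex", k = k, buckets = b,
               nreads = length(reads))
}

#' @describeIn buildKmerIndex display bucket summary.
#' @param object a KmerIndex.
#' @export
setMethod("show", "KmerIndex", function(object) {
  occ <- sum(vapply(object@buckets, nrow, integer(1)))
  cat(sprintf(
    "KmerIndex: k = %d, %d distinct k-mers, %d occurrences over %d reads\n",
    object@k, length(object@buckets), occ, object@nreads))
  invisible(NULL)
})

#' Candidate neighbors from shared k-mer buckets
#'
#' For every read R, collects the set C(R) of reads that fall into at least
#' one bucket R falls into, i.e. share at least one indexed k-mer with R.
#' Each candidate entry carries all shared anchor position pairs, which the
#' overlap step needs to place the two reads against each other. Buckets
#' holding more than \code{bucketCap} occurrences are skipped: such
#' mega-buckets arise from low-complexity repeats and would make the
#' neighbor-selection step quadratic.
#'
#' Candidacy is symmetric (R' in C(R) iff R in C(R')) and irreflexive.
#'
#' @param index a [KmerIndex-class] built over \code{reads}.
#' @param reads the same [ReadSet-class] the index was built from.
#' @param bucketCap occupancy cap; see above.
#'
#' @return A [CandidateSet-class].
#' @examples
#' rs <- ReadSet(c("AAAACCCC", "CCCCGGGG"))
#' cs <- candidateNeighbors(buildKmerIndex(rs, 4), rs)
#' candidateAnchors(cs, 1)
#' @export
candidateNeighbors <- function(index, reads, bucketCap = 1000) {
  stopifnot(methods::is(index, "KmerIndex"), methods::is(reads, "ReadSet"))
  if (index@nreads != length(reads))
    stop("index was built over a different number of reads")
  n <- length(reads)
  pieces <- vector("list", length(index@buckets))
  j <- 0L
  for (m in index@buckets) {
    nr <- nrow(m)
    if (nr < 2L || nr > bucketCap) next
    i1 <- rep(seq_len(nr), each = nr)
    i2 <- rep(seq_len(nr), times = nr)
    keep <- m[i1, 1L] != m[i2, 1L]      # ordered pairs of distinct reads
    if (!any(keep)) next
    j <- j + 1L
    pieces[[j]] <- cbind(read = m[i1[keep], 1L], neighbor = m[i2[keep], 1L],
                         posR = m[i1[keep], 2L], posN = m[i2[keep], 2L])
  }
  cand <- rep(list(data.frame(neighbor = integer(), posR = integer(),
                              posN = integer())), n)
  if (j > 0L) {
    all <- do.call(rbind, pieces[seq_len(j)])
    sp <- split.data.frame(all, factor(all[, "read"], levels = seq_len(n)))
    cand <- lapply(sp, function(m) {
      d <- data.frame(neighbor = m[, "neighbor"], posR = m[, "posR"],
                      posN = m[, "posN"])
      d <- unique(d)
      d[order(d$neighbor, d$posR, d$posN), , drop = FALSE]
    })
    cand <- unname(lapply(cand, function(d) {
      rownames(d) <- NULL
      d
    }))
  }
  methods::new("CandidateSet", candidates = cand, k = index@k)
}

#' @describeIn candidateNeighbors anchors shared between read \code{i} and
#'   its candidates: a data.frame with columns \code{neighbor},
#'   \code{posR}, \code{posN}.
#' @param x a CandidateSet.
#' @param i read index.
#' @export
candidateAnchors <- function(x, i) {
  stopifnot(methods::is(x, "CandidateSet"))
  x@candidates[[i]]
}

#' @describeIn candidateNeighbors display summary.
#' @param object a CandidateSet.
#' @export
setMethod("show", "CandidateSet", function(object) {
  sizes <- vapply(object@candidates,
                  function(d) length(unique(d$neighbor)), integer(1))
  cat(sprintf(
    "CandidateSet over %d reads (k = %d); mean |C(R)| = %.2f, max = %d\n",
    length(object@candidates), object@k,
    if (length(sizes)) mean(sizes) else 0,
    if (length(sizes)) max(sizes) else 0L))
  invisible(NULL)
})
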