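#' Correction parameters
#'
#' Constructs an [ECParams-class] object holding the tunable parameters of
#' the corrector. Defaults target typical short Illumina reads (length about
#' 60, substitution rate about 2%): \code{k = 15} (inside the 14--17
#' operating range), \code{minOverlap = 30} (half a typical read),
#' \code{maxMismatch = 2} (a single fixed Hamming threshold in the 1--3
#' range), \code{perfectWeight = 2}, \code{passes = 2} and
#' \code{minSupport = 2}. Use [autoParams()] to estimate \code{k},
#' \code{minOverlap} and \code{maxMismatch} from the data instead.
#'
#' @param k k-mer length for bucket hashing.
#' @param maxMismatch maximum Hamming distance inside a true neighbor's
#'   overlap.
#' @param minOverlap minimum overlap length (bases) of a true neighbor;
#'   must be >= \code{k}.
#' @param perfectWeight consensus weight w > 1 for bases voted by perfect
#'   reads.
#' @param passes number of correction passes. The first pass mostly
#'   establishes perfect flags with uniform weights; later passes exploit
#'   them.
#' @param minSupport minimum accumulated vote weight required before a base
#'   may be replaced; a lone non-perfect neighbor can never flip a base at
#'   the default of 2.
#' @param bucketCap occupancy cap above which a bucket is ignored during
#'   candidate generation (repeat guard).
#'
#' @return An [ECParams-class] object.
#' @examples
#' ecParams()
#' ecParams(k = 16, maxMismatch = 3)
#' @export
ecParams <- function(k = 15, maxMismatch = 2, minOverlap = 30,
                     perfectWeight = 2, passes = 2, minSupport = 2,
                     bucketCap = 1000) {
  methods::new("ECParams",
    k = as.integer(k),
    maxMismatch = as.integer(maxMismatch),
    minOverlap = as.integer(minOverlap),
    perfectWeight = as.numeric(perfectWeight),
    passes = as.integer(passes),
    minSupport = as.numeric(minSupport),
    bucketCap = as.integer(bucketCap))
}

#' @describeIn ecParams display resolved parameter values.
#' @param object an ECParams object.
#' @export
setMethod("show", "ECParams", function(object) {
  cat("ECParams:\n")
  cat(sprintf("  k            = %d\n", object@k))
  cat(sprintf("  maxMismatch  = %d\n", object@maxMismatch))
  cat(sprintf("  minOverlap   = %d\n", object@minOverlap))
  cat(sprintf("  perfectWeight= %g\n", object@perfectWeight))
  cat(sprintf("  passes       = %d\n", object@passes))
  cat(sprintf("  minSupport   = %g\n", object@minSupport))
  cat(sprintf("  bucketCap    = %d\n", object@bucketCap))
  invisible(NULL)
})

#' Estimate correction parameters from the input reads
#'
#' Data-driven parameter choice: \code{k} is set from the total base count
#' as \code{round(log4(n * r)) + 1}, then clamped to the 14--17 operating
#' range (large enough that unrelated reads essentially never share a
#' k-mer -- see [falseCandidateBound()] -- yet small enough that true
#' overlaps are found despite errors); \code{minOverlap} is half the median
#' read length (rounded up); \code{maxMismatch} is the expected number of
#' mismatches between two eps-error reads across \code{minOverlap} bases,
#' \code{round(2 * eps * minOverlap)}, clamped to 1--3. Any parameter given
#' explicitly in \code{...} overrides its estimate.
#'
#' @param reads a non-empty [ReadSet-class].
#' @param eps assumed per-base substitution error rate when no other
#'   estimate is available (default 0.02).
#' @param ... explicit overrides passed on to [ecParams()] (e.g.
#'   \code{k = 16}).
#'
#' @return An [ECParams-class] object.
#' @examples
#' rs <- ReadSet(strrep(c("ACGT", "CGTA"), 15))
#' autoParams(rs)
#' autoParams(rs, k = 15)  # explicit value wins
#' @export
autoParams <- function(reads, eps = 0.02, ...) {
  stopifnot(methods::is(reads, "ReadSet"))
  if (length(reads) == 0L)
    stop("cannot estimate parameters from an empty ReadSet")
  override <- list(...)
  widths <- nchar(reads@seqs)
  est <- list()
  est$k <- max(14L, min(17L, as.integer(round(log(sum(widths), base = 4))) + 1L))
  est$minOverlap <- as.integer(ceiling(stats::median(widths) / 2))
  est$maxMismatch <- max(1L, min(3L, as.integer(round(2 * eps * est$minOverlap))))
  est[names(override)] <- NULL
  p <- c(est, override)
  kFinal <- if (is.null(p$k)) 15L else as.integer(p$k)
  if (!("minOverlap" %in% names(override)))   # estimated overlap never below k
    p$minOverlap <- max(p$minOverlap, kFinal)
  do.call(ecParams, p)
}
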