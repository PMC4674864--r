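#' @import methods
NULL

#' ReadSet: an ordered collection of short sequencing reads
#'
#' The central container of the package. Each read carries an identifier, a
#' sequence over the 5-letter alphabet \{A, C, G, T, N\}, and two state flags
#' maintained by the corrector: \code{corrected} (the correction pass has
#' examined the read) and \code{perfect} (the pass examined it, found neighbor
#' support, and changed nothing -- such reads are treated as error-free and
#' their consensus votes carry extra weight in later passes).
#'
#' Correction is substitution-only: read lengths are invariant under every
#' operation in the package.
#'
#' @slot ids character vector of unique read identifiers.
#' @slot seqs character vector of read sequences (uppercase A/C/G/T/N).
#' @slot perfect logical vector; \code{TRUE} only for reads the corrector
#'   flagged as error-free. Implies \code{corrected}.
#' @slot corrected logical vector; \code{TRUE} once a correction pass has
#'   examined the read.
#'
#' @seealso [ReadSet()] for construction, [readFastx()] to read from file.
#' @exportClass ReadSet
setClass("ReadSet",
  slots = c(
    ids       = "character",
    seqs      = "character",
    perfect   = "logical",
    corrected = "logical"
  )
)

setValidity("ReadSet", function(object) {
  n <- length(object@seqs)
  if (length(object@ids) != n || length(object@perfect) != n ||
      length(object@corrected) != n)
    return("ids, seqs, perfect and corrected must have equal length")
  if (n == 0L)
    return(TRUE)
  if (anyDuplicated(object@ids))
    return("read ids must be unique within a ReadSet")
  if (any(nchar(object@seqs) < 1L))
    return("read sequences must have length >= 1")
  bad <- grep("^[ACGTN]+$", object@seqs, invert = TRUE)
  if (length(bad))
    return(sprintf("read %d contains characters outside {A,C,G,T,N}", bad[1L]))
  if (any(object@perfect & !object@corrected))
    return("a read can be flagged perfect only after it has been corrected")
  TRUE
})

#' ECParams: parameters of the correction algorithm
#'
#' @slot k integer, k-mer length used for bucket hashing. The algorithm's
#'   operating range on typical Illumina data is 14--17.
#' @slot maxMismatch integer, maximum Hamming distance allowed inside the
#'   overlap of a true neighbor (typical range 1--3).
#' @slot minOverlap integer, minimum overlap length (bases) for a candidate to
#'   qualify as a true neighbor; must be >= \code{k}.
#' @slot perfectWeight numeric >= 1, consensus vote weight w given to bases
#'   from perfect reads (non-perfect reads vote with weight 1).
#' @slot passes integer >= 1, number of correction passes; the k-mer index and
#'   neighbor lists are rebuilt each pass.
#' @slot minSupport numeric >= 1, minimum accumulated vote weight a base needs
#'   before it may replace the read's current base.
#' @slot bucketCap integer, buckets holding more occurrences than this are
#'   skipped during candidate generation (guards against low-complexity
#'   repeats).
#'
#' @seealso [ecParams()], [autoParams()]
#' @exportClass ECParams
setClass("ECParams",
  slots = c(
    k             = "integer",
    maxMismatch   = "integer",
    minOverlap    = "integer",
    perfectWeight = "numeric",
    passes        = "integer",
    minSupport    = "numeric",
    bucketCap     = "integer"
  )
)

setValidity("ECParams", function(object) {
  if (length(object@k) != 1L || object@k < 1L)
    return("k must be a single integer >= 1")
  if (object@maxMismatch < 0L)
    return("maxMismatch must be >= 0")
  if (object@minOverlap < object@k)
    return("minOverlap must be >= k")
  if (object@perfectWeight < 1)
    return("perfectWeight must be >= 1")
  if (object@passes < 1L)
    return("passes must be >= 1")
  if (object@minSupport < 1)
    return("minSupport must be >= 1")
  if (object@bucketCap < 1L)
    return("bucketCap must be >= 1")
  TRUE
})

#' KmerIndex: k-mer bucket index over a ReadSet
#'
#' Maps every k-mer occurring in a read collection (k-mers containing N are
#' skipped) to the list of its occurrences. Keying is exact, so two
#' occurrences share a bucket if and only if their k-mers are identical --
#' a collision-free realization of the hash table the algorithm is built on.
#'
#' @slot k integer k-mer length.
#' @slot buckets named list; names are k-mer strings, each element an integer
#'   matrix with columns \code{read} (read index) and \code{pos} (1-based
#'   start position of the k-mer within the read).
#' @slot nreads integer, number of reads the index was built over.
#'
#' @seealso [buildKmerIndex()], [candidateNeighbors()]
#' @exportClass KmerIndex
setClass("KmerIndex",
  slots = c(
    k       = "integer",
    buckets = "list",
    nreads  = "integer"
  )
)

setValidity("KmerIndex", function(object) {
  if (length(object@k) != 1L || object@k < 1L)
    return("k must be a single integer >= 1")
  if (length(object@buckets) &&
      any(nchar(names(object@buckets)) != object@k))
    return("every bucket key must be a k-mer of length k")
  TRUE
})

#' CandidateSet: per-read candidate neighbors with shared k-mer anchors
#'
#' For each read R, C(R) lists every other read sharing at least one indexed
#' k-mer with R, together with all shared anchor positions. Candidacy is
#' symmetric and a read is never its own candidate.
#'
#' @slot candidates list of length \code{nreads}; element i is a data.frame
#'   with columns \code{neighbor}, \code{posR}, \code{posN}: read i carries
#'   the same k-mer at \code{posR} as read \code{neighbor} does at
#'   \code{posN} (1-based).
#' @slot k integer k-mer length of the underlying index.
#' @exportClass CandidateSet
setClass("CandidateSet",
  slots = c(candidates = "list", k = "integer")
)

#' NeighborList: true neighbors retained for correction
#'
#' For each read R, T(R) is the subset of C(R) whose best (largest) overlap
#' with R is at least \code{minOverlap} long and has at most
#' \code{maxMismatch} mismatches.
#'
#' @slot neighbors list of length \code{nreads}; element i is a data.frame
#'   with columns \code{neighbor}, \code{offset}, \code{length},
#'   \code{mismatches}. \code{offset} is the signed shift of the neighbor
#'   relative to read i: neighbor position j aligns read position j + offset.
#' @exportClass NeighborList
setClass("NeighborList", slots = c(neighbors = "list"))

#' EvalCounts: per-base outcome tallies of a correction run
#'
#' Every base of every read falls in exactly one class when the original
#' reads, the corrected reads, and the simulator truth are compared:
#' \describe{
#'   \item{TP}{erroneous base changed to the true base}
#'   \item{be}{erroneous base changed, but to another wrong base}
#'   \item{FN}{erroneous base left unchanged (error not detected)}
#'   \item{FP}{originally-correct base changed (to anything)}
#'   \item{TN}{originally-correct base left unchanged}
#' }
#' So TP + be + FN equals the number of injected errors and FP + TN the
#' number of originally-correct bases.
#'
#' @slot tp,fp,tn,fn,be numeric tallies (>= 0).
#' @seealso [classifyCorrections()], [correctionMetrics()]
#' @exportClass EvalCounts
setClass("EvalCounts",
  slots = c(tp = "numeric", fp = "numeric", tn = "numeric",
            fn = "numeric", be = "numeric")
)

setValidity("EvalCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn, object@be)
  if (length(v) != 5L || any(v < 0))
    return("all counts must be single non-negative numbers")
  TRUE
})
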