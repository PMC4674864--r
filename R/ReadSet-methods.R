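#' Construct a ReadSet
#'
#' @param seqs character vector of sequences, or a
#'   [Biostrings::DNAStringSet]. Lowercase input is uppercased; characters
#'   outside \{A,C,G,T,N\} are rejected.
#' @param ids character vector of unique identifiers; defaults to the names
#'   of \code{seqs} or \code{"read1" ... "readn"}.
#' @param perfect,corrected logical vectors (recycled from length 1);
#'   normally left at \code{FALSE} and set by [correctReads()].
#'
#' @return A [ReadSet-class] object.
#' @examples
#' rs <- ReadSet(c("ACGT", "acgtn"))
#' readSeqs(rs)
#' @export
ReadSet <- function(seqs = character(), ids = NULL,
                    perfect = FALSE, corrected = FALSE) {
  if (methods::is(seqs, "XStringSet")) {
    if (is.null(ids)) ids <- names(seqs)
    seqs <- as.character(seqs)
  }
  seqs <- toupper(as.character(unname(seqs)))
  n <- length(seqs)
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- if (n) sprintf("read%d", seq_len(n)) else character()
  perfect <- rep_len(as.logical(perfect), n)
  corrected <- rep_len(as.logical(corrected), n)
  methods::new("ReadSet", ids = as.character(ids), seqs = seqs,
               perfect = perfect, corrected = corrected)
}

#' @rdname ReadSet
#' @export
setMethod("readIds", "ReadSet", function(x) x@ids)

#' @rdname ReadSet
#' @export
setMethod("readSeqs", "ReadSet", function(x) stats::setNames(x@seqs, x@ids))

#' @rdname ReadSet
#' @export
setMethod("isPerfect", "ReadSet", function(x) x@perfect)

#' @rdname ReadSet
#' @export
setMethod("isCorrected", "ReadSet", function(x) x@corrected)

#' @describeIn ReadSet number of reads in the set.
#' @export
setMethod("length", "ReadSet", function(x) length(x@seqs))

#' @describeIn ReadSet widths (base lengths) of the reads.
#' @export
setMethod("nchar", "ReadSet", function(x) nchar(x@seqs))

#' @describeIn ReadSet subset by index, logical mask or read id.
#' @param i index vector.
#' @param j,drop,... ignored (matrix-style arguments).
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  methods::new("ReadSet", ids = x@ids[i], seqs = x@seqs[i],
               perfect = x@perfect[i], corrected = x@corrected[i])
})

#' @describeIn ReadSet compact display.
#' @param object a ReadSet.
#' @export
setMethod("show", "ReadSet", function(object) {
  n <- length(object)
  cat(sprintf("ReadSet with %d read%s", n, if (n == 1L) "" else "s"))
  if (n) {
    w <- nchar(object@seqs)
    cat(sprintf(" (width %s%s)",
                min(w), if (min(w) == max(w)) "" else paste0("-", max(w))))
    cat(sprintf("; corrected: %d, perfect: %d",
                sum(object@corrected), sum(object@perfect)))
  }
  cat("\n")
  if (n) {
    k <- seq_len(min(n, 5L))
    s <- object@seqs[k]
    long <- nchar(s) > 40L
    s[long] <- paste0(substr(s[long], 1L, 37L), "...")
    cat(sprintf("  %s  %s\n", format(object@ids[k]), s))
    if (n > 5L) cat(sprintf("  ... and %d more\n", n - 5L))
  }
  invisible(NULL)
})

setAs("ReadSet", "DNAStringSet", function(from) {
  Biostrings::DNAStringSet(stats::setNames(from@seqs, from@ids))
})

setAs("DNAStringSet", "ReadSet", function(from) ReadSet(from))

## internal: replace sequences/flags without re-running full validity per read
.updateReads <- function(x, seqs = x@seqs, perfect = x@perfect,
                         corrected = x@corrected) {
  methods::new("ReadSet", ids = x@ids, seqs = seqs,
               perfect = perfect, corrected = corrected)
}
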