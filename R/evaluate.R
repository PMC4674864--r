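#' Classify per-base correction outcomes against simulator truth
#'
#' Compares every base of every read across the original (corrupted)
#' reads, the corrected reads and the true source substrings, and tallies
#' the five outcome classes (see [EvalCounts-class]): an erroneous base
#' restored to the truth is TP; an erroneous base changed to another wrong
#' base is b_e; an erroneous base left alone is FN; an originally-correct
#' base changed to anything is FP; an originally-correct base left alone
#' is TN.
#'
#' @param original the [ReadSet-class] before correction.
#' @param corrected the [ReadSet-class] after correction; same reads, same
#'   order, same lengths.
#' @param truth the truth data.frame from [simulateReads()] (one row per
#'   read, index-aligned).
#'
#' @return An [EvalCounts-class] object.
#' @seealso [correctionMetrics()], [cumulativeHamming()], [mappedFraction()]
#' @export
classifyCorrections <- function(original, corrected, truth) {
  stopifnot(methods::is(original, "ReadSet"), methods::is(corrected, "ReadSet"))
  n <- length(original)
  if (length(corrected) != n || nrow(truth) != n)
    stop("original, corrected and truth must cover the same reads")
  if (!all(nchar(original@seqs) == nchar(corrected@seqs)) ||
      !all(nchar(original@seqs) == nchar(truth$trueSeq)))
    stop("read lengths differ between original, corrected and truth")
  tp <- fp <- tn <- fn <- be <- 0
  for (i in seq_len(n)) {
    o <- charToRaw(original@seqs[i])
    c_ <- charToRaw(corrected@seqs[i])
    t_ <- charToRaw(truth$trueSeq[i])
    wasError <- o != t_
    changed <- c_ != o
    nowCorrect <- c_ == t_
    tp <- tp + sum(wasError & changed & nowCorrect)
    be <- be + sum(wasError & changed & !nowCorrect)
    fn <- fn + sum(wasError & !changed)
    fp <- fp + sum(!wasError & changed)
    tn <- tn + sum(!wasError & !changed)
  }
  methods::new("EvalCounts", tp = tp, fp = fp, tn = tn, fn = fn, be = be)
}

#' @rdname EvalCounts-class
#' @export
setMethod("evalCounts", "EvalCounts", function(x) {
  c(TP = x@tp, FP = x@fp, TN = x@tn, FN = x@fn, b_e = x@be)
})

#' @rdname EvalCounts-class
#' @param object an EvalCounts.
#' @export
setMethod("show", "EvalCounts", function(object) {
  cat("EvalCounts:\n")
  v <- evalCounts(object)
  for (nm in names(v)) cat(sprintf("  %-3s = %g\n", nm, v[[nm]]))
  invisible(NULL)
})

#' Corrector performance metrics from outcome tallies
#'
#' \describe{
#'   \item{sensitivity}{TP / (TP + FN) -- fraction of errors the corrector
#'     fixed among those it either fixed or missed.}
#'   \item{specificity}{TN / (TN + FP) -- fraction of correct bases left
#'     untouched.}
#'   \item{accuracy}{(TP - FP) / (TP + FN), the \emph{gain}: net fraction
#'     of errors effectively removed. Negative when the corrector
#'     introduces more errors than it removes.}
#'   \item{eba}{b_e / (TP + b_e) -- among bases the corrector identified as
#'     erroneous and changed, the fraction it changed to the wrong base
#'     (lower is better).}
#' }
#' A metric whose denominator is 0 is reported as \code{NA} (undefined),
#' never as 0.
#'
#' @param counts an [EvalCounts-class] from [classifyCorrections()].
#' @return Named numeric vector with elements \code{sensitivity},
#'   \code{specificity}, \code{accuracy}, \code{eba}.
#' @examples
#' correctionMetrics(methods::new("EvalCounts", tp = 9, fp = 1, tn = 90,
#'                                fn = 1, be = 0))
#' @export
correctionMetrics <- function(counts) {
  stopifnot(methods::is(counts, "EvalCounts"))
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = rate(counts@tp, counts@tp + counts@fn),
    specificity = rate(counts@tn, counts@tn + counts@fp),
    accuracy    = rate(counts@tp - counts@fp, counts@tp + counts@fn),
    eba         = rate(counts@be, counts@tp + counts@be))
}

#' Cumulative Hamming distance to the true source sequences
#'
#' Sums, over all reads, the Hamming distance between the corrected read
#' and its true source substring: the total residual substitution load
#' after correction. 0 means every read was restored exactly.
#'
#' @param corrected a [ReadSet-class] after correction.
#' @param truth the index-aligned truth data.frame.
#' @return Integer total distance.
#' @export
cumulativeHamming <- function(corrected, truth) {
  stopifnot(methods::is(corrected, "ReadSet"))
  if (length(corrected) != nrow(truth))
    stop("corrected reads and truth must cover the same reads")
  sum(vapply(seq_len(length(corrected)), function(i)
    hammingDistance(corrected@seqs[i], truth$trueSeq[i]), numeric(1)))
}

#' Fraction of reads within d mismatches of their source
#'
#' The truth-based analogue of the fraction of reads mappable to the
#' reference with at most d mismatches: since the simulator records each
#' read's source substring, no alignment is needed.
#'
#' @param corrected a [ReadSet-class] after correction.
#' @param truth the index-aligned truth data.frame.
#' @param d maximum number of mismatches (>= 0).
#' @return Fraction in [0, 1] (NA for an empty read set).
#' @export
mappedFraction <- function(corrected, truth, d) {
  stopifnot(methods::is(corrected, "ReadSet"), d >= 0)
  n <- length(corrected)
  if (n == 0L) return(NA_real_)
  hd <- vapply(seq_len(n), function(i)
    hammingDistance(corrected@seqs[i], truth$trueSeq[i]), numeric(1))
  mean(hd <= d)
}

#' One-row TSV of all evaluation metrics
#'
#' @param counts an [EvalCounts-class].
#' @param corrected corrected [ReadSet-class].
#' @param truth index-aligned truth data.frame.
#' @param path output file path.
#' @param d mismatch allowance for [mappedFraction()].
#' @return The one-row data.frame, invisibly; written to \code{path}.
#' @export
writeMetrics <- function(counts, corrected, truth, path, d = 10) {
  m <- correctionMetrics(counts)
  row <- data.frame(t(evalCounts(counts)), t(m),
                    chd = cumulativeHamming(corrected, truth),
                    mappedFraction = mappedFraction(corrected, truth, d))
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(row)
}
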