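#' Per-column weighted consensus votes for one read
#'
#' Accumulates, for every position of read \code{i}, the vote weight each
#' base receives from the true neighbors covering that position. A
#' non-perfect neighbor votes with weight 1, a perfect neighbor with
#' \code{params@perfectWeight}; an N in a neighbor votes for nothing. The
#' read's own base does not vote -- it is the incumbent that a winning base
#' must strictly beat in [correctRead()].
#'
#' @param i index of the read in \code{reads}.
#' @param neighbors the [trueNeighbors()] entry for read \code{i} (a
#'   data.frame with columns \code{neighbor} and \code{offset}), e.g.
#'   \code{neighborsOf(nbl, i)}.
#' @param reads the [ReadSet-class] (current sequences and perfect flags).
#' @param params an [ECParams-class].
#'
#' @return A 4 x r numeric matrix of vote weights, rows named A, C, G, T.
#' @export
columnVotes <- function(i, neighbors, reads, params = ecParams()) {
  stopifnot(methods::is(reads, "ReadSet"))
  r <- nchar(reads@seqs[i])
  votes <- matrix(0, nrow = 4L, ncol = r, dimnames = list(c("A", "C", "G", "T")))
  if (is.null(neighbors) || nrow(neighbors) == 0L)
    return(votes)
  for (row in seq_len(nrow(neighbors))) {
    j <- neighbors$neighbor[row]
    off <- neighbors$offset[row]
    w <- if (reads@perfect[j]) params@perfectWeight else 1
    tseq <- reads@seqs[j]
    startR <- max(1L, 1L + off)
    endR <- min(r, off + nchar(tseq))
    if (endR < startR) next
    bases <- strsplit(substr(tseq, startR - off, endR - off), "", fixed = TRUE)[[1L]]
    code <- match(bases, c("A", "C", "G", "T"))   # N -> NA, votes for nothing
    pos <- startR:endR
    ok <- !is.na(code)
    for (p in which(ok))
      votes[code[p], pos[p]] <- votes[code[p], pos[p]] + w
  }
  votes
}

#' Apply consensus correction to a single read sequence
#'
#' Position i of the read is changed to the base with the maximum vote
#' weight iff that weight is at least \code{params@minSupport} and strictly
#' exceeds the weight accumulated for the read's current base; on a tie the
#' current base is retained. An N in the read holds weight 0 and is thus
#' replaced by any base reaching \code{minSupport}. If two bases tie at the
#' winning weight, the alphabetically first is taken (deterministic).
#'
#' The read is \emph{perfect} if nothing changed and at least one column
#' had nonzero support: the procedure looked for incorrect bases and found
#' none. A read with no neighbor evidence at all is never perfect.
#'
#' @param seq character, the read's current sequence.
#' @param votes 4 x r vote matrix from [columnVotes()].
#' @param params an [ECParams-class].
#'
#' @return A list with \code{seq} (corrected sequence), \code{nChanged}
#'   (positions changed) and \code{perfect} (logical).
#' @export
correctRead <- function(seq, votes, params = ecParams()) {
  r <- nchar(seq)
  stopifnot(ncol(votes) == r, nrow(votes) == 4L)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  incumbent <- match(bases, c("A", "C", "G", "T"))
  changed <- 0L
  for (p in seq_len(r)) {
    col <- votes[, p]
    best <- which.max(col)                     # ties -> first (A<C<G<T)
    bw <- col[best]
    iw <- if (is.na(incumbent[p])) 0 else col[incumbent[p]]
    if (bw >= params@minSupport && bw > iw) {
      bases[p] <- c("A", "C", "G", "T")[best]
      changed <- changed + 1L
    }
  }
  list(seq = paste(bases, collapse = ""),
       nChanged = changed,
       perfect = changed == 0L && any(colSums(votes) > 0))
}

#' Correct a read set by k-mer-anchored weighted consensus
#'
#' Runs the full correction algorithm: each pass builds the k-mer bucket
#' index, derives candidate neighbors from shared buckets, prunes them to
#' true neighbors by overlap length and Hamming distance, and then corrects
#' the reads \emph{sequentially in input order}, updating sequences and
#' perfect flags in place so that later reads are corrected against the
#' already-corrected (and possibly perfect-flagged) earlier ones -- both
#' corrected and uncorrected reads take part in every consensus. The index
#' and neighbor lists are rebuilt for each of \code{params@passes} passes,
#' since correction changes the k-mer content of the reads. Read lengths
#' are never altered (substitution-only model).
#'
#' @param reads a [ReadSet-class].
#' @param params an [ECParams-class]; see [ecParams()] and [autoParams()].
#' @param verbose print per-pass progress to the console.
#'
#' @return A list with elements
#'   \describe{
#'     \item{reads}{the corrected [ReadSet-class] (all reads flagged
#'       corrected; perfect flags as of the final pass).}
#'     \item{report}{a list with \code{perRead} (integer vector, positions
#'       changed per read, summed over passes), \code{basesChanged},
#'       \code{readsChanged}, \code{readsPerfect} and \code{passChanges}
#'       (bases changed in each pass).}
#'   }
#' @examples
#' sim <- simulateReads(genomeLen = 2000, readLen = 60, coverage = 20,
#'                      eps = 0.01, seed = 7)
#' res <- correctReads(sim$reads, ecParams())
#' res$report$basesChanged
#' @export
correctReads <- function(reads, params = ecParams(), verbose = FALSE) {
  stopifnot(methods::is(reads, "ReadSet"), methods::is(params, "ECParams"))
  methods::validObject(params)
  if (length(reads) == 0L)
    return(list(reads = reads,
                report = list(perRead = integer(), basesChanged = 0L,
                              readsChanged = 0L, readsPerfect = 0L,
                              passChanges = integer(params@passes))))
  seqs <- reads@seqs
  perfect <- reads@perfect
  perRead <- integer(length(seqs))
  passChanges <- integer(params@passes)
  for (pass in seq_len(params@passes)) {
    res <- cpp_correct_pass(seqs, perfect, params@k, params@minOverlap,
                            params@maxMismatch, params@perfectWeight,
                            params@minSupport, params@bucketCap)
    seqs <- res$seqs
    perfect <- res$perfect
    perRead <- perRead + res$changes
    passChanges[pass] <- sum(res$changes)
    if (verbose)
      message(sprintf("pass %d: %d bases changed, %d perfect reads",
                      pass, passChanges[pass], sum(perfect)))
  }
  out <- .updateReads(reads, seqs = seqs, perfect = perfect,
                      corrected = rep(TRUE, length(seqs)))
  list(reads = out,
       report = list(perRead = perRead,
                     basesChanged = sum(perRead),
                     readsChanged = sum(perRead > 0L),
                     readsPerfect = sum(perfect),
                     passChanges = passChanges))
}

#' Write a correction report as TSV
#'
#' One row per read (id, positions changed, perfect flag) preceded by
#' commented summary lines.
#'
#' @param result the list returned by [correctReads()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCorrectionReport <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rep <- result$report
  writeLines(sprintf("# basesChanged\t%d", rep$basesChanged), con)
  writeLines(sprintf("# readsChanged\t%d", rep$readsChanged), con)
  writeLines(sprintf("# readsPerfect\t%d", rep$readsPerfect), con)
  df <- data.frame(id = readIds(result$reads),
                   changed = rep$perRead,
                   perfect = as.integer(isPerfect(result$reads)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
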