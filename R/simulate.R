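#' Random genome sequence
#'
#' Each base is drawn independently and uniformly from \{A, C, G, T\} --
#' the random-genome model under which the package's probability formulas
#' are derived.
#'
#' @param length genome length in bases (>= 1).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return A single character string.
#' @examples
#' substr(randomGenome(50, seed = 1), 1, 10)
#' @export
randomGenome <- function(length, seed = NULL) {
  if (length < 1) stop("genome length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Number of simulated reads at a given coverage
#'
#' The simulator generates \code{floor(coverage * genomeLen / readLen)}
#' reads, so that the total sequenced bases are as close to
#' \code{coverage * genomeLen} as whole reads allow.
#'
#' @param genomeLen genome length |G| in bases.
#' @param readLen read length r in bases.
#' @param coverage fold-coverage c.
#' @return Integer read count.
#' @examples
#' nSimReads(2598144, 60, 50)  # 2165120
#' @export
nSimReads <- function(genomeLen, readLen, coverage) {
  floor(coverage * genomeLen / readLen)
}

#' Sample error-free reads from random genome positions
#'
#' Draws \code{nSimReads(...)} reads of fixed length, each starting at a
#' position chosen uniformly so the read never runs off the genome end,
#' and records the ground truth needed to evaluate a corrector without any
#' mapping step.
#'
#' @param genome genome sequence (character string over A/C/G/T).
#' @param readLen read length r (<= nchar(genome)).
#' @param coverage fold-coverage c (>= 0).
#' @param seed optional integer seed.
#'
#' @return A list with
#'   \describe{
#'     \item{reads}{a [ReadSet-class] of error-free reads.}
#'     \item{truth}{a data.frame with columns \code{read} (id),
#'       \code{start} (1-based genome offset), \code{trueSeq} (the
#'       uncorrupted substring) and \code{errorPos} (list column of read
#'       offsets carrying injected substitutions; empty here).}
#'   }
#' @seealso [injectErrors()], [simulateReads()]
#' @export
sampleReads <- function(genome, readLen, coverage, seed = NULL) {
  g <- nchar(genome)
  if (readLen > g) stop("read length exceeds genome length")
  if (readLen < 1) stop("read length must be >= 1")
  if (coverage < 0) stop("coverage must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nSimReads(g, readLen, coverage)
  if (n == 0L) {
    return(list(reads = ReadSet(),
                truth = data.frame(read = character(), start = integer(),
                                   trueSeq = character(),
                                   errorPos = I(list()))))
  }
  starts <- sample.int(g - readLen + 1L, n, replace = TRUE)
  seqs <- substring(genome, starts, starts + readLen - 1L)
  ids <- sprintf("sim%d", seq_len(n))
  truth <- data.frame(read = ids, start = starts, trueSeq = seqs,
                      stringsAsFactors = FALSE)
  truth$errorPos <- rep(list(integer()), n)
  list(reads = ReadSet(seqs, ids = ids), truth = truth)
}

#' Inject uniform substitution errors
#'
#' Each base of each read is independently replaced, with probability
#' \code{eps}, by one of the three other bases chosen uniformly; the
#' positions of the injected substitutions are appended to the truth
#' records. This emulates a substitution-only sequencer with a uniform,
#' position-independent error profile.
#'
#' @param reads a [ReadSet-class] of (typically error-free) reads.
#' @param truth the truth data.frame from [sampleReads()].
#' @param eps per-base substitution probability in [0, 1].
#' @param seed optional integer seed.
#'
#' @return A list with the corrupted \code{reads} and the updated
#'   \code{truth}.
#' @export
injectErrors <- function(reads, truth, eps, seed = NULL) {
  stopifnot(methods::is(reads, "ReadSet"))
  if (eps < 0 || eps > 1) stop("eps must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(reads)
  if (n == 0L || eps == 0)
    return(list(reads = reads, truth = truth))
  seqs <- reads@seqs
  widths <- nchar(seqs)
  alphabet <- c("A", "C", "G", "T")
  errlist <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- which(stats::runif(widths[i]) < eps)
    errlist[[i]] <- hit
    if (length(hit)) {
      bases <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (p in hit) {
        others <- alphabet[alphabet != bases[p]]
        bases[p] <- others[sample.int(3L, 1L)]
      }
      seqs[i] <- paste(bases, collapse = "")
    }
  }
  truth$errorPos <- lapply(seq_len(n), function(i)
    sort(unique(c(truth$errorPos[[i]], errlist[[i]]))))
  list(reads = .updateReads(reads, seqs = seqs), truth = truth)
}

#' Simulate a truth-tracked read set
#'
#' Convenience wrapper: generates (or accepts) a genome, samples reads
#' from uniform random start positions at the requested coverage, and
#' injects uniform substitution errors. All randomness is derived from
#' \code{seed}, so identical arguments reproduce identical data.
#'
#' @param genomeLen length of the random genome to generate; ignored when
#'   \code{genome} is supplied.
#' @param readLen read length r.
#' @param coverage fold-coverage c.
#' @param eps per-base substitution probability.
#' @param seed optional integer seed.
#' @param genome optional genome sequence to use instead of a random one.
#'
#' @return A list with \code{genome}, \code{reads} (corrupted
#'   [ReadSet-class]) and \code{truth} (see [sampleReads()]).
#' @examples
#' sim <- simulateReads(genomeLen = 1000, readLen = 50, coverage = 10,
#'                      eps = 0.02, seed = 42)
#' length(sim$reads)
#' @export
simulateReads <- function(genomeLen = NULL, readLen, coverage, eps,
                          seed = NULL, genome = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genome)) {
    if (is.null(genomeLen)) stop("supply either genome or genomeLen")
    genome <- randomGenome(genomeLen)
  } else {
    genome <- toupper(genome)
  }
  sam <- sampleReads(genome, readLen, coverage)
  err <- injectErrors(sam$reads, sam$truth, eps)
  list(genome = genome, reads = err$reads, truth = err$truth)
}

#' Write simulator truth records as TSV
#'
#' Columns: read id, 1-based genome start, true (uncorrupted) sequence and
#' comma-separated 1-based error positions.
#'
#' @param truth truth data.frame from [simulateReads()] or [sampleReads()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readTruth()]
#' @export
writeTruth <- function(truth, path) {
  df <- data.frame(read = truth$read, start = truth$start,
                   trueSeq = truth$trueSeq,
                   errorPos = vapply(truth$errorPos, paste,
                                     character(1), collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @return \code{readTruth}: the truth data.frame with \code{errorPos}
#'   restored as a list of integer vectors.
#' @export
readTruth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer",
                                         "character", "character"),
                          na.strings = NULL)
  df$errorPos <- lapply(df$errorPos, function(s)
    if (is.na(s) || !nzchar(s)) integer()
    else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
  df
}
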