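#' Read short reads from FASTA or FASTQ
#'
#' Parses a FASTA or FASTQ file into a [ReadSet-class]. Lowercase bases are
#' uppercased; FASTQ quality strings are parsed (the record structure is
#' validated) but discarded, since the corrector does not use base
#' qualities. Reads containing characters outside \{A,C,G,T,N\} are rejected
#' with an error naming the first offending record: silently masking
#' ambiguity codes would corrupt downstream per-base truth accounting.
#'
#' @param path path to the input file.
#' @param format \code{"auto"} (default; decided by the first non-empty
#'   character, \code{">"} for FASTA and \code{"@"} for FASTQ),
#'   \code{"fasta"} or \code{"fastq"}.
#'
#' @return A [ReadSet-class] with \code{perfect = corrected = FALSE}, records
#'   in file order. An empty file yields an empty ReadSet with a warning.
#' @seealso [writeFastx()]
#' @export
readFastx <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 50L, warn = FALSE)
    head1 <- head1[nzchar(trimws(head1))]
    format <- if (!length(head1)) "fasta"
              else if (startsWith(head1[1L], "@")) "fastq"
              else if (startsWith(head1[1L], ">")) "fasta"
              else stop("cannot determine format of ", path,
                        ": first record starts with neither '>' nor '@'")
  }
  if (file.size(path) == 0L ||
      !length(grep("\\S", readLines(path, n = 10L, warn = FALSE)))) {
    warning("empty input file: ", path)
    return(ReadSet())
  }
  if (format == "fastq") {
    # catch structurally broken files the 4-line parser would tolerate,
    # e.g. a truncated final record
    lines <- readLines(path, warn = FALSE)
    while (length(lines) && !nzchar(lines[length(lines)]))
      lines <- lines[-length(lines)]
    if (length(lines) %% 4L != 0L)
      stop(sprintf("malformed FASTQ in %s: record %d is incomplete",
                   path, length(lines) %/% 4L + 1L))
    bad4 <- which(!startsWith(lines[seq(1L, length(lines), by = 4L)], "@"))
    if (length(bad4))
      stop(sprintf("malformed FASTQ in %s: record %d does not start with '@'",
                   path, bad4[1L]))
  }
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", toupper(format), " in ", path,
                             ": ", conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(ss))
  bad <- grep("^[ACGTN]+$", seqs, invert = TRUE)
  if (length(bad))
    stop(sprintf(
      "record %d ('%s') contains characters outside {A,C,G,T,N}",
      bad[1L], names(ss)[bad[1L]]))
  ReadSet(seqs, ids = names(ss))
}

#' Write a ReadSet as FASTA or FASTQ
#'
#' FASTA output is single-line per record; multi-line FASTA is accepted on
#' input only. FASTQ output assigns the constant placeholder quality
#' \code{"I"} (Phred 40) to every base -- the corrector has no quality
#' model, and a constant quality keeps the file standard-valid.
#'
#' @param reads a [ReadSet-class].
#' @param path output file path.
#' @param format \code{"fasta"} or \code{"fastq"}.
#'
#' @return \code{path}, invisibly.
#' @seealso [readFastx()]
#' @export
writeFastx <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(methods::is(reads, "ReadSet"))
  methods::validObject(reads)
  dss <- methods::as(reads, "DNAStringSet")
  if (format == "fastq") {
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads@seqs)))
    Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  } else {
    w <- if (length(reads)) max(nchar(reads@seqs)) else 80L
    Biostrings::writeXStringSet(dss, path, format = "fasta", width = w)
  }
  invisible(path)
}
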