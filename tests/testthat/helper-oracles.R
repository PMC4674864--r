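# Brute-force oracles, written with plain loops and independent of the
# package's data structures, used to cross-check every stage.

ALPHA <- c("A", "C", "G", "T")

oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- 0L
  for (i in seq_along(x))
    if (x[i] != y[i] || x[i] == "N" || y[i] == "N") d <- d + 1L
  d
}

# all N-free k-mers of a sequence with their 1-based start positions
oracle_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(data.frame(kmer = character(), pos = integer()))
  pos <- seq_len(L - k + 1L)
  km <- substring(s, pos, pos + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  data.frame(kmer = km[keep], pos = pos[keep])
}

# candidate neighbor indices per read by all-pairs shared-substring test
oracle_candidates <- function(seqs, k) {
  n <- length(seqs)
  kms <- lapply(seqs, oracle_kmers, k = k)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- integer()
    for (j in seq_len(n)) {
      if (j == i) next
      if (any(kms[[i]]$kmer %in% kms[[j]]$kmer)) hits <- c(hits, j)
    }
    out[[i]] <- hits
  }
  out
}

# shared anchor pairs between two sequences
oracle_anchors <- function(a, b, k) {
  ka <- oracle_kmers(a, k)
  kb <- oracle_kmers(b, k)
  out <- NULL
  for (i in seq_len(nrow(ka)))
    for (j in seq_len(nrow(kb)))
      if (ka$kmer[i] == kb$kmer[j])
        out <- rbind(out, c(posR = ka$pos[i], posN = kb$pos[j]))
  out
}

# best overlap among anchor-consistent offsets (max length, then fewest
# mismatches, then smallest |offset|)
oracle_best_overlap <- function(a, b, anchors) {
  offs <- sort(unique(as.integer(anchors[, 1] - anchors[, 2])))
  best <- NULL
  for (off in offs) {
    sa <- max(1L, 1L + off)
    ea <- min(nchar(a), off + nchar(b))
    len <- ea - sa + 1L
    if (len < 1L) next
    mm <- oracle_hamming(substr(a, sa, ea), substr(b, sa - off, ea - off))
    if (is.null(best) || len > best$length ||
        (len == best$length && (mm < best$mismatches ||
          (mm == best$mismatches && abs(off) < abs(best$offset)))))
      best <- list(offset = off, length = len, mismatches = mm)
  }
  best
}

# per-base outcome classification over aligned original/corrected/truth
oracle_classify <- function(orig, corr, true) {
  cls <- c(tp = 0, fp = 0, tn = 0, fn = 0, be = 0)
  for (i in seq_along(orig)) {
    o <- strsplit(orig[i], "")[[1]]
    c_ <- strsplit(corr[i], "")[[1]]
    t_ <- strsplit(true[i], "")[[1]]
    for (p in seq_along(o)) {
      if (o[p] != t_[p]) {            # injected error
        if (c_[p] == o[p]) cls["fn"] <- cls["fn"] + 1
        else if (c_[p] == t_[p]) cls["tp"] <- cls["tp"] + 1
        else cls["be"] <- cls["be"] + 1
      } else {                        # originally correct
        if (c_[p] == o[p]) cls["tn"] <- cls["tn"] + 1
        else cls["fp"] <- cls["fp"] + 1
      }
    }
  }
  cls
}

# Independent slow re-implementation of the whole correction procedure:
# per pass, neighbor lists from pass-start sequences, then sequential
# correction with live sequences and live perfect flags.
oracle_correct_all <- function(seqs, k, min_overlap, max_mismatch, w,
                               min_support, passes, cap = 1000) {
  n <- length(seqs)
  perfect <- rep(FALSE, n)
  for (pass in seq_len(passes)) {
    start_seqs <- seqs
    occ <- list()
    for (i in seq_len(n)) {
      km <- oracle_kmers(start_seqs[i], k)
      for (r in seq_len(nrow(km)))
        occ[[km$kmer[r]]] <- rbind(occ[[km$kmer[r]]], c(i, km$pos[r]))
    }
    nbrs <- vector("list", n)
    for (i in seq_len(n)) {
      s <- start_seqs[i]
      offs_by_j <- list()
      km <- oracle_kmers(s, k)
      for (r in seq_len(nrow(km))) {
        b <- occ[[km$kmer[r]]]
        if (is.null(b) || nrow(b) > cap) next
        for (row in seq_len(nrow(b))) {
          j <- b[row, 1]
          if (j == i) next
          key <- as.character(j)
          offs_by_j[[key]] <- union(offs_by_j[[key]], km$pos[r] - b[row, 2])
        }
      }
      keep <- NULL
      for (key in names(offs_by_j)) {
        j <- as.integer(key)
        anchors <- cbind(1 + offs_by_j[[key]], 1)  # offset-encoding anchors
        best <- oracle_best_overlap(s, start_seqs[j], anchors)
        if (!is.null(best) && best$length >= min_overlap &&
            best$mismatches <= max_mismatch)
          keep <- rbind(keep, c(j, best$offset))
      }
      if (!is.null(keep)) keep <- keep[order(keep[, 1]), , drop = FALSE]
      nbrs[[i]] <- keep
    }
    for (i in seq_len(n)) {
      s <- strsplit(seqs[i], "")[[1]]
      L <- length(s)
      votes <- matrix(0, 4, L)
      if (!is.null(nbrs[[i]])) for (row in seq_len(nrow(nbrs[[i]]))) {
        j <- nbrs[[i]][row, 1]
        off <- nbrs[[i]][row, 2]
        wgt <- if (perfect[j]) w else 1
        t_ <- strsplit(seqs[j], "")[[1]]
        sa <- max(1L, 1L + off)
        ea <- min(L, off + length(t_))
        if (ea >= sa) for (p in sa:ea) {
          code <- match(t_[p - off], ALPHA)
          if (!is.na(code)) votes[code, p] <- votes[code, p] + wgt
        }
      }
      ch <- 0L
      any_sup <- FALSE
      for (p in seq_len(L)) {
        col <- votes[, p]
        if (max(col) > 0) any_sup <- TRUE
        best <- which.max(col)
        ic <- match(s[p], ALPHA)
        iw <- if (is.na(ic)) 0 else col[ic]
        if (col[best] >= min_support && col[best] > iw) {
          s[p] <- ALPHA[best]
          ch <- ch + 1L
        }
      }
      seqs[i] <- paste(s, collapse = "")
      perfect[i] <- ch == 0L && any_sup
    }
  }
  list(seqs = seqs, perfect = perfect)
}

digest_file <- function(f) unname(tools::md5sum(f))

# random sequences, optionally with N, for property tests
rand_seq <- function(len, n_prob = 0) {
  ab <- if (n_prob > 0) c(ALPHA, "N") else ALPHA
  pr <- if (n_prob > 0) c(rep((1 - n_prob) / 4, 4), n_prob) else NULL
  paste(sample(ab, len, replace = TRUE, prob = pr), collapse = "")
}

# overlapping reads from a shared random source with substitution noise
rand_related_reads <- function(n, glen, rlen, eps) {
  g <- rand_seq(glen)
  starts <- sample.int(glen - rlen + 1L, n, replace = TRUE)
  seqs <- substring(g, starts, starts + rlen - 1L)
  for (i in seq_len(n)) {
    s <- strsplit(seqs[i], "")[[1]]
    hit <- which(stats::runif(length(s)) < eps)
    for (p in hit) s[p] <- sample(setdiff(ALPHA, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}
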