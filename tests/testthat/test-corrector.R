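test_that("column votes accumulate neighbor weights position by position", {
  # no neighbors: all-zero columns
  rs <- ReadSet(c("ACGT", "ACGT"))
  v0 <- columnVotes(1, data.frame(neighbor = integer(), offset = integer()),
                    rs, ecParams(k = 4, minOverlap = 4))
  expect_true(all(v0 == 0))

  # three identical neighbors at offset 0: every column weight 3 on their base
  rs3 <- ReadSet(rep("ACGT", 4))
  nb <- data.frame(neighbor = 2:4, offset = 0L)
  v3 <- columnVotes(1, nb, rs3, ecParams(k = 4, minOverlap = 4))
  expect_equal(unname(colSums(v3)), rep(3, 4))
  expect_equal(unname(v3["A", 1]), 3)
  expect_equal(unname(v3["T", 4]), 3)

  # a perfect neighbor votes with weight w, the others with 1
  rsw <- ReadSet(c("AAAA", "CCCC", "GGGG", "GGGG"),
                 perfect = c(FALSE, TRUE, FALSE, FALSE),
                 corrected = c(FALSE, TRUE, FALSE, FALSE))
  vw <- columnVotes(1, data.frame(neighbor = 2:4, offset = 0L), rsw,
                    ecParams(k = 4, minOverlap = 4, perfectWeight = 3))
  expect_equal(unname(vw["C", 1]), 3)
  expect_equal(unname(vw["G", 1]), 2)

  # a neighbor contributes only where its overlap covers; N votes for nothing
  rsn <- ReadSet(c("ACGTACGT", "GTNC"))
  vn <- columnVotes(1, data.frame(neighbor = 2L, offset = 2L), rsn,
                    ecParams(k = 2, minOverlap = 2))
  expect_equal(unname(colSums(vn)), c(0, 0, 1, 1, 0, 1, 0, 0))
})

test_that("correctRead applies the consensus rules", {
  p <- ecParams(k = 4, minOverlap = 4, minSupport = 2)
  mkv <- function(...) {
    m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T")))
    for (x in list(...)) m[x[[1]], as.integer(x[[2]])] <- as.numeric(x[[3]])
    m
  }
  # unanimous majority flips the base
  v <- mkv(list("A", 1, 3), list("C", 2, 3), list("G", 3, 3), list("T", 4, 3))
  out <- correctRead("ACGA", v, p)
  expect_equal(out$seq, "ACGT")
  expect_equal(out$nChanged, 1L)
  expect_false(out$perfect)

  # tie with the incumbent keeps the original
  vt <- mkv(list("G", 1, 2), list("T", 1, 2), list("A", 2, 2),
            list("C", 3, 2), list("G", 4, 2))
  out2 <- correctRead("GACG", vt, p)
  expect_equal(out2$seq, "GACG")
  expect_true(out2$perfect)   # support seen, nothing to fix

  # no evidence at all: unchanged and NOT perfect
  out3 <- correctRead("ACGT", matrix(0, 4, 4,
                      dimnames = list(c("A", "C", "G", "T"))), p)
  expect_equal(out3$seq, "ACGT")
  expect_false(out3$perfect)

  # minSupport gates a lone voter even against N
  v1 <- mkv(list("T", 2, 1))
  expect_equal(correctRead("ANGT", v1, p)$seq, "ANGT")
  v2 <- mkv(list("T", 2, 2))
  expect_equal(correctRead("ANGT", v2, p)$seq, "ATGT")
})

test_that("error-free simulated reads are never altered", {
  sim <- simulateReads(genomeLen = 10000, readLen = 60, coverage = 30,
                       eps = 0, seed = 5)
  res <- correctReads(sim$reads, ecParams())
  expect_equal(res$report$basesChanged, 0L)
  expect_equal(readSeqs(res$reads), readSeqs(sim$reads))
  expect_true(all(isCorrected(res$reads)))
  cnt <- classifyCorrections(sim$reads, res$reads, sim$truth)
  expect_equal(unname(correctionMetrics(cnt)["specificity"]), 1)
})

test_that("a single planted error at high local coverage is reverted exactly", {
  set.seed(13)
  g <- randomGenome(300)
  starts <- rep(seq(1, 241, by = 8), each = 2)   # dense tiling, 60-mers
  seqs <- substring(g, starts, starts + 59)
  true1 <- seqs[1]
  bases <- strsplit(seqs[1], "")[[1]]
  bases[30] <- setdiff(c("A", "C", "G", "T"), bases[30])[1]
  seqs[1] <- paste(bases, collapse = "")
  rs <- ReadSet(seqs)
  res <- correctReads(rs, ecParams())
  expect_equal(unname(readSeqs(res$reads))[1], true1)
  expect_equal(res$report$basesChanged, 1L)
  expect_equal(unname(readSeqs(res$reads))[-1], seqs[-1])
})

test_that("empty input and length preservation contracts hold", {
  res <- correctReads(ReadSet(), ecParams())
  expect_equal(length(res$reads), 0L)
  expect_equal(res$report$basesChanged, 0L)

  sim <- simulateReads(genomeLen = 3000, readLen = 55, coverage = 15,
                       eps = 0.03, seed = 19)
  res2 <- correctReads(sim$reads, ecParams())
  expect_equal(nchar(res2$reads), nchar(sim$reads))
})

test_that("a converged read set is a fixed point of another pass", {
  sim <- simulateReads(genomeLen = 8000, readLen = 60, coverage = 30,
                       eps = 0.02, seed = 23)
  p1 <- ecParams(passes = 1)
  cur <- correctReads(sim$reads, ecParams())$reads
  step <- NULL
  for (it in 1:8) {                       # iterate to convergence
    step <- correctReads(cur, p1)
    cur <- step$reads
    if (step$report$basesChanged == 0L) break
  }
  expect_equal(step$report$basesChanged, 0L)
  again <- correctReads(cur, p1)          # converged set is a fixed point
  expect_equal(again$report$basesChanged, 0L)
  expect_equal(readSeqs(again$reads), readSeqs(cur))
})

test_that("the fused correction pass matches an independent reimplementation", {
  set.seed(37)
  for (rep in 1:6) {
    seqs <- rand_related_reads(n = 25, glen = 120, rlen = 30, eps = 0.04)
    p <- ecParams(k = 8, minOverlap = 15, maxMismatch = 2,
                  perfectWeight = 2, passes = 2, minSupport = 2)
    got <- correctReads(ReadSet(seqs), p)
    want <- oracle_correct_all(seqs, k = 8, min_overlap = 15,
                               max_mismatch = 2, w = 2, min_support = 2,
                               passes = 2)
    expect_equal(unname(readSeqs(got$reads)), want$seqs)
    expect_equal(unname(isPerfect(got$reads)), want$perfect)
  }
})

test_that("stagewise module composition agrees with correctReads for one pass", {
  set.seed(41)
  seqs <- rand_related_reads(n = 15, glen = 80, rlen = 24, eps = 0.05)
  rs <- ReadSet(seqs)
  p <- ecParams(k = 7, minOverlap = 12, maxMismatch = 2, passes = 1)
  got <- correctReads(rs, p)

  # hand-composed single pass: index -> candidates -> neighbors -> votes
  cur <- rs
  cs <- candidateNeighbors(buildKmerIndex(cur, p@k), cur, p@bucketCap)
  tn <- trueNeighbors(cs, cur, p)
  seqs2 <- readSeqs(cur)
  perf2 <- isPerfect(cur)
  for (i in seq_along(seqs2)) {
    live <- ReadSet(unname(seqs2), perfect = perf2, corrected = perf2)
    v <- columnVotes(i, neighborsOf(tn, i), live, p)
    out <- correctRead(unname(seqs2[i]), v, p)
    seqs2[i] <- out$seq
    perf2[i] <- out$perfect
  }
  expect_equal(unname(readSeqs(got$reads)), unname(seqs2))
  expect_equal(isPerfect(got$reads), unname(perf2))
})
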