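mk_truth <- function(true_seqs) {
  data.frame(read = sprintf("t%d", seq_along(true_seqs)),
             start = 1L, trueSeq = true_seqs)
}

test_that("per-base outcomes are classified by the five-way truth table", {
  true <- strrep("A", 60)
  orig <- paste0(strrep("A", 20), "C", strrep("A", 20), "G", strrep("A", 18))
  corr <- strrep("A", 60)  # both errors fixed, nothing else touched
  cnt <- classifyCorrections(ReadSet(orig), ReadSet(corr), mk_truth(true))
  expect_equal(evalCounts(cnt),
               c(TP = 2, FP = 0, TN = 58, FN = 0, b_e = 0))

  # an error changed to a third, still-wrong base is b_e, not TP
  cnt2 <- classifyCorrections(ReadSet("ACGT"), ReadSet("AGGT"),
                              mk_truth("ATGT"))
  expect_equal(evalCounts(cnt2), c(TP = 0, FP = 0, TN = 3, FN = 0, b_e = 1))

  # a true base changed to anything is FP; an untouched error is FN
  cnt3 <- classifyCorrections(ReadSet("ACGT"), ReadSet("TCGT"),
                              mk_truth("ACGA"))
  expect_equal(evalCounts(cnt3), c(TP = 0, FP = 1, TN = 2, FN = 1, b_e = 0))

  expect_error(
    classifyCorrections(ReadSet("ACGT"), ReadSet("ACG"), mk_truth("ACGT")),
    "lengths")
})

test_that("random correction masks match the exhaustive per-position oracle", {
  set.seed(47)
  for (rep in 1:100) {
    n <- sample(1:6, 1)
    L <- sample(5:30, 1)
    true <- replicate(n, rand_seq(L))
    orig <- vapply(true, function(s) {
      x <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(L) < 0.15)
      for (p in hit) x[p] <- sample(setdiff(ALPHA, x[p]), 1)
      paste(x, collapse = "")
    }, character(1))
    corr <- vapply(orig, function(s) {      # a random, imperfect "corrector"
      x <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(L) < 0.2)
      for (p in hit) x[p] <- sample(ALPHA, 1)
      paste(x, collapse = "")
    }, character(1))
    got <- evalCounts(classifyCorrections(ReadSet(orig), ReadSet(corr),
                                          mk_truth(unname(true))))
    want <- oracle_classify(unname(orig), unname(corr), unname(true))
    expect_equal(unname(got), unname(want[c("tp", "fp", "tn", "fn", "be")]))
    # conservation: the classes partition errors and clean bases exactly
    nerr <- sum(vapply(seq_len(n), function(i)
      oracle_hamming(orig[i], true[i]), integer(1)))
    expect_equal(got[["TP"]] + got[["FN"]] + got[["b_e"]], nerr)
    expect_equal(got[["TN"]] + got[["FP"]], n * L - nerr)
  }
})

test_that("metric formulas, undefined cases and sign behavior", {
  mkc <- function(tp = 0, fp = 0, tn = 0, fn = 0, be = 0)
    methods::new("EvalCounts", tp = tp, fp = fp, tn = tn, fn = fn, be = be)

  m <- correctionMetrics(mkc(tp = 9, fp = 1, fn = 1, tn = 89))
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["specificity"]), 89 / 90)

  expect_equal(unname(correctionMetrics(mkc(tp = 8, be = 2))["eba"]), 0.2)

  # negative gain when more errors are introduced than removed
  neg <- correctionMetrics(mkc(tp = 2, fp = 5, fn = 0, tn = 10))
  expect_lt(unname(neg["accuracy"]), 0)

  # zero denominators are undefined, not zero
  und <- correctionMetrics(mkc(tn = 10))
  expect_true(is.na(und["sensitivity"]))
  expect_true(is.na(und["eba"]))
  expect_equal(unname(und["specificity"]), 1)

  # rates are scale-free
  a <- correctionMetrics(mkc(tp = 3, fp = 1, tn = 20, fn = 2, be = 1))
  b <- correctionMetrics(mkc(tp = 30, fp = 10, tn = 200, fn = 20, be = 10))
  expect_equal(a, b)

  # accuracy never exceeds sensitivity
  set.seed(59)
  for (rep in 1:50) {
    cc <- mkc(tp = sample(0:20, 1), fp = sample(0:20, 1),
              tn = sample(1:50, 1), fn = sample(0:20, 1), be = sample(0:5, 1))
    mm <- correctionMetrics(cc)
    if (!is.na(mm["sensitivity"]))
      expect_lte(mm[["accuracy"]], mm[["sensitivity"]])
  }
})

test_that("the identity corrector scores as expected", {
  sim <- simulateReads(genomeLen = 500, readLen = 25, coverage = 8,
                       eps = 0.1, seed = 61)
  cnt <- classifyCorrections(sim$reads, sim$reads, sim$truth)
  v <- evalCounts(cnt)
  expect_equal(v[["TP"]], 0)
  expect_equal(v[["FP"]], 0)
  expect_equal(v[["b_e"]], 0)
  m <- correctionMetrics(cnt)
  expect_equal(unname(m["sensitivity"]), 0)
  expect_equal(unname(m["specificity"]), 1)
  expect_equal(cumulativeHamming(sim$reads, sim$truth),
               sum(lengths(sim$truth$errorPos)))
})

test_that("cumulative Hamming distance and mapped fraction", {
  true <- c(strrep("A", 10), strrep("C", 10))
  corr <- c(paste0("T", strrep("A", 9)),            # residual distance 1
            paste0("GGG", strrep("C", 7)))          # residual distance 3
  rs <- ReadSet(corr)
  tr <- mk_truth(true)
  expect_equal(cumulativeHamming(rs, tr), 4)
  expect_equal(mappedFraction(rs, tr, d = 0), 0)
  expect_equal(mappedFraction(rs, tr, d = 1), 0.5)
  expect_equal(mappedFraction(rs, tr, d = 3), 1)
  expect_equal(mappedFraction(rs, tr, d = 10), 1)   # d >= r maps everything

  perfect <- ReadSet(true)
  expect_equal(cumulativeHamming(perfect, tr), 0)
  expect_equal(mappedFraction(perfect, tr, 0), 1)

  # matches a direct count on a random fixture
  set.seed(67)
  true2 <- replicate(20, rand_seq(15))
  corr2 <- vapply(true2, function(s) {
    x <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(15) < 0.2)
    for (p in hit) x[p] <- sample(setdiff(ALPHA, x[p]), 1)
    paste(x, collapse = "")
  }, character(1))
  hd <- vapply(seq_len(20), function(i) oracle_hamming(corr2[i], true2[i]),
               integer(1))
  rs2 <- ReadSet(unname(corr2))
  tr2 <- mk_truth(true2)
  expect_equal(cumulativeHamming(rs2, tr2), sum(hd))
  for (d in 0:4)
    expect_equal(mappedFraction(rs2, tr2, d), mean(hd <= d))
})

test_that("metrics TSV writer emits one complete row", {
  sim <- simulateReads(genomeLen = 400, readLen = 20, coverage = 5,
                       eps = 0.05, seed = 71)
  res <- correctReads(sim$reads, ecParams(k = 8, minOverlap = 10))
  cnt <- classifyCorrections(sim$reads, res$reads, sim$truth)
  f <- tempfile(fileext = ".tsv")
  row <- writeMetrics(cnt, res$reads, sim$truth, f, d = 2)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 1L)
  expect_true(all(c("TP", "FP", "TN", "FN", "b_e", "sensitivity",
                    "specificity", "accuracy", "eba", "chd",
                    "mappedFraction") %in% names(back)))
  expect_equal(back$chd, cumulativeHamming(res$reads, sim$truth))
})
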