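#' False-candidate probability bound
#'
#' Under a uniform random genome, the probability that two unrelated
#' (non-overlapping) reads of length r share at least one k-mer -- and so
#' wrongly become candidate neighbors -- is at most
#' \deqn{r^2 (1/4)^k.}
#' Each read has at most r k-mers, any fixed pair of random k-mers agrees
#' with probability (1/4)^k, and a union bound covers the r^2 pairs; per-base
#' substitution errors leave the 1/4 agreement probability unchanged. The
#' bound motivates choosing k large enough that chance candidacy is
#' negligible (e.g. about 2.3e-6 at r = 50, k = 15). Being a union bound it
#' is vacuous (exceeds 1) for very small k.
#'
#' @param r read length (bases).
#' @param k k-mer length, 1 <= k <= r.
#' @return Upper bound on the probability, in [0, 1] for all practical r, k.
#' @examples
#' falseCandidateBound(50, 15)
#' falseCandidateBound(50, 20)
#' @export
falseCandidateBound <- function(r, k) {
  if (any(k < 1) || any(k > r))
    stop("require 1 <= k <= r")
  r^2 * 0.25^k
}

#' Probability that two k-mers from the same genomic position match
#'
#' Both reads observe the same genomic k-mer through independent per-base
#' substitution noise of rate eps. A single base pair agrees when both
#' copies are unmutated, (1-eps)^2, or both mutated to the same of the
#' three alternatives, eps^2/3; over k independent positions
#' \deqn{p = \left((1-\varepsilon)^2 + \varepsilon^2/3\right)^k.}
#'
#' @param eps per-base substitution error rate in [0, 1].
#' @param k k-mer length (>= 1).
#' @return Probability p in [0, 1].
#' @examples
#' trueKmerMatchProb(0.05, 20)  # 0.1309
#' trueKmerMatchProb(0, 17)     # error-free copies always match
#' @export
trueKmerMatchProb <- function(eps, k) {
  if (any(eps < 0) || any(eps > 1)) stop("eps must lie in [0, 1]")
  if (any(k < 1)) stop("k must be >= 1")
  ((1 - eps)^2 + eps^2 / 3)^k
}

#' Probability that two truly overlapping reads share no k-mer
#'
#' If two reads overlap by w bases, each contributes w - k + 1 k-mers to
#' the overlap. Treating the (w - k + 1)^2 k-mer pairs as independent, the
#' probability that none matches is
#' \deqn{(1-p)^{(w-k+1)^2}}
#' with p from [trueKmerMatchProb()]. Its complement,
#' \code{sharedKmerProb()}, is the chance the pair is discovered through
#' the bucket index at all. The independence assumption is optimistic --
#' overlapping k-mers share bases -- so treat these as design guidance, not
#' exact event probabilities (see the methods vignette). Evaluation is in
#' log space; values near 1e-27 are routine.
#'
#' @param wOlap overlap length w in bases (>= k).
#' @param k k-mer length.
#' @param eps per-base substitution error rate.
#' @return Miss probability (or its complement) in [0, 1].
#' @examples
#' sharedKmerMissProb(40, 20, 0.05)  # ~1.34e-27
#' sharedKmerProb(40, 20, 0.05)
#' @export
sharedKmerMissProb <- function(wOlap, k, eps) {
  if (any(k > wOlap)) stop("require k <= wOlap")
  p <- trueKmerMatchProb(eps, k)
  n <- (wOlap - k + 1)^2
  ifelse(p >= 1, 0, exp(n * log1p(-p)))
}

#' @rdname sharedKmerMissProb
#' @export
sharedKmerProb <- function(wOlap, k, eps) {
  1 - sharedKmerMissProb(wOlap, k, eps)
}

#' Exact tail probability of consensus errors at one column
#'
#' With q neighbors covering a read position, the number of erroneous
#' neighbor bases at that column is Binomial(q, eps). Consensus correction
#' works while errors stay a minority, so the relevant failure quantity is
#' the exact upper tail
#' \deqn{P(X \ge m) = \sum_{i=m}^{q} \binom{q}{i} \varepsilon^i
#'   (1-\varepsilon)^{q-i},}
#' computed by summation of exact binomial terms (no normal
#' approximation); q is at most a few hundred in practice. The expected
#' number of errors, q * eps, is available as [consensusErrorMean()].
#'
#' @param q number of neighbors covering the position.
#' @param eps per-base substitution error rate.
#' @param m tail threshold, 0 <= m <= q.
#' @return P(X >= m).
#' @examples
#' consensusErrorExact(20, 0.05, 10)  # ~1.134e-8
#' consensusErrorMean(20, 0.05)       # 1
#' @export
consensusErrorExact <- function(q, eps, m) {
  if (any(m < 0) || any(m > q)) stop("require 0 <= m <= q")
  stats::pbinom(m - 1, size = q, prob = eps, lower.tail = FALSE)
}

#' @rdname consensusErrorExact
#' @export
consensusErrorMean <- function(q, eps) q * eps

#' Chernoff-style tail estimate for consensus errors
#'
#' A closed-form estimate of the probability that errors reach 0.4q of the
#' q neighbor bases at a column: with slack alpha = 0.4/eps - 1,
#' \deqn{P(e > 0.4 q) \lesssim \exp(-\alpha^2 q \varepsilon / 3).}
#' This is the multiplicative Chernoff form exp(-alpha^2 mu / 3); it is a
#' guaranteed upper bound on the tail only for alpha <= 1 (i.e. eps >=
#' 0.2). For smaller eps the slack exceeds that regime and the expression
#' is a guide rather than a bound -- compare with the exact tail from
#' [consensusErrorExact()] when it matters. Requires eps < 0.4 so that the
#' slack is positive.
#'
#' @param q number of neighbors covering the position.
#' @param eps per-base substitution error rate, 0 < eps < 0.4.
#' @return The Chernoff expression exp(-alpha^2 q eps / 3).
#' @examples
#' consensusErrorChernoff(20, 0.05)  # exp(-49/3)
#' @export
consensusErrorChernoff <- function(q, eps) {
  if (any(eps <= 0) || any(eps >= 0.4))
    stop("require 0 < eps < 0.4 (the slack alpha = 0.4/eps - 1 must be > 0)")
  alpha <- 0.4 / eps - 1
  exp(-alpha^2 * q * eps / 3)
}
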