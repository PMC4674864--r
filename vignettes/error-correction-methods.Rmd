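---
title: "Consensus error correction of short reads: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus error correction of short reads: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecorrect)
```

## The correction model

`ecorrect` corrects substitution errors in short sequencing reads without a
reference genome. The premise is the standard one for overlap-consensus
correctors: reads drawn from the same genomic region agree at almost every
aligned position, so a base where one read disagrees with a strong majority
of its overlapping neighbors is very likely a sequencing error, and the
majority base is very likely the truth.

The algorithm has three stages, repeated for a configurable number of
passes:

1. **Candidate neighbors by k-mer bucket hashing.** Every read is
   decomposed into its overlapping k-mers and each occurrence is placed in
   a bucket keyed by the exact k-mer. Reads sharing at least one bucket
   with a read R form its candidate set C(R). Exact keying realizes a
   collision-free hash: two occurrences meet if and only if their k-mers
   are identical. A read of length r contributes at most r − k + 1
   occurrences; k-mers containing N are skipped, since an ambiguous base
   cannot attest sequence identity.

2. **True neighbors by overlap and Hamming pruning.** Each shared k-mer
   anchors a relative placement of the two reads (neighbor position j
   aligns read position j + offset). Among the anchor-induced offsets the
   *largest* overlap is used; a candidate is kept in T(R) only if that
   overlap spans at least `minOverlap` bases and its Hamming distance is at
   most `maxMismatch`. Because the error model is substitution-only, the
   placement is ungapped and no dynamic-programming alignment is needed.

3. **Weighted per-column consensus.** For every position of R, the bases
   that T(R)'s members place at that column vote: weight 1 from an
   ordinary read, weight w (`perfectWeight`) from a *perfect* read — one
   that a previous correction examined, with neighbor support, and left
   unchanged, so it is very likely error-free. R's own base does not vote;
   it is the incumbent that the winning base must *strictly* outweigh, and
   it must also reach `minSupport` total weight, so a lone neighbor can
   never flip a base. Reads are corrected sequentially in input order with
   in-place updates: later reads are corrected against already-corrected
   earlier reads and their live perfect flags, so both corrected and
   uncorrected reads participate in every consensus. Correction never
   changes a read's length.

### Why the parameters are what they are

The closed-form helpers in the theory module quantify the two failure
modes the parameters trade off.

* **Chance candidacy.** For two unrelated reads of length r under a
  uniform random genome, the probability of sharing any k-mer is at most
  r²(1/4)^k (`falseCandidateBound`). At r = 50 this is ≈ 2.33 × 10⁻⁶ for
  k = 15 and ≈ 2.27 × 10⁻⁹ for k = 20, so for k in the package's 14–17
  operating range candidate sets are essentially free of chance members —
  which keeps the quadratic neighbor-selection step cheap.
* **Missed true neighbors.** Two reads covering the same position carry
  identical k-mers there with probability
  p = ((1−ε)² + ε²/3)^k per aligned pair (`trueKmerMatchProb`; ≈ 0.131 at
  ε = 0.05, k = 20), and treating the (w−k+1)² k-mer pairs in a w-base
  overlap as independent gives a miss probability (1−p)^((w−k+1)²)
  (`sharedKmerMissProb`), astronomically small in realistic regimes.
  Larger k suppresses chance candidacy but raises the miss risk, hence
  the bounded range.
* **Consensus safety.** With q neighbors covering a column, the number of
  erroneous votes is Binomial(q, ε) (`consensusErrorExact`): at q = 20,
  ε = 0.05 the expected number is 1 and the probability of 10 or more is
  ≈ 1.1 × 10⁻⁸, so a majority of honest votes is all but guaranteed at
  usable coverage.

Defaults (`ecParams()`): `k = 15`, `minOverlap = 30` bases (half a typical
60-base read — long enough to be specific, short enough to keep neighbor
yield), `maxMismatch = 2` (a fixed threshold in the 1–3 range; the
expected mismatch count between two 2%-error reads across a 30-base
overlap is ≈ 1.2), `perfectWeight = 2`, `passes = 2`, `minSupport = 2`.
`autoParams()` estimates `k`, `minOverlap` and `maxMismatch` from the
input (k from round(log₄(total bases)) + 1 clamped to 14–17; the Hamming
threshold from the expected mismatch count at the assumed error rate,
clamped to 1–3); explicit arguments always win.

Two passes are the default because the perfect-read weighting only
becomes effective once a first pass has flagged perfect reads: pass 1
corrects mostly with uniform weights and marks the reads it found clean,
pass 2 exploits those flags. The k-mer index and neighbor lists are
rebuilt every pass because correction changes the reads' k-mer content. A
weight schedule that shrinks w as coverage grows is plausible but not
prescribed anywhere we trust; the package keeps w fixed by default and
leaves tuning to the user.

## Numerical and degenerate-input choices

* Coordinates in the R API are 1-based and inclusive, the R/Bioconductor
  convention.
* Hamming distance treats N as matching nothing — including another N —
  so ambiguity never counts as evidence of agreement. In a consensus
  column an N in a neighbor votes for nothing, and an N in the read being
  corrected is an incumbent with weight 0, replaceable by any base that
  reaches `minSupport`.
* Tie-breaks are deterministic everywhere: among equal-length best
  overlaps, fewer mismatches, then smaller |offset|; among equal-weight
  winning bases, alphabetical order; a winner that only ties the
  incumbent's weight never replaces it.
* A read is flagged perfect only if a pass changed nothing *and* at least
  one column had nonzero support; a read with no neighbors is never
  perfect.
* Buckets holding more than `bucketCap` (default 1000) occurrences are
  skipped during candidate generation. Low-complexity repeats otherwise
  produce mega-buckets that make neighbor selection quadratic; the cap is
  an engineering guard, exposed as a parameter.
* Reverse complements are not indexed: the strand model is forward-only,
  and the simulator matches it.
* Miss probabilities are evaluated in log space (`log1p`) before
  exponentiating, so values near 10⁻²⁷ are representable without
  underflow. Binomial tails use exact summation via `pbinom`, never a
  normal approximation.
* The Chernoff-style column-failure estimate exp(−α²qε/3) with
  α = 0.4/ε − 1 is a guaranteed upper bound on P(e > 0.4q) only while
  α ≤ 1, i.e. ε ≥ 0.2; for smaller ε it can undershoot the exact tail
  (at q = 20, ε = 0.05 it gives 8.1 × 10⁻⁸ against an exact
  2.0 × 10⁻⁷). The package therefore treats it as design guidance,
  verifies domination only on ε ∈ [0.2, 0.4), and recommends
  `consensusErrorExact` whenever the number matters.
* The shared-k-mer formulas assume independence among overlapping k-mers,
  which is knowingly optimistic: overlapping k-mers share bases, and the
  (w−k+1)² exponent counts cross-position pairs that essentially never
  match in a random genome. Monte-Carlo checks in the test suite
  therefore validate the aligned-pair probability p exactly (it is a true
  distributional identity) and hold the shared-k-mer closed form only to
  qualitative agreement.

## What the simulator emulates — and what it does not

`simulateReads()` draws `floor(coverage · |G| / readLen)` fixed-length
reads from uniform random start positions of a uniform random (or
user-supplied) genome and substitutes each base independently with
probability ε, uniformly over the three alternatives, recording every
read's source position, uncorrupted sequence and injected error
positions. That truth record is what makes reference-free evaluation
possible: `classifyCorrections()` tallies TP / FP / TN / FN / b\_e per
base, and `correctionMetrics()` derives sensitivity TP/(TP+FN),
specificity TN/(TN+FP), accuracy (gain) (TP−FP)/(TP+FN) and
EBA b\_e/(TP+b\_e), with 0-denominator cases reported as undefined
(`NA`), never as 0. An error changed to a *different wrong* base is
counted once, as b\_e — not as TP, and not as FN, which is reserved for
errors left untouched.

The simulator deliberately omits features of real Illumina data: indels,
position- and context-dependent error rates, quality strings, GC bias,
paired ends, reverse-strand reads and genome repeats beyond what a
uniform random sequence produces. Passing the package's benchmarks
therefore demonstrates correctness of the algorithm under its own model
assumptions — substitution-only errors, uniform coverage, mostly unique
k-mers — not performance on real libraries, where repeat structure and
indels are the dominant hazards.

## Benchmark problem sizes

The test suite exercises two simulated regimes chosen to keep the suite
quick while staying in the regime where consensus correction should
work: a no-harm check on an error-free library (10 kb genome, 60-base
reads, 30× coverage, ε = 0) that must change zero bases, and an
error-recovery benchmark (50 kb genome, 60-base reads, 50× coverage,
ε = 0.02, default parameters) with conservative floors of sensitivity
≥ 0.90, gain ≥ 0.85 and specificity ≥ 0.999. Typical observed values on
the latter are sensitivity ≈ 0.98 with zero false positives. Stage
outputs (candidate sets, best overlaps, Hamming distances, per-base
outcome classification) are additionally verified against brute-force
oracles on hundreds of small random instances, and the fused C++
correction pass against an independent plain-R reimplementation of the
whole procedure.

## Known limitations

* Substitution errors only; an indel in a read shifts every downstream
  base and will defeat ungapped placement.
* No strand handling: libraries containing reverse-complement pairs need
  prior orientation (a `revcomp` indexing mode is a possible extension).
* Highly repetitive genomes violate the near-unique-k-mer assumption;
  the bucket cap keeps the run time bounded but repeats reduce usable
  neighbor evidence and can cause consensus toward a paralog.
* Quality scores are parsed and discarded; FASTQ output carries a
  constant placeholder quality ('I').
* The sequential in-place update makes results dependent on read input
  order (deterministically so); reordering the input can change
  individual corrections.
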