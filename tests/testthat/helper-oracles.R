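# Independent dense matrix exponential: scaling-and-squaring with a
# truncated Taylor series.  Deliberately does not share code with the
# package's propagation paths (Matrix::expm / uniformization) so it can
# act as an oracle for them.
expmOracle <- function(A, order = 30L) {
  A <- as.matrix(A)
  nrm <- max(colSums(abs(A)))
  j <- if (nrm > 0.5) ceiling(log2(nrm)) + 3L else 0L
  As <- A / 2^j
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% As / k
    X <- X + term
  }
  for (s in seq_len(j)) X <- X %*% X
  X
}

# Random small parameter draws for property tests.
randomParams <- function(model = sample(c("SIS", "SIR"), 1L),
                         nMax = 50L) {
  epidemicParams(beta = stats::runif(1L, 0, 1.5),
                 gamma = stats::runif(1L, 0.05, 1),
                 N = sample(2:nMax, 1L), model = model)
}

# Empirical distribution of counts on support 0..N.
empiricalPmf <- function(counts, n) tabulate(counts + 1L, nbins = n + 1L) /
  length(counts)

totalVariation <- function(p, q) 0.5 * sum(abs(p - q))
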