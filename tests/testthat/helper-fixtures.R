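# shared small fixtures, built once per test run

fixSmallPanel <- function(n = 60, m = 120, seed = 101) {
  simGenotypes(n, m, chromLengths = c(chr1 = 5e5, chr2 = 5e5),
               mafRange = c(0.1, 0.5), seed = seed)
}

# independent closed-form restricted likelihood on an h2 grid for a
# single-GRM model, profiled over the total variance (eigen-rotated).
# Used as the REML oracle; shares no code with fitREML.
gridSearchREML <- function(y, G, grid = seq(0, 1, by = 0.01)) {
  n <- length(y)
  eg <- eigen(G, symmetric = TRUE)
  w <- drop(crossprod(eg$vectors, y))
  x <- drop(crossprod(eg$vectors, rep(1, n)))
  d <- eg$values
  ll <- vapply(grid, function(h2) {
    v0 <- h2 * d + (1 - h2)
    if (any(v0 <= 0)) return(-Inf)
    iv <- 1 / v0
    xtvx <- sum(x^2 * iv)
    Pw <- w * iv - x * iv * sum(x * w * iv) / xtvx
    quad <- sum(w * Pw)
    s <- quad / (n - 1)                     # profiled total variance
    -0.5 * (sum(log(v0)) + (n - 1) * log(s) + log(xtvx) +
              (n - 1) + (n - 1) * log(2 * pi))
  }, 0)
  list(grid = grid, loglik = ll, h2 = grid[which.max(ll)],
       maxLoglik = max(ll))
}

# brute-force one-sided Fisher p by full hypergeometric enumeration
enumFisherP <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c            # targets
  nn <- a + b           # negatives
  lo <- max(0, nn - (N - K))
  hi <- min(K, nn)
  probs <- vapply(lo:hi, function(k)
    choose(K, k) * choose(N - K, nn - k) / choose(N, nn), 0)
  sum(probs[(lo:hi) >= a])
}

# circular inter-site distance multiset on the concatenated genome
circularGaps <- function(chrom, pos, layout) {
  cont <- sort(toContinuous(chrom, pos, layout))
  if (length(cont) < 2) return(numeric())
  gaps <- diff(cont)
  sort(c(gaps, layout$total - sum(gaps)))
}
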