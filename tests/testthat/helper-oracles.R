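# Independent brute-force oracles used to freeze expected values.

# Two-sided Mann-Whitney p by full enumeration of all allocations of the
# pooled sample into the two group sizes (no ties assumed).
enumMannWhitneyP <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  uStat <- function(ix) {
    a <- pool[ix]; b <- pool[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  uobs <- uStat(seq_len(n1))
  mid <- n1 * (n - n1) / 2
  allU <- apply(combn(n, n1), 2L, uStat)
  mean(abs(allU - mid) >= abs(uobs - mid) - 1e-12)
}

# PERMANOVA p by enumeration over all distinct two-group splits, with the
# pseudo-F of every split taken from vegan::adonis2 (independent engine).
enumPermanovaP <- function(d, groups) {
  lev <- unique(groups)
  n1 <- sum(groups == lev[1L])
  n <- attr(as.dist(d), "Size")
  fOf <- function(g) {
    df <- data.frame(g = factor(g))
    as.data.frame(vegan::adonis2(as.dist(d) ~ g, data = df,
                                 permutations = 0))$F[1L]
  }
  fobs <- fOf(groups)
  splits <- combn(n, n1)
  fall <- apply(splits, 2L, function(ix) {
    g <- rep(lev[2L], n); g[ix] <- lev[1L]; fOf(g)
  })
  list(F = fobs, p = mean(fall >= fobs - 1e-9))
}

# Shannon index by direct hand summation.
handShannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Bray-Curtis by the definition.
handBray <- function(a, b) sum(abs(a - b)) / sum(a + b)

# NB2 log-likelihood by direct density summation (fixed effects only).
handNbLogLik <- function(y, mu, theta) sum(dnbinom(y, mu = mu, size = theta,
                                                   log = TRUE))
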