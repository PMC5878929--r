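# Independent oracles shared across test files.

# Independent transcription of the Weir & Cockerham (1984) theta estimator,
# written scalar-by-scalar from the published variance components, used as
# an oracle against the package implementation.
wc_theta_oracle <- function(tb, popA, popB) {
  num <- den <- 0
  for (l in seq_along(tb$locus_names)) {
    sub <- list()
    for (p in c(popA, popB)) {
      rows <- tb$population_labels == p & !is.na(tb$allele1[, l])
      sub[[p]] <- cbind(tb$allele1[rows, l], tb$allele2[rows, l])
    }
    if (nrow(sub[[popA]]) < 2 || nrow(sub[[popB]]) < 2) next
    alleles <- unique(c(sub[[popA]], sub[[popB]]))
    r <- 2
    n1 <- nrow(sub[[popA]]); n2 <- nrow(sub[[popB]])
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p1 <- mean(sub[[popA]] == al); p2 <- mean(sub[[popB]] == al)
      h1 <- mean((sub[[popA]][, 1] == al) != (sub[[popA]][, 2] == al))
      h2 <- mean((sub[[popB]][, 1] == al) != (sub[[popB]][, 2] == al))
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# Exact conditional HWE p for a biallelic sample by full enumeration over
# heterozygote counts (probability of the genotype array given allele counts).
hwe_exact_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    haa <- (nA - h) / 2; hbb <- (2 * n - nA - h) / 2
    h * log(2) - lgamma(haa + 1) - lgamma(h + 1) - lgamma(hbb + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hs == nAB)
  sum(p[p <= p[obs] + 1e-12])
}

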