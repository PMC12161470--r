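# In-code fixtures shared across test files.

# small matrix with dimnames
mkMat <- function(vals, genes, samples) {
  matrix(vals, length(genes), length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

# two-layer bundle with three well-separated sample blocks
mkBlockBundle <- function(n = 60L, p = 40L, sep = 6, seed = 42L, k = 3L) {
  set.seed(seed)
  labels <- rep(seq_len(k), length.out = n)
  samples <- sprintf("S%03d", seq_len(n))
  mk <- function(prefix) {
    m <- matrix(rnorm(p * n), p, n,
                dimnames = list(paste0(prefix, seq_len(p)), samples))
    for (s in seq_len(k)) {
      rows <- seq_len(p %/% k) + (s - 1L) * (p %/% k)
      m[rows, labels == s] <- m[rows, labels == s] + sep
    }
    m
  }
  list(bundle = alignBundle(expression = mk("G"), methylation = NULL),
       expr = mk("G"), lnc = mk("L"),
       labels = setNames(labels, samples))
}

# small simulated cohort used by several files (kept modest for speed)
smallSim <- function(seed = 1L, effectSize = 2.0) {
  simulateCohort(simConfig(nSamples = 60L, nGenes = 400L, nLnc = 200L,
                           nProbes = 400L, nMutGenes = 40L,
                           nMarkersPerSubtype = 25L,
                           nLncMarkersPerSubtype = 15L,
                           demethBlockSize = 25L,
                           effectSize = effectSize, seed = seed))
}

writeTsvFixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent double-loop oracle for the ssGSEA running-sum definition
ssgseaOracle <- function(x, members, alpha) {
  N <- length(x)
  rk <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  inSet <- names(x) %in% members
  sumW <- 0
  for (i in seq_len(N)) if (inSet[ord[i]]) sumW <- sumW + rk[ord[i]]^alpha
  nOut <- N - sum(inSet)
  es <- 0; cIn <- 0; cOut <- 0
  for (i in seq_len(N)) {
    g <- ord[i]
    if (inSet[g]) cIn <- cIn + rk[g]^alpha / sumW else cOut <- cOut + 1 / nOut
    es <- es + (cIn - cOut)
  }
  es
}

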