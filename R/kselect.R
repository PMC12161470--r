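# Cluster-number selection: the gap statistic against a uniform reference,
# a partition-stability index (mean pairwise adjusted Rand index across
# algorithm x subsample partitions), and silhouettes on the consensus matrix.

#' Gap statistic for the number of clusters
#'
#' Gap(k) = mean_b log(W*_kb) - log(W_k), with W the total within-cluster
#' dispersion (sum over clusters of within-cluster pairwise squared distances
#' divided by twice the cluster size) under k-means with 10 restarts, and
#' reference datasets drawn uniformly over each feature's observed range.
#' The chosen k is the smallest k with Gap(k) >= Gap(k+1) - s_{k+1}, where
#' s_k is the reference SE inflated by sqrt(1 + 1/nRefs).
#'
#' @param data samples x features matrix (standardize features beforehand if
#'   they are on different scales).
#' @param kRange integer vector of k values starting at 1.
#' @param nRefs number of uniform reference datasets.
#' @param seed RNG seed.
#' @return list with `table` (data.frame: k, gap, se) and `chosenK`.
#' @export
gapStatistic <- function(data, kRange = 1:8, nRefs = 50L, seed = 1L) {
  stopifnot(min(kRange) == 1L)
  kMax <- max(kRange)
  if (kMax >= nrow(data)) stop("k must be smaller than the number of samples")
  gs <- .withSeed(seed,
    cluster::clusGap(data,
                     FUNcluster = function(x, k)
                       list(cluster = kmeans(x, k, nstart = 10,
                                             iter.max = 50)$cluster),
                     K.max = kMax, B = nRefs, d.power = 2,
                     spaceH0 = "original", verbose = FALSE))
  tab <- as.data.frame(gs$Tab)[kRange, ]
  se <- tab$SE.sim
  se[!is.finite(se)] <- 0   # a single reference draw has no spread
  out <- data.frame(k = kRange, gap = tab$gap, se = se)
  chosen <- cluster::maxSE(out$gap, out$se, method = "Tibs2001SEmax")
  list(table = out, chosenK = as.integer(kRange[chosen]))
}

#' Partition-stability index over algorithms and subsamples
#'
#' For every candidate k, each requested algorithm is run `nReps` times on
#' random 80% sample subsets; the index at k is the mean adjusted Rand index
#' over all pairs of resulting partitions, computed on the samples the two
#' partitions share. Values near 1 indicate that the clustering at k is
#' stable across both resampling and methodology.
#'
#' @param bundle a feature-reduced [OmicsBundle-class].
#' @param kRange integer vector of candidate k (each >= 2).
#' @param algorithms algorithm names understood by [consensusEnsemble()];
#'   the default uses the three fastest methods.
#' @param nReps subsamples per algorithm and k.
#' @param subsampleFrac fraction of samples per subsample.
#' @param seed RNG seed.
#' @return named numeric vector, stability index per k.
#' @export
cpi <- function(bundle, kRange = 2:5,
                algorithms = c("snf", "lra", "nemo"), nReps = 10L,
                subsampleFrac = 0.8, seed = 1L) {
  stopifnot(length(algorithms) >= 2L, all(kRange >= 2L))
  ids <- sampleIDs(bundle)
  n <- length(ids)
  m <- max(2L, floor(subsampleFrac * n))
  out <- setNames(numeric(length(kRange)), kRange)
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    parts <- list()
    r <- 0L
    for (alg in algorithms) {
      for (rep in seq_len(nReps)) {
        r <- r + 1L
        sub <- .withSeed(.subSeed(seed, 1000L * ki + r), sort(sample(n, m)))
        sb <- .subsetBundle(bundle, ids[sub])
        lab <- try(.runAlgorithm(alg, sb, k,
                                 seed = .subSeed(seed, 2000L * ki + r)),
                   silent = TRUE)
        if (inherits(lab, "try-error")) {
          message("cpi: ", alg, " failed on a subsample; partition skipped")
          next
        }
        parts[[length(parts) + 1L]] <- lab
      }
    }
    if (length(parts) < 2L) stop("fewer than 2 usable partitions at k = ", k)
    ari <- c()
    for (i in seq_len(length(parts) - 1L)) {
      for (j in seq(i + 1L, length(parts))) {
        shared <- intersect(names(parts[[i]]), names(parts[[j]]))
        if (length(shared) < 2L) next
        ari <- c(ari, mclust::adjustedRandIndex(parts[[i]][shared],
                                                parts[[j]][shared]))
      }
    }
    out[ki] <- mean(ari)
  }
  out
}

#' Silhouette widths on a consensus matrix
#'
#' Standard silhouette on the dissimilarity 1 - consensus. Samples in
#' singleton clusters get width 0; if both a(i) and b(i) are 0 the width is 0.
#'
#' @param consensus symmetric n x n matrix in \[0,1\] with unit diagonal.
#' @param labels cluster labels, length n.
#' @return list with `samples` (named per-sample widths) and `mean`.
#' @export
consensusSilhouette <- function(consensus, labels) {
  stopifnot(nrow(consensus) == ncol(consensus),
            length(labels) == nrow(consensus))
  if (max(abs(consensus - t(consensus))) > 1e-8)
    stop("consensus matrix must be symmetric")
  d <- 1 - consensus
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sum(d[i, labels == own]) / (sizes[own] - 1L)  # excludes d[i,i] = 0
    b <- Inf
    for (cl in setdiff(unique(labels), own))
      b <- min(b, mean(d[i, labels == cl]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(consensus)
  list(samples = s, mean = mean(s))
}

#' Combine stability and gap evidence into one choice of k
#'
#' Min-max normalizes the stability index and the gap values over the shared
#' k >= 2 range, sums them, and returns the k with the largest sum (ties go
#' to the smaller k). A flat criterion contributes zero everywhere, so the
#' other criterion decides alone.
#'
#' @param report a [KSelectionReport-class] (with `cpi` and `gap` filled), or
#'   the list output of [kSelection()].
#' @return integer, the chosen k.
#' @export
chooseK <- function(report) {
  cpiVals <- if (is(report, "KSelectionReport")) report@cpi else report$cpi
  gapTab <- if (is(report, "KSelectionReport")) report@gap else report$gap$table
  ks <- intersect(as.integer(names(cpiVals)), gapTab$k[gapTab$k >= 2L])
  if (!length(ks)) stop("no overlapping k >= 2 between the two criteria")
  norm <- function(v) {
    if (diff(range(v)) == 0) return(rep(0, length(v)))
    (v - min(v)) / (max(v) - min(v))
  }
  score <- norm(cpiVals[as.character(ks)]) +
    norm(gapTab$gap[match(ks, gapTab$k)])
  as.integer(ks[which.max(score)])  # which.max takes the first (smallest) k on ties
}

#' Full cluster-number selection report
#'
#' Runs the gap statistic (k from 1) and the partition-stability index
#' (k from 2) on the reduced bundle, then applies [chooseK()].
#'
#' @param bundle a feature-reduced [OmicsBundle-class].
#' @param kMin,kMax candidate range for the stability index (gap always
#'   starts at 1).
#' @param algorithms,nReps,subsampleFrac passed to [cpi()].
#' @param nRefs passed to [gapStatistic()].
#' @param seed RNG seed.
#' @return a [KSelectionReport-class].
#' @export
kSelection <- function(bundle, kMin = 2L, kMax = 5L,
                       algorithms = c("snf", "lra", "nemo"), nReps = 10L,
                       subsampleFrac = 0.8, nRefs = 50L, seed = 1L) {
  kRange <- seq.int(kMin, kMax)
  data <- .concatContinuous(bundle)
  gap <- gapStatistic(data, kRange = 1:kMax, nRefs = nRefs,
                      seed = .subSeed(seed, 11L))
  cpiVals <- cpi(bundle, kRange = kRange, algorithms = algorithms,
                 nReps = nReps, subsampleFrac = subsampleFrac,
                 seed = .subSeed(seed, 12L))
  rep <- new("KSelectionReport", kRange = as.integer(kRange), cpi = cpiVals,
             gap = gap$table, chosenK = NA_integer_,
             ruleUsed = "argmax of min-max-normalized stability + gap over k >= 2; ties to smaller k")
  rep@chosenK <- chooseK(rep)
  rep
}
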