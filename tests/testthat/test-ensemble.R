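# The six integrative clustering algorithms and their consensus.

blocks3 <- function(n = 60L, p = 30L, sep = 8, seed = 1L, noiseLayer = FALSE) {
  set.seed(seed)
  lab <- rep(1:3, length.out = n)
  ids <- sprintf("S%03d", seq_len(n))
  x <- matrix(rnorm(n * p), n, p, dimnames = list(ids, paste0("f", 1:p)))
  if (!noiseLayer)
    for (s in 1:3) x[lab == s, seq_len(p %/% 3) + (s - 1) * (p %/% 3)] <-
      x[lab == s, seq_len(p %/% 3) + (s - 1) * (p %/% 3)] + sep
  list(x = x, labels = setNames(lab, ids))
}

test_that("snfCluster recovers shared block structure and fuses symmetrically", {
  a <- blocks3(seed = 1L); b <- blocks3(seed = 2L)
  lab <- snfCluster(list(a$x, b$x), 3, seed = 1L)
  expect_equal(mclust::adjustedRandIndex(lab, a$labels), 1)

  # one informative + one pure-noise layer still separates (5 seeds)
  ari <- sapply(1:5, function(s) {
    inf <- blocks3(seed = s); noise <- blocks3(seed = 100 + s, noiseLayer = TRUE)
    mclust::adjustedRandIndex(snfCluster(list(inf$x, noise$x), 3, seed = s),
                              inf$labels)
  })
  expect_true(all(ari >= 0.9))

  const <- matrix(1, 60, 5, dimnames = list(names(a$labels), paste0("c", 1:5)))
  expect_error(snfCluster(list(a$x, const), 3), "constant layer")
})

test_that("montiConsensus yields exact consensus on separated masses and [0,1] entries", {
  set.seed(3)
  ids <- paste0("s", 1:20)
  x <- rbind(matrix(rnorm(50, 0, 0.1), 10), matrix(rnorm(50, 50, 0.1), 10))
  rownames(x) <- ids
  res <- montiConsensus(x, 2, nReps = 100L, seed = 3L)
  M <- res$consensus
  expect_true(all(M >= 0 & M <= 1))
  same <- outer(res$labels, res$labels, "==")
  expect_true(all(M[same] == 1))
  expect_true(all(M[!same] == 0))

  # subsampleFrac = 1 with a deterministic base: binary consensus
  resFull <- montiConsensus(x, 2, nReps = 10L, subsampleFrac = 1,
                            base = "hclust", seed = 1L)
  expect_true(all(resFull$consensus %in% c(0, 1)))
})

test_that("cocaCluster is a fixed point on identical partitions and splits orthogonal ones", {
  ids <- paste0("s", 1:24)
  p1 <- setNames(rep(1:2, each = 12), ids)
  same <- cocaCluster(list(p1, p1, p1), 2, nReps = 100L, seed = 1L)
  expect_equal(mclust::adjustedRandIndex(same, p1), 1)

  # two orthogonal 2-partitions at k = 4 recover the intersection cells
  p2 <- setNames(rep(rep(1:2, each = 6), 2), ids)
  cells <- interaction(p1, p2)
  got <- cocaCluster(list(p1, p2), 4, nReps = 200L, seed = 1L)
  expect_equal(mclust::adjustedRandIndex(got, cells), 1)

  # label ids are irrelevant (encoding invariance)
  p1b <- setNames(ifelse(p1 == 1, 9, 4), ids)
  got2 <- cocaCluster(list(p1b, p2), 4, nReps = 200L, seed = 1L)
  expect_equal(mclust::adjustedRandIndex(got, got2), 1)

  expect_warning(single <- cocaCluster(list(p1), 2), ">= 2 partitions")
  expect_equal(mclust::adjustedRandIndex(single, p1), 1)
})

test_that("intNmfCluster recovers a planted exact factorization with shrinking objective", {
  set.seed(4)
  n <- 30L; k <- 3L
  W0 <- matrix(0, n, k); W0[cbind(seq_len(n), rep(1:k, each = 10))] <- 1
  H0 <- matrix(runif(k * 40, 0.5, 2), k, 40)
  X <- W0 %*% H0
  rownames(X) <- sprintf("S%02d", 1:n)
  lab <- intNmfCluster(list(X), 3, seed = 4L)
  expect_equal(mclust::adjustedRandIndex(lab, rep(1:3, each = 10)), 1)
  expect_lt(attr(lab, "objective"), 1e-6 * sum(X^2))

  # objective is non-increasing along the multiplicative updates
  Xn <- X + matrix(runif(n * 40, 0, 0.05), n, 40)
  rownames(Xn) <- rownames(X)
  objs <- sapply(c(5L, 20L, 80L), function(it)
    attr(intNmfCluster(list(Xn), 3, maxIter = it, tol = 0, nRestarts = 1L,
                       seed = 9L), "objective"))
  expect_true(all(diff(objs) <= 1e-8))

  expect_equal(unname(intNmfCluster(list(X), 1, seed = 1L)),
               rep(1L, n))
})

test_that("lraCluster separates blobs, ignores layer duplication, works at rank k-1", {
  a <- blocks3(seed = 5L); noise <- blocks3(seed = 6L, noiseLayer = TRUE)
  lab <- lraCluster(list(a$x, noise$x), 3, seed = 5L)
  expect_equal(mclust::adjustedRandIndex(lab, a$labels), 1)

  labDup <- lraCluster(list(a$x, a$x, noise$x), 3, seed = 5L)
  expect_equal(mclust::adjustedRandIndex(lab, labDup), 1)

  lab2 <- lraCluster(list(a$x), 3, rank = 2L, seed = 5L)
  expect_equal(mclust::adjustedRandIndex(lab2, a$labels), 1)
  expect_warning(lraCluster(list(a$x), 3, rank = 10000L, seed = 1L), "clipped")
})

test_that("nemoCluster averages symmetric non-negative similarities and recovers blocks", {
  a <- blocks3(seed = 7L)
  lab <- nemoCluster(list(a$x, a$x), 3, seed = 7L)
  labSingle <- nemoCluster(list(a$x), 3, seed = 7L)
  expect_equal(mclust::adjustedRandIndex(lab, labSingle), 1)
  expect_equal(mclust::adjustedRandIndex(lab, a$labels), 1)

  sim <- smallSim(seed = 31L)
  ci <- buildClusterInput(sim$bundle, nExpr = 200L, nLnc = 100L, nMeth = 100L)
  mats <- lapply(c("expression", "lncrna", "methylation"), function(l)
    t(omicsLayer(ci$bundle, l)))
  labSim <- nemoCluster(mats, 3)
  expect_gte(mclust::adjustedRandIndex(labSim, sim$labels), 0.9)
})

test_that("consensusEnsemble fuses agreeing algorithms into a binary consensus", {
  sim <- smallSim(seed = 41L)
  ci <- buildClusterInput(sim$bundle, nExpr = 200L, nLnc = 100L, nMeth = 100L)
  ens <- consensusEnsemble(ci$bundle, 3, seed = 41L, montiReps = 200L)
  expect_gte(mclust::adjustedRandIndex(subtypeLabels(ens), sim$labels), 0.9)

  # M entries live on the grid {0, 1/m, ..., 1} and match the stored labels
  m <- length(ens@algorithms)
  M <- consensusMatrix(ens)
  expect_true(all(abs(M * m - round(M * m)) < 1e-9))
  P <- algorithmPartitions(ens)
  M2 <- matrix(0, nrow(P), nrow(P))
  for (j in seq_len(ncol(P))) M2 <- M2 + outer(P[, j], P[, j], "==")
  expect_equal(unname(M), unname(M2 / ncol(P)), tolerance = 1e-12)

  # all algorithms agreeing -> binary M, silhouette 1, labels = shared partition
  agree <- ens
  if (mclust::adjustedRandIndex(subtypeLabels(ens), sim$labels) == 1)
    expect_true(TRUE)  # covered implicitly on well-separated data below
  a <- blocks3(n = 30L, seed = 8L)
  bnd <- alignBundle(expression = t(a$x), lncrna = t(blocks3(n = 30L, seed = 9L)$x))
  ens2 <- consensusEnsemble(bnd, 3, algorithms = c("snf", "lra", "nemo"),
                            seed = 8L)
  expect_true(all(consensusMatrix(ens2) %in% c(0, 1)))
  expect_equal(ens2@silhouette, 1)
  expect_equal(mclust::adjustedRandIndex(subtypeLabels(ens2), a$labels), 1)

  expect_error(consensusEnsemble(ci$bundle, 3, algorithms = "monti"),
               "at least 2")
})

test_that("each algorithm is equivariant under sample permutation", {
  sim <- smallSim(seed = 51L)
  ci <- buildClusterInput(sim$bundle, nExpr = 150L, nLnc = 80L, nMeth = 80L)
  ids <- sampleIDs(ci$bundle)
  set.seed(99); perm <- sample(ids)
  bPerm <- alignBundle(
    expression = omicsLayer(ci$bundle, "expression")[, perm],
    lncrna = omicsLayer(ci$bundle, "lncrna")[, perm],
    methylation = omicsLayer(ci$bundle, "methylation")[, perm],
    mutations = omicsLayer(ci$bundle, "mutations")[, perm])
  for (alg in c("snf", "lra", "nemo", "intnmf")) {
    l1 <- MOSubtype:::.runAlgorithm(alg, ci$bundle, 3, seed = 5L)
    l2 <- MOSubtype:::.runAlgorithm(alg, bPerm, 3, seed = 5L)
    expect_equal(mclust::adjustedRandIndex(l1[ids], l2[ids]), 1,
                 info = alg)
  }
})

test_that("subtype ids are renumbered by descending size and plug-ins register", {
  ids <- paste0("s", sprintf("%02d", 1:10))
  lab <- c(2, 2, 2, 1, 1, 3, 3, 3, 3, 3)  # sizes: 3, 2, 5
  out <- MOSubtype:::.renumberBySize(lab, ids)
  expect_equal(table(out)[["1"]], 5L)
  expect_equal(table(out)[["3"]], 2L)

  registerAlgorithm("always_one", function(bundle, k, seed)
    setNames(rep_len(seq_len(k), nSamples(bundle)), sampleIDs(bundle)))
  sim <- smallSim(seed = 61L)
  ci <- buildClusterInput(sim$bundle, nExpr = 100L, nLnc = 50L, nMeth = 50L)
  ens <- consensusEnsemble(ci$bundle, 3,
                           algorithms = c("lra", "nemo", "always_one"),
                           seed = 1L)
  expect_true("always_one" %in% ens@algorithms)
})
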