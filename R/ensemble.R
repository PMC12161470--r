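# Integrative clustering ensemble. Six algorithms spanning the main
# methodological families are implemented natively: similarity network
# fusion (kernel fusion), Monti consensus clustering (resampling),
# cluster-of-cluster-assignments (meta-clustering), joint non-negative matrix
# factorization (factorization), low-rank approximation + k-means, and a
# neighborhood-based average-kernel method (spectral). Their partitions are
# averaged into a co-assignment consensus matrix that yields the final
# subtype labels. Additional algorithms can be registered as plug-ins.

# ---- shared helpers ----------------------------------------------------------

.zscoreFeatures <- function(x) {
  # x: samples x features; z-score each feature, dropping constant ones
  mu <- colMeans(x)
  sd <- apply(x, 2L, sd)
  keep <- sd > 0
  sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd[keep], "/")
}

.continuousLayers <- function(bundle, zscore = TRUE) {
  # list of samples x features matrices for the continuous layers
  out <- list()
  for (nm in c("expression", "lncrna", "methylation")) {
    m <- omicsLayer(bundle, nm)
    if (is.null(m)) next
    x <- t(m)
    out[[nm]] <- if (zscore) .zscoreFeatures(x) else x
  }
  if (!length(out)) stop("bundle has no continuous layers")
  out
}

.concatContinuous <- function(bundle) do.call(cbind, .continuousLayers(bundle))

.subsetBundle <- function(bundle, ids) {
  sub <- function(m) if (is.null(m)) NULL else m[, ids, drop = FALSE]
  cl <- clinicalTable(bundle)
  if (!is.null(cl)) { cl <- cl[match(ids, cl$sample), , drop = FALSE]; rownames(cl) <- NULL }
  sg <- segmentTable(bundle)
  if (!is.null(sg)) sg <- sg[sg$sample %in% ids, , drop = FALSE]
  new("OmicsBundle", expression = sub(omicsLayer(bundle, "expression")),
      lncrna = sub(omicsLayer(bundle, "lncrna")),
      methylation = sub(omicsLayer(bundle, "methylation")),
      mutations = sub(omicsLayer(bundle, "mutations")),
      segments = sg, clinical = cl, scaleTag = bundle@scaleTag)
}

.euclid <- function(x) as.matrix(dist(x))

.affinityMatrix <- function(d, K = 20L, alpha = 0.5) {
  # scaled exponential kernel with local scaling (similarity-network style):
  # eps_ij = (mean distance of i to its K nearest neighbors + same for j +
  # d_ij) / 3; W_ij = exp(-d_ij^2 / (2 (alpha eps_ij)^2))
  n <- nrow(d)
  K <- min(K, n - 1L)
  knnMean <- vapply(seq_len(n), function(i) {
    di <- sort(d[i, -i])[seq_len(K)]
    mean(di)
  }, 1)
  eps <- (outer(knnMean, knnMean, "+") + d) / 3
  eps[eps <= .Machine$double.eps] <- .Machine$double.eps
  W <- exp(-d^2 / (2 * (alpha * eps)^2))
  (W + t(W)) / 2
}

.knnSparsify <- function(W, K) {
  # row-normalized kernel restricted to each row's K nearest neighbors
  n <- nrow(W)
  K <- min(K, n - 1L)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(W[i, -i], decreasing = TRUE)[seq_len(K)]
    nb <- seq_len(n)[-i][nb]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

.fullNormalize <- function(W) {
  # P_ij = W_ij / (2 sum_{k != i} W_ik) off-diagonal, 1/2 on the diagonal
  n <- nrow(W)
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

#' Spectral clustering of a similarity matrix
#'
#' Symmetric normalized Laplacian; the k eigenvectors of smallest eigenvalue
#' are row-normalized and clustered by k-means with 10 restarts.
#'
#' @param W symmetric non-negative similarity matrix.
#' @param k number of clusters.
#' @param seed RNG seed for the k-means restarts.
#' @return integer labels named by the rownames of `W`.
#' @export
spectralCluster <- function(W, k, seed = 1L) {
  stopifnot(nrow(W) == ncol(W), k >= 1L)
  if (k == 1L) return(setNames(rep(1L, nrow(W)), rownames(W)))
  dg <- rowSums(W)
  dg[dg <= 0] <- .Machine$double.eps
  Dm <- 1 / sqrt(dg)
  A <- t(W * Dm) * Dm            # D^{-1/2} W D^{-1/2}
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]  # largest eigenvalues of A =
  nrm <- sqrt(rowSums(U^2))                    # smallest of L = I - A
  nrm[nrm == 0] <- 1
  U <- U / nrm
  km <- .withSeed(seed, kmeans(U, k, nstart = 10, iter.max = 100))
  setNames(as.integer(km$cluster), rownames(W))
}

# ---- algorithms --------------------------------------------------------------

#' Similarity network fusion clustering
#'
#' Builds a locally scaled exponential-kernel affinity per continuous layer,
#' cross-diffuses the full kernels through kNN-sparsified kernels for `tIter`
#' rounds, averages the fused networks, and spectrally clusters the result.
#'
#' @param matrices list of samples x features matrices (>= 2 layers).
#' @param k number of clusters.
#' @param nNeighbors kNN size of the sparse kernels.
#' @param alpha kernel bandwidth multiplier.
#' @param tIter diffusion iterations.
#' @param seed RNG seed (k-means restarts).
#' @return integer labels named by sample.
#' @export
snfCluster <- function(matrices, k, nNeighbors = 20L, alpha = 0.5,
                       tIter = 20L, seed = 1L) {
  stopifnot(length(matrices) >= 2L)
  n <- nrow(matrices[[1L]])
  if (nNeighbors >= n) nNeighbors <- n - 1L
  ids <- rownames(matrices[[1L]])
  Ws <- lapply(matrices, function(x) {
    d <- .euclid(x)
    if (max(d) == 0) stop("constant layer: all pairwise distances are zero")
    .affinityMatrix(d, K = nNeighbors, alpha = alpha)
  })
  Ps <- lapply(Ws, .fullNormalize)
  Ss <- lapply(Ws, .knnSparsify, K = nNeighbors)
  m <- length(Ps)
  for (it in seq_len(tIter)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      avg <- Reduce(`+`, Ps[-v]) / (m - 1L)
      P <- Ss[[v]] %*% avg %*% t(Ss[[v]])
      Pnew[[v]] <- .fullNormalize((P + t(P)) / 2)
    }
    Ps <- Pnew
  }
  fused <- Reduce(`+`, Ps) / m
  fused <- (fused + t(fused)) / 2
  rownames(fused) <- colnames(fused) <- ids
  spectralCluster(fused, k, seed = seed)
}

#' Monti consensus clustering
#'
#' Repeated subsampling of the samples, base clustering of each subsample,
#' and accumulation of co-clustering (connectivity) and co-selection
#' (indicator) counts; the consensus matrix is their elementwise ratio and
#' final labels come from average-linkage hierarchical clustering of
#' 1 - consensus.
#'
#' @param x samples x features matrix, or a `dist` object / square distance
#'   matrix (then only `base = "hclust"` applies).
#' @param k number of clusters.
#' @param nReps number of subsampling repetitions.
#' @param subsampleFrac fraction of samples drawn per repetition.
#' @param base base clusterer: "kmeans" or "hclust" (average linkage).
#' @param seed RNG seed.
#' @return list with `labels` (named integer) and `consensus` (n x n matrix).
#' @export
montiConsensus <- function(x, k, nReps = 500L, subsampleFrac = 0.8,
                           base = c("kmeans", "hclust"), seed = 1L) {
  base <- match.arg(base)
  stopifnot(subsampleFrac > 0, subsampleFrac <= 1)
  isDist <- inherits(x, "dist") || (is.matrix(x) && isSymmetric(unname(x)) &&
                                      all(diag(as.matrix(x)) == 0))
  D <- if (isDist) as.matrix(x) else NULL
  if (isDist && base == "kmeans") base <- "hclust"
  n <- if (isDist) nrow(D) else nrow(x)
  ids <- if (isDist) rownames(D) else rownames(x)
  m <- max(2L, floor(subsampleFrac * n))
  conn <- matrix(0, n, n)
  indic <- matrix(0, n, n)
  .withSeed(seed, {
    for (r in seq_len(nReps)) {
      sub <- if (m == n) seq_len(n) else sort(sample(n, m))
      lab <- if (base == "kmeans") {
        kmeans(x[sub, , drop = FALSE], k, nstart = 1, iter.max = 50)$cluster
      } else {
        dSub <- if (isDist) as.dist(D[sub, sub]) else dist(x[sub, , drop = FALSE])
        cutree(hclust(dSub, method = "average"), k)
      }
      same <- outer(lab, lab, "==") * 1
      conn[sub, sub] <- conn[sub, sub] + same
      indic[sub, sub] <- indic[sub, sub] + 1
    }
  })
  never <- indic == 0
  if (any(never & row(indic) != col(indic)))
    warning("some sample pairs were never co-drawn; their consensus is set to 0")
  M <- ifelse(indic > 0, conn / pmax(indic, 1), 0)
  diag(M) <- 1
  M <- (M + t(M)) / 2
  rownames(M) <- colnames(M) <- ids
  lab <- cutree(hclust(as.dist(1 - M), method = "average"), k)
  list(labels = setNames(as.integer(lab), ids), consensus = M)
}

#' Cluster-of-cluster-assignments (COCA)
#'
#' One-hot encodes every input partition into a binary sample x cluster
#' matrix and runs [montiConsensus()] on it at the requested k.
#'
#' @param partitions list of (named) label vectors over the same samples.
#' @param k number of clusters.
#' @param nReps,seed passed to [montiConsensus()].
#' @return integer labels named by sample.
#' @export
cocaCluster <- function(partitions, k, nReps = 500L, seed = 1L) {
  if (length(partitions) < 2L) {
    warning("COCA needs >= 2 partitions; returning the single input unchanged")
    p <- partitions[[1L]]
    return(setNames(as.integer(factor(p)), names(p)))
  }
  ids <- names(partitions[[1L]])
  oneHot <- do.call(cbind, lapply(seq_along(partitions), function(i) {
    p <- factor(partitions[[i]][ids])
    m <- matrix(0L, length(ids), nlevels(p))
    m[cbind(seq_along(ids), as.integer(p))] <- 1L
    m
  }))
  rownames(oneHot) <- ids
  montiConsensus(oneHot, k, nReps = nReps, base = "kmeans", seed = seed)$labels
}

#' Joint non-negative matrix factorization clustering
#'
#' Minimizes sum_d w_d ||X_d - W H_d||_F^2 with a shared non-negative sample
#' factor W (samples x k) and per-layer loadings H_d, by multiplicative
#' updates; w_d = 1 / ||X_d||_F^2 balances the layers. Each layer is shifted
#' per feature to be non-negative. Labels are the argmax column of W from the
#' best of `nRestarts` random restarts.
#'
#' @param matrices list of samples x features matrices.
#' @param k number of clusters.
#' @param maxIter maximum multiplicative updates per restart.
#' @param tol relative objective change declaring convergence.
#' @param nRestarts random restarts; the lowest-objective fit is kept.
#' @param seed RNG seed.
#' @return integer labels named by sample, with attributes `objective` (best
#'   final value) and `converged`.
#' @export
intNmfCluster <- function(matrices, k, maxIter = 500L, tol = 1e-6,
                          nRestarts = 10L, seed = 1L) {
  Xs <- lapply(matrices, function(x) {
    x <- sweep(x, 2L, pmin(apply(x, 2L, min), 0))  # shift features >= 0
    x
  })
  n <- nrow(Xs[[1L]])
  ids <- rownames(Xs[[1L]])
  if (k == 1L) return(setNames(rep(1L, n), ids))
  w <- vapply(Xs, function(x) 1 / max(sum(x^2), .Machine$double.eps), 1)
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(nRestarts)) {
    res <- .withSeed(.subSeed(seed, 300L + r), {
      W <- matrix(runif(n * k, 0.1, 1), n, k)
      Hs <- lapply(Xs, function(x) matrix(runif(k * ncol(x), 0.1, 1), k, ncol(x)))
      obj <- Inf
      conv <- FALSE
      for (it in seq_len(maxIter)) {
        num <- matrix(0, n, k); den <- matrix(0, n, k)
        for (d in seq_along(Xs)) {
          num <- num + w[d] * (Xs[[d]] %*% t(Hs[[d]]))
          den <- den + w[d] * (W %*% (Hs[[d]] %*% t(Hs[[d]])))
        }
        W <- W * num / (den + eps)
        WtW <- crossprod(W)
        for (d in seq_along(Xs))
          Hs[[d]] <- Hs[[d]] * crossprod(W, Xs[[d]]) / (WtW %*% Hs[[d]] + eps)
        newObj <- sum(vapply(seq_along(Xs), function(d)
          w[d] * sum((Xs[[d]] - W %*% Hs[[d]])^2), 1))
        if (is.finite(obj) && abs(obj - newObj) <= tol * max(obj, eps)) {
          obj <- newObj; conv <- TRUE; break
        }
        obj <- newObj
      }
      list(W = W, objective = obj, converged = conv)
    })
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (!best$converged)
    message("intNmfCluster: best restart stopped at maxIter without converging")
  lab <- max.col(best$W, ties.method = "first")
  structure(setNames(as.integer(lab), ids),
            objective = best$objective, converged = best$converged)
}

#' Low-rank approximation clustering
#'
#' Z-scores every feature, concatenates the layers, projects the samples onto
#' the top singular components, and k-means-clusters the scores.
#'
#' @param matrices list of samples x features matrices.
#' @param k number of clusters.
#' @param rank number of singular components (clipped if too large).
#' @param seed RNG seed.
#' @return integer labels named by sample.
#' @export
lraCluster <- function(matrices, k, rank = 10L, seed = 1L) {
  X <- do.call(cbind, lapply(matrices, .zscoreFeatures))
  maxRank <- min(dim(X))
  if (rank > maxRank) {
    warning("rank clipped from ", rank, " to ", maxRank)
    rank <- maxRank
  }
  sv <- svd(X, nu = rank, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(rank)], rank)
  km <- .withSeed(seed, kmeans(scores, k, nstart = 10, iter.max = 100))
  setNames(as.integer(km$cluster), rownames(matrices[[1L]]))
}

#' Neighborhood-based multi-omics clustering
#'
#' Per layer, a locally scaled kernel is reduced to each sample's
#' `nNeighbors` nearest neighbors and row-normalized into a relative
#' similarity; layer matrices are averaged and spectrally clustered.
#'
#' @param matrices list of samples x features matrices.
#' @param k number of clusters.
#' @param nNeighbors neighborhood size (clipped to n - 1).
#' @param seed RNG seed.
#' @return integer labels named by sample.
#' @export
nemoCluster <- function(matrices, k, nNeighbors = 20L, seed = 1L) {
  stopifnot(length(matrices) >= 1L)
  n <- nrow(matrices[[1L]])
  if (nNeighbors >= n) nNeighbors <- n - 1L
  ids <- rownames(matrices[[1L]])
  Ss <- lapply(matrices, function(x) {
    W <- .affinityMatrix(.euclid(x), K = nNeighbors)
    S <- .knnSparsify(W, nNeighbors)
    (S + t(S)) / 2
  })
  A <- Reduce(`+`, Ss) / length(Ss)
  rownames(A) <- colnames(A) <- ids
  spectralCluster(A, k, seed = seed)
}

# ---- ensemble ----------------------------------------------------------------

.multiOmicsDist <- function(bundle) {
  # average of per-layer distances: normalized Euclidean on z-scored
  # continuous layers, Jaccard on the binary mutation layer
  ds <- lapply(.continuousLayers(bundle), function(x) {
    d <- .euclid(x)
    d / max(d, .Machine$double.eps)
  })
  mut <- omicsLayer(bundle, "mutations")
  if (!is.null(mut) && nrow(mut) > 0L) {
    dj <- as.matrix(dist(t(mut), method = "binary"))
    dj[is.na(dj)] <- 0
    ds$mutations <- dj
  }
  Reduce(`+`, ds) / length(ds)
}

.algorithmRegistry <- new.env(parent = emptyenv())

#' Register a plug-in clustering algorithm for the ensemble
#'
#' @param name algorithm name (used in the `algorithms` argument of
#'   [consensusEnsemble()]).
#' @param fun function(bundle, k, seed) returning integer labels named by
#'   sample.
#' @return invisibly, `name`.
#' @export
registerAlgorithm <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .algorithmRegistry)
  invisible(name)
}

.runAlgorithm <- function(alg, bundle, k, seed, montiReps = 500L) {
  cont <- .continuousLayers(bundle)
  switch(alg,
    snf = snfCluster(cont, k, seed = seed),
    monti = montiConsensus(as.dist(.multiOmicsDist(bundle)), k,
                           nReps = montiReps, base = "hclust",
                           seed = seed)$labels,
    coca = {
      parts <- lapply(seq_along(cont), function(i)
        .withSeed(.subSeed(seed, 40L + i),
                  setNames(kmeans(cont[[i]], k, nstart = 10,
                                  iter.max = 100)$cluster,
                           rownames(cont[[i]]))))
      mut <- omicsLayer(bundle, "mutations")
      if (!is.null(mut) && nrow(mut) > 1L) {
        dj <- dist(t(mut), method = "binary")
        dj[is.na(dj)] <- 0
        parts[[length(parts) + 1L]] <-
          cutree(hclust(dj, method = "average"), k)
      }
      cocaCluster(parts, k, nReps = montiReps, seed = .subSeed(seed, 50L))
    },
    intnmf = {
      mats <- .continuousLayers(bundle, zscore = TRUE)
      mut <- omicsLayer(bundle, "mutations")
      if (!is.null(mut) && nrow(mut) > 0L) mats$mutations <- t(mut)
      as.integer(intNmfCluster(mats, k, seed = seed)) |>
        setNames(sampleIDs(bundle))
    },
    lra = lraCluster(.continuousLayers(bundle, zscore = FALSE), k, seed = seed),
    nemo = nemoCluster(cont, k, seed = seed),
    {
      if (!exists(alg, envir = .algorithmRegistry))
        stop("unknown algorithm: ", alg)
      get(alg, envir = .algorithmRegistry)(bundle, k, seed)
    })
}

#' Consensus ensemble of integrative clustering algorithms
#'
#' Runs every requested algorithm on the bundle, forms the consensus matrix
#' M (entry ij = fraction of successful algorithms co-assigning samples i and
#' j), cuts average-linkage hierarchical clustering of 1 - M at k, renumbers
#' the subtypes 1..k by descending size (ties by smallest member sample id),
#' and attaches the consensus silhouette.
#'
#' Continuous layers feed all algorithms; the binary mutation layer is used
#' only where it is meaningful (Jaccard distance in "monti" and the COCA
#' input partitions, non-negative passthrough in "intnmf") and excluded from
#' z-score-based methods.
#'
#' @param bundle a feature-reduced [OmicsBundle-class].
#' @param k number of subtypes.
#' @param algorithms subset of snf, monti, coca, intnmf, lra, nemo, plus any
#'   name registered via [registerAlgorithm()].
#' @param seed master seed; each algorithm draws a derived substream.
#' @param montiReps subsampling repetitions for the resampling-based members.
#' @return a [PartitionEnsemble-class].
#' @export
consensusEnsemble <- function(bundle, k,
                              algorithms = c("snf", "monti", "coca",
                                             "intnmf", "lra", "nemo"),
                              seed = 1L, montiReps = 500L) {
  stopifnot(is(bundle, "OmicsBundle"), k >= 2L)
  if (length(algorithms) < 2L) stop("the ensemble needs at least 2 algorithms")
  ids <- sampleIDs(bundle)
  n <- length(ids)
  parts <- list()
  for (i in seq_along(algorithms)) {
    alg <- algorithms[i]
    lab <- try(.runAlgorithm(alg, bundle, k, seed = .subSeed(seed, i),
                             montiReps = montiReps), silent = TRUE)
    if (inherits(lab, "try-error")) {
      warning("algorithm ", alg, " failed and was excluded: ",
              conditionMessage(attr(lab, "condition")))
      next
    }
    parts[[alg]] <- as.integer(lab[ids])
  }
  if (length(parts) < 2L) stop("fewer than 2 algorithms succeeded")
  P <- do.call(cbind, parts)
  rownames(P) <- ids
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(ncol(P))) M <- M + outer(P[, j], P[, j], "==")
  M <- M / ncol(P)
  lab <- cutree(hclust(as.dist(1 - M), method = "average"), k)
  lab <- .renumberBySize(lab, ids)
  sil <- consensusSilhouette(M, lab)
  new("PartitionEnsemble", algorithms = colnames(P), partitions = P,
      consensus = M, labels = setNames(as.integer(lab), ids), k = as.integer(k),
      silhouette = sil$mean, silhouetteSamples = sil$samples)
}

.renumberBySize <- function(lab, ids) {
  sizes <- table(lab)
  firstMember <- vapply(names(sizes), function(cl) min(ids[lab == cl]), "")
  ord <- order(-as.integer(sizes), firstMember)
  map <- setNames(seq_along(ord), names(sizes)[ord])
  as.integer(map[as.character(lab)])
}
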